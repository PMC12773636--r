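# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Multiplicative Gaussian noise with coefficient of variation cv, clamped at 0
# (HPLC-style error scales with signal).
.noisy <- function(x, cv) {
  if (cv <= 0) return(x)
  pmax(0, x * (1 + stats::rnorm(length(x), 0, cv)))
}

#' Simulate a replicated batch growth course
#'
#' Generates the data shape of a batch fermentation: exponential OD growth
#' capped at a plateau, \eqn{OD(t) = \min(od_0 e^{\mu t}, od_{max})}, with
#' growth-associated substrate consumption and product formation
#' (Luedeking-Piret with zero non-growth term): consumption is proportional
#' to the OD increment and scaled so the substrate is exhausted exactly when
#' the OD plateaus. Products follow their molar yields; a negative yield marks
#' a co-substrate (e.g. CO2) that is consumed rather than formed, and its
#' channel starts at the stoichiometrically required level. Per-replicate
#' multiplicative Gaussian noise of coefficient of variation \code{noise_cv}
#' is applied; output is deterministic under a fixed seed.
#'
#' @param mu Specific growth rate, per hour.
#' @param od0 Initial OD600.
#' @param od_max Plateau OD600.
#' @param substrate0 Initial substrate concentration, mM.
#' @param yields Named numeric vector, mol product per mol substrate.
#' @param substrate Substrate channel name (registered compound).
#' @param time Time grid in hours.
#' @param noise_cv Multiplicative noise CV (0 = noise-free).
#' @param replicate_count Number of replicates.
#' @param seed Integer seed (NULL = use current RNG stream).
#' @param condition Condition label.
#' @return A [timecourse()] object.
#' @examples
#' tc <- simulate_growth_course(mu = 0.69, yields = c(acetate = 0.97),
#'                              noise_cv = 0, seed = 1)
#' @export
simulate_growth_course <- function(mu, od0 = 0.25, od_max = 5.05,
                                   substrate0 = 20,
                                   yields = c(acetate = 0.97, succinate = 0.42,
                                              lactate = 0.15, formate = 0.15,
                                              h2 = 0.17),
                                   substrate = "glucose",
                                   time = seq(0, 12, by = 0.5),
                                   noise_cv = 0.05, replicate_count = 3L,
                                   seed = NULL, condition = substrate) {
  stopifnot(mu >= 0, od0 > 0, od_max > od0, substrate0 > 0, noise_cv >= 0)
  with_seed(seed, {
    od <- pmin(od0 * exp(mu * time), od_max)
    frac <- (od - od0) / (od_max - od0)     # fraction of substrate consumed
    chans <- list(od600 = od, sub = substrate0 * (1 - frac))
    names(chans)[2] <- substrate
    for (p in names(yields)) {
      y <- yields[[p]]
      chans[[p]] <- if (y >= 0) y * substrate0 * frac
                    else abs(y) * substrate0 * (1 - frac)
    }
    chans <- lapply(chans, function(x) {
      vapply(seq_len(replicate_count), function(j) .noisy(x, noise_cv),
             numeric(length(x)))
    })
    timecourse(time, chans, condition = condition)
  })
}

#' Simulate a resting-cell fermentation course
#'
#' Non-growing washed-cell suspensions: the substrate is consumed at a
#' constant rate until exhaustion at the end of the time grid, and products
#' accumulate at their molar yields. The transient-intermediate mode makes
#' formate rise piecewise-linearly to a peak and then fall to its terminal
#' value (its endpoint yield), emulating formate that is produced early and
#' later reconsumed through the Wood-Ljungdahl pathway. A negative yield
#' (e.g. \code{co}) marks a co-substrate consumed in ratio to the primary
#' substrate.
#'
#' @param substrate0 Initial substrate, mM.
#' @param yields Named numeric vector of endpoint yields (mol/mol substrate).
#' @param substrate Substrate channel name.
#' @param time Time grid, hours.
#' @param formate_transient \code{NULL}, or \code{list(peak = mM, t_peak =
#'   hours)} describing the transient formate maximum.
#' @param noise_cv,replicate_count,seed,condition As in
#'   [simulate_growth_course()].
#' @return A [timecourse()] object.
#' @export
simulate_resting_cells <- function(substrate0 = 10,
                                   yields = c(acetate = 1.12, succinate = 0.83,
                                              lactate = 0.03, formate = 0.43,
                                              h2 = 0.41),
                                   substrate = "glucose",
                                   time = seq(0, 10, by = 1),
                                   formate_transient = NULL,
                                   noise_cv = 0, replicate_count = 2L,
                                   seed = NULL,
                                   condition = paste0("resting:", substrate)) {
  stopifnot(substrate0 > 0, noise_cv >= 0)
  with_seed(seed, {
    frac <- (time - time[1]) / (time[length(time)] - time[1])
    chans <- list(sub = substrate0 * (1 - frac))
    names(chans) <- substrate
    for (p in names(yields)) {
      y <- yields[[p]]
      chans[[p]] <- if (y >= 0) y * substrate0 * frac
                    else abs(y) * substrate0 * (1 - frac)
    }
    if (!is.null(formate_transient)) {
      peak <- formate_transient$peak
      t_peak <- formate_transient$t_peak
      terminal <- if ("formate" %in% names(yields)) {
        yields[["formate"]] * substrate0
      } else 0
      if (terminal < 0) stop("negative terminal formate", call. = FALSE)
      if (peak < terminal) stop("transient peak below terminal formate",
                                call. = FALSE)
      up <- time <= t_peak
      f <- numeric(length(time))
      f[up] <- peak * (time[up] - time[1]) / (t_peak - time[1])
      f[!up] <- peak + (terminal - peak) * (time[!up] - t_peak) /
        (time[length(time)] - t_peak)
      chans[["formate"]] <- f
    }
    chans <- lapply(chans, function(x) {
      vapply(seq_len(replicate_count), function(j) .noisy(x, noise_cv),
             numeric(length(x)))
    })
    timecourse(time, chans, condition = condition)
  })
}

#' Simulate a spectrophotometric assay trace
#'
#' Generates the absorbance trace an enzyme of known specific activity would
#' produce: a linear segment at the implied Beer-Lambert slope, an optional
#' plateau once the monitored substrate pool is exhausted, and additive
#' Gaussian noise. \code{specific_activity_from_trace()} on a noise-free
#' trace recovers \code{rate} exactly (inverse pair).
#'
#' @param rate Specific activity to emulate, mU/mg.
#' @param protein mg protein per mL cuvette.
#' @param extinction,path_length,chromophores_per_turnover Optical context,
#'   as in [assay_trace()].
#' @param a0 Starting absorbance.
#' @param direction \code{"decrease"} (chromophore consumed, e.g. NADH
#'   oxidation) or \code{"increase"}.
#' @param substrate_mM Monitored-pool size; the trace plateaus once this much
#'   has been converted (NULL = no plateau).
#' @param time Minutes.
#' @param noise_sd Additive absorbance noise SD.
#' @param seed Integer seed.
#' @return An [assay_trace()] object.
#' @examples
#' tr <- simulate_assay_trace(50, protein = 1, noise_sd = 0)
#' specific_activity_from_trace(tr)$value  # 50
#' @export
simulate_assay_trace <- function(rate, protein = 1, extinction = 6.22,
                                 path_length = 0.2,
                                 chromophores_per_turnover = 1, a0 = 1,
                                 direction = c("decrease", "increase"),
                                 substrate_mM = NULL,
                                 time = seq(0, 5, by = 0.25), noise_sd = 0,
                                 seed = NULL) {
  stopifnot(rate >= 0, protein > 0)
  direction <- match.arg(direction)
  with_seed(seed, {
    rate_mM <- rate * protein * chromophores_per_turnover / 1000
    conc <- rate_mM * (time - time[1])
    if (!is.null(substrate_mM)) conc <- pmin(conc, substrate_mM)
    da <- conc * extinction * path_length
    a <- if (direction == "decrease") a0 - da else a0 + da
    if (noise_sd > 0) a <- a + stats::rnorm(length(a), 0, noise_sd)
    assay_trace(time, a, extinction = extinction, path_length = path_length,
                protein = protein,
                chromophores_per_turnover = chromophores_per_turnover)
  })
}
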