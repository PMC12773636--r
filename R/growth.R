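# Closed-form least squares of y on x; returns slope, intercept, r.squared.
# Used instead of lm() inside window scans for speed.
.lsq <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  fit <- my + slope * (x - mx)
  sst <- sum((y - my)^2)
  r2 <- if (sst > 0) 1 - sum((y - fit)^2) / sst else 0
  list(slope = slope, intercept = my - slope * mx, r.squared = r2)
}

#' Detect the exponential-phase window of an OD series
#'
#' Scans all contiguous windows of at least \code{min_points} points and,
#' among those whose log-linear fit reaches \eqn{r^2 \ge} \code{r2_threshold},
#' returns the one maximizing \eqn{r^2}; exact ties are broken toward the
#' longer and then the earlier window (so a noise-free exponential yields the
#' full series, while plateau points, which depress \eqn{r^2}, are excluded).
#' If no window reaches the threshold, the best-\eqn{r^2} window of length
#' \code{min_points} is returned with a warning flag.
#'
#' @param series A \code{summary_series} (from [summarize_timecourse()]) or a
#'   data frame with \code{time} and \code{mean} columns.
#' @param r2_threshold Minimum \eqn{r^2} for an acceptable window.
#' @param min_points Minimum window length (points).
#' @return List with \code{t_start}, \code{t_end}, \code{indices},
#'   \code{r_squared} and logical \code{fallback}.
#' @export
auto_window <- function(series, r2_threshold = 0.98, min_points = 4L) {
  time <- series$time
  od <- series$mean
  keep <- !is.na(od) & od > 0
  if (sum(keep) < min_points) {
    stop("need at least ", min_points, " positive OD points", call. = FALSE)
  }
  time <- time[keep]; lod <- log(od[keep])
  n <- length(time)
  best <- NULL
  for (i in seq_len(n - min_points + 1L)) {
    for (j in seq(i + min_points - 1L, n)) {
      r2 <- .lsq(time[i:j], lod[i:j])$r.squared
      cand <- list(i = i, j = j, len = j - i + 1L, r2 = r2)
      if (is.null(best)) { best <- cand; next }
      ok_c <- cand$r2 >= r2_threshold
      ok_b <- best$r2 >= r2_threshold
      better <-
        if (ok_c != ok_b) ok_c
        else if (ok_c) {
          # both admissible: max r2, then longest, then earliest
          if (cand$r2 != best$r2) cand$r2 > best$r2
          else if (cand$len != best$len) cand$len > best$len
          else cand$i < best$i
        } else {
          # neither admissible: track the best-r2 minimal window for fallback
          cand$len == min_points && (best$len != min_points || cand$r2 > best$r2)
        }
      if (better) best <- cand
    }
  }
  fallback <- best$r2 < r2_threshold
  if (fallback) {
    warning("no window reached r^2 >= ", r2_threshold,
            "; falling back to best ", min_points, "-point window",
            call. = FALSE)
  }
  list(t_start = time[best$i], t_end = time[best$j],
       indices = which(keep)[best$i:best$j],
       r_squared = best$r2, fallback = fallback)
}

#' Estimate the specific growth rate from an OD time course
#'
#' Fits \eqn{\ln(OD)} against time by least squares over the exponential
#' window; the slope is the specific growth rate \eqn{\mu} (per hour). The
#' window is auto-detected with [auto_window()] unless given. The maximal OD
#' reported is the maximum of the mean series (cultures may decline after the
#' peak, so the last point is not used).
#'
#' @param series A \code{summary_series}, a [timecourse()] (its \code{od600}
#'   channel is summarized), or a data frame with \code{time} and \code{mean}.
#' @param window Optional numeric \code{c(t_start, t_end)} in hours; when
#'   supplied it is used as-is.
#' @param r2_threshold,min_points Passed to [auto_window()].
#' @return An object of class \code{growth_fit} with components \code{mu},
#'   \code{intercept}, \code{window}, \code{od_final}, \code{r_squared},
#'   \code{n_points}, \code{fallback}.
#' @examples
#' s <- data.frame(time = 0:3, mean = 0.1 * 2^(0:3))
#' fit_growth_rate(s, window = c(0, 3))$mu  # ln 2
#' @export
fit_growth_rate <- function(series, window = NULL, r2_threshold = 0.98,
                            min_points = 4L) {
  if (inherits(series, "timecourse")) {
    series <- summarize_timecourse(series, "od600")
  }
  time <- series$time
  od <- series$mean
  od_final <- max(od, na.rm = TRUE)
  if (is.null(window)) {
    w <- auto_window(series, r2_threshold = r2_threshold,
                     min_points = min_points)
    idx <- w$indices
    fallback <- w$fallback
  } else {
    stopifnot(length(window) == 2L, window[1] < window[2])
    idx <- which(time >= window[1] & time <= window[2] & !is.na(od))
    fallback <- FALSE
    if (length(idx) < 3L) {
      stop("fewer than 3 points in the requested window", call. = FALSE)
    }
    if (any(od[idx] <= 0)) {
      stop("zero or negative OD inside the fit window", call. = FALSE)
    }
  }
  fit <- .lsq(time[idx], log(od[idx]))
  structure(list(mu = fit$slope, intercept = fit$intercept,
                 window = c(t_start = time[idx[1]],
                            t_end = time[idx[length(idx)]]),
                 od_final = od_final, r_squared = fit$r.squared,
                 n_points = length(idx), fallback = fallback),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, digits = 4, ...) {
  cat("Exponential growth fit\n")
  cat("  mu       :", format(x$mu, digits = digits), "h^-1\n")
  cat("  window   : [", x$window[1], ",", x$window[2], "] h (",
      x$n_points, " points)\n")
  cat("  od_final :", format(x$od_final, digits = digits), "\n")
  cat("  r^2      :", format(x$r_squared, digits = digits),
      if (x$fallback) " (fallback window)" else "", "\n")
  invisible(x)
}

#' @export
summary.growth_fit <- function(object, ...) {
  out <- c(mu = object$mu, od_final = object$od_final,
           r_squared = object$r_squared,
           t_start = unname(object$window[1]),
           t_end = unname(object$window[2]))
  class(out) <- "summary.growth_fit"
  out
}

#' @export
print.summary.growth_fit <- function(x, ...) {
  print(unclass(x), ...)
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) {
  c(mu = object$mu, log_od0 = object$intercept)
}

#' Predicted OD under the fitted exponential
#'
#' @param object A \code{growth_fit}.
#' @param time Hours at which to predict; defaults to the fit window limits.
#' @param ... Unused.
#' @return Numeric vector of predicted OD600.
#' @export
predict.growth_fit <- function(object, time = NULL, ...) {
  if (is.null(time)) time <- object$window
  exp(object$intercept + object$mu * time)
}

#' Per-replicate growth-rate fits
#'
#' Fits each replicate's OD series separately over a common window, giving a
#' mean and SEM for \eqn{\mu} — the companion to the default mean-series fit.
#'
#' @param tc A [timecourse()] with an \code{od600} channel.
#' @param window Optional window, as in [fit_growth_rate()]; defaults to the
#'   auto-window of the mean series.
#' @return Data frame with one row per replicate (\code{mu}, \code{r_squared})
#'   plus attributes \code{mu_mean} and \code{mu_sem}.
#' @export
fit_growth_rate_replicates <- function(tc, window = NULL) {
  stopifnot(inherits(tc, "timecourse"))
  s <- summarize_timecourse(tc, "od600")
  if (is.null(window)) {
    w <- auto_window(s)
    window <- c(w$t_start, w$t_end)
  }
  m <- tc$channels[["od600"]]
  fits <- lapply(seq_len(ncol(m)), function(j) {
    fit_growth_rate(data.frame(time = tc$time, mean = m[, j]), window = window)
  })
  mu <- vapply(fits, `[[`, numeric(1), "mu")
  out <- data.frame(replicate = seq_along(mu), mu = mu,
                    r_squared = vapply(fits, `[[`, numeric(1), "r_squared"))
  attr(out, "mu_mean") <- mean(mu)
  attr(out, "mu_sem") <- if (length(mu) > 1) stats::sd(mu) / sqrt(length(mu)) else 0
  out
}
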