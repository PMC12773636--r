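#' Molar product yields per mole of primary substrate
#'
#' @param consumed Named numeric vector of consumed substrates (mM, positive).
#' @param formed Named numeric vector of products formed (mM, positive).
#' @param primary Name of the primary substrate in \code{consumed}.
#' @return Named numeric vector: mol product per mol primary substrate.
#' @examples
#' molar_yields(c(glucose = 12.15), c(acetate = 13.62), "glucose")
#' @export
molar_yields <- function(consumed, formed, primary) {
  if (!primary %in% names(consumed) || consumed[primary] <= 0) {
    stop("no consumption of primary substrate '", primary, "'", call. = FALSE)
  }
  formed / consumed[[primary]]
}

#' Carbon recovery of a fermentation
#'
#' Percentage of substrate carbon recovered in the measured products:
#' \eqn{100 \sum_p C_p \cdot mM_p / \sum_s C_s \cdot mM_s}. CO2 (and
#' bicarbonate buffer) is excluded from both sides unless explicitly listed,
#' which is why net CO2-fixing fermentations (succinate production, a running
#' Wood-Ljungdahl pathway) can exceed 100%.
#'
#' @inheritParams molar_yields
#' @param registry Compound registry, see [compounds()].
#' @return Percent carbon recovery (numeric scalar).
#' @examples
#' carbon_recovery(c(glucose = 1), c(acetate = 3))  # homoacetogenesis: 100
#' @export
carbon_recovery <- function(consumed, formed, registry = compounds()) {
  cs <- registry_lookup(names(consumed), "carbons", registry)
  cp <- if (length(formed)) registry_lookup(names(formed), "carbons", registry) else numeric(0)
  denom <- sum(cs * consumed)
  if (denom <= 0) stop("no substrate carbon consumed", call. = FALSE)
  100 * sum(cp * formed) / denom
}

#' Degree-of-reduction electron recovery of a fermentation
#'
#' Percentage of available electrons recovered:
#' \eqn{100 \sum_p \gamma_p \cdot mM_p / \sum_s \gamma_s \cdot mM_s}, with
#' gaseous H2 counted among the products and CO (when supplied) among the
#' substrates. CO2 and water carry gamma 0 and drop out automatically.
#'
#' @inheritParams carbon_recovery
#' @return Percent electron recovery (numeric scalar).
#' @examples
#' electron_recovery(c(glucose = 1), c(lactate = 2))  # 100
#' @export
electron_recovery <- function(consumed, formed, registry = compounds()) {
  gs <- registry_lookup(names(consumed), "gamma", registry)
  gp <- if (length(formed)) registry_lookup(names(formed), "gamma", registry) else numeric(0)
  denom <- sum(gs * consumed)
  if (denom <= 0) stop("no substrate electrons consumed", call. = FALSE)
  100 * sum(gp * formed) / denom
}

#' Per-product carbon fractions
#'
#' For each product \eqn{p}, the percentage of primary-substrate carbon ending
#' up in \eqn{p}: \eqn{100 \cdot y_p \cdot C_p / C_{primary}}, from the molar
#' yields \eqn{y_p}.
#'
#' @param yields Named numeric vector of molar yields (mol/mol primary).
#' @param primary Primary substrate name (must have carbon).
#' @param registry Compound registry.
#' @return Named numeric vector of percentages.
#' @examples
#' carbon_fractions(c(formate = 0.15), "glucose")  # 2.5
#' @export
carbon_fractions <- function(yields, primary, registry = compounds()) {
  cprim <- registry_lookup(primary, "carbons", registry)[[1]]
  if (cprim <= 0) stop("primary substrate has no carbon", call. = FALSE)
  cp <- registry_lookup(names(yields), "carbons", registry)
  100 * yields * cp / cprim
}

# Canonical product order of fermentation equations.
.product_order <- c("acetate", "succinate", "lactate", "formate", "h2")

#' Render a fermentation balance equation
#'
#' Formats yields as the customary one-line molar equation, e.g.
#' \code{"1glucose→0.97acetate+0.42succinate+..."}. Products appear in
#' the canonical order acetate, succinate, lactate, formate, H2, then any
#' others alphabetically. Zero-coefficient products are dropped unless
#' \code{include_zero = TRUE} (used when an absent product is itself the
#' point, as in a PFL-inhibited fermentation printing \code{0.00formate}).
#'
#' @inheritParams carbon_fractions
#' @param precision Decimals for the coefficients (default 2).
#' @param include_zero Keep zero-coefficient products?
#' @param co_substrates Named numeric vector of co-substrate coefficients
#'   (e.g. \code{c(co = 1.57)}) rendered on the left-hand side.
#' @return The equation as a single character string.
#' @export
render_balance_equation <- function(yields, primary, precision = 2,
                                    include_zero = FALSE,
                                    co_substrates = NULL,
                                    registry = compounds()) {
  ord <- c(intersect(.product_order, names(yields)),
           sort(setdiff(names(yields), .product_order)))
  y <- yields[ord]
  if (!include_zero) y <- y[round(y, precision) > 0]
  disp <- registry_lookup(names(y), "display", registry)
  rhs <- paste0(formatC(y, format = "f", digits = precision), disp,
                collapse = "+")
  lhs <- paste0("1", registry_lookup(primary, "display", registry))
  if (!is.null(co_substrates)) {
    cdisp <- registry_lookup(names(co_substrates), "display", registry)
    lhs <- paste(c(lhs, paste0(formatC(co_substrates, format = "f",
                                       digits = precision), cdisp)),
                 collapse = "+")
  }
  paste0(lhs, "→", rhs)
}

#' Fermentation balance of a time course
#'
#' Computes endpoint substrate consumption and product formation, molar
#' yields, carbon recovery, per-product carbon fractions and
#' degree-of-reduction electron recovery from a replicated time course.
#'
#' Deltas are (last mean - first mean) per channel. A nominal product whose
#' endpoint delta is negative is clamped to zero with a warning — formate in
#' particular is a transient intermediate that can be produced and then fully
#' reconsumed. \code{mode = "peak"} instead reports each product's transient
#' maximum minus its initial value, for quantifying such intermediates.
#'
#' @param tc A [timecourse()] object.
#' @param primary Primary substrate channel name.
#' @param co_substrates Optional character vector of additional consumed
#'   channels (e.g. \code{"co"}).
#' @param mode \code{"endpoint"} (default) or \code{"peak"}.
#' @param registry Compound registry.
#' @return Object of class \code{fermentation_balance}: list with
#'   \code{substrates_consumed}, \code{products_formed}, \code{yields},
#'   \code{carbon_recovery}, \code{carbon_fractions},
#'   \code{electron_recovery}, \code{equation}, \code{primary}, \code{mode}.
#' @export
fermentation_balance <- function(tc, primary, co_substrates = character(0),
                                 mode = c("endpoint", "peak"),
                                 registry = compounds()) {
  stopifnot(inherits(tc, "timecourse"))
  mode <- match.arg(mode)
  chans <- setdiff(names(tc$channels), "od600")
  if (!primary %in% chans) {
    stop("primary substrate '", primary, "' not among channels", call. = FALSE)
  }
  subs <- c(primary, co_substrates)
  delta <- vapply(chans, function(ch) {
    s <- summarize_timecourse(tc, ch)
    m <- s$mean[!is.na(s$mean)]
    if (length(m) < 2L) return(0)
    if (mode == "peak" && !ch %in% subs) max(m) - m[1] else m[length(m)] - m[1]
  }, numeric(1))
  consumed <- -delta[subs]
  if (any(consumed < 0)) {
    stop("substrate '", subs[which(consumed < 0)[1]], "' increased over the course",
         call. = FALSE)
  }
  prod_ch <- setdiff(chans, subs)
  formed <- delta[prod_ch]
  if (any(formed < 0)) {
    warning("product(s) decreased over the course (clamped to 0): ",
            paste(prod_ch[formed < 0], collapse = ", "), call. = FALSE)
    formed[formed < 0] <- 0
  }
  yields <- molar_yields(consumed, formed, primary)
  structure(list(
    substrates_consumed = consumed,
    products_formed = formed,
    yields = yields,
    carbon_recovery = carbon_recovery(consumed, formed, registry),
    carbon_fractions = carbon_fractions(yields, primary, registry),
    electron_recovery = electron_recovery(consumed, formed, registry),
    equation = render_balance_equation(yields, primary, registry = registry),
    primary = primary, mode = mode, condition = tc$condition
  ), class = "fermentation_balance")
}

#' @export
print.fermentation_balance <- function(x, digits = 1, ...) {
  cat("Fermentation balance",
      if (nzchar(x$condition)) paste0(" [", x$condition, "]"), "\n", sep = "")
  cat("  ", x$equation, "\n", sep = "")
  cat("  carbon recovery  : ",
      formatC(x$carbon_recovery, format = "f", digits = digits), "%\n", sep = "")
  cat("  electron recovery: ",
      formatC(x$electron_recovery, format = "f", digits = digits), "%\n", sep = "")
  invisible(x)
}

#' @export
summary.fermentation_balance <- function(object, ...) {
  data.frame(product = names(object$yields),
             yield = unname(object$yields),
             carbon_fraction = unname(object$carbon_fractions),
             row.names = NULL)
}
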