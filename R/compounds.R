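#' Parse a molecular formula string
#'
#' Parses a Hill-style formula such as \code{"C6H12O6"} into a named count
#' vector. Only the elements C, H, O and N are accepted; the compounds used in
#' fermentation balancing contain nothing else.
#'
#' @param formula Character scalar, e.g. \code{"C4H6O4"}.
#' @return Named integer vector with elements \code{C}, \code{H}, \code{O},
#'   \code{N} (zero where absent).
#' @examples
#' parse_formula("C6H12O6")
#' parse_formula("H2")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula, perl = TRUE)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula)) {
    stop("cannot parse formula: ", formula, call. = FALSE)
  }
  counts <- c(C = 0L, H = 0L, O = 0L, N = 0L)
  for (tok in tokens) {
    el <- gsub("[0-9]", "", tok)
    n <- gsub("[A-Za-z]", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% names(counts)) {
      stop("unknown element '", el, "' in formula ", formula, call. = FALSE)
    }
    counts[el] <- counts[el] + n
  }
  counts
}

#' Degree of reduction (available electrons per mole)
#'
#' The degree of reduction of a compound with composition
#' \eqn{C_c H_h O_o} is \eqn{\gamma = 4c + h - 2o}: the number of available
#' electrons transferred to oxygen on complete combustion. Nitrogen is ignored
#' (no N-containing metabolite enters the balances here). The convention puts
#' \eqn{\gamma = 0} for both CO2 and H2O, so an electron balance over a
#' fermentation can ignore them.
#'
#' @param formula Formula string or named element-count vector as returned by
#'   [parse_formula()].
#' @return Available electrons per mole (numeric scalar).
#' @examples
#' degree_of_reduction("C6H12O6")  # 24
#' degree_of_reduction("CO2")      # 0
#' degree_of_reduction("H2")       # 2
#' @export
degree_of_reduction <- function(formula) {
  f <- if (is.character(formula)) parse_formula(formula) else formula
  if (!all(names(f) %in% c("C", "H", "O", "N"))) {
    bad <- setdiff(names(f), c("C", "H", "O", "N"))
    stop("unknown element '", bad[1], "'", call. = FALSE)
  }
  f <- f[f != 0]
  if ("N" %in% names(f)) {
    stop("degree of reduction is defined here for C/H/O compounds only",
         call. = FALSE)
  }
  g <- function(el) if (el %in% names(f)) unname(f[el]) else 0
  4 * g("C") + g("H") - 2 * g("O")
}

#' Carbon atoms per molecule
#'
#' @inheritParams degree_of_reduction
#' @return Integer carbon count.
#' @examples
#' carbon_count("C12H22O11")  # 12
#' carbon_count("H2")         # 0
#' @export
carbon_count <- function(formula) {
  f <- if (is.character(formula)) parse_formula(formula) else formula
  if ("C" %in% names(f)) as.integer(f["C"]) else 0L
}

# Registry rows. Organic acids are registered as the neutral (fully protonated)
# acids, which keeps element and electron balances charge-free and matches the
# molar bookkeeping of fermentation equations. Water carries gamma 0 and is
# excluded from recovery sums; biomass is deliberately absent (balances of
# growing cultures are expected not to close).
.compound_defs <- data.frame(
  name = c("glucose", "sorbitol", "xylose", "arabinose", "sucrose",
           "trehalose", "maltose", "raffinose", "acetate", "succinate",
           "lactate", "formate", "pyruvate", "h2", "co", "co2", "h2o"),
  formula = c("C6H12O6", "C6H14O6", "C5H10O5", "C5H10O5", "C12H22O11",
              "C12H22O11", "C12H22O11", "C18H32O16", "C2H4O2", "C4H6O4",
              "C3H6O3", "CH2O2", "C3H4O3", "H2", "CO", "CO2", "H2O"),
  display = c("glucose", "sorbitol", "xylose", "arabinose", "sucrose",
              "trehalose", "maltose", "raffinose", "acetate", "succinate",
              "lactate", "formate", "pyruvate", "H2", "CO", "CO2", "H2O"),
  stringsAsFactors = FALSE
)

#' Compound registry
#'
#' Table of every compound the package's balances touch, with molecular
#' formula, carbon count and degree of reduction. Additional compounds can be
#' appended by giving \code{extra} as a named character vector of formulas.
#'
#' @param extra Optional named character vector, \code{c(name = "formula")},
#'   appended to the built-in registry.
#' @return A data frame with columns \code{name}, \code{formula},
#'   \code{display}, \code{carbons}, \code{gamma}.
#' @examples
#' head(compounds())
#' compounds(extra = c(ethanol = "C2H6O"))
#' @export
compounds <- function(extra = NULL) {
  defs <- .compound_defs
  if (!is.null(extra)) {
    stopifnot(is.character(extra), !is.null(names(extra)))
    defs <- rbind(defs, data.frame(name = names(extra), formula = unname(extra),
                                   display = names(extra),
                                   stringsAsFactors = FALSE))
  }
  defs$carbons <- vapply(defs$formula, carbon_count, integer(1))
  defs$gamma <- vapply(defs$formula, degree_of_reduction, numeric(1))
  if (any(defs$gamma < 0)) {
    stop("negative degree of reduction in registry", call. = FALSE)
  }
  rownames(defs) <- NULL
  defs
}

# Look up one registry column for a vector of compound names; errors name the
# offending compound.
registry_lookup <- function(names, column, registry = compounds()) {
  idx <- match(names, registry$name)
  if (anyNA(idx)) {
    stop("compound not in registry: ",
         paste(names[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  stats::setNames(registry[[column]][idx], names)
}
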