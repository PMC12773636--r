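#' Run the growth / balance / flux pipeline
#'
#' Executes the full analysis on one condition: load (or simulate) a
#' replicated time course, fit the exponential growth rate, compute the
#' fermentation balance with carbon and electron recoveries, and optionally
#' solve the stoichiometric flux model for the resulting yields under one or
#' more hydrogenase scenarios. Results are aggregated into a single report
#' object that serializes losslessly to JSON, with provenance (input file
#' hash, configuration, seed, package version) attached.
#'
#' The configuration is a named list (or a path to a YAML/JSON file) with
#' keys:
#' \describe{
#'   \item{\code{input}}{path to a time-course table (see
#'     [read_timecourse()]); mutually exclusive with \code{simulate}.}
#'   \item{\code{sep}}{field separator of \code{input} (default ",").}
#'   \item{\code{simulate}}{a [simulation_preset()] name to generate the
#'     input instead of reading it.}
#'   \item{\code{seed}}{integer seed for simulation.}
#'   \item{\code{primary}}{primary substrate channel (default
#'     \code{"glucose"}).}
#'   \item{\code{co_substrates}}{additional consumed channels.}
#'   \item{\code{growth}}{\code{FALSE} to skip, or a list with optional
#'     \code{window = c(t0, t1)}.}
#'   \item{\code{balance}}{list with optional \code{mode}
#'     (\code{"endpoint"}/\code{"peak"}).}
#'   \item{\code{flux}}{\code{NULL} to skip, or a list with
#'     \code{scenarios} (subset of \code{"hydM"}, \code{"hydABC"},
#'     \code{"none"}), \code{h_per_atp}, \code{rnf_h_per_2e},
#'     \code{fumarate_reductase_donor}.}
#'   \item{\code{condition}}{report label.}
#' }
#'
#' @param config Named list or path to a YAML/JSON config file.
#' @param permissive If \code{FALSE} (default), an infeasible flux solution
#'   raises an error; if \code{TRUE} it is reported with its residuals.
#' @return Object of class \code{analysis_report}.
#' @export
run_pipeline <- function(config, permissive = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_config(config)
  }
  stopifnot(is.list(config))
  known <- c("input", "sep", "simulate", "seed", "primary", "co_substrates",
             "growth", "balance", "flux", "condition")
  bad <- setdiff(names(config), known)
  if (length(bad)) {
    stop("invalid config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  primary <- config$primary %||% "glucose"
  input_hash <- NULL
  if (!is.null(config$input)) {
    tc <- read_timecourse(config$input, sep = config$sep %||% ",")
    input_hash <- unname(tools::md5sum(config$input))
  } else if (!is.null(config$simulate)) {
    args <- simulation_preset(config$simulate)
    tc <- do.call(simulate_growth_course,
                  c(args, list(seed = config$seed %||% 1L)))
    primary <- config$primary %||% args$substrate
  } else {
    stop("config needs either 'input' or 'simulate'", call. = FALSE)
  }

  growth <- NULL
  if (!isFALSE(config$growth) && "od600" %in% names(tc$channels)) {
    growth <- fit_growth_rate(tc, window = config$growth$window)
  }
  bal <- fermentation_balance(
    tc, primary = primary,
    co_substrates = config$co_substrates %||% character(0),
    mode = config$balance$mode %||% "endpoint")

  flux <- NULL
  if (!is.null(config$flux)) {
    fl <- config$flux
    scen_names <- fl$scenarios %||% c("hydM", "hydABC")
    known_yields <- intersect(names(bal$yields),
                              c("acetate", "succinate", "lactate",
                                "formate", "h2"))
    flux <- lapply(scen_names, function(h) {
      sol <- solve_fluxes(
        yields = bal$yields[known_yields],
        scenario = scenario(h,
                            fl$fumarate_reductase_donor %||% "NADH",
                            fl$h_per_atp %||% 3.6,
                            fl$rnf_h_per_2e %||% 2))
      if (!sol$feasible && !permissive) {
        stop("flux model infeasible under scenario '", h, "' at node(s): ",
             paste(sol$infeasible_nodes, collapse = ", "), call. = FALSE)
      }
      sol
    })
    names(flux) <- scen_names
  }

  structure(list(
    condition = config$condition %||% tc$condition,
    growth = growth, balance = bal, flux = flux,
    provenance = list(
      input = config$input, input_md5 = input_hash,
      simulate = config$simulate, seed = config$seed,
      config = config[setdiff(names(config), c("input"))],
      package_version = as.character(utils::packageVersion("fermflux")))
  ), class = "analysis_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Read a YAML or JSON config file (by extension; YAML parser also reads JSON).
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

#' Serialize an analysis report to JSON
#'
#' Lossless, deterministic JSON rendering of a pipeline report (no
#' timestamps, so identical config + inputs + seed give byte-identical
#' output).
#'
#' @param report An \code{analysis_report}.
#' @param path Optional output file; when \code{NULL} the JSON string is
#'   returned.
#' @return JSON string (invisibly, when written to \code{path}).
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "analysis_report"))
  x <- list(
    condition = report$condition,
    growth = if (!is.null(report$growth)) {
      g <- report$growth
      list(mu = g$mu, window = unname(g$window), od_final = g$od_final,
           r_squared = g$r_squared, n_points = g$n_points)
    },
    balance = {
      b <- report$balance
      list(substrates_consumed = as.list(b$substrates_consumed),
           products_formed = as.list(b$products_formed),
           yields = as.list(b$yields),
           carbon_recovery = b$carbon_recovery,
           electron_recovery = b$electron_recovery,
           carbon_fractions = as.list(b$carbon_fractions),
           equation = b$equation, mode = b$mode)
    },
    flux = if (!is.null(report$flux)) {
      lapply(report$flux, function(s) {
        list(fluxes = as.list(s$fluxes), atp_slp = s$atp_slp,
             atp_chemiosmotic = s$atp_chemiosmotic, atp_net = s$atp_net,
             feasible = s$feasible,
             residual_max = max(abs(s$residuals)))
      })
    },
    provenance = report$provenance
  )
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path, useBytes = TRUE)
  invisible(as.character(json))
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("== Analysis report:", x$condition, "==\n")
  if (!is.null(x$growth)) print(x$growth)
  print(x$balance)
  if (!is.null(x$flux)) {
    for (nm in names(x$flux)) print(x$flux[[nm]])
  }
  invisible(x)
}
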