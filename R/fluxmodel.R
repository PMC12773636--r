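# Proxy formulas for element-balance checks of network reactions. Phosphoryl
# groups are not tracked: PEP and acetyl-CoA are represented by their free-acid
# parents (pyruvate, acetate). Redox carriers (NADH, NADPH, reduced
# ferredoxin) are two-electron tokens with formula H2; ATP and translocated
# protons are pure bookkeeping species excluded from the element check.
.species_formula <- c(
  glucose = "C6H12O6", pep = "C3H4O3", pyruvate = "C3H4O3", oaa = "C4H4O5",
  malate = "C4H6O5", fumarate = "C4H4O4", succinate = "C4H6O4",
  accoa = "C2H4O2", acetate = "C2H4O2", lactate = "C3H6O3",
  formate = "CH2O2", co2 = "CO2", h2o = "H2O", h2 = "H2",
  nadh = "H2", nadph = "H2", fdred = "H2"
)

#' Define a bioenergetic scenario
#'
#' Bundles the assumptions under which the glucose-fermentation network is
#' built and solved: which hydrogenase produces H2, the electron donor of
#' fumarate reductase, and the chemiosmotic stoichiometries (protons per ATP
#' at the synthase; protons translocated per 2 electrons at Rnf).
#'
#' \code{hydrogenase = "hydM"} is the ferredoxin-dependent single-subunit
#' enzyme; \code{"hydABC"} the electron-bifurcating complex drawing equal
#' electron amounts from NADH and reduced ferredoxin; \code{"none"} removes H2
#' production entirely.
#'
#' @param hydrogenase One of \code{"hydM"}, \code{"hydABC"}, \code{"none"}.
#' @param fumarate_reductase_donor \code{"NADH"} (default) or \code{"none"}
#'   (reaction absent; the in vivo donor is unresolved, the assay used
#'   methylviologen).
#' @param h_per_atp Protons per ATP at the synthase (default 3.6).
#' @param rnf_h_per_2e Protons translocated per 2 electrons at Rnf (default 2).
#' @return Object of class \code{flux_scenario}.
#' @export
scenario <- function(hydrogenase = c("hydM", "hydABC", "none"),
                     fumarate_reductase_donor = c("NADH", "none"),
                     h_per_atp = 3.6, rnf_h_per_2e = 2) {
  hydrogenase <- match.arg(hydrogenase)
  fumarate_reductase_donor <- match.arg(fumarate_reductase_donor)
  stopifnot(h_per_atp > 0, rnf_h_per_2e >= 0)
  structure(list(hydrogenase = hydrogenase,
                 fumarate_reductase_donor = fumarate_reductase_donor,
                 h_per_atp = h_per_atp, rnf_h_per_2e = rnf_h_per_2e),
            class = "flux_scenario")
}

reaction <- function(name, stoich, atp = 0, reversible = FALSE) {
  list(name = name, stoich = stoich, atp = atp, reversible = reversible)
}

#' Build the glucose-fermentation reaction network
#'
#' Returns the stoichiometric network of heterotrophic glucose fermentation
#' with a formate-fed Wood-Ljungdahl pathway (WLP):
#' \itemize{
#'   \item glycolysis to PEP (per glucose: 2 PEP + 2 NADH, net 0 ATP under
#'     plain Embden-Meyerhof-Parnas accounting),
#'   \item pyruvate kinase (+1 ATP) and the succinate branch: PEP
#'     carboxykinase (+1 ATP), malate dehydrogenase (NADH), fumarase,
#'     fumarate reductase (donor per scenario),
#'   \item the pyruvate node: PFL (acetyl-CoA + formate), PFOR (acetyl-CoA +
#'     CO2 + reduced ferredoxin), lactate dehydrogenase (NADH),
#'   \item phosphotransacetylase/acetate kinase (+1 ATP),
#'   \item the WLP lumped to one reaction per acetate: formate + CO2 + NADPH
#'     (methylene-THF dehydrogenase) + NADH (methylene-THF reductase) +
#'     reduced ferredoxin (CODH) -> acetate, net 0 ATP (-1 formyl-THF
#'     synthetase, +1 acetate kinase),
#'   \item carrier coupling: Nfn (NADH + Fd_red + 2 NADP+ -> 2 NADPH), Rnf
#'     (Fd_red -> NADH, translocating \code{rnf_h_per_2e} protons;
#'     reversible), ATP synthase (\code{h_per_atp} protons per ATP;
#'     reversible), and the scenario's hydrogenase.
#' }
#' Every reaction is element-balanced for C, H and O with carriers counted as
#' two-electron (H2-equivalent) tokens.
#'
#' @param scenario A [scenario()] object.
#' @return Object of class \code{flux_network}: list of reactions plus the
#'   scenario.
#' @export
build_network <- function(scenario = fermflux::scenario()) {
  stopifnot(inherits(scenario, "flux_scenario"))
  rx <- list(
    reaction("glycolysis",
             c(glucose = -1, pep = 2, nadh = 2)),
    reaction("pyruvate_kinase",
             c(pep = -1, pyruvate = 1), atp = 1),
    reaction("pep_carboxykinase",
             c(pep = -1, co2 = -1, oaa = 1), atp = 1),
    reaction("malate_dehydrogenase",
             c(oaa = -1, nadh = -1, malate = 1)),
    reaction("fumarase",
             c(malate = -1, fumarate = 1, h2o = 1)),
    reaction("pfl",
             c(pyruvate = -1, h2o = -1, accoa = 1, formate = 1)),
    reaction("pfor",
             c(pyruvate = -1, h2o = -1, accoa = 1, co2 = 1, fdred = 1)),
    reaction("ldh",
             c(pyruvate = -1, nadh = -1, lactate = 1)),
    reaction("acetate_kinase",
             c(accoa = -1, acetate = 1), atp = 1),
    reaction("wlp",
             c(formate = -1, co2 = -1, nadph = -1, nadh = -1, fdred = -1,
               acetate = 1, h2o = 2), atp = 0),
    reaction("nfn",
             c(nadh = -1, fdred = -1, nadph = 2)),
    reaction("rnf",
             c(fdred = -1, nadh = 1, h_trans = scenario$rnf_h_per_2e),
             reversible = TRUE),
    reaction("atp_synthase",
             c(h_trans = -scenario$h_per_atp), atp = 1, reversible = TRUE)
  )
  if (scenario$fumarate_reductase_donor == "NADH") {
    rx <- append(rx, list(reaction("fumarate_reductase",
                                   c(fumarate = -1, nadh = -1, succinate = 1))),
                 after = 5L)
  }
  if (scenario$hydrogenase == "hydM") {
    rx <- c(rx, list(reaction("hydM", c(fdred = -1, h2 = 1))))
  } else if (scenario$hydrogenase == "hydABC") {
    rx <- c(rx, list(reaction("hydABC", c(nadh = -0.5, fdred = -0.5, h2 = 1))))
  }
  names(rx) <- vapply(rx, `[[`, character(1), "name")
  structure(list(reactions = rx, scenario = scenario),
            class = "flux_network")
}

#' @export
print.flux_network <- function(x, ...) {
  cat("Flux network:", length(x$reactions), "reactions; hydrogenase =",
      x$scenario$hydrogenase, "\n")
  for (r in x$reactions) {
    s <- r$stoich
    lhs <- s[s < 0]; rhs <- s[s > 0]
    fmt <- function(v) paste(paste0(ifelse(abs(v) == 1, "", abs(v)), names(v)),
                             collapse = " + ")
    cat(sprintf("  %-20s %s -> %s%s\n", r$name, fmt(lhs), fmt(rhs),
                if (r$atp != 0) sprintf("  [ATP %+g]", r$atp) else ""))
  }
  invisible(x)
}

#' Stoichiometric matrix of a network
#'
#' @param network A [build_network()] object.
#' @param species Optional species subset/order for the rows.
#' @return Numeric matrix, species x reactions.
#' @export
stoichiometric_matrix <- function(network, species = NULL) {
  rx <- network$reactions
  if (is.null(species)) {
    species <- unique(unlist(lapply(rx, function(r) names(r$stoich))))
  }
  S <- matrix(0, length(species), length(rx),
              dimnames = list(species, names(rx)))
  for (j in seq_along(rx)) {
    st <- rx[[j]]$stoich
    st <- st[names(st) %in% species]
    S[names(st), j] <- st
  }
  S
}

# Minimum-norm least-squares solution of A v = b via SVD: among all v
# minimizing ||A v - b||, the one of least Euclidean norm.
minnorm_solve <- function(A, b) {
  sv <- svd(A)
  tol <- max(dim(A)) * .Machine$double.eps * max(sv$d, 0)
  dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
  drop(sv$v %*% (dinv * crossprod(sv$u, b)))
}

#' Solve steady-state fluxes for measured product yields
#'
#' Fixes the exchange fluxes (glucose uptake normalized to 1; acetate,
#' succinate, lactate, formate and H2 at their measured molar yields), balances
#' every internal metabolite and redox carrier (NADH, NADPH, reduced
#' ferredoxin) and the translocated-proton pool to zero, and solves the linear
#' steady-state system \eqn{S v = b}. CO2 and water are left free (the
#' bicarbonate-buffered system exchanges both). When the system is
#' underdetermined the minimum-norm solution is returned; irreversible
#' reactions driven negative are clamped to zero by an active-set iteration.
#' When no exact solution exists the least-squares solution is returned with
#' per-node residuals flagged (measured yields whose electron balance is below
#' 100\% cannot close exactly).
#'
#' @param network A [build_network()] object (or it is built from
#'   \code{scenario}).
#' @param yields Named numeric vector, mol per mol glucose, over
#'   \code{acetate}, \code{succinate}, \code{lactate}, \code{formate},
#'   \code{h2}; missing names default to 0.
#' @param scenario Used when \code{network} is missing.
#' @param tol Feasibility tolerance on node residuals.
#' @return Object of class \code{flux_solution}: \code{fluxes} (mol per mol
#'   glucose), \code{atp_slp}, \code{atp_chemiosmotic}, \code{atp_net},
#'   \code{residuals} (per balanced node), \code{feasible}, \code{clamped},
#'   \code{exchange} (net exchange fluxes incl. CO2), \code{scenario}.
#' @examples
#' sol <- solve_fluxes(yields = c(acetate = 3), scenario = scenario("none"))
#' sol$atp_slp  # 4: the homoacetogenic substrate-level maximum
#' @export
solve_fluxes <- function(network = NULL, yields, scenario = fermflux::scenario(),
                         tol = 1e-9) {
  if (is.null(network)) network <- build_network(scenario)
  stopifnot(inherits(network, "flux_network"))
  exch <- c(acetate = 0, succinate = 0, lactate = 0, formate = 0, h2 = 0)
  if (length(yields)) {
    bad <- setdiff(names(yields), names(exch))
    if (length(bad)) {
      stop("unknown yield name(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    exch[names(yields)] <- yields
  }
  if (any(exch < 0)) stop("yields must be nonnegative", call. = FALSE)

  free <- c("co2", "h2o")                       # unconstrained exchanges
  all_species <- unique(unlist(lapply(network$reactions,
                                      function(r) names(r$stoich))))
  balanced <- setdiff(all_species, free)
  S <- stoichiometric_matrix(network, species = balanced)
  b <- stats::setNames(numeric(length(balanced)), balanced)
  b["glucose"] <- -1
  b[intersect(names(exch), balanced)] <- exch[intersect(names(exch), balanced)]
  orphan <- setdiff(names(exch)[exch > 0], balanced)
  if (length(orphan)) {
    stop("no reaction in this scenario can produce: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }

  rev_flag <- vapply(network$reactions, `[[`, logical(1), "reversible")
  active <- rep(TRUE, ncol(S))                  # columns still in the system
  v <- stats::setNames(numeric(ncol(S)), colnames(S))
  repeat {
    v[] <- 0
    v[active] <- minnorm_solve(S[, active, drop = FALSE], b)
    neg <- which(active & !rev_flag & v < -tol)
    if (!length(neg)) break
    active[neg[which.min(v[neg])]] <- FALSE     # clamp most negative, resolve
    if (!any(active)) break
  }
  res <- drop(S %*% v) - b
  feasible <- max(abs(res)) < tol
  atp_coef <- vapply(network$reactions, `[[`, numeric(1), "atp")
  atp_slp <- sum(atp_coef[names(v) != "atp_synthase"] *
                   v[names(v) != "atp_synthase"])
  atp_chem <- if ("atp_synthase" %in% names(v)) unname(v["atp_synthase"]) else 0

  Sfull <- stoichiometric_matrix(network, species = all_species)
  exchange <- drop(Sfull %*% v)[c("glucose", names(exch), intersect(free, all_species))]

  structure(list(fluxes = v, atp_slp = atp_slp, atp_chemiosmotic = atp_chem,
                 atp_net = atp_slp + atp_chem, residuals = res,
                 feasible = feasible,
                 clamped = colnames(S)[!active],
                 infeasible_nodes = names(res)[abs(res) >= tol],
                 exchange = exchange, scenario = network$scenario),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, digits = 4, ...) {
  cat("Steady-state flux solution (hydrogenase =", x$scenario$hydrogenase, ")\n")
  cat("  ATP substrate-level :", format(x$atp_slp, digits = digits), "\n")
  cat("  ATP chemiosmotic    :", format(x$atp_chemiosmotic, digits = digits), "\n")
  cat("  ATP net             :", format(x$atp_net, digits = digits),
      "per glucose\n")
  if (!x$feasible) {
    cat("  NOT feasible; residual nodes:",
        paste(x$infeasible_nodes, collapse = ", "), "\n")
  }
  if (length(x$clamped)) {
    cat("  clamped at zero:", paste(x$clamped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.flux_solution <- function(object, ...) {
  data.frame(reaction = names(object$fluxes), flux = unname(object$fluxes),
             row.names = NULL)
}

#' @export
coef.flux_solution <- function(object, ...) object$fluxes

#' ATP ledger of a flux solution
#'
#' Splits net ATP per glucose into the substrate-level component (pyruvate
#' kinase + PEP carboxykinase + acetate kinase - formyl-THF synthetase, the
#' last folded into the lumped WLP reaction) and the chemiosmotic component
#' \eqn{rnf\_flux \cdot rnf\_h\_per\_2e / h\_per\_atp}.
#'
#' @param solution A \code{flux_solution}.
#' @return Named numeric vector \code{c(atp_slp, atp_chemiosmotic, atp_net)}.
#' @export
atp_ledger <- function(solution) {
  stopifnot(inherits(solution, "flux_solution"))
  c(atp_slp = solution$atp_slp,
    atp_chemiosmotic = solution$atp_chemiosmotic,
    atp_net = solution$atp_net)
}

#' Compare hydrogenase scenarios at fixed exchange fluxes
#'
#' Solves the network for the same measured yields under the
#' ferredoxin-dependent hydrogenase (HydM) and the electron-bifurcating
#' hydrogenase (HydABC). HydABC draws half its electrons from NADH, freeing
#' ferredoxin for Rnf and thus for chemiosmotic ATP; the net-ATP gap equals
#' \eqn{y_{H2}/2 \cdot rnf\_h\_per\_2e / h\_per\_atp}.
#'
#' @inheritParams solve_fluxes
#' @param h_per_atp,rnf_h_per_2e,fumarate_reductase_donor Scenario settings
#'   shared by both solutions.
#' @return List with both \code{flux_solution}s (\code{hydM},
#'   \code{hydABC}), a summary data frame \code{table}, and
#'   \code{delta_atp_net} (HydABC - HydM).
#' @export
compare_scenarios <- function(yields, h_per_atp = 3.6, rnf_h_per_2e = 2,
                              fumarate_reductase_donor = "NADH") {
  sols <- lapply(c("hydM", "hydABC"), function(h) {
    solve_fluxes(yields = yields,
                 scenario = scenario(h, fumarate_reductase_donor,
                                     h_per_atp, rnf_h_per_2e))
  })
  names(sols) <- c("hydM", "hydABC")
  tab <- do.call(rbind, lapply(names(sols), function(nm) {
    data.frame(scenario = nm, t(atp_ledger(sols[[nm]])),
               feasible = sols[[nm]]$feasible)
  }))
  list(hydM = sols$hydM, hydABC = sols$hydABC, table = tab,
       delta_atp_net = sols$hydABC$atp_net - sols$hydM$atp_net)
}

#' Check element balance of every network reaction
#'
#' Verifies C, H and O conservation for each reaction using the proxy
#' formulas (carriers as two-electron H2 tokens; ATP and translocated protons
#' excluded).
#'
#' @param network A [build_network()] object.
#' @return Named logical vector, one entry per reaction.
#' @export
check_element_balance <- function(network) {
  vapply(network$reactions, function(r) {
    st <- r$stoich[names(r$stoich) %in% names(.species_formula)]
    tot <- c(C = 0, H = 0, O = 0)
    for (sp in names(st)) {
      f <- parse_formula(.species_formula[[sp]])
      tot <- tot + st[[sp]] * f[c("C", "H", "O")]
    }
    all(abs(tot) < 1e-9)
  }, logical(1))
}
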