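# Default activation tolerance on fluxes; LP solutions carry ~1e-9 noise.
.EPS_ACT <- 1e-6

#' Maximal flux of a reaction (flux balance analysis)
#'
#' Maximises the flux of `objective` subject to steady-state mass balance over
#' the internal metabolites (products positive, reactants negative) and
#' `0 <= v_r <= ub_r` for every irreversible reaction, optionally with
#' additional fixed-flux equality constraints. Variables are ordered
#' lexicographically by reaction id, so results are deterministic.
#'
#' @param net A [metabolic_network()].
#' @param objective Reaction id to maximise; defaults to the network target.
#' @param fixed Optional named numeric vector of fixed fluxes
#'   (reaction id -> value), imposed as equalities.
#' @param knockout Optional character vector of reaction ids forced to zero
#'   flux; the mirror member of a reversible pair is knocked out jointly.
#' @return A list of class `"lp_result"`: `status` (`"optimal"` or
#'   `"infeasible"`), `objective_value` and `fluxes` (named vector).
#' @examples
#' fx <- pem_fixture("fig1")
#' max_flux(fx$network)$objective_value
#' @export
max_flux <- function(net, objective = net$target, fixed = NULL,
                     knockout = NULL) {
  stopifnot(inherits(net, "metabolic_network"))
  if (is.na(objective)) stop("no objective reaction given")
  .get_reaction(net, objective)
  S <- stoichiometric_matrix(net)
  rxns <- colnames(S)
  ub <- upper_bounds(net)[rxns]

  if (!is.null(knockout)) {
    for (k in knockout) {
      rk <- .get_reaction(net, k)
      ub[[k]] <- 0
      if (!is.na(rk$reverse_of)) ub[[rk$reverse_of]] <- 0
    }
  }

  A <- S
  b <- rep(0, nrow(S))
  if (!is.null(fixed)) {
    stopifnot(is.numeric(fixed), !is.null(names(fixed)))
    for (fr in names(fixed)) {
      .get_reaction(net, fr)
      if (fixed[[fr]] < -.EPS_ACT || fixed[[fr]] > ub[[fr]] + .EPS_ACT) {
        stop("fixed flux for '", fr, "' outside [0, ub]")
      }
      row <- stats::setNames(rep(0, length(rxns)), rxns)
      row[[fr]] <- 1
      A <- rbind(A, row)
      b <- c(b, fixed[[fr]])
    }
  }

  c_obj <- stats::setNames(rep(0, length(rxns)), rxns)
  c_obj[[objective]] <- 1
  sol <- lp_max(c_obj, A, b, ub)
  structure(
    list(status = sol$status,
         objective_value = if (sol$status == "optimal") sol$objective else NA_real_,
         fluxes = if (sol$status == "optimal")
           stats::setNames(sol$x, rxns) else NULL),
    class = "lp_result"
  )
}

#' @export
print.lp_result <- function(x, ...) {
  cat("LP result:", x$status)
  if (identical(x$status, "optimal")) {
    cat(", objective =", format(x$objective_value))
  }
  cat("\n")
  invisible(x)
}

#' Stoichiometric activation of a reaction
#'
#' A reaction is stoichiometrically activated when some non-negative, bounded,
#' mass-balanced flux vector gives it strictly positive flux, i.e. its maximal
#' flux exceeds the activation tolerance.
#'
#' @inheritParams max_flux
#' @param r Reaction id.
#' @param eps Activation tolerance on fluxes.
#' @return Logical scalar.
#' @export
stoichiometrically_activated <- function(net, r, eps = .EPS_ACT) {
  res <- max_flux(net, objective = r)
  if (!identical(res$status, "optimal")) {
    warning("flux system infeasible for '", r, "'; treating as inactive")
    return(FALSE)
  }
  res$objective_value > eps
}

#' Producibility-PEM enumeration
#'
#' A metabolite `m` (neither a seed nor a reactant of the target) is a
#' producibility-PEM when the target reaction is stoichiometrically activated
#' in the full network but not in the network pruned with respect to `m`. This
#' covers both substrates of single lethal reactions and metabolites whose
#' whole consuming reaction set is jointly lethal though no single removal is.
#'
#' @inheritParams sustainability_pems
#' @param eps Activation tolerance on fluxes.
#' @return Character vector of producibility-PEM ids, sorted.
#' @examples
#' fx <- pem_fixture("fig2")
#' producibility_pems(fx$network)  # "E" and "G"
#' @export
producibility_pems <- function(net, seeds = NULL, target = NULL,
                               eps = .EPS_ACT) {
  seeds <- .as_seeds(net, seeds)
  target <- .as_target(net, target)
  mu0 <- max_flux(net, target$target_reaction_id)
  if (!identical(mu0$status, "optimal") || mu0$objective_value <= eps) {
    stop("target '", target$target_reaction_id,
         "' carries no flux in the unpruned network")
  }
  consumed <- unique(unlist(lapply(net$reactions, function(r)
    names(r$reactants)), use.names = FALSE))
  cands <- .sort_ids(setdiff(consumed, c(seeds, target$targeted_metabolites)))
  is_pem <- vapply(cands, function(m) {
    res <- max_flux(prune(net, m), target$target_reaction_id)
    !identical(res$status, "optimal") || res$objective_value <= eps
  }, logical(1))
  cands[is_pem]
}

#' Essential reactions at the optimal target flux
#'
#' A reaction is essential (optimal-flux sense) when forcing its flux to zero
#' strictly lowers the maximal flux of the target reaction: the knocked-out
#' optimum must be below the unconstrained optimum by more than `delta`
#' (absolute) and by more than a fraction `rho` (relative). Reversible pairs
#' are knocked out jointly.
#'
#' @inheritParams max_flux
#' @param target A [target_spec()], reaction id, or `NULL` (network target).
#' @param delta Absolute essentiality threshold (flux units).
#' @param rho Relative essentiality threshold.
#' @return Character vector of essential reaction ids (the lexicographically
#'   smaller id represents a reversible pair), sorted.
#' @export
essential_reactions <- function(net, target = NULL, delta = .EPS_ACT,
                                rho = .EPS_ACT) {
  target <- .as_target(net, target)
  mu0 <- max_flux(net, target$target_reaction_id)
  if (!identical(mu0$status, "optimal")) {
    stop("flux system infeasible for target '", target$target_reaction_id, "'")
  }
  mu_star <- mu0$objective_value
  # one representative per reversible pair
  reps <- Filter(function(r) {
    rx <- net$reactions[[r]]
    is.na(rx$reverse_of) || rx$id < rx$reverse_of
  }, names(net$reactions))
  ess <- vapply(reps, function(r) {
    res <- max_flux(net, target$target_reaction_id, knockout = r)
    mu_k <- if (identical(res$status, "optimal")) res$objective_value else 0
    (mu_k < mu_star - delta) && (mu_k < mu_star * (1 - rho))
  }, logical(1))
  .sort_ids(reps[ess])
}

#' Optimal-efficiency-PEM enumeration
#'
#' The union of the reactant sets of all essential reactions (optimal-flux
#' sense). Unlike the sustainability and producibility classes, no seed or
#' target-reactant exclusion applies: the definition is deliberately
#' single-reaction based, so there is no causality between the three classes.
#' For a reversible pair, the substrates of both directions are included.
#'
#' @inheritParams essential_reactions
#' @return Character vector of optimal-efficiency-PEM ids, sorted.
#' @export
optimal_efficiency_pems <- function(net, target = NULL, delta = .EPS_ACT,
                                    rho = .EPS_ACT) {
  target <- .as_target(net, target)
  ess <- essential_reactions(net, target, delta = delta, rho = rho)
  mets <- c(character(0), unlist(lapply(ess, function(r) {
    rx <- net$reactions[[r]]
    out <- names(rx$reactants)
    if (!is.na(rx$reverse_of)) {
      out <- c(out, names(net$reactions[[rx$reverse_of]]$reactants))
    }
    out
  }), use.names = FALSE))
  .sort_ids(unique(mets))
}

#' Flux variability analysis for one reaction
#'
#' Minimum and maximum flux of `r` over the feasible polytope, optionally with
#' the target flux first maximised and then fixed at its optimum.
#'
#' @inheritParams max_flux
#' @param r Reaction id to analyse.
#' @param at_optimum If `TRUE`, impose `v_target = mu*` before scanning `r`.
#' @param target Reaction id whose optimum is imposed when `at_optimum`;
#'   defaults to the network target.
#' @return A list of class `"flux_interval"`: `min_v`, `max_v`, `reaction`.
#' @export
fva <- function(net, r, at_optimum = FALSE, target = net$target) {
  .get_reaction(net, r)
  fixed <- NULL
  if (isTRUE(at_optimum)) {
    mu0 <- max_flux(net, target)
    if (!identical(mu0$status, "optimal")) {
      stop("cannot constrain to optimum: infeasible system for '", target, "'")
    }
    fixed <- stats::setNames(mu0$objective_value, target)
  }
  S <- stoichiometric_matrix(net)
  rxns <- colnames(S)
  ub <- upper_bounds(net)[rxns]
  A <- S
  b <- rep(0, nrow(S))
  if (!is.null(fixed)) {
    row <- stats::setNames(rep(0, length(rxns)), rxns)
    row[[names(fixed)]] <- 1
    A <- rbind(A, row)
    b <- c(b, unname(fixed))
  }
  c_obj <- stats::setNames(rep(0, length(rxns)), rxns)
  c_obj[[r]] <- 1
  hi <- lp_max(c_obj, A, b, ub)
  lo <- lp_max(-c_obj, A, b, ub)
  if (!identical(hi$status, "optimal") || !identical(lo$status, "optimal")) {
    stop("infeasible constrained polytope for '", r, "'")
  }
  structure(list(min_v = -lo$objective, max_v = hi$objective, reaction = r),
            class = "flux_interval")
}

#' @export
print.flux_interval <- function(x, ...) {
  cat(sprintf("FVA %s: [%g, %g]\n", x$reaction, x$min_v, x$max_v))
  invisible(x)
}
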