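# Independent reference implementations used to validate the package's
# fixpoint engine and LP solver. They deliberately use different algorithms
# (naive set iteration; exhaustive basic-solution enumeration) from the
# production code paths.

# Naive scope: iterate M_{i+1} = M_i + products of reactions whose reactants
# are all in M_i, until stable. Reactant-free inflow reactions are only
# considered available through the seed set, matching the package semantics.
oracle_scope <- function(net, seeds) {
  M <- unique(seeds)
  repeat {
    added <- FALSE
    for (r in net$reactions) {
      if (length(r$reactants) == 0L) next
      if (all(names(r$reactants) %in% M)) {
        new <- setdiff(names(r$products), M)
        if (length(new) > 0L) {
          M <- c(M, new)
          added <- TRUE
        }
      }
    }
    if (!added) break
  }
  sort(M)
}

# Naive prune: drop consumers of m and reversible producers of m, using a
# from-scratch mirror-pair scan rather than the stored reverse_of links.
oracle_prune <- function(net, m) {
  sides_equal <- function(a, b) {
    identical(names(a), names(b)) && isTRUE(all.equal(unname(a), unname(b)))
  }
  is_reversible <- vapply(net$reactions, function(r) {
    any(vapply(net$reactions, function(q) {
      !identical(q$id, r$id) &&
        sides_equal(q$reactants, r$products) &&
        sides_equal(q$products, r$reactants)
    }, logical(1)))
  }, logical(1))
  drop <- vapply(net$reactions, function(r) {
    m %in% names(r$reactants) ||
      (is_reversible[[r$id]] && m %in% names(r$products))
  }, logical(1))
  out <- net
  out$reactions <- net$reactions[!drop]
  out
}

# Brute-force sustainability-PEMs: for every metabolite that is neither a
# seed nor a target reactant, recompute the scope of the pruned network from
# scratch and test whether the target's reactants all remain reachable.
oracle_sustainability <- function(net, seeds, target_id) {
  tm <- names(net$reactions[[target_id]]$reactants)
  if (!all(tm %in% oracle_scope(net, seeds))) {
    stop("target not activated in the unpruned network")
  }
  cands <- setdiff(net$metabolites$id, c(seeds, tm))
  pems <- character(0)
  for (m in cands) {
    pr <- oracle_prune(net, m)
    if (length(pr$reactions) == 0L) next
    if (!all(tm %in% oracle_scope(pr, seeds))) pems <- c(pems, m)
  }
  sort(pems)
}

# Exhaustive basic-solution enumeration for max c'v over
# {S v = 0, 0 <= v <= ub}. Every vertex of the polytope has linearly
# independent columns for its non-bound variables, so scanning all
# free-variable subsets with independent columns and all 0/ub assignments of
# the rest visits every vertex.
oracle_lp_max <- function(net, objective, tol = 1e-8) {
  S <- stoichiometric_matrix(net)
  ub <- upper_bounds(net)[colnames(S)]
  n <- ncol(S)
  cvec <- stats::setNames(rep(0, n), colnames(S))
  cvec[[objective]] <- 1
  best <- -Inf
  for (k in 0:n) {
    free_sets <- if (k == 0L) list(integer(0)) else
      utils::combn(n, k, simplify = FALSE)
    for (fr in free_sets) {
      Sf <- S[, fr, drop = FALSE]
      if (k > 0L && qr(Sf)$rank < k) next
      bound <- setdiff(seq_len(n), fr)
      for (mask in 0:(2^length(bound) - 1L)) {
        v <- numeric(n)
        at_ub <- as.logical(bitwAnd(mask, 2^(seq_along(bound) - 1L)))
        v[bound[at_ub]] <- ub[bound[at_ub]]
        rhs <- -S %*% v
        if (k > 0L) {
          sol <- qr.coef(qr(Sf), rhs)
          if (any(is.na(sol))) next
          v[fr] <- sol
        }
        if (any(v < -tol) || any(v > ub + tol)) next
        if (max(abs(S %*% v)) > tol) next
        best <- max(best, sum(cvec * v))
      }
    }
  }
  best
}

# FBA optimum from cobrapy/GLPK on an SBML export (dual-route cross-check).
cobra_max_flux <- function(sbml_path, target_id) {
  script <- sprintf(
    "import cobra, warnings\nwarnings.filterwarnings('ignore')\nm = cobra.io.read_sbml_model(%s)\nm.objective = %s\nprint(repr(m.optimize().objective_value))",
    deparse(sbml_path), deparse(target_id))
  out <- suppressWarnings(
    system2("python", c("-c", shQuote(script)), stdout = TRUE, stderr = FALSE))
  as.numeric(utils::tail(out, 1L))
}

has_cobra <- function() {
  nzchar(Sys.which("python")) &&
    suppressWarnings(identical(
      tryCatch(system2("python", c("-c", shQuote("import cobra")),
                       stdout = FALSE, stderr = FALSE), error = function(e) 1L),
      0L))
}
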