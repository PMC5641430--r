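#' Scope (network expansion) of a seed set
#'
#' Computes the least fixpoint of metabolites reachable from the seeds: a
#' reaction fires once all of its reactants are reachable, and its products
#' then become reachable. This is the strict recursive semantics of network
#' expansion: a reaction with a self-loop (a metabolite that is both reactant
#' and product) only fires once that metabolite is already in scope.
#'
#' Reactant-free (boundary) reactions are not fired during the closure: a
#' boundary inflow is considered available only when its compound is declared a
#' seed. Under the standing assumption that all boundary seeds are seeds this
#' coincides with the literal fixpoint; it additionally allows scope queries on
#' seed subsets, which emulate the removal of the other nutrients.
#'
#' @param net A [metabolic_network()].
#' @param seeds Character vector of seed metabolite ids, or a [seed_set()].
#' @return An object of class `"pem_scope"`: list with `activated_metabolites`,
#'   `activated_reactions` (reactions with at least one reactant, all in
#'   scope), and `iterations` (number of reaction firings + 1).
#' @examples
#' fx <- pem_fixture("fig1")
#' compute_scope(fx$network, "S1")$activated_metabolites  # S1, A, G, F
#' @export
compute_scope <- function(net, seeds) {
  stopifnot(inherits(net, "metabolic_network"))
  if (inherits(seeds, "seed_set")) seeds <- seeds$seeds
  .check_metabolite(net, seeds)

  rxns <- net$reactions
  has_rcts <- vapply(rxns, function(r) length(r$reactants) > 0L, logical(1))
  # worklist over reactions keyed by unmet-reactant counters
  unmet <- vapply(rxns, function(r) length(unique(names(r$reactants))),
                  integer(1))
  consumers <- new.env(parent = emptyenv())
  for (r in names(rxns)) {
    for (m in names(rxns[[r]]$reactants)) {
      assign(m, c(mget(m, envir = consumers, ifnotfound = list(character(0)))[[1]], r),
             envir = consumers)
    }
  }
  in_scope <- new.env(parent = emptyenv())
  queue <- unique(seeds)
  for (m in queue) assign(m, TRUE, envir = in_scope)
  fired <- character(0)
  iterations <- 1L
  while (length(queue) > 0L) {
    m <- queue[[1L]]
    queue <- queue[-1L]
    for (r in mget(m, envir = consumers, ifnotfound = list(character(0)))[[1]]) {
      unmet[[r]] <- unmet[[r]] - 1L
      if (unmet[[r]] == 0L) {
        fired <- c(fired, r)
        iterations <- iterations + 1L
        for (p in names(rxns[[r]]$products)) {
          if (!exists(p, envir = in_scope, inherits = FALSE)) {
            assign(p, TRUE, envir = in_scope)
            queue <- c(queue, p)
          }
        }
      }
    }
  }
  structure(
    list(activated_metabolites = .sort_ids(ls(in_scope)),
         activated_reactions = .sort_ids(fired),
         iterations = iterations),
    class = "pem_scope"
  )
}

#' @export
print.pem_scope <- function(x, ...) {
  cat("Scope:", length(x$activated_metabolites), "metabolites,",
      length(x$activated_reactions), "activated reactions\n")
  invisible(x)
}

#' Topological activation of a reaction
#'
#' A reaction is topologically activated from a seed set when all of its
#' reactants belong to the scope of the seeds. A reactant-free reaction is
#' trivially activated (the empty set is contained in any scope).
#'
#' @inheritParams compute_scope
#' @param r Reaction id.
#' @return Logical scalar.
#' @export
topologically_activated <- function(net, seeds, r) {
  rx <- .get_reaction(net, r)
  sc <- compute_scope(net, seeds)
  all(names(rx$reactants) %in% sc$activated_metabolites)
}

# Candidate metabolites shared by the sustainability enumeration: members of
# the scope that are consumed by at least one reaction and are neither seeds
# nor reactants of the target.
.sustainability_candidates <- function(net, seeds, target) {
  sc <- compute_scope(net, seeds)
  consumed <- unique(unlist(lapply(net$reactions, function(r)
    names(r$reactants)), use.names = FALSE))
  .sort_ids(setdiff(intersect(sc$activated_metabolites, consumed),
               c(seeds, target$targeted_metabolites)))
}

.as_seeds <- function(net, seeds) {
  if (is.null(seeds)) seeds <- seed_set(net)
  if (inherits(seeds, "seed_set")) seeds <- seeds$seeds
  seeds
}

.as_target <- function(net, target) {
  if (is.null(target)) return(target_spec(net))
  if (inherits(target, "target_spec")) return(target)
  target_spec(net, target)
}

#' Sustainability-PEM enumeration
#'
#' A metabolite `m` (neither a seed nor a reactant of the target) is a
#' sustainability-PEM when the target reaction is topologically activated from
#' the seeds in the full network, but no longer activated once the network is
#' pruned with respect to `m` (all reactions consuming `m` removed). Each
#' candidate is checked by recomputing the scope of the pruned network.
#'
#' @param net A [metabolic_network()].
#' @param seeds A [seed_set()], character vector, or `NULL` (boundary seeds).
#' @param target A [target_spec()], reaction id, or `NULL` (network target).
#' @return Character vector of sustainability-PEM ids, sorted.
#' @examples
#' fx <- pem_fixture("fig2")
#' sustainability_pems(fx$network)  # "E"
#' @export
sustainability_pems <- function(net, seeds = NULL, target = NULL) {
  seeds <- .as_seeds(net, seeds)
  target <- .as_target(net, target)
  sc0 <- compute_scope(net, seeds)
  missing0 <- setdiff(target$targeted_metabolites, sc0$activated_metabolites)
  if (length(missing0) > 0L) {
    stop("target '", target$target_reaction_id,
         "' is not topologically activated from the seeds; ",
         "missing reactant(s): ", paste(missing0, collapse = ", "))
  }
  cands <- .sustainability_candidates(net, seeds, target)
  is_pem <- vapply(cands, function(m) {
    scm <- compute_scope(prune(net, m), seeds)
    !all(target$targeted_metabolites %in% scm$activated_metabolites)
  }, logical(1))
  cands[is_pem]
}

#' Target reactants blocked by pruning a metabolite
#'
#' Returns the reactants of the target reaction that leave the scope of the
#' seeds when the network is pruned with respect to `m`. The result is
#' non-empty exactly when `m` is a sustainability-PEM.
#'
#' @inheritParams sustainability_pems
#' @param m Metabolite id.
#' @return Character vector of blocked target reactants (possibly empty).
#' @export
blocked_targets <- function(net, seeds = NULL, target = NULL, m) {
  seeds <- .as_seeds(net, seeds)
  target <- .as_target(net, target)
  .check_metabolite(net, m)
  scm <- compute_scope(prune(net, m), seeds)
  .sort_ids(setdiff(target$targeted_metabolites, scm$activated_metabolites))
}
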