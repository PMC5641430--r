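# Locale-independent (C collation) ordering, so reports are byte-reproducible.
.sort_ids <- function(x) x[order(x, method = "radix")]

#' Build a reaction
#'
#' A reaction transforms reactants into products with positive stoichiometric
#' coefficients and carries a non-negative flux upper bound. Networks are kept
#' in canonical irreversible form: a biologically reversible reaction is
#' represented by two irreversible reactions that mirror each other
#' (see [metabolic_network()], field `reverse_of`).
#'
#' @param id Unique reaction identifier.
#' @param reactants Named numeric vector of reactant coefficients (all > 0);
#'   names are metabolite ids. May be empty (a boundary/inflow reaction).
#' @param products Named numeric vector of product coefficients (all > 0).
#' @param upper_bound Non-negative flux upper bound (e.g. mmol/gDW/h).
#' @return A list of class `"pem_reaction"`.
#' @examples
#' reaction("r4", reactants = c(E = 1), products = c(C = 2), upper_bound = 10)
#' @export
reaction <- function(id, reactants = numeric(0), products = numeric(0),
                     upper_bound = 1000) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  reactants <- .check_side(reactants, id, "reactants")
  products <- .check_side(products, id, "products")
  if (!is.numeric(upper_bound) || length(upper_bound) != 1L ||
      is.na(upper_bound) || upper_bound < 0 || !is.finite(upper_bound)) {
    stop("reaction '", id, "': upper_bound must be a finite non-negative number")
  }
  structure(
    list(id = id, reactants = reactants, products = products,
         upper_bound = as.numeric(upper_bound), reverse_of = NA_character_),
    class = "pem_reaction"
  )
}

.check_side <- function(x, id, what) {
  if (length(x) == 0L) return(stats::setNames(numeric(0), character(0)))
  if (!is.numeric(x) || is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("reaction '", id, "': ", what, " must be a named numeric vector")
  }
  if (anyDuplicated(names(x))) {
    stop("reaction '", id, "': duplicated metabolite in ", what)
  }
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("reaction '", id, "': all ", what, " coefficients must be > 0")
  }
  storage.mode(x) <- "double"
  x[order(names(x), method = "radix")]
}

#' Assemble a stoichiometric metabolic network
#'
#' Builds the directed bipartite reaction/metabolite graph used throughout the
#' package. Metabolites are inferred from the reactions unless given
#' explicitly; mirror pairs of irreversible reactions (identical reactants and
#' products swapped, equal coefficients up to `1e-9`) are detected and linked
#' through `reverse_of`, which realises the set of reversible reactions of the
#' system.
#'
#' @param reactions List of [reaction()] objects.
#' @param target Reaction id of the targeted reaction (usually biomass). May be
#'   `NA` for networks used without a target.
#' @param metabolites Optional data frame with columns `id`, and optionally
#'   `name`, `compartment` and `boundary_condition` (logical; species excluded
#'   from the mass-balance rows). Defaults are derived from the reactions.
#' @return An object of class `"metabolic_network"` with elements
#'   `metabolites` (data frame), `reactions` (named list) and `target`.
#' @export
metabolic_network <- function(reactions, target = NA_character_,
                              metabolites = NULL) {
  stopifnot(is.list(reactions), length(reactions) > 0L)
  ids <- vapply(reactions, function(r) r$id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicated reaction id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(reactions) <- ids
  reactions <- reactions[order(ids, method = "radix")]

  used <- .sort_ids(unique(unlist(lapply(reactions, function(r)
    c(names(r$reactants), names(r$products))), use.names = FALSE)))
  if (is.null(metabolites)) {
    metabolites <- data.frame(id = used, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(metabolites), "id" %in% names(metabolites))
  if (anyDuplicated(metabolites$id)) stop("duplicated metabolite id(s)")
  if (!all(used %in% metabolites$id)) {
    stop("reaction references unknown metabolite(s): ",
         paste(setdiff(used, metabolites$id), collapse = ", "))
  }
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$compartment)) metabolites$compartment <- NA_character_
  if (is.null(metabolites$boundary_condition)) {
    metabolites$boundary_condition <- FALSE
  }
  metabolites <- metabolites[order(metabolites$id, method = "radix"),
                             c("id", "name", "compartment",
                               "boundary_condition")]
  rownames(metabolites) <- NULL

  if (!is.na(target) && !target %in% names(reactions)) {
    stop("target reaction '", target, "' not found in the network")
  }

  net <- structure(
    list(metabolites = metabolites, reactions = reactions, target = target),
    class = "metabolic_network"
  )
  net$reactions <- .link_reverse_pairs(net$reactions)
  net
}

# Structural detection of reversible pairs: r belongs to the reversible set iff
# some other reaction mirrors its reactants/products with equal coefficients.
# Pairs are matched greedily in lexicographic id order.
.link_reverse_pairs <- function(reactions, tol = 1e-9) {
  key <- function(side) {
    paste(names(side), formatC(side, digits = 12, format = "g"),
          sep = ":", collapse = ";")
  }
  fwd <- vapply(reactions, function(r) paste(key(r$reactants), "->",
                                             key(r$products)), character(1))
  bwd <- vapply(reactions, function(r) paste(key(r$products), "->",
                                             key(r$reactants)), character(1))
  for (r in names(reactions)) reactions[[r]]$reverse_of <- NA_character_
  taken <- character(0)
  for (r in names(reactions)) {
    if (r %in% taken) next
    if (length(reactions[[r]]$reactants) == 0L &&
        length(reactions[[r]]$products) == 0L) next
    cand <- setdiff(names(reactions)[bwd == fwd[[r]]], c(r, taken))
    if (length(cand) > 0L) {
      partner <- cand[[1L]]
      reactions[[r]]$reverse_of <- partner
      reactions[[partner]]$reverse_of <- r
      taken <- c(taken, r, partner)
    }
  }
  reactions
}

#' @export
print.metabolic_network <- function(x, ...) {
  n_rev <- sum(!is.na(vapply(x$reactions, `[[`, character(1), "reverse_of")))
  cat("Stoichiometric metabolic network\n")
  cat("  metabolites:", nrow(x$metabolites),
      sprintf("(%d boundary-condition)", sum(x$metabolites$boundary_condition)),
      "\n")
  cat("  reactions:  ", length(x$reactions),
      sprintf("(%d in reversible pairs)", n_rev), "\n")
  cat("  target:     ", x$target, "\n")
  invisible(x)
}

#' Reactant and product sets of a reaction
#'
#' @param net A [metabolic_network()].
#' @param r Reaction id.
#' @return Character vector of metabolite ids, in lexicographic order.
#' @export
reactants <- function(net, r) {
  names(.get_reaction(net, r)$reactants)
}

#' @rdname reactants
#' @export
products <- function(net, r) {
  names(.get_reaction(net, r)$products)
}

.get_reaction <- function(net, r) {
  stopifnot(inherits(net, "metabolic_network"))
  if (!r %in% names(net$reactions)) {
    stop("unknown reaction id '", r, "'")
  }
  net$reactions[[r]]
}

.check_metabolite <- function(net, m) {
  if (!all(m %in% net$metabolites$id)) {
    stop("unknown metabolite id(s): ",
         paste(setdiff(m, net$metabolites$id), collapse = ", "))
  }
  invisible(m)
}

#' Boundary seeds of a network
#'
#' Boundary seeds are the products of reactant-free reactions: their production
#' is intrinsically assumed to be activated, so they behave as inputs of the
#' system. Species flagged `boundary_condition` in the SBML sense are also
#' reported as boundary seeds.
#'
#' @param net A [metabolic_network()].
#' @return Character vector of metabolite ids in lexicographic order.
#' @examples
#' fx <- pem_fixture("fig1")
#' boundary_seeds(fx$network)  # S1, S2 and H
#' @export
boundary_seeds <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  from_rxn <- unlist(lapply(net$reactions, function(r) {
    if (length(r$reactants) == 0L) names(r$products) else character(0)
  }), use.names = FALSE)
  flagged <- net$metabolites$id[net$metabolites$boundary_condition]
  .sort_ids(unique(c(from_rxn, flagged)))
}

#' Seed set of a network
#'
#' The nutrients assumed present in the initial state of the system. All
#' boundary seeds of the network are included by default (the standing
#' assumption of the scope semantics); explicit seeds may `"extend"` them
#' (default) or `"replace"` them.
#'
#' @param net A [metabolic_network()].
#' @param seeds Optional character vector of additional seed metabolite ids.
#' @param mode Either `"extend"` (boundary seeds plus `seeds`) or `"replace"`
#'   (`seeds` only).
#' @return An object of class `"seed_set"`: list with `seeds` and
#'   `boundary_seeds`.
#' @export
seed_set <- function(net, seeds = NULL, mode = c("extend", "replace")) {
  mode <- match.arg(mode)
  sb <- boundary_seeds(net)
  if (!is.null(seeds)) .check_metabolite(net, seeds)
  s <- if (mode == "extend") union(sb, seeds) else unique(seeds)
  structure(list(seeds = .sort_ids(s), boundary_seeds = sb), class = "seed_set")
}

#' Target specification
#'
#' The targeted metabolic compounds are the reactants of the targeted reaction.
#'
#' @param net A [metabolic_network()].
#' @param target Reaction id; defaults to the network's stored target.
#' @return An object of class `"target_spec"`: list with `target_reaction_id`
#'   and `targeted_metabolites`.
#' @export
target_spec <- function(net, target = net$target) {
  if (is.na(target)) stop("no target reaction set for this network")
  r <- .get_reaction(net, target)
  structure(list(target_reaction_id = target,
                 targeted_metabolites = names(r$reactants)),
            class = "target_spec")
}

#' Degree of connectivity of a metabolite
#'
#' Number of distinct reactions that consume or produce the metabolite. A
#' reversible pair (two mirror irreversible reactions) counts as one reaction,
#' so degrees refer to the biological reaction rather than its directional
#' split.
#'
#' @param net A [metabolic_network()].
#' @param m Metabolite id (vectorised).
#' @return Integer vector of degrees, named by metabolite id.
#' @export
connectivity <- function(net, m = net$metabolites$id) {
  stopifnot(inherits(net, "metabolic_network"))
  .check_metabolite(net, m)
  # collapse each reversible pair under a single key
  grp <- vapply(net$reactions, function(r) {
    if (is.na(r$reverse_of)) r$id else min(r$id, r$reverse_of)
  }, character(1))
  touch <- lapply(net$reactions, function(r)
    unique(c(names(r$reactants), names(r$products))))
  deg <- vapply(m, function(mi) {
    hit <- vapply(touch, function(tt) mi %in% tt, logical(1))
    length(unique(grp[hit]))
  }, integer(1))
  stats::setNames(as.integer(deg), m)
}

#' Prune a network with respect to a metabolite
#'
#' Removes every reaction that consumes `m`, including both directions of any
#' reversible pair whose members consume or produce `m` (a reversible producer
#' of `m` is the mirror of a consumer). The metabolite set is unchanged and the
#' input network is not modified.
#'
#' @param net A [metabolic_network()].
#' @param m Metabolite id.
#' @return A new `"metabolic_network"` in which no remaining reaction has `m`
#'   among its reactants.
#' @examples
#' fx <- pem_fixture("fig2")
#' pruned <- prune(fx$network, "E")   # drops r6, the sole consumer of E
#' @export
prune <- function(net, m) {
  stopifnot(inherits(net, "metabolic_network"), length(m) == 1L)
  .check_metabolite(net, m)
  drop <- vapply(net$reactions, function(r) {
    m %in% names(r$reactants) ||
      (!is.na(r$reverse_of) && m %in% names(r$products))
  }, logical(1))
  keep <- net$reactions[!drop]
  if (length(keep) == 0L) {
    stop("pruning w.r.t. '", m, "' removes every reaction in the network")
  }
  out <- net
  out$reactions <- .link_reverse_pairs(keep)
  if (!is.na(out$target) && !out$target %in% names(out$reactions)) {
    out$target <- NA_character_
  }
  out
}

#' Stoichiometric matrix of a network
#'
#' Rows are internal metabolites (species flagged `boundary_condition` are
#' excluded from mass balance), columns are the irreversible reactions in
#' lexicographic order; entries are net stoichiometric coefficients (products
#' positive, reactants negative).
#'
#' @param net A [metabolic_network()].
#' @return A dense numeric matrix with dimnames (metabolites x reactions).
#' @export
stoichiometric_matrix <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  mets <- net$metabolites$id[!net$metabolites$boundary_condition]
  rxns <- names(net$reactions)
  S <- matrix(0, nrow = length(mets), ncol = length(rxns),
              dimnames = list(mets, rxns))
  for (r in rxns) {
    rx <- net$reactions[[r]]
    pr <- rx$products[names(rx$products) %in% mets]
    rc <- rx$reactants[names(rx$reactants) %in% mets]
    if (length(pr)) S[names(pr), r] <- S[names(pr), r] + pr
    if (length(rc)) S[names(rc), r] <- S[names(rc), r] - rc
  }
  S
}

#' Upper bounds of all reactions
#'
#' @param net A [metabolic_network()].
#' @return Named numeric vector in lexicographic reaction order.
#' @export
upper_bounds <- function(net) {
  vapply(net$reactions, `[[`, numeric(1), "upper_bound")
}
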