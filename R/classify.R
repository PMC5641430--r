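#' Classify the metabolites of a network as phenotypic essential metabolites
#'
#' Runs the three enumerations — [sustainability_pems()] (graph-based scope),
#' [producibility_pems()] (steady-state flux) and [optimal_efficiency_pems()]
#' (knockouts against the maximal target flux) — and combines them into a
#' per-metabolite classification with the seven-region overlap partition and a
#' functional role for every compound.
#'
#' Roles follow the precedence seed > target > PEM > other: a compound that is
#' a seed is reported as seed even when the optimal-efficiency set contains it
#' (the sustainability and producibility definitions already exclude seeds and
#' target reactants; the optimal-efficiency definition deliberately does not).
#'
#' If the target is not topologically activated the sustainability flags are
#' `NA`; if it carries no flux the two flux-based sets are empty; both cases
#' produce a warning and a partial classification.
#'
#' @param net A [metabolic_network()].
#' @param seeds A [seed_set()], character vector of metabolite ids, or `NULL`
#'   to use the boundary seeds of the network.
#' @param target A [target_spec()], reaction id, or `NULL` for the network
#'   target.
#' @param eps Activation tolerance on fluxes (also used as the absolute and
#'   relative essentiality thresholds).
#' @return An object of class `"pem_classification"`: list with
#'   `metabolites` (data frame: id, connectivity, sustainability,
#'   producibility, optimal_efficiency, venn_region, role), `sets` (the three
#'   PEM sets and the essential reactions), `mu_star` (maximal target flux),
#'   `scope_size`, `network`, `seeds`, `target`.
#' @examples
#' fx <- pem_fixture("fig2")
#' cl <- classify_pems(fx$network)
#' summary(cl)
#' @export
classify_pems <- function(net, seeds = NULL, target = NULL, eps = 1e-6) {
  stopifnot(inherits(net, "metabolic_network"))
  if (is.null(seeds)) seeds <- seed_set(net)
  if (!inherits(seeds, "seed_set")) seeds <- seed_set(net, seeds, mode = "extend")
  target <- .as_target(net, target)

  sc <- compute_scope(net, seeds$seeds)
  topo_ok <- all(target$targeted_metabolites %in% sc$activated_metabolites)
  mu0 <- max_flux(net, target$target_reaction_id)
  mu_star <- if (identical(mu0$status, "optimal")) mu0$objective_value else 0
  flux_ok <- mu_star > eps

  s_set <- character(0)
  if (topo_ok) {
    s_set <- sustainability_pems(net, seeds, target)
  } else {
    warning("target '", target$target_reaction_id,
            "' is not topologically activated; sustainability flags are NA")
  }
  p_set <- character(0)
  o_set <- character(0)
  ess <- character(0)
  if (flux_ok) {
    p_set <- producibility_pems(net, seeds, target, eps = eps)
    ess <- essential_reactions(net, target, delta = eps, rho = eps)
    o_set <- optimal_efficiency_pems(net, target, delta = eps, rho = eps)
  } else {
    warning("target '", target$target_reaction_id,
            "' carries no flux; producibility and optimal-efficiency sets ",
            "are empty")
  }

  ids <- net$metabolites$id
  su <- if (topo_ok) ids %in% s_set else rep(NA, length(ids))
  pr <- ids %in% p_set
  oe <- ids %in% o_set
  tab <- data.frame(
    id = ids,
    connectivity = unname(connectivity(net, ids)),
    sustainability = su,
    producibility = pr,
    optimal_efficiency = oe,
    venn_region = .venn_region(su, pr, oe),
    role = .pem_role(ids, su, pr, oe, seeds, target),
    stringsAsFactors = FALSE
  )
  structure(
    list(metabolites = tab,
         sets = list(sustainability = s_set, producibility = p_set,
                     optimal_efficiency = o_set, essential_reactions = ess),
         mu_star = mu_star, scope_size = length(sc$activated_metabolites),
         network = net, seeds = seeds, target = target),
    class = "pem_classification"
  )
}

.venn_region <- function(su, pr, oe) {
  su0 <- ifelse(is.na(su), FALSE, su)
  key <- paste0(ifelse(su0, "S", ""), ifelse(pr, "P", ""), ifelse(oe, "O", ""))
  out <- c(S = "S-only", P = "P-only", O = "O-only", SP = "SP", SO = "SO",
           PO = "PO", SPO = "SPO")[key]
  out[is.na(out)] <- "none"
  unname(out)
}

.pem_role <- function(ids, su, pr, oe, seeds, target) {
  any_pem <- ifelse(is.na(su), FALSE, su) | pr | oe
  role <- ifelse(ids %in% seeds$seeds, "seed",
          ifelse(ids %in% target$targeted_metabolites, "target",
          ifelse(any_pem, "PEM", "other")))
  role
}

#' @export
print.pem_classification <- function(x, ...) {
  cat("PEM classification (target:", x$target$target_reaction_id, ")\n")
  cat(sprintf("  maximal target flux: %g\n", x$mu_star))
  cat(sprintf("  sustainability-PEMs: %d | producibility-PEMs: %d | optimal-efficiency-PEMs: %d\n",
              length(x$sets$sustainability), length(x$sets$producibility),
              length(x$sets$optimal_efficiency)))
  pem <- x$metabolites[x$metabolites$venn_region != "none", ]
  if (nrow(pem) > 0L) {
    cat("  regions:\n")
    print(table(pem$venn_region))
  }
  invisible(x)
}

#' Network-level PEM summary
#'
#' Counts of reactions (reversible pairs collapsed), metabolites, the PEM
#' union and the three classes, with percentages relative to the total
#' metabolite count of the network.
#'
#' @param object A `"pem_classification"`.
#' @param ... Unused.
#' @return A data frame of class `"pem_summary"` with one row: counts and
#'   `pct_*` percentage columns.
#' @export
summary.pem_classification <- function(object, ...) {
  tab <- object$metabolites
  flags <- cbind(
    sustainability = ifelse(is.na(tab$sustainability), FALSE,
                            tab$sustainability),
    producibility = tab$producibility,
    optimal_efficiency = tab$optimal_efficiency
  )
  grp <- vapply(object$network$reactions, function(r) {
    if (is.na(r$reverse_of)) r$id else min(r$id, r$reverse_of)
  }, character(1))
  .pem_summary_counts(flags, n_metabolites = nrow(tab),
                      n_reactions = length(unique(grp)))
}

# Table-style summary arithmetic, shared with the multi-network report path.
.pem_summary_counts <- function(flags, n_metabolites, n_reactions = NA_integer_) {
  n_union <- sum(rowSums(flags) > 0L)
  n_s <- sum(flags[, "sustainability"])
  n_p <- sum(flags[, "producibility"])
  n_o <- sum(flags[, "optimal_efficiency"])
  pct <- function(k) if (n_metabolites > 0) 100 * k / n_metabolites else 0
  structure(
    data.frame(
      reactions = n_reactions, metabolites = n_metabolites,
      pems = n_union, sustainability = n_s, producibility = n_p,
      optimal_efficiency = n_o,
      pct_pems = pct(n_union), pct_sustainability = pct(n_s),
      pct_producibility = pct(n_p), pct_optimal_efficiency = pct(n_o)
    ),
    class = c("pem_summary", "data.frame")
  )
}

#' @export
print.pem_summary <- function(x, ...) {
  cat("Network PEM summary\n")
  cat(sprintf("  reactions: %s | metabolites: %d\n",
              ifelse(is.na(x$reactions), "?", x$reactions), x$metabolites))
  cat(sprintf("  PEMs: %d (%.1f%%)  S: %d (%.1f%%)  P: %d (%.1f%%)  O: %d (%.1f%%)\n",
              x$pems, x$pct_pems, x$sustainability, x$pct_sustainability,
              x$producibility, x$pct_producibility, x$optimal_efficiency,
              x$pct_optimal_efficiency))
  invisible(x)
}

#' Connectivity-degree versus functional-role table
#'
#' Bins metabolites by degree of connectivity and cross-tabulates the bins
#' against the functional roles (PEM, seed, target, other). Supports the check
#' that the most highly connected compounds are all PEMs, seeds or biomass
#' components.
#'
#' @param classification A `"pem_classification"`.
#' @param bin_edges Strictly increasing integer vector of bin edges; bins are
#'   `[e1,e2), [e2,e3), ...` with the last bin closed on the right.
#' @return Data frame with one row per non-empty bin: `bin`, per-role counts
#'   (`n_PEM`, `n_seed`, `n_target`, `n_other`), total `n`, and per-role
#'   percentages summing to 100 within each bin.
#' @export
degree_role_table <- function(classification, bin_edges) {
  stopifnot(inherits(classification, "pem_classification"),
            length(bin_edges) >= 2L, all(diff(bin_edges) > 0))
  tab <- classification$metabolites
  bins <- cut(tab$connectivity, breaks = bin_edges, right = FALSE,
              include.lowest = TRUE,
              labels = paste0("[", utils::head(bin_edges, -1L), ",",
                              utils::tail(bin_edges, -1L), ")"))
  roles <- factor(tab$role, levels = c("PEM", "seed", "target", "other"))
  keep <- !is.na(bins)
  ct <- table(bins[keep], roles[keep])
  out <- data.frame(bin = rownames(ct),
                    n_PEM = as.integer(ct[, "PEM"]),
                    n_seed = as.integer(ct[, "seed"]),
                    n_target = as.integer(ct[, "target"]),
                    n_other = as.integer(ct[, "other"]))
  out$n <- rowSums(out[, c("n_PEM", "n_seed", "n_target", "n_other")])
  out <- out[out$n > 0L, , drop = FALSE]
  for (rl in c("PEM", "seed", "target", "other")) {
    out[[paste0("pct_", rl)]] <- 100 * out[[paste0("n_", rl)]] / out$n
  }
  rownames(out) <- NULL
  out
}

#' Cross-network PEM skeleton
#'
#' Metabolites that carry all three PEM properties (region SPO) in every one
#' of several classified networks, e.g. several reconstructions of the same
#' organism. Identifiers are compared in the namespace of the first
#' classification; supply `id_mapping` when the networks do not share a
#' metabolite namespace.
#'
#' @param classifications List of two or more `"pem_classification"` objects.
#' @param id_mapping Optional data frame with one column per classification
#'   (in the same order); each row maps corresponding metabolite ids. `NULL`
#'   means the networks share one namespace.
#' @return Character vector of skeleton metabolite ids (namespace of the first
#'   classification), sorted.
#' @export
skeleton_pems <- function(classifications, id_mapping = NULL) {
  stopifnot(is.list(classifications), length(classifications) >= 2L,
            all(vapply(classifications, inherits, logical(1),
                       "pem_classification")))
  spo <- lapply(classifications, function(cl) {
    cl$metabolites$id[cl$metabolites$venn_region == "SPO"]
  })
  if (!is.null(id_mapping)) {
    stopifnot(is.data.frame(id_mapping),
              ncol(id_mapping) == length(classifications))
    if (nrow(id_mapping) == 0L) stop("empty id mapping")
    spo <- lapply(seq_along(spo), function(i) {
      id_mapping[[1L]][id_mapping[[i]] %in% spo[[i]]]
    })
  }
  out <- Reduce(intersect, spo)
  if (length(out) == 0L && is.null(id_mapping)) {
    shared <- Reduce(intersect, lapply(classifications, function(cl)
      cl$metabolites$id))
    if (length(shared) == 0L) {
      stop("networks share no metabolite ids; supply an id_mapping")
    }
  }
  .sort_ids(out)
}

#' Plot a PEM classification
#'
#' Stacked barplot of functional roles per connectivity bin (the
#' connectivity-versus-role view of [degree_role_table()]).
#'
#' @param x A `"pem_classification"`.
#' @param bin_edges Bin edges; defaults to powers of two covering the degrees.
#' @param ... Passed to [graphics::barplot()].
#' @return The degree-role table, invisibly.
#' @export
plot.pem_classification <- function(x, bin_edges = NULL, ...) {
  if (is.null(bin_edges)) {
    top <- max(x$metabolites$connectivity, 1L)
    bin_edges <- unique(c(0L, 2L^(0:ceiling(log2(top + 1))), top + 1L))
  }
  drt <- degree_role_table(x, bin_edges)
  h <- t(as.matrix(drt[, c("pct_PEM", "pct_seed", "pct_target", "pct_other")]))
  colnames(h) <- drt$bin
  graphics::barplot(h, col = c("steelblue", "seagreen", "firebrick", "gold"),
                    ylab = "% of compounds in bin",
                    xlab = "degree of connectivity",
                    legend.text = c("PEM", "seed", "target", "other"), ...)
  invisible(drt)
}

#' Write classification reports
#'
#' Writes the per-metabolite classification (TSV), the network summary (TSV)
#' and the overlap-region counts (JSON) into a directory.
#'
#' @param classification A `"pem_classification"`.
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_pem_report <- function(classification, dir) {
  stopifnot(inherits(classification, "pem_classification"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f1 <- file.path(dir, "classification.tsv")
  tab <- classification$metabolites
  blocked <- vapply(tab$id, function(m) {
    if (!isTRUE(tab$sustainability[tab$id == m])) return("")
    paste(blocked_targets(classification$network, classification$seeds,
                          classification$target, m), collapse = ";")
  }, character(1))
  tab$blocked_target_metabolites <- blocked
  utils::write.table(tab, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  f2 <- file.path(dir, "summary.tsv")
  utils::write.table(summary(classification), f2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  f3 <- file.path(dir, "venn.json")
  regions <- table(factor(tab$venn_region,
                          levels = c("S-only", "P-only", "O-only", "SP", "SO",
                                     "PO", "SPO", "none")))
  jsonlite::write_json(as.list(regions), f3, auto_unbox = TRUE)
  invisible(c(f1, f2, f3))
}
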