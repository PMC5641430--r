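#' Read a metabolic network from SBML
#'
#' Parses SBML Level 2 or Level 3 (with or without the fbc extension) into the
#' canonical irreversible form: every SBML-reversible reaction (attribute
#' `reversible="true"`, or a negative lower flux bound) is split into a
#' forward/backward pair (`<id>` and `<id>_rev`) linked through `reverse_of`.
#' Flux bounds are taken from fbc bound parameters when present, else from the
#' COBRA-style `UPPER_BOUND`/`LOWER_BOUND` kineticLaw parameters, else a
#' default cap of 1000 applies; the backward upper bound is `|lower bound|`
#' when explicit bounds exist, else equals the forward bound.
#'
#' Boundary seeds are species flagged `boundaryCondition="true"` plus any
#' product of a reactant-free reaction.
#'
#' @param path Path to an SBML file.
#' @param target_id Reaction id of the targeted reaction in the file.
#' @param seed_override Optional character vector of additional seed
#'   metabolite ids.
#' @param seed_mode `"extend"` (default: boundary seeds plus overrides) or
#'   `"replace"` (overrides only).
#' @param default_ub Upper bound used when the file states none.
#' @return A list with elements `network` (a [metabolic_network()]), `seeds`
#'   (a [seed_set()]) and `target` (a [target_spec()]).
#' @export
read_sbml <- function(path, target_id, seed_override = NULL,
                      seed_mode = c("extend", "replace"), default_ub = 1000) {
  seed_mode <- match.arg(seed_mode)
  if (!file.exists(path)) stop("SBML file not found: '", path, "'")
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed SBML in '", path, "': ",
                                           conditionMessage(e)))

  sp_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  if (length(sp_nodes) == 0L) stop("malformed SBML in '", path, "': no species")
  species <- data.frame(
    id = xml2::xml_attr(sp_nodes, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp_nodes, "name")),
                  xml2::xml_attr(sp_nodes, "id"),
                  xml2::xml_attr(sp_nodes, "name")),
    compartment = xml2::xml_attr(sp_nodes, "compartment"),
    boundary_condition =
      tolower(xml2::xml_attr(sp_nodes, "boundaryCondition")) %in% "true",
    stringsAsFactors = FALSE
  )

  # global parameters (fbc flux-bound values live here)
  par_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  pars <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                          xml2::xml_attr(par_nodes, "id"))

  rx_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (length(rx_nodes) == 0L) stop("malformed SBML in '", path, "': no reactions")

  fbc_attr <- function(node, what) {
    at <- xml2::xml_attrs(node)
    hit <- grepl(paste0("(^|:)", what, "$"), names(at))
    if (any(hit)) at[[which(hit)[1L]]] else NA_character_
  }
  side <- function(node, which) {
    refs <- xml2::xml_find_all(
      node, sprintf("./*[local-name()='%s']/*[local-name()='speciesReference']",
                    which))
    if (length(refs) == 0L) return(stats::setNames(numeric(0), character(0)))
    st <- xml2::xml_attr(refs, "stoichiometry")
    st <- ifelse(is.na(st), 1, as.numeric(st))     # SBML default stoichiometry
    sp <- xml2::xml_attr(refs, "species")
    out <- tapply(st, sp, sum)                     # merge duplicate refs
    stats::setNames(as.numeric(out), names(out))
  }

  rxns <- list()
  for (node in rx_nodes) {
    rid <- xml2::xml_attr(node, "id")
    rev_attr <- xml2::xml_attr(node, "reversible")
    reversible <- is.na(rev_attr) || tolower(rev_attr) == "true"  # L2 default
    rcts <- side(node, "listOfReactants")
    prds <- side(node, "listOfProducts")

    lb <- ub <- NA_real_
    ub_ref <- fbc_attr(node, "upperFluxBound")
    lb_ref <- fbc_attr(node, "lowerFluxBound")
    if (!is.na(ub_ref) && ub_ref %in% names(pars)) ub <- pars[[ub_ref]]
    if (!is.na(lb_ref) && lb_ref %in% names(pars)) lb <- pars[[lb_ref]]
    if (is.na(ub) || is.na(lb)) {
      kl <- xml2::xml_find_all(node, ".//*[local-name()='kineticLaw']//*[local-name()='parameter']")
      if (length(kl) > 0L) {
        kid <- xml2::xml_attr(kl, "id")
        kid[is.na(kid)] <- xml2::xml_attr(kl, "name")[is.na(kid)]
        kv <- as.numeric(xml2::xml_attr(kl, "value"))
        if (is.na(ub) && "UPPER_BOUND" %in% kid) ub <- kv[match("UPPER_BOUND", kid)]
        if (is.na(lb) && "LOWER_BOUND" %in% kid) lb <- kv[match("LOWER_BOUND", kid)]
      }
    }
    had_bounds <- !is.na(ub) || !is.na(lb)
    if (is.na(ub)) ub <- default_ub
    if (!is.na(lb) && lb < 0) reversible <- TRUE
    if (!is.na(lb) && lb >= 0) reversible <- FALSE

    fwd <- reaction(rid, rcts, prds, upper_bound = max(ub, 0))
    rxns[[length(rxns) + 1L]] <- fwd
    if (reversible && (length(rcts) > 0L || length(prds) > 0L)) {
      bub <- if (had_bounds && !is.na(lb)) abs(lb) else max(ub, 0)
      rxns[[length(rxns) + 1L]] <- reaction(paste0(rid, "_rev"), prds, rcts,
                                            upper_bound = bub)
    }
  }

  rids <- vapply(rxns, `[[`, character(1), "id")
  if (!target_id %in% rids) {
    stop("target reaction '", target_id, "' not found in '", path, "'")
  }
  net <- metabolic_network(rxns, target = target_id, metabolites = species)
  if (!is.null(seed_override)) {
    bad <- setdiff(seed_override, net$metabolites$id)
    if (length(bad) > 0L) {
      stop("unknown seed id(s) in seed_override: ", paste(bad, collapse = ", "))
    }
  }
  seeds <- seed_set(net, seeds = seed_override, mode = seed_mode)
  list(network = net, seeds = seeds, target = target_spec(net))
}

#' Write a network to SBML
#'
#' Writes the canonical irreversible form as SBML Level 3 Version 1 with the
#' fbc extension: every reaction is emitted with `reversible="false"`, a zero
#' lower flux bound and its own upper-bound parameter. Reading the file back
#' with [read_sbml()] reproduces the network (reversible pairs are re-detected
#' structurally).
#'
#' @param net A [metabolic_network()].
#' @param path Output file path.
#' @param model_id Model id attribute.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(net, path, model_id = "model") {
  stopifnot(inherits(net, "metabolic_network"))
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    "xmlns:fbc" = "http://www.sbml.org/sbml/level3/version1/fbc/version2",
    level = "3", version = "1", "fbc:required" = "false"
  )
  model <- xml2::xml_add_child(doc, "model", id = model_id,
                               "fbc:strict" = "true")
  comps <- unique(net$metabolites$compartment)
  comps[is.na(comps)] <- "c"
  loc <- xml2::xml_add_child(model, "listOfCompartments")
  for (cp in unique(comps)) {
    xml2::xml_add_child(loc, "compartment", id = cp, constant = "true")
  }
  los <- xml2::xml_add_child(model, "listOfSpecies")
  for (i in seq_len(nrow(net$metabolites))) {
    m <- net$metabolites[i, ]
    xml2::xml_add_child(
      los, "species", id = m$id, name = m$name,
      compartment = if (is.na(m$compartment)) "c" else m$compartment,
      boundaryCondition = tolower(as.character(m$boundary_condition)),
      hasOnlySubstanceUnits = "false", constant = "false"
    )
  }
  lop <- xml2::xml_add_child(model, "listOfParameters")
  xml2::xml_add_child(lop, "parameter", id = "FB_zero", value = "0",
                      constant = "true")
  for (r in names(net$reactions)) {
    xml2::xml_add_child(lop, "parameter", id = paste0("FB_ub_", r),
                        value = format(net$reactions[[r]]$upper_bound,
                                       digits = 15),
                        constant = "true")
  }
  lor <- xml2::xml_add_child(model, "listOfReactions")
  add_side <- function(rnode, side, which) {
    if (length(side) == 0L) return(invisible())
    ls <- xml2::xml_add_child(rnode, which)
    for (m in names(side)) {
      xml2::xml_add_child(ls, "speciesReference", species = m,
                          stoichiometry = format(side[[m]], digits = 15),
                          constant = "true")
    }
  }
  for (r in names(net$reactions)) {
    rx <- net$reactions[[r]]
    rnode <- xml2::xml_add_child(
      lor, "reaction", id = rx$id, reversible = "false", fast = "false",
      "fbc:lowerFluxBound" = "FB_zero",
      "fbc:upperFluxBound" = paste0("FB_ub_", rx$id)
    )
    add_side(rnode, rx$reactants, "listOfReactants")
    add_side(rnode, rx$products, "listOfProducts")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Write the bipartite edge list of a network
#'
#' Tab-separated columns: `reaction_id`, `metabolite_id`, `role`
#' (reactant/product), `coefficient`; rows in lexicographic order.
#'
#' @param net A [metabolic_network()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "metabolic_network"))
  rows <- do.call(rbind, lapply(names(net$reactions), function(r) {
    rx <- net$reactions[[r]]
    rbind(
      if (length(rx$reactants))
        data.frame(reaction_id = r, metabolite_id = names(rx$reactants),
                   role = "reactant", coefficient = unname(rx$reactants)),
      if (length(rx$products))
        data.frame(reaction_id = r, metabolite_id = names(rx$products),
                   role = "product", coefficient = unname(rx$products))
    )
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
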