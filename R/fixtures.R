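#' Built-in toy-network fixtures
#'
#' Programmatic generators for the small metabolic networks used throughout
#' the documentation and tests. `fig1` and `fig2` are the didactic networks
#' illustrating the three activation semantics (including the reversible
#' r0/r1 pair, the 2C stoichiometry on r4 and the H/J coupling on r2 in
#' `fig1`); `fig4`, `fig5`, `fig6_motif`, `fig7_motif` and `fig8_motif` encode
#' the mechanisms behind the seven overlap regions (alternative pathway pairs,
#' optimal pathway choice, cycle initiation, internal cycles, co-product
#' export). The motif fixtures reproduce the described mechanism of the
#' corresponding genome-scale sub-networks, not their exact reaction sets.
#'
#' @param name One of `"fig1"`, `"fig2"`, `"fig2_bounds"`, `"fig4"`, `"fig5"`,
#'   `"fig6_motif"`, `"fig7_motif"`, `"fig8_motif"`, `"chain_n"`,
#'   `"random_small"`.
#' @param n Chain length for `"chain_n"` (number of internal reactions, >= 1).
#' @param seed Integer seed for `"random_small"`; the generated network is a
#'   deterministic function of it.
#' @param default_ub Default flux upper bound for fixture reactions.
#' @return A list of class `"pem_fixture"`: `name`, `network`
#'   (a [metabolic_network()]), `seeds` (a [seed_set()]) and `target`
#'   (a [target_spec()]).
#' @examples
#' fx <- pem_fixture("fig2")
#' fx$network
#' @export
pem_fixture <- function(name, n = 3L, seed = 1L, default_ub = 10) {
  name <- match.arg(name, c("fig1", "fig2", "fig2_bounds", "fig4", "fig5",
                            "fig6_motif", "fig7_motif", "fig8_motif",
                            "chain_n", "random_small"))
  ub <- default_ub
  rxn <- reaction
  net <- switch(
    name,
    fig1 = metabolic_network(list(
      rxn("r_S1", products = c(S1 = 1), upper_bound = ub),
      rxn("r_S2", products = c(S2 = 1), upper_bound = ub),
      rxn("r_H", products = c(H = 1), upper_bound = ub),
      rxn("r0", c(S2 = 1), c(B = 1), ub),           # reversible pair with r1
      rxn("r1", c(B = 1), c(S2 = 1), ub),
      rxn("r7", c(B = 1), c(C = 1), ub),
      rxn("r2", c(C = 1, H = 1), c(D = 1, J = 1), ub),
      rxn("r3", c(D = 1), c(E = 1), ub),
      rxn("r4", c(E = 1), c(C = 2), ub),            # 2C feeds the cycle + r_T
      rxn("r8", c(J = 1, S2 = 1), c(E = 1), ub),
      rxn("r6", c(S1 = 1), c(A = 1, G = 1), ub),
      rxn("r9", c(G = 1), c(F = 1), ub),
      rxn("r_e", c(F = 1), upper_bound = ub),
      rxn("r_T", c(A = 1, C = 1), upper_bound = ub)
    ), target = "r_T"),
    fig2 = ,
    fig2_bounds = metabolic_network(list(
      rxn("r_S", products = c(S = 1), upper_bound = ub),
      rxn("r1", c(S = 1), c(B = 1), ub),
      rxn("r8", c(B = 1), c(E = 1), ub),
      rxn("r7", c(S = 1), c(E = 1),
          if (name == "fig2_bounds") 1 else ub),
      rxn("r6", c(E = 1), c(C = 1, G = 1), ub),
      rxn("r9", c(G = 1), upper_bound = ub),
      rxn("r_T", c(C = 1), upper_bound = ub)
    ), target = "r_T"),
    fig4 = metabolic_network(list(
      rxn("r_S", products = c(bf6p = 1), upper_bound = ub),
      rxn("r1", c(bf6p = 1), c(bg6p = 1), ub),
      rxn("r2", c(bg6p = 1), c(ag6p = 1), ub),      # two alternative pairs
      rxn("r3", c(bg6p = 1), c(bg1p = 1), ub),
      rxn("r4", c(ag6p = 1), c(g1p = 1), ub),
      rxn("r5", c(bg1p = 1), c(g1p = 1), ub),
      rxn("r_T", c(g1p = 1), upper_bound = ub)
    ), target = "r_T"),
    fig5 = metabolic_network(list(
      rxn("r_arg", products = c(arg = 1), upper_bound = ub),
      rxn("r_pe", products = c(putr_e = 1), upper_bound = ub),
      rxn("r_imp", c(putr_e = 1), c(putr = 1), 1),  # low-capacity import
      rxn("r_adc", c(arg = 1), c(agm = 1), ub),
      rxn("r_agm", c(agm = 1), c(putr = 1, urea = 1), ub),
      rxn("r_ure", c(urea = 1), upper_bound = ub),  # co-product outlet
      rxn("r_T", c(putr = 1), upper_bound = 2 * ub)
    ), target = "r_T"),
    fig6_motif = {
      chain <- c("pyr", paste0("x", 1:9), "u1")
      rs <- c(list(rxn("r_pyr", products = c(pyr = 1), upper_bound = ub)),
              lapply(seq_len(10), function(i) {
                rxn(sprintf("r_ch%d", i - 1L),
                    stats::setNames(1, chain[i]),
                    stats::setNames(1, chain[i + 1L]), ub)
              }),
              list(rxn("r_k1", c(u1 = 1), c(u2 = 1), ub),
                   rxn("r_k2", c(u2 = 1), c(peptido = 1, u1 = 1), ub),
                   rxn("r_T", c(peptido = 1), upper_bound = ub)))
      metabolic_network(rs, target = "r_T")
    },
    fig7_motif = metabolic_network(list(
      rxn("r_thm", products = c(thm_p = 1), upper_bound = ub),
      rxn("r_imp", c(thm_p = 1), c(thm_c = 1), ub),
      rxn("r_tmp", c(thm_c = 1), c(tmp = 1), ub),
      rxn("r_w1", c(w1 = 1), c(w2 = 1), ub),        # internal cycle, seed-disconnected
      rxn("r_w2", c(w2 = 1), c(tmp = 1, w1 = 1), ub),
      rxn("r_T", c(tmp = 1), upper_bound = 2 * ub)
    ), target = "r_T"),
    fig8_motif = metabolic_network(list(
      rxn("r_m", products = c(m5p5p = 1), upper_bound = ub),
      rxn("r_mur", c(m5p5p = 1), c(m5px4p = 1, alaP = 1), ub),
      rxn("r_ex1", c(alaP = 1), upper_bound = ub),  # two export routes
      rxn("r_ex2", c(alaP = 1), c(ala_c = 1), ub),
      rxn("r_ex3", c(ala_c = 1), upper_bound = ub),
      rxn("r_T", c(m5px4p = 1), upper_bound = ub)
    ), target = "r_T"),
    chain_n = {
      stopifnot(n >= 1L)
      mets <- paste0("c", 0:n)
      rs <- c(list(rxn("r_b", products = c(c0 = 1), upper_bound = ub)),
              lapply(seq_len(n), function(i) {
                rxn(sprintf("r%03d", i), stats::setNames(1, mets[i]),
                    stats::setNames(1, mets[i + 1L]), ub)
              }),
              list(rxn("r_T", stats::setNames(1, mets[n + 1L]),
                       upper_bound = ub)))
      metabolic_network(rs, target = "r_T")
    },
    random_small = .random_small_network(seed)
  )
  structure(list(name = name, network = net, seeds = seed_set(net),
                 target = target_spec(net)),
            class = "pem_fixture")
}

#' @export
print.pem_fixture <- function(x, ...) {
  cat("Fixture '", x$name, "':\n", sep = "")
  print(x$network)
  invisible(x)
}

# Deterministic random small network: a handful of metabolites, one boundary
# inflow, random 1-2 reactant / 1-2 product reactions with small integer
# bounds, and a terminal sink as target. RNG state of the session is restored.
.random_small_network <- function(seed, n_met = 6L, n_rxn = 5L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  mets <- paste0("m", seq_len(n_met))
  rs <- list(reaction("r_b", products = stats::setNames(1, mets[1L]),
                      upper_bound = sample(1:3, 1L)))
  for (i in seq_len(n_rxn)) {
    nr <- sample(1:2, 1L)
    np <- sample(1:2, 1L)
    rct <- sample(mets, nr)
    prd <- sample(setdiff(mets, rct), np)
    coef_r <- stats::setNames(sample(1:2, nr, replace = TRUE), rct)
    coef_p <- stats::setNames(sample(1:2, np, replace = TRUE), prd)
    rs[[length(rs) + 1L]] <- reaction(sprintf("r%02d", i), coef_r, coef_p,
                                      upper_bound = sample(1:3, 1L))
  }
  tgt_met <- sample(mets, 1L)
  rs[[length(rs) + 1L]] <- reaction("r_T", stats::setNames(1, tgt_met),
                                    upper_bound = sample(1:3, 1L))
  metabolic_network(rs, target = "r_T")
}
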