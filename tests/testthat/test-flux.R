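test_that("maximal flux solves hand-checkable chains and respects bounds", {
  # linear chain with bottleneck: optimum is the minimum bound along the path
  net <- metabolic_network(list(
    reaction("r_b", products = c(A = 1), upper_bound = 5),
    reaction("r1", c(A = 1), c(B = 1), 3),
    reaction("r_T", c(B = 1), upper_bound = 10)
  ), target = "r_T")
  res <- max_flux(net)
  expect_identical(res$status, "optimal")
  expect_equal(res$objective_value, 3)
  expect_equal(unname(res$fluxes["r_T"]), 3)
  # a fixed flux outside the feasible polytope is infeasible
  res2 <- max_flux(net, fixed = c(r_T = 8))
  expect_identical(res2$status, "infeasible")
  expect_true(is.na(res2$objective_value))
})

test_that("optimal solutions are mass balanced on every internal metabolite", {
  for (nm in c("fig1", "fig2", "fig5", "fig6_motif", "fig7_motif")) {
    fx <- pem_fixture(nm)
    res <- max_flux(fx$network)
    S <- stoichiometric_matrix(fx$network)
    expect_lt(max(abs(S %*% res$fluxes[colnames(S)])), 1e-6, label = nm)
    ub <- upper_bounds(fx$network)
    expect_true(all(res$fluxes >= -1e-9 & res$fluxes <= ub + 1e-9))
  }
})

test_that("the LP optimum equals the basic-solution enumeration oracle", {
  for (sd in 1:15) {
    fx <- pem_fixture("random_small", seed = sd)
    mine <- max_flux(fx$network)$objective_value
    ref <- oracle_lp_max(fx$network, "r_T")
    expect_equal(mine, ref, tolerance = 1e-7,
                 info = paste("random seed", sd))
  }
  # small named fixtures too
  for (nm in c("fig2", "fig4", "fig8_motif")) {
    fx <- pem_fixture(nm)
    expect_equal(max_flux(fx$network)$objective_value,
                 oracle_lp_max(fx$network, "r_T"), tolerance = 1e-7,
                 info = nm)
  }
})

test_that("the FBA optimum matches cobrapy on an SBML export", {
  skip_if_not(has_cobra(), "python cobra unavailable")
  for (nm in c("fig1", "fig2_bounds", "fig5")) {
    fx <- pem_fixture(nm)
    f <- tempfile(fileext = ".xml")
    write_sbml(fx$network, f)
    expect_equal(max_flux(fx$network)$objective_value,
                 cobra_max_flux(f, "r_T"), tolerance = 1e-6, info = nm)
  }
})

test_that("stoichiometric activation distinguishes open and closed nutrients", {
  fx <- pem_fixture("fig1")
  # every reaction is activated when all inflows are open
  for (r in names(fx$network$reactions)) {
    expect_true(stoichiometrically_activated(fx$network, r), label = r)
  }
  # closing the S2 inflow forces v7 = v8 = 0 and removes all target flux
  net0 <- fx$network
  net0$reactions[["r_S2"]]$upper_bound <- 0
  expect_false(stoichiometrically_activated(net0, "r_T"))
  expect_equal(max_flux(net0)$objective_value, 0)
  expect_equal(fva(net0, "r7")$max_v, 0)
  expect_equal(fva(net0, "r8")$max_v, 0)
  # a reaction consuming an unproducible non-boundary metabolite is inactive
  net <- metabolic_network(list(reaction("r_b", products = c(A = 1), upper_bound = 5),
                                reaction("rx", c(Z = 1), c(A = 1), 5)))
  expect_false(stoichiometrically_activated(net, "rx"))
  # a zero-bound boundary reaction is inactive
  net2 <- metabolic_network(list(reaction("r_b", products = c(A = 1), upper_bound = 0),
                                 reaction("r_T", c(A = 1), upper_bound = 5)))
  expect_false(stoichiometrically_activated(net2, "r_b"))
})

test_that("producibility-PEMs cover lethal substrates and accumulation cases", {
  fx <- pem_fixture("fig2")
  expect_identical(producibility_pems(fx$network), c("E", "G"))
  # G qualifies through co-product accumulation: removing r9 blocks r6
  expect_false("S" %in% producibility_pems(fx$network))   # never a seed
  # multi-reaction essential metabolite (no single knockout is lethal)
  fx8 <- pem_fixture("fig8_motif")
  expect_identical(producibility_pems(fx8$network), "alaP")
  expect_false("alaP" %in% optimal_efficiency_pems(fx8$network))
  # unreachable target raises
  net0 <- fx$network
  net0$reactions[["r_S"]]$upper_bound <- 0
  expect_error(producibility_pems(net0), "carries no flux")
})

test_that("essential reactions respond to the upper-bound asymmetry", {
  fx <- pem_fixture("fig2")
  ess <- essential_reactions(fx$network)
  expect_true(all(c("r6", "r9") %in% ess))
  expect_false(any(c("r1", "r7", "r8") %in% ess))
  # raising the parallel-path capacity makes r1 and r8 essential
  fxb <- pem_fixture("fig2_bounds")
  essb <- essential_reactions(fxb$network)
  expect_true(all(c("r1", "r8") %in% essb))
  expect_false("r7" %in% essb)
  # a permanently zero-flux reaction is never essential
  fx6 <- pem_fixture("fig6_motif")
  expect_false("r_ch5" %in% essential_reactions(fx6$network))
})

test_that("optimal-efficiency-PEMs are substrates of essential reactions", {
  fx <- pem_fixture("fig2")
  oe <- optimal_efficiency_pems(fx$network)
  expect_true("E" %in% oe)
  expect_false("B" %in% oe)
  oeb <- optimal_efficiency_pems(pem_fixture("fig2_bounds")$network)
  expect_true(all(c("B", "E") %in% oeb))
  # no seed exclusion applies to this class
  expect_true("S" %in% oeb)
  # unreachable target: no essential reactions, empty set
  net <- metabolic_network(list(reaction("r_b", products = c(A = 1), upper_bound = 0),
                                reaction("r_T", c(A = 1), upper_bound = 5)),
                           target = "r_T")
  expect_identical(optimal_efficiency_pems(net), character(0))
})

test_that("knockout essentiality is equivalent to a positive FVA minimum", {
  for (nm in c("fig1", "fig2", "fig2_bounds", "fig4", "fig5", "fig8_motif")) {
    fx <- pem_fixture(nm)
    ess <- essential_reactions(fx$network)
    singles <- Filter(function(r) is.na(fx$network$reactions[[r]]$reverse_of),
                      names(fx$network$reactions))
    for (r in singles) {
      iv <- fva(fx$network, r, at_optimum = TRUE)
      expect_identical(r %in% ess, iv$min_v > 1e-6,
                       info = paste(nm, r))
    }
  }
  # the reversible futile pair: not essential, zero minimum in both directions
  fx1 <- pem_fixture("fig1")
  expect_false("r0" %in% essential_reactions(fx1$network))
  expect_lt(fva(fx1$network, "r0", at_optimum = TRUE)$min_v, 1e-6)
  expect_lt(fva(fx1$network, "r1", at_optimum = TRUE)$min_v, 1e-6)
})

test_that("FVA brackets fluxes and honours the optimum constraint", {
  fx <- pem_fixture("fig2")
  # reaction with zero bound
  net0 <- fx$network
  net0$reactions[["r7"]]$upper_bound <- 0
  iv <- fva(net0, "r7")
  expect_equal(c(iv$min_v, iv$max_v), c(0, 0))
  # the consumer of E carries flux in every optimal distribution
  iv6 <- fva(fx$network, "r6", at_optimum = TRUE)
  expect_gt(iv6$min_v, 1e-6)
  expect_lte(iv6$min_v, iv6$max_v)
  # all-closed inflows: loop reactions pinned at zero
  fx7 <- pem_fixture("fig7_motif")
  netc <- fx7$network
  netc$reactions[["r_thm"]]$upper_bound <- 0
  ivw <- fva(netc, "r_w1")
  expect_gte(ivw$max_v, 0)   # self-activated loop may still run
})

test_that("pruning to a single-reaction removal matches its knockout", {
  for (nm in c("fig2", "fig5", "fig8_motif")) {
    fx <- pem_fixture(nm)
    net <- fx$network
    seeds <- fx$seeds$seeds
    tm <- fx$target$targeted_metabolites
    mu <- max_flux(net)$objective_value
    p_set <- producibility_pems(net)
    for (m in setdiff(net$metabolites$id, c(seeds, tm))) {
      removed <- setdiff(names(net$reactions), names(prune(net, m)$reactions))
      if (length(removed) != 1L) next
      mu_k <- max_flux(net, knockout = removed)$objective_value
      expect_identical(m %in% p_set, mu_k <= 1e-6, info = paste(nm, m))
    }
  }
})

test_that("rescaling all upper bounds rescales the optimum, not the PEM sets", {
  for (nm in c("fig2_bounds", "fig5")) {
    fx <- pem_fixture(nm)
    net <- fx$network
    lam <- 2.5
    net2 <- net
    for (r in names(net2$reactions)) {
      net2$reactions[[r]]$upper_bound <- lam * net2$reactions[[r]]$upper_bound
    }
    expect_equal(max_flux(net2)$objective_value,
                 lam * max_flux(net)$objective_value, tolerance = 1e-8)
    expect_identical(sustainability_pems(net2), sustainability_pems(net))
    expect_identical(producibility_pems(net2), producibility_pems(net))
    expect_identical(optimal_efficiency_pems(net2),
                     optimal_efficiency_pems(net))
  }
})
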