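test_that("the combined classification reproduces the didactic regions", {
  cl <- classify_pems(pem_fixture("fig2")$network)
  tab <- cl$metabolites
  region <- function(t, m) t$venn_region[t$id == m]
  expect_identical(region(tab, "E"), "SPO")
  expect_identical(region(tab, "G"), "PO")
  expect_identical(region(tab, "B"), "none")
  clb <- classify_pems(pem_fixture("fig2_bounds")$network)
  expect_identical(region(clb$metabolites, "B"), "O-only")
  # motif fixtures: one exemplar per remaining region
  expect_identical(
    region(classify_pems(pem_fixture("fig4")$network)$metabolites, "bg6p"),
    "SP")
  cl5 <- classify_pems(pem_fixture("fig5")$network)$metabolites
  expect_identical(region(cl5, "agm"), "O-only")
  expect_identical(region(cl5, "urea"), "O-only")
  cl6 <- classify_pems(pem_fixture("fig6_motif")$network)$metabolites
  expect_identical(unique(cl6$venn_region[grepl("^x[1-9]$", cl6$id)]),
                   "S-only")
  expect_identical(
    region(classify_pems(pem_fixture("fig7_motif")$network)$metabolites,
           "thm_c"), "SO")
  expect_identical(
    region(classify_pems(pem_fixture("fig8_motif")$network)$metabolites,
           "alaP"), "P-only")
})

test_that("roles follow the seed > target > PEM > other precedence", {
  cl <- classify_pems(pem_fixture("fig2_bounds")$network)
  tab <- cl$metabolites
  # S is an optimal-efficiency-PEM but reported as seed
  expect_true(tab$optimal_efficiency[tab$id == "S"])
  expect_identical(tab$role[tab$id == "S"], "seed")
  expect_identical(tab$role[tab$id == "C"], "target")
  expect_identical(tab$role[tab$id == "B"], "PEM")
})

test_that("venn regions partition the PEM union and agree with the flag sets", {
  for (nm in c("fig2", "fig2_bounds", "fig5", "fig6_motif")) {
    cl <- classify_pems(pem_fixture(nm)$network)
    tab <- cl$metabolites
    union_flags <- tab$sustainability | tab$producibility |
      tab$optimal_efficiency
    expect_identical(tab$venn_region != "none", union_flags, info = nm)
    sm <- summary(cl)
    expect_identical(sm$pems, sum(union_flags), info = nm)
    expect_identical(
      sm$pems,
      length(unique(c(cl$sets$sustainability, cl$sets$producibility,
                      cl$sets$optimal_efficiency))), info = nm)
    expect_lte(sm$pems, sm$sustainability + sm$producibility +
                 sm$optimal_efficiency)
  }
})

test_that("summary percentages are counts over the metabolite total", {
  cl <- classify_pems(pem_fixture("fig2")$network)
  sm <- summary(cl)
  expect_identical(sm$metabolites, 5L)
  expect_equal(sm$pct_pems, 100 * sm$pems / 5)
  # the summary arithmetic at genome scale: 113 of 904 metabolites -> 12.5%
  flags <- cbind(sustainability = rep(FALSE, 904),
                 producibility = rep(FALSE, 904),
                 optimal_efficiency = c(rep(TRUE, 113), rep(FALSE, 791)))
  big <- pemnet:::.pem_summary_counts(flags, n_metabolites = 904,
                                      n_reactions = 1075L)
  expect_equal(round(big$pct_pems, 1), 12.5)
  # no PEMs -> all percentages zero
  none <- pemnet:::.pem_summary_counts(flags & FALSE, n_metabolites = 10)
  expect_identical(c(none$pct_pems, none$pct_sustainability), c(0, 0))
})

test_that("classification is invariant under metabolite relabelling", {
  fx <- pem_fixture("fig2")
  relabel <- function(x) if (length(x) == 0L) character(0) else paste0("met_", x)
  rx <- lapply(fx$network$reactions, function(r) {
    reaction(r$id,
             stats::setNames(unname(r$reactants), relabel(names(r$reactants))),
             stats::setNames(unname(r$products), relabel(names(r$products))),
             r$upper_bound)
  })
  net2 <- metabolic_network(unname(rx), target = "r_T")
  s1 <- summary(classify_pems(fx$network))
  s2 <- summary(classify_pems(net2))
  expect_equal(as.data.frame(s1), as.data.frame(s2))
})

test_that("degree-role bins partition the metabolites and sum to 100%", {
  cl <- classify_pems(pem_fixture("fig1")$network)
  drt <- degree_role_table(cl, c(0L, 2L, 5L))
  expect_equal(sum(drt$n), nrow(cl$metabolites))
  pct <- rowSums(drt[, c("pct_PEM", "pct_seed", "pct_target", "pct_other")])
  expect_equal(pct, rep(100, nrow(drt)), tolerance = 1e-9)
  expect_error(degree_role_table(cl, c(3L, 1L)))
  # a lone high-degree seed occupies its bin entirely
  cl2 <- cl
  cl2$metabolites <- cl$metabolites[cl$metabolites$id == "S2", ]
  drt2 <- degree_role_table(cl2, c(0L, 10L))
  expect_equal(drt2$pct_seed, 100)
  # the top-degree compounds of the fixture are all PEM/seed/target
  top <- cl$metabolites[cl$metabolites$connectivity ==
                          max(cl$metabolites$connectivity), ]
  expect_true(all(top$role %in% c("PEM", "seed", "target")))
})

test_that("the cross-network skeleton intersects SPO sets", {
  cl <- classify_pems(pem_fixture("fig2")$network)
  spo <- cl$metabolites$id[cl$metabolites$venn_region == "SPO"]
  expect_identical(skeleton_pems(list(cl, cl)), sort(spo))
  # disjoint namespaces without a mapping is an error
  cl6 <- classify_pems(pem_fixture("fig6_motif")$network)
  expect_error(skeleton_pems(list(cl, cl6)), "id_mapping")
  expect_error(
    skeleton_pems(list(cl, cl), id_mapping = data.frame(a = character(0),
                                                        b = character(0))),
    "empty"
  )
  # an explicit mapping translates between namespaces
  map <- data.frame(a = c("E", "G"), b = c("u1", "u2"))
  expect_identical(skeleton_pems(list(cl, cl6), id_mapping = map), "E")
})

test_that("partial classifications warn instead of failing", {
  # unreachable target: sustainability flags NA, warning raised
  net <- metabolic_network(list(
    reaction("r_b", products = c(A = 1), upper_bound = 0),
    reaction("r1", c(Z = 1), c(B = 1), 5),
    reaction("r_T", c(B = 1), upper_bound = 5)
  ), target = "r_T")
  expect_warning(expect_warning(cl <- classify_pems(net),
                                "not topologically activated"),
                 "carries no flux")
  expect_true(all(is.na(cl$metabolites$sustainability)))
  expect_identical(cl$sets$producibility, character(0))
  expect_identical(unique(cl$metabolites$venn_region), "none")
})

test_that("report writers produce readable tables and region counts", {
  cl <- classify_pems(pem_fixture("fig2")$network)
  dir <- withr::local_tempdir()
  files <- write_pem_report(cl, dir)
  expect_true(all(file.exists(files)))
  tab <- read.delim(file.path(dir, "classification.tsv"))
  expect_identical(tab$blocked_target_metabolites[tab$id == "E"], "C")
  venn <- jsonlite::read_json(file.path(dir, "venn.json"))
  expect_identical(venn$SPO, 1L)
  expect_identical(venn$PO, 1L)
  sm <- read.delim(file.path(dir, "summary.tsv"))
  expect_identical(sm$pems, 3L)
})
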