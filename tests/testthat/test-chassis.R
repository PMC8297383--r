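test_that("gene frequencies count solution membership per target", {
  fr <- gene_frequencies(list(S = list("g2", c("g1", "g2")), M = list("g2")))
  expect_equal(fr["g2", "S"], 1.0)
  expect_equal(fr["g1", "S"], 0.5)
  expect_equal(fr["g2", "M"], 1.0)
  expect_equal(fr["g1", "M"], 0)
  one <- gene_frequencies(list(S = list("g2")))
  expect_equal(dim(one), c(1L, 1L))
  expect_equal(one["g2", "S"], 1.0)
  sat <- gene_frequencies(list(S = list("g1", "g1"), M = list("g1")))
  expect_true(all(sat["g1", ] == 1.0))
  expect_error(gene_frequencies(list(S = list())), "empty solution set.*S")
})

test_that("gscore follows its defining formula, including the worked values", {
  fr <- rbind(gA = c(0.8, 0.6), gB = c(0.5, 0), gC = c(0, 0))
  colnames(fr) <- c("t1", "t2")
  gs <- gene_score(fr)
  expect_equal(gs[["gA"]], 2.8)     # (0.8 + 0.6) * 2
  expect_equal(gs[["gB"]], 0.5)     # single-target gene penalised
  expect_equal(gs[["gC"]], 0)
})

test_that("gscore matches the literal oracle on random frequency fixtures", {
  set.seed(21)
  for (i in 1:100) {
    fr <- matrix(round(stats::runif(12) * (stats::runif(12) > 0.3), 3),
                 nrow = 4, dimnames = list(paste0("g", 1:4), paste0("t", 1:3)))
    gs <- gene_score(fr)
    for (g in rownames(fr))
      expect_equal(gs[[g]], oracle_gscore(fr[g, ]))
  }
})

test_that("frequency clustering filters, sorts and merges as documented", {
  fr <- rbind(gA = c(1, 0), gB = c(0, 1), gC = c(0.1, 0.05), gD = c(1, 0))
  colnames(fr) <- c("t1", "t2")
  cl <- cluster_frequencies(fr, min_freq = 0.2)
  expect_false("gC" %in% rownames(cl$matrix))          # below the filter
  expect_equal(cl$row_hclust$height[1], 0)             # identical rows merge at 0
  expect_equal(max(cl$row_hclust$height), sqrt(2), tolerance = 1e-9)
  # leaf order is invariant to input row order
  cl2 <- cluster_frequencies(fr[c(3, 1, 4, 2), ], min_freq = 0.2)
  expect_identical(cl$row_order, cl2$row_order)
  expect_identical(cl$col_order, cl2$col_order)
  expect_warning(cluster_frequencies(fr[1, , drop = FALSE], 0.2), "degenerate")
})

test_that("chassis enumeration combines the top-scoring genes", {
  gs4 <- stats::setNames(c(4, 3, 2, 1), c("a", "b", "c", "d"))
  out <- enumerate_chassis(gs4, top_fraction = 0.5, max_size = 2)
  expect_length(out, 3L)                                # 2 singletons + 1 pair
  expect_setequal(vapply(out, paste, "", collapse = "+"), c("a", "b", "a+b"))
  expect_length(enumerate_chassis(stats::setNames(1, "a"), 0.3, 5), 1L)
  gs3 <- stats::setNames(c(3, 2, 1), c("a", "b", "c"))
  expect_length(enumerate_chassis(gs3, 1.0, 5), 7L)     # 2^3 - 1 subsets
  # ties at the cut are all included
  tied <- stats::setNames(c(2, 1, 1, 0), c("a", "b", "c", "d"))
  out2 <- enumerate_chassis(tied, top_fraction = 0.5, max_size = 1)
  expect_setequal(unlist(out2), c("a", "b", "c"))
  expect_length(enumerate_chassis(stats::setNames(numeric(), character())), 0L)
})

test_that("cscore reproduces the worked example and edge conventions", {
  sols <- list(
    t1 = list(list(genes = "g2", metrics = list(cyield = 0.60, cost = 3)),
              list(genes = "g2", metrics = list(cyield = 0.66, cost = 2))),
    t2 = list(list(genes = "g2", metrics = list(cyield = 0.50, cost = 2))))
  cc <- chassis_score("g2", sols, cyield_fraction = 0)
  expect_equal(cc$cscore, 0.66 / 2 + 0.50 / 2)          # 0.58
  expect_identical(cc$targets_covered, 2L)
  # a chassis contained in no solution scores zero
  expect_equal(chassis_score("gX", sols)$cscore, 0)
  one <- list(t1 = list(list(genes = c("g1"), metrics = list(cyield = 0.5, cost = 1))))
  expect_equal(chassis_score("g1", one)$cscore, 0.5)
})

test_that("cscore matches the literal oracle on random fixtures", {
  set.seed(31)
  for (i in 1:100) {
    sols <- random_sol_fixture()
    chassis <- sort(sample(paste0("g", 1:6), sample(1:2, 1)))
    expect_equal(chassis_score(chassis, sols, 0.95)$cscore,
                 oracle_cscore(chassis, sols, 0.95), tolerance = 1e-12)
  }
})

test_that("adding a supporting solution never decreases a chassis score", {
  set.seed(41)
  for (i in 1:20) {
    sols <- random_sol_fixture(n_targets = 2)
    chassis <- "g1"
    base <- chassis_score(chassis, sols, cyield_fraction = 0)$cscore
    # append a chassis-containing solution with max yield so it passes any
    # identified-maximum filter without displacing existing members
    grown <- sols
    cy_max <- max(vapply(sols$t1, function(s) s$metrics$cyield, numeric(1)))
    grown$t1 <- c(grown$t1, list(list(genes = c("g1", "g9"),
                                      metrics = list(cyield = cy_max, cost = 2))))
    expect_gte(chassis_score(chassis, grown, cyield_fraction = 0)$cscore,
               base - 1e-12)
  }
})

test_that("ranking orders by score, then size, then name", {
  mk <- function(genes, score) structure(
    list(genes = genes, cscore = score, targets_covered = 1L, groups = list()),
    class = "chassis_candidate")
  rep <- rank_chassis(list(mk(c("a", "b"), 0.58), mk("c", 0.58), mk("z", 0.9)))
  expect_identical(rep$table$chassis_genes, c("z", "c", "a,b"))
  empty <- rank_chassis(list())
  expect_identical(nrow(empty$table), 0L)
})

test_that("end-to-end chassis analysis ranks the shared coupling gene first", {
  # two target products on the branched two-product toy: every productive
  # solution for either target deletes the direct route gene g2, so its
  # singleton chassis must outrank product-specific gene sets
  t2 <- make_toy_model("T2"); env <- toy_env()
  cs <- select_candidates(t2, env)
  sets <- list()
  for (prod in c("EX_P", "EX_Q")) {
    cfg <- search_config(prod, max_deletions = 3, budget = 500,
                         archive_size = 10, pop_size = 10, runs = 2, seed = 11)
    sets[[prod]] <- optimize_knockouts(t2, env, cs, cfg)
  }
  rep <- analyze_chassis(sets, top_fraction = 0.67, max_size = 2)
  expect_gt(nrow(rep$table), 0)
  expect_identical(rep$table$chassis_genes[1], "g2")
  expect_identical(rep$table$targets_covered[1], 2L)
  # report serialisation
  dir <- tempfile()
  write_chassis_report(rep, gene_frequencies(sets), dir)
  expect_true(all(file.exists(file.path(
    dir, c("frequencies.tsv", "gscore.tsv", "linkage.tsv",
           "chassis_ranked.tsv")))))
})
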