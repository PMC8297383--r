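test_that("solution metrics compose pFBA, FVA and the yield formulas", {
  t1 <- make_toy_model("T1"); env <- toy_env()
  m <- evaluate_solution(t1, env, "R2", "EX_P")
  expect_equal(m$growth, 10, tolerance = 1e-6)
  expect_equal(m$product_flux, 10, tolerance = 1e-6)
  expect_equal(m$uptake, 10, tolerance = 1e-6)
  expect_equal(c(m$fva_min, m$fva_max), c(10, 10), tolerance = 1e-6)
  expect_equal(m$cyield, (10 * 4) / (10 * 6), tolerance = 1e-6)   # 0.6667
  expect_equal(m$bpcy, 10 * 10 / 10, tolerance = 1e-6)
  expect_identical(m$cost, 1L)

  wt <- evaluate_solution(t1, env, character(), "EX_P")
  expect_equal(wt$product_flux, 0, tolerance = 1e-6)   # pFBA vertex
  expect_equal(wt$cyield, 0, tolerance = 1e-6)
  expect_equal(c(wt$fva_min, wt$fva_max), c(0, 10), tolerance = 1e-6)

  dead <- evaluate_solution(t1, env, c("R1", "R2"), "EX_P")
  expect_equal(c(dead$growth, dead$cyield, dead$bpcy), c(0, 0, 0))

  # carbon metadata is mandatory for yields unless a map is supplied
  t1b <- t1; t1b$metabolites["P", "carbons"] <- NA
  expect_error(evaluate_solution(t1b, env, "R2", "EX_P"), "carbon map")
  m2 <- evaluate_solution(t1b, env, "R2", "EX_P", carbons = c(EX_P = 4))
  expect_equal(m2$cyield, 2 / 3, tolerance = 1e-6)
})

test_that("carbon yield never exceeds the theoretical maximum", {
  for (s in c(1, 4, 9)) {
    m <- make_toy_model("random", s); env <- toy_env()
    # theoretical maximum: maximise product flux directly
    mp <- m; mp$objective <- "EX_P"
    vmax <- fba(mp, env)$objective
    cp <- carbon_content(m, "P"); cs <- carbon_content(m, "A")
    cy_max <- vmax * cp / (10 * cs)
    cs_set <- select_candidates(m, env)
    for (rid in cs_set$candidates) {
      met <- evaluate_solution(m, env, rid, "EX_P")
      expect_lte(met$cyield, cy_max + 1e-6)
    }
  }
})

test_that("the SPEA2 archive recovers the exhaustive Pareto set on T1", {
  t1 <- make_toy_model("T1"); env <- toy_env()
  cands <- select_candidates(t1, env)
  cfg <- search_config("EX_P", max_deletions = 2, budget = 200,
                       archive_size = 10, pop_size = 10, seed = 42)
  arch <- spea2_search(t1, env, cands, cfg)
  keys <- vapply(arch, function(s) paste(s$reactions, collapse = ","), "")
  expect_true("R2" %in% keys)
  best <- arch[[which(keys == "R2")]]
  expect_equal(best$metrics$product_flux, 10, tolerance = 1e-6)
  expect_identical(best$genes, "g2")
  # brute force over the 3 non-empty subsets: {R2} is the only point with
  # positive product at optimal growth, so the archive front is exactly it
  expect_equal(archive_front(arch),
               oracle_front(t1, env, cands$candidates, "EX_P", 2),
               ignore_attr = TRUE, tolerance = 1e-6)
})

test_that("identical seeds give identical archives, different seeds may differ", {
  t1 <- make_toy_model("T1"); env <- toy_env()
  cands <- select_candidates(t1, env)
  cfg <- search_config("EX_P", max_deletions = 2, budget = 200,
                       archive_size = 10, pop_size = 10, seed = 42)
  runs <- lapply(1:3, function(i) spea2_search(t1, env, cands, cfg))
  expect_identical(runs[[1]], runs[[2]])
  expect_identical(runs[[2]], runs[[3]])
})

test_that("degenerate search inputs raise the documented errors", {
  t1 <- make_toy_model("T1"); env <- toy_env()
  cfg <- search_config("EX_P", budget = 200, pop_size = 10)
  expect_error(spea2_search(t1, env, character(), cfg), "empty")
  cfg2 <- search_config("EX_P", budget = 5, pop_size = 10)
  expect_error(spea2_search(t1, env, c("R1", "R2"), cfg2), "budget")
})

test_that("archive members never dominate each other", {
  for (s in c(2, 6)) {
    m <- make_toy_model("random", s); env <- toy_env()
    cands <- select_candidates(m, env)
    cfg <- search_config("EX_P", max_deletions = 3, budget = 300,
                         archive_size = 20, pop_size = 15, seed = 7 + s)
    arch <- spea2_search(m, env, cands, cfg)
    objs <- do.call(rbind, lapply(arch, function(x)
      c(x$metrics$growth, x$metrics$product_flux)))
    for (i in seq_len(nrow(objs))) for (j in seq_len(nrow(objs)))
      if (i != j)
        expect_false(all(objs[i, ] >= objs[j, ] + 1e-9))
  }
})

test_that("the archive front matches brute force on random toy models", {
  for (s in c(3, 11, 17)) {
    m <- make_toy_model("random", s); env <- toy_env()
    cands <- select_candidates(m, env)
    cfg <- search_config("EX_P", max_deletions = 3, budget = 2000,
                         archive_size = 20, pop_size = 20, seed = 100 + s)
    arch <- spea2_search(m, env, cands, cfg)
    expect_equal(archive_front(arch),
                 oracle_front(m, env, cands$candidates, "EX_P", 3),
                 ignore_attr = TRUE, tolerance = 1e-5)
  }
})

test_that("simplification drops non-contributing deletions and is idempotent", {
  t1 <- make_toy_model("T1"); env <- toy_env()
  # {R1, R2} is lethal; dropping R1 improves both objectives
  expect_identical(simplify_solution(t1, env, c("R1", "R2"), "EX_P"), "R2")
  expect_identical(simplify_solution(t1, env, "R2", "EX_P"), "R2")
  t2 <- make_toy_model("T2")
  # R3 deletion is irrelevant once R2 and R4 force the coupling... check the
  # simplified set never worsens either objective and never grows
  before <- evaluate_solution(t2, env, c("R2", "R4", "R3"), "EX_P")
  simp <- simplify_solution(t2, env, c("R2", "R4", "R3"), "EX_P")
  after <- evaluate_solution(t2, env, simp, "EX_P")
  expect_lte(length(simp), 3L)
  expect_gte(after$growth, before$growth - 1e-6)
  expect_gte(after$product_flux, before$product_flux - 1e-6)
  expect_identical(simplify_solution(t2, env, simp, "EX_P"), simp)
})

test_that("reaction-to-gene conversion yields minimal cut combinations", {
  t1 <- make_toy_model("T1")
  expect_identical(reactions_to_genes(t1, "R2"), list("g2"))
  iso <- metabolic_model(
    list(list(id = "IN", stoich = c(a = 1), lb = 0, ub = 10),
         list(id = "R", stoich = c(a = -1, b = 1), lb = 0, ub = 10,
              gpr = "g1 or g2"),
         list(id = "Rc", stoich = c(b = -1), lb = 0, ub = 10,
              gpr = "g3 and g4")),
    data.frame(id = c("a", "b")), objective = "Rc")
  expect_identical(reactions_to_genes(iso, "R"), list(c("g1", "g2")))
  expect_identical(reactions_to_genes(iso, "Rc"), list("g3", "g4"))
  expect_identical(reactions_to_genes(iso, c("R", "Rc")),
                   list(c("g1", "g2", "g3"), c("g1", "g2", "g4")))
  expect_error(reactions_to_genes(t1, "UP"), "no gene association")
})

test_that("gene conversion discards cuts with objective-changing side effects", {
  # one gene shared between the target reaction and the only growth route:
  # the shared cut kills growth and must be dropped in favour of the clean one
  m <- metabolic_model(
    list(list(id = "IN", stoich = c(a = 1), lb = 0, ub = 10),
         list(id = "GROW", stoich = c(a = -1, c = 1), lb = 0, ub = 1000,
              gpr = "gS"),
         list(id = "ALT", stoich = c(a = -1, c = 1, p = 1), lb = 0, ub = 1000,
              gpr = "gS and gA"),
         list(id = "BIO", stoich = c(c = -1), lb = 0, ub = 1000),
         list(id = "EX_P", stoich = c(p = -1), lb = 0, ub = 1000)),
    data.frame(id = c("a", "c", "p"), carbons = c(2, NA, 2)),
    objective = "BIO")
  env <- flux_environment(substrate = "IN")
  sets <- reactions_to_genes(m, "ALT", env, "EX_P")
  expect_identical(sets, list("gA"))    # the gS cut would also close GROW
})

test_that("run merging deduplicates by gene-deletion set", {
  t1 <- make_toy_model("T1"); env <- toy_env()
  sol <- function(dels) structure(
    list(reactions = dels, genes = unlist(reactions_to_genes(t1, dels)[1]),
         gene_sets = reactions_to_genes(t1, dels),
         metrics = evaluate_solution(t1, env, dels, "EX_P")),
    class = "knockout_solution", product = "EX_P")
  a <- list(sol("R2")); b <- list(sol("R2")); c <- list(sol("R1"))
  expect_length(merge_runs(list(a, b), "EX_P")$solutions, 1L)
  expect_length(merge_runs(list(a, c), "EX_P")$solutions, 2L)
  expect_length(merge_runs(list(list(), list()), "EX_P")$solutions, 0L)
  bad <- a; attr(bad[[1]], "product") <- "EX_Q"
  expect_error(merge_runs(list(bad), "EX_P"), "mix")
})

test_that("solution sets serialise to the documented TSV layout", {
  t1 <- make_toy_model("T1"); env <- toy_env()
  cfg <- search_config("EX_P", max_deletions = 2, budget = 100,
                       archive_size = 5, pop_size = 5, runs = 2, seed = 3)
  ss <- optimize_knockouts(t1, env, select_candidates(t1, env), cfg)
  f <- tempfile(fileext = ".tsv")
  write_solutions_tsv(ss, f)
  d <- utils::read.table(f, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  expect_identical(names(d), c("solution_id", "reaction_dels", "gene_dels",
                               "growth", "uptake", "product", "fva_min",
                               "fva_max", "bpcy", "cyield", "cost"))
  expect_true("g2" %in% d$gene_dels)
})
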