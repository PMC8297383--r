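test_that("the T1 fixture has the documented structure and is deterministic", {
  t1 <- make_toy_model("T1", seed = 1)
  expect_identical(reaction_ids(t1), c("UP", "R1", "R2", "R3", "BIO", "EX_P"))
  expect_identical(sort(t1$genes), c("g1", "g2", "g3"))
  expect_identical(t1$objective, "BIO")
  expect_equal(t1$reactions$UP$lb, 0)
  expect_equal(t1$reactions$UP$ub, 10)
  expect_equal(carbon_content(t1, "A"), 6L)
  expect_equal(carbon_content(t1, "P"), 4L)
  expect_identical(make_toy_model("T1", seed = 1), make_toy_model("T1", seed = 2))
  expect_error(make_toy_model("nope"), "available")
})

test_that("random toy models are seed-deterministic and growth-capable", {
  expect_identical(make_toy_model("random", 7), make_toy_model("random", 7))
  for (s in 1:5) {
    m <- make_toy_model("random", s)
    expect_s3_class(m, "metabolic_model")
    expect_equal(fba(m, toy_env())$objective, 10, tolerance = 1e-6)
  }
})

test_that("reaction kinds are derived from topology", {
  t1 <- make_toy_model("T1")
  kinds <- vapply(t1$reactions, `[[`, character(1), "kind")
  expect_identical(unname(kinds[c("UP", "EX_P", "R1")]),
                   c("exchange", "exchange", "internal"))
  # a reaction moving the same base metabolite across compartments
  m <- metabolic_model(
    list(list(id = "T", stoich = c(a_c = -1, a_m = 1), lb = 0, ub = 1),
         list(id = "OBJ", stoich = c(a_m = -1), lb = 0, ub = 1)),
    data.frame(id = c("a_c", "a_m"), name = c("a", "a"),
               compartment = c("c", "m")),
    objective = "OBJ")
  expect_identical(m$reactions$T$kind, "transport")
})

test_that("carbon counting distinguishes elements and rejects unknowns", {
  expect_equal(parse_formula_carbons("C6H12O6"), 6L)
  expect_equal(parse_formula_carbons("CaCl2"), 0L)
  expect_equal(parse_formula_carbons("C10H12CuN5O4"), 10L)
  expect_true(is.na(parse_formula_carbons("XH2")))     # polymeric placeholder
  expect_true(is.na(parse_formula_carbons("(C6H10O5)n")))
  m <- make_toy_model("T1")
  expect_error(carbon_content(m, "B"), "unknown carbon content")
  expect_error(carbon_content(m, "nope"), "unknown metabolite")
})

test_that("gene deletions close the right reactions and are idempotent", {
  t1 <- make_toy_model("T1")
  d <- apply_gene_deletions(t1, "g2")
  expect_equal(c(d$reactions$R2$lb, d$reactions$R2$ub), c(0, 0))
  expect_equal(d$reactions$R1$ub, t1$reactions$R1$ub)
  expect_identical(apply_gene_deletions(t1, character()), t1)
  expect_identical(apply_gene_deletions(d, "g2"), d)    # idempotent
  all3 <- apply_gene_deletions(t1, c("g1", "g2", "g3"))
  for (rid in c("R1", "R2", "R3"))
    expect_equal(all3$reactions[[rid]]$ub, 0)
  expect_error(apply_gene_deletions(t1, "gX"), "gX")
})

test_that("model patching applies edits in order and validates", {
  t1 <- make_toy_model("T1")
  expect_identical(patch_model(t1, list()), t1)         # empty edit = identity
  p <- patch_model(t1, list(list(
    op = "add_reaction",
    reaction = list(id = "R4", stoich = c(C = -1, P = 1), lb = 0, ub = 1000,
                    gpr = "g4"))))
  expect_length(p$reactions, 7L)
  expect_true("g4" %in% p$genes)
  p2 <- patch_model(t1, list(list(op = "set_bounds", id = "UP", ub = 5)))
  expect_equal(fba(p2, toy_env())$objective, 5, tolerance = 1e-6)
  expect_error(patch_model(t1, list(list(op = "remove_reaction", id = "nope"))),
               "edit 1")
  rm1 <- patch_model(t1, list(list(op = "remove_reaction", id = "EX_P")))
  expect_length(rm1$reactions, 5L)
  rev <- patch_model(t1, list(list(op = "set_reversibility", id = "R1",
                                   reversible = TRUE)))
  expect_lt(rev$reactions$R1$lb, 0)
})

test_that("edit lists round-trip through YAML and JSON files", {
  edits <- list(list(op = "set_bounds", id = "UP", lb = 0, ub = 5),
                list(op = "remove_reaction", id = "EX_P"))
  fy <- tempfile(fileext = ".yaml"); fj <- tempfile(fileext = ".json")
  yaml::write_yaml(edits, fy)
  jsonlite::write_json(edits, fj, auto_unbox = TRUE)
  t1 <- make_toy_model("T1")
  for (f in c(fy, fj)) {
    p <- patch_model(t1, read_model_edits(f))
    expect_equal(p$reactions$UP$ub, 5)
    expect_false("EX_P" %in% reaction_ids(p))
  }
})

# structural comparison used for round-trip checks (SBML re-derives some
# representation details, e.g. carbon metadata as a formula)
expect_same_network <- function(a, b) {
  expect_setequal(reaction_ids(a), reaction_ids(b))
  for (rid in reaction_ids(a)) {
    ra <- a$reactions[[rid]]; rb <- b$reactions[[rid]]
    expect_equal(sort(names(ra$stoich)), sort(names(rb$stoich)))
    expect_equal(ra$stoich[sort(names(ra$stoich))],
                 rb$stoich[sort(names(rb$stoich))])
    expect_equal(c(ra$lb, ra$ub), c(rb$lb, rb$ub))
    expect_identical(ra$gpr, rb$gpr)
  }
  expect_identical(a$objective, b$objective)
  expect_setequal(a$genes, b$genes)
}

test_that("models round-trip through the JSON dialect", {
  for (variant in c("T1", "T2")) {
    m <- make_toy_model(variant)
    f <- tempfile(fileext = ".json")
    write_model(m, f)
    m2 <- read_model(f)
    expect_same_network(m, m2)
    expect_equal(carbon_content(m2, "A"), 6L)
    expect_equal(fba(m2, toy_env())$objective, fba(m, toy_env())$objective)
  }
})

test_that("models round-trip through SBML Level 3 + fbc", {
  for (seed in c(1, 4)) {
    m <- make_toy_model("random", seed)
    f <- tempfile(fileext = ".xml")
    write_model(m, f)
    m2 <- read_model(f)
    expect_same_network(m, m2)
    expect_equal(carbon_content(m2, "A"), carbon_content(m, "A"))
    expect_equal(fba(m2, toy_env())$objective, 10, tolerance = 1e-6)
  }
})

test_that("unreadable model files raise named format errors", {
  t1 <- make_toy_model("T1")
  f <- tempfile(fileext = ".xml")
  write_model(t1, f)
  txt <- readLines(f)
  # swap the UP bounds so lower > upper
  txt <- sub('id="UP" reversible="false" fast="false" fbc:lowerFluxBound="([^"]*)" fbc:upperFluxBound="([^"]*)"',
             'id="UP" reversible="false" fast="false" fbc:lowerFluxBound="\\2" fbc:upperFluxBound="\\1"',
             txt)
  writeLines(txt, f)
  expect_error(read_model(f), "format error.*UP|UP.*bound")

  write_model(t1, f)
  txt <- readLines(f)
  txt <- txt[!grepl("Objective", txt) & !grepl("fluxObjective", txt)]
  writeLines(txt, f)
  expect_error(read_model(f), "no objective")
  expect_error(read_model(tempfile()), "no such file")
})
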