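#' Built-in toy metabolic models
#'
#' Small branched networks that reproduce, at desk scale, the structural
#' situation growth-coupled strain design exploits: a substrate can reach the
#' biomass precursor through an efficient product-free route or through a
#' route that co-produces a secreted compound, so that knocking out the
#' efficient route couples growth to secretion.
#'
#' Variants:
#' \describe{
#'   \item{`"T1"`}{the canonical 6-reaction fixture. Internal metabolites
#'     A, B, C, P; reactions `UP` (source of A, bounds \[0, 10\]), `R1`
#'     (A to B, gene `g1`), `R2` (A to C, gene `g2`), `R3` (B to C + P, gene
#'     `g3`), `BIO` (drain of C, the objective) and `EX_P` (drain of P).
#'     Carbon metadata: A = 6, P = 4 (bookkeeping for yield metrics; the toy
#'     network is deliberately not elementally balanced). Deterministic.}
#'   \item{`"T2"`}{`T1` extended with a second secreted product Q (`R4`:
#'     B to C + Q, gene `g4`; drain `EX_Q`; Q carries 3 carbons), used for
#'     multi-target chassis analyses. Deterministic.}
#'   \item{`"random"`}{a seeded random branched network with one guaranteed
#'     growth-coupling knockout: an efficient direct route (one or two steps),
#'     a product route of randomised carbon cost, optionally a product-free
#'     leak from the branch point, blocked dead-end decoys, and occasional
#'     isozyme/complex GPRs. Identical seeds give identical models.}
#' }
#'
#' The returned model carries an `annotation` element naming the substrate
#' exchange (`UP`) and the product drains, which the toy environments and the
#' examples use for yield metrics.
#'
#' @param variant `"T1"`, `"T2"` or `"random"`.
#' @param seed integer seed (only the `"random"` variant draws from it).
#' @return a `metabolic_model`.
#' @export
make_toy_model <- function(variant = "T1", seed = 1) {
  known <- c("T1", "T2", "random")
  if (!variant %in% known)
    stop("unknown toy-model variant ", sQuote(variant),
         "; available: ", paste(known, collapse = ", "))
  if (variant == "T1") return(toy_t1(with_q = FALSE))
  if (variant == "T2") return(toy_t1(with_q = TRUE))
  with_local_seed(seed, toy_random())
}

toy_t1 <- function(with_q = FALSE) {
  mets <- data.frame(
    id = c("A", "B", "C", "P", if (with_q) "Q"),
    carbons = c(6, NA, NA, 4, if (with_q) 3),
    stringsAsFactors = FALSE)
  rxns <- list(
    list(id = "UP",  stoich = c(A = 1),          lb = 0, ub = 10),
    list(id = "R1",  stoich = c(A = -1, B = 1),  lb = 0, ub = FLUX_BIG, gpr = "g1"),
    list(id = "R2",  stoich = c(A = -1, C = 1),  lb = 0, ub = FLUX_BIG, gpr = "g2"),
    list(id = "R3",  stoich = c(B = -1, C = 1, P = 1), lb = 0, ub = FLUX_BIG, gpr = "g3"),
    list(id = "BIO", stoich = c(C = -1),         lb = 0, ub = FLUX_BIG),
    list(id = "EX_P", stoich = c(P = -1),        lb = 0, ub = FLUX_BIG))
  if (with_q) {
    rxns <- append(rxns, list(
      list(id = "R4", stoich = c(B = -1, C = 1, Q = 1), lb = 0, ub = FLUX_BIG,
           gpr = "g4"),
      list(id = "EX_Q", stoich = c(Q = -1), lb = 0, ub = FLUX_BIG)))
  }
  m <- metabolic_model(rxns, mets, objective = "BIO",
                       id = if (with_q) "toy_T2" else "toy_T1")
  m$annotation <- list(substrate = "UP",
                       products = c("EX_P", if (with_q) "EX_Q"))
  m
}

toy_random <- function() {
  uptake <- 10
  mets <- data.frame(id = c("A", "B", "C", "P"),
                     carbons = c(sample(4:8, 1), NA, NA, sample(2:6, 1)),
                     stringsAsFactors = FALSE)
  gene_n <- 0L
  fresh_gene <- function() { gene_n <<- gene_n + 1L; sprintf("g%02d", gene_n) }
  # occasionally decorate a reaction with an isozyme pair or a complex
  rand_gpr <- function() {
    u <- stats::runif(1)
    if (u < 0.15) paste0("(", fresh_gene(), " or ", fresh_gene(), ")")
    else if (u < 0.30) paste0("(", fresh_gene(), " and ", fresh_gene(), ")")
    else fresh_gene()
  }
  rxns <- list(
    list(id = "UP", stoich = c(A = 1), lb = 0, ub = uptake),
    list(id = "BIO", stoich = c(C = -1), lb = 0, ub = FLUX_BIG),
    list(id = "EX_P", stoich = c(P = -1), lb = 0, ub = FLUX_BIG))
  add <- function(id, stoich, gpr)
    rxns[[length(rxns) + 1L]] <<- list(id = id, stoich = stoich, lb = 0,
                                       ub = FLUX_BIG, gpr = gpr)
  # efficient direct route A -> C, in one or two steps (two steps form a
  # fully coupled pair the target filter must collapse)
  if (stats::runif(1) < 0.5) {
    add("D1", c(A = -1, C = 1), rand_gpr())
  } else {
    mets <- rbind(mets, data.frame(id = "D", carbons = NA))
    add("D1", c(A = -1, D = 1), rand_gpr())
    add("D2", c(D = -1, C = 1), rand_gpr())
  }
  # product route A -> B -> cost*C + P; cost > 1 makes coupling trade growth
  cost <- sample(1:2, 1)
  add("P1", c(A = -1, B = 1), rand_gpr())
  st <- c(B = -cost, C = 1, P = 1)
  add("P2", st, rand_gpr())
  # optional product-free leak from the branch point
  if (stats::runif(1) < 0.5) add("P3", c(B = -1, C = 1), rand_gpr())
  # blocked decoys: a dead-end sink and an orphan-substrate reaction
  if (stats::runif(1) < 0.5) {
    mets <- rbind(mets, data.frame(id = "Z", carbons = NA))
    add("Z1", c(A = -1, Z = 1), rand_gpr())
  }
  if (stats::runif(1) < 0.3) {
    mets <- rbind(mets, data.frame(id = "W", carbons = NA))
    add("W1", c(W = -1, C = 1), rand_gpr())
  }
  m <- metabolic_model(rxns, mets, objective = "BIO", id = "toy_random")
  m$annotation <- list(substrate = "UP", products = "EX_P")
  m
}
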