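# Element symbols recognised by the formula parser. The token scan
# distinguishes C from two-letter symbols (Cl, Ca, Cu, ...), so "CaCl2"
# correctly reports zero carbon atoms.
.ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Cr", "Mn", "Fe", "Co", "Ni",
  "Cu", "Zn", "As", "Se", "Br", "Mo", "Cd", "Sn", "I", "W", "Hg", "Pb"
)

#' Construct a metabolic model
#'
#' The central container for a constraint-based metabolic network: a list of
#' reactions (stoichiometry, flux bounds in mmol/gDW/h, optional GPR rule),
#' a metabolite table carrying compartments, chemical formulae and/or explicit
#' carbon counts, the gene set, and the objective (biomass) reaction.
#'
#' @param reactions list of reactions; each a list with elements `id`,
#'   `stoich` (named numeric, metabolite ids to signed coefficients; negative
#'   consumes), `lb`, `ub`, and optionally `gpr` (rule string) and `kind`
#'   (`"internal"`, `"exchange"` or `"transport"`; derived when missing).
#' @param metabolites data frame with columns `id` and optionally `name`,
#'   `compartment`, `formula`, `carbons`.
#' @param objective reaction id maximised by flux balance analysis.
#' @param genes character vector of gene ids; defaults to the union of all
#'   genes referenced by GPR rules.
#' @param id model identifier string.
#' @return object of class `metabolic_model`.
#' @export
metabolic_model <- function(reactions, metabolites, objective,
                            genes = NULL, id = "model") {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$compartment)) metabolites$compartment <- "c"
  if (is.null(metabolites$formula)) metabolites$formula <- NA_character_
  if (is.null(metabolites$carbons)) metabolites$carbons <- NA_real_
  metabolites$name[is.na(metabolites$name)] <- metabolites$id[is.na(metabolites$name)]
  rownames(metabolites) <- metabolites$id

  reactions <- lapply(reactions, function(r) {
    stopifnot(!is.null(r$id), !is.null(r$stoich), !is.null(r$lb), !is.null(r$ub))
    r$stoich <- unlist(r$stoich)
    if (is.null(r$gpr)) r$gpr <- ""
    r$rule <- parse_gpr(r$gpr)
    r$gpr <- deparse_gpr(r$rule)
    r
  })
  names(reactions) <- vapply(reactions, `[[`, character(1), "id")

  if (is.null(genes))
    genes <- unique(unlist(lapply(reactions, function(r) gpr_genes(r$rule))))
  genes <- sort(unique(as.character(genes)))

  m <- structure(
    list(id = id, reactions = reactions, metabolites = metabolites,
         genes = genes, objective = objective),
    class = "metabolic_model")
  for (rid in names(m$reactions))
    if (is.null(m$reactions[[rid]]$kind))
      m$reactions[[rid]]$kind <- derive_reaction_kind(m, rid)
  validate_model(m)
  m
}

# Reaction kind heuristic: an exchange (drain/source) touches exactly one
# metabolite; a transport moves the same base metabolite (shared `name`)
# between two compartments; everything else is internal. Overridable by
# setting `kind` on the reaction.
derive_reaction_kind <- function(model, rid) {
  st <- model$reactions[[rid]]$stoich
  if (length(st) == 1L) return("exchange")
  met <- model$metabolites[names(st), , drop = FALSE]
  split_comp <- split(met$compartment, met$name)
  if (any(vapply(split_comp, function(x) length(unique(x)) > 1L, logical(1))))
    return("transport")
  "internal"
}

#' Validate a metabolic model
#'
#' Checks the structural invariants: referenced metabolites exist, the
#' objective reaction is present, bounds are ordered, every exchange reaction
#' touches exactly one metabolite, and all GPR genes are in the gene set.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly; errors name the offending element.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  for (r in model$reactions) {
    missing <- setdiff(names(r$stoich), model$metabolites$id)
    if (length(missing) > 0L)
      stop("reaction ", sQuote(r$id), " references unknown metabolite(s): ",
           paste(missing, collapse = ", "))
    if (r$lb > r$ub)
      stop("reaction ", sQuote(r$id), ": lower bound ", r$lb,
           " exceeds upper bound ", r$ub)
    if (identical(r$kind, "exchange") && length(r$stoich) != 1L)
      stop("reaction ", sQuote(r$id),
           " is tagged exchange but touches more than one metabolite")
    bad <- setdiff(gpr_genes(r$rule), model$genes)
    if (length(bad) > 0L)
      stop("reaction ", sQuote(r$id), " GPR references unknown gene(s): ",
           paste(bad, collapse = ", "))
  }
  if (!model$objective %in% names(model$reactions))
    stop("objective reaction ", sQuote(model$objective), " is not in the model")
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n", sep = "")
  cat("  reactions:   ", length(x$reactions), "\n", sep = "")
  cat("  metabolites: ", nrow(x$metabolites), "\n", sep = "")
  cat("  genes:       ", length(x$genes), "\n", sep = "")
  cat("  objective:   ", x$objective, "\n", sep = "")
  invisible(x)
}

#' Reaction identifiers of a model
#' @param model a `metabolic_model`.
#' @return character vector in model order.
#' @export
reaction_ids <- function(model) names(model$reactions)

#' Stoichiometric matrix of a model
#' @param model a `metabolic_model`.
#' @return dense numeric matrix, metabolites in rows, reactions in columns.
#' @export
stoich_matrix <- function(model) {
  mets <- model$metabolites$id
  rxns <- names(model$reactions)
  S <- matrix(0, nrow = length(mets), ncol = length(rxns),
              dimnames = list(mets, rxns))
  for (r in model$reactions) S[names(r$stoich), r$id] <- r$stoich
  S
}

reaction_bounds <- function(model) {
  lb <- vapply(model$reactions, `[[`, numeric(1), "lb")
  ub <- vapply(model$reactions, `[[`, numeric(1), "ub")
  cbind(lb = lb, ub = ub)
}

#' Apply gene deletions to a model
#'
#' Every reaction whose GPR rule evaluates to `FALSE` with the given genes
#' deleted has its flux bounds closed to `[0, 0]`; other reactions (including
#' those with no gene association) are untouched. The input model is not
#' modified.
#'
#' @param model a `metabolic_model`.
#' @param genes character vector of gene ids to delete; all must exist.
#' @return a modified copy of the model.
#' @export
apply_gene_deletions <- function(model, genes) {
  genes <- unique(as.character(genes))
  unknown <- setdiff(genes, model$genes)
  if (length(unknown) > 0L)
    stop("unknown gene(s): ", paste(unknown, collapse = ", "))
  if (length(genes) == 0L) return(model)
  for (rid in names(model$reactions)) {
    rule <- model$reactions[[rid]]$rule
    if (is.null(rule)) next
    if (!evaluate_gpr(rule, genes)) {
      model$reactions[[rid]]$lb <- 0
      model$reactions[[rid]]$ub <- 0
    }
  }
  model
}

# Close a set of reactions (bounds [0,0]); used by knockout simulation at the
# reaction level and by the essentiality/coupling screens.
close_reactions <- function(model, rxns) {
  unknown <- setdiff(rxns, names(model$reactions))
  if (length(unknown) > 0L)
    stop("unknown reaction(s): ", paste(unknown, collapse = ", "))
  for (rid in rxns) {
    model$reactions[[rid]]$lb <- 0
    model$reactions[[rid]]$ub <- 0
  }
  model
}

#' Carbon atoms of a metabolite
#'
#' Explicit carbon-count metadata takes precedence; otherwise the count is
#' parsed from the chemical formula. Formulae with unknown element tokens or
#' polymeric placeholders (`X`, `R`, parentheses) are rejected rather than
#' silently treated as carbon-free.
#'
#' @param model a `metabolic_model`.
#' @param met metabolite id.
#' @return integer number of carbon atoms.
#' @export
carbon_content <- function(model, met) {
  if (!met %in% model$metabolites$id)
    stop("unknown metabolite ", sQuote(met))
  row <- model$metabolites[met, ]
  if (!is.na(row$carbons)) return(as.integer(row$carbons))
  if (!is.na(row$formula)) {
    n <- parse_formula_carbons(row$formula)
    if (!is.na(n)) return(n)
  }
  stop("unknown carbon content for metabolite ", sQuote(met),
       ": no carbon metadata and no parsable formula; supply a carbon map")
}

#' Count carbon atoms in a chemical formula
#'
#' @param formula formula string such as `"C6H12O6"`.
#' @return integer carbon count, or `NA` when the formula cannot be
#'   interpreted as a plain element-count formula.
#' @export
parse_formula_carbons <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(NA_integer_)
  toks <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  if (nchar(paste(toks, collapse = "")) != nchar(formula)) return(NA_integer_)
  total <- 0L
  for (t in toks) {
    el <- sub("[0-9]*$", "", t)
    if (!el %in% .ELEMENTS) return(NA_integer_)
    cnt <- sub("^[A-Za-z]+", "", t)
    cnt <- if (nzchar(cnt)) as.integer(cnt) else 1L
    if (el == "C") total <- total + cnt
  }
  total
}

# Run code with a locally pinned RNG state; the caller's stream is restored
# on exit so seeded helpers never perturb user code.
with_local_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}
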