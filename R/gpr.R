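#' Parse a gene-protein-reaction (GPR) rule
#'
#' GPR rules are boolean expressions over gene identifiers linking gene
#' deletions to reaction availability. The grammar accepts case-insensitive
#' `AND` / `OR` keywords (also `&`, `&&`, `|`, `||`), parentheses, and bare
#' gene tokens, matching both SBML fbc associations and legacy rule strings.
#'
#' @param text rule string; `""`, `NA` or `NULL` yield an empty rule (`NULL`),
#'   meaning the reaction has no gene association.
#' @return a rule tree: either a gene id (character scalar) or a list with
#'   elements `op` (`"and"` / `"or"`) and `args` (list of sub-rules with at
#'   least two elements), or `NULL` for the empty rule.
#' @examples
#' parse_gpr("(g1 and g2) or g3")
#' @export
parse_gpr <- function(text) {
  if (is.null(text) || length(text) == 0 || is.na(text) || !nzchar(trimws(text)))
    return(NULL)
  toks <- regmatches(text, gregexpr("\\(|\\)|&&|\\|\\||&|\\||[^\\s()&|]+",
                                    text, perl = TRUE))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  is_op <- function(t, op) {
    !is.na(t) && ((op == "and" && tolower(t) %in% c("and", "&", "&&")) ||
                  (op == "or"  && tolower(t) %in% c("or", "|", "||")))
  }
  parse_expr <- function() {
    args <- list(parse_term())
    while (is_op(peek(), "or")) { take(); args <- c(args, list(parse_term())) }
    if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (is_op(peek(), "and")) { take(); args <- c(args, list(parse_factor())) }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  parse_factor <- function() {
    t <- take()
    if (is.na(t)) stop("GPR parse error: unexpected end of rule in ", sQuote(text))
    if (t == "(") {
      e <- parse_expr()
      if (!identical(take(), ")"))
        stop("GPR parse error: unbalanced parentheses in ", sQuote(text))
      return(e)
    }
    if (t %in% c(")") || is_op(t, "and") || is_op(t, "or"))
      stop("GPR parse error: unexpected token ", sQuote(t), " in ", sQuote(text))
    t
  }
  out <- parse_expr()
  if (pos <= length(toks))
    stop("GPR parse error: trailing tokens in ", sQuote(text))
  out
}

#' Evaluate a GPR rule under a set of gene deletions
#'
#' Deleted genes evaluate to `FALSE`, all other genes to `TRUE`. The empty
#' rule evaluates to `TRUE`: a reaction without gene association cannot be
#' removed by gene deletion.
#'
#' @param rule a rule tree from [parse_gpr()] (or a rule string).
#' @param deleted character vector of deleted gene ids.
#' @return logical scalar: is the reaction still available?
#' @export
evaluate_gpr <- function(rule, deleted = character()) {
  if (is.character(rule) && length(rule) == 1L && (is.na(rule) || grepl("[ ()&|]", rule)))
    rule <- parse_gpr(rule)
  if (is.null(rule)) return(TRUE)
  if (is.character(rule)) return(!(rule %in% deleted))
  vals <- vapply(rule$args, evaluate_gpr, logical(1), deleted = deleted)
  if (rule$op == "and") all(vals) else any(vals)
}

#' Genes referenced by a GPR rule
#' @param rule rule tree from [parse_gpr()].
#' @return character vector of gene ids (unique, in first-appearance order).
#' @export
gpr_genes <- function(rule) {
  if (is.null(rule)) return(character())
  if (is.character(rule)) return(rule)
  unique(unlist(lapply(rule$args, gpr_genes)))
}

#' Render a GPR rule tree back to a string
#' @param rule rule tree.
#' @return rule string with explicit parentheses (empty string for `NULL`).
#' @export
deparse_gpr <- function(rule) {
  if (is.null(rule)) return("")
  if (is.character(rule)) return(rule)
  parts <- vapply(rule$args, function(a) {
    s <- deparse_gpr(a)
    if (is.list(a)) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = if (rule$op == "and") " and " else " or ")
}

# All minimal gene sets whose deletion falsifies the rule (minimal cut sets
# over the rule's DNF terms), found by subset enumeration in increasing size.
# GPRs of individual reactions are small, so enumeration is exact and cheap.
minimal_gene_cuts <- function(rule) {
  genes <- gpr_genes(rule)
  if (length(genes) == 0L)
    stop("cannot compute gene cuts for a reaction without gene association")
  cuts <- list()
  for (k in seq_along(genes)) {
    for (idx in utils::combn(length(genes), k, simplify = FALSE)) {
      cand <- genes[idx]
      if (any(vapply(cuts, function(c) all(c %in% cand), logical(1)))) next
      if (!evaluate_gpr(rule, cand)) cuts[[length(cuts) + 1L]] <- sort(cand)
    }
  }
  cuts
}
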