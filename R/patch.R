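#' Apply a list of edits to a model
#'
#' A small, serialisable edit language for curating models (the kind of
#' changes needed to, e.g., add a missing peroxisomal dehydrogenase reaction
#' or restrict a transporter to one direction). Edits are applied in order;
#' the result must pass [validate_model()].
#'
#' Supported operations:
#' \describe{
#'   \item{`add_reaction`}{payload `reaction`: a list with `id`, `stoich`,
#'     `lb`, `ub`, optional `gpr`; payload `metabolites` may add rows for
#'     metabolites not yet in the model (otherwise they are auto-added with
#'     unknown formula/carbons).}
#'   \item{`remove_reaction`}{payload `id`.}
#'   \item{`set_bounds`}{payload `id` plus `lb` and/or `ub`.}
#'   \item{`set_reversibility`}{payload `id`, `reversible`; `TRUE` opens the
#'     lower bound to the flux box, `FALSE` clamps it at zero.}
#' }
#'
#' @param model a `metabolic_model`.
#' @param edits list of edits, each a list with an `op` element and the
#'   payload for that operation (see Details). [read_model_edits()] loads
#'   such lists from YAML or JSON.
#' @return the edited model.
#' @export
patch_model <- function(model, edits) {
  for (i in seq_along(edits)) {
    e <- edits[[i]]
    res <- tryCatch(apply_one_edit(model, e),
                    error = function(err)
                      stop("edit ", i, " (", e$op %||% "?", "): ",
                           conditionMessage(err), call. = FALSE))
    model <- res
  }
  validate_model(model)
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

apply_one_edit <- function(model, e) {
  op <- e$op %||% stop("edit has no 'op' field")
  if (op == "add_reaction") {
    r <- e$reaction %||% stop("add_reaction needs a 'reaction' payload")
    if (r$id %in% names(model$reactions))
      stop("reaction ", sQuote(r$id), " already exists")
    for (m in e$metabolites %||% list()) {
      if (m$id %in% model$metabolites$id) next
      model$metabolites[m$id, ] <- list(
        id = m$id, name = m$name %||% m$id, compartment = m$compartment %||% "c",
        formula = m$formula %||% NA_character_,
        carbons = as.numeric(m$carbons %||% NA_real_))
    }
    new_mets <- setdiff(names(unlist(r$stoich)), model$metabolites$id)
    for (mid in new_mets)
      model$metabolites[mid, ] <- list(id = mid, name = mid, compartment = "c",
                                       formula = NA_character_, carbons = NA_real_)
    r$stoich <- unlist(r$stoich)
    r$gpr <- r$gpr %||% ""
    r$rule <- parse_gpr(r$gpr)
    r$gpr <- deparse_gpr(r$rule)
    model$reactions[[r$id]] <- r
    model$genes <- sort(unique(c(model$genes, gpr_genes(r$rule))))
    model$reactions[[r$id]]$kind <- r$kind %||% derive_reaction_kind(model, r$id)
    return(model)
  }
  rid <- e$id %||% stop(op, " needs an 'id' payload")
  if (!rid %in% names(model$reactions))
    stop("no reaction ", sQuote(rid), " in the model")
  if (op == "remove_reaction") {
    model$reactions[[rid]] <- NULL
  } else if (op == "set_bounds") {
    if (!is.null(e$lb)) model$reactions[[rid]]$lb <- as.numeric(e$lb)
    if (!is.null(e$ub)) model$reactions[[rid]]$ub <- as.numeric(e$ub)
  } else if (op == "set_reversibility") {
    rev <- isTRUE(e$reversible)
    if (rev) {
      if (model$reactions[[rid]]$lb >= 0) model$reactions[[rid]]$lb <- -FLUX_BIG
    } else {
      model$reactions[[rid]]$lb <- max(model$reactions[[rid]]$lb, 0)
    }
  } else {
    stop("unknown edit operation ", sQuote(op))
  }
  model
}

#' Read a model edit list from YAML or JSON
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml` vs
#'   `.json`). The file holds a top-level list of edit objects as described
#'   in [patch_model()].
#' @return list of edits.
#' @export
read_model_edits <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
}
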