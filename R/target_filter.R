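#' Essential and nearly essential reactions
#'
#' A reaction is (nearly) essential when closing it (bounds `[0, 0]`) drops
#' the FBA optimum below `threshold_fraction` of the wild-type optimum. The
#' single 1% threshold covers both strictly essential and nearly essential
#' reactions.
#'
#' @param model a `metabolic_model`.
#' @param env optional `flux_environment`.
#' @param threshold_fraction growth fraction below which a knockout counts
#'   as lethal (default 0.01).
#' @return character vector of essential reaction ids.
#' @export
find_essential_reactions <- function(model, env = NULL, threshold_fraction = 0.01) {
  model <- apply_environment(model, env)
  wt <- fba(model)
  if (wt$status != "optimal" || wt$objective <= FLUX_TOL)
    stop("model cannot grow: wild-type optimum is ",
         if (wt$status == "optimal") format(wt$objective) else wt$status)
  ess <- character()
  for (rid in names(model$reactions)) {
    ko <- fba(close_reactions(model, rid))
    if (ko$status != "optimal" || ko$objective < threshold_fraction * wt$objective)
      ess <- c(ess, rid)
  }
  ess
}

#' Reactions unable to carry flux
#'
#' A reaction is blocked when flux variability analysis over the whole
#' feasible region (no objective constraint) confines its flux to zero.
#'
#' @param model a `metabolic_model`.
#' @param env optional `flux_environment`.
#' @param tol absolute flux threshold (default 1e-9).
#' @return character vector of blocked reaction ids.
#' @export
find_blocked_reactions <- function(model, env = NULL, tol = 1e-9) {
  rng <- fva(model, env, objective_fraction = NULL)
  rng$reaction[abs(rng$min) < tol & abs(rng$max) < tol]
}

#' Fully coupled reaction groups among candidates
#'
#' Two reactions are fully coupled (members of one co-set) when forcing
#' either to zero forces the other to zero; such reactions are
#' interchangeable as knockout targets. Coupling is tested pairwise in both
#' directions by FVA with the counterpart closed, and groups are the
#' transitive closure. Singleton groups are allowed.
#'
#' @param model a `metabolic_model`.
#' @param env optional `flux_environment`.
#' @param candidates reaction ids to partition (must be unblocked).
#' @return list of character vectors (sorted within and between groups).
#' @export
find_coupled_sets <- function(model, env = NULL, candidates) {
  model <- apply_environment(model, env)
  k <- length(candidates)
  if (k == 0L) return(list())
  forced <- matrix(FALSE, k, k, dimnames = list(candidates, candidates))
  for (i in seq_len(k)) {
    closed <- close_reactions(model, candidates[i])
    rng <- fva(closed, env = NULL, reactions = candidates[-i],
               objective_fraction = NULL)
    zero <- rng$reaction[abs(rng$min) < 1e-9 & abs(rng$max) < 1e-9]
    forced[i, match(zero, candidates)] <- TRUE
  }
  coupled <- forced & t(forced)
  # union-find over the coupling graph
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(k)) for (j in seq_len(k))
    if (coupled[i, j]) parent[find(j)] <- find(i)
  roots <- vapply(seq_len(k), find, integer(1))
  groups <- split(candidates, roots)
  groups <- lapply(groups, sort)
  names(groups) <- NULL
  groups[order(vapply(groups, `[`, character(1), 1))]
}

#' Select admissible knockout targets
#'
#' Reduces the model's reaction list to the candidate deletion targets for
#' the optimisation stage by applying, in order: (1) drop essential and
#' nearly essential reactions (growth below `essential_threshold` of wild
#' type when closed); (2) drop reactions without gene association; (3) drop
#' drains and transport reactions; (4) drop blocked reactions; (5) collapse
#' fully coupled groups to one representative (lexicographically smallest
#' id). The exclusion ledger records the first matching reason for every
#' excluded reaction.
#'
#' @param model a `metabolic_model`.
#' @param env optional `flux_environment`.
#' @param essential_threshold growth fraction defining (near-)essentiality.
#' @param exclude_transport drop transport reactions categorically (default
#'   `TRUE`); with `FALSE` transporters are only dropped if blocked.
#' @param kind_overrides optional named character vector overriding the
#'   derived reaction kind (`reaction id -> kind`), for models with
#'   inconsistent annotations.
#' @return object of class `candidate_set`: list with `candidates` (ordered
#'   ids), `ledger` (data frame `reaction_id`, `status`, `reason`,
#'   `coupled_group`) and `groups` (the coupled partition of the candidates
#'   before collapsing).
#' @export
select_candidates <- function(model, env = NULL, essential_threshold = 0.01,
                              exclude_transport = TRUE, kind_overrides = NULL) {
  all_rxns <- names(model$reactions)
  reason <- stats::setNames(rep(NA_character_, length(all_rxns)), all_rxns)

  ess <- find_essential_reactions(model, env, essential_threshold)
  reason[ess] <- "essential"

  kinds <- vapply(model$reactions, `[[`, character(1), "kind")
  if (!is.null(kind_overrides)) kinds[names(kind_overrides)] <- kind_overrides
  no_gene <- all_rxns[vapply(model$reactions, function(r) is.null(r$rule), logical(1))]
  reason[setdiff(no_gene, names(reason)[!is.na(reason)])] <- "non_gene"

  drains <- all_rxns[kinds == "exchange" |
                       (exclude_transport & kinds == "transport")]
  drains <- setdiff(drains, names(reason)[!is.na(reason)])
  reason[drains] <- "drain_or_transport"

  blocked <- find_blocked_reactions(model, env)
  blocked <- setdiff(blocked, names(reason)[!is.na(reason)])
  reason[blocked] <- "blocked"

  remaining <- all_rxns[is.na(reason)]
  groups <- if (length(remaining) > 0)
    find_coupled_sets(model, env, remaining) else list()
  group_id <- stats::setNames(rep(NA_integer_, length(all_rxns)), all_rxns)
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    group_id[g] <- gi
    if (length(g) > 1L) reason[g[-1L]] <- "coupled_duplicate"
  }
  candidates <- all_rxns[is.na(reason)]
  if (length(candidates) == 0L)
    warning("no admissible knockout candidates remain after filtering")

  ledger <- data.frame(
    reaction_id = all_rxns,
    status = ifelse(is.na(reason), "candidate", "excluded"),
    reason = ifelse(is.na(reason), "", reason),
    coupled_group = group_id,
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(candidates = candidates, ledger = ledger, groups = groups),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("<candidate_set> ", length(x$candidates), " candidate(s): ",
      paste(x$candidates, collapse = ", "), "\n", sep = "")
  excl <- x$ledger[x$ledger$status == "excluded", ]
  if (nrow(excl) > 0) {
    tab <- table(excl$reason)
    cat("  excluded: ", paste(sprintf("%s (%d)", names(tab), tab),
                              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Write a candidate set as TSV
#' @param cs a `candidate_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_candidates_tsv <- function(cs, path) {
  utils::write.table(cs$ledger, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
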