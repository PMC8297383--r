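#' Read a fold-change table
#'
#' Expects a TSV with header `feature_id`, `layer`, `log2fc`, `qvalue`:
#' one row per measured feature, where `layer` tags the omics layer
#' (`gene`, `protein` or `metabolite`), `log2fc` is the log2 fold change
#' between the two compared conditions and `qvalue` the multiple-testing
#' adjusted significance. Duplicate `(feature, layer)` rows and q-values
#' outside \[0, 1\] are rejected.
#'
#' @param path TSV file path.
#' @return an `omics_table` data frame.
#' @export
read_omics_table <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("feature_id", "layer", "log2fc", "qvalue")
  if (!all(need %in% names(d)))
    stop("omics table must have columns: ", paste(need, collapse = ", "))
  bad <- which(!d$layer %in% c("gene", "protein", "metabolite") |
                 is.na(d$log2fc) | is.na(d$qvalue) |
                 d$qvalue < 0 | d$qvalue > 1)
  if (length(bad) > 0)
    stop("malformed omics record at line ", bad[1] + 1L,
         " (layer must be gene/protein/metabolite, q-value in [0,1])")
  dup <- duplicated(d[, c("feature_id", "layer")])
  if (any(dup))
    stop("duplicate (feature, layer) record at line ", which(dup)[1] + 1L)
  class(d) <- c("omics_table", "data.frame")
  d
}

# fold-change aggregation over a GPR tree: a complex (AND) is limited by
# its scarcest subunit (min), isozymes (OR) by the dominant one (max);
# members without a measurement are neutral (dropped from the aggregate).
aggregate_gpr_fc <- function(rule, fc_map, and_fun = min, or_fun = max) {
  if (is.character(rule)) {
    if (rule %in% names(fc_map)) return(fc_map[[rule]])
    return(NA_real_)
  }
  vals <- vapply(rule$args, aggregate_gpr_fc, numeric(1),
                 fc_map = fc_map, and_fun = and_fun, or_fun = or_fun)
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) return(NA_real_)
  if (rule$op == "and") and_fun(vals) else or_fun(vals)
}

#' Map omics fold changes onto reactions
#'
#' Keeps significantly changed features (`qvalue < q_max`), converts log2
#' fold changes to linear ratios, and propagates them through the GPR rules:
#' AND nodes take the minimum of their members' fold changes, OR nodes the
#' maximum. When both the transcript and the protein layer cover a reaction
#' the protein value wins (protein abundance is the nearer proxy for flux
#' capacity). Features matching no model gene are skipped with a message.
#'
#' @param model a `metabolic_model`.
#' @param omics an `omics_table` (or data frame with the same columns).
#' @param q_max significance cut-off (default 0.1, strict `<`).
#' @param prefer which layer wins when both cover a reaction
#'   (default `"protein"`).
#' @return named numeric vector `reaction id -> linear fold change`;
#'   reactions with no covered feature are absent.
#' @export
build_reaction_fold_changes <- function(model, omics, q_max = 0.1,
                                        prefer = c("protein", "gene")) {
  prefer <- match.arg(prefer)
  sig <- omics[omics$qvalue < q_max & omics$layer %in% c("gene", "protein"), ,
               drop = FALSE]
  unknown <- setdiff(unique(sig$feature_id), model$genes)
  if (length(unknown) > 0)
    message("skipping ", length(unknown),
            " feature(s) matching no model gene: ",
            paste(utils::head(unknown, 5), collapse = ", "),
            if (length(unknown) > 5) ", ...")
  sig <- sig[sig$feature_id %in% model$genes, , drop = FALSE]
  layer_map <- function(layer) {
    rows <- sig[sig$layer == layer, , drop = FALSE]
    stats::setNames(2^rows$log2fc, rows$feature_id)
  }
  maps <- list(gene = layer_map("gene"), protein = layer_map("protein"))
  out <- numeric(0)
  for (rid in names(model$reactions)) {
    rule <- model$reactions[[rid]]$rule
    if (is.null(rule)) next
    first <- aggregate_gpr_fc(rule, maps[[prefer]])
    second <- aggregate_gpr_fc(rule, maps[[setdiff(c("gene", "protein"), prefer)]])
    val <- if (!is.na(first)) first else second
    if (!is.na(val)) out[rid] <- val
  }
  out
}

#' Fit condition-specific fluxes to omics constraints
#'
#' Estimates a flux distribution for a perturbed condition by requiring each
#' constrained reaction to scale its reference flux by the measured fold
#' change, as softly as the network allows. For every reaction `r` with fold
#' change `f_r` a soft constraint `v_r = f_r * v_ref_r` is enforced through
#' a non-negative slack pair; exometabolite fold changes constrain the
#' corresponding exchange flux the same way. Growth is required to reach
#' `growth_frac` of the reference optimum (`growth_frac = 1` is wild type).
#' The LP minimises total slack, then minimises total absolute flux among
#' the minimal-slack solutions.
#'
#' @param model the (perturbed) `metabolic_model`.
#' @param env optional `flux_environment`.
#' @param reference a `flux_distribution` (or named fluxes) of the reference
#'   condition, typically wild-type pFBA of the unperturbed model.
#' @param rxn_fold_changes named numeric `reaction id -> linear fold change`
#'   (from [build_reaction_fold_changes()]).
#' @param metabolite_fold_changes named numeric `metabolite id -> linear
#'   fold change` applied to that metabolite's exchange reaction.
#' @param growth_frac fraction of the reference FBA optimum the fit must
#'   attain (default 1).
#' @param reference_optimum the reference optimum used for the growth
#'   constraint; defaults to the FBA optimum of `model` under `env`
#'   (supply the unperturbed optimum when `model` is a knockout).
#' @return a `condition_fit`: list with `fitted` (`flux_distribution`),
#'   `reference`, `growth_frac`, `applied` (reaction targets) and
#'   `total_slack`.
#' @export
fit_condition_fluxes <- function(model, env = NULL, reference,
                                 rxn_fold_changes = numeric(),
                                 metabolite_fold_changes = numeric(),
                                 growth_frac = 1,
                                 reference_optimum = NULL) {
  model <- apply_environment(model, env)
  ref <- if (inherits(reference, "flux_distribution")) reference$fluxes else reference
  S <- stoich_matrix(model)
  n <- ncol(S); m <- nrow(S)
  bnds <- reaction_bounds(model)

  # exometabolite changes -> exchange-reaction fold changes
  for (met in names(metabolite_fold_changes)) {
    exch <- names(model$reactions)[vapply(model$reactions, function(r)
      length(r$stoich) == 1L && names(r$stoich) == met, logical(1))]
    if (length(exch) == 0L) {
      message("no exchange reaction found for metabolite ", sQuote(met),
              "; skipped")
      next
    }
    for (e in exch)
      if (!e %in% names(rxn_fold_changes))
        rxn_fold_changes[e] <- metabolite_fold_changes[[met]]
  }

  con <- intersect(names(rxn_fold_changes), colnames(S))
  targets <- vapply(con, function(r) {
    vr <- if (r %in% names(ref)) ref[[r]] else 0
    rxn_fold_changes[[r]] * vr
  }, numeric(1))
  zero_ref <- con[vapply(con, function(r)
    !(r %in% names(ref)) || abs(ref[[r]]) < FLUX_TOL, logical(1))]
  if (length(zero_ref) > 0)
    message("fold change on zero reference flux pins ",
            paste(zero_ref, collapse = ", "), " at 0")

  opt_ref <- reference_optimum
  if (is.null(opt_ref)) {
    base <- fba(model)
    if (base$status != "optimal") stop("reference problem is ", base$status)
    opt_ref <- base$objective
  }
  need_growth <- growth_frac * opt_ref

  k <- length(con)
  lb <- bnds[, "lb"]; ub <- bnds[, "ub"]
  iobj <- which(colnames(S) == model$objective)
  lb[iobj] <- max(lb[iobj], need_growth - 1e-9 * max(1, abs(need_growth)))
  if (lb[iobj] > ub[iobj] + FLUX_TOL)
    stop("growth_frac constraint infeasible: requires objective ",
         format(need_growth), " but its upper bound is ", format(ub[iobj]))

  # stage 1: vars (v, p, q); rows S v = 0 and v_r - p_r + q_r = target_r
  sel <- matrix(0, k, n); if (k > 0) sel[cbind(seq_len(k), match(con, colnames(S)))] <- 1
  A1 <- rbind(cbind(S, matrix(0, m, 2 * k)),
              if (k > 0) cbind(sel, -diag(k), diag(k)))
  colnames(A1) <- c(colnames(S), if (k > 0) paste0("slack_pos_", con),
                    if (k > 0) paste0("slack_neg_", con))
  obj1 <- c(rep(0, n), rep(1, 2 * k))
  res1 <- solve_lp(obj1, A1, c(rep(0, m), targets),
                   c(lb, rep(0, 2 * k)), c(ub, rep(Inf, 2 * k)),
                   maximize = FALSE)
  if (res1$status != "optimal") {
    diag_msg <- paste0(
      "omics fit infeasible (growth_frac = ", format(growth_frac),
      "); binding constraints: objective >= ", format(need_growth),
      if (k > 0) paste0("; soft targets on ", paste(con, collapse = ", ")))
    stop(diag_msg)
  }
  slack <- res1$objective

  # stage 2: among minimal-slack solutions, minimise total |v|:
  # vars (w+, w-, p, q, t); extra row caps total slack at its optimum
  lo <- c(pmax(0, lb), pmax(0, -ub), rep(0, 2 * k), 0)
  hi <- c(pmax(0, ub), pmax(0, -lb), rep(Inf, 2 * k), Inf)
  A2 <- rbind(
    cbind(S, -S, matrix(0, m, 2 * k + 1)),
    if (k > 0) cbind(sel, -sel, -diag(k), diag(k), matrix(0, k, 1)),
    c(rep(0, 2 * n), rep(1, 2 * k), 1))
  colnames(A2) <- c(colnames(S), paste0(colnames(S), "__rev"),
                    if (k > 0) paste0("slack_pos_", con),
                    if (k > 0) paste0("slack_neg_", con), "slack_cap")
  obj2 <- c(rep(1, 2 * n), rep(0, 2 * k), 0)
  res2 <- solve_lp(obj2, A2, c(rep(0, m), targets, slack + 1e-9),
                   lo, hi, maximize = FALSE)
  v <- if (res2$status == "optimal") {
    out <- res2$x[seq_len(n)] - res2$x[n + seq_len(n)]
    names(out) <- colnames(S)
    out
  } else {
    out <- res1$x[seq_len(n)]
    names(out) <- colnames(S)
    out
  }

  structure(list(
    fitted = new_flux_distribution(v, v[[model$objective]], "optimal"),
    reference = ref, growth_frac = growth_frac,
    applied = stats::setNames(targets, con), total_slack = slack),
    class = "condition_fit")
}

#' @export
print.condition_fit <- function(x, ...) {
  cat("<condition_fit> growth:", format(x$fitted$objective),
      " constrained reactions:", length(x$applied),
      " total slack:", format(x$total_slack), "\n")
  invisible(x)
}

#' Pairwise distances between flux distributions
#'
#' Euclidean distances over the union of reaction ids (missing reactions
#' count as zero flux); the matrix feeding ordination of condition-specific
#' flux states.
#'
#' @param distributions list of `flux_distribution` objects, `condition_fit`
#'   objects or named flux vectors (named list names label the output).
#' @return symmetric numeric distance matrix with zero diagonal.
#' @export
compare_flux_distributions <- function(distributions) {
  if (length(distributions) == 0L) stop("no flux distributions given")
  vecs <- lapply(distributions, function(d) {
    if (inherits(d, "condition_fit")) d <- d$fitted
    if (inherits(d, "flux_distribution")) d <- d$fluxes
    d
  })
  ids <- sort(unique(unlist(lapply(vecs, names))))
  M <- do.call(rbind, lapply(vecs, function(v) {
    out <- stats::setNames(rep(0, length(ids)), ids)
    out[names(v)] <- v
    out
  }))
  rownames(M) <- names(distributions) %||% paste0("d", seq_along(vecs))
  as.matrix(stats::dist(M, method = "euclidean"))
}
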