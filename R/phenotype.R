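# Post-hoc numerical tolerance for all flux comparisons (mmol/gDW/h scale);
# the LP core itself works at 1e-9.
FLUX_TOL <- 1e-6

#' Define an environment (medium) for simulation
#'
#' An environment caps the uptake of boundary metabolites. Limits are given
#' as non-negative magnitudes on exchange reactions and translated onto the
#' model's flux-sign convention: for a drain-form exchange (metabolite out,
#' negative flux = uptake) the limit sets the lower bound to `-limit`; for a
#' source-form exchange (positive flux = uptake, as in the toy fixtures) it
#' sets the upper bound. Exchanges named in `unrestricted` (typically oxygen)
#' get the full flux box.
#'
#' @param uptake_limits named numeric vector: exchange reaction id to maximum
#'   uptake magnitude in mmol/gDW/h.
#' @param unrestricted character vector of exchange reaction ids with no
#'   uptake cap.
#' @param substrate id of the carbon-substrate exchange reaction, used to
#'   report substrate uptake and carbon yields; defaults to the single
#'   limited exchange when exactly one limit is given.
#' @return object of class `flux_environment`.
#' @export
flux_environment <- function(uptake_limits = numeric(), unrestricted = character(),
                             substrate = NULL) {
  if (length(uptake_limits) > 0) {
    stopifnot(!is.null(names(uptake_limits)), all(uptake_limits >= 0))
  }
  if (is.null(substrate) && length(uptake_limits) == 1L)
    substrate <- names(uptake_limits)
  structure(list(uptake_limits = uptake_limits,
                 unrestricted = unrestricted,
                 substrate = substrate),
            class = "flux_environment")
}

#' Apply an environment to a model
#' @param model a `metabolic_model`.
#' @param env a `flux_environment` (or `NULL`, returning the model as-is).
#' @return the constrained model.
#' @export
apply_environment <- function(model, env) {
  if (is.null(env)) return(model)
  stopifnot(inherits(env, "flux_environment"))
  set_uptake <- function(model, rid, mag) {
    if (!rid %in% names(model$reactions))
      stop("environment references unknown exchange reaction ", sQuote(rid))
    coef <- model$reactions[[rid]]$stoich
    if (length(coef) != 1L)
      stop("environment limit on non-exchange reaction ", sQuote(rid))
    if (coef > 0) {            # source form: positive flux = uptake
      model$reactions[[rid]]$ub <- mag
      model$reactions[[rid]]$lb <- max(model$reactions[[rid]]$lb, 0)
    } else {                   # drain form: negative flux = uptake
      model$reactions[[rid]]$lb <- -mag
    }
    model
  }
  for (rid in names(env$uptake_limits))
    model <- set_uptake(model, rid, env$uptake_limits[[rid]])
  for (rid in env$unrestricted)
    model <- set_uptake(model, rid, FLUX_BIG)
  model
}

# substrate exchange id from env or the model's own annotation
substrate_of <- function(model, env) {
  if (!is.null(env) && !is.null(env$substrate)) return(env$substrate)
  if (!is.null(model$annotation$substrate)) return(model$annotation$substrate)
  NULL
}

new_flux_distribution <- function(fluxes, objective, status) {
  structure(list(fluxes = fluxes, objective = objective, status = status),
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat("<flux_distribution> status:", x$status,
      " objective:", format(x$objective), "\n")
  invisible(x)
}

#' Flux balance analysis
#'
#' Maximises the objective reaction flux subject to steady-state mass balance
#' (`S v = 0`) and flux bounds merged with the environment. Returns the
#' optimum and one optimal vertex; alternate optima are explored with
#' [fva()], never inferred from the returned vertex.
#'
#' @param model a `metabolic_model` with an objective reaction.
#' @param env optional `flux_environment`.
#' @return a `flux_distribution` with `status` `"optimal"`, `"infeasible"`
#'   or `"unbounded"`.
#' @export
fba <- function(model, env = NULL) {
  model <- apply_environment(model, env)
  S <- stoich_matrix(model)
  bnds <- reaction_bounds(model)
  obj <- as.numeric(colnames(S) == model$objective)
  res <- solve_lp(obj, S, rep(0, nrow(S)), bnds[, "lb"], bnds[, "ub"],
                  maximize = TRUE)
  if (res$status != "optimal")
    return(new_flux_distribution(NULL, NA_real_, res$status))
  new_flux_distribution(res$x, res$objective, "optimal")
}

# Minimise total absolute flux at (a fraction of) a fixed objective value by
# splitting each net flux into non-negative forward/reverse parts.
# Returns list(fluxes, total_flux, status).
min_total_flux <- function(model, fix_objective) {
  S <- stoich_matrix(model)
  bnds <- reaction_bounds(model)
  n <- ncol(S)
  lb <- pmax(bnds[, "lb"], -FLUX_BIG); ub <- pmin(bnds[, "ub"], FLUX_BIG)
  lo <- c(pmax(0, lb), pmax(0, -ub))
  hi <- c(pmax(0, ub), pmax(0, -lb))
  iobj <- which(colnames(S) == model$objective)
  if (!is.null(fix_objective) && fix_objective > 0)
    lo[iobj] <- max(lo[iobj], fix_objective)
  A <- cbind(S, -S)
  colnames(A) <- c(colnames(S), paste0(colnames(S), "__rev"))
  w <- rep(1, 2 * n)
  res <- solve_lp(w, A, rep(0, nrow(S)), lo, hi, maximize = FALSE)
  if (res$status != "optimal")
    return(list(fluxes = NULL, total_flux = NA_real_, status = res$status))
  v <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
  names(v) <- colnames(S)
  list(fluxes = v, total_flux = res$objective, status = "optimal")
}

new_phenotype_result <- function(method, growth, fluxes, status,
                                 substrate = NULL, extra = list()) {
  uptake <- if (!is.null(substrate) && !is.null(fluxes) &&
                substrate %in% names(fluxes)) abs(fluxes[[substrate]]) else NA_real_
  structure(c(list(method = method, growth = growth,
                   substrate_uptake = uptake,
                   fluxes = new_flux_distribution(fluxes, growth, status),
                   status = status), extra),
            class = "phenotype_result")
}

#' @export
print.phenotype_result <- function(x, ...) {
  cat("<phenotype_result> method:", x$method, " status:", x$status,
      " growth:", format(x$growth), "\n")
  invisible(x)
}

#' Parsimonious flux balance analysis (pFBA)
#'
#' Two-stage linear program: (1) maximise the objective flux; (2) holding
#' the objective at its optimum (relative tolerance 1e-6), minimise the sum
#' of absolute fluxes. The reported growth is the stage-1 optimum. Among
#' flux-minimal optima the returned vertex is whichever the solver reaches
#' deterministically; robustness statements about individual fluxes should
#' use [fva()].
#'
#' @param model a `metabolic_model`.
#' @param env optional `flux_environment`.
#' @param objective_fraction fraction of the stage-1 optimum enforced in
#'   stage 2 (default 1, i.e. full optimality).
#' @return a `phenotype_result`; element `total_flux` holds the minimised
#'   sum of absolute fluxes.
#' @export
pfba <- function(model, env = NULL, objective_fraction = 1) {
  model <- apply_environment(model, env)
  stage1 <- fba(model)
  if (stage1$status != "optimal")
    return(new_phenotype_result("pfba", 0, NULL, stage1$status,
                                substrate_of(model, env),
                                extra = list(total_flux = NA_real_)))
  fix <- stage1$objective * objective_fraction * (1 - 1e-9)
  stage2 <- min_total_flux(model, fix_objective = fix)
  if (stage2$status != "optimal")   # should not happen: stage-1 vertex feasible
    return(new_phenotype_result("pfba", stage1$objective, stage1$fluxes,
                                stage2$status, substrate_of(model, env),
                                extra = list(total_flux = NA_real_)))
  new_phenotype_result("pfba", stage1$objective, stage2$fluxes, "optimal",
                       substrate_of(model, env),
                       extra = list(total_flux = stage2$total_flux))
}

#' Linear minimisation of metabolic adjustment (lMOMA)
#'
#' Finds the mutant flux distribution of minimal L1 distance to a reference
#' distribution, subject to the mutant's steady-state and bound constraints.
#' The growth reported is whatever the distance-minimal distribution
#' achieves; it is not re-optimised. Reactions absent from the reference
#' contribute `|v|` (reference flux 0).
#'
#' @param model the (typically perturbed) `metabolic_model`.
#' @param env optional `flux_environment`.
#' @param reference a `flux_distribution` (or named flux vector), usually
#'   wild-type pFBA.
#' @return a `phenotype_result`; element `distance` holds the achieved L1
#'   distance.
#' @export
lmoma <- function(model, env = NULL, reference) {
  model <- apply_environment(model, env)
  ref <- if (inherits(reference, "flux_distribution")) reference$fluxes else reference
  S <- stoich_matrix(model)
  n <- ncol(S); m <- nrow(S)
  bnds <- reaction_bounds(model)
  refv <- ifelse(colnames(S) %in% names(ref), ref[colnames(S)], 0)
  refv[is.na(refv)] <- 0
  # variables: v (n), p (n), q (n); rows: S v = 0 ; v - p + q = ref
  A <- rbind(cbind(S, matrix(0, m, 2 * n)),
             cbind(diag(n), -diag(n), diag(n)))
  colnames(A) <- c(colnames(S), paste0("dev_pos_", colnames(S)),
                   paste0("dev_neg_", colnames(S)))
  obj <- c(rep(0, n), rep(1, 2 * n))
  lo <- c(bnds[, "lb"], rep(0, 2 * n))
  hi <- c(bnds[, "ub"], rep(Inf, 2 * n))
  res <- solve_lp(obj, A, c(rep(0, m), refv), lo, hi, maximize = FALSE)
  if (res$status != "optimal")
    return(new_phenotype_result("lmoma", 0, NULL, res$status,
                                substrate_of(model, env),
                                extra = list(distance = NA_real_)))
  v <- res$x[seq_len(n)]
  names(v) <- colnames(S)
  new_phenotype_result("lmoma", v[[model$objective]], v, "optimal",
                       substrate_of(model, env),
                       extra = list(distance = res$objective))
}

#' Flux variability analysis (FVA)
#'
#' For each requested reaction, minimises and maximises its flux subject to
#' the objective flux being at least `objective_fraction` of its optimum.
#' With `objective_fraction = NULL` (or 0) the objective is unconstrained,
#' which is the setting used to detect blocked reactions.
#'
#' @param model a `metabolic_model`.
#' @param env optional `flux_environment`.
#' @param reactions reaction ids to scan (default: all).
#' @param objective_fraction fraction of the optimal objective to enforce
#'   (default 1: variability among fully optimal solutions).
#' @return data frame with columns `reaction`, `min`, `max`.
#' @export
fva <- function(model, env = NULL, reactions = NULL, objective_fraction = 1) {
  model <- apply_environment(model, env)
  if (is.null(reactions)) reactions <- names(model$reactions)
  if (length(reactions) == 0L)
    return(data.frame(reaction = character(), min = numeric(),
                      max = numeric(), stringsAsFactors = FALSE))
  unknown <- setdiff(reactions, names(model$reactions))
  if (length(unknown) > 0)
    stop("unknown reaction(s): ", paste(unknown, collapse = ", "))
  S <- stoich_matrix(model)
  bnds <- reaction_bounds(model)
  lb <- bnds[, "lb"]; ub <- bnds[, "ub"]
  if (!is.null(objective_fraction) && objective_fraction > 0) {
    opt <- fba(model)
    if (opt$status != "optimal")
      stop("FVA base problem is ", opt$status)
    iobj <- model$objective
    lb[iobj] <- max(lb[iobj],
                    objective_fraction * opt$objective * (1 - 1e-9) - 1e-12)
  }
  out <- data.frame(reaction = reactions, min = NA_real_, max = NA_real_,
                    stringsAsFactors = FALSE)
  b0 <- rep(0, nrow(S))
  for (k in seq_along(reactions)) {
    obj <- as.numeric(colnames(S) == reactions[k])
    lo <- solve_lp(obj, S, b0, lb, ub, maximize = FALSE)
    hi <- solve_lp(obj, S, b0, lb, ub, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("FVA subproblem for ", reactions[k], " is ", lo$status)
    out$min[k] <- lo$objective
    out$max[k] <- hi$objective
  }
  out
}

#' Simulate a gene-knockout phenotype
#'
#' Composes [apply_gene_deletions()] with a phenotype predictor under a fixed
#' environment: the setting used to assess the contribution of individual
#' knockouts to production. Substrate uptake is reported as a non-negative
#' magnitude regardless of the exchange sign convention.
#'
#' @param model a `metabolic_model`.
#' @param env optional `flux_environment`.
#' @param genes character vector of gene ids to delete.
#' @param method `"pfba"` (default) or `"lmoma"`.
#' @param reference reference distribution for lMOMA; defaults to the pFBA
#'   distribution of the unmodified model.
#' @param product optional product exchange id; when given, the result
#'   carries `product_flux`.
#' @return a `phenotype_result`.
#' @export
simulate_knockout <- function(model, env = NULL, genes = character(),
                              method = c("pfba", "lmoma"), reference = NULL,
                              product = NULL) {
  method <- match.arg(method)
  mutant <- apply_gene_deletions(model, genes)
  res <- if (method == "pfba") {
    pfba(mutant, env)
  } else {
    if (is.null(reference)) reference <- pfba(model, env)$fluxes
    lmoma(mutant, env, reference)
  }
  if (!is.null(product) && !is.null(res$fluxes$fluxes))
    res$product_flux <- res$fluxes$fluxes[[product]]
  res$deleted_genes <- sort(unique(genes))
  res
}
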