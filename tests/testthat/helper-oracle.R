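# Independent oracles used throughout the suite. These deliberately avoid
# the package's own LP layer and scoring code: LPs go through boot::simplex
# (pure-R, recommended-package routine), Pareto fronts through exhaustive
# subset enumeration, and the gene/chassis scores through literal
# re-implementations of their defining formulas.

# Solve min/max obj'v s.t. A v = b, lo <= v <= up with boot::simplex by
# splitting v into non-negative parts. Returns list(status, objective).
oracle_lp <- function(obj, A, b, lo, up, maximize = FALSE) {
  n <- ncol(A)
  lo <- pmax(lo, -1000); up <- pmin(up, 1000)
  A3 <- cbind(A, -A); b3 <- b
  A1 <- NULL; b1 <- NULL; A2 <- NULL; b2 <- NULL
  for (j in seq_len(n)) {
    e <- rep(0, 2 * n); e[j] <- 1; e[n + j] <- -1
    if (up[j] >= 0) { A1 <- rbind(A1, e); b1 <- c(b1, up[j]) }
    else { A2 <- rbind(A2, -e); b2 <- c(b2, -up[j]) }
    if (lo[j] <= 0) { A1 <- rbind(A1, -e); b1 <- c(b1, -lo[j]) }
    else { A2 <- rbind(A2, e); b2 <- c(b2, lo[j]) }
  }
  neg <- b3 < 0
  A3[neg, ] <- -A3[neg, , drop = FALSE]; b3[neg] <- -b3[neg]
  r <- boot::simplex(a = c(obj, -obj), A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                     A3 = A3, b3 = b3, maxi = maximize)
  if (r$solved != 1) return(list(status = "not_optimal", objective = NA_real_))
  list(status = "optimal", objective = unname(r$value))
}

# FBA optimum through the oracle LP.
oracle_fba <- function(model, env = NULL) {
  model <- apply_environment(model, env)
  S <- stoich_matrix(model)
  lb <- vapply(model$reactions, `[[`, numeric(1), "lb")
  ub <- vapply(model$reactions, `[[`, numeric(1), "ub")
  obj <- as.numeric(colnames(S) == model$objective)
  oracle_lp(obj, S, rep(0, nrow(S)), lb, ub, maximize = TRUE)
}

# Exhaustive Pareto front over all non-empty deletion subsets of size <=
# max_d, in (growth, product) objective space, deduplicated and sorted.
oracle_front <- function(model, env, candidates, product, max_d = 3) {
  objs <- list()
  for (k in seq_len(min(max_d, length(candidates)))) {
    for (idx in utils::combn(length(candidates), k, simplify = FALSE)) {
      dels <- candidates[idx]
      m2 <- patch_model(model, lapply(dels, function(d)
        list(op = "set_bounds", id = d, lb = 0, ub = 0)))
      ph <- pfba(m2, env)
      objs[[length(objs) + 1L]] <-
        if (ph$status != "optimal" || ph$growth < 1e-6) c(0, 0)
        else c(ph$growth, ph$fluxes$fluxes[[product]])
    }
  }
  M <- unique(round(do.call(rbind, objs), 6))
  nd <- vapply(seq_len(nrow(M)), function(i)
    !any(vapply(seq_len(nrow(M)), function(j)
      j != i && all(M[j, ] >= M[i, ]) && any(M[j, ] > M[i, ]), logical(1))),
    logical(1))
  F <- M[nd, , drop = FALSE]
  F[order(F[, 1], F[, 2]), , drop = FALSE]
}

# front of an archive returned by spea2_search, in the same normal form
archive_front <- function(archive) {
  M <- unique(round(do.call(rbind, lapply(archive, function(s)
    c(s$metrics$growth, s$metrics$product_flux))), 6))
  M[order(M[, 1], M[, 2]), , drop = FALSE]
}

# Literal gene score: sum of frequencies times the count of targets with
# positive frequency.
oracle_gscore <- function(freq_row) {
  sum(freq_row) * sum(freq_row > 0)
}

# Literal chassis score over explicit solution lists:
# sum over targets of max(CYIELD)/min(COST) among solutions that contain
# the chassis and pass the identified-maximum yield filter.
oracle_cscore <- function(chassis, sol_lists, cyield_fraction = 0.95) {
  total <- 0
  for (t in names(sol_lists)) {
    sols <- sol_lists[[t]]
    cy_all <- vapply(sols, function(s) s$metrics$cyield, numeric(1))
    ok <- vapply(sols, function(s)
      all(chassis %in% s$genes), logical(1)) &
      cy_all >= cyield_fraction * max(cy_all)
    if (!any(ok)) next
    total <- total + max(cy_all[ok]) /
      min(vapply(sols[ok], function(s) s$metrics$cost, numeric(1)))
  }
  total
}

# random solution-set fixture for scoring tests: each target gets a few
# solutions over a small gene pool with random yields/costs
random_sol_fixture <- function(n_targets = 3, pool = paste0("g", 1:6)) {
  sets <- lapply(seq_len(n_targets), function(t) {
    lapply(seq_len(sample(2:5, 1)), function(i) {
      genes <- sort(sample(pool, sample(1:3, 1)))
      list(genes = genes,
           metrics = list(cyield = round(stats::runif(1, 0.1, 0.9), 3),
                          cost = length(genes)))
    })
  })
  names(sets) <- paste0("t", seq_len(n_targets))
  sets
}

toy_env <- function() flux_environment(substrate = "UP")
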