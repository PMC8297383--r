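#' Configuration for the knockout search
#'
#' Bundles the search parameters: the target product drain, the deletion-set
#' size cap, the evaluation budget, SPEA2 population/archive sizes, the
#' variation-operator rates and the master seed. Defaults follow canonical
#' SPEA2 practice (binary tournament mating, k-nearest-neighbour density,
#' uniform set crossover at rate 0.8, one add/remove/replace mutation event
#' per offspring); population and archive default to 100 and a run spends
#' 100,000 evaluations.
#'
#' @param product target product exchange reaction id.
#' @param max_deletions maximum deletion-set size (default 20).
#' @param budget function evaluations allowed per run (default 100000).
#' @param archive_size solutions retained by the archive manager (default 100).
#' @param pop_size offspring generated per generation (default 100).
#' @param runs independent optimisation runs to merge (default 10).
#' @param cross_rate crossover probability (default 0.8).
#' @param seed master seed; run `i` uses `seed + i - 1`.
#' @return a `search_config` list.
#' @export
search_config <- function(product, max_deletions = 20, budget = 100000,
                          archive_size = 100, pop_size = 100, runs = 10,
                          cross_rate = 0.8, seed = 1) {
  stopifnot(max_deletions >= 1, budget >= 1, archive_size >= 1,
            pop_size >= 1, runs >= 1, cross_rate >= 0, cross_rate <= 1)
  structure(list(product = product, max_deletions = max_deletions,
                 budget = budget, archive_size = archive_size,
                 pop_size = pop_size, runs = runs, cross_rate = cross_rate,
                 seed = seed),
            class = "search_config")
}

#' Evaluate a knockout solution
#'
#' Applies the reaction deletions, predicts the phenotype with pFBA and
#' scores it: growth, substrate uptake magnitude, product flux, the FVA
#' range of the product at optimal growth, the carbon yield
#' `CYIELD = (v_product * C_product) / (v_substrate * C_substrate)`, the
#' biomass-product coupled yield `BPCY = (growth * v_product) / v_substrate`
#' and the implementation cost (size of the smallest gene-deletion set
#' realising the reaction deletions). Dead or infeasible phenotypes score
#' zero everywhere; they are kept, not discarded, so the search can traverse
#' them.
#'
#' @param model a `metabolic_model`.
#' @param env a `flux_environment` naming the substrate exchange.
#' @param deletions character vector of reaction ids to knock out.
#' @param product product exchange reaction id.
#' @param carbons optional named numeric map `exchange id -> carbon count`
#'   overriding metabolite metadata (required when the model lacks carbon
#'   information for the product or substrate).
#' @return a `solution_metrics` list: `growth`, `uptake`, `product_flux`,
#'   `fva_min`, `fva_max`, `bpcy`, `cyield`, `cost`.
#' @export
evaluate_solution <- function(model, env, deletions, product, carbons = NULL) {
  if (!product %in% names(model$reactions))
    stop("unknown product exchange ", sQuote(product))
  substrate <- substrate_of(model, env)
  if (is.null(substrate))
    stop("environment does not name a substrate exchange")
  exch_carbons <- function(exch) {
    if (!is.null(carbons) && exch %in% names(carbons)) return(carbons[[exch]])
    met <- names(model$reactions[[exch]]$stoich)
    tryCatch(carbon_content(model, met),
             error = function(e) stop(
               "unknown carbon content for ", sQuote(exch),
               "; supply a carbon map (carbons = c(", exch, " = <atoms>))",
               call. = FALSE))
  }
  cp <- exch_carbons(product)
  cs <- exch_carbons(substrate)

  mutant <- close_reactions(model, deletions)
  ph <- pfba(mutant, env)
  dead <- ph$status != "optimal" || ph$growth < FLUX_TOL
  if (dead) {
    metrics <- list(growth = 0, uptake = 0, product_flux = 0,
                    fva_min = 0, fva_max = 0, bpcy = 0, cyield = 0)
  } else {
    v_p <- ph$fluxes$fluxes[[product]]
    up <- ph$substrate_uptake
    rng <- fva(mutant, env, product, objective_fraction = 1)
    metrics <- list(
      growth = ph$growth, uptake = up, product_flux = v_p,
      fva_min = rng$min[1], fva_max = rng$max[1],
      bpcy = if (up > FLUX_TOL) ph$growth * v_p / up else 0,
      cyield = if (up > FLUX_TOL) max(0, v_p * cp) / (up * cs) else 0)
  }
  metrics$cost <- tryCatch(length(gene_deletion_sets(model, deletions)[[1]]),
                           error = function(e) NA_integer_)
  structure(metrics, class = "solution_metrics")
}

# Minimal gene-deletion sets realising a set of reaction deletions: the
# cross-combination of each reaction's minimal GPR cut sets, reduced to the
# minimal combinations, smallest first (ties broken lexicographically).
gene_deletion_sets <- function(model, deletions) {
  per_rxn <- lapply(deletions, function(rid) {
    r <- model$reactions[[rid]]
    if (is.null(r)) stop("unknown reaction ", sQuote(rid))
    if (is.null(r$rule))
      stop("reaction ", sQuote(rid), " has no gene association",
           " (should have been filtered)")
    minimal_gene_cuts(r$rule)
  })
  combos <- list(character())
  for (cuts in per_rxn) {
    combos <- unlist(lapply(combos, function(base)
      lapply(cuts, function(cut) sort(unique(c(base, cut))))), recursive = FALSE)
    combos <- unique(combos)
  }
  # drop non-minimal combinations
  keep <- vapply(seq_along(combos), function(i) {
    !any(vapply(seq_along(combos), function(j)
      j != i && length(combos[[j]]) < length(combos[[i]]) &&
        all(combos[[j]] %in% combos[[i]]), logical(1)))
  }, logical(1))
  combos <- combos[keep]
  keys <- vapply(combos, paste, character(1), collapse = "|")
  combos[order(lengths(combos), keys)]
}

#' Convert reaction deletions to minimal gene-deletion sets
#'
#' Computes, for each deleted reaction, the minimal gene sets whose removal
#' silences its GPR rule, cross-combines them across reactions, and keeps
#' the minimal combinations. Gene sets that additionally silence other
#' reactions are kept only when that closure leaves both objectives (growth
#' and product flux) unchanged within tolerance — a gene knockout can have
#' side effects the reaction-level solution did not ask for.
#'
#' @param model a `metabolic_model`.
#' @param deletions character vector of reaction ids (all with GPR rules).
#' @param env,product when both are supplied the side-effect check is run;
#'   otherwise the purely combinatorial conversion is returned.
#' @return list of character vectors (gene sets), smallest first.
#' @export
reactions_to_genes <- function(model, deletions, env = NULL, product = NULL) {
  sets <- gene_deletion_sets(model, deletions)
  if (is.null(env) || is.null(product)) return(sets)
  ref <- pfba(close_reactions(model, deletions), env)
  ref_growth <- if (ref$status == "optimal") ref$growth else 0
  ref_prod <- if (ref$status == "optimal") ref$fluxes$fluxes[[product]] else 0
  ok <- vapply(sets, function(gs) {
    ph <- pfba(apply_gene_deletions(model, gs), env)
    g <- if (ph$status == "optimal") ph$growth else 0
    p <- if (ph$status == "optimal") ph$fluxes$fluxes[[product]] else 0
    abs(g - ref_growth) <= FLUX_TOL && abs(p - ref_prod) <= FLUX_TOL
  }, logical(1))
  if (any(ok)) sets[ok] else sets
}

#' Drop deletions that do not contribute to the objectives
#'
#' Greedily removes each deletion whose removal either leaves both
#' objectives (growth and product flux) unchanged within 1e-6 or improves
#' both — so dead supersets of viable solutions also shrink. The scan
#' repeats until no deletion can be removed; the result is idempotent.
#'
#' @param model a `metabolic_model`.
#' @param env a `flux_environment`.
#' @param deletions character vector of reaction ids.
#' @param product product exchange id.
#' @return the simplified deletion set (character vector, sorted).
#' @export
simplify_solution <- function(model, env, deletions, product) {
  objectives <- function(dels) {
    ph <- pfba(close_reactions(model, dels), env)
    if (ph$status != "optimal" || ph$growth < FLUX_TOL) return(c(0, 0))
    c(ph$growth, ph$fluxes$fluxes[[product]])
  }
  dels <- sort(unique(deletions))
  cur <- objectives(dels)
  repeat {
    removed <- FALSE
    for (d in dels) {
      if (length(dels) == 0L) break
      cand <- setdiff(dels, d)
      if (length(cand) == 0L) next      # solutions stay non-empty
      obj <- objectives(cand)
      unchanged <- all(abs(obj - cur) <= FLUX_TOL)
      improves <- all(obj > cur + FLUX_TOL)
      if (unchanged || improves) {
        dels <- cand; cur <- obj; removed <- TRUE
      }
    }
    if (!removed) break
  }
  dels
}

# ---- SPEA2 -----------------------------------------------------------------

# Pareto dominance for maximisation of (growth, product).
dominates <- function(a, b) all(a >= b) && any(a > b)

spea2_fitness <- function(objs) {
  n <- nrow(objs)
  dom <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j) dom[i, j] <- dominates(objs[i, ], objs[j, ])
  strength <- rowSums(dom)
  raw <- vapply(seq_len(n), function(i) sum(strength[dom[, i]]), numeric(1))
  d <- as.matrix(stats::dist(objs))
  k <- max(1L, floor(sqrt(n)))
  sigma_k <- apply(d, 1, function(row) sort(row)[min(k + 1L, n)])
  density <- 1 / (sigma_k + 2)
  list(fitness = raw + density, raw = raw, dist = d)
}

# SPEA2 environmental selection, restricted to nondominated individuals:
# when they exceed the archive size, truncate by iterated removal of the
# individual with the lexicographically smallest sorted distance vector.
# (A short archive is not topped up with dominated individuals, so the
# archive invariantly holds a mutually nondominating set.)
spea2_select <- function(objs, fitness, raw, d, size) {
  nd <- which(raw == 0)
  if (length(nd) <= size) return(nd)
  keep <- nd
  while (length(keep) > size) {
    dk <- d[keep, keep, drop = FALSE]
    vecs <- lapply(seq_along(keep), function(i) sort(dk[i, -i]))
    worst <- 1L
    for (i in seq_along(keep)[-1L]) {
      cmp <- sign(vecs[[i]] - vecs[[worst]])
      first <- cmp[cmp != 0][1]
      if (!is.na(first) && first < 0) worst <- i
    }
    keep <- keep[-worst]
  }
  keep
}

#' SPEA2 search for growth-coupling knockout sets
#'
#' Multi-objective evolutionary search over variable-size sets of candidate
#' reaction deletions, simultaneously maximising biomass flux and product
#' flux (both from pFBA). Fitness assignment, environmental selection and
#' archive truncation follow SPEA2; the archive manager keeps the
#' `archive_size` best solutions seen. Identical seeds give identical
#' archives.
#'
#' @param model a `metabolic_model`.
#' @param env a `flux_environment`.
#' @param candidates a `candidate_set` from [select_candidates()], or a
#'   character vector of admissible reaction ids.
#' @param config a [search_config()].
#' @return list of `knockout_solution` entries, each with `reactions`
#'   (deleted reaction ids), `genes` (canonical minimal gene-deletion set),
#'   `gene_sets` (all minimal alternatives) and `metrics`
#'   (a `solution_metrics`).
#' @export
spea2_search <- function(model, env, candidates, config) {
  if (inherits(candidates, "candidate_set")) candidates <- candidates$candidates
  if (length(candidates) == 0L) stop("candidate list is empty")
  cfg <- config
  if (cfg$budget < cfg$pop_size)
    stop("evaluation budget (", cfg$budget, ") is smaller than one generation (",
         cfg$pop_size, ")")
  max_d <- min(cfg$max_deletions, length(candidates))

  cache <- new.env(parent = emptyenv())
  evals <- 0L
  score <- function(dels) {
    key <- paste(sort(dels), collapse = "|")
    hit <- cache[[key]]
    evals <<- evals + 1L
    if (!is.null(hit)) return(hit)
    ph <- pfba(close_reactions(model, dels), env)
    out <- if (ph$status != "optimal" || ph$growth < FLUX_TOL) c(0, 0)
           else c(ph$growth, ph$fluxes$fluxes[[cfg$product]])
    cache[[key]] <- out
    out
  }
  rand_set <- function() sort(sample(candidates, sample.int(max_d, 1)))
  mutate <- function(s) {
    ops <- c(if (length(s) < max_d && length(s) < length(candidates)) "add",
             if (length(s) > 1L) "remove",
             if (length(s) < length(candidates)) "replace")
    op <- if (length(ops) == 1L) ops else sample(ops, 1)
    pool <- setdiff(candidates, s)
    if (op == "add") s <- c(s, sample(pool, 1))
    else if (op == "remove") s <- sample(s, length(s) - 1L)
    else { s <- sample(s, length(s) - 1L); s <- c(s, sample(setdiff(pool, s), 1)) }
    sort(s)
  }
  crossover <- function(a, b) {
    u <- union(a, b)
    child <- u[stats::runif(length(u)) < 0.5]
    if (length(child) == 0L) child <- sample(u, 1)
    if (length(child) > max_d) child <- sample(child, max_d)
    sort(child)
  }

  with_local_seed(cfg$seed, {
    pop <- replicate(cfg$pop_size, rand_set(), simplify = FALSE)
    archive <- list()
    while (evals < cfg$budget) {
      pool <- c(archive, pop)
      keys <- vapply(pool, paste, character(1), collapse = "|")
      pool <- pool[!duplicated(keys)]
      objs <- do.call(rbind, lapply(pool, score))
      fit <- spea2_fitness(objs)
      sel <- spea2_select(objs, fit$fitness, fit$raw, fit$dist,
                          min(cfg$archive_size, length(pool)))
      archive <- pool[sel]
      arch_fit <- fit$fitness[sel]
      if (evals >= cfg$budget) break
      tournament <- function() {
        ij <- sample.int(length(archive), min(2L, length(archive)), replace = TRUE)
        ij[which.min(arch_fit[ij])]
      }
      pop <- replicate(cfg$pop_size, {
        p1 <- archive[[tournament()]]
        child <- if (stats::runif(1) < cfg$cross_rate)
          crossover(p1, archive[[tournament()]]) else p1
        mutate(child)
      }, simplify = FALSE)
    }

    lapply(archive, function(dels) {
      gs <- gene_deletion_sets(model, dels)
      structure(list(reactions = dels, genes = gs[[1]], gene_sets = gs,
                     metrics = evaluate_solution(model, env, dels, cfg$product)),
                class = "knockout_solution", product = cfg$product)
    })
  })
}

#' Merge archives from repeated runs into one solution set
#'
#' Takes the union of the (already simplified, gene-converted) archive
#' solutions of several runs and discards repetitions, deduplicating by
#' gene-deletion set; metrics are retained from the first occurrence.
#'
#' @param archives list of archives (each a list of `knockout_solution`).
#' @param product the product exchange id all archives were optimised for;
#'   mixing products is an error.
#' @return a `solution_set`: list with `product` and `solutions`.
#' @export
merge_runs <- function(archives, product) {
  for (a in archives) for (s in a)
    if (!is.null(attr(s, "product")) && !identical(attr(s, "product"), product))
      stop("archives mix target products")
  sols <- unlist(archives, recursive = FALSE)
  keys <- vapply(sols, function(s) paste(sort(s$genes), collapse = "|"),
                 character(1))
  sols <- sols[!duplicated(keys)]
  structure(list(product = product, solutions = sols), class = "solution_set")
}

#' @export
print.solution_set <- function(x, ...) {
  cat("<solution_set> product:", x$product, " solutions:",
      length(x$solutions), "\n")
  invisible(x)
}

#' Full optimisation stage for one target product
#'
#' Runs `config$runs` independent SPEA2 searches (run `i` seeded with
#' `seed + i - 1`), simplifies every archive solution, converts it to its
#' minimal gene-deletion sets (with the side-effect check), re-evaluates,
#' and merges the runs into a deduplicated solution set.
#'
#' @param model a `metabolic_model`.
#' @param env a `flux_environment`.
#' @param candidates a `candidate_set` or character vector.
#' @param config a [search_config()].
#' @return a `solution_set` for `config$product`.
#' @export
optimize_knockouts <- function(model, env, candidates, config) {
  archives <- lapply(seq_len(config$runs), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    arch <- spea2_search(model, env, candidates, cfg)
    lapply(arch, function(s) {
      dels <- simplify_solution(model, env, s$reactions, config$product)
      gs <- reactions_to_genes(model, dels, env, config$product)
      structure(list(reactions = dels, genes = gs[[1]], gene_sets = gs,
                     metrics = evaluate_solution(model, env, dels, config$product)),
                class = "knockout_solution", product = config$product)
    })
  })
  merge_runs(archives, config$product)
}

#' Write a solution set (or archive) as TSV
#' @param sols a `solution_set` or a list of `knockout_solution`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_solutions_tsv <- function(sols, path) {
  if (inherits(sols, "solution_set")) sols <- sols$solutions
  rows <- lapply(seq_along(sols), function(i) {
    s <- sols[[i]]
    m <- s$metrics
    data.frame(solution_id = i,
               reaction_dels = paste(s$reactions, collapse = ","),
               gene_dels = paste(s$genes, collapse = ","),
               growth = m$growth, uptake = m$uptake, product = m$product_flux,
               fva_min = m$fva_min, fva_max = m$fva_max,
               bpcy = m$bpcy, cyield = m$cyield, cost = m$cost,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
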