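#' Gene frequencies across target-product solution sets
#'
#' For every gene appearing in any solution, computes `freq(g, t)`: the
#' fraction of target `t`'s merged solutions whose gene-deletion set
#' contains `g`. Genes absent from every solution are omitted.
#'
#' @param solution_sets named list `target id -> solution_set` (or plain
#'   list of gene-set character vectors per target).
#' @return numeric matrix, genes in rows (sorted), targets in columns.
#' @export
gene_frequencies <- function(solution_sets) {
  stopifnot(length(solution_sets) > 0, !is.null(names(solution_sets)))
  gene_lists <- lapply(names(solution_sets), function(t) {
    ss <- solution_sets[[t]]
    sols <- if (inherits(ss, "solution_set"))
      lapply(ss$solutions, `[[`, "genes") else ss
    if (length(sols) == 0L)
      stop("empty solution set for target ", sQuote(t))
    sols
  })
  names(gene_lists) <- names(solution_sets)
  genes <- sort(unique(unlist(gene_lists)))
  freq <- matrix(0, nrow = length(genes), ncol = length(gene_lists),
                 dimnames = list(genes, names(gene_lists)))
  for (t in names(gene_lists)) {
    sols <- gene_lists[[t]]
    for (g in genes)
      freq[g, t] <- mean(vapply(sols, function(s) g %in% s, logical(1)))
  }
  freq
}

#' Hierarchical clustering of the gene-frequency matrix
#'
#' Rows (genes) whose maximum frequency falls below `min_freq` are dropped,
#' then genes and targets are clustered agglomeratively with Euclidean
#' distance and complete linkage. Rows are sorted by gene id before
#' clustering so the leaf order does not depend on input order.
#'
#' @param freq frequency matrix from [gene_frequencies()].
#' @param min_freq minimum row-maximum frequency to retain a gene
#'   (default 0.20).
#' @return list with `matrix` (the filtered, sorted matrix), `row_hclust`,
#'   `col_hclust` (`hclust` objects, `NULL` when fewer than two leaves) and
#'   `row_order`, `col_order` (dendrogram leaf orders as labels).
#' @export
cluster_frequencies <- function(freq, min_freq = 0.20) {
  keep <- apply(freq, 1, max) >= min_freq
  mat <- freq[keep, , drop = FALSE]
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  row_h <- col_h <- NULL
  row_order <- rownames(mat)
  col_order <- colnames(mat)
  if (nrow(mat) < 2L)
    warning("fewer than 2 gene rows remain after the frequency filter; ",
            "clustering is degenerate")
  if (nrow(mat) >= 2L) {
    row_h <- stats::hclust(stats::dist(mat, method = "euclidean"),
                           method = "complete")
    row_order <- rownames(mat)[row_h$order]
  }
  if (ncol(mat) >= 2L) {
    col_h <- stats::hclust(stats::dist(t(mat), method = "euclidean"),
                           method = "complete")
    col_order <- colnames(mat)[col_h$order]
  }
  list(matrix = mat, row_hclust = row_h, col_hclust = col_h,
       row_order = row_order, col_order = col_order)
}

#' Cross-product gene score (gscore)
#'
#' `gscore(g) = (sum over targets of freq(g, t)) * (number of targets with
#' freq(g, t) > 0)`: the summed frequency weighted by how many targets the
#' gene serves, promoting genes useful for multiple products.
#'
#' @param freq frequency matrix from [gene_frequencies()].
#' @return named numeric vector of gene scores.
#' @export
gene_score <- function(freq) {
  rowSums(freq) * rowSums(freq > 0)
}

#' Enumerate candidate chassis gene sets
#'
#' Takes the `ceiling(top_fraction * n)` highest-scoring genes (genes tied
#' with the score at the cut are all included, so the outcome is independent
#' of input order) and emits every non-empty subset up to `max_size` genes.
#'
#' @param gscores named vector from [gene_score()].
#' @param top_fraction fraction of genes to combine (default 0.30).
#' @param max_size largest chassis size (default 5).
#' @return list of character vectors (sorted within; smaller sets first).
#' @export
enumerate_chassis <- function(gscores, top_fraction = 0.30, max_size = 5) {
  if (length(gscores) == 0L) return(list())
  ord <- order(-gscores, names(gscores))
  k <- min(length(gscores), ceiling(top_fraction * length(gscores)))
  cutoff <- gscores[ord[k]]
  top <- sort(names(gscores)[gscores >= cutoff])
  out <- list()
  for (sz in seq_len(min(max_size, length(top))))
    out <- c(out, utils::combn(top, sz, simplify = FALSE))
  out
}

#' Score one chassis against the per-target solution sets
#'
#' For each target `t`, the group `S[t, c]` holds the solutions whose
#' gene-deletion set contains the chassis `c` and whose carbon yield is at
#' least `cyield_fraction` of the maximum carbon yield identified in `t`'s
#' merged solution set. The chassis score is
#' `cscore(c) = sum over t of max(CYIELDs of S[t, c]) / min(COSTs of
#' S[t, c])`, an empty group contributing 0: chassis serving several
#' products with high yield per knockout rank high.
#'
#' @param chassis character vector of gene ids.
#' @param solution_sets named list `target -> solution_set`.
#' @param cyield_fraction the identified-maximum yield fraction a solution
#'   must reach to support a chassis (default 0.95).
#' @return a `chassis_candidate`: list with `genes`, `cscore`,
#'   `targets_covered` and `groups` (per-target data frames of supporting
#'   solutions).
#' @export
chassis_score <- function(chassis, solution_sets, cyield_fraction = 0.95) {
  chassis <- sort(unique(chassis))
  total <- 0
  covered <- 0L
  groups <- list()
  for (t in names(solution_sets)) {
    ss <- solution_sets[[t]]
    sols <- if (inherits(ss, "solution_set")) ss$solutions else ss
    cy <- vapply(sols, function(s) s$metrics$cyield, numeric(1))
    cost <- vapply(sols, function(s) s$metrics$cost, numeric(1))
    has <- vapply(sols, function(s) all(chassis %in% s$genes), logical(1))
    eligible <- has & cy >= cyield_fraction * max(cy)
    groups[[t]] <- data.frame(
      solution = which(eligible),
      cyield = cy[eligible], cost = cost[eligible])
    if (any(eligible)) {
      total <- total + max(cy[eligible]) / min(cost[eligible])
      covered <- covered + 1L
    }
  }
  structure(list(genes = chassis, cscore = total, targets_covered = covered,
                 groups = groups),
            class = "chassis_candidate")
}

#' Rank chassis candidates into a report
#'
#' Sorts by decreasing chassis score, breaking ties by fewer genes and then
#' lexicographically. The score orders the list for analysis; it excludes
#' nothing.
#'
#' @param candidates list of `chassis_candidate` objects.
#' @param gscores optional gscore table to attach.
#' @param clustering optional [cluster_frequencies()] output to attach.
#' @param params optional list of the parameters used.
#' @return a `chassis_report`: list with `table` (data frame
#'   `chassis_genes`, `n_genes`, `cscore`, `targets_covered`), `candidates`
#'   (ranked), plus the attached metadata.
#' @export
rank_chassis <- function(candidates, gscores = NULL, clustering = NULL,
                         params = list()) {
  if (length(candidates) == 0L) {
    return(structure(list(table = data.frame(), candidates = list(),
                          gscores = gscores, clustering = clustering,
                          params = params),
                     class = "chassis_report"))
  }
  key <- vapply(candidates, function(c) paste(c$genes, collapse = ","),
                character(1))
  score <- vapply(candidates, `[[`, numeric(1), "cscore")
  size <- vapply(candidates, function(c) length(c$genes), integer(1))
  ord <- order(-score, size, key)
  candidates <- candidates[ord]
  tab <- data.frame(
    chassis_genes = key[ord], n_genes = size[ord], cscore = score[ord],
    targets_covered = vapply(candidates, `[[`, integer(1), "targets_covered"),
    stringsAsFactors = FALSE)
  structure(list(table = tab, candidates = candidates, gscores = gscores,
                 clustering = clustering, params = params),
            class = "chassis_report")
}

#' @export
print.chassis_report <- function(x, ...) {
  cat("<chassis_report> ", nrow(x$table), " chassis\n", sep = "")
  if (nrow(x$table) > 0) print(utils::head(x$table, 10))
  invisible(x)
}

#' Full chassis-analysis stage
#'
#' From the merged solution sets of several target products: computes gene
#' frequencies, clusters them, scores genes (gscore), enumerates candidate
#' chassis from the top-scoring genes, scores each chassis (cscore) against
#' the yield-filtered solution groups and returns the ranked report.
#'
#' @param solution_sets named list `target -> solution_set`.
#' @param min_freq frequency filter for the clustering display (default
#'   0.20; it does not affect scoring).
#' @param top_fraction fraction of genes combined into chassis (default 0.30).
#' @param max_size largest chassis size (default 5).
#' @param cyield_fraction yield filter for supporting solutions (default 0.95).
#' @return a `chassis_report`.
#' @export
analyze_chassis <- function(solution_sets, min_freq = 0.20,
                            top_fraction = 0.30, max_size = 5,
                            cyield_fraction = 0.95) {
  freq <- gene_frequencies(solution_sets)
  clus <- suppressWarnings(cluster_frequencies(freq, min_freq))
  gs <- gene_score(freq)
  chassis <- enumerate_chassis(gs, top_fraction, max_size)
  cands <- lapply(chassis, chassis_score, solution_sets = solution_sets,
                  cyield_fraction = cyield_fraction)
  rank_chassis(cands, gscores = gs, clustering = clus,
               params = list(min_freq = min_freq, top_fraction = top_fraction,
                             max_size = max_size,
                             cyield_fraction = cyield_fraction))
}

#' Write a chassis report's tables to a directory
#'
#' Emits `frequencies.tsv`, `gscore.tsv`, `linkage.tsv` (merge heights and
#' leaf orders) and `chassis_ranked.tsv`.
#'
#' @param report a `chassis_report` from [analyze_chassis()].
#' @param freq the frequency matrix used (attached clustering only stores
#'   the filtered rows).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_chassis_report <- function(report, freq, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(data.frame(gene = rownames(freq), freq,
                                check.names = FALSE),
                     file.path(dir, "frequencies.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene = names(report$gscores),
                                gscore = as.numeric(report$gscores)),
                     file.path(dir, "gscore.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cl <- report$clustering
  link <- if (!is.null(cl$row_hclust))
    data.frame(step = seq_along(cl$row_hclust$height),
               height = cl$row_hclust$height)
  else data.frame(step = integer(), height = numeric())
  utils::write.table(link, file.path(dir, "linkage.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(paste("row_order", paste(cl$row_order, collapse = ",")),
               paste("col_order", paste(cl$col_order, collapse = ","))),
             file.path(dir, "leaf_orders.txt"))
  utils::write.table(report$table, file.path(dir, "chassis_ranked.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
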