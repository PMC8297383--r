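#' @useDynLib chassiscraft, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Large but finite box used in place of an open flux bound (mmol/gDW/h).
# Genome-scale conventions use 1000; all toy fluxes are O(10).
FLUX_BIG <- 1000

# Solve  min/max c'v  s.t.  A v = b,  lower <= v <= upper.
#
# Thin wrapper over the compiled two-phase simplex. Infinite lower bounds are
# clamped to -FLUX_BIG (and uppers to +FLUX_BIG) so the feasible region is a
# polytope; fluxes at the clamp are physically meaningless and never arise in
# the shipped models.
solve_lp <- function(obj, A, rhs, lower, upper, maximize = FALSE) {
  stopifnot(length(obj) == ncol(A), length(rhs) == nrow(A),
            length(lower) == ncol(A), length(upper) == ncol(A))
  lower <- pmax(lower, -FLUX_BIG)
  upper <- pmin(upper, FLUX_BIG)
  res <- simplex_core(as.numeric(obj), as.matrix(A), as.numeric(rhs),
                      as.numeric(lower), as.numeric(upper), isTRUE(maximize))
  if (res$status == "optimal" && !is.null(colnames(A)))
    names(res$x) <- colnames(A)
  res
}
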