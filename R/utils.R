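#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor lm.fit pf pt p.adjust poly pbinom qnorm rnorm runif
#'   sd var median mvfft t.test setNames fft
#' @importFrom utils write.table read.table head modifyList
NULL

stop2 <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic small integer stream seed derived from a base seed;
# kept well below 2^31 so set.seed() never overflows
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 2048L + (as.integer(offset) %% 2048L)
}

check_square_symmetric <- function(m, what = "matrix", tol = 1e-10) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop2("%s must be a square matrix", what)
  if (max(abs(m - t(m))) > tol)
    stop2("%s is not symmetric (max asymmetry %.3g)", what, max(abs(m - t(m))))
  invisible(TRUE)
}

# upper-triangle index pairs (i < j) in column-major order, as a 2-column matrix
upper_pairs <- function(n) {
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  idx[order(idx[, "col"], idx[, "row"]), , drop = FALSE]
}

# canonical "a--b" key for an undirected labelled edge
edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "--")
}
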