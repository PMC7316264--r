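#' Group consensus structural backbone
#'
#' Votes over individual binary structural connectomes: an edge enters the
#' group-representative mask when it is present in at least `threshold` of
#' the subjects ("at least" is inclusive, so 13 of 26 passes a 0.5
#' threshold). Weighted inputs are binarized at > 0 before voting.
#'
#' @param structural list of square matrices with identical ROI dimnames.
#' @param threshold required fraction of subjects (default 0.5).
#' @return object of class `consensus_backbone` with fields `mask`
#'   (binary symmetric matrix), `roi_labels`, `threshold`,
#'   `n_subjects_used`.
#' @export
consensus_binary <- function(structural, threshold = 0.5) {
  if (length(structural) < 2) stop2("need at least 2 structural matrices")
  if (threshold <= 0 || threshold > 1) stop2("threshold must be in (0, 1]")
  ref <- structural[[1]]
  check_square_symmetric(ref, "structural matrix")
  labels <- rownames(ref)
  for (k in seq_along(structural)) {
    m <- structural[[k]]
    if (!identical(dim(m), dim(ref)))
      stop2("structural matrix %d has mismatched shape", k)
    if (!is.null(labels) && !identical(rownames(m), labels))
      stop2("structural matrix %d has mismatched ROI labels", k)
  }
  votes <- Reduce(`+`, lapply(structural, function(m) (m != 0) * 1L))
  mask <- (votes / length(structural) >= threshold) * 1L
  mask <- mask * (t(mask) == mask)  # defensive; inputs are symmetric
  diag(mask) <- 0L
  dimnames(mask) <- dimnames(ref)
  structure(list(mask = mask, roi_labels = labels, threshold = threshold,
                 n_subjects_used = length(structural)),
            class = "consensus_backbone")
}

#' @export
print.consensus_backbone <- function(x, ...) {
  cat(sprintf("<consensus_backbone> %d ROIs, %d edges at threshold %.2f (%d subjects)\n",
              nrow(x$mask), sum(x$mask[upper.tri(x$mask)]), x$threshold,
              x$n_subjects_used))
  invisible(x)
}

#' Mask a functional matrix by the structural backbone
#'
#' Produces the mixed structural-functional matrix: a cell keeps its
#' Fisher-z value where a consensus structural connection exists and is set
#' to zero otherwise. Path-based graph metrics are computed on these mixed
#' matrices because functional correlations alone do not represent
#' information flow.
#'
#' @param func a [functional_matrix()].
#' @param backbone a [consensus_backbone()].
#' @return object of class `mixed_matrix` with fields `z_masked`,
#'   `roi_labels`, `backbone`.
#' @export
apply_mask <- function(func, backbone) {
  if (!identical(func$roi_labels, backbone$roi_labels %||% func$roi_labels))
    stop2("functional matrix and backbone have different ROI labels")
  zm <- func$z * backbone$mask
  diag(zm) <- 0
  structure(list(z_masked = zm, roi_labels = func$roi_labels,
                 backbone = backbone),
            class = "mixed_matrix")
}

#' @export
print.mixed_matrix <- function(x, ...) {
  cat(sprintf("<mixed_matrix> %d ROIs, %d retained edges\n",
              nrow(x$z_masked), sum(x$z_masked[upper.tri(x$z_masked)] != 0)))
  invisible(x)
}
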