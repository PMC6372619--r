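#' Rank-transform an expression matrix within each sample
#'
#' Converts each sample (column) into the ranks of its genes, ascending
#' (rank 1 = lowest expression), with ties receiving the average rank.
#' Ranking makes downstream z-scores invariant to any strictly monotone
#' per-sample transformation of the raw values (normalization, log scale,
#' unit changes).
#'
#' @param em An [expression_matrix()].
#' @return An object of class `olsa_ranks`: list with `ranks` (genes x
#'   samples matrix) and `control_mask`.
#' @export
rank_transform <- function(em) {
  stopifnot(inherits(em, "olsa_expression"))
  ranks <- apply(em$values, 2, rank, ties.method = "average")
  dimnames(ranks) <- dimnames(em$values)
  structure(list(ranks = ranks, control_mask = em$control_mask),
            class = "olsa_ranks")
}

#' Robust z-score of gene ranks against the control distribution
#'
#' For gene g in treated sample i,
#' `z = (rank_gi - median(control ranks of g)) / (IQR(control ranks of g) * niqr_constant)`.
#' The denominator is the normalized interquartile range (NIQR): the IQR of
#' the control ranks scaled by 0.7413 (= 1/1.349) so it estimates a normal
#' standard deviation. The IQR uses linear interpolation between order
#' statistics (the default sample-quantile rule). Genes whose control IQR is
#' zero cannot be scaled; their z entries are set to 0 and the gene ids are
#' recorded in `zero_iqr_genes` so that gene indexing stays aligned across
#' data sets.
#'
#' @param rm An `olsa_ranks` object from [rank_transform()].
#' @param niqr_constant Positive scale applied to the IQR (default 0.7413,
#'   the normal-consistent convention).
#' @param keep_controls If `TRUE`, control columns are themselves z-scored
#'   and retained in the output; by default only treated samples form the
#'   response-profile matrix.
#' @return A response-profile matrix: object of class `olsa_response` with
#'   `z` (genes x samples), `provenance = "ranked_robust_z"` and
#'   `zero_iqr_genes`.
#' @export
robust_zscore <- function(rm, niqr_constant = 0.7413, keep_controls = FALSE) {
  stopifnot(inherits(rm, "olsa_ranks"))
  if (niqr_constant <= 0) stop("`niqr_constant` must be > 0")
  ctrl <- rm$control_mask
  if (sum(ctrl) < 2)
    stop("robust z-scoring needs >= 2 control samples, got ", sum(ctrl))
  Y <- rm$ranks[, ctrl, drop = FALSE]
  med <- apply(Y, 1, median)
  qs <- apply(Y, 1, quantile, probs = c(0.25, 0.75), names = FALSE)
  niqr <- (qs[2, ] - qs[1, ]) * niqr_constant
  flat <- niqr == 0
  if (all(flat))
    stop("degenerate controls: every gene has zero control IQR")
  out_cols <- if (keep_controls) rep(TRUE, ncol(rm$ranks)) else !ctrl
  X <- rm$ranks[, out_cols, drop = FALSE]
  z <- (X - med) / niqr
  z[flat, ] <- 0
  response_profile(z, provenance = "ranked_robust_z",
                   zero_iqr_genes = rownames(rm$ranks)[flat])
}

response_profile <- function(z, provenance, zero_iqr_genes = character()) {
  if (ncol(z) < 2)
    stop("a response-profile matrix needs >= 2 sample columns, got ", ncol(z))
  if (any(!is.finite(z))) stop("response-profile entries must be finite")
  structure(list(z = z, provenance = provenance,
                 zero_iqr_genes = zero_iqr_genes),
            class = "olsa_response")
}

#' Wrap a precomputed response matrix for decomposition
#'
#' Bypass input path: any genes x samples matrix of differential values
#' versus control (log fold change, z-score, ...) can be decomposed
#' directly. The origin of the value space must represent the untreated
#' state for the mirror augmentation to be meaningful.
#'
#' @param z Numeric matrix, genes x samples, with dimnames.
#' @return An `olsa_response` with `provenance = "user_supplied"`.
#' @export
as_response_profile <- function(z) {
  if (!is.matrix(z) || !is.numeric(z))
    stop("`z` must be a numeric matrix")
  if (is.null(rownames(z)) || is.null(colnames(z)))
    stop("`z` must have gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(z)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(z)[duplicated(rownames(z))]), collapse = ", "))
  if (anyDuplicated(colnames(z)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(z)[duplicated(colnames(z))]), collapse = ", "))
  response_profile(z, provenance = "user_supplied")
}

#' @export
print.olsa_response <- function(x, ...) {
  cat(sprintf("Response-profile matrix: %d genes x %d samples [%s]\n",
              nrow(x$z), ncol(x$z), x$provenance))
  if (length(x$zero_iqr_genes))
    cat(sprintf("  %d gene(s) with zero control IQR (z set to 0)\n",
                length(x$zero_iqr_genes)))
  invisible(x)
}

#' @export
dim.olsa_response <- function(x) dim(x$z)
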