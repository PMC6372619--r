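#' Specification for synthetic response-profile data
#'
#' Describes the generative model used for testing and calibration:
#' `k_factors` sparse orthonormal gene-loading vectors (disjoint-leaning
#' supports covering `sparsity` of the genes each), per-sample factor
#' scores drawn from heavy-tailed Laplace distributions whose scales decay
#' geometrically (`score_ratio`) so the contribution spectrum is steep,
#' i.i.d. Gaussian gene noise, log-normal per-sample stimulation strengths,
#' and optionally a minority of "irreversible" outlier samples whose
#' strength is inflated by `outlier_multiplier`.
#'
#' @param n_genes,n_samples Matrix dimensions.
#' @param k_factors Number of planted factors (<= min(n_genes, n_samples)).
#' @param sparsity Fraction of genes with nonzero loading per factor.
#' @param score_scale Laplace scale of the top factor's scores.
#' @param score_ratio Geometric decay of scales across factors.
#' @param noise_sd Standard deviation of additive gene noise.
#' @param strength_meanlog,strength_sdlog Log-normal parameters of the
#'   per-sample strength multiplier.
#' @param n_outliers Number of outlier samples.
#' @param outlier_multiplier Strength multiplier applied to outliers.
#' @param seed RNG seed; generation is fully reproducible from it.
#' @return A validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 2000, n_samples = 150, k_factors = 6,
                           sparsity = 0.05, score_scale = 4,
                           score_ratio = 0.7, noise_sd = 0.1,
                           strength_meanlog = 0, strength_sdlog = 0.4,
                           n_outliers = 0, outlier_multiplier = 10,
                           seed = 1L) {
  spec <- list(n_genes = as.integer(n_genes),
               n_samples = as.integer(n_samples),
               k_factors = as.integer(k_factors), sparsity = sparsity,
               score_scale = score_scale, score_ratio = score_ratio,
               noise_sd = noise_sd, strength_meanlog = strength_meanlog,
               strength_sdlog = strength_sdlog,
               n_outliers = as.integer(n_outliers),
               outlier_multiplier = outlier_multiplier,
               seed = as.integer(seed))
  if (spec$k_factors > min(spec$n_genes, spec$n_samples))
    stop("k_factors must be <= min(n_genes, n_samples)")
  if (spec$sparsity <= 0 || spec$sparsity > 1)
    stop("`sparsity` must be in (0, 1]")
  if (floor(spec$sparsity * spec$n_genes) < 1)
    stop("sparsity * n_genes < 1: no genes per factor")
  if (spec$noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (spec$n_outliers >= spec$n_samples)
    stop("n_outliers must be < n_samples")
  class(spec) <- "synthetic_spec"
  spec
}

.rlaplace <- function(n, scale) (rexp(n) - rexp(n)) * scale

#' Generate a synthetic response-profile matrix with known factors
#'
#' Draws data per [synthetic_spec()]: loadings `W` (genes x k, sparse,
#' exactly orthonormal), scores `s_j` per sample, profiles
#' `y_j = W s_j + noise`, and observed columns `D_j = l_j * y_j` with
#' per-sample strength multiplier `l_j` (inflated for outliers). Sets the
#' RNG seed from the spec.
#'
#' @param spec A `synthetic_spec`.
#' @return List with `response` (an `olsa_response`, provenance
#'   `user_supplied`) and `truth`: `loadings` (W), `scores` (k x samples,
#'   raw), `scores_normalized` (raw scores divided by each profile's
#'   pre-strength norm -- the factor activity of the unit-normalized
#'   profile, directly comparable to fitted response scores), `strengths`,
#'   `outliers`.
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_genes; N <- spec$n_samples; k <- spec$k_factors
  nz <- max(1L, floor(spec$sparsity * n))
  gene_ids <- sprintf("g%05d", seq_len(n))
  sample_ids <- sprintf("s%04d", seq_len(N))
  W <- matrix(0, n, k, dimnames = list(gene_ids, paste0("F", seq_len(k))))
  if (nz * k <= n) {
    # disjoint supports: orthogonality is exact and varimax-simple
    support <- matrix(sample.int(n, nz * k), nz, k)
    for (j in seq_len(k)) W[support[, j], j] <- rnorm(nz)
    W <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  } else {
    for (j in seq_len(k)) W[sample.int(n, nz), j] <- rnorm(nz)
    qr_ <- qr(W)
    if (qr_$rank < k)
      stop("infeasible sparsity/orthogonality: loadings are rank deficient")
    W <- qr.Q(qr_)
    dimnames(W) <- list(gene_ids, paste0("F", seq_len(k)))
  }
  scales <- spec$score_scale * spec$score_ratio^(seq_len(k) - 1)
  S <- matrix(0, k, N, dimnames = list(paste0("F", seq_len(k)), sample_ids))
  for (j in seq_len(k)) S[j, ] <- .rlaplace(N, scales[j])
  Y <- W %*% S + matrix(rnorm(n * N, sd = spec$noise_sd), n, N)
  ynorm <- sqrt(colSums(Y^2))
  if (any(ynorm == 0)) stop("degenerate zero profile generated")
  l <- rlnorm(N, spec$strength_meanlog, spec$strength_sdlog)
  outliers <- character()
  if (spec$n_outliers > 0) {
    idx <- sample.int(N, spec$n_outliers)
    l[idx] <- l[idx] * spec$outlier_multiplier
    outliers <- sample_ids[idx]
  }
  D <- sweep(Y, 2, l, "*")
  dimnames(D) <- list(gene_ids, sample_ids)
  list(response = as_response_profile(D),
       truth = list(loadings = W, scores = S,
                    scores_normalized = sweep(S, 2, ynorm, "/"),
                    strengths = stats::setNames(l * ynorm, sample_ids),
                    multipliers = stats::setNames(l, sample_ids),
                    outliers = outliers, spec = spec))
}

#' Match fitted response vectors to planted loadings
#'
#' Greedy assignment of fitted factors to planted factors by absolute
#' cosine similarity (signs and order are not identifiable, so both are
#' ignored): repeatedly pairs the most similar unmatched (planted, fitted)
#' couple. Planted factors left unmatched (fewer fitted than planted
#' factors) score 0.
#'
#' @param truth The `truth` element of [generate_synthetic()] (or any list
#'   with an orthonormal `loadings` matrix, genes x k).
#' @param r An `olsa_vectors` over the same genes.
#' @return List: `cosine` (named |cos| per planted factor), `matched`
#'   (fitted factor id per planted factor, NA if unmatched), and
#'   `cosine_matrix` (planted x fitted).
#' @export
recovery_score <- function(truth, r) {
  stopifnot(inherits(r, "olsa_vectors"))
  W <- truth$loadings
  if (!identical(rownames(W), colnames(r$loadings)))
    stop("gene spaces of truth and fit differ")
  M <- abs(t(W) %*% t(r$loadings))  # planted x fitted
  k_true <- nrow(M); k_fit <- ncol(M)
  cosine <- stats::setNames(numeric(k_true), rownames(M))
  matched <- stats::setNames(rep(NA_character_, k_true), rownames(M))
  A <- M
  for (step in seq_len(min(k_true, k_fit))) {
    ij <- which(A == max(A), arr.ind = TRUE)[1, ]
    cosine[ij[1]] <- M[ij[1], ij[2]]
    matched[ij[1]] <- colnames(M)[ij[2]]
    A[ij[1], ] <- -Inf
    A[, ij[2]] <- -Inf
  }
  list(cosine = cosine, matched = matched, cosine_matrix = M)
}

#' Write a synthetic data set to a directory
#'
#' Writes `matrix.tsv` (the response matrix), `truth_loadings.tsv`,
#' `truth_scores.tsv`, `truth_strengths.tsv`, `outliers.txt`, and
#' `spec.yaml` (the generating parameters).
#'
#' @param sim Result of [generate_synthetic()].
#' @param dir Output directory.
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix(sim$response, file.path(dir, "matrix.tsv"))
  .write_tsv(data.frame(gene = rownames(sim$truth$loadings),
                        sim$truth$loadings, check.names = FALSE),
             file.path(dir, "truth_loadings.tsv"))
  .write_tsv(data.frame(factor = rownames(sim$truth$scores),
                        sim$truth$scores, check.names = FALSE),
             file.path(dir, "truth_scores.tsv"))
  .write_tsv(data.frame(sample = names(sim$truth$strengths),
                        strength = unname(sim$truth$strengths)),
             file.path(dir, "truth_strengths.tsv"))
  writeLines(sim$truth$outliers, file.path(dir, "outliers.txt"))
  yaml::write_yaml(unclass(sim$truth$spec), file.path(dir, "spec.yaml"))
  invisible(dir)
}
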