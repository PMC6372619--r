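#' Analysis configuration
#'
#' Collects every tunable of the decomposition and the downstream tools,
#' with the defaults used throughout: retain components to 80% cumulative
#' contribution, screen mirror candidates at Grubbs alpha 0.05, scale the
#' control IQR by 0.7413, feed the top 1% of genes to enrichment, cut
#' signatures at 90% cumulative contribution, and call enrichment at
#' BH-adjusted alpha 0.05.
#'
#' @param cum_threshold Cumulative-contribution cutoff for component
#'   retention, in (0, 1].
#' @param grubbs_alpha One-sided significance level of the mirror screen.
#' @param niqr_constant IQR-to-sigma scale for robust z-scoring.
#' @param varimax_tol,varimax_max_iter Rotation convergence controls.
#' @param keep_controls Retain z-scored control columns in the response
#'   matrix.
#' @param fraction Top-gene fraction for enrichment queries.
#' @param signature_cutoff Cumulative-contribution cutoff for factor
#'   signatures.
#' @param alpha BH-adjusted significance level for enrichment.
#' @param sign_flip Optional character vector of factor ids whose loadings
#'   and scores are negated after the canonical sign rule (analyst
#'   override).
#' @return A list of class `olsa_config`.
#' @export
olsa_config <- function(cum_threshold = 0.8, grubbs_alpha = 0.05,
                        niqr_constant = 0.7413, varimax_tol = 1e-8,
                        varimax_max_iter = 1000L, keep_controls = FALSE,
                        fraction = 0.01, signature_cutoff = 0.9,
                        alpha = 0.05, sign_flip = NULL) {
  cfg <- list(cum_threshold = cum_threshold, grubbs_alpha = grubbs_alpha,
              niqr_constant = niqr_constant, varimax_tol = varimax_tol,
              varimax_max_iter = as.integer(varimax_max_iter),
              keep_controls = keep_controls, fraction = fraction,
              signature_cutoff = signature_cutoff, alpha = alpha,
              sign_flip = sign_flip)
  stopifnot(cfg$cum_threshold > 0, cfg$cum_threshold <= 1,
            cfg$grubbs_alpha > 0, cfg$grubbs_alpha < 1,
            cfg$niqr_constant > 0, cfg$varimax_tol > 0,
            cfg$varimax_max_iter >= 1, cfg$fraction > 0, cfg$fraction <= 1,
            cfg$signature_cutoff > 0, cfg$signature_cutoff < 1,
            cfg$alpha > 0, cfg$alpha < 1)
  class(cfg) <- "olsa_config"
  cfg
}

#' Run the full decomposition
#'
#' Chains the stages on a response-profile matrix `D`: total strength
#' (`l_i`), Grubbs-gated mirror selection, L2 normalization (`D'`), mirror
#' concatenation (`DM = [D' | -P']`), uncentred component extraction to the
#' cumulative-contribution threshold, varimax rotation (response-vector
#' matrix `R`), and score projection (`S = R %*% D'`). The factorization
#' recovered is `D ~ t(R) %*% S %*% T` with `T = diag(l)`.
#'
#' @param d An `olsa_response` (from [robust_zscore()] or
#'   [as_response_profile()]).
#' @param config An [olsa_config()].
#' @return Object of class `olsa_fit` with elements `vectors` (`R`),
#'   `scores` (`S`), `strength`, `selection`, `components`, `normalized`,
#'   `concat`, and `config`. Deterministic given inputs and config.
#' @export
run_olsa <- function(d, config = olsa_config()) {
  stopifnot(inherits(d, "olsa_response"), inherits(config, "olsa_config"))
  ts <- total_strength(d)
  sel <- select_mirror_samples(ts, alpha = config$grubbs_alpha)
  dprime <- normalize_profiles(d, ts)
  dm <- build_concatenated(dprime, sel)
  cs <- extract_components(dm, threshold = config$cum_threshold)
  r <- varimax_rotate(cs, tol = config$varimax_tol,
                      max_iter = config$varimax_max_iter)
  if (length(config$sign_flip)) {
    unknown <- setdiff(config$sign_flip, rownames(r$loadings))
    if (length(unknown))
      stop("sign_flip names unknown factors: ",
           paste(unknown, collapse = ", "))
    idx <- rownames(r$loadings) %in% config$sign_flip
    r$loadings[idx, ] <- -r$loadings[idx, ]
    r$rotation[, idx] <- -r$rotation[, idx]
  }
  s <- compute_scores(r, dprime, dm = dm)
  r$contribution <- s$contribution
  structure(list(vectors = r, scores = s, strength = ts, selection = sel,
                 components = cs, normalized = dprime, concat = dm,
                 config = config),
            class = "olsa_fit")
}

#' Decompose directly from raw expression
#'
#' Convenience wrapper: rank transform, robust z-score against the flagged
#' controls, then [run_olsa()].
#'
#' @param em An [expression_matrix()] with >= 2 controls flagged.
#' @param config An [olsa_config()].
#' @export
olsa_from_expression <- function(em, config = olsa_config()) {
  d <- robust_zscore(rank_transform(em),
                     niqr_constant = config$niqr_constant,
                     keep_controls = config$keep_controls)
  run_olsa(d, config)
}

#' @export
print.olsa_fit <- function(x, ...) {
  cat(sprintf(
    "OLSA fit: %d factors from %d genes x %d samples (threshold %.2f)\n",
    nrow(x$vectors$loadings), ncol(x$vectors$loadings),
    ncol(x$scores$scores), x$config$cum_threshold))
  cat(sprintf("  mirror set: %d kept, %d removed (Grubbs alpha %.3g)\n",
              length(x$selection$kept), length(x$selection$removed),
              x$selection$alpha))
  invisible(x)
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write decomposition artifacts to a directory
#'
#' Writes `response_vectors.tsv` (factors x genes), `response_scores.tsv`
#' (factors x samples), `total_strength.tsv`, `contributions.tsv`
#' (pre- and post-rotation ratios and cumulative ratios),
#' `mirror_selection.tsv` (the Grubbs audit trail), and
#' `run_metadata.json` (config echo plus dimensions and package version).
#'
#' @param fit An `olsa_fit`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named character vector of files written.
#' @export
write_olsa_results <- function(fit, dir) {
  stopifnot(inherits(fit, "olsa_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- c(
    response_vectors = file.path(dir, "response_vectors.tsv"),
    response_scores = file.path(dir, "response_scores.tsv"),
    total_strength = file.path(dir, "total_strength.tsv"),
    contributions = file.path(dir, "contributions.tsv"),
    mirror_selection = file.path(dir, "mirror_selection.tsv"),
    run_metadata = file.path(dir, "run_metadata.json"))
  rv <- data.frame(factor = rownames(fit$vectors$loadings),
                   fit$vectors$loadings, check.names = FALSE)
  .write_tsv(rv, out["response_vectors"])
  sc <- data.frame(factor = rownames(fit$scores$scores),
                   fit$scores$scores, check.names = FALSE)
  .write_tsv(sc, out["response_scores"])
  .write_tsv(data.frame(sample = fit$strength$sample_ids,
                        l2_norm = unname(fit$strength$l)),
             out["total_strength"])
  k <- length(fit$vectors$contribution)
  .write_tsv(data.frame(
    factor = names(fit$vectors$contribution),
    component_contribution = fit$components$contribution[seq_len(k)],
    component_cumulative = fit$components$cumulative[seq_len(k)],
    rotated_contribution = unname(fit$vectors$contribution),
    rotated_cumulative = cumsum(unname(fit$vectors$contribution))),
    out["contributions"])
  .write_tsv(fit$selection$trail, out["mirror_selection"])
  meta <- list(
    package = "olsar",
    version = as.character(utils::packageVersion("olsar")),
    config = unclass(fit$config),
    n_genes = ncol(fit$vectors$loadings),
    n_samples = ncol(fit$scores$scores),
    n_factors = nrow(fit$vectors$loadings),
    mirror_kept = length(fit$selection$kept),
    mirror_removed = fit$selection$removed,
    varimax = fit$vectors$meta)
  jsonlite::write_json(meta, out["run_metadata"], auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  invisible(out)
}

#' Read a factors x genes response-vector table
#'
#' Reads the `response_vectors.tsv` layout written by
#' [write_olsa_results()] back into an `olsa_vectors`-compatible object (no
#' rotation metadata; contributions recomputed are not available and are
#' set to squared-mass shares of the stored rows, which are equal for
#' orthonormal rows and serve only for ordering).
#'
#' @param path TSV path, first column `factor`, remaining columns genes.
#' @export
read_response_vectors <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- df[[1]]
  structure(list(loadings = m,
                 contribution = stats::setNames(
                   rep(NA_real_, nrow(m)), rownames(m)),
                 rotation = NULL, sigma = NULL, total_ss = NULL,
                 meta = list(source = path)),
            class = "olsa_vectors")
}

#' Read a factors x samples response-score table
#' @param path TSV path, first column `factor`, remaining columns samples.
#' @export
read_response_scores <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- df[[1]]
  structure(list(scores = m,
                 contribution = stats::setNames(
                   rep(NA_real_, nrow(m)), rownames(m))),
            class = "olsa_scores")
}
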