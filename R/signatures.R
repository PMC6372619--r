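.factor_loadings <- function(r, factor_id) {
  stopifnot(inherits(r, "olsa_vectors"))
  if (!factor_id %in% rownames(r$loadings))
    stop("unknown factor id: ", factor_id)
  r$loadings[factor_id, ]
}

#' Top-fraction genes of a factor by squared loading
#'
#' Sorts a factor's genes by squared loading (sign-blind) and returns the
#' top fraction: `floor(fraction * n_genes)` genes, at least 1. Ties at the
#' boundary are broken by gene id so the selection is deterministic.
#'
#' @param r An `olsa_vectors`.
#' @param factor_id Factor name, e.g. `"P5"`.
#' @param fraction Fraction of genes to keep, in (0, 1].
#' @return Data frame with columns `gene`, `loading`, `squared`, in
#'   selection order.
#' @export
top_fraction_genes <- function(r, factor_id, fraction = 0.01) {
  if (fraction <= 0 || fraction > 1) stop("`fraction` must be in (0, 1]")
  v <- .factor_loadings(r, factor_id)
  n <- length(v)
  count <- max(1L, floor(fraction * n))
  ord <- order(-v^2, names(v))
  sel <- ord[seq_len(count)]
  data.frame(gene = names(v)[sel], loading = unname(v[sel]),
             squared = unname(v[sel]^2), stringsAsFactors = FALSE)
}

#' Extract a factor's gene signature by cumulative contribution
#'
#' Each gene's contribution to a factor is its squared loading divided by
#' the factor's total squared mass. Genes are taken in contribution order
#' (descending; ties broken by gene id) until the cumulative contribution
#' first exceeds `cutoff` -- the crossing gene is included, so the list
#' always reaches the cutoff. The signature is the portable unit used for
#' enrichment and cross-dataset validation.
#'
#' @param r An `olsa_vectors`.
#' @param factor_id Factor name.
#' @param cutoff Cumulative-contribution cutoff in (0, 1), default 0.9.
#' @return Object of class `olsa_signature`: data frame `genes` (gene,
#'   loading, contribution, cumulative), plus `factor_id` and `cutoff`.
#' @export
extract_signature <- function(r, factor_id, cutoff = 0.9) {
  if (cutoff <= 0 || cutoff >= 1) stop("`cutoff` must be in (0, 1)")
  v <- .factor_loadings(r, factor_id)
  total <- sum(v^2)
  if (total == 0) stop("factor ", factor_id, " has zero loading mass")
  contrib <- v^2 / total
  ord <- order(-contrib, names(v))
  cum <- cumsum(contrib[ord])
  # the crossing gene is included; a cumulative contribution landing
  # exactly on the cutoff (within fp tolerance) counts as having reached it
  size <- which(cum >= cutoff - 1e-9)[1]
  if (is.na(size)) size <- length(ord)  # numerically, cum may top out < 1
  sel <- ord[seq_len(size)]
  genes <- data.frame(gene = names(v)[sel], loading = unname(v[sel]),
                      contribution = unname(contrib[sel]),
                      cumulative = unname(cum[seq_len(size)]),
                      stringsAsFactors = FALSE)
  structure(list(genes = genes, factor_id = factor_id, cutoff = cutoff),
            class = "olsa_signature")
}

#' @export
print.olsa_signature <- function(x, ...) {
  cat(sprintf("Signature of %s: %d genes (cumulative %.3f, cutoff %.2f)\n",
              x$factor_id, nrow(x$genes),
              x$genes$cumulative[nrow(x$genes)], x$cutoff))
  invisible(x)
}

#' Rank samples by factor score
#'
#' Samples sorted by their response score on one factor; high positive
#' scores flag perturbagens driving the factor's response, high negative
#' scores its reverse (e.g. agonists vs antagonists). Tied scores are
#' ordered by sample id.
#'
#' @param s An `olsa_scores`.
#' @param factor_id Factor name.
#' @param direction `"desc"` (default) or `"asc"`.
#' @return Data frame with columns `rank`, `sample`, `score`.
#' @export
rank_by_score <- function(s, factor_id, direction = c("desc", "asc")) {
  direction <- match.arg(direction)
  stopifnot(inherits(s, "olsa_scores"))
  if (!factor_id %in% rownames(s$scores))
    stop("unknown factor id: ", factor_id)
  v <- s$scores[factor_id, ]
  ord <- if (direction == "desc") order(-v, names(v)) else order(v, names(v))
  data.frame(rank = seq_along(ord), sample = names(v)[ord],
             score = unname(v[ord]), stringsAsFactors = FALSE)
}

#' Validate a factor signature against an independent data set
#'
#' For each sample of a held-out response matrix, computes the Spearman
#' correlation between the signature genes' loadings and the sample's
#' response values over the gene-id intersection (rank-based, so any
#' monotone per-sample scaling of the test data is irrelevant). Samples
#' whose profiles rank the signature genes like the factor does score near
#' +1; reversed responses score near -1.
#'
#' @param sig An `olsa_signature`.
#' @param test An `olsa_response` (the held-out set).
#' @return Object of class `olsa_validation`: data frame `result` (sample,
#'   rho, rank, sorted by rho descending, ties by sample id), plus
#'   `factor_id`, `n_signature`, `n_overlap`, `coverage`.
#' @export
spearman_validate <- function(sig, test) {
  stopifnot(inherits(sig, "olsa_signature"), inherits(test, "olsa_response"))
  common <- intersect(sig$genes$gene, rownames(test$z))
  n_missing <- nrow(sig$genes) - length(common)
  if (length(common) < 3)
    stop("signature/test overlap is ", length(common),
         " genes; need >= 3 for Spearman validation")
  if (n_missing > 0)
    warning(n_missing, " signature gene(s) absent from the test matrix")
  w <- sig$genes$loading[match(common, sig$genes$gene)]
  rho <- apply(test$z[common, , drop = FALSE], 2, cor, x = w,
               method = "spearman")
  ord <- order(-rho, names(rho))
  result <- data.frame(sample = names(rho)[ord], rho = unname(rho[ord]),
                       rank = seq_along(ord), stringsAsFactors = FALSE)
  structure(list(result = result, factor_id = sig$factor_id,
                 n_signature = nrow(sig$genes), n_overlap = length(common),
                 coverage = length(common) / nrow(sig$genes)),
            class = "olsa_validation")
}

#' @export
print.olsa_validation <- function(x, ...) {
  cat(sprintf(
    "Validation of %s: %d/%d signature genes in test set (%.0f%%)\n",
    x$factor_id, x$n_overlap, x$n_signature, 100 * x$coverage))
  print(head(x$result, 5))
  invisible(x)
}
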