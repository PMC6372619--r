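#' Extract principal components of the mirror-augmented matrix
#'
#' Singular value decomposition of `DM` WITHOUT re-centering: the mirror
#' construction already anchors the centroid at the origin, and an
#' off-the-shelf centred PCA would silently shift the origin whenever
#' Grubbs screening removed samples. With no removals the two are
#' identical. Component j's contribution ratio is `sigma_j^2 / sum(sigma^2)`;
#' the smallest k whose cumulative contribution reaches `threshold` is
#' retained (ties broken toward inclusion).
#'
#' @param dm An `olsa_concat`.
#' @param threshold Cumulative-contribution cutoff in (0, 1].
#' @return Object of class `olsa_components`: `loadings` (genes x k,
#'   orthonormal columns), `sigma` (retained singular values),
#'   `contribution`, `cumulative`, `threshold`, `total_ss` (sum of all
#'   squared singular values), and `contribution_all`.
#' @export
extract_components <- function(dm, threshold = 0.8) {
  stopifnot(inherits(dm, "olsa_concat"))
  if (threshold <= 0 || threshold > 1)
    stop("`threshold` must be in (0, 1]")
  sv <- svd(dm$dm)
  ss <- sv$d^2
  total_ss <- sum(ss)
  if (total_ss == 0) stop("concatenated matrix is identically zero")
  contrib <- ss / total_ss
  nonzero <- sv$d > max(sv$d) * 1e-12
  cum <- cumsum(contrib)
  k <- which(cum >= threshold & nonzero)[1]
  if (is.na(k)) {
    warning(sprintf(
      "threshold %g not reachable with nonzero components; retaining all %d",
      threshold, sum(nonzero)))
    k <- sum(nonzero)
  }
  loadings <- sv$u[, seq_len(k), drop = FALSE]
  rownames(loadings) <- rownames(dm$dm)
  colnames(loadings) <- paste0("C", seq_len(k))
  structure(list(loadings = loadings, sigma = sv$d[seq_len(k)],
                 contribution = contrib[seq_len(k)],
                 cumulative = cum[seq_len(k)], threshold = threshold,
                 total_ss = total_ss, contribution_all = contrib),
            class = "olsa_components")
}

#' Raw varimax criterion
#'
#' Sum over factors of the (population) variance of the squared loadings
#' across genes. No Kaiser row-normalization is applied: the rows here are
#' gene coordinates of orthonormal vectors, not differently-scaled
#' variables.
#'
#' @param loadings Numeric matrix, genes x factors.
#' @export
varimax_criterion <- function(loadings) {
  n <- nrow(loadings)
  sq <- loadings^2
  sum(colMeans(sq^2) - colMeans(sq)^2) * n
}

#' Varimax rotation of retained components
#'
#' Rotates the retained orthonormal loadings to maximize the raw varimax
#' criterion, concentrating each factor's mass on few genes while keeping
#' the factors exactly orthogonal. Uses classical pairwise (Jacobi) planar
#' rotations, sweeping all factor pairs until the criterion improves by
#' less than `tol` in a sweep or `max_iter` sweeps elapse. Factors are then
#' re-sorted by post-rotation contribution (descending), renamed P1..Pk,
#' and sign-canonicalized so that each factor's largest-|loading| gene has
#' a positive loading.
#'
#' @param cs An `olsa_components`.
#' @param tol Convergence tolerance on the criterion (default 1e-8).
#' @param max_iter Maximum number of sweeps (default 1000).
#' @return Object of class `olsa_vectors`: `loadings` (factors x genes,
#'   orthonormal rows), `contribution` (post-rotation, descending),
#'   `rotation` (the k x k orthogonal matrix applied), `sigma`, `total_ss`,
#'   and `meta` (iterations, criterion, converged).
#' @export
varimax_rotate <- function(cs, tol = 1e-8, max_iter = 1000L) {
  stopifnot(inherits(cs, "olsa_components"))
  L <- cs$loadings
  k <- ncol(L)
  n <- nrow(L)
  G <- diag(k)
  crit <- varimax_criterion(L)
  iter <- 0L
  converged <- TRUE
  if (k > 1) {
    converged <- FALSE
    for (iter in seq_len(max_iter)) {
      for (p in seq_len(k - 1)) for (q in (p + 1):k) {
        x <- L[, p]; y <- L[, q]
        u <- x^2 - y^2
        v <- 2 * x * y
        A <- sum(u); B <- sum(v)
        C <- sum(u^2 - v^2); D <- 2 * sum(u * v)
        num <- D - 2 * A * B / n
        den <- C - (A^2 - B^2) / n
        phi <- atan2(num, den) / 4
        if (abs(phi) < 1e-14) next
        cphi <- cos(phi); sphi <- sin(phi)
        L[, p] <- cphi * x + sphi * y
        L[, q] <- -sphi * x + cphi * y
        gp <- G[, p]; gq <- G[, q]
        G[, p] <- cphi * gp + sphi * gq
        G[, q] <- -sphi * gp + cphi * gq
      }
      new_crit <- varimax_criterion(L)
      if (new_crit - crit < tol) {
        crit <- max(new_crit, crit)
        converged <- TRUE
        break
      }
      crit <- new_crit
    }
    if (!converged)
      warning("varimax rotation did not converge in ", max_iter, " sweeps")
  }
  # post-rotation contribution: factor j carries sum_m G[m,j]^2 sigma_m^2
  contrib <- as.numeric(crossprod(G^2, cs$sigma^2)) / cs$total_ss
  ord <- order(contrib, decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  G <- G[, ord, drop = FALSE]
  contrib <- contrib[ord]
  # sign canon: largest-|loading| gene positive per factor
  flip <- vapply(seq_len(ncol(L)),
                 function(j) sign(L[which.max(abs(L[, j])), j]), 0)
  flip[flip == 0] <- 1
  L <- sweep(L, 2, flip, "*")
  G <- sweep(G, 2, flip, "*")
  R <- t(L)
  rownames(R) <- paste0("P", seq_len(nrow(R)))
  names(contrib) <- rownames(R)
  structure(list(loadings = R, contribution = contrib, rotation = G,
                 sigma = cs$sigma, total_ss = cs$total_ss,
                 meta = list(iterations = iter, criterion = crit,
                             tol = tol, converged = converged)),
            class = "olsa_vectors")
}

#' @export
print.olsa_vectors <- function(x, ...) {
  cat(sprintf("Response-vector matrix: %d factors x %d genes\n",
              nrow(x$loadings), ncol(x$loadings)))
  cat("  contribution:",
      paste(sprintf("%s=%.3f", names(x$contribution),
                    x$contribution)[seq_len(min(6, length(x$contribution)))],
            collapse = " "),
      if (length(x$contribution) > 6) "..." else "", "\n")
  invisible(x)
}

#' Project normalized profiles onto the response vectors
#'
#' The response-score matrix is the inner-product projection `S = R %*% D'`:
#' entry (j, i) is sample i's activity on factor j. Because each column of
#' `D'` is a unit vector and the rows of `R` are orthonormal, each sample's
#' squared scores sum to at most 1.
#'
#' @param r An `olsa_vectors`.
#' @param dprime An `olsa_normalized` over the same genes (re-aligned by
#'   gene id; a mismatch in the gene sets is an error).
#' @param dm Optional `olsa_concat`; when supplied, per-factor contributions
#'   are recomputed as the factor's share of the squared mass of `DM` and
#'   attached as the `contribution` element.
#' @return Object of class `olsa_scores`: `scores` (factors x samples) and
#'   `contribution`.
#' @export
compute_scores <- function(r, dprime, dm = NULL) {
  stopifnot(inherits(r, "olsa_vectors"), inherits(dprime, "olsa_normalized"))
  g_r <- colnames(r$loadings)
  g_d <- rownames(dprime$u)
  if (!setequal(g_r, g_d)) {
    diff <- c(setdiff(g_r, g_d), setdiff(g_d, g_r))
    stop("gene id mismatch between response vectors and profiles: ",
         paste(head(diff, 10), collapse = ", "),
         if (length(diff) > 10) sprintf(" (and %d more)", length(diff) - 10))
  }
  u <- dprime$u[g_r, , drop = FALSE]
  s <- r$loadings %*% u
  contribution <- r$contribution
  if (!is.null(dm)) {
    stopifnot(inherits(dm, "olsa_concat"))
    sm <- r$loadings %*% dm$dm[g_r, , drop = FALSE]
    contribution <- rowSums(sm^2) / sum(dm$dm^2)
  }
  structure(list(scores = s, contribution = contribution),
            class = "olsa_scores")
}
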