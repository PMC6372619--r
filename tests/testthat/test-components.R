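test_that("component extraction follows the singular-value spectrum", {
  # one repeated profile and its mirror: rank 1, contribution 1
  v <- rnorm(20); v <- v / sqrt(sum(v^2))
  dm <- concat_from_matrix(
    matrix(c(v, v, v, -v, -v, -v), 20, 6,
           dimnames = list(sprintf("g%02d", 1:20), sprintf("c%d", 1:6))),
    n_mirror = 3)
  cs <- extract_components(dm, threshold = 0.8)
  expect_equal(ncol(cs$loadings), 1)
  expect_equal(cs$contribution, 1)

  # planted 70/30 variance split: threshold 0.8 retains both components
  set.seed(21)
  u_ <- qr.Q(qr(matrix(rnorm(40 * 2), 40, 2)))
  v_ <- qr.Q(qr(matrix(rnorm(12 * 2), 12, 2)))
  X <- u_ %*% diag(c(sqrt(7), sqrt(3))) %*% t(v_)
  dimnames(X) <- list(sprintf("g%02d", 1:40), sprintf("c%02d", 1:12))
  cs2 <- extract_components(concat_from_matrix(X), threshold = 0.8)
  expect_equal(ncol(cs2$loadings), 2)
  expect_equal(cs2$contribution, c(0.7, 0.3), tolerance = 1e-10)
  expect_equal(cs2$sigma, c(sqrt(7), sqrt(3)), tolerance = 1e-10)

  # retained loadings are orthonormal
  G <- crossprod(cs2$loadings)
  expect_lt(max(abs(G - diag(2))), 1e-10)

  expect_error(extract_components(dm, threshold = 0), "threshold")
})

test_that("uncentred SVD equals centred PCA when the mirror mean is exactly zero", {
  d <- rand_response(30, 8, seed = 13)
  u <- normalize_profiles(d)
  sel <- structure(list(kept = colnames(u$u), removed = character(),
                        alpha = 0.05, trail = NULL),
                   class = "olsa_mirror_selection")
  dm <- build_concatenated(u, sel)
  cs <- extract_components(dm, threshold = 0.9)
  pc <- prcomp(t(dm$dm), center = TRUE, scale. = FALSE)
  k <- ncol(cs$loadings)
  ang <- principal_angles(cs$loadings, pc$rotation[, seq_len(k)])
  expect_lt(max(ang), 1e-6)
  expect_equal(cs$contribution,
               unname(pc$sdev[seq_len(k)]^2 / sum(pc$sdev^2)),
               tolerance = 1e-10)
})

test_that("varimax leaves perfectly simple structure fixed and ascends the criterion", {
  L <- matrix(0, 10, 2, dimnames = list(sprintf("g%02d", 1:10), NULL))
  L[1:5, 1] <- c(5, 4, 3, 2, 1); L[6:10, 2] <- c(1, 1, 2, 3, 5)
  L <- sweep(L, 2, sqrt(colSums(L^2)), "/")
  cs <- structure(list(loadings = L, sigma = c(2, 1),
                       contribution = c(0.8, 0.2), cumulative = c(0.8, 1),
                       threshold = 0.8, total_ss = 5,
                       contribution_all = c(0.8, 0.2)),
                  class = "olsa_components")
  rv <- varimax_rotate(cs)
  # rotation is identity up to sign/permutation
  M <- abs(rv$loadings %*% L)
  expect_equal(sort(diag(M[, c(1, 2)])), c(1, 1), tolerance = 1e-8)
  expect_gte(rv$meta$criterion, varimax_criterion(L) - 1e-12)

  # criterion never decreases, rows stay orthonormal, signs canonical
  for (seed in 1:5) {
    set.seed(seed)
    Q <- qr.Q(qr(matrix(rnorm(60 * 3), 60, 3)))
    rownames(Q) <- sprintf("g%02d", 1:60)
    cs3 <- structure(list(loadings = Q, sigma = c(3, 2, 1),
                          contribution = c(9, 4, 1) / 14,
                          cumulative = cumsum(c(9, 4, 1) / 14),
                          threshold = 1, total_ss = 14,
                          contribution_all = c(9, 4, 1) / 14),
                     class = "olsa_components")
    rv3 <- varimax_rotate(cs3)
    expect_gte(rv3$meta$criterion, varimax_criterion(Q) - 1e-12)
    R <- rv3$loadings
    expect_lt(max(abs(R %*% t(R) - diag(3))), 1e-10)
    expect_false(is.unsorted(rev(rv3$contribution)))
    for (j in seq_len(3))
      expect_gt(R[j, which.max(abs(R[j, ]))], 0)
    # spans the same subspace as the unrotated components
    expect_lt(max(principal_angles(Q, t(R))), 1e-6)
  }
})

test_that("varimax matches the grid-search oracle and stats::varimax for k = 2", {
  for (seed in 1:10) {
    set.seed(100 + seed)
    Q <- qr.Q(qr(matrix(rnorm(200 * 2), 200, 2)))
    rownames(Q) <- sprintf("g%03d", 1:200)
    cs <- structure(list(loadings = Q, sigma = c(2, 1),
                         contribution = c(0.8, 0.2), cumulative = c(0.8, 1),
                         threshold = 1, total_ss = 5,
                         contribution_all = c(0.8, 0.2)),
                    class = "olsa_components")
    achieved <- varimax_rotate(cs)$meta$criterion
    expect_equal(achieved, grid_varimax_best(Q), tolerance = 1e-6,
                 ignore_attr = TRUE)
    # independent implementation agrees on the achieved criterion
    sv <- stats::varimax(Q, normalize = FALSE, eps = 1e-10)
    expect_equal(achieved, varimax_criterion(sv$loadings),
                 tolerance = 1e-6)
  }
})

test_that("k = 1 rotation is the identity", {
  v <- rnorm(15); v <- v / sqrt(sum(v^2))
  L <- matrix(v, ncol = 1, dimnames = list(sprintf("g%02d", 1:15), NULL))
  cs <- structure(list(loadings = L, sigma = 2, contribution = 1,
                       cumulative = 1, threshold = 0.8, total_ss = 4,
                       contribution_all = 1),
                  class = "olsa_components")
  rv <- varimax_rotate(cs)
  expect_equal(abs(as.numeric(rv$loadings)), abs(v))
  expect_equal(rv$contribution, c(P1 = 1))
})

test_that("scores are inner products and reconstruct the projection", {
  d <- rand_response(50, 12, seed = 6)
  u <- normalize_profiles(d)
  sel <- structure(list(kept = colnames(u$u), removed = character(),
                        alpha = 0.05, trail = NULL),
                   class = "olsa_mirror_selection")
  dm <- build_concatenated(u, sel)
  cs <- extract_components(dm, threshold = 0.8)
  rv <- varimax_rotate(cs)
  sc <- compute_scores(rv, u, dm = dm)

  # a sample equal to a response vector scores 1 on it, 0 elsewhere
  probe <- t(rv$loadings[c(1, 2), , drop = FALSE])
  colnames(probe) <- c("p1", "p2")
  sc_probe <- compute_scores(
    rv, structure(list(u = probe, l = c(1, 1)), class = "olsa_normalized"))
  expect_equal(unname(sc_probe$scores[, "p1"]),
               c(1, rep(0, nrow(rv$loadings) - 1)), tolerance = 1e-10)

  # t(R) S is the orthogonal projection of D' onto the retained subspace
  proj <- cs$loadings %*% crossprod(cs$loadings, u$u)
  expect_lt(max(abs(t(rv$loadings) %*% sc$scores - proj)), 1e-10)
  # rotation preserves the Frobenius norm of the scores
  expect_equal(norm(sc$scores, "F"), norm(crossprod(cs$loadings, u$u), "F"),
               tolerance = 1e-10)
  # each column of D' is a unit vector: squared scores sum to <= 1
  expect_lt(max(colSums(sc$scores^2)), 1 + 1e-10)

  u_bad <- u
  rownames(u_bad$u)[1] <- "other"
  expect_error(compute_scores(rv, u_bad), "gene id mismatch")
})
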