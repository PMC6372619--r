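# Shared builders and independent oracles for the test suite.

tiny_expression <- function() {
  set.seed(42)
  m <- matrix(rnorm(8 * 6, mean = 100, sd = 10), 8, 6,
              dimnames = list(sprintf("g%02d", 1:8), sprintf("s%d", 1:6)))
  expression_matrix(m, control_mask = c("s1", "s2", "s3"))
}

rand_response <- function(n_genes = 50, n_samples = 10, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n_samples))))
  as_response_profile(m)
}

# olsa_vectors with prescribed rows (tests of signature/score tooling)
vectors_from_rows <- function(rows) {
  structure(list(loadings = rows,
                 contribution = stats::setNames(
                   rep(1 / nrow(rows), nrow(rows)), rownames(rows)),
                 rotation = diag(nrow(rows)), sigma = rep(1, nrow(rows)),
                 total_ss = nrow(rows), meta = list()),
            class = "olsa_vectors")
}

concat_from_matrix <- function(dm, n_mirror = 0) {
  structure(list(dm = dm,
                 is_mirror = c(rep(FALSE, ncol(dm) - n_mirror),
                               rep(TRUE, n_mirror))),
            class = "olsa_concat")
}

# independent grid-search oracle: best raw varimax criterion over planar
# rotations of a two-column loading matrix, 0.001-rad steps
grid_varimax_best <- function(L, step = 0.001) {
  theta <- seq(0, pi / 2, by = step)
  x <- L[, 1]; y <- L[, 2]
  n <- nrow(L)
  A1 <- outer(x, cos(theta)) + outer(y, sin(theta))
  A2 <- -outer(x, sin(theta)) + outer(y, cos(theta))
  crit <- function(A) (colMeans(A^4) - colMeans(A^2)^2) * n
  max(crit(A1) + crit(A2))
}

# brute-force upper hypergeometric tail: P(overlap >= x) for a query of
# size n against a set of size K in a universe of size N
hyper_tail_bruteforce <- function(x, K, N, n) {
  js <- x:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# principal angles (radians) between the column spans of two orthonormal
# bases
principal_angles <- function(Q1, Q2) {
  sv <- svd(crossprod(Q1, Q2))$d
  acos(pmin(pmax(sv, -1), 1))
}

small_spec <- function(seed = 1, ...) {
  args <- modifyList(list(n_genes = 400, n_samples = 50, k_factors = 3,
                          sparsity = 0.05, score_scale = 2,
                          score_ratio = 0.7, noise_sd = 0.05, seed = seed),
                     list(...))
  do.call(synthetic_spec, args)
}

# calm generator settings for the Grubbs-gate check: noise-dominated
# profile norms and near-constant strengths, so the only extreme L2-norms
# are the planted outliers
gate_spec <- function(seed, n_outliers = 2, outlier_multiplier = 20) {
  synthetic_spec(n_genes = 400, n_samples = 40, k_factors = 3,
                 sparsity = 0.05, score_scale = 0.5, score_ratio = 0.7,
                 noise_sd = 1.0, strength_sdlog = 0.01,
                 n_outliers = n_outliers,
                 outlier_multiplier = outlier_multiplier, seed = seed)
}

write_tsv_fixture <- function(lines, path) {
  writeLines(lines, path)
  path
}
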