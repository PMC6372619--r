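gmt_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gmt",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("GMT files are parsed with the dialect's edge cases", {
  p <- gmt_fixture(c("setA\tdesc A\tg1\tg2\tg3",
                     "setB\tdesc B\tg2\tg4"))
  gsc <- read_gmt(p)
  expect_length(gsc$sets, 2)
  expect_equal(gsc$sets$setA, c("g1", "g2", "g3"))

  dupmem <- gmt_fixture(c("setA\td\tg1\tg1\tg2"))
  expect_warning(g2 <- read_gmt(dupmem), "duplicated member")
  expect_length(g2$sets$setA, 2)

  empty <- gmt_fixture(c("setA\td\tg1", "setB\td"))
  expect_warning(g3 <- read_gmt(empty), "empty gene set")
  expect_length(g3$sets, 1)

  dupname <- gmt_fixture(c("setA\td\tg1", "setA\td\tg2"))
  expect_error(read_gmt(dupname), "duplicate gene set names")

  # round trip preserves sets
  out <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gsc, out)
  expect_equal(read_gmt(out)$sets, gsc$sets)
})

test_that("enrichment p-values equal the hypergeometric tail", {
  universe <- sprintf("g%03d", 1:100)
  gsc <- structure(list(sets = list(full = universe[1:10],
                                    none = universe[91:95]),
                        descriptions = c(full = "", none = ""),
                        source = "test"),
                   class = "gene_set_collection")
  # query identical to a 10-gene set: p = C(10,10)C(90,0)/C(100,10)
  tab <- fisher_enrich(universe[1:10], gsc, universe)
  expect_equal(tab$p[tab$set == "full"], 1 / choose(100, 10),
               tolerance = 1e-12)
  expect_equal(tab$overlap[tab$set == "none"], 0)
  expect_equal(tab$p[tab$set == "none"], 1)

  # query = universe: every set has p = 1
  tab2 <- fisher_enrich(universe, gsc, universe)
  expect_equal(tab2$p, c(1, 1))

  # random 2x2 tables, universe <= 200: agree with brute-force tail sums
  # and with one-sided Fisher's exact test
  set.seed(12)
  for (i in 1:25) {
    N <- sample(20:200, 1)
    uni <- sprintf("u%03d", 1:N)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    set_ <- sample(uni, K)
    query <- sample(uni, n)
    g <- structure(list(sets = list(s = set_), descriptions = c(s = ""),
                        source = "t"), class = "gene_set_collection")
    p <- fisher_enrich(query, g, uni)$p
    x <- length(intersect(set_, query))
    expect_equal(p, hyper_tail_bruteforce(x, K, N, n), tolerance = 1e-12)
    ft <- fisher.test(matrix(c(x, K - x, n - x, N - K - n + x), 2),
                      alternative = "greater")
    expect_equal(p, unname(ft$p.value), tolerance = 1e-9)
  }

  expect_error(fisher_enrich(character(), gsc, universe), "empty query")
  expect_warning(fisher_enrich(c(universe[1], "zzz"), gsc, universe),
                 "outside the universe")
})

test_that("BH adjustment and the significant-enrichment ratio behave as computed by hand", {
  tab <- data.frame(factor = paste0("P", 1:4), set = "s",
                    p = c(0.01, 0.02, 0.03, 0.04))
  res <- bh_adjust_and_segr(tab, alpha = 0.05)
  # hand BH: q_i = min_j>=i p_(j) * m / j = 0.04 for all four
  expect_equal(res$table$q, rep(0.04, 4))
  expect_true(all(res$table$significant))
  expect_equal(res$segr, 1)

  null_tab <- data.frame(factor = paste0("P", 1:3), set = "s", p = 1)
  expect_equal(bh_adjust_and_segr(null_tab)$segr, 0)

  # q >= p elementwise and monotone in p
  set.seed(7)
  rt <- data.frame(factor = rep(paste0("P", 1:6), each = 4),
                   set = rep(paste0("s", 1:4), 6), p = runif(24))
  r2 <- bh_adjust_and_segr(rt)
  expect_true(all(r2$table$q >= r2$table$p))
  o <- order(r2$table$p)
  expect_false(is.unsorted(r2$table$q[o]))
  expect_gte(r2$segr, 0); expect_lte(r2$segr, 1)

  # the ratio arithmetic: 65 enriched factors of 118 -> 0.551
  big <- data.frame(factor = paste0("P", 1:118), set = "s",
                    p = c(rep(1e-6, 65), rep(1, 53)))
  expect_equal(round(bh_adjust_and_segr(big)$segr, 3), 0.551)
  expect_equal(bh_adjust_and_segr(big)$segr, 65 / 118)

  # per-factor-min family adjusts each factor's best p
  pf <- bh_adjust_and_segr(rt, family = "per_factor_min")
  mins <- tapply(rt$p, rt$factor, min)
  qmin <- p.adjust(mins, "BH")
  by_factor <- tapply(pf$table$q, pf$table$factor, unique)
  expect_equal(as.numeric(by_factor[names(qmin)]), as.numeric(qmin))
})

test_that("factor-level enrichment flags the planted gene set", {
  sim <- generate_synthetic(small_spec(seed = 23, n_genes = 300,
                                       n_samples = 40))
  fit <- run_olsa(sim$response)
  rec <- recovery_score(sim$truth, fit$vectors)
  # gene set = support of planted factor 1; its matched fitted factor's
  # top genes should be strongly enriched
  support <- rownames(sim$truth$loadings)[sim$truth$loadings[, 1] != 0]
  decoy <- sample(colnames(fit$vectors$loadings), 20)
  gsc <- structure(list(sets = list(planted = support, decoy = decoy),
                        descriptions = c(planted = "", decoy = ""),
                        source = "synthetic"),
                   class = "gene_set_collection")
  res <- enrich_factors(fit$vectors, gsc, fraction = 0.05, alpha = 0.05)
  hit <- res$table[res$table$factor == rec$matched[1] &
                     res$table$set == "planted", ]
  expect_true(hit$significant)
  expect_gte(res$segr, 1 / nrow(fit$vectors$loadings))
})
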