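#' Read a gene-set collection from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated `name`,
#' `description`, then member gene ids. Duplicate members within a set are
#' dropped with a warning; lines with no members are skipped with a
#' warning; duplicate set names are an error.
#'
#' @param path GMT file path.
#' @return Object of class `gene_set_collection`: named list `sets`,
#'   `descriptions`, and `source`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t")
  names_ <- vapply(fields, `[`, "", 1L)
  dup <- unique(names_[duplicated(names_)])
  if (length(dup))
    stop("duplicate gene set names: ", paste(dup, collapse = ", "))
  sets <- list(); descs <- character()
  for (f in fields) {
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (!length(members)) {
      warning("skipping empty gene set: ", f[1])
      next
    }
    if (anyDuplicated(members)) {
      warning("duplicated member gene(s) in set ", f[1], "; deduplicated")
      members <- unique(members)
    }
    sets[[f[1]]] <- members
    descs[f[1]] <- if (length(f) >= 2) f[2] else ""
  }
  if (!length(sets)) stop("no non-empty gene sets in ", path)
  structure(list(sets = sets, descriptions = descs, source = path),
            class = "gene_set_collection")
}

#' Write a gene-set collection to GMT
#' @param gsc A `gene_set_collection`.
#' @param path Output path.
#' @export
write_gmt <- function(gsc, path) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  lines <- vapply(names(gsc$sets), function(nm) {
    paste(c(nm, gsc$descriptions[[nm]] %||% "", gsc$sets[[nm]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("Gene set collection: %d sets (source: %s)\n",
              length(x$sets), x$source))
  invisible(x)
}

#' Gene-set over-representation of a query list
#'
#' One-sided (enrichment) hypergeometric test of a query gene list against
#' each set, relative to a universe. The universe should be the genes that
#' could have been selected -- all genes of the analyzed matrix, not all
#' genes of the collection. Query genes outside the universe are dropped
#' with a warning; each set is intersected with the universe before
#' testing. For a 2x2 table with `x` overlap genes, the p-value is the
#' upper hypergeometric tail P(X >= x), identical to one-sided Fisher's
#' exact test.
#'
#' @param query Character vector of gene ids.
#' @param gsc A `gene_set_collection`.
#' @param universe Character vector of background gene ids.
#' @return Data frame: set, overlap, set_size, query_size, universe_size,
#'   odds_ratio, p.
#' @export
fisher_enrich <- function(query, gsc, universe) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  universe <- unique(universe)
  query <- unique(query)
  if (!length(universe)) stop("empty universe")
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  if (!length(query)) stop("empty query after universe filtering")
  N <- length(universe); n <- length(query)
  rows <- lapply(names(gsc$sets), function(nm) {
    K <- length(intersect(gsc$sets[[nm]], universe))
    x <- length(intersect(gsc$sets[[nm]], query))
    p <- if (K == 0) 1 else phyper(x - 1, K, N - K, n, lower.tail = FALSE)
    or <- (x * (N - K - n + x)) / ((K - x) * (n - x))
    data.frame(set = nm, overlap = x, set_size = K, query_size = n,
               universe_size = N, odds_ratio = or, p = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' BH correction across factors and the significant-enrichment ratio
#'
#' Adjusts enrichment p-values across factors by Benjamini-Hochberg and
#' summarizes the decomposition with the significant-enrichment ratio:
#' the fraction of factors with at least one gene set at `q < alpha`. The
#' correction family is either all (factor, set) pairs jointly
#' (`"pairs"`, the default and most conservative interpretable choice) or
#' each factor's minimum p across sets (`"per_factor_min"`).
#'
#' @param tables Data frame with at least columns `factor` and `p`
#'   (typically rbind-ed [fisher_enrich()] results with a `factor` column).
#' @param alpha Significance level in (0, 1).
#' @param family `"pairs"` or `"per_factor_min"`.
#' @return List: `table` (input plus `q` and `significant`; for
#'   `per_factor_min`, `q` is the factor-level adjusted minimum p attached
#'   to every row of the factor), `segr` (significant factors / total
#'   factors), and `significant_factors`.
#' @export
bh_adjust_and_segr <- function(tables, alpha = 0.05,
                               family = c("pairs", "per_factor_min")) {
  family <- match.arg(family)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)")
  stopifnot(is.data.frame(tables), all(c("factor", "p") %in% names(tables)))
  if (family == "pairs") {
    tables$q <- p.adjust(tables$p, method = "BH")
  } else {
    pmin_ <- tapply(tables$p, tables$factor, min)
    qmin <- p.adjust(pmin_, method = "BH")
    tables$q <- unname(qmin[as.character(tables$factor)])
  }
  tables$significant <- tables$q < alpha
  factors <- unique(as.character(tables$factor))
  sig <- vapply(factors, function(f)
    any(tables$significant[tables$factor == f]), TRUE)
  list(table = tables, segr = sum(sig) / length(factors),
       significant_factors = factors[sig])
}

#' Enrichment screen of every factor's top genes
#'
#' For each factor, selects the top `fraction` of genes by squared loading
#' ([top_fraction_genes()]), tests them against the collection with
#' [fisher_enrich()] over the universe of all genes in the decomposition,
#' then applies [bh_adjust_and_segr()].
#'
#' @param r An `olsa_vectors`.
#' @param gsc A `gene_set_collection`.
#' @param fraction Top-gene fraction (default 0.01).
#' @param alpha BH significance level (default 0.05).
#' @param family Correction family, see [bh_adjust_and_segr()].
#' @return As [bh_adjust_and_segr()], with the per-pair table carrying
#'   `factor` and all [fisher_enrich()] columns.
#' @export
enrich_factors <- function(r, gsc, fraction = 0.01, alpha = 0.05,
                           family = c("pairs", "per_factor_min")) {
  stopifnot(inherits(r, "olsa_vectors"))
  universe <- colnames(r$loadings)
  tabs <- lapply(rownames(r$loadings), function(f) {
    tg <- top_fraction_genes(r, f, fraction)
    cbind(factor = f, fisher_enrich(tg$gene, gsc, universe),
          stringsAsFactors = FALSE)
  })
  bh_adjust_and_segr(do.call(rbind, tabs), alpha = alpha,
                     family = match.arg(family))
}
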