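#' Total strength: per-sample L2-norm of the response profile
#'
#' The Euclidean norm `l_i = sqrt(sum_k z_ik^2)` of sample i's response
#' profile measures how strongly the perturbagen moved the transcriptome
#' away from the control state, independent of direction. Collected in a
#' diagonal matrix it factors stimulation intensity out of the
#' decomposition: `D = D' %*% diag(l)`.
#'
#' @param d An `olsa_response` matrix.
#' @return Object of class `olsa_strength`: list with `l` (named positive
#'   numeric) and `sample_ids`.
#' @export
total_strength <- function(d) {
  stopifnot(inherits(d, "olsa_response"))
  l <- sqrt(colSums(d$z^2))
  zero <- l == 0
  if (any(zero))
    stop("all-zero response profile(s): ",
         paste(colnames(d$z)[zero], collapse = ", "))
  structure(list(l = l, sample_ids = colnames(d$z)), class = "olsa_strength")
}

#' Diagonal total-strength matrix
#' @param ts An `olsa_strength`.
#' @return Diagonal matrix T with l on the diagonal.
#' @export
strength_matrix <- function(ts) {
  stopifnot(inherits(ts, "olsa_strength"))
  diag(ts$l, nrow = length(ts$l))
}

#' One-sided Grubbs critical value
#'
#' Upper-tail critical value for the Grubbs outlier statistic at sample size
#' `n`: `((n-1)/sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))` with `t` the upper
#' `alpha/n` quantile of the t distribution on `n - 2` degrees of freedom.
#'
#' @param n Sample size (>= 3).
#' @param alpha Significance level in (0, 1).
#' @export
grubbs_critical <- function(n, alpha = 0.05) {
  if (n < 3) stop("Grubbs test needs n >= 3")
  t <- qt(1 - alpha / n, df = n - 2)
  (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2))
}

#' Select samples for the mirror data set by iterative Grubbs screening
#'
#' Samples whose total strength is extreme are interpreted as irreversible
#' responses (e.g. overt toxicity); mirroring them would plant a fictitious
#' "recovery" profile, so they are excluded from the mirror set. The
#' screening is a one-sided (upper-tail) Grubbs test on the L2-norms,
#' applied iteratively: while the largest norm's statistic
#' `G = (max(l) - mean(l)) / sd(l)` exceeds the critical value at `alpha`,
#' that sample is removed and the test repeated on the remainder.
#'
#' @param ts An `olsa_strength`.
#' @param alpha One-sided significance level (default 0.05).
#' @return Object of class `olsa_mirror_selection`: `kept`, `removed`,
#'   `alpha`, and a `trail` data frame with one row per iteration
#'   (sample tested, G, critical value, removed flag).
#' @export
select_mirror_samples <- function(ts, alpha = 0.05) {
  stopifnot(inherits(ts, "olsa_strength"))
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)")
  l <- ts$l
  if (length(l) < 3) stop("Grubbs screening needs >= 3 samples")
  removed <- character()
  trail <- data.frame(iteration = integer(), sample = character(),
                      l = numeric(), G = numeric(), critical = numeric(),
                      removed = logical(), stringsAsFactors = FALSE)
  it <- 0L
  repeat {
    it <- it + 1L
    n <- length(l)
    s <- sd(l)
    i_max <- which.max(l)
    G <- if (s == 0) 0 else (l[i_max] - mean(l)) / s
    crit <- grubbs_critical(n, alpha)
    hit <- is.finite(G) && G > crit
    trail <- rbind(trail, data.frame(
      iteration = it, sample = names(l)[i_max], l = unname(l[i_max]),
      G = unname(G), critical = crit, removed = hit,
      stringsAsFactors = FALSE))
    if (!hit) break
    removed <- c(removed, names(l)[i_max])
    l <- l[-i_max]
    if (length(l) < 3)
      stop("Grubbs screening removed too many samples; ",
           "fewer than 3 would remain for the mirror set")
  }
  structure(list(kept = names(l), removed = removed, alpha = alpha,
                 trail = trail),
            class = "olsa_mirror_selection")
}

#' @export
print.olsa_mirror_selection <- function(x, ...) {
  cat(sprintf("Mirror selection: kept %d, removed %d (alpha = %g)\n",
              length(x$kept), length(x$removed), x$alpha))
  if (length(x$removed))
    cat("  removed:", paste(x$removed, collapse = ", "), "\n")
  invisible(x)
}

#' Normalize response profiles to unit L2-norm
#'
#' Divides each sample column by its total strength so that every profile
#' is a pure direction; comparisons between samples then reflect the kind
#' of response, not the intensity of stimulation.
#'
#' @param d An `olsa_response`.
#' @param ts Optional `olsa_strength` (recomputed when missing).
#' @return Object of class `olsa_normalized`: `u` (genes x samples, unit
#'   columns) plus the strengths used.
#' @export
normalize_profiles <- function(d, ts = NULL) {
  stopifnot(inherits(d, "olsa_response"))
  if (is.null(ts)) ts <- total_strength(d)
  if (!identical(ts$sample_ids, colnames(d$z)))
    stop("strength/sample id mismatch")
  u <- sweep(d$z, 2, ts$l, "/")
  structure(list(u = u, l = ts$l), class = "olsa_normalized")
}

#' Concatenate normalized profiles with their mirror image
#'
#' The mirror set `M = -P'` is the point-symmetric image of the selected
#' normalized profiles; concatenating `DM = [D' | M]` pins the centroid of
#' the combined cloud at (or next to) the origin, so that component
#' extraction without re-centering is anchored at the control state. When
#' no samples were removed the column mean of `DM` is exactly zero.
#'
#' @param dprime An `olsa_normalized`.
#' @param sel An `olsa_mirror_selection` whose kept ids are a subset of the
#'   samples of `dprime`.
#' @return Object of class `olsa_concat`: `dm` (genes x (N + m)), with
#'   mirror columns labelled `mirror:<sample>`, and `is_mirror` flags.
#' @export
build_concatenated <- function(dprime, sel) {
  stopifnot(inherits(dprime, "olsa_normalized"),
            inherits(sel, "olsa_mirror_selection"))
  missing <- setdiff(sel$kept, colnames(dprime$u))
  if (length(missing))
    stop("mirror selection refers to unknown samples: ",
         paste(missing, collapse = ", "))
  if (!length(sel$kept)) stop("mirror selection kept no samples")
  p <- dprime$u[, sel$kept, drop = FALSE]
  dm <- cbind(dprime$u, -p)
  colnames(dm) <- c(colnames(dprime$u), paste0("mirror:", sel$kept))
  structure(list(dm = dm,
                 is_mirror = c(rep(FALSE, ncol(dprime$u)),
                               rep(TRUE, ncol(p)))),
            class = "olsa_concat")
}
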