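#' Cohen's (weighted) kappa with interpretation bins
#'
#' Chance-corrected agreement between two aligned categorical vectors:
#' `kappa = 1 - sum(W * O) / sum(W * E)` with disagreement weights `W`
#' (`"none"`: 0/1; `"linear"`: |i - j| / (k - 1); `"quadratic"`:
#' squared), observed table `O` and the outer product of the margins `E`.
#' For binary data all three schemes coincide.  The interpretation bin
#' follows the cut points <0.20 none, 0.20–0.39 minimal, 0.40–0.59 weak,
#' 0.60–0.79 moderate, 0.80–0.89 strong, and 0.89–1.00 almost perfect;
#' values in \[0.89, 0.90) bin as almost perfect.
#'
#' When both raters are constant and identical, expected agreement is 1
#' and kappa is undefined; this is signalled by `kappa = NA` with a
#' warning.
#'
#' @param a,b Aligned vectors of ratings (coerced to factors over the
#'   union of observed levels).
#' @param weights `"linear"` (default), `"quadratic"` or `"none"`.
#' @return A list of class `agreement_result`: `kappa`,
#'   `interpretation`, `observed_agreement`, `expected_agreement`,
#'   `weights`, `n`.
#' @export
cohens_kappa <- function(a, b, weights = c("linear", "quadratic", "none")) {
  weights <- match.arg(weights)
  if (length(a) != length(b)) stop("rating vectors must be aligned (equal length)")
  if (length(a) == 0L) stop("empty rating vectors")
  lev <- sort(unique(c(a, b)))
  fa <- factor(a, levels = lev); fb <- factor(b, levels = lev)
  k <- length(lev)
  O <- table(fa, fb) / length(a)
  E <- outer(rowSums(O), colSums(O))
  W <- if (k == 1L) matrix(0, 1, 1) else switch(weights,
    none = 1 - diag(k),
    linear = abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1),
    quadratic = (outer(seq_len(k), seq_len(k), "-") / (k - 1))^2)
  wo <- sum(W * O); we <- sum(W * E)
  po <- sum(diag(O)); pe <- sum(diag(E))
  if (we == 0) {
    warning("both raters are constant and identical; kappa is undefined")
    kap <- NA_real_
  } else {
    kap <- 1 - wo / we
  }
  structure(list(kappa = kap,
                 interpretation = kappa_interpretation(kap),
                 observed_agreement = po, expected_agreement = pe,
                 weights = weights, n = length(a)),
            class = "agreement_result")
}

#' Interpretation bin for a kappa value
#' @param kappa Numeric kappa (may be `NA`).
#' @return Character bin label.
#' @export
kappa_interpretation <- function(kappa) {
  if (is.na(kappa)) return(NA_character_)
  if (kappa < 0.20) "no agreement"
  else if (kappa < 0.40) "minimal"
  else if (kappa < 0.60) "weak"
  else if (kappa < 0.80) "moderate"
  else if (kappa < 0.89) "strong"
  else "almost perfect"
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa (%s weights): %.3f (%s); p_o = %.3f, p_e = %.3f, n = %d\n",
              x$weights, x$kappa, x$interpretation,
              x$observed_agreement, x$expected_agreement, x$n))
  invisible(x)
}

#' Concordance category between two pathologic-segment sets
#'
#' Total concordance: both modalities identified the same segments (two
#' empty sets count as total, vacuously).  No concordance: the first
#' modality identified none of the reference's segments while the
#' reference found at least one.  Everything else (more or fewer
#' segments, but overlapping) is partial.
#'
#' @param ct_segments,mri_segments Vectors of pathologic segment numbers.
#' @return `"total"`, `"partial"`, or `"none"`.
#' @export
concordance_category <- function(ct_segments, mri_segments) {
  ct <- unique(ct_segments); mri <- unique(mri_segments)
  if (setequal(ct, mri)) return("total")
  if (length(intersect(ct, mri)) == 0L && length(mri) > 0L) return("none")
  "partial"
}

#' Median and interquartile range
#'
#' The median is the midpoint of the order statistics; quartiles use a
#' configurable convention (default: linear interpolation of order
#' statistics, `stats::quantile` type 7).
#'
#' @param values Non-empty numeric vector.
#' @param type Quantile type passed to [stats::quantile()].
#' @return Named numeric vector `c(median, q1, q3)`.
#' @export
median_iqr <- function(values, type = 7) {
  if (length(values) == 0L) stop("empty value vector")
  q <- stats::quantile(values, c(0.25, 0.75), type = type, names = FALSE)
  c(median = stats::median(values), q1 = q[1], q3 = q[2])
}

#' Wilcoxon signed-rank test
#'
#' Paired signed-rank test with the classic zero-handling policy: zero
#' differences are dropped before ranking.  The exact distribution is
#' used for n <= 25 non-zero differences without ties; above that (or
#' with ties) the normal approximation with tie correction is used.  If
#' every difference is zero the test is vacuous and p = 1 is returned
#' with a warning.
#'
#' @param x,y Equal-length numeric vectors (`y` defaults to zeros, i.e.
#'   `x` are the differences).
#' @param alternative `"two.sided"` (default), `"less"`, or `"greater"`.
#' @return A list: `statistic` (V, sum of positive ranks), `p_value`,
#'   `n` (non-zero differences), `method`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL,
                                 alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (is.null(y)) y <- rep(0, length(x))
  if (length(x) != length(y)) stop("x and y must have equal length")
  d <- x - y
  d <- d[d != 0]
  if (length(d) == 0L) {
    warning("all differences are zero; the test is vacuous")
    return(list(statistic = NA_real_, p_value = 1, n = 0L,
                method = "degenerate (all zero differences)"))
  }
  ties <- any(duplicated(abs(d)))
  exact <- length(d) <= 25L && !ties
  res <- suppressWarnings(
    stats::wilcox.test(d, alternative = alternative, exact = exact,
                       correct = FALSE))
  list(statistic = unname(res$statistic), p_value = res$p.value,
       n = length(d),
       method = if (exact) "exact" else "normal approximation with tie correction")
}

#' Noise-reduction factor of 2-D median filtration
#'
#' Generates an i.i.d. Gaussian matrix of about `n_cells` cells, applies
#' [median_filter_matrix()], and returns the ratio of input to output
#' standard deviation, measured on interior cells only (the replicated
#' layer edges are excluded; the sector wrap is exact and needs no
#' margin).  For a `k` x `k` kernel the asymptotic value is
#' `sqrt(2 k^2 / pi)`: about 4.0 for 5 x 5 and about 2.4 for 3 x 3.
#'
#' @param kernel Odd kernel size.
#' @param n_cells Approximate number of matrix cells (default 1e6; fewer
#'   than 1e4 triggers a warning about estimator stability).
#' @param sigma Noise standard deviation of the input field.
#' @param seed Integer seed.
#' @return Scalar fold-reduction in noise standard deviation.
#' @export
simulate_filter_noise_reduction <- function(kernel, n_cells = 1e6,
                                            sigma = 1, seed = 1L) {
  kernel <- as.integer(kernel)
  if (kernel < 1L || kernel %% 2L == 0L)
    stop("kernel must be an odd positive integer")
  if (n_cells < 1e4)
    warning("fewer than 1e4 cells; the reduction-factor estimate may be unstable")
  side <- as.integer(ceiling(sqrt(n_cells)))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  m <- matrix(stats::rnorm(side * side, 0, sigma), side, side)
  f <- median_filter_matrix(m, kernel)
  h <- kernel %/% 2L
  rows <- if (side > 2L * h) (h + 1L):(side - h) else seq_len(side)
  stats::sd(m[rows, ]) / stats::sd(f[rows, ])
}

#' Pooled intermodality agreement over segment calls
#'
#' Pools per-segment binary calls across patients into two aligned
#' vectors and computes Cohen's weighted kappa plus the per-patient
#' concordance taxonomy.
#'
#' @param ct,ref Lists (one element per patient) of equal-length binary
#'   vectors of segment calls for the index and reference modality.
#' @param weights Kappa weighting scheme.
#' @return A list: `kappa` (an `agreement_result`), `concordance`
#'   (character vector per patient), `n_patients`, `n_segments`.
#' @export
agreement_summary <- function(ct, ref, weights = "linear") {
  if (length(ct) != length(ref)) stop("ct and ref must have one entry per patient")
  conc <- character(length(ct))
  for (i in seq_along(ct)) {
    if (length(ct[[i]]) != length(ref[[i]]))
      stop(sprintf("patient %d: call vectors differ in length", i))
    conc[i] <- concordance_category(which(ct[[i]] != 0), which(ref[[i]] != 0))
  }
  kap <- cohens_kappa(unlist(ct), unlist(ref), weights = weights)
  list(kappa = kap, concordance = conc, n_patients = length(ct),
       n_segments = length(unlist(ct)))
}
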