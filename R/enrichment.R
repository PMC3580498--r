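#' MA transformation of two region count tables
#'
#' Per region, `M = log2((b + pc) / (a + pc))` with `b` the treated and `a`
#' the untreated sample, and `A = (log2(a + pc) + log2(b + pc)) / 2`.  The
#' inputs should be TRPK-normalized so `M` is free of depth effects; the
#' pseudocount keeps both finite for empty regions.
#'
#' @param counts_a untreated/reference sample: a `region_counts` table (its
#'   `trpk` column is used when present, else `rpk`) or a numeric vector.
#' @param counts_b treated sample, same regions in the same order.
#' @param pseudocount added to both values before the logs (default 0.5).
#' @return data.frame of class `"ma_points"`: `region_id`, `M`, `A` (and
#'   `Z = NA` until [zscore_stratified()] is applied).
#' @export
ma_transform <- function(counts_a, counts_b, pseudocount = 0.5) {
  ids_a <- region_ids(counts_a)
  ids_b <- region_ids(counts_b)
  if (!identical(ids_a, ids_b))
    stop("ma_transform(): region sets differ between the two samples")
  a <- region_values(counts_a, "trpk_or_rpk")
  b <- region_values(counts_b, "trpk_or_rpk")
  if (length(a) != length(b)) stop("ma_transform(): tables have different sizes")
  M <- log2((b + pseudocount) / (a + pseudocount))
  A <- 0.5 * (log2(a + pseudocount) + log2(b + pseudocount))
  out <- data.frame(region_id = if (is.null(ids_a)) seq_along(a) else ids_a,
                    M = M, A = A, Z = NA_real_, stringsAsFactors = FALSE)
  class(out) <- c("ma_points", "data.frame")
  out
}

region_ids <- function(x) if (is.numeric(x)) NULL else x$region_id

#' A-stratified standardization of M values (enrichment Z-scores)
#'
#' Points are sorted by `A` and split into `n_strata` equal-count strata
#' (fewer when the input is small, so that each stratum keeps at least
#' `min_per_stratum` points); within each stratum `M` is standardized to a
#' Z-score.  The default standardization is robust — median centre, MAD
#' scale — so that a minority of genuinely enriched regions inside a
#' stratum does not inflate the scale estimate against which they are
#' judged.  Because genuine enrichment raises A together with M, the
#' highest-A strata can end up with a *majority* of enriched regions, where
#' even median/MAD breaks down; the null trend and spread vary smoothly
#' with A, so the per-stratum centre and scale are additionally regularized
#' by a running median over `smooth_strata` neighbouring strata, letting a
#' signal-dominated stratum inherit the null statistics of its neighbours.
#' `method = "moments"` uses the classical per-stratum mean/SD with no
#' regularization.  Strata with zero scale yield `Z = 0` with a warning.
#'
#' @param points an `ma_points` data.frame from [ma_transform()].
#' @param n_strata target number of A-strata (default 20).
#' @param min_per_stratum minimum points per stratum (default 25).
#' @param method `"robust"` (median/MAD, default) or `"moments"` (mean/SD).
#' @param smooth_strata width (in strata) of the running median applied to
#'   the robust per-stratum centres and scales (default 5; 1 disables).
#' @return `points` with the `Z` column filled, input order preserved.
#' @export
zscore_stratified <- function(points, n_strata = 20, min_per_stratum = 25,
                              method = c("robust", "moments"),
                              smooth_strata = 5) {
  method <- match.arg(method)
  n <- nrow(points)
  if (n < 2) stop("zscore_stratified(): need at least 2 points")
  k <- max(1L, min(as.integer(n_strata), n %/% as.integer(min_per_stratum)))
  ord <- order(points$A)
  stratum <- integer(n)
  stratum[ord] <- ceiling(seq_len(n) * k / n)
  groups <- split(points$M, stratum)
  if (method == "robust") {
    centre <- vapply(groups, stats::median, 0)
    scale <- vapply(groups, stats::mad, 0)
    if (smooth_strata > 1 && k > 1) {
      centre <- running_median(centre, smooth_strata)
      scale <- running_median(scale, smooth_strata)
    }
  } else {
    centre <- vapply(groups, mean, 0)
    scale <- vapply(groups, stats::sd, 0)
  }
  bad <- !is.finite(scale) | scale == 0
  if (any(bad)) {
    warning("stratum with zero M spread: Z set to 0 there")
    scale[bad] <- Inf
  }
  points$Z <- (points$M - centre[stratum]) / scale[stratum]
  points
}

## running median with truncated (centred) windows at the edges
running_median <- function(x, w) {
  half <- w %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i)
    stats::median(x[max(1, i - half):min(n, i + half)]), 0)
}

#' Call significantly enriched regions at a fixed Z threshold
#'
#' Significance is the strict one-sided rule `Z > threshold` (enrichment
#' only); `alternative = "two.sided"` calls `|Z| > threshold`, for
#' down-regulation analyses.  Conventional thresholds: 4 for Hog1 binding
#' and differential recruitment, 6 for Pol II recruitment.
#'
#' @param points an `ma_points` data.frame with `Z` set.
#' @param z_threshold the Z cutoff (default 4).
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return data.frame of class `"enrichment_calls"`: `region_id`, `M`, `Z`,
#'   `significant`, `direction` (sign of M).
#' @export
call_enriched <- function(points, z_threshold = 4,
                          alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (any(is.na(points$Z))) stop("Z is unset; run zscore_stratified() first")
  sig <- if (alternative == "greater") points$Z > z_threshold
         else abs(points$Z) > z_threshold
  out <- data.frame(region_id = points$region_id, M = points$M, Z = points$Z,
                    significant = sig, direction = sign(points$M),
                    stringsAsFactors = FALSE)
  attr(out, "z_threshold") <- z_threshold
  class(out) <- c("enrichment_calls", "data.frame")
  out
}

#' Hog1-dependent differential recruitment between strains
#'
#' Runs the MA / stratified-Z machinery with the salt-treated wild-type
#' sample as "treated" and the salt-treated hog1 sample as "untreated", so
#' that significant regions (Z > 4 by default) are those where recruitment
#' requires the kinase.
#'
#' @param counts_wt_stress,counts_hog1_stress TRPK `region_counts` tables
#'   over identical regions.
#' @param pseudocount passed to [ma_transform()].
#' @param n_strata,min_per_stratum,method passed to [zscore_stratified()].
#' @param z_threshold the differential cutoff (default 4).
#' @return an `enrichment_calls` data.frame.
#' @export
differential_recruitment <- function(counts_wt_stress, counts_hog1_stress,
                                     pseudocount = 0.5, n_strata = 20,
                                     min_per_stratum = 25, method = "robust",
                                     z_threshold = 4) {
  pts <- ma_transform(counts_hog1_stress, counts_wt_stress, pseudocount)
  pts <- zscore_stratified(pts, n_strata, min_per_stratum, method)
  call_enriched(pts, z_threshold)
}

#' MA scatter plot
#'
#' @param x an `ma_points` data.frame.
#' @param highlight optional logical vector marking points to colour.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.ma_points <- function(x, highlight = NULL, ...) {
  graphics::plot(x$A, x$M, pch = 16, cex = 0.4,
                 col = if (is.null(highlight)) "grey30"
                       else ifelse(highlight, "red", "grey60"),
                 xlab = "A (mean log2 intensity)", ylab = "M (log2 ratio)", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
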