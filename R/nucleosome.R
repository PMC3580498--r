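#' TSS-aligned coverage matrix and mean profile
#'
#' Builds a genes-by-offsets matrix of coverage values around each TSS
#' (offsets `-flank .. +flank`, offset 0 at the TSS base), with rows of
#' minus-strand genes reversed so positive offsets always run in the
#' direction of transcription.  Genes whose flanks fall off the chromosome
#' are dropped with a warning.
#'
#' @param track a `coverage_track`, normally rpm-normalized ([to_rpm()]).
#' @param genes `gene_model` data.frame.
#' @param flank half-width of the window in bp (default 1000).
#' @param group optional label stored with the profile.
#' @return object of class `"tss_profile"`: list with `matrix` (genes x
#'   offsets), `offsets`, `mean` (column means) and `group`.
#' @export
tss_profile <- function(track, genes, flank = 1000, group = NULL) {
  offs <- seq(-flank, flank)
  keep <- logical(nrow(genes))
  for (ch in unique(genes$chrom)) {
    len <- length(track$tracks[[ch]])
    if (is.null(len) || len == 0) stop("track lacks chromosome ", ch)
    sel <- genes$chrom == ch
    keep[sel] <- genes$tss[sel] - flank >= 0 & genes$tss[sel] + flank < len
  }
  if (!all(keep))
    warning(sum(!keep), " gene(s) dropped: profile window exceeds chromosome")
  genes <- genes[keep, , drop = FALSE]
  if (nrow(genes) == 0) stop("tss_profile(): no eligible genes")
  mat <- matrix(NA_real_, nrow = nrow(genes), ncol = length(offs),
                dimnames = list(genes$gene_id, offs))
  for (ch in unique(genes$chrom)) {
    v <- track$tracks[[ch]]
    sel <- which(genes$chrom == ch)
    idx <- outer(genes$tss[sel], offs, "+") + 1  # 0-based pos -> R index
    rows <- v[idx]
    dim(rows) <- dim(idx)
    minus <- genes$strand[sel] == "-"
    rows[minus, ] <- rows[minus, rev(seq_along(offs)), drop = FALSE]
    mat[sel, ] <- rows
  }
  structure(list(matrix = mat, offsets = offs, mean = colMeans(mat),
                 group = group, norm = track$norm),
            class = "tss_profile")
}

#' @export
print.tss_profile <- function(x, ...) {
  cat("<tss_profile> ", nrow(x$matrix), " genes x ", length(x$offsets),
      " offsets (", min(x$offsets), "..", max(x$offsets), "), norm: ",
      x$norm, if (!is.null(x$group)) paste0(", group: ", x$group), "\n", sep = "")
  invisible(x)
}

#' @export
plot.tss_profile <- function(x, ...) {
  graphics::plot(x$offsets, x$mean, type = "l",
                 xlab = "distance from TSS (bp)",
                 ylab = paste0("mean coverage (", x$norm, ")"), ...)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}

## centred moving average with truncated windows at the edges
moving_average <- function(x, w) {
  half <- w %/% 2
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Simplified nucleosome peak calling on a mean profile
#'
#' A deliberately simple stand-in for dedicated nucleosome-positioning
#' software: the profile is smoothed by a centred moving average, local
#' maxima above `min_height_frac` of the global maximum are kept, maxima
#' closer than `min_distance` are merged (the higher wins), the width is
#' the span where the smoothed signal stays above half the peak height, and
#' the score combines relative height with the agreement between smoothed
#' and raw maxima.
#'
#' @param profile a `tss_profile` (its mean profile is used) or a numeric
#'   vector.
#' @param offsets positions of the profile values; taken from the
#'   `tss_profile` when available, else `seq_along(profile) - 1`.
#' @param smooth_window moving-average window, bp (default 75).
#' @param min_distance minimum centre separation before merging, bp
#'   (default 120).
#' @param min_height_frac minimum peak height as a fraction of the global
#'   smoothed maximum (default 0.25).
#' @return data.frame of class `"nucleosome_calls"`: `center`, `width`,
#'   `height`, `score`; zero rows for a flat profile.
#' @export
call_nucleosomes <- function(profile, offsets = NULL, smooth_window = 75,
                             min_distance = 120, min_height_frac = 0.25) {
  if (inherits(profile, "tss_profile")) {
    offsets <- profile$offsets
    profile <- profile$mean
  }
  if (is.null(offsets)) offsets <- seq_along(profile) - 1
  n <- length(profile)
  if (n < smooth_window) stop("profile shorter than the smoothing window")
  empty <- data.frame(center = numeric(0), width = numeric(0),
                      height = numeric(0), score = numeric(0))
  class(empty) <- c("nucleosome_calls", "data.frame")
  if (max(profile) == min(profile)) return(empty)
  s <- moving_average(profile, smooth_window)
  smax <- max(s)
  if (smax <= 0 || max(s) == min(s)) return(empty)
  ## local maxima (first index of a plateau)
  left <- c(-Inf, s[-n])
  right <- c(s[-1], -Inf)
  peaks <- which(s > left & s >= right)
  peaks <- peaks[s[peaks] >= min_height_frac * smax]
  if (length(peaks) == 0) return(empty)
  ## merge close maxima, keeping the higher of each offending pair
  repeat {
    if (length(peaks) < 2) break
    gaps <- diff(offsets[peaks])
    j <- which(gaps < min_distance)
    if (length(j) == 0) break
    j <- j[1]
    drop <- if (s[peaks[j]] >= s[peaks[j + 1]]) j + 1 else j
    peaks <- peaks[-drop]
  }
  calls <- lapply(peaks, function(p) {
    half <- s[p] / 2
    lo <- p; while (lo > 1 && s[lo - 1] >= half) lo <- lo - 1
    hi <- p; while (hi < n && s[hi + 1] >= half) hi <- hi + 1
    width <- offsets[hi] - offsets[lo] + 1
    raw_peak <- lo - 1 + which.max(profile[lo:hi])
    jitter <- abs(offsets[raw_peak] - offsets[p])
    data.frame(center = offsets[p], width = width, height = s[p],
               score = (s[p] / smax) * max(0, 1 - jitter / width))
  })
  out <- do.call(rbind, calls)
  class(out) <- c("nucleosome_calls", "data.frame")
  out
}

#' Nucleosome occupancy and eviction in the +1 window
#'
#' Per gene, occupancy is the ratio (in percent) of the treated to the
#' untreated mean TRPK over the 200 bp immediately downstream of the TSS —
#' the window that encompasses the +1 nucleosome.  The untreated sample of
#' the same strain defines maximum occupancy (100%); eviction is
#' `100 - occupancy`.  Fragment counts per window are normalized by a TMM
#' factor computed between the two samples over all windows, so a global
#' depth difference does not masquerade as remodeling.
#'
#' @param frags_treated,frags_untreated BED-style fragment data.frames from
#'   the same strain (stress and time-zero samples).
#' @param genes `gene_model` data.frame.
#' @param genome a [genome_build()].
#' @param window window width downstream of the TSS, bp (default 200).
#' @param groups optional named character vector (or factor) of group
#'   labels per gene (names = gene_id) used for the per-group summary.
#' @param trim_m,trim_a TMM trim fractions, see [tmm_factor()].
#' @return object of class `"occupancy_result"`: list with `per_gene`
#'   (`gene_id`, `group`, `occupancy_pct`, `eviction_pct`), `groups` (mean
#'   occupancy/eviction, paired-t statistic and p-value of treated vs
#'   untreated window TRPK within the group) and `tmm_factor`.
#' @export
occupancy_percent <- function(frags_treated, frags_untreated, genes, genome,
                              window = 200, groups = NULL,
                              trim_m = 0.30, trim_a = 0.05) {
  if (nrow(genes) == 0) stop("occupancy_percent(): empty gene set")
  win <- tss_window(genes, genome, width = window)
  win$region_id <- win$gene_id
  ct <- count_regions(frags_treated, win)
  cu <- count_regions(frags_untreated, win)
  fac <- tmm_factor(ct, cu, trim_m, trim_a)
  ct <- trpk(ct, fac)
  cu <- trpk(cu, 1)
  zero <- cu$trpk == 0
  if (any(zero))
    warning(sum(zero), " gene(s) excluded: no untreated signal in the TSS window")
  keep <- !zero
  occ <- 100 * ct$trpk[keep] / cu$trpk[keep]
  gid <- ct$region_id[keep]
  grp <- if (is.null(groups)) rep("all", length(gid))
         else as.character(groups[gid])
  per_gene <- data.frame(gene_id = gid, group = grp,
                         occupancy_pct = occ, eviction_pct = 100 - occ,
                         stringsAsFactors = FALSE)
  groups_df <- do.call(rbind, lapply(split(seq_along(gid), grp), function(i) {
    tt <- paired_t(ct$trpk[keep][i], cu$trpk[keep][i])
    data.frame(group = grp[i[1]], n = length(i),
               mean_occupancy_pct = mean(occ[i]),
               mean_eviction_pct = mean(100 - occ[i]),
               t = tt$t, p_value = tt$p, stringsAsFactors = FALSE)
  }))
  rownames(groups_df) <- NULL
  structure(list(per_gene = per_gene, groups = groups_df, tmm_factor = fac),
            class = "occupancy_result")
}

#' @export
print.occupancy_result <- function(x, ...) {
  cat("<occupancy_result> ", nrow(x$per_gene), " genes, TMM factor ",
      signif(x$tmm_factor, 4), "\n", sep = "")
  print(x$groups, ...)
  invisible(x)
}

## paired t on two aligned vectors; degenerate zero-spread differences give
## t = 0, p = 1 (identical vectors) rather than an error
paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  if (n < 2) return(list(t = NA_real_, df = n - 1, p = NA_real_))
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (all(d == 0)) return(list(t = 0, df = n - 1, p = 1))
    return(list(t = sign(mean(d)) * Inf, df = n - 1, p = 0))
  }
  t <- mean(d) / (sdd / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1))
}

#' Paired comparison of eviction between wild type and the hog1 strain
#'
#' Two-sided paired Student t-test on per-gene eviction percentages over a
#' common gene set; this is the significance contract used to decide whether
#' stress-induced nucleosome loss requires the kinase.
#'
#' @param occ_wt,occ_hog1 `occupancy_result` objects (or their `per_gene`
#'   data.frames) for the two strains; gene sets must match.
#' @param genes optional character vector restricting the comparison to a
#'   gene subset.
#' @return list of class `"eviction_test"`: `t`, `df`, `p_value`,
#'   `mean_diff` (wt minus hog1 eviction, percentage points), `n`.
#' @export
compare_eviction <- function(occ_wt, occ_hog1, genes = NULL) {
  pw <- if (inherits(occ_wt, "occupancy_result")) occ_wt$per_gene else occ_wt
  ph <- if (inherits(occ_hog1, "occupancy_result")) occ_hog1$per_gene else occ_hog1
  if (!is.null(genes)) {
    pw <- pw[pw$gene_id %in% genes, , drop = FALSE]
    ph <- ph[ph$gene_id %in% genes, , drop = FALSE]
  }
  if (!setequal(pw$gene_id, ph$gene_id))
    stop("compare_eviction(): gene sets differ between strains")
  ph <- ph[match(pw$gene_id, ph$gene_id), , drop = FALSE]
  if (nrow(pw) < 3) stop("compare_eviction(): need at least 3 genes")
  tt <- paired_t(pw$eviction_pct, ph$eviction_pct)
  structure(list(t = tt$t, df = tt$df, p_value = tt$p,
                 mean_diff = mean(pw$eviction_pct - ph$eviction_pct),
                 n = nrow(pw)),
            class = "eviction_test")
}

#' @export
print.eviction_test <- function(x, ...) {
  cat("Paired t-test, wt vs hog1 eviction: t = ", signif(x$t, 5),
      ", df = ", x$df, ", p = ", format.pval(x$p_value, digits = 3),
      " (mean difference ", signif(x$mean_diff, 4), " points, n = ",
      x$n, ")\n", sep = "")
  invisible(x)
}
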