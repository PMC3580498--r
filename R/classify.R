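#' Classify genes from an expression fold-change table
#'
#' Implements the stress-response gene-class rules on linear fold changes
#' (stressed over unstressed):
#'
#' * osmoresponsive: `fc_wt > 1.75` (strict);
#' * NaCl group (strongly up-regulated): `fc_wt > 3` (strict);
#' * Hog1-dependent: osmoresponsive genes whose induction depends at least
#'   25% on the kinase, read as residual induction ratio
#'   `r = fc_hog1 / fc_wt <= 0.75`;
#' * Hog1-independent: osmoresponsive genes whose induction in the hog1
#'   strain is at least 90% of wild type, `r >= 0.90`;
#' * genes in the `0.75 < r < 0.90` gap are `neither` and excluded from
#'   dependent/independent comparisons;
#' * housekeeping: `1 <= fc_wt <= 1.1` (inclusive);
#' * down-regulated: `fc_wt <= 0.5` (inclusive).
#'
#' `scale = "log2"` applies the dependency thresholds to the ratio of log2
#' fold changes instead of the linear ratio.
#'
#' @param expression data.frame with `gene_id`, `fc_wt`, `fc_hog1`
#'   (positive linear fold changes).
#' @param osmo_fc,nacl_fc,hk_range,down_fc,dependent_max,independent_min
#'   the thresholds above.
#' @param scale `"linear"` (default) or `"log2"` for the dependency ratio.
#' @return data.frame of class `"gene_classes"`: per gene, the flags, the
#'   dependency call and a single consolidated `label` drawn from
#'   `hog1_dependent`, `hog1_independent`, `housekeeping`,
#'   `down_regulated`, `unchanged`.
#' @export
classify_genes <- function(expression, osmo_fc = 1.75, nacl_fc = 3,
                           hk_range = c(1, 1.1), down_fc = 0.5,
                           dependent_max = 0.75, independent_min = 0.90,
                           scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (any(expression$fc_wt <= 0) || any(expression$fc_hog1 <= 0))
    stop("classify_genes(): fold changes must be positive")
  fc_wt <- expression$fc_wt
  fc_hog1 <- expression$fc_hog1
  osmo <- fc_wt > osmo_fc
  nacl <- fc_wt > nacl_fc
  hk <- fc_wt >= hk_range[1] & fc_wt <= hk_range[2]
  down <- fc_wt <= down_fc
  ratio <- if (scale == "linear") fc_hog1 / fc_wt
           else log2(fc_hog1) / log2(fc_wt)
  dependency <- rep("neither", nrow(expression))
  dependency[osmo & ratio <= dependent_max] <- "hog1_dependent"
  dependency[osmo & ratio >= independent_min] <- "hog1_independent"
  dependency[!osmo] <- NA_character_
  label <- rep("unchanged", nrow(expression))
  label[hk] <- "housekeeping"
  label[down] <- "down_regulated"
  label[osmo & !is.na(dependency) & dependency == "hog1_dependent"] <- "hog1_dependent"
  label[osmo & !is.na(dependency) & dependency == "hog1_independent"] <- "hog1_independent"
  out <- data.frame(gene_id = expression$gene_id, fc_wt = fc_wt,
                    fc_hog1 = fc_hog1, ratio = ratio,
                    osmoresponsive = osmo, nacl_group = nacl,
                    dependency = dependency, housekeeping = hk,
                    down_regulated = down, label = label,
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_classes", "data.frame")
  out
}

#' The n most stress-responsive genes of a class
#'
#' Selects the `n` genes of a class with the highest wild-type fold change,
#' with a deterministic tie-break by `gene_id`; mirrors the construction of
#' curated top-100 subsets of dependent/independent genes.
#'
#' @param labels a `gene_classes` data.frame.
#' @param n how many genes (default 100); more than the class size returns
#'   the whole class.
#' @param class the consolidated label to draw from.
#' @return character vector of gene ids, strongest first.
#' @export
top_n_by_fc <- function(labels, n = 100, class = "hog1_dependent") {
  x <- labels[labels$label == class, , drop = FALSE]
  x <- x[order(-x$fc_wt, x$gene_id), , drop = FALSE]
  utils::head(x$gene_id, n)
}

#' Promoter/ORF binding assignment per gene
#'
#' Combines promoter-level and ORF-level enrichment calls for the kinase
#' (and optionally gene-level Pol II recruitment calls) into per-gene flags
#' and the promoter/ORF category.  A gene counts as bound when either of
#' its two regions exceeds the threshold.
#'
#' @param promoter_calls,orf_calls `enrichment_calls` with `region_id` equal
#'   to the gene id.
#' @param polii_recruited optional character vector of gene ids with
#'   significant Pol II recruitment.
#' @return data.frame of class `"binding_assignment"`: `gene_id`,
#'   `hog1_promoter`, `hog1_orf`, `bound`, `polii_recruited`, `category`
#'   (`both`, `promoter_only`, `orf_only`, `none`).
#' @export
binding_assignment <- function(promoter_calls, orf_calls,
                               polii_recruited = NULL) {
  if (!setequal(promoter_calls$region_id, orf_calls$region_id))
    stop("binding_assignment(): promoter and ORF call sets differ")
  orf_calls <- orf_calls[match(promoter_calls$region_id, orf_calls$region_id), ]
  p <- promoter_calls$significant
  o <- orf_calls$significant
  category <- ifelse(p & o, "both",
              ifelse(p, "promoter_only", ifelse(o, "orf_only", "none")))
  out <- data.frame(gene_id = promoter_calls$region_id,
                    hog1_promoter = p, hog1_orf = o, bound = p | o,
                    polii_recruited = promoter_calls$region_id %in%
                      (polii_recruited %||% character(0)),
                    category = category, stringsAsFactors = FALSE)
  class(out) <- c("binding_assignment", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Three-set Venn overlap counts
#'
#' Exact set algebra over three gene sets (e.g. Hog1-bound, Pol II
#' recruited, strongly up-regulated); the seven exclusive cells sum to the
#' size of the union.
#'
#' @param set_a,set_b,set_c character vectors of gene ids.
#' @param labels names of the three sets.
#' @return named numeric vector of the 7 exclusive cell counts
#'   (`A_only`, `B_only`, `C_only`, `A_B`, `A_C`, `B_C`, `A_B_C` with the
#'   supplied labels substituted), with the union size as attribute `union`.
#' @export
venn_counts <- function(set_a, set_b, set_c, labels = c("A", "B", "C")) {
  a <- unique(set_a); b <- unique(set_b); c <- unique(set_c)
  u <- union(union(a, b), c)
  ina <- u %in% a; inb <- u %in% b; inc <- u %in% c
  cells <- c(sum(ina & !inb & !inc), sum(!ina & inb & !inc),
             sum(!ina & !inb & inc), sum(ina & inb & !inc),
             sum(ina & !inb & inc), sum(!ina & inb & inc),
             sum(ina & inb & inc))
  names(cells) <- c(paste0(labels, "_only"),
                    paste(labels[1], labels[2], sep = "_"),
                    paste(labels[1], labels[3], sep = "_"),
                    paste(labels[2], labels[3], sep = "_"),
                    paste(labels, collapse = "_"))
  attr(cells, "union") <- length(u)
  cells
}

#' Colocalization statistics between binding and expression
#'
#' Pairwise rank correlations (Spearman by default) between kinase
#' enrichment Z, Pol II enrichment Z and expression fold change over a gene
#' set.
#'
#' @param hog1_z,polii_z,fc aligned numeric vectors (one value per gene).
#' @param method correlation method passed to [stats::cor.test()]
#'   (default `"spearman"`).
#' @return data.frame with one row per pair: `pair`, `rho`, `p_value`, `n`.
#' @export
colocalization_stats <- function(hog1_z, polii_z, fc, method = "spearman") {
  n <- length(fc)
  stopifnot(length(hog1_z) == n, length(polii_z) == n)
  pairs <- list(hog1_vs_polii = list(hog1_z, polii_z),
                hog1_vs_fc = list(hog1_z, fc),
                polii_vs_fc = list(polii_z, fc))
  out <- do.call(rbind, lapply(names(pairs), function(nm) {
    ct <- suppressWarnings(stats::cor.test(pairs[[nm]][[1]], pairs[[nm]][[2]],
                                           method = method, exact = FALSE))
    data.frame(pair = nm, rho = unname(ct$estimate), p_value = ct$p.value,
               n = n, stringsAsFactors = FALSE)
  }))
  out
}

#' Mean fold change of a gene group
#'
#' Arithmetic mean of the wild-type fold change over the members of one
#' consolidated class label.
#'
#' @param labels a `gene_classes` data.frame.
#' @param group a label value (e.g. `"hog1_dependent"`) or a character
#'   vector of gene ids.
#' @return the mean `fc_wt`.
#' @export
group_mean_fc <- function(labels, group) {
  sel <- if (all(group %in% unique(labels$label)) && length(group) == 1)
    labels$label == group else labels$gene_id %in% group
  if (!any(sel)) stop("group_mean_fc(): empty group")
  mean(labels$fc_wt[sel])
}
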