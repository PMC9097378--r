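#' Median-of-ratios size factors
#'
#' For each sample, the median over all-nonzero features of the ratio
#' between the sample's count and the feature's geometric mean across
#' samples.
#'
#' @param counts Integer matrix, features x samples.
#' @return Named numeric vector of positive factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  all_nz <- rowSums(counts == 0) == 0
  if (!any(all_nz))
    stop("no feature with nonzero counts in every sample; ",
         "consider adding a pseudocount")
  lg <- log(counts[all_nz, , drop = FALSE])
  geo <- rowMeans(lg)
  f <- apply(lg, 2, function(col) exp(stats::median(col - geo)))
  stats::setNames(f, colnames(counts))
}

#' Normalise counts by size factors
#'
#' @param counts Features x samples matrix.
#' @param factors Output of [size_factors()].
#' @return Matrix of normalised counts.
#' @export
normalize_counts <- function(counts, factors = size_factors(counts)) {
  sweep(as.matrix(counts), 2, factors, "/")
}

#' Log2 fold change between sample groups
#'
#' `log2((mean(trt) + pc) / (mean(base) + pc))` on the normalised scale.
#'
#' @param norm Normalised count matrix.
#' @param trt_samples,base_samples Column names of the two groups.
#' @param pseudocount Stabilising pseudocount (default 1).
#' @return Named numeric vector over features.
#' @export
log2fc <- function(norm, trt_samples, base_samples, pseudocount = 1) {
  mt <- rowMeans(norm[, trt_samples, drop = FALSE])
  mb <- rowMeans(norm[, base_samples, drop = FALSE])
  log2((mt + pseudocount) / (mb + pseudocount))
}

.baseline_samples <- function(design, base, tp) {
  s <- design$sample[design$condition == base & design$timepoint == tp]
  if (length(s) == 0L) s <- design$sample[design$condition == base]
  s
}

#' Per-timepoint differential test
#'
#' For every timepoint of the treatment condition, a Welch two-sample
#' t-test on log2(normalised + 1) counts against the baseline condition
#' (matched timepoint when present, otherwise all baseline samples, as for
#' a common time-zero control), with Benjamini-Hochberg adjustment across
#' features within each timepoint, plus the log2 fold change on the
#' normalised scale.
#'
#' @param counts Raw count matrix, features x samples.
#' @param design `data.frame` with `sample`, `condition`, `timepoint`,
#'   `replicate`.
#' @param contrast `c(treatment, baseline)` condition labels.
#' @param pseudocount Pseudocount for the fold change (default 1).
#' @return `data.frame` with `feature_id`, `timepoint`, `log2fc`,
#'   `pvalue`, `padj`.
#' @export
de_test <- function(counts, design, contrast, pseudocount = 1) {
  counts <- as.matrix(counts)
  stopifnot(identical(sort(colnames(counts)), sort(design$sample)))
  norm <- normalize_counts(counts)
  lnorm <- log2(norm + 1)
  tps <- sort(unique(design$timepoint[design$condition == contrast[1]]))
  out <- lapply(tps, function(tp) {
    trt <- design$sample[design$condition == contrast[1] &
                           design$timepoint == tp]
    base <- .baseline_samples(design, contrast[2], tp)
    if (length(trt) < 2L || length(base) < 2L)
      stop("need at least two replicates per group (timepoint ", tp, ")")
    x <- lnorm[, trt, drop = FALSE]
    y <- lnorm[, base, drop = FALSE]
    p <- vapply(seq_len(nrow(lnorm)), function(i) {
      xi <- x[i, ]; yi <- y[i, ]
      if (stats::var(xi) == 0 && stats::var(yi) == 0) {
        if (mean(xi) == mean(yi)) 1 else 0
      } else stats::t.test(xi, yi)$p.value
    }, numeric(1))
    data.frame(feature_id = rownames(counts),
               timepoint = tp,
               log2fc = unname(log2fc(norm, trt, base, pseudocount)),
               pvalue = p,
               padj = stats::p.adjust(p, method = "BH"))
  })
  do.call(rbind, out)
}

#' Call differentially expressed features
#'
#' A feature is DE when, at one or more timepoints, its adjusted p-value is
#' below `de_padj` and its log2 fold change exceeds `de_lfc` (in absolute
#' value when `de_two_sided`, the default; up-regulation only otherwise).
#'
#' @param de Output of [de_test()] (or an externally produced table with
#'   the same columns, e.g. from a negative-binomial engine).
#' @param config [analysis_config()].
#' @param universe Optional feature ids to which calls are restricted (e.g.
#'   expressed genes or trackable candidates).
#' @return `data.frame` with `feature_id`, `is_DE`, `direction`
#'   (up/down/mixed/none by the sign of significant fold changes).
#' @export
call_de <- function(de, config = analysis_config(), universe = NULL) {
  if (!is.null(universe)) de <- de[de$feature_id %in% universe, ,
                                   drop = FALSE]
  eff <- if (config$de_two_sided) abs(de$log2fc) else de$log2fc
  sig <- de$padj < config$de_padj & eff > config$de_lfc
  by_f <- split(seq_len(nrow(de)), de$feature_id)
  res <- lapply(by_f, function(i) {
    s <- sig[i]
    dir <- if (!any(s)) "none"
    else {
      signs <- sign(de$log2fc[i][s])
      if (all(signs > 0)) "up" else if (all(signs < 0)) "down" else "mixed"
    }
    data.frame(is_DE = any(s), direction = dir)
  })
  out <- do.call(rbind, res)
  data.frame(feature_id = names(by_f), is_DE = out$is_DE,
             direction = out$direction, row.names = NULL)
}

.pattern_name <- function(m) {
  last <- m[length(m)]
  at3h <- if (length(m) >= 2) m[2] else m[1]
  if (max(abs(m)) <= 1) "flat"
  else if (at3h > 1 && abs(last) < 1) "up-back"
  else if (at3h < -1 && abs(last) < 1) "down-back"
  else if (mean(m) > 0) "up"
  else "down"
}

#' Cluster time-course fold-change patterns
#'
#' Agglomerative clustering (Ward linkage on Euclidean distances) of
#' per-feature log2 fold-change vectors across timepoints. When `k` is not
#' given it is chosen by maximum mean silhouette width over 2..8. Each
#' cluster is named by a rule applied to its mean profile: `up-back` (up at
#' 3 h, back near baseline by 12 h), `down-back`, monotone-trend `up` /
#' `down`, or `flat`.
#'
#' @param lfc Matrix, features x timepoints (columns in time order).
#' @param k Number of clusters; `NULL` for silhouette selection.
#' @return `data.frame` with `feature_id`, `cluster`, `pattern`.
#' @export
cluster_patterns <- function(lfc, k = NULL) {
  lfc <- as.matrix(lfc)
  n <- nrow(lfc)
  if (n < 2L) stop("need at least two features to cluster")
  d <- stats::dist(lfc)
  hc <- stats::hclust(d, method = "ward.D2")
  if (is.null(k)) {
    ks <- 2:min(8L, n - 1L)
    sil <- vapply(ks, function(kk) {
      cl <- stats::cutree(hc, k = kk)
      if (length(unique(cl)) < 2L) return(-Inf)
      mean(cluster::silhouette(cl, d)[, "sil_width"])
    }, numeric(1))
    k <- ks[which.max(sil)]
  }
  if (k > n) stop("k exceeds the number of features")
  cl <- stats::cutree(hc, k = k)
  centers <- do.call(rbind, lapply(split(seq_len(n), cl), function(i)
    colMeans(lfc[i, , drop = FALSE])))
  patterns <- apply(centers, 1, .pattern_name)
  data.frame(feature_id = rownames(lfc),
             cluster = unname(cl),
             pattern = unname(patterns[as.character(cl)]),
             row.names = NULL)
}

#' Pair co-localised DETEs and DEGs and score pattern concordance
#'
#' A pair exists for every differentially expressed TE locus lying inside a
#' differentially expressed gene's unit or its 2 kb flanks (one row per
#' DETE-DEG pair; a DETE co-localised with several DEGs contributes several
#' pairs). Concordance means both members fell into the same cluster of a
#' joint clustering of their fold-change profiles.
#'
#' @param te TE `GRanges`.
#' @param dete_ids,deg_ids Feature ids of the called DETEs and DEGs.
#' @param compartments [build_compartments()] output (gene units + flanks).
#' @param clusters Named cluster labels over pooled DETE+DEG ids (e.g. from
#'   [cluster_patterns()] on the pooled fold-change matrix).
#' @return `list` with `pairs` (`dete_id`, `deg_id`, `relationship`,
#'   `dete_cluster`, `deg_cluster`, `concordant`) and
#'   `concordant_fraction`.
#' @export
pair_and_concordance <- function(te, dete_ids, deg_ids, compartments,
                                 clusters) {
  dte <- te[te$locus_id %in% dete_ids]
  comp <- compartments[compartments$gene_id %in% deg_ids]
  hits <- GenomicRanges::findOverlaps(dte, comp, ignore.strand = TRUE)
  if (length(hits) == 0L)
    return(list(pairs = data.frame(dete_id = character(),
                                   deg_id = character(),
                                   relationship = character(),
                                   dete_cluster = integer(),
                                   deg_cluster = integer(),
                                   concordant = logical()),
                concordant_fraction = NA_real_))
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  pr <- match(comp$label[sh], .location_priority)
  key <- paste(dte$locus_id[qh], comp$gene_id[sh])
  best <- tapply(seq_along(key), key, function(i) i[which.min(pr[i])])
  idx <- unname(unlist(best))
  pairs <- data.frame(
    dete_id = dte$locus_id[qh[idx]],
    deg_id = comp$gene_id[sh[idx]],
    relationship = comp$label[sh[idx]],
    dete_cluster = unname(clusters[dte$locus_id[qh[idx]]]),
    deg_cluster = unname(clusters[comp$gene_id[sh[idx]]]))
  pairs$concordant <- !is.na(pairs$dete_cluster) &
    !is.na(pairs$deg_cluster) & pairs$dete_cluster == pairs$deg_cluster
  pairs <- pairs[order(pairs$dete_id, pairs$deg_id), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs,
       concordant_fraction = mean(pairs$concordant))
}

#' Percentage summary arithmetic
#'
#' The rounding-aware proportion used throughout the reporting tables
#' (trackable fractions, location proportions, concordance and
#' alternative-splicing summaries).
#'
#' @param n,total Counts.
#' @param digits Rounding of the printed percentage (default 2).
#' @return Percentage.
#' @export
proportion_percent <- function(n, total, digits = 2) {
  round(100 * n / total, digits)
}

#' Concordant fraction from pair counts
#'
#' @param n_concordant,n_pairs Pair counts.
#' @param digits Rounding (default 2).
#' @return Percentage.
#' @export
concordance_percent <- function(n_concordant, n_pairs, digits = 2) {
  proportion_percent(n_concordant, n_pairs, digits)
}
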