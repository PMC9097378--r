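#' Assign each TE locus a hierarchical genomic location
#'
#' Any overlap with a genic compartment makes a locus genic; its location is
#' the highest-priority overlapped label (exon > intron > N-flank >
#' C-flank). When compartments of several genes supply that label, the gene
#' with the largest overlap wins, ties broken by lower gene-compartment
#' start coordinate. Loci overlapping no compartment are intergenic.
#'
#' @param te TE `GRanges` (all annotated loci or a candidate subset).
#' @param compartments Output of [build_compartments()].
#' @return `data.frame` with `locus_id`, `region` (genic/intergenic),
#'   `location` (exon/intron/N-flank/C-flank/none), `gene_id` (NA for
#'   intergenic).
#' @export
assign_location <- function(te, compartments) {
  hits <- GenomicRanges::findOverlaps(te, compartments, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  location <- rep("none", length(te))
  gene <- rep(NA_character_, length(te))
  if (length(hits) > 0L) {
    ov <- GenomicRanges::width(IRanges::pintersect(
      GenomicRanges::granges(te)[qh],
      GenomicRanges::granges(compartments)[sh], ignore.strand = TRUE))
    pr <- match(compartments$label[sh], .location_priority)
    cstart <- GenomicRanges::start(compartments)[sh]
    for (i in unique(qh)) {
      sel <- which(qh == i)
      best_pr <- min(pr[sel])
      sel <- sel[pr[sel] == best_pr]
      # largest overlap, then lower start
      sel <- sel[order(-ov[sel], cstart[sel])][1]
      location[i] <- .location_priority[best_pr]
      gene[i] <- compartments$gene_id[sh[sel]]
    }
  }
  data.frame(locus_id = te$locus_id,
             region = ifelse(location == "none", "intergenic", "genic"),
             location = location,
             gene_id = gene)
}

#' Expressed-gene status from abundance tables
#'
#' Short-read mode: expressed iff FPKM strictly exceeds the threshold.
#' Long-read mode: requires both long-read TPM and short-read FPKM to
#' exceed their thresholds. Genes absent from the table are treated as not
#' expressed (with a message).
#'
#' @param gene_ids Genes to flag.
#' @param expression `data.frame` with `gene_id`, `fpkm` and (long mode)
#'   `tpm`.
#' @param config [analysis_config()].
#' @param mode `"short"` or `"long"`.
#' @return Named logical vector over `gene_ids`.
#' @export
gene_expression_status <- function(gene_ids, expression,
                                   config = analysis_config(),
                                   mode = c("short", "long")) {
  mode <- match.arg(mode)
  i <- match(gene_ids, expression$gene_id)
  if (anyNA(i))
    message(sum(is.na(i)), " gene(s) missing from expression table; ",
            "treated as not expressed")
  fpkm <- expression$fpkm[i]
  expressed <- !is.na(fpkm) & fpkm > config$gene_expressed_fpkm
  if (mode == "long") {
    tpm <- expression$tpm[i]
    expressed <- expressed & !is.na(tpm) & tpm > config$gene_expressed_tpm
  }
  stats::setNames(expressed, gene_ids)
}

#' Hierarchical candidate classification table
#'
#' Cross-tabulates assignments in the order region -> co-localised gene
#' activity -> location -> integrity -> trackability and returns the leaf
#' counts as a tidy table. Counts at every level sum to their parent (leaf
#' totals equal the number of loci).
#'
#' @param assignments Output of [assign_location()] joined with candidate
#'   calls: needs columns `region`, `location`, plus logical
#'   `gene_expressed`, `is_full_length`, `trackable`.
#' @return `data.frame` with the five layer columns and `n`.
#' @export
hierarchical_summary <- function(assignments) {
  a <- data.frame(
    region = assignments$region,
    gene_activity = ifelse(assignments$region == "intergenic", "none",
                           ifelse(assignments$gene_expressed,
                                  "expressed", "non-expressed")),
    location = assignments$location,
    integrity = ifelse(assignments$is_full_length, "full-length",
                       "fragmented"),
    trackability = ifelse(assignments$trackable, "trackable",
                          "un-trackable"))
  agg <- stats::aggregate(list(n = rep(1L, nrow(a))), a, FUN = sum)
  agg[order(agg$region, agg$gene_activity, agg$location, agg$integrity,
            agg$trackability), , drop = FALSE]
}

#' Goodness-of-fit chi-square test for location bias
#'
#' Compares observed candidate counts across location categories against
#' expected proportions taken from the full annotated TE set:
#' \eqn{X^2 = \sum_i (O_i - N p_i)^2 / (N p_i)} with `length(observed) - 1`
#' degrees of freedom.
#'
#' @param observed Named vector of candidate counts per category.
#' @param expected_proportions Proportions from all annotated loci (same
#'   categories, summing to 1).
#' @param alpha Significance level (default 0.01).
#' @return `list` with `categories`, `observed`, `expected_proportions`,
#'   `statistic`, `df`, `p_value`, `significant`.
#' @export
chisq_location_bias <- function(observed, expected_proportions,
                                alpha = 0.01) {
  if (length(observed) < 2L) stop("need at least two categories")
  if (length(observed) != length(expected_proportions))
    stop("observed and expected_proportions differ in length")
  if (any(expected_proportions <= 0))
    stop("zero expected count; merge the affected categories before testing")
  p <- expected_proportions / sum(expected_proportions)
  ct <- suppressWarnings(stats::chisq.test(observed, p = p))
  list(categories = names(observed),
       observed = observed,
       expected_proportions = p,
       statistic = unname(ct$statistic),
       df = unname(ct$parameter),
       p_value = unname(ct$p.value),
       significant = unname(ct$p.value) < alpha)
}

#' Per-family candidate composition
#'
#' Counts expression candidates per TE family cross-tabulated by
#' trackability and integrity. Families without candidates are omitted.
#'
#' @param calls Output of [assemble_candidates()].
#' @return `data.frame` with `family`, the four class counts and `total`.
#' @export
family_summary <- function(calls) {
  cand <- calls[calls$is_candidate, , drop = FALSE]
  if (nrow(cand) == 0L)
    return(data.frame(family = character(), trackable_fragmented = integer(),
                      trackable_full_length = integer(),
                      untrackable_fragmented = integer(),
                      untrackable_full_length = integer(),
                      total = integer()))
  cls <- interaction(cand$trackable, cand$is_full_length)
  tab <- table(cand$family, cls)
  out <- data.frame(
    family = rownames(tab),
    trackable_fragmented = as.integer(tab[, "TRUE.FALSE"]),
    trackable_full_length = as.integer(tab[, "TRUE.TRUE"]),
    untrackable_fragmented = as.integer(tab[, "FALSE.FALSE"]),
    untrackable_full_length = as.integer(tab[, "FALSE.TRUE"]))
  out$total <- as.integer(rowSums(out[, -1]))
  rownames(out) <- NULL
  out[order(-out$total, out$family), , drop = FALSE]
}

#' Read sharing across the four candidate classes
#'
#' Maps every read to the set of candidate classes (full-length/fragmented
#' x trackable/un-trackable) of the loci it aligns to and tabulates all
#' non-empty class combinations. Combination counts sum to the number of
#' distinct reads hitting at least one candidate.
#'
#' @param alignments `GRanges` of alignment records.
#' @param te TE `GRanges` (all loci; candidate status from `calls`).
#' @param calls Output of [assemble_candidates()].
#' @return `data.frame` with `classes` (sorted, `+`-joined) and `n_reads`.
#' @export
read_class_sharing <- function(alignments, te, calls) {
  stopifnot(identical(calls$locus_id, te$locus_id))
  cand <- which(calls$is_candidate)
  cls <- paste0(ifelse(calls$is_full_length, "full-length", "fragmented"),
                "_",
                ifelse(calls$trackable, "trackable", "un-trackable"))
  hits <- GenomicRanges::findOverlaps(alignments, te[cand],
                                      ignore.strand = TRUE)
  if (length(hits) == 0L)
    return(data.frame(classes = character(), n_reads = integer()))
  rid <- alignments$read_id[S4Vectors::queryHits(hits)]
  rcls <- cls[cand][S4Vectors::subjectHits(hits)]
  combo <- tapply(rcls, rid, function(x)
    paste(sort(unique(x)), collapse = "+"))
  tab <- table(combo)
  data.frame(classes = names(tab), n_reads = as.integer(tab),
             row.names = NULL)
}
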