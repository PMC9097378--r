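#' Count unique-mapping reads per TE locus
#'
#' Filter-1-style counting (intersection-nonempty semantics): a
#' unique-mapping record contributes to a locus iff it overlaps that locus
#' by at least one base and overlaps no other TE locus. Records overlapping
#' two or more distinct loci are ambiguous and dropped; each record is
#' counted at most once.
#'
#' @param alignments `GRanges` from [read_short_read_alignments()].
#' @param te TE `GRanges`.
#' @return Named integer vector over `te$locus_id`.
#' @export
count_unique_overlaps <- function(alignments, te) {
  uq <- alignments[alignments$is_unique]
  hits <- GenomicRanges::findOverlaps(uq, te, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits)
  n_loci <- tabulate(q, nbins = length(uq))
  unambig <- hits[n_loci[q] == 1L]
  counts <- tabulate(S4Vectors::subjectHits(unambig), nbins = length(te))
  stats::setNames(counts, te$locus_id)
}

#' Unique-count filter
#'
#' @param counts Named vector from [count_unique_overlaps()].
#' @param min_reads Strict threshold: pass needs `count > min_reads`.
#' @return Named logical vector.
#' @export
filter_unique <- function(counts, min_reads = 10) {
  counts > min_reads
}

#' Multi-mapping-inclusive coverage statistics per locus
#'
#' Every reported alignment record (unique or one of a multi-read's
#' placements) counts once at each locus it overlaps. `covered_bases` is
#' the number of locus bases covered at least once; `mean_depth` is the
#' total per-base depth inside the locus divided by `covered_bases` (0 when
#' nothing is covered).
#'
#' @param alignments `GRanges` of all alignment records.
#' @param te TE `GRanges`.
#' @return `data.frame` with `locus_id`, `total_count`, `covered_bases`,
#'   `mean_depth`.
#' @export
compute_coverage_stats <- function(alignments, te) {
  hits <- GenomicRanges::findOverlaps(alignments, te, ignore.strand = TRUE)
  total <- tabulate(S4Vectors::subjectHits(hits), nbins = length(te))
  cov <- GenomicRanges::coverage(alignments)
  covered <- integer(length(te))
  depth_sum <- numeric(length(te))
  chr <- as.character(GenomicRanges::seqnames(te))
  present <- chr %in% names(cov)
  for (i in which(present)) {
    v <- cov[[chr[i]]]
    if (GenomicRanges::end(te)[i] > length(v)) {
      v <- c(v, S4Vectors::Rle(0L, GenomicRanges::end(te)[i] - length(v)))
    }
    w <- S4Vectors::window(v, GenomicRanges::start(te)[i],
                           GenomicRanges::end(te)[i])
    covered[i] <- sum(w > 0L)
    depth_sum[i] <- sum(as.numeric(S4Vectors::runValue(w)) *
                          S4Vectors::runLength(w))
  }
  data.frame(locus_id = te$locus_id,
             total_count = total,
             covered_bases = covered,
             mean_depth = ifelse(covered > 0, depth_sum / covered, 0))
}

#' Coverage filter
#'
#' Pass iff `total_count > min_reads` and `mean_depth > min_depth`
#' (both strict).
#'
#' @param stats Output of [compute_coverage_stats()].
#' @param min_reads,min_depth Strict thresholds.
#' @return Named logical vector over `locus_id`.
#' @export
filter_coverage <- function(stats, min_reads = 10, min_depth = 5) {
  stats::setNames(stats$total_count > min_reads &
                    stats$mean_depth > min_depth, stats$locus_id)
}

#' Find dangler reads flanking TE loci
#'
#' A dangler is a uniquely mapped genome alignment whose paired mate aligned
#' to the canonical TE library. A dangler is assigned to the left/right side
#' of a locus when its alignment lies entirely outside the locus, within
#' `window` bp of the corresponding boundary, and is oriented toward the
#' locus (forward strand on the left side, reverse on the right). With
#' `exclude_tails`, alignments crossing a locus boundary are discarded from
#' dangler assignment at that locus. `internal_reads` counts all records
#' (unique or multi) mapped wholly within the locus.
#'
#' @param genome_alignments `GRanges` of genome alignments.
#' @param te_library_hits Character vector of read ids whose mate aligned to
#'   the canonical TE library.
#' @param te TE `GRanges`.
#' @param window Assignment window in bp (default 1000).
#' @param exclude_tails Discard boundary-crossing alignments (default TRUE).
#' @return `data.frame` with `locus_id`, `dangler_left`, `dangler_right`,
#'   `internal_reads`.
#' @export
find_danglers <- function(genome_alignments, te_library_hits, te,
                          window = 1000, exclude_tails = TRUE) {
  d <- genome_alignments[genome_alignments$is_unique &
                           genome_alignments$read_id %in% te_library_hits]
  flanked <- GenomicRanges::resize(GenomicRanges::granges(te),
                                   GenomicRanges::width(te) + 2L * window,
                                   fix = "center")
  # flanked windows may poke past chromosome ends; that is intended
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(d, flanked, ignore.strand = TRUE))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ds <- GenomicRanges::start(d)[qi]
  de <- GenomicRanges::end(d)[qi]
  dstr <- as.character(GenomicRanges::strand(d))[qi]
  ls <- GenomicRanges::start(te)[si]
  le <- GenomicRanges::end(te)[si]
  crosses <- (ds < ls & de >= ls) | (ds <= le & de > le)
  keep <- if (exclude_tails) !crosses else rep(TRUE, length(qi))
  left <- keep & de < ls & ds >= ls - window & dstr == "+"
  right <- keep & ds > le & de <= le + window & dstr == "-"
  dl <- tabulate(si[left], nbins = length(te))
  dr <- tabulate(si[right], nbins = length(te))

  inner <- GenomicRanges::findOverlaps(genome_alignments, te,
                                       type = "within", ignore.strand = TRUE)
  internal <- tabulate(S4Vectors::subjectHits(inner), nbins = length(te))
  data.frame(locus_id = te$locus_id,
             dangler_left = dl, dangler_right = dr,
             internal_reads = internal)
}

#' Dangler filter
#'
#' The side condition depends on `side_mode`: `"any"` requires more than
#' `min_reads` danglers on at least one side, `"both"` on both sides; in
#' either mode more than `min_reads` internally mapped reads are also
#' required (all strict).
#'
#' @param counts Output of [find_danglers()].
#' @param min_reads Strict threshold.
#' @param side_mode `"any"` or `"both"`.
#' @return Named logical vector over `locus_id`.
#' @export
filter_danglers <- function(counts, min_reads = 10,
                            side_mode = c("any", "both")) {
  side_mode <- match.arg(side_mode)
  side_ok <- if (side_mode == "any")
    pmax(counts$dangler_left, counts$dangler_right) > min_reads
  else
    pmin(counts$dangler_left, counts$dangler_right) > min_reads
  stats::setNames(side_ok & counts$internal_reads > min_reads,
                  counts$locus_id)
}

#' Assemble the TE expression-candidate pool
#'
#' Unites the three filters: a locus is an expression candidate when it
#' passes at least one. Trackability (presence of unique-mapping reads),
#' length integrity (genomic span / canonical element length) and the
#' full-length flag (integrity above `integrity_threshold`) are populated
#' for every annotated locus.
#'
#' @param te TE `GRanges`.
#' @param unique_counts From [count_unique_overlaps()].
#' @param coverage_stats From [compute_coverage_stats()].
#' @param dangler_counts From [find_danglers()].
#' @param config [analysis_config()].
#' @return `data.frame` with one row per annotated locus (the
#'   `CandidateCall` record): filter verdicts, evidence counts,
#'   `is_candidate`, `trackable`, `integrity`, `is_full_length`.
#' @export
assemble_candidates <- function(te, unique_counts, coverage_stats,
                                dangler_counts, config = analysis_config()) {
  stopifnot(identical(names(unique_counts), te$locus_id),
            identical(coverage_stats$locus_id, te$locus_id),
            identical(dangler_counts$locus_id, te$locus_id))
  p1 <- filter_unique(unique_counts, config$min_reads)
  p2 <- filter_coverage(coverage_stats, config$min_reads, config$min_depth)
  p3 <- filter_danglers(dangler_counts, config$min_reads,
                        config$dangler_side_mode)
  integrity <- GenomicRanges::width(te) / te$canonical_length
  data.frame(
    locus_id = te$locus_id,
    family = te$family,
    superfamily = te$superfamily,
    unique_count = unname(unique_counts),
    total_count = coverage_stats$total_count,
    covered_bases = coverage_stats$covered_bases,
    mean_depth = coverage_stats$mean_depth,
    dangler_left = dangler_counts$dangler_left,
    dangler_right = dangler_counts$dangler_right,
    internal_reads = dangler_counts$internal_reads,
    passed_filter1 = unname(p1),
    passed_filter2 = unname(p2),
    passed_filter3 = unname(p3),
    is_candidate = unname(p1 | p2 | p3),
    trackable = unname(unique_counts) > 0L,
    integrity = integrity,
    is_full_length = integrity > config$integrity_threshold
  )
}

#' Partition annotated loci by candidate evidence
#'
#' Mirrors the exclusion accounting of the candidate pipeline: candidates,
#' loci with some read evidence that fell below threshold, and loci with no
#' read evidence at all. The three counts always sum to the number of
#' annotated loci.
#'
#' @param calls Output of [assemble_candidates()].
#' @return `data.frame` with `class` and `n`.
#' @export
exclusion_summary <- function(calls) {
  no_evidence <- calls$unique_count == 0L & calls$total_count == 0L &
    calls$dangler_left == 0L & calls$dangler_right == 0L
  cls <- ifelse(calls$is_candidate, "candidate",
                ifelse(no_evidence, "no_evidence", "below_threshold"))
  data.frame(class = c("candidate", "below_threshold", "no_evidence"),
             n = c(sum(cls == "candidate"), sum(cls == "below_threshold"),
                   sum(cls == "no_evidence")))
}
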