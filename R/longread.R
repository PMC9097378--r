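#' Read long-read (cDNA) alignments from SAM/BAM
#'
#' Loads primary and secondary placements of spliced long-read alignments,
#' keeping per-record geometry: soft-clip lengths at the read's biological
#' 5'/3' ends (strand-aware), aligned (non-clipped) read bases, full read
#' length, and the spliced alignment blocks.
#'
#' @param path SAM or BAM file of spliced genome alignments.
#' @return A `"long_reads"` object: list with `records` (`GRanges`, mcols
#'   `read_id`, `read_length`, `clip5`, `clip3`, `mapped_bases`,
#'   `is_multi`) and `blocks` (`GRangesList` parallel to `records`).
#' @export
read_long_read_alignments <- function(path) {
  bam <- .as_bam(path)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "mapq"), tag = "NH",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  aln <- GenomicAlignments::readGAlignments(bam, param = param)
  meta <- S4Vectors::mcols(aln)
  cig <- GenomicAlignments::cigar(aln)
  clips <- .soft_clips(cig)
  minus <- as.character(GenomicAlignments::strand(aln)) == "-"
  gr <- GenomicRanges::granges(aln)
  gr$read_id <- meta$qname
  gr$read_length <- GenomicAlignments::qwidth(aln)
  gr$clip5 <- ifelse(minus, clips$right, clips$left)
  gr$clip3 <- ifelse(minus, clips$left, clips$right)
  gr$mapped_bases <- GenomicAlignments::cigarWidthAlongQuerySpace(
    cig, after.soft.clipping = TRUE)
  nh <- meta$NH
  secondary <- bitwAnd(meta$flag, 256L) > 0L
  gr$is_multi <- if (!is.null(nh)) !is.na(nh) & nh > 1L else secondary
  multi_ids <- unique(gr$read_id[secondary])
  gr$is_multi <- gr$is_multi | gr$read_id %in% multi_ids
  structure(list(records = gr,
                 blocks = GenomicAlignments::grglist(aln)),
            class = "long_reads")
}

.soft_clips <- function(cigar) {
  grab <- function(pattern) {
    m <- regmatches(cigar, regexpr(pattern, cigar))
    out <- integer(length(cigar))
    hit <- grepl(pattern, cigar)
    out[hit] <- as.integer(sub("S", "", m))
    out
  }
  list(left = grab("^\\d+S"), right = grab("\\d+S$"))
}

#' @export
print.long_reads <- function(x, ...) {
  cat(sprintf("long_reads: %d alignment record(s), %d distinct read(s)\n",
              length(x$records), length(unique(x$records$read_id))))
  invisible(x)
}

#' Subset a long_reads object
#'
#' @param lr `"long_reads"` object.
#' @param i Indices.
#' @return `"long_reads"` object.
#' @export
subset_long_reads <- function(lr, i) {
  structure(list(records = lr$records[i], blocks = lr$blocks[i]),
            class = "long_reads")
}

#' Sense-overlapping reads of a locus
#'
#' Records whose alignment strand equals the locus strand and whose spliced
#' blocks overlap the locus by at least one base.
#'
#' @param lr `"long_reads"` object.
#' @param locus TE `GRanges` of length 1.
#' @return `"long_reads"` subset.
#' @export
sense_overlap_reads <- function(lr, locus) {
  same <- as.character(GenomicRanges::strand(lr$records)) ==
    as.character(GenomicRanges::strand(locus))
  ov <- IRanges::overlapsAny(lr$blocks, locus, ignore.strand = TRUE)
  subset_long_reads(lr, which(same & ov))
}

# biological 5' alignment position of each record (strand-aware)
.read_start5 <- function(records) {
  ifelse(as.character(GenomicRanges::strand(records)) == "-",
         GenomicRanges::end(records), GenomicRanges::start(records))
}

#' Transcription-start category of a locus
#'
#' A sense read "initiates within" the locus when its biological 5'
#' alignment position (strand-aware) falls at or inside the annotated
#' boundaries, and "upstream" when it lies 5' of the locus's 5' boundary in
#' locus orientation (de novo vs read-through transcription). Reads
#' starting downstream of the 3' boundary count as within-class internal
#' starts.
#'
#' @param sense `"long_reads"` subset from [sense_overlap_reads()].
#' @param locus TE `GRanges` of length 1.
#' @return `"All_within"`, `"All_upstream"` or `"Mix"`.
#' @export
start_category <- function(sense, locus) {
  if (length(sense$records) == 0L)
    stop("start_category needs at least one sense read")
  p5 <- .read_start5(sense$records)
  upstream <- if (as.character(GenomicRanges::strand(locus)) == "-")
    p5 > GenomicRanges::end(locus)
  else
    p5 < GenomicRanges::start(locus)
  if (all(upstream)) "All_upstream"
  else if (any(upstream)) "Mix"
  else "All_within"
}

#' Origin of read-through transcription relative to genes
#'
#' For loci with upstream-initiating (non-de-novo) reads: each such read's
#' 5' start is classified against the compartment map (exonic, intronic,
#' or not from an annotated gene unit); the locus label is the majority
#' over those reads, ties resolved exonic > intronic > no_gene.
#'
#' @param sense `"long_reads"` subset from [sense_overlap_reads()].
#' @param locus TE `GRanges` of length 1.
#' @param compartments [build_compartments()] output.
#' @return `"exonic"`, `"intronic"` or `"no_gene"` (NA when no upstream
#'   read exists).
#' @export
origin_category <- function(sense, locus, compartments) {
  p5 <- .read_start5(sense$records)
  upstream <- if (as.character(GenomicRanges::strand(locus)) == "-")
    p5 > GenomicRanges::end(locus)
  else
    p5 < GenomicRanges::start(locus)
  if (!any(upstream)) return(NA_character_)
  pos <- GenomicRanges::GRanges(GenomicRanges::seqnames(locus),
                                IRanges::IRanges(p5[upstream], width = 1))
  lab <- classify_position(compartments, pos)
  origin <- ifelse(lab == "exon", "exonic",
                   ifelse(lab == "intron", "intronic", "no_gene"))
  lev <- c("exonic", "intronic", "no_gene")
  counts <- table(factor(origin, levels = lev))
  lev[which.max(counts)]  # which.max keeps priority order on ties
}

#' Breadth of coverage over a feature interval
#'
#' Fraction of the feature's bases covered by the union of the reads'
#' aligned blocks.
#'
#' @param reads `"long_reads"` object (typically sense-overlapping reads).
#' @param feature `GRanges` of length 1.
#' @return Fraction in [0, 1].
#' @export
breadth_of_coverage <- function(reads, feature) {
  if (length(reads$records) == 0L) return(0)
  blk <- unlist(reads$blocks, use.names = FALSE)
  blk <- blk[as.character(GenomicRanges::seqnames(blk)) ==
               as.character(GenomicRanges::seqnames(feature))]
  if (length(blk) == 0L) return(0)
  inter <- GenomicRanges::intersect(
    GenomicRanges::reduce(GenomicRanges::granges(blk),
                          ignore.strand = TRUE),
    GenomicRanges::granges(feature), ignore.strand = TRUE)
  sum(GenomicRanges::width(inter)) / GenomicRanges::width(feature)
}

#' Classify alignment ends of a read at a locus
#'
#' Each read end (biological 5'/3', strand-aware) gets exactly one label:
#' `clipped` when its soft clip is at least `clip_min` bp; otherwise
#' `external` when the alignment extends past the corresponding locus
#' boundary; otherwise `internal`.
#'
#' @param reads `"long_reads"` object of sense-overlapping records.
#' @param locus TE `GRanges` of length 1.
#' @param clip_min Soft-clip threshold in bp (default 20).
#' @return `data.frame` with `read_id`, `end5`, `end3`.
#' @export
classify_ends <- function(reads, locus, clip_min = 20) {
  r <- reads$records
  minus <- as.character(GenomicRanges::strand(r)) == "-"
  ls <- GenomicRanges::start(locus)
  le <- GenomicRanges::end(locus)
  # genomic position of each biological end
  p5 <- ifelse(minus, GenomicRanges::end(r), GenomicRanges::start(r))
  p3 <- ifelse(minus, GenomicRanges::start(r), GenomicRanges::end(r))
  ext5 <- ifelse(minus, p5 > le, p5 < ls)
  ext3 <- ifelse(minus, p3 < ls, p3 > le)
  lab <- function(clip, ext) ifelse(clip >= clip_min, "clipped",
                                    ifelse(ext, "external", "internal"))
  data.frame(read_id = r$read_id,
             end5 = lab(r$clip5, ext5),
             end3 = lab(r$clip3, ext3))
}

#' Full-length transcript evidence per read
#'
#' A read evidences a full-length (potentially autonomous) transcript when
#' it is at least as long as the superfamily-specific feature (INT domain
#' for LTR-TEs, transposase ORF for TIR-TEs, whole element for LINEs) and
#' its aligned bases make up at least `mapped_fraction_threshold` of its
#' read length.
#'
#' @param reads `"long_reads"` object.
#' @param feature_length Length in bp of the required feature.
#' @param config [analysis_config()].
#' @return Logical vector parallel to the records.
#' @export
full_length_evidence <- function(reads, feature_length,
                                 config = analysis_config()) {
  r <- reads$records
  r$read_length >= feature_length &
    r$mapped_bases / r$read_length >= config$mapped_fraction_threshold
}

#' Per-locus long-read transcription profile
#'
#' Combines sense-read collection, transcription-start category, origin
#' relative to genes, breadth of coverage over the superfamily-specific
#' feature, and full-length read evidence.
#'
#' @param lr `"long_reads"` object.
#' @param te TE `GRanges`.
#' @param locus_id Locus to profile.
#' @param compartments [build_compartments()] output.
#' @param config [analysis_config()].
#' @return `list` (`LocusTranscriptionProfile`): `locus_id`,
#'   `n_sense_reads`, `start_category`, `origin_category`, `breadth`,
#'   `full_length_read_ids`.
#' @export
locus_transcription_profile <- function(lr, te, locus_id, compartments,
                                        config = analysis_config()) {
  locus <- te[match(locus_id, te$locus_id)]
  sense <- sense_overlap_reads(lr, locus)
  n <- length(sense$records)
  feat <- superfamily_feature(te, locus_id)
  breadth <- if (is.null(feat)) NA_real_
             else breadth_of_coverage(sense, feat)
  start_cat <- if (n > 0L) start_category(sense, locus) else NA_character_
  origin <- if (n > 0L && !identical(start_cat, "All_within"))
    origin_category(sense, locus, compartments) else NA_character_
  fl_ids <- character()
  if (n > 0L && !is.null(feat)) {
    fl <- full_length_evidence(sense, GenomicRanges::width(feat), config)
    fl_ids <- unique(sense$records$read_id[fl])
  }
  list(locus_id = locus_id,
       n_sense_reads = n,
       start_category = start_cat,
       origin_category = origin,
       breadth = breadth,
       full_length_read_ids = fl_ids)
}

#' Select structurally intact loci with autonomous-transcription evidence
#'
#' Among structurally intact loci, keeps those whose superfamily-specific
#' feature has breadth of coverage above `breadth_threshold`; each is
#' reported with its full-length read ids (possibly none — transcribed but
#' without convincing full-length evidence). Loci lacking the required
#' sub-feature are skipped with a message.
#'
#' @param lr `"long_reads"` object.
#' @param te TE `GRanges`.
#' @param compartments [build_compartments()] output.
#' @param config [analysis_config()].
#' @return `data.frame` with `locus_id`, `family`, `superfamily`,
#'   `breadth`, `n_full_length_reads`, `full_length_read_ids`
#'   (comma-joined).
#' @export
select_autonomous_candidates <- function(lr, te, compartments,
                                         config = analysis_config()) {
  intact <- te$locus_id[te$structurally_intact]
  rows <- lapply(intact, function(id) {
    if (is.null(superfamily_feature(te, id))) {
      message("skipping ", id, ": required structural sub-feature missing")
      return(NULL)
    }
    pr <- locus_transcription_profile(lr, te, id, compartments, config)
    if (is.na(pr$breadth) || pr$breadth <= config$breadth_threshold)
      return(NULL)
    i <- match(id, te$locus_id)
    data.frame(locus_id = id, family = te$family[i],
               superfamily = te$superfamily[i],
               breadth = pr$breadth,
               n_full_length_reads = length(pr$full_length_read_ids),
               full_length_read_ids =
                 paste(pr$full_length_read_ids, collapse = ","))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(locus_id = character(), family = character(),
                      superfamily = character(), breadth = numeric(),
                      n_full_length_reads = integer(),
                      full_length_read_ids = character())
  out
}
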