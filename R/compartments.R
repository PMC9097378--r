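#' Build the genomic compartment map
#'
#' Partitions the genome around gene units into labelled compartments:
#' `exon` and `intron` inside each gene's transcription bounds, `N-flank`
#' (`flank_width` bp upstream of the transcription start, strand-aware) and
#' `C-flank` (downstream of the stop). Flanks are truncated at chromosome
#' ends when sequence lengths are known. Positions covered by no label are
#' intergenic. Overlapping genes are allowed: a position may carry several
#' labels, and downstream assignment resolves them by priority
#' (exon > intron > N-flank > C-flank).
#'
#' @param genes A `"gene_models"` object.
#' @param flank_width Flank width in bp (default 2000).
#' @param seqlengths Optional named vector of chromosome lengths used to
#'   truncate flanks.
#' @return `GRanges` with mcols `label` (exon/intron/N-flank/C-flank) and
#'   `gene_id`.
#' @export
build_compartments <- function(genes, flank_width = 2000, seqlengths = NULL) {
  bounds <- genes$bounds
  ids <- names(bounds)
  ex <- unlist(genes$exons, use.names = FALSE)
  ex_id <- rep(ids, S4Vectors::elementNROWS(genes$exons))
  intr <- gene_introns(genes)
  ir <- unlist(intr, use.names = FALSE)
  ir_id <- rep(ids, S4Vectors::elementNROWS(intr))

  plus <- as.character(GenomicRanges::strand(bounds)) != "-"
  s <- GenomicRanges::start(bounds)
  e <- GenomicRanges::end(bounds)
  chr <- as.character(GenomicRanges::seqnames(bounds))
  # upstream flank in gene orientation
  nfl_start <- ifelse(plus, s - flank_width, e + 1L)
  nfl_end <- ifelse(plus, s - 1L, e + flank_width)
  cfl_start <- ifelse(plus, e + 1L, s - flank_width)
  cfl_end <- ifelse(plus, e + flank_width, s - 1L)
  clip <- function(st, en) {
    st <- pmax(st, 1L)
    if (!is.null(seqlengths)) en <- pmin(en, unname(seqlengths[chr]))
    keep <- st <= en
    GenomicRanges::GRanges(chr[keep], IRanges::IRanges(st[keep], en[keep]),
                           strand = GenomicRanges::strand(bounds)[keep],
                           gene_id = ids[keep])
  }
  nfl <- clip(nfl_start, nfl_end)
  cfl <- clip(cfl_start, cfl_end)

  mk <- function(gr, id, lab) {
    g <- GenomicRanges::granges(gr)
    g$label <- rep(lab, length(g))
    g$gene_id <- rep(id, length.out = length(g))
    g
  }
  out <- c(mk(ex, ex_id, "exon"),
           mk(ir, ir_id, "intron"),
           mk(nfl, nfl$gene_id, "N-flank"),
           mk(cfl, cfl$gene_id, "C-flank"))
  GenomicRanges::sort(out, ignore.strand = TRUE)
}

.location_priority <- c("exon", "intron", "N-flank", "C-flank")

#' Classify single positions against the compartment map
#'
#' Each query position gets the highest-priority label of the compartments
#' covering it (`exon` > `intron` > `N-flank` > `C-flank`), or
#' `"intergenic"` when none do.
#'
#' @param compartments Output of [build_compartments()].
#' @param positions `GRanges` (widths of 1 are typical).
#' @return Character vector parallel to `positions`.
#' @export
classify_position <- function(compartments, positions) {
  hits <- GenomicRanges::findOverlaps(positions, compartments,
                                      ignore.strand = TRUE)
  lab <- rep("intergenic", length(positions))
  if (length(hits) > 0L) {
    h_lab <- compartments$label[S4Vectors::subjectHits(hits)]
    pr <- match(h_lab, .location_priority)
    best <- tapply(pr, S4Vectors::queryHits(hits), min)
    lab[as.integer(names(best))] <- .location_priority[best]
  }
  lab
}
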