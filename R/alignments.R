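#' Read short-read alignments from SAM/BAM
#'
#' Loads mapped records with their multiplicity (`NH`-style tag). A record
#' is unique-mapping when its reported alignment count is 1; if the tag is
#' absent, a MAPQ >= 10 fallback is used (mirroring the default filter of
#' unique-count tools). Unmapped records are skipped and counted.
#'
#' @param path SAM or BAM file. SAM input is converted on the fly.
#' @return `GRanges` with mcols `read_id`, `mate` (1 or 2), `n_hits`,
#'   `is_unique`; the number of skipped unmapped records is stored in
#'   `metadata()$n_unmapped`.
#' @export
read_short_read_alignments <- function(path) {
  bam <- .as_bam(path)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "mapq"), tag = "NH",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  aln <- GenomicAlignments::readGAlignments(bam, param = param)
  gr <- GenomicRanges::granges(aln)
  meta <- S4Vectors::mcols(aln)
  gr$read_id <- meta$qname
  gr$mate <- ifelse(bitwAnd(meta$flag, 128L) > 0L, 2L, 1L)
  nh <- meta$NH
  if (is.null(nh)) nh <- rep(NA_integer_, length(gr))
  gr$n_hits <- nh
  gr$is_unique <- ifelse(!is.na(nh), nh == 1L,
                         !is.na(meta$mapq) & meta$mapq >= 10L)
  n_total <- Rsamtools::countBam(bam)$records
  S4Vectors::metadata(gr)$n_unmapped <- as.integer(n_total - length(gr))
  gr
}

# SAM input -> sorted, indexed BAM in tempdir; BAM passed through.
.as_bam <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) return(path)
  dest <- tempfile(fileext = "")
  Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                   indexDestination = TRUE)
}
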