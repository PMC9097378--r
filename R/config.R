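#' Analysis configuration
#'
#' Collects every numeric threshold used across the pipeline in one place.
#' Defaults reproduce the filtering scheme of the locus-level TE expression
#' analysis: all read-count and depth thresholds are strict (a locus needs
#' *more than* `min_reads` reads, i.e. at least 11 with the default of 10).
#'
#' @param min_reads Read-count threshold shared by all three candidate
#'   filters; strict (`count > min_reads`). Default 10.
#' @param min_depth Mean per-base depth threshold of the coverage filter;
#'   strict. Default 5.
#' @param integrity_threshold Fraction of the canonical element length a
#'   locus must exceed to be called full-length. Default 0.9.
#' @param flank_width Width in bp of the N-flank (upstream of the
#'   transcription start) and C-flank (downstream of the stop). Default 2000.
#' @param gene_expressed_fpkm FPKM above which a gene counts as expressed
#'   (strict). Default 1.
#' @param gene_expressed_tpm Long-read TPM above which a gene counts as
#'   expressed (strict); the long-read mode requires both FPKM and TPM
#'   thresholds to be exceeded. Default 1.
#' @param de_padj Adjusted p-value threshold for differential expression
#'   calls. Default 0.05.
#' @param de_lfc Absolute log2 fold-change threshold for differential
#'   expression calls (strict). Default 1.
#' @param de_two_sided Call both up- and down-regulation (`|lfc| > de_lfc`)
#'   rather than up only. Default TRUE.
#' @param breadth_threshold Breadth-of-coverage fraction a structurally
#'   intact locus must exceed over its superfamily-specific feature to count
#'   as transcribed for autonomous-candidate selection. Default 0.9.
#' @param mapped_fraction_threshold Minimum fraction of a long read's length
#'   that must be aligned for full-length transcript evidence. Default 0.9.
#' @param clip_min Soft-clip length in bp at or above which a long-read
#'   alignment end is labelled "clipped". Default 20.
#' @param substitution_rate Substitution rate r per site per year used to
#'   convert LTR-pair divergence K into an insertion time T = K / (2 r).
#'   Default 1.3e-8, a commonly used plant rate.
#' @param chisq_alpha Significance level of the location-bias chi-square
#'   tests. Default 0.01.
#' @param dangler_window Maximum distance in bp from a locus boundary within
#'   which a dangler read is assigned to that side. Default 1000.
#' @param dangler_side_mode `"any"` (danglers above threshold on at least one
#'   side) or `"both"`. Default `"any"`.
#' @param ptc_rule_nt A stop codon this many nt or more upstream of the final
#'   splice junction marks an isoform as PTC (NMD 50-nt convention).
#'   Default 50.
#' @param min_family_loci Minimum number of dated loci for a per-family
#'   insertion-age profile. Default 10.
#'
#' @return A named list of class `"teloci_config"`.
#' @export
#' @examples
#' cfg <- analysis_config()
#' cfg$min_reads
analysis_config <- function(min_reads = 10,
                            min_depth = 5,
                            integrity_threshold = 0.9,
                            flank_width = 2000,
                            gene_expressed_fpkm = 1,
                            gene_expressed_tpm = 1,
                            de_padj = 0.05,
                            de_lfc = 1,
                            de_two_sided = TRUE,
                            breadth_threshold = 0.9,
                            mapped_fraction_threshold = 0.9,
                            clip_min = 20,
                            substitution_rate = 1.3e-8,
                            chisq_alpha = 0.01,
                            dangler_window = 1000,
                            dangler_side_mode = c("any", "both"),
                            ptc_rule_nt = 50,
                            min_family_loci = 10) {
  dangler_side_mode <- match.arg(dangler_side_mode)
  cfg <- list(
    min_reads = min_reads,
    min_depth = min_depth,
    integrity_threshold = integrity_threshold,
    flank_width = flank_width,
    gene_expressed_fpkm = gene_expressed_fpkm,
    gene_expressed_tpm = gene_expressed_tpm,
    de_padj = de_padj,
    de_lfc = de_lfc,
    de_two_sided = de_two_sided,
    breadth_threshold = breadth_threshold,
    mapped_fraction_threshold = mapped_fraction_threshold,
    clip_min = clip_min,
    substitution_rate = substitution_rate,
    chisq_alpha = chisq_alpha,
    dangler_window = dangler_window,
    dangler_side_mode = dangler_side_mode,
    ptc_rule_nt = ptc_rule_nt,
    min_family_loci = min_family_loci
  )
  num <- vapply(cfg[!(names(cfg) %in% c("dangler_side_mode", "de_two_sided"))],
                is.numeric, logical(1))
  stopifnot(all(num))
  if (any(unlist(cfg[names(num)[num]]) <= 0))
    stop("all numeric thresholds must be positive")
  class(cfg) <- "teloci_config"
  cfg
}

#' @export
print.teloci_config <- function(x, ...) {
  cat("teloci analysis configuration\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
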