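# shared fixtures, built once per test run and cached

.fixture_env <- new.env(parent = emptyenv())

# the standard synthetic cohort used across module tests
shared_reference <- function(seed = 11) {
  key <- paste0("ref", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_reference(simulation_plan(), seed = seed)
  .fixture_env[[key]]
}

shared_chrom_lengths <- function(plan = simulation_plan()) {
  stats::setNames(rep(plan$chrom_length, plan$n_chromosomes),
                  paste0("chr", seq_len(plan$n_chromosomes)))
}

shared_compartments <- function(seed = 11) {
  key <- paste0("comp", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- build_compartments(
      shared_reference(seed)$genes, 2000, shared_chrom_lengths())
  .fixture_env[[key]]
}

# quick GRanges builders for hand-made cases
gr <- function(chrom, start, end, strand = "+", ...) {
  n <- length(start)
  GenomicRanges::GRanges(rep(chrom, length.out = n),
                         IRanges::IRanges(start, end),
                         strand = rep(strand, length.out = n), ...)
}

make_te <- function(chrom, start, end, strand = "+",
                    family = "FamA", superfamily = "Copia",
                    canonical_length = 1000L, intact = FALSE) {
  te <- gr(chrom, start, end, strand)
  te$locus_id <- sprintf("%s_%s_%d-%d", family, chrom, start, end)
  te$family <- family
  te$superfamily <- superfamily
  te$canonical_length <- canonical_length
  te$structurally_intact <- intact
  te$integrity <- GenomicRanges::width(te) / canonical_length
  names(te) <- te$locus_id
  te
}

# alignment records as produced by read_short_read_alignments()
make_aln <- function(chrom, start, end, strand = "+", read_id = NULL,
                     is_unique = TRUE, n_hits = NULL) {
  a <- gr(chrom, start, end, strand)
  a$read_id <- if (is.null(read_id)) sprintf("r%04d", seq_along(a))
  else read_id
  a$mate <- 1L
  a$n_hits <- if (is.null(n_hits)) ifelse(is_unique, 1L, 2L) else n_hits
  a$is_unique <- is_unique
  a
}

# minimal gene_models object from an exon GRangesList
make_genes <- function(exons_by_gene, bounds = NULL) {
  if (is.null(bounds)) {
    bounds <- unlist(GenomicRanges::GRangesList(lapply(
      exons_by_gene, function(e) range(GenomicRanges::granges(e)))))
  }
  names(bounds) <- names(exons_by_gene)
  bounds$gene_id <- names(exons_by_gene)
  structure(list(bounds = bounds,
                 exons = GenomicRanges::GRangesList(exons_by_gene)),
            class = "gene_models")
}

# hand-made long_reads object
make_long_reads <- function(chrom, start, end, strand = "+",
                            read_id = NULL, read_length = NULL,
                            clip5 = 0L, clip3 = 0L, mapped_bases = NULL,
                            is_multi = FALSE) {
  r <- gr(chrom, start, end, strand)
  n <- length(r)
  r$read_id <- if (is.null(read_id)) sprintf("lr%03d", seq_len(n))
  else read_id
  aligned <- GenomicRanges::width(r)
  r$clip5 <- rep(clip5, length.out = n)
  r$clip3 <- rep(clip3, length.out = n)
  r$mapped_bases <- if (is.null(mapped_bases)) aligned else mapped_bases
  r$read_length <- if (is.null(read_length))
    r$mapped_bases + r$clip5 + r$clip3 else read_length
  r$is_multi <- rep(is_multi, length.out = n)
  structure(list(records = r,
                 blocks = S4Vectors::split(GenomicRanges::granges(r),
                                           seq_along(r))),
            class = "long_reads")
}
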