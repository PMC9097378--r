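#' Read gene models from a GFF3 file
#'
#' Parses `gene`/`mRNA`/`exon` records and collapses multi-transcript genes
#' to a single "gene unit": the exon chain of the primary transcript, taken
#' to be the transcript with the largest summed exon length. Gene bounds are
#' the annotated transcription start/stop of the gene record; introns are
#' the gaps between consecutive exons.
#'
#' @param path GFF3 file (optionally gzip-compressed).
#' @return An object of class `"gene_models"`: a list with
#'   \describe{
#'     \item{bounds}{`GRanges` named by gene id (strand-aware gene units).}
#'     \item{exons}{`GRangesList` parallel to `bounds`, exons sorted 5'->3'
#'       in genomic order, non-overlapping.}
#'   }
#' @export
read_gene_annotation <- function(path) {
  gff <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gff$type)
  genes <- gff[type == "gene"]
  mrnas <- gff[type == "mRNA"]
  exons <- gff[type == "exon"]
  if (length(genes) == 0L) stop("no gene records found in ", path)
  if (length(mrnas) == 0L || length(exons) == 0L)
    stop("GFF3 must contain mRNA and exon records")

  mrna_parent <- vapply(mrnas$Parent, function(p) p[1], character(1))
  exon_parent <- vapply(exons$Parent, function(p) p[1], character(1))

  # primary transcript per gene: largest summed exon length
  exon_len_by_tx <- tapply(GenomicRanges::width(exons), exon_parent, sum)
  tx_gene <- split(mrnas$ID, mrna_parent)
  primary <- vapply(tx_gene, function(txs) {
    len <- exon_len_by_tx[txs]
    len[is.na(len)] <- 0
    txs[which.max(len)]
  }, character(1))

  gene_ids <- genes$ID
  missing_tx <- setdiff(gene_ids, names(primary))
  if (length(missing_tx) > 0L)
    stop("genes without mRNA records: ", paste(missing_tx, collapse = ", "))

  keep <- exon_parent %in% primary
  ex <- exons[keep]
  ex_gene <- names(primary)[match(exon_parent[keep], primary)]
  exl <- GenomicRanges::reduce(
    S4Vectors::split(GenomicRanges::granges(ex), ex_gene))
  exl <- exl[gene_ids]

  bounds <- GenomicRanges::granges(genes)
  names(bounds) <- gene_ids
  bounds$gene_id <- gene_ids

  ok <- unlist(S4Vectors::endoapply(exl, function(e) e)) # flatten for check
  idx <- rep(seq_along(exl), S4Vectors::elementNROWS(exl))
  inside <- GenomicRanges::start(ok) >= GenomicRanges::start(bounds)[idx] &
    GenomicRanges::end(ok) <= GenomicRanges::end(bounds)[idx] &
    as.character(GenomicRanges::seqnames(ok)) ==
      as.character(GenomicRanges::seqnames(bounds))[idx]
  if (!all(inside)) {
    bad <- unique(gene_ids[idx[!inside]])
    stop("exons outside gene bounds for: ", paste(bad, collapse = ", "))
  }
  structure(list(bounds = bounds, exons = exl), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes on %d sequence(s)\n",
              length(x$bounds),
              length(unique(as.character(GenomicRanges::seqnames(x$bounds))))))
  invisible(x)
}

#' Derive introns of each gene unit
#'
#' Introns are the gaps between consecutive exons within the gene bounds;
#' a single-exon gene has zero introns.
#'
#' @param genes A `"gene_models"` object.
#' @return `GRangesList` named by gene id.
#' @export
gene_introns <- function(genes) {
  strand_less <- GenomicRanges::granges(genes$bounds)
  GenomicRanges::strand(strand_less) <- "*"
  ex <- genes$exons
  GenomicRanges::strand(ex@unlistData) <- "*"
  ir <- GenomicRanges::psetdiff(strand_less, ex)
  GenomicRanges::strand(ir@unlistData) <-
    rep(GenomicRanges::strand(genes$bounds), S4Vectors::elementNROWS(ir))
  names(ir) <- names(genes$exons)
  ir
}

#' Write gene models to GFF3
#'
#' Emits one `gene`, one `mRNA` and its `exon` records per gene, suitable
#' for round-tripping through [read_gene_annotation()].
#'
#' @param genes A `"gene_models"` object.
#' @param path Output file.
#' @export
write_gene_annotation <- function(genes, path) {
  ids <- names(genes$bounds)
  g <- GenomicRanges::granges(genes$bounds)
  g$type <- "gene"
  g$ID <- ids
  g$Parent <- IRanges::CharacterList(vector("list", length(g)))
  m <- g
  m$type <- "mRNA"
  m$ID <- paste0(ids, ".1")
  m$Parent <- IRanges::CharacterList(as.list(ids))
  ex <- unlist(genes$exons, use.names = FALSE)
  exg <- rep(ids, S4Vectors::elementNROWS(genes$exons))
  ex$type <- "exon"
  ex$ID <- NA_character_
  ex$Parent <- IRanges::CharacterList(as.list(paste0(exg, ".1")))
  out <- c(g, m, ex)
  out$type <- factor(out$type, levels = c("gene", "mRNA", "exon"))
  rtracklayer::export(out, path, format = "gff3")
  invisible(path)
}

.known_superfamilies <- c("Copia", "Gypsy", "LINE", "hAT", "MULE",
                          "Harbinger", "CACTA", "other")

#' Read TE loci from a BED6 file
#'
#' The BED name column carries the TE family; the score column carries the
#' structurally-intact flag (1 = intact). Family metadata (superfamily and
#' canonical element length) comes from `canonical_lengths`; optional
#' structural sub-features (LTR5/LTR3/INT/ORF) from a companion table.
#'
#' @param path BED6 file (0-based half-open; optionally gzipped).
#' @param canonical_lengths `data.frame` with columns `family`,
#'   `superfamily`, `canonical_length`.
#' @param sub_features Optional `data.frame` with columns `locus_id`,
#'   `feature_type` (one of LTR5, LTR3, INT, ORF), `chrom`, `start`, `end`
#'   (1-based closed).
#' @return `GRanges` with mcols `locus_id`, `family`, `superfamily`,
#'   `canonical_length`, `structurally_intact`, `integrity`; any sub-features
#'   are attached as a `GRanges` in `metadata(x)$sub_features`.
#' @export
read_te_annotation <- function(path, canonical_lengths, sub_features = NULL) {
  stopifnot(all(c("family", "superfamily", "canonical_length") %in%
                  names(canonical_lengths)))
  bed <- rtracklayer::import(path, format = "bed")
  fam <- bed$name
  unknown <- setdiff(unique(fam), canonical_lengths$family)
  if (length(unknown) > 0L)
    stop("families missing from canonical_lengths: ",
         paste(unknown, collapse = ", "))
  i <- match(fam, canonical_lengths$family)
  te <- GenomicRanges::granges(bed)
  te$locus_id <- sprintf("%s_%s_%d-%d", fam,
                         as.character(GenomicRanges::seqnames(te)),
                         GenomicRanges::start(te), GenomicRanges::end(te))
  if (anyDuplicated(te$locus_id))
    te$locus_id <- make.unique(te$locus_id, sep = "_dup")
  te$family <- fam
  sf <- canonical_lengths$superfamily[i]
  sf[!(sf %in% .known_superfamilies)] <- "other"
  te$superfamily <- sf
  te$canonical_length <- canonical_lengths$canonical_length[i]
  if (any(te$canonical_length <= 0)) stop("canonical_length must be > 0")
  te$structurally_intact <- !is.na(bed$score) & bed$score >= 1
  te$integrity <- GenomicRanges::width(te) / te$canonical_length
  names(te) <- te$locus_id
  if (!is.null(sub_features) && nrow(sub_features) > 0L) {
    sfg <- GenomicRanges::GRanges(
      sub_features$chrom,
      IRanges::IRanges(sub_features$start, sub_features$end),
      locus_id = sub_features$locus_id,
      feature_type = sub_features$feature_type)
    j <- match(sfg$locus_id, te$locus_id)
    if (anyNA(j)) stop("sub-features reference unknown loci: ",
                       paste(unique(sfg$locus_id[is.na(j)]), collapse = ", "))
    contained <- GenomicRanges::start(sfg) >= GenomicRanges::start(te)[j] &
      GenomicRanges::end(sfg) <= GenomicRanges::end(te)[j] &
      as.character(GenomicRanges::seqnames(sfg)) ==
        as.character(GenomicRanges::seqnames(te))[j]
    if (!all(contained))
      stop("sub-feature outside locus bounds for: ",
           paste(unique(sfg$locus_id[!contained]), collapse = ", "))
    S4Vectors::metadata(te)$sub_features <- sfg
  }
  te
}

#' Write TE loci to BED6 (+ sub-feature table)
#'
#' @param te `GRanges` from [read_te_annotation()] or the synthetic
#'   generator.
#' @param path Output BED file.
#' @param sub_features_path Optional TSV for structural sub-features.
#' @export
write_te_annotation <- function(te, path, sub_features_path = NULL) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(te)),
    start = GenomicRanges::start(te) - 1L,  # BED is 0-based half-open
    end = GenomicRanges::end(te),
    name = te$family,
    score = as.integer(te$structurally_intact),
    strand = as.character(GenomicRanges::strand(te)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  sfg <- S4Vectors::metadata(te)$sub_features
  if (!is.null(sub_features_path) && !is.null(sfg)) {
    sdf <- data.frame(
      locus_id = sfg$locus_id,
      feature_type = sfg$feature_type,
      chrom = as.character(GenomicRanges::seqnames(sfg)),
      start = GenomicRanges::start(sfg),
      end = GenomicRanges::end(sfg))
    utils::write.table(sdf, sub_features_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Select the structural feature dated or required per superfamily
#'
#' LTR retrotransposons use the INT domain, DNA (TIR) transposons the
#' transposase ORF, and LINEs the whole element.
#'
#' @param te TE `GRanges` (with `metadata(te)$sub_features`).
#' @param locus_id Locus identifier.
#' @return `GRanges` of length 1 (the feature interval) or `NULL` when the
#'   required sub-feature is absent.
#' @export
superfamily_feature <- function(te, locus_id) {
  i <- match(locus_id, te$locus_id)
  if (is.na(i)) stop("unknown locus: ", locus_id)
  sfam <- te$superfamily[i]
  if (sfam == "LINE") return(GenomicRanges::granges(te[i]))
  want <- if (sfam %in% c("Copia", "Gypsy")) "INT" else "ORF"
  sfg <- S4Vectors::metadata(te)$sub_features
  if (is.null(sfg)) return(NULL)
  hit <- sfg[sfg$locus_id == locus_id & sfg$feature_type == want]
  if (length(hit) == 0L) return(NULL)
  GenomicRanges::granges(hit[1])
}
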