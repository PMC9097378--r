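#' Construct an isoform model
#'
#' @param id Isoform id.
#' @param gene_id Owning gene.
#' @param exons `GRanges` of exon blocks (one chromosome, one strand);
#'   sorted and merged internally.
#' @return A `"isoform_model"` list: `id`, `gene_id`, `chrom`, `strand`,
#'   `exons` (genomic order).
#' @export
isoform_model <- function(id, gene_id, exons) {
  chrom <- unique(as.character(GenomicRanges::seqnames(exons)))
  strand <- unique(as.character(GenomicRanges::strand(exons)))
  if (length(chrom) != 1L || length(strand) != 1L || !strand %in% c("+", "-"))
    stop("isoform exons must share one chromosome and one explicit strand")
  exons <- GenomicRanges::reduce(GenomicRanges::sort(exons))
  structure(list(id = id, gene_id = gene_id, chrom = chrom,
                 strand = strand, exons = exons),
            class = "isoform_model")
}

# introns of an isoform (genomic order)
.iso_introns <- function(iso) {
  ex <- iso$exons
  n <- length(ex)
  if (n < 2L) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(
    iso$chrom,
    IRanges::IRanges(GenomicRanges::end(ex)[-n] + 1L,
                     GenomicRanges::start(ex)[-1] - 1L),
    strand = iso$strand)
}

#' Spliced transcript sequence of an isoform
#'
#' Concatenates exon sequences in transcript order; reverse-complemented
#' for minus-strand isoforms.
#'
#' @param iso `"isoform_model"`.
#' @param genome `DNAStringSet` named by chromosome.
#' @return Character DNA string.
#' @export
spliced_sequence <- function(iso, genome) {
  chr <- genome[[iso$chrom]]
  pieces <- Biostrings::DNAStringSet(Biostrings::Views(
    chr, GenomicRanges::start(iso$exons), GenomicRanges::end(iso$exons)))
  s <- Biostrings::DNAString(paste(as.character(pieces), collapse = ""))
  if (iso$strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Splice-junction positions in transcript coordinates
#'
#' Position of the last transcribed base of each exon but the final one
#' (0 junctions for single-exon isoforms).
#'
#' @param iso `"isoform_model"`.
#' @return Integer vector.
#' @export
junction_positions <- function(iso) {
  w <- GenomicRanges::width(iso$exons)
  if (iso$strand == "-") w <- rev(w)
  n <- length(w)
  if (n < 2L) return(integer())
  cumsum(w)[-n]
}

#' Map genomic positions into transcript coordinates
#'
#' @param iso `"isoform_model"`.
#' @param gpos Genomic positions (must fall in exons; NA otherwise).
#' @return Integer transcript positions (1-based, 5' to 3').
#' @export
genomic_to_transcript <- function(iso, gpos) {
  ex <- iso$exons
  w <- GenomicRanges::width(ex)
  if (iso$strand == "+") {
    off <- c(0L, cumsum(w))[seq_along(w)]
    vapply(gpos, function(p) {
      i <- which(p >= GenomicRanges::start(ex) & p <= GenomicRanges::end(ex))
      if (length(i) == 0L) return(NA_integer_)
      off[i] + (p - GenomicRanges::start(ex)[i] + 1L)
    }, integer(1))
  } else {
    ord <- rev(seq_along(ex))  # transcript order for minus strand
    off <- c(0L, cumsum(w[ord]))[seq_along(w)]
    vapply(gpos, function(p) {
      i <- which(p >= GenomicRanges::start(ex) & p <= GenomicRanges::end(ex))
      if (length(i) == 0L) return(NA_integer_)
      k <- match(i, ord)
      off[k] + (GenomicRanges::end(ex)[i] - p + 1L)
    }, integer(1))
  }
}

#' Detect alternative-splicing features of an isoform vs a reference
#'
#' Feature types: `IR` (a reference intron fully exonic in the isoform;
#' the feature interval is that intron), `ES` (a reference exon absent
#' from the isoform while an isoform intron splices across it; the feature
#' interval is the skipped exon), `Alt5`/`Alt3` (a junction shared at one
#' edge whose other edge shifted; the feature interval is the shifted
#' delta, typed by whether the donor (5') or acceptor (3') side moved, in
#' transcript orientation). An isoform identical to its reference yields
#' no features.
#'
#' @param iso,ref `"isoform_model"` objects of the same gene and strand.
#' @return `GRanges` of features with mcols `type`, `isoform_id`.
#' @export
detect_as_features <- function(iso, ref) {
  if (iso$chrom != ref$chrom || iso$strand != ref$strand)
    stop("isoform and reference differ in chromosome or strand")
  feats <- GenomicRanges::GRanges()
  ri <- .iso_introns(ref)
  ii <- .iso_introns(iso)

  # IR: reference intron fully inside an isoform exon
  if (length(ri) > 0L) {
    inside <- IRanges::overlapsAny(ri, iso$exons, type = "within",
                                   ignore.strand = TRUE)
    if (any(inside)) {
      f <- GenomicRanges::granges(ri[inside])
      f$type <- "IR"
      feats <- c(feats, f)
    }
  }
  # ES: reference exon with no isoform-exon overlap, spanned by an
  # isoform intron (flanking junctions spliced)
  if (length(ii) > 0L) {
    no_ov <- !IRanges::overlapsAny(ref$exons, iso$exons,
                                   ignore.strand = TRUE)
    spanned <- IRanges::overlapsAny(ref$exons, ii, type = "within",
                                    ignore.strand = TRUE)
    if (any(no_ov & spanned)) {
      f <- GenomicRanges::granges(ref$exons[no_ov & spanned])
      f$type <- "ES"
      feats <- c(feats, f)
    }
  }
  # Alt5/Alt3: overlapping intron pairs sharing exactly one edge.
  # Introns that splice across a whole exon of the other model belong to
  # exon-skipping/inclusion events, not shifted junctions — exclude them.
  if (length(ri) > 0L && length(ii) > 0L) {
    ii_es <- IRanges::overlapsAny(ii, ref$exons, type = "any",
                                  ignore.strand = TRUE) &
      vapply(seq_along(ii), function(j)
        any(IRanges::overlapsAny(ref$exons, ii[j], type = "within",
                                 ignore.strand = TRUE)), logical(1))
    ri_es <- vapply(seq_along(ri), function(j)
      any(IRanges::overlapsAny(iso$exons, ri[j], type = "within",
                               ignore.strand = TRUE)), logical(1))
    hits <- GenomicRanges::findOverlaps(ii, ri, ignore.strand = TRUE)
    hits <- hits[!ii_es[S4Vectors::queryHits(hits)] &
                   !ri_es[S4Vectors::subjectHits(hits)]]
    for (h in seq_along(hits)) {
      a <- ii[S4Vectors::queryHits(hits)[h]]
      b <- ri[S4Vectors::subjectHits(hits)[h]]
      ss <- GenomicRanges::start(a) == GenomicRanges::start(b)
      se <- GenomicRanges::end(a) == GenomicRanges::end(b)
      if (ss == se) next  # identical or both edges moved
      delta <- if (ss)
        IRanges::IRanges(min(GenomicRanges::end(a), GenomicRanges::end(b)) + 1L,
                         max(GenomicRanges::end(a), GenomicRanges::end(b)))
      else
        IRanges::IRanges(min(GenomicRanges::start(a), GenomicRanges::start(b)),
                         max(GenomicRanges::start(a), GenomicRanges::start(b)) - 1L)
      # moved edge: intron start is donor on "+", acceptor on "-"
      start_moved <- !ss
      type <- if (iso$strand == "+") {
        if (start_moved) "Alt5" else "Alt3"
      } else {
        if (start_moved) "Alt3" else "Alt5"
      }
      f <- GenomicRanges::GRanges(iso$chrom, delta, strand = iso$strand)
      f$type <- type
      feats <- c(feats, f)
    }
  }
  if (length(feats) > 0L) {
    feats$isoform_id <- iso$id
    feats <- GenomicRanges::sort(feats, ignore.strand = TRUE)
  }
  feats
}

#' Annotate alternative-splicing features with TE overlaps
#'
#' Records every TE locus intersecting a feature by at least one base.
#'
#' @param features `GRanges` from [detect_as_features()] (possibly
#'   concatenated over isoforms).
#' @param te TE `GRanges`.
#' @return `features` with added mcols `te_ids` (`CharacterList`) and
#'   `te_overlap_bp` (`IntegerList`).
#' @export
annotate_te_overlap <- function(features, te) {
  ids <- vector("list", length(features))
  bps <- vector("list", length(features))
  hits <- GenomicRanges::findOverlaps(features, te, ignore.strand = TRUE)
  if (length(hits) > 0L) {
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    ov <- GenomicRanges::width(IRanges::pintersect(
      GenomicRanges::granges(features)[qh], GenomicRanges::granges(te)[sh],
      ignore.strand = TRUE))
    for (i in unique(qh)) {
      sel <- qh == i
      ids[[i]] <- te$locus_id[sh[sel]]
      bps[[i]] <- ov[sel]
    }
  }
  features$te_ids <- IRanges::CharacterList(ids)
  features$te_overlap_bp <- IRanges::IntegerList(bps)
  features
}

#' Classify isoform productivity
#'
#' Translation is initiated at the first ATG of the spliced sequence and
#' scanned in-frame: no ATG gives `NGO`; no in-frame stop gives `NST`; a
#' stop at least `ptc_rule_nt` nt upstream of the final splice junction
#' gives `PTC` (NMD convention); otherwise `PRO`. Single-exon isoforms
#' have no junction and cannot be PTC.
#'
#' @param iso `"isoform_model"`.
#' @param genome `DNAStringSet`.
#' @param config [analysis_config()].
#' @return `list` (`ProductivityCall`): `isoform_id`, `class`,
#'   `start_pos`, `stop_pos` (transcript position of the stop codon's last
#'   base; NA when absent).
#' @export
classify_productivity <- function(iso, genome, config = analysis_config()) {
  s <- spliced_sequence(iso, genome)
  if (grepl("[^ACGTN]", s)) stop("spliced sequence contains non-ACGTN")
  call <- list(isoform_id = iso$id, class = NULL,
               start_pos = NA_integer_, stop_pos = NA_integer_)
  start <- regexpr("ATG", s, fixed = TRUE)
  if (start < 0L) {
    call$class <- "NGO"
    return(call)
  }
  call$start_pos <- as.integer(start)
  stops <- c("TAA", "TAG", "TGA")
  stop_pos <- NA_integer_
  i <- call$start_pos + 3L
  while (i + 2L <= nchar(s)) {
    codon <- substr(s, i, i + 2L)
    if (codon %in% stops) {
      stop_pos <- i + 2L
      break
    }
    i <- i + 3L
  }
  if (is.na(stop_pos)) {
    call$class <- "NST"
    return(call)
  }
  call$stop_pos <- stop_pos
  jx <- junction_positions(iso)
  call$class <- if (length(jx) > 0L &&
                    max(jx) - stop_pos >= config$ptc_rule_nt) "PTC" else "PRO"
  call
}

#' Locate a premature stop relative to a TE inside a retained intron
#'
#' Projects the TE locus into transcript coordinates through the isoform's
#' exon chain and places the premature stop codon within, before (5' of)
#' or after (3' of) the TE projection; for before/after the
#' transcript-coordinate gap is reported.
#'
#' @param call [classify_productivity()] output with class `"PTC"`.
#' @param iso `"isoform_model"` carrying the TE-overlapping retained
#'   intron.
#' @param te_locus TE `GRanges` of length 1.
#' @return `list`: `stop_vs_te` (within/before/after) and `distance_bp`
#'   (NA for within).
#' @export
locate_stop_vs_te <- function(call, iso, te_locus) {
  if (!identical(call$class, "PTC"))
    stop("stop localisation applies to PTC isoforms only")
  ex_ov <- GenomicRanges::intersect(
    GenomicRanges::granges(iso$exons), GenomicRanges::granges(te_locus),
    ignore.strand = TRUE)
  if (length(ex_ov) == 0L)
    stop("TE locus does not intersect the isoform's exons")
  tpos <- genomic_to_transcript(
    iso, c(GenomicRanges::start(ex_ov), GenomicRanges::end(ex_ov)))
  lo <- min(tpos, na.rm = TRUE)
  hi <- max(tpos, na.rm = TRUE)
  sp <- call$stop_pos
  if (sp >= lo && sp <= hi)
    list(stop_vs_te = "within", distance_bp = NA_integer_)
  else if (sp < lo)
    list(stop_vs_te = "before", distance_bp = lo - sp)
  else
    list(stop_vs_te = "after", distance_bp = sp - hi)
}

#' Productivity composition of AS-feature groups
#'
#' Summary arithmetic for feature/productivity tables: percentage of each
#' productivity class within a group.
#'
#' @param classes Character vector of productivity classes.
#' @param digits Rounding (default 1).
#' @return Named percentage vector over PRO/PTC/NGO/NST.
#' @export
productivity_percent <- function(classes, digits = 1) {
  lev <- c("PRO", "PTC", "NGO", "NST")
  tab <- table(factor(classes, levels = lev))
  round(100 * as.numeric(tab) / length(classes), digits) |>
    stats::setNames(lev)
}
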