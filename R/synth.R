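#' Simulation plan for the synthetic cohort
#'
#' Describes a small, fully specified toy genome: chromosome count and
#' length, gene geometry, TE families with canonical lengths and per-family
#' locus numbers, compartment quotas for TE placement, planted LTR-pair
#' divergences for structurally intact LTR loci, and read-simulation
#' defaults. The defaults emulate the study conditions the pipeline is
#' aimed at: a minority of genic TE loci (about 43% genic, over half of the
#' gene-unit fraction intronic), mostly fragmented loci with a small
#' full-length tail, short reads of 150 bp, and long reads spanning 0.5-6
#' kb.
#'
#' @param n_chromosomes,chrom_length Genome shape (default 2 x 200 kb).
#' @param n_genes_per_chrom Genes per chromosome (default 10).
#' @param n_exons_range,exon_length_range,intron_length_range Gene geometry
#'   (bp).
#' @param te_families `data.frame` with `family`, `superfamily`,
#'   `canonical_length`, `ltr_length` (NA for non-LTR), `orf_length` (NA
#'   unless TIR), `n_intact`, `n_fragmented`, `divergence` (planted
#'   LTR-pair divergence of intact loci).
#' @param compartment_quotas Named proportions over
#'   intergenic/intron/exon/N-flank/C-flank summing to 1, governing where
#'   fragmented loci are placed (intact loci need room and are placed in
#'   introns and intergenic space).
#' @param flank_width Flank width used for placement quotas (bp).
#' @param short_read_length,long_read_range Read lengths (bp).
#' @param nb_dispersion Negative-binomial dispersion of simulated counts.
#' @return `list` of class `"simulation_plan"`.
#' @export
simulation_plan <- function(n_chromosomes = 2,
                            chrom_length = 200000,
                            n_genes_per_chrom = 10,
                            n_exons_range = c(2, 4),
                            exon_length_range = c(150, 300),
                            intron_length_range = c(2500, 4000),
                            te_families = default_te_families(),
                            compartment_quotas = c(intergenic = 0.57,
                                                   intron = 0.18,
                                                   exon = 0.04,
                                                   `N-flank` = 0.105,
                                                   `C-flank` = 0.105),
                            flank_width = 2000,
                            short_read_length = 150,
                            long_read_range = c(500, 6000),
                            nb_dispersion = 0.1) {
  stopifnot(abs(sum(compartment_quotas) - 1) < 1e-8,
            all(compartment_quotas >= 0),
            all(te_families$canonical_length > 0),
            all(te_families$n_intact + te_families$n_fragmented >= 0))
  structure(list(n_chromosomes = n_chromosomes,
                 chrom_length = chrom_length,
                 n_genes_per_chrom = n_genes_per_chrom,
                 n_exons_range = n_exons_range,
                 exon_length_range = exon_length_range,
                 intron_length_range = intron_length_range,
                 te_families = te_families,
                 compartment_quotas = compartment_quotas,
                 flank_width = flank_width,
                 short_read_length = short_read_length,
                 long_read_range = long_read_range,
                 nb_dispersion = nb_dispersion),
            class = "simulation_plan")
}

#' Default synthetic TE family table
#'
#' Five families spanning the superfamilies the pipeline distinguishes:
#' two LTR retrotransposon families (with LTR/INT structure and planted
#' LTR divergences), one LINE, and two DNA-transposon families (one with a
#' transposase ORF sub-feature).
#'
#' @return `data.frame`.
#' @export
default_te_families <- function() {
  data.frame(
    family = c("Copia-3", "Gypsy-12", "VLINE1", "hAT-7", "MULE-1"),
    superfamily = c("Copia", "Gypsy", "LINE", "hAT", "MULE"),
    canonical_length = c(2000L, 2400L, 1500L, 1200L, 900L),
    ltr_length = c(300L, 350L, NA, NA, NA),
    orf_length = c(NA, NA, NA, 800L, NA),
    n_intact = c(4L, 3L, 2L, 2L, 0L),
    n_fragmented = c(20L, 18L, 25L, 15L, 18L),
    divergence = c(0.02, 0.05, NA, NA, NA))
}

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# plant exactly round(d * len) substitutions, transitions:transversions 2:1
.mutate_dna <- function(seq, d) {
  x <- strsplit(seq, "")[[1]]
  n_sub <- round(d * length(x))
  if (n_sub == 0L) return(seq)
  pos <- sample.int(length(x), n_sub)
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  transversion <- list(A = c("C", "T"), G = c("C", "T"),
                       C = c("A", "G"), T = c("A", "G"))
  is_ts <- sample(c(TRUE, FALSE), n_sub, replace = TRUE,
                  prob = c(2 / 3, 1 / 3))
  for (k in seq_len(n_sub)) {
    b <- x[pos[k]]
    x[pos[k]] <- if (is_ts[k]) transition[[b]]
    else transversion[[b]][sample.int(2, 1)]
  }
  paste(x, collapse = "")
}

.place_genes <- function(plan) {
  rows <- list()
  exl <- list()
  gid <- 0L
  chrom_names <- paste0("chr", seq_len(plan$n_chromosomes))
  for (chrom in chrom_names) {
    cursor <- 6000L
    for (g in seq_len(plan$n_genes_per_chrom)) {
      n_ex <- sample(seq(plan$n_exons_range[1], plan$n_exons_range[2]), 1)
      ex_w <- sample(seq(plan$exon_length_range[1],
                         plan$exon_length_range[2]), n_ex, replace = TRUE)
      in_w <- if (n_ex > 1)
        sample(seq(plan$intron_length_range[1],
                   plan$intron_length_range[2]), n_ex - 1, replace = TRUE)
      else integer()
      glen <- sum(ex_w) + sum(in_w)
      if (cursor + glen > plan$chrom_length - 6000L) break
      gid <- gid + 1L
      id <- sprintf("gene%03d", gid)
      starts <- cursor + cumsum(c(0L, utils::head(ex_w, -1) + in_w))
      strand <- sample(c("+", "-"), 1)
      exl[[id]] <- GenomicRanges::GRanges(
        factor(chrom, levels = chrom_names),
        IRanges::IRanges(starts, width = ex_w), strand = strand)
      rows[[gid]] <- data.frame(chrom = chrom, start = cursor,
                                end = cursor + glen - 1L, strand = strand,
                                gene_id = id)
      cursor <- cursor + glen + sample(6000:9000, 1)
    }
  }
  df <- do.call(rbind, rows)
  bounds <- GenomicRanges::GRanges(
    factor(df$chrom, levels = chrom_names),
    IRanges::IRanges(df$start, df$end), strand = df$strand,
    gene_id = df$gene_id)
  names(bounds) <- bounds$gene_id
  structure(list(bounds = bounds,
                 exons = GenomicRanges::GRangesList(exl)),
            class = "gene_models")
}

# free-slot bookkeeping: pick a sub-interval of length len from the slots
# of one compartment label, with a safety margin, and split the used slot
.take_slot <- function(slots, label, len, margin = 300L) {
  s <- slots[[label]]
  fit <- which(IRanges::width(s$ranges) >= len + 2L * margin)
  if (length(fit) == 0L)
    return(NULL)
  i <- fit[sample.int(length(fit), 1)]
  room <- IRanges::width(s$ranges)[i] - len - 2L * margin
  off <- if (room > 0) sample.int(room + 1L, 1) - 1L else 0L
  start <- IRanges::start(s$ranges)[i] + margin + off
  chrom <- s$chrom[i]
  old_start <- IRanges::start(s$ranges)[i]
  old_end <- IRanges::end(s$ranges)[i]
  left <- IRanges::IRanges(old_start, start - 1L)
  right <- IRanges::IRanges(start + len, old_end)
  keep <- IRanges::width(c(left, right)) >= 1L
  s$ranges <- c(s$ranges[-i], c(left, right)[keep])
  s$chrom <- c(s$chrom[-i], rep(chrom, sum(keep)))
  slots[[label]] <- s
  list(chrom = chrom, start = start, end = start + len - 1L,
       slots = slots)
}

.init_slots <- function(genes, plan) {
  comp <- build_compartments(genes, plan$flank_width,
                             seqlengths = stats::setNames(
                               rep(plan$chrom_length, plan$n_chromosomes),
                               paste0("chr", seq_len(plan$n_chromosomes))))
  slots <- list()
  for (lab in c("intron", "exon", "N-flank", "C-flank")) {
    g <- comp[comp$label == lab]
    slots[[lab]] <- list(ranges = IRanges::ranges(g),
                         chrom = as.character(GenomicRanges::seqnames(g)))
  }
  # intergenic: chromosome minus all labels, trimmed away from flanks so
  # placed loci stay unambiguous
  all_lab <- GenomicRanges::reduce(GenomicRanges::granges(comp),
                                   ignore.strand = TRUE)
  inter <- GenomicRanges::GRanges()
  for (ch in paste0("chr", seq_len(plan$n_chromosomes))) {
    full <- GenomicRanges::GRanges(
      ch, IRanges::IRanges(1L, plan$chrom_length))
    gaps <- suppressWarnings(GenomicRanges::setdiff(
      full, all_lab[GenomicRanges::seqnames(all_lab) == ch],
      ignore.strand = TRUE))
    inter <- c(inter, gaps)
  }
  slots[["intergenic"]] <- list(
    ranges = IRanges::ranges(inter),
    chrom = as.character(GenomicRanges::seqnames(inter)))
  slots
}

#' Generate the synthetic reference: genome, genes, TE loci, manifest
#'
#' Places genes, then TE loci according to the plan's compartment quotas:
#' structurally intact loci at full canonical length (with LTR5/INT/LTR3 or
#' ORF sub-features; LTR pairs copied identically and then mutated to the
#' planted divergence), fragmented loci at 20-80% of canonical length.
#' Chromosome sequence is uniform random DNA with the intact-locus
#' structures written in. Deterministic under `(plan, seed)`.
#'
#' @param plan [simulation_plan()].
#' @param seed Integer seed.
#' @return `list`: `genome` (`DNAStringSet`), `genes` (`"gene_models"`),
#'   `te` (`GRanges` with sub-features in metadata), `canonical`
#'   (`DNAStringSet` of family canonical sequences), `canonical_lengths`
#'   (`data.frame`), `manifest` (`list` with `loci`, `genes`, `seed`).
#' @export
generate_reference <- function(plan = simulation_plan(), seed = 1) {
  set.seed(seed)
  genes <- .place_genes(plan)
  slots <- .init_slots(genes, plan)
  fam <- plan$te_families

  chrom_names <- paste0("chr", seq_len(plan$n_chromosomes))
  chrom_seq <- lapply(chrom_names, function(ch) .rand_dna(plan$chrom_length))
  names(chrom_seq) <- chrom_names

  quotas <- plan$compartment_quotas
  labs <- names(quotas)
  loci <- list()
  subf <- list()
  li <- 0L
  # intact loci need room: restrict them to intron and intergenic slots
  intact_labs <- c("intron", "intergenic")
  intact_q <- quotas[intact_labs] / sum(quotas[intact_labs])
  for (f in seq_len(nrow(fam))) {
    n_int <- fam$n_intact[f]
    n_frag <- fam$n_fragmented[f]
    lens <- c(rep(fam$canonical_length[f], n_int),
              round(fam$canonical_length[f] *
                      stats::runif(n_frag, 0.2, 0.8)))
    lab_draws <- c(sample(intact_labs, n_int, replace = TRUE,
                          prob = intact_q),
                   sample(labs, n_frag, replace = TRUE, prob = quotas))
    intact_flags <- c(rep(TRUE, n_int), rep(FALSE, n_frag))
    for (j in seq_along(lens)) {
      hit <- .take_slot(slots, lab_draws[j], lens[j])
      tries <- 0L
      while (is.null(hit) && tries < length(labs)) {
        # fall back through remaining compartments before giving up
        tries <- tries + 1L
        alt <- if (intact_flags[j]) intact_labs else labs
        lab_draws[j] <- alt[(match(lab_draws[j], alt) %% length(alt)) + 1L]
        hit <- .take_slot(slots, lab_draws[j], lens[j])
      }
      if (is.null(hit))
        stop("infeasible compartment quotas: no room for a ", lens[j],
             " bp locus")
      slots <- hit$slots
      li <- li + 1L
      strand <- sample(c("+", "-"), 1)
      id <- sprintf("%s_%s_%d-%d", fam$family[f], hit$chrom, hit$start,
                    hit$end)
      loci[[li]] <- data.frame(
        locus_id = id, family = fam$family[f],
        superfamily = fam$superfamily[f], chrom = hit$chrom,
        start = hit$start, end = hit$end, strand = strand,
        canonical_length = fam$canonical_length[f],
        compartment = lab_draws[j], intact = intact_flags[j],
        ltr_divergence = if (intact_flags[j]) fam$divergence[f] else NA)
      if (intact_flags[j] && !is.na(fam$ltr_length[f])) {
        lw <- fam$ltr_length[f]
        ltr_seq <- .rand_dna(lw)
        ltr3_seq <- .mutate_dna(ltr_seq, fam$divergence[f])
        int_len <- lens[j] - 2L * lw
        chrom_seq[[hit$chrom]] <- paste0(
          substr(chrom_seq[[hit$chrom]], 1, hit$start - 1L),
          ltr_seq, .rand_dna(int_len), ltr3_seq,
          substr(chrom_seq[[hit$chrom]], hit$end + 1L,
                 nchar(chrom_seq[[hit$chrom]])))
        subf[[length(subf) + 1L]] <- data.frame(
          locus_id = id,
          feature_type = c("LTR5", "INT", "LTR3"),
          chrom = hit$chrom,
          start = c(hit$start, hit$start + lw, hit$end - lw + 1L),
          end = c(hit$start + lw - 1L, hit$end - lw, hit$end))
      } else if (intact_flags[j] && !is.na(fam$orf_length[f])) {
        ow <- fam$orf_length[f]
        os <- hit$start + floor((lens[j] - ow) / 2)
        subf[[length(subf) + 1L]] <- data.frame(
          locus_id = id, feature_type = "ORF", chrom = hit$chrom,
          start = os, end = os + ow - 1L)
      }
    }
  }
  loci <- do.call(rbind, loci)
  te <- GenomicRanges::GRanges(loci$chrom,
                               IRanges::IRanges(loci$start, loci$end),
                               strand = loci$strand)
  te$locus_id <- loci$locus_id
  te$family <- loci$family
  te$superfamily <- loci$superfamily
  te$canonical_length <- loci$canonical_length
  te$structurally_intact <- loci$intact
  te$integrity <- GenomicRanges::width(te) / te$canonical_length
  names(te) <- te$locus_id
  if (length(subf) > 0L) {
    sdf <- do.call(rbind, subf)
    S4Vectors::metadata(te)$sub_features <- GenomicRanges::GRanges(
      sdf$chrom, IRanges::IRanges(sdf$start, sdf$end),
      locus_id = sdf$locus_id, feature_type = sdf$feature_type)
  }
  genome <- Biostrings::DNAStringSet(unlist(chrom_seq))
  canonical <- Biostrings::DNAStringSet(
    vapply(fam$canonical_length, .rand_dna, character(1)))
  names(canonical) <- fam$family
  list(genome = genome,
       genes = genes,
       te = te,
       canonical = canonical,
       canonical_lengths = fam[, c("family", "superfamily",
                                   "canonical_length")],
       manifest = list(loci = loci,
                       genes = data.frame(
                         gene_id = names(genes$bounds),
                         chrom = as.character(
                           GenomicRanges::seqnames(genes$bounds)),
                         start = GenomicRanges::start(genes$bounds),
                         end = GenomicRanges::end(genes$bounds),
                         strand = as.character(
                           GenomicRanges::strand(genes$bounds))),
                       plan = plan, seed = seed))
}

#' Write a synthetic reference to disk
#'
#' Emits genome FASTA, gene GFF3, TE BED6 (+ sub-feature and canonical
#' length TSVs), canonical-library FASTA and the locus manifest TSV.
#'
#' @param ref Output of [generate_reference()].
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths.
#' @export
write_reference <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             genes = file.path(dir, "genes.gff3"),
             te = file.path(dir, "te_loci.bed"),
             sub_features = file.path(dir, "te_sub_features.tsv"),
             canonical = file.path(dir, "te_canonical.fa"),
             canonical_lengths = file.path(dir, "te_canonical_lengths.tsv"),
             manifest = file.path(dir, "manifest_loci.tsv"))
  Biostrings::writeXStringSet(ref$genome, paths["genome"])
  write_gene_annotation(ref$genes, paths["genes"])
  write_te_annotation(ref$te, paths["te"], paths["sub_features"])
  Biostrings::writeXStringSet(ref$canonical, paths["canonical"])
  utils::write.table(ref$canonical_lengths, paths["canonical_lengths"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ref$manifest$loci, paths["manifest"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths
}

.sam_header <- function(chrom_lengths) {
  c("@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
            as.integer(chrom_lengths)))
}

.sam_line <- function(qname, flag, chrom, pos, mapq, cigar, nh) {
  sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*\tNH:i:%d",
          qname, flag, chrom, pos, mapq, cigar, nh)
}

#' Simulate short-read genome alignments with planted evidence
#'
#' Writes a SAM file realising, per locus, the planted numbers of
#' unique-mapping reads (inside the locus), multi-mapping read groups
#' (each read placed once at every locus of its group, with matching
#' multiplicity tags), left/right dangler reads (uniquely mapped within
#' the dangler window, oriented toward the locus, mates recorded as TE
#' library hits), and optional boundary-crossing reads. Alignments are
#' authored directly — no aligner is involved — so the manifest predicts
#' every downstream count exactly.
#'
#' @param te TE `GRanges`.
#' @param counts_plan `data.frame` with `locus_id` and any of `n_unique`,
#'   `n_dangler_left`, `n_dangler_right`, `n_boundary`, `multi_group`
#'   (group label or NA), `n_multi` (reads per group, constant within a
#'   group).
#' @param chrom_lengths Named chromosome lengths.
#' @param path Output SAM path.
#' @param read_length Read length in bp (default 150).
#' @param window Dangler window (default 1000).
#' @param seed Integer seed.
#' @return `list`: `sam` (path), `te_library_hits` (read ids whose mate
#'   aligned to the TE library).
#' @export
simulate_short_read_alignments <- function(te, counts_plan, chrom_lengths,
                                           path, read_length = 150,
                                           window = 1000, seed = 1) {
  set.seed(seed)
  cp <- counts_plan
  for (col in c("n_unique", "n_dangler_left", "n_dangler_right",
                "n_boundary", "n_multi"))
    if (is.null(cp[[col]])) cp[[col]] <- 0L
  if (is.null(cp$multi_group)) cp$multi_group <- NA_character_
  lines <- character()
  lib_hits <- character()
  rid <- 0L
  nxt <- function() {
    rid <<- rid + 1L
    sprintf("read%06d", rid)
  }
  place_in <- function(i, n) {
    s <- GenomicRanges::start(te)[i]
    e <- GenomicRanges::end(te)[i]
    if (e - s + 1L < read_length)
      stop("locus ", te$locus_id[i], " shorter than the read length")
    s + sample.int(e - s + 2L - read_length, n, replace = TRUE) - 1L
  }
  idx <- match(cp$locus_id, te$locus_id)
  if (anyNA(idx)) stop("counts_plan references unknown loci")
  chrom <- as.character(GenomicRanges::seqnames(te))
  cigar <- paste0(read_length, "M")
  # flanking reads must stay clear of all OTHER annotated loci so that the
  # manifest predicts every per-locus count exactly
  clear_of_loci <- function(ch, p, except) {
    # vectorised over p: TRUE when [p, p+read_length-1] overlaps no locus
    # other than the excepted one and stays on the chromosome
    q <- GenomicRanges::GRanges(ch, IRanges::IRanges(pmax(p, 1L),
                                                     width = read_length))
    other <- if (length(except) > 0L) te[-except] else te
    p >= 1L & p + read_length - 1L <= unname(chrom_lengths[ch]) &
      !IRanges::overlapsAny(q, other, ignore.strand = TRUE)
  }
  draw_flank <- function(i, side) {
    s <- GenomicRanges::start(te)[i]
    e <- GenomicRanges::end(te)[i]
    gaps <- seq_len(window - read_length)
    pos <- if (side == "left") s - gaps - read_length else e + gaps + 1L
    ok <- clear_of_loci(chrom[i], pos, integer())
    if (!any(ok))
      stop("no clear dangler placement near ", te$locus_id[i])
    cand <- pos[ok]
    cand[sample.int(length(cand), 1)]
  }

  for (r in seq_len(nrow(cp))) {
    i <- idx[r]
    if (cp$n_unique[r] > 0L) {
      pos <- place_in(i, cp$n_unique[r])
      for (p in pos)
        lines <- c(lines, .sam_line(nxt(), 0L, chrom[i], p, 60L, cigar, 1L))
    }
    if (cp$n_dangler_left[r] > 0L) {
      for (k in seq_len(cp$n_dangler_left[r])) {
        p <- draw_flank(i, "left")
        q <- nxt()
        lines <- c(lines, .sam_line(q, 0L, chrom[i], p, 60L, cigar, 1L))
        lib_hits <- c(lib_hits, q)
      }
    }
    if (cp$n_dangler_right[r] > 0L) {
      for (k in seq_len(cp$n_dangler_right[r])) {
        p <- draw_flank(i, "right")
        q <- nxt()
        lines <- c(lines, .sam_line(q, 16L, chrom[i], p, 60L, cigar, 1L))
        lib_hits <- c(lib_hits, q)
      }
    }
    if (cp$n_boundary[r] > 0L) {
      s <- GenomicRanges::start(te)[i]
      for (k in seq_len(cp$n_boundary[r])) {
        shifts <- seq_len(read_length - 2L)
        ok <- clear_of_loci(chrom[i], s - shifts, i)
        if (!any(ok)) stop("no boundary-read placement at ", te$locus_id[i])
        p <- (s - shifts)[ok][sample.int(sum(ok), 1)]
        q <- nxt()
        lines <- c(lines, .sam_line(q, 0L, chrom[i], p, 60L, cigar, 1L))
        lib_hits <- c(lib_hits, q)
      }
    }
  }
  # multi-mapping groups: each read aligned once at every member locus
  groups <- unique(cp$multi_group[!is.na(cp$multi_group) & cp$n_multi > 0])
  for (g in groups) {
    members <- idx[which(cp$multi_group == g & cp$n_multi > 0)]
    n_reads <- cp$n_multi[which(cp$multi_group == g & cp$n_multi > 0)][1]
    k <- length(members)
    for (m in seq_len(n_reads)) {
      q <- nxt()
      for (jj in seq_along(members)) {
        i <- members[jj]
        p <- place_in(i, 1L)
        flag <- if (jj == 1L) 0L else 256L
        lines <- c(lines, .sam_line(q, flag, chrom[i], p, 0L, cigar,
                                    as.integer(k)))
      }
    }
  }
  writeLines(c(.sam_header(chrom_lengths), lines), path)
  list(sam = path, te_library_hits = unique(lib_hits))
}

#' Simulate long-read alignments with planted geometry
#'
#' Writes a SAM file of spliced long-read records according to a per-row
#' read plan: sense or antisense relative to the locus, start within or
#' upstream of the locus (at an explicit genomic 5' position when given),
#' soft-clip lengths at the biological 5'/3' ends, full coverage of the
#' superfamily-specific feature on demand, and an optional central splice
#' gap.
#'
#' @param te TE `GRanges`.
#' @param read_plan `data.frame`, one row per read group, with `locus_id`,
#'   `n_reads` and any of `start_mode` ("within"/"upstream"),
#'   `upstream_pos` (genomic 5' start for upstream reads; NA draws
#'   50-500 bp upstream), `clip5`, `clip3`, `full_feature` (alignment
#'   spans the superfamily feature), `antisense`, `splice_gap` (bp),
#'   `nh` (multiplicity tag).
#' @param chrom_lengths Named chromosome lengths.
#' @param path Output SAM path.
#' @param seed Integer seed.
#' @return `list`: `sam` (path), `read_ids` per plan row.
#' @export
simulate_long_read_alignments <- function(te, read_plan, chrom_lengths,
                                          path, seed = 1) {
  set.seed(seed)
  rp <- read_plan
  defaults <- list(start_mode = "within", upstream_pos = NA_integer_,
                   clip5 = 0L, clip3 = 0L, full_feature = FALSE,
                   antisense = FALSE, splice_gap = 0L, nh = 1L)
  for (col in names(defaults))
    if (is.null(rp[[col]])) rp[[col]] <- defaults[[col]]
  lines <- character()
  ids <- vector("list", nrow(rp))
  rid <- 0L
  for (r in seq_len(nrow(rp))) {
    i <- match(rp$locus_id[r], te$locus_id)
    if (is.na(i)) stop("unknown locus ", rp$locus_id[r])
    ls <- GenomicRanges::start(te)[i]
    le <- GenomicRanges::end(te)[i]
    lstr <- as.character(GenomicRanges::strand(te))[i]
    chrom <- as.character(GenomicRanges::seqnames(te))[i]
    rstr <- if (rp$antisense[r]) setdiff(c("+", "-"), lstr) else lstr
    feat <- superfamily_feature(te, rp$locus_id[r])
    row_ids <- character(rp$n_reads[r])
    for (k in seq_len(rp$n_reads[r])) {
      rid <- rid + 1L
      q <- sprintf("ont%05d", rid)
      row_ids[k] <- q
      if (rp$full_feature[r] && !is.null(feat)) {
        a_start <- GenomicRanges::start(feat)
        a_end <- GenomicRanges::end(feat)
      } else {
        w <- le - ls + 1L
        span <- max(100L, floor(w * 0.6))
        a_start <- ls + sample.int(max(w - span, 1L), 1) - 1L
        a_end <- min(a_start + span - 1L, le)
      }
      if (rp$start_mode[r] == "upstream") {
        p5 <- if (!is.na(rp$upstream_pos[r])) as.integer(rp$upstream_pos[r])
        else if (lstr == "+") ls - sample(50:500, 1)
        else le + sample(50:500, 1)
        if (lstr == "+") a_start <- p5 else a_end <- p5
      }
      aligned <- a_end - a_start + 1L
      gap <- rp$splice_gap[r]
      m1 <- if (gap > 0L) floor((aligned - gap) / 2) else aligned
      m2 <- if (gap > 0L) aligned - gap - m1 else 0L
      body <- if (gap > 0L) sprintf("%dM%dN%dM", m1, gap, m2)
      else sprintf("%dM", aligned)
      # clips are given in read orientation; SAM stores them in
      # alignment orientation
      cl <- if (rstr == "-") rp$clip3[r] else rp$clip5[r]
      cr <- if (rstr == "-") rp$clip5[r] else rp$clip3[r]
      cigar <- paste0(if (cl > 0L) paste0(cl, "S") else "", body,
                      if (cr > 0L) paste0(cr, "S") else "")
      flag <- if (rstr == "-") 16L else 0L
      lines <- c(lines, .sam_line(q, flag, chrom, a_start,
                                  if (rp$nh[r] > 1L) 0L else 60L, cigar,
                                  as.integer(rp$nh[r])))
    }
    ids[[r]] <- row_ids
  }
  writeLines(c(.sam_header(chrom_lengths), lines), path)
  list(sam = path, read_ids = ids)
}

.archetype_profiles <- function(effect = 4) {
  list(flat = c(0, 0, 0, 0),
       up = effect * c(0.4, 0.7, 0.9, 1),
       down = -effect * c(0.4, 0.7, 0.9, 1),
       `up-back` = effect * c(0.5, 1, 0.35, 0.05),
       `down-back` = -effect * c(0.5, 1, 0.35, 0.05))
}

#' Simulate a time-course count matrix with planted archetypes
#'
#' Negative-binomial counts for a common time-zero baseline condition plus
#' one treatment condition sampled at 1, 3, 6 and 12 h, three replicates
#' each. Each feature follows a planted fold-change archetype (`flat`,
#' `up`, `down`, `up-back`, `down-back`).
#'
#' @param features `data.frame` with `feature_id`, `archetype`, and
#'   optionally `base_mean` (default drawn from 100-1000).
#' @param effect Log2 fold-change scale of the archetypes (default 4,
#'   i.e. a 16-fold peak: planted DE features represent strongly
#'   stress-responsive loci that are unambiguously above the |lfc| > 1
#'   call threshold).
#' @param dispersion NB dispersion (default 0.1).
#' @param n_replicates Replicates per condition/timepoint (default 3).
#' @param baseline,treatment Condition labels.
#' @param seed Integer seed.
#' @return `list`: `counts` (matrix), `design` (`data.frame`),
#'   `truth` (features with the profile actually planted).
#' @export
simulate_counts <- function(features, effect = 4, dispersion = 0.1,
                            n_replicates = 3, baseline = "T0",
                            treatment = "Mock", seed = 1) {
  set.seed(seed)
  profiles <- .archetype_profiles(effect)
  stopifnot(all(features$archetype %in% names(profiles)))
  nf <- nrow(features)
  base_mean <- if (is.null(features$base_mean))
    stats::runif(nf, 100, 1000) else features$base_mean
  tps <- c(1, 3, 6, 12)
  design <- rbind(
    data.frame(condition = baseline, timepoint = 0,
               replicate = seq_len(n_replicates)),
    expand.grid(replicate = seq_len(n_replicates), timepoint = tps,
                condition = treatment)[, c("condition", "timepoint",
                                           "replicate")])
  design$sample <- sprintf("%s_%gh_r%d", design$condition,
                           design$timepoint, design$replicate)
  size <- 1 / dispersion
  counts <- matrix(0L, nf, nrow(design),
                   dimnames = list(features$feature_id, design$sample))
  for (s in seq_len(nrow(design))) {
    tp <- design$timepoint[s]
    mu <- if (design$condition[s] == baseline) base_mean
    else {
      fc <- vapply(features$archetype, function(a)
        profiles[[a]][match(tp, tps)], numeric(1))
      base_mean * 2^fc
    }
    counts[, s] <- stats::rnbinom(nf, mu = mu, size = size)
  }
  truth <- features
  truth$base_mean <- base_mean
  truth$is_de_planted <- features$archetype != "flat"
  list(counts = counts, design = design[, c("sample", "condition",
                                            "timepoint", "replicate")],
       truth = truth)
}
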