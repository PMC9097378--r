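te_plus <- function() make_te("chr1", 10001, 14000, strand = "+",
                              canonical_length = 4000L, intact = TRUE)

test_that("sense-overlap collection is strand- and overlap-aware", {
  locus <- te_plus()
  lr <- make_long_reads("chr1",
                        start = c(11001, 11001, 14000, 14001, 9000),
                        end = c(12000, 12000, 14500, 15000, 9500),
                        strand = c("+", "-", "+", "+", "+"))
  sense <- sense_overlap_reads(lr, locus)
  # antisense excluded; the 1 bp overlap at 14000 included; the
  # alignment starting at 14001 and the distant one excluded
  expect_identical(sense$records$read_id, c("lr001", "lr003"))
})

test_that("start categories follow the strand-aware 5' rule", {
  locus <- te_plus()
  within2 <- make_long_reads("chr1", c(10001, 12000), c(11000, 13500))
  expect_identical(start_category(within2, locus), "All_within")
  up2 <- make_long_reads("chr1", c(9500, 9900), c(11000, 13500))
  expect_identical(start_category(up2, locus), "All_upstream")
  mix <- make_long_reads("chr1", c(9500, 12000), c(11000, 13500))
  expect_identical(start_category(mix, locus), "Mix")
  # Mix iff both subsets are non-empty (property over random cohorts)
  set.seed(9)
  for (i in 1:10) {
    n <- sample(2:6, 1)
    starts <- sample(9000:13000, n)
    lr <- make_long_reads("chr1", starts, starts + 800)
    got <- start_category(lr, locus)
    upstream <- starts < 10001
    want <- if (all(upstream)) "All_upstream"
    else if (any(upstream)) "Mix" else "All_within"
    expect_identical(got, want)
  }
  # minus-strand locus: upstream is to the genomic right
  locus_m <- make_te("chr2", 10001, 14000, strand = "-")
  up_m <- make_long_reads("chr2", 13000, 14500, strand = "-")
  expect_identical(start_category(up_m, locus_m), "All_upstream")
  expect_error(start_category(make_long_reads("chr1", integer(0),
                                              integer(0)), locus),
               "at least one")
})

test_that("read-through origin is classified against the compartment map", {
  genes <- make_genes(list(g = gr("chr1", c(8001, 9501), c(8400, 9900))))
  comp <- build_compartments(genes, 2000, seqlengths = c(chr1 = 50000L))
  locus <- te_plus()
  # starts: one in the exon, two in the intron, one intergenic
  lr <- make_long_reads("chr1", c(8200, 8600, 8700, 5000, 11000),
                        c(11000, 11000, 11000, 11000, 12000))
  expect_identical(origin_category(lr, locus, comp), "intronic")
  exonic_only <- make_long_reads("chr1", 8200, 11000)
  expect_identical(origin_category(exonic_only, locus, comp), "exonic")
  no_gene <- make_long_reads("chr1", 9980, 11000)  # flank start: no gene unit
  expect_identical(origin_category(no_gene, locus, comp), "no_gene")
  # tie between exonic and intronic resolves to exonic
  tie <- make_long_reads("chr1", c(8200, 8600), c(11000, 11000))
  expect_identical(origin_category(tie, locus, comp), "exonic")
  within_only <- make_long_reads("chr1", 11000, 12000)
  expect_true(is.na(origin_category(within_only, locus, comp)))
})

test_that("breadth of coverage equals a per-base bitmap oracle", {
  feat <- gr("chr1", 11001, 12000)
  one <- make_long_reads("chr1", 11001, 12000)
  expect_equal(breadth_of_coverage(one, feat), 1.0)
  halves <- make_long_reads("chr1", c(11001, 11501), c(11500, 12000))
  expect_equal(breadth_of_coverage(halves, feat), 1.0)  # union, not sum
  partial <- make_long_reads("chr1", c(11001, 11301), c(11250, 11500))
  expect_equal(breadth_of_coverage(partial, feat), 0.45)
  expect_equal(breadth_of_coverage(
    make_long_reads("chr1", integer(0), integer(0)), feat), 0)
  set.seed(14)
  for (i in 1:10) {
    n <- sample(1:8, 1)
    starts <- sample(10500:12500, n)
    ends <- starts + sample(50:800, n, replace = TRUE)
    lr <- make_long_reads("chr1", starts, ends)
    bitmap <- logical(1000)
    for (j in seq_len(n)) {
      a <- max(starts[j], 11001); b <- min(ends[j], 12000)
      if (a <= b) bitmap[(a - 11000):(b - 11000)] <- TRUE
    }
    expect_equal(breadth_of_coverage(lr, feat), mean(bitmap))
  }
})

test_that("alignment ends are typed clipped > external > internal", {
  locus <- te_plus()
  lr <- make_long_reads("chr1",
                        start = c(11001, 9500, 11001, 11001),
                        end = c(13000, 13000, 14500, 13000),
                        clip5 = c(0L, 0L, 0L, 0L),
                        clip3 = c(0L, 0L, 0L, 150L))
  ends <- classify_ends(lr, locus, clip_min = 20)
  expect_identical(ends$end5, c("internal", "external", "internal",
                                "internal"))
  expect_identical(ends$end3, c("internal", "internal", "external",
                                "clipped"))
  # clip below clip_min falls back to the positional label
  small <- make_long_reads("chr1", 11001, 13000, clip3 = 10L)
  expect_identical(classify_ends(small, locus)$end3, "internal")
  # minus-strand read: biological 5' is the right end
  lr_m <- make_long_reads("chr1", 11001, 14500, strand = "-")
  locus_m <- make_te("chr1", 10001, 14000, strand = "-")
  e_m <- classify_ends(lr_m, locus_m)
  expect_identical(c(e_m$end5, e_m$end3), c("external", "internal"))
})

test_that("full-length evidence needs feature-length reads mostly aligned", {
  cfg <- analysis_config()
  r1 <- make_long_reads("chr1", 10001, 14084, read_length = 4200L,
                        mapped_bases = 3990L)   # 0.95 mapped fraction
  expect_true(full_length_evidence(r1, 4084, cfg))
  r2 <- make_long_reads("chr1", 10001, 12900, read_length = 2900L,
                        mapped_bases = 2900L)   # shorter than the INT
  expect_false(full_length_evidence(r2, 4084, cfg))
  r3 <- make_long_reads("chr1", 10001, 12500, read_length = 5000L,
                        mapped_bases = 2500L)   # mapped fraction 0.5
  expect_false(full_length_evidence(r3, 4084, cfg))
})

test_that("planted long-read geometry round-trips through SAM", {
  ref <- shared_reference()
  te <- ref$te
  m <- ref$manifest$loci
  comp <- shared_compartments()
  id <- m$locus_id[m$intact & m$superfamily == "Copia"][1]
  rp <- data.frame(locus_id = id,
                   n_reads = c(3L, 2L, 2L),
                   start_mode = c("within", "upstream", "within"),
                   clip5 = 0L,
                   clip3 = c(0L, 0L, 150L),
                   full_feature = c(TRUE, FALSE, TRUE))
  path <- withr::local_tempfile(fileext = ".sam")
  sim <- simulate_long_read_alignments(te, rp, shared_chrom_lengths(),
                                       path, seed = 5)
  lr <- read_long_read_alignments(sim$sam)
  expect_identical(length(lr$records), 7L)
  pr <- locus_transcription_profile(lr, te, id, comp)
  expect_identical(pr$n_sense_reads, 7L)
  expect_identical(pr$start_category, "Mix")
  expect_equal(pr$breadth, 1.0)
  # the 150 bp 3' soft-clips come back as clipped ends
  sense <- sense_overlap_reads(lr, te[id])
  ends <- classify_ends(sense, te[id])
  clipped <- ends$read_id[ends$end3 == "clipped"]
  expect_setequal(clipped, sim$read_ids[[3]])
  # full-feature reads with small clips carry full-length evidence
  expect_true(all(sim$read_ids[[1]] %in% pr$full_length_read_ids))
})

test_that("autonomous-candidate selection gates on breadth, not read proof", {
  ref <- shared_reference()
  te <- ref$te
  m <- ref$manifest$loci
  comp <- shared_compartments()
  intact <- m$locus_id[m$intact]
  covered <- intact[1:2]
  rp <- data.frame(locus_id = covered, n_reads = c(2L, 3L),
                   full_feature = TRUE)
  path <- withr::local_tempfile(fileext = ".sam")
  sim <- simulate_long_read_alignments(te, rp, shared_chrom_lengths(),
                                       path, seed = 6)
  lr <- read_long_read_alignments(sim$sam)
  sel <- select_autonomous_candidates(lr, te, comp)
  expect_setequal(sel$locus_id, covered)
  expect_true(all(sel$breadth > 0.9))
  expect_true(all(sel$n_full_length_reads > 0))
  # partial coverage (no full-feature read) stays unselected
  part <- data.frame(locus_id = intact[3], n_reads = 1L,
                     full_feature = FALSE)
  path2 <- withr::local_tempfile(fileext = ".sam")
  sim2 <- simulate_long_read_alignments(te, part, shared_chrom_lengths(),
                                        path2, seed = 7)
  lr2 <- read_long_read_alignments(sim2$sam)
  sel2 <- select_autonomous_candidates(lr2, te, comp)
  expect_false(intact[3] %in% sel2$locus_id)
})

test_that("mirroring coordinates and strands leaves all labels unchanged", {
  L <- 30000L  # mirror: x -> L + 1 - x
  genes <- make_genes(list(g = gr("chr1", c(8001, 9501), c(8400, 9900))))
  comp <- build_compartments(genes, 2000, seqlengths = c(chr1 = L))
  locus <- te_plus()
  lr <- make_long_reads("chr1", c(8200, 11000, 9000),
                        c(11000, 12000, 13500),
                        clip5 = c(0L, 30L, 0L), clip3 = c(150L, 0L, 0L))
  mirror_gr <- function(g) {
    out <- gr("chr1", L + 1L - GenomicRanges::end(g),
              L + 1L - GenomicRanges::start(g),
              strand = ifelse(as.character(GenomicRanges::strand(g)) == "+",
                              "-", "+"))
    S4Vectors::mcols(out) <- S4Vectors::mcols(g)
    out
  }
  genes_m <- make_genes(list(g = mirror_gr(genes$exons[["g"]])))
  comp_m <- build_compartments(genes_m, 2000, seqlengths = c(chr1 = L))
  locus_m <- mirror_gr(locus)
  lr_m <- structure(list(records = mirror_gr(lr$records),
                         blocks = S4Vectors::split(
                           GenomicRanges::granges(mirror_gr(lr$records)),
                           1:3)),
                    class = "long_reads")
  s1 <- sense_overlap_reads(lr, locus)
  s2 <- sense_overlap_reads(lr_m, locus_m)
  expect_identical(length(s1$records), length(s2$records))
  expect_identical(start_category(s1, locus), start_category(s2, locus_m))
  expect_identical(origin_category(s1, locus, comp),
                   origin_category(s2, locus_m, comp_m))
  e1 <- classify_ends(s1, locus)
  e2 <- classify_ends(s2, locus_m)
  expect_identical(e1[, c("end5", "end3")], e2[, c("end5", "end3")])
  expect_equal(breadth_of_coverage(s1, locus),
               breadth_of_coverage(s2, locus_m))
})
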