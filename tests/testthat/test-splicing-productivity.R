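# reference gene used throughout: three exons on the plus strand
ref_iso <- function(strand = "+")
  isoform_model("ref.1", "g1",
                gr("chr1", c(1001, 1501, 2001), c(1100, 1600, 2100),
                   strand = strand))

# write a motif into an all-C chromosome
put <- function(seq, pos, s) {
  substr(seq, pos, pos + nchar(s) - 1) <- s
  seq
}
blank_genome <- function(len = 3000)
  paste(rep("C", len), collapse = "")

test_that("alternative-splicing features are typed against the reference", {
  ref <- ref_iso()
  expect_length(detect_as_features(ref, ref), 0L)
  ir <- isoform_model("iso.ir", "g1",
                      gr("chr1", c(1001, 2001), c(1600, 2100)))
  f_ir <- detect_as_features(ir, ref)
  expect_identical(as.character(f_ir$type), "IR")
  expect_identical(c(GenomicRanges::start(f_ir), GenomicRanges::end(f_ir)),
                   c(1101L, 1500L))
  es <- isoform_model("iso.es", "g1",
                      gr("chr1", c(1001, 2001), c(1100, 2100)))
  f_es <- detect_as_features(es, ref)
  expect_identical(as.character(f_es$type), "ES")
  expect_identical(c(GenomicRanges::start(f_es), GenomicRanges::end(f_es)),
                   c(1501L, 1600L))
  # shifted acceptor of intron 1 (transcript 3' side on the plus strand)
  a3 <- isoform_model("iso.a3", "g1",
                      gr("chr1", c(1001, 1521, 2001), c(1100, 1600, 2100)))
  f_a3 <- detect_as_features(a3, ref)
  expect_identical(as.character(f_a3$type), "Alt3")
  expect_identical(c(GenomicRanges::start(f_a3), GenomicRanges::end(f_a3)),
                   c(1501L, 1520L))
  # shifted donor (5' side): exon 1 shortened
  a5 <- isoform_model("iso.a5", "g1",
                      gr("chr1", c(1001, 1501, 2001), c(1080, 1600, 2100)))
  expect_identical(as.character(detect_as_features(a5, ref)$type), "Alt5")
  expect_error(detect_as_features(ref_iso("-"), ref), "strand")
})

test_that("the same genomic shift swaps Alt5/Alt3 on the minus strand", {
  ref_m <- ref_iso("-")
  a_m <- isoform_model("iso.m", "g1",
                       gr("chr1", c(1001, 1521, 2001), c(1100, 1600, 2100),
                          strand = "-"))
  # on the minus strand the shifted intron edge is the donor side
  expect_identical(as.character(detect_as_features(a_m, ref_m)$type),
                   "Alt5")
})

test_that("feature-TE overlaps are recorded with their sizes", {
  ref <- ref_iso()
  ir <- isoform_model("iso.ir", "g1",
                      gr("chr1", c(1001, 2001), c(1600, 2100)))
  feats <- detect_as_features(ir, ref)
  te <- c(make_te("chr1", 1201, 1300),
          make_te("chr1", 20001, 20300, family = "FamB"))
  ann <- annotate_te_overlap(feats, te)
  expect_identical(unlist(ann$te_ids), te$locus_id[1])
  expect_identical(unlist(ann$te_overlap_bp), 100L)  # TE wholly inside IR
  far <- annotate_te_overlap(feats, te[2])
  expect_length(unlist(far$te_ids), 0L)
})

test_that("productivity classes cover PRO, PTC, NGO and NST", {
  ref <- ref_iso()
  # ATG at transcript position 10; stop in the final exon -> PRO
  g_pro <- Biostrings::DNAStringSet(c(
    chr1 = put(put(blank_genome(), 1010, "ATG"), 2050, "TAA")))
  pro <- classify_productivity(ref, g_pro)
  expect_identical(pro$class, "PRO")
  expect_identical(pro$start_pos, 10L)
  expect_identical(pro$stop_pos, 252L)
  # in-frame stop 68 nt upstream of the final junction (200) -> PTC
  g_ptc <- Biostrings::DNAStringSet(c(
    chr1 = put(put(blank_genome(), 1010, "ATG"), 1530, "TAA")))
  ptc <- classify_productivity(ref, g_ptc)
  expect_identical(ptc$class, "PTC")
  expect_identical(ptc$stop_pos, 132L)
  expect_identical(classify_productivity(
    ref, Biostrings::DNAStringSet(c(chr1 = blank_genome())))$class, "NGO")
  expect_identical(classify_productivity(
    ref, Biostrings::DNAStringSet(c(
      chr1 = put(blank_genome(), 1010, "ATG"))))$class, "NST")
  # a single-exon isoform has no junction and cannot be PTC
  mono <- isoform_model("mono", "g1", gr("chr1", 1001, 1600))
  g_mono <- Biostrings::DNAStringSet(c(
    chr1 = put(put(blank_genome(), 1010, "ATG"), 1529, "TAA")))
  expect_identical(classify_productivity(mono, g_mono)$class, "PRO")
  bad <- Biostrings::DNAStringSet(c(chr1 = put(blank_genome(), 1050, "W")))
  expect_error(classify_productivity(ref, bad), "non-ACGTN")
})

test_that("productivity is invariant under reverse-complement mirroring", {
  L <- 3000L
  g_plus <- put(put(blank_genome(L), 1010, "ATG"), 1530, "TAA")
  mirror <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  g_minus <- Biostrings::DNAStringSet(c(chr1 = mirror(g_plus)))
  iso_m <- isoform_model("ref.m", "g1",
                         gr("chr1", L + 1L - c(2100, 1600, 1100),
                            L + 1L - c(2001, 1501, 1001), strand = "-"))
  call_p <- classify_productivity(
    ref_iso(), Biostrings::DNAStringSet(c(chr1 = g_plus)))
  call_m <- classify_productivity(iso_m, g_minus)
  expect_identical(call_m$class, call_p$class)
  expect_identical(call_m$start_pos, call_p$start_pos)
  expect_identical(call_m$stop_pos, call_p$stop_pos)
})

test_that("premature stops are located relative to the TE projection", {
  # IR isoform: intron 1 retained; TE inside the retained intron
  iso <- isoform_model("iso.ir", "g1",
                       gr("chr1", c(1001, 2001), c(1600, 2100)))
  te <- make_te("chr1", 1520, 1580)
  # stop upstream of the TE projection
  g1 <- Biostrings::DNAStringSet(c(
    chr1 = put(put(blank_genome(), 1010, "ATG"), 1100, "TAA")))
  call1 <- classify_productivity(iso, g1)
  expect_identical(call1$class, "PTC")
  loc1 <- locate_stop_vs_te(call1, iso, te)
  # TE transcript projection starts at 520; stop codon ends at 102
  expect_identical(loc1$stop_vs_te, "before")
  expect_identical(loc1$distance_bp, 418L)
  # stop inside the TE projection (transcript 520-580; stop ends at 522)
  g2 <- Biostrings::DNAStringSet(c(
    chr1 = put(put(blank_genome(), 1010, "ATG"), 1520, "TAA")))
  call2 <- classify_productivity(iso, g2)
  loc2 <- locate_stop_vs_te(call2, iso, te)
  expect_identical(loc2$stop_vs_te, "within")
  expect_true(is.na(loc2$distance_bp))
  # the same stop lies 3' of an earlier TE (projection 220-280)
  te_early <- make_te("chr1", 1220, 1280, family = "FamB")
  loc3 <- locate_stop_vs_te(call2, iso, te_early)
  expect_identical(loc3$stop_vs_te, "after")
  expect_identical(loc3$distance_bp, 242L)
  expect_error(locate_stop_vs_te(list(class = "PRO"), iso, te), "PTC")
})

test_that("a constructed before-distance of 311 bp is measured exactly", {
  te <- make_te("chr1", 1520, 1580)
  iso2 <- isoform_model("iso.ir2", "g1",
                        gr("chr1", c(1001, 2301), c(1600, 2400)))
  # ATG at transcript 12; stop codon at 207-209; the TE projects to
  # transcript 520-580, so the stop-to-TE gap is 311 bp
  g <- Biostrings::DNAStringSet(c(
    chr1 = put(put(blank_genome(), 1012, "ATG"), 1207, "TAA")))
  call <- classify_productivity(iso2, g)
  expect_identical(call$class, "PTC")
  expect_identical(call$stop_pos, 209L)
  loc <- locate_stop_vs_te(call, iso2, te)
  expect_identical(loc$stop_vs_te, "before")
  expect_identical(loc$distance_bp, 311L)
})

test_that("planted TE-in-retained-intron constructions split PTC vs PRO", {
  # a four-exon gene whose second intron carries a TE with an in-frame
  # stop: the intron-retaining isoform is PTC (the stop sits upstream of
  # the final junction), the clean isoform is PRO. Offsets are drawn per
  # repetition; reading frames are offset-invariant by construction.
  set.seed(77)
  for (i in 1:5) {
    offset <- sample(500:1500, 1)
    e1 <- c(offset + 1L, offset + 100L)     # transcript 1-100
    e2 <- c(offset + 401L, offset + 500L)   # clean transcript 101-200
    e3 <- c(offset + 901L, offset + 1000L)  # clean transcript 201-300
    e4 <- c(offset + 1301L, offset + 1400L) # clean transcript 301-400
    g <- blank_genome(4000)
    g <- put(g, e1[1] + 9L, "ATG")           # start at transcript 10
    # TE inside intron 2 with an in-frame (IR-transcript) stop
    te <- make_te("chr1", offset + 550L, offset + 610L)
    g <- put(g, offset + 562L, "TAA")
    # clean isoform stop in exon 4, in frame
    g <- put(g, e4[1] + 9L, "TAA")
    genome <- Biostrings::DNAStringSet(c(chr1 = g))
    clean <- isoform_model("clean", "g1",
                           gr("chr1", c(e1[1], e2[1], e3[1], e4[1]),
                              c(e1[2], e2[2], e3[2], e4[2])))
    ir <- isoform_model("ir", "g1",
                        gr("chr1", c(e1[1], e2[1], e4[1]),
                           c(e1[2], e3[2], e4[2])))
    expect_identical(classify_productivity(clean, genome)$class, "PRO",
                     info = paste("rep", i))
    call_ir <- classify_productivity(ir, genome)
    expect_identical(call_ir$class, "PTC", info = paste("rep", i))
    loc <- locate_stop_vs_te(call_ir, ir, te)
    expect_identical(loc$stop_vs_te, "within")
  }
})
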