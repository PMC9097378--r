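test_that("read-count filters are strict at their boundaries", {
  counts <- c(a = 10, b = 11, c = 0)
  expect_identical(unname(filter_unique(counts, 10)),
                   c(FALSE, TRUE, FALSE))
  stats <- data.frame(locus_id = c("a", "b", "c"),
                      total_count = c(11, 100, 11),
                      covered_bases = c(100, 100, 100),
                      mean_depth = c(5.1, 5.0, 5.1))
  expect_identical(unname(filter_coverage(stats, 10, 5)),
                   c(TRUE, FALSE, TRUE))
  dg <- data.frame(locus_id = c("a", "b", "c"),
                   dangler_left = c(11, 11, 11),
                   dangler_right = c(0, 0, 12),
                   internal_reads = c(11, 11, 10))
  expect_identical(unname(filter_danglers(dg, 10, "any")),
                   c(TRUE, TRUE, FALSE))
  expect_identical(unname(filter_danglers(dg, 10, "both")),
                   c(FALSE, FALSE, FALSE))
})

test_that("raising the unique-count threshold never adds a passing locus", {
  set.seed(1)
  counts <- stats::setNames(rpois(200, 12), sprintf("L%03d", 1:200))
  prev <- filter_unique(counts, 5)
  for (thr in 6:20) {
    cur <- filter_unique(counts, thr)
    expect_true(all(!cur | prev))
    prev <- cur
  }
})

test_that("unique counting drops reads that touch two TE loci", {
  te <- make_te("chr1", c(1001, 2001), c(1900, 2900),
                family = c("FamA", "FamB"))
  aln <- c(make_aln("chr1", 1100, 1199),              # inside locus 1
           make_aln("chr1", 1850, 2050),              # spans both: ambiguous
           make_aln("chr1", 3000, 3099))              # outside both
  counts <- count_unique_overlaps(aln, te)
  expect_identical(unname(counts), c(1L, 0L))
  # multi-mapping reads never enter the unique counter
  aln_multi <- make_aln("chr1", 1100, 1199, is_unique = FALSE)
  expect_identical(unname(count_unique_overlaps(aln_multi, te)), c(0L, 0L))
})

test_that("coverage statistics follow the worked examples", {
  te <- make_te("chr1", 1001, 1200)  # 200 bp locus
  tiling <- make_aln("chr1", c(1001, 1101), c(1100, 1200))
  st <- compute_coverage_stats(tiling, te)
  expect_identical(st$covered_bases, 200L)
  expect_equal(st$mean_depth, 1.0)
  stack <- make_aln("chr1", rep(1001, 5), rep(1100, 5))
  st2 <- compute_coverage_stats(stack, te)
  expect_identical(st2$covered_bases, 100L)
  expect_equal(st2$mean_depth, 5.0)
  expect_identical(st2$total_count, 5L)
})

test_that("coverage matches a naive per-base oracle on random pileups", {
  set.seed(7)
  te <- make_te("chr1", c(501, 2001), c(1500, 2600),
                family = c("FamA", "FamB"))
  for (rep in 1:5) {
    n <- sample(20:60, 1)
    starts <- sample(300:2800, n, replace = TRUE)
    widths <- sample(50:150, n, replace = TRUE)
    aln <- make_aln("chr1", starts, starts + widths - 1)
    st <- compute_coverage_stats(aln, te)
    for (i in seq_along(te)) {
      lo <- GenomicRanges::start(te)[i]
      hi <- GenomicRanges::end(te)[i]
      depth <- integer(hi - lo + 1)
      for (j in seq_along(aln)) {
        a <- max(GenomicRanges::start(aln)[j], lo)
        b <- min(GenomicRanges::end(aln)[j], hi)
        if (a <= b) {
          idx <- (a - lo + 1):(b - lo + 1)
          depth[idx] <- depth[idx] + 1L
        }
      }
      expect_identical(st$covered_bases[i], sum(depth > 0))
      expect_equal(st$mean_depth[i],
                   if (any(depth > 0)) sum(depth) / sum(depth > 0) else 0)
      expect_identical(st$total_count[i],
                       sum(GenomicRanges::start(aln) <= hi &
                             GenomicRanges::end(aln) >= lo))
    }
  }
})

test_that("danglers assign by side, orientation and window; tails excluded", {
  te <- make_te("chr1", 5001, 6000)
  lib <- c("d1", "d2", "d3", "d4", "d5", "tail1")
  aln <- c(
    make_aln("chr1", 4701, 4800, read_id = "d1"),             # left, ->
    make_aln("chr1", 4701, 4800, strand = "-", read_id = "d2"), # wrong strand
    make_aln("chr1", 3801, 3900, read_id = "d3"),             # outside window
    make_aln("chr1", 6101, 6200, strand = "-", read_id = "d4"), # right, <-
    make_aln("chr1", 4701, 4800, read_id = "nolib"),          # mate not in lib
    make_aln("chr1", 4951, 5050, read_id = "tail1"),          # straddles start
    make_aln("chr1", 5101, 5200, read_id = "d5"))             # internal
  dg <- find_danglers(aln, lib, te, window = 1000, exclude_tails = TRUE)
  expect_identical(dg$dangler_left, 1L)
  expect_identical(dg$dangler_right, 1L)
  # internal: d5 and nothing else maps wholly inside
  expect_identical(dg$internal_reads, 1L)
  # without tail exclusion the straddler still fails the side geometry
  dg2 <- find_danglers(aln, lib, te, window = 1000, exclude_tails = FALSE)
  expect_identical(dg2$dangler_left, 1L)
})

test_that("planted dangler and internal counts are recovered exactly", {
  ref <- shared_reference()
  te <- ref$te
  plan <- data.frame(locus_id = te$locus_id[5],
                     n_unique = 0L, n_dangler_left = 15L,
                     n_dangler_right = 0L, n_multi = 20L,
                     multi_group = "grp")
  path <- withr::local_tempfile(fileext = ".sam")
  sim <- simulate_short_read_alignments(te, plan, shared_chrom_lengths(),
                                        path, seed = 21)
  aln <- read_short_read_alignments(sim$sam)
  dg <- find_danglers(aln, sim$te_library_hits, te)
  expect_identical(dg$dangler_left[5], 15L)
  expect_identical(dg$dangler_right[5], 0L)
  expect_identical(dg$internal_reads[5], 20L)
  expect_true(filter_danglers(dg, 10, "any")[5])
  expect_false(filter_danglers(dg, 10, "both")[5])
})

test_that("the candidate pool is the union of the three filters", {
  ref <- shared_reference()
  te <- ref$te
  ids <- te$locus_id
  plan <- data.frame(
    locus_id = ids[1:12],
    n_unique = c(rep(20L, 4), rep(0L, 8)),
    n_dangler_left = c(rep(0L, 8), rep(15L, 4)),
    n_multi = c(rep(0L, 4), rep(30L, 4), rep(15L, 4)),
    multi_group = c(rep(NA, 4), rep(c("a", "b"), each = 2), rep("c", 4)))
  path <- withr::local_tempfile(fileext = ".sam")
  sim <- simulate_short_read_alignments(te, plan, shared_chrom_lengths(),
                                        path, seed = 8)
  aln <- read_short_read_alignments(sim$sam)
  uc <- count_unique_overlaps(aln, te)
  cov <- compute_coverage_stats(aln, te)
  dg <- find_danglers(aln, sim$te_library_hits, te)
  calls <- assemble_candidates(te, uc, cov, dg)

  # independent set-algebra oracle over the three filter verdicts
  f1 <- names(which(filter_unique(uc, 10)))
  f2 <- names(which(filter_coverage(cov, 10, 5)))
  f3 <- names(which(filter_danglers(dg, 10, "any")))
  expect_setequal(calls$locus_id[calls$is_candidate],
                  union(union(f1, f2), f3))
  # dropping any one filter never grows the pool
  for (drop in list(c(f2, f3), c(f1, f3), c(f1, f2))) {
    expect_true(all(unique(drop) %in%
                      calls$locus_id[calls$is_candidate]))
  }
  # trackability is equivalent to unique-read presence
  expect_identical(calls$trackable, calls$unique_count > 0L)
  # exclusion accounting partitions the annotation
  es <- exclusion_summary(calls)
  expect_identical(sum(es$n), nrow(calls))
})

test_that("integrity and the full-length call sit strictly above 0.9", {
  te <- c(make_te("chr1", 1001, 1910, canonical_length = 1000L),
          make_te("chr1", 5001, 5900, family = "FamB",
                  canonical_length = 1000L))
  zero <- stats::setNames(integer(2), te$locus_id)
  cov <- data.frame(locus_id = te$locus_id, total_count = 0L,
                    covered_bases = 0L, mean_depth = 0)
  dg <- data.frame(locus_id = te$locus_id, dangler_left = 0L,
                   dangler_right = 0L, internal_reads = 0L)
  calls <- assemble_candidates(te, zero, cov, dg)
  expect_equal(calls$integrity, c(0.91, 0.90))
  expect_identical(calls$is_full_length, c(TRUE, FALSE))
})

test_that("planted expressed loci are all recalled; zero-read loci never called", {
  ref <- shared_reference()
  te <- ref$te
  ids <- te$locus_id
  expressed <- ids[seq(1, 40, by = 2)]
  plan <- data.frame(locus_id = expressed, n_unique = 11L)
  path <- withr::local_tempfile(fileext = ".sam")
  sim <- simulate_short_read_alignments(te, plan, shared_chrom_lengths(),
                                        path, seed = 13)
  aln <- read_short_read_alignments(sim$sam)
  calls <- assemble_candidates(
    te, count_unique_overlaps(aln, te), compute_coverage_stats(aln, te),
    find_danglers(aln, sim$te_library_hits, te))
  called <- calls$locus_id[calls$is_candidate]
  expect_setequal(called, expressed)          # recall 1.0, no false calls
  zero <- calls$unique_count == 0 & calls$total_count == 0
  expect_false(any(calls$is_candidate[zero]))
})
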