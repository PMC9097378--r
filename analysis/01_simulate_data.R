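#!/usr/bin/env Rscript
# Builds the synthetic study cohort every later step consumes: a toy
# genome with annotated genes and TE loci (known compartments, planted
# LTR divergences), short-read alignments with planted per-locus
# evidence, long-read alignments over the structurally intact loci, and
# a time-course count matrix with planted fold-change archetypes.
# Outputs land under scratch/synthetic_data/ (bulky, regenerable); the
# later scripts read them from there and write their tables to results/.

suppressMessages(library(teloci))
set.seed(1)

out <- "scratch/synthetic_data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

plan <- simulation_plan()
ref <- generate_reference(plan, seed = 11)
paths <- write_reference(ref, out)
chrom_lengths <- stats::setNames(rep(plan$chrom_length, plan$n_chromosomes),
                                 paste0("chr", seq_len(plan$n_chromosomes)))
te <- ref$te
cat(sprintf("reference: %d genes, %d TE loci (%d structurally intact)\n",
            length(ref$genes$bounds), length(te),
            sum(te$structurally_intact)))

## short reads: 30 trackable loci, 10 multi-only loci in two families,
## 3 dangler-supported loci
expressed <- sort(sample(te$locus_id, 40))
trackable <- expressed[1:30]
multi_only <- expressed[31:40]
dangler_loci <- sample(setdiff(te$locus_id, expressed), 3)
n_multi <- ceiling(max(GenomicRanges::width(
  te[match(multi_only, te$locus_id)])) * 5 / 150) + 10L
counts_plan <- rbind(
  data.frame(locus_id = trackable, n_unique = 15L, n_multi = 0L,
             multi_group = NA, n_dangler_left = 0L, n_dangler_right = 0L),
  data.frame(locus_id = multi_only, n_unique = 0L, n_multi = n_multi,
             multi_group = rep(c("m1", "m2"), each = 5),
             n_dangler_left = 0L, n_dangler_right = 0L),
  data.frame(locus_id = dangler_loci, n_unique = 0L, n_multi = 12L,
             multi_group = c("d1", "d2", "d3"),
             n_dangler_left = 14L, n_dangler_right = 12L))
sr <- simulate_short_read_alignments(te, counts_plan, chrom_lengths,
                                     file.path(out, "short_reads.sam"),
                                     seed = 12)
writeLines(sr$te_library_hits, file.path(out, "te_library_hits.txt"))
write.table(counts_plan, file.path(out, "planted_short_reads.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("short reads: planted evidence at %d loci (%d trackable)\n",
            nrow(counts_plan), length(trackable)))

## long reads over the intact loci: full-feature coverage for most,
## read-through (upstream) initiation at a couple, clipped tails
m <- ref$manifest$loci
intact <- m$locus_id[m$intact]
read_plan <- rbind(
  data.frame(locus_id = intact, n_reads = 3L, start_mode = "within",
             clip3 = 0L, full_feature = TRUE),
  data.frame(locus_id = intact[1:2], n_reads = 2L, start_mode = "upstream",
             clip3 = 0L, full_feature = FALSE),
  data.frame(locus_id = intact[1], n_reads = 2L, start_mode = "within",
             clip3 = 150L, full_feature = TRUE))
lr <- simulate_long_read_alignments(te, read_plan, chrom_lengths,
                                    file.path(out, "long_reads.sam"),
                                    seed = 13)
write.table(read_plan, file.path(out, "planted_long_reads.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("long reads: %d records over %d intact loci\n",
            sum(read_plan$n_reads), length(intact)))

## counts: genic TEs share their host gene's archetype 90% of the time
comp <- build_compartments(ref$genes, plan$flank_width, chrom_lengths)
assign <- assign_location(te, comp)
genic <- assign[assign$region == "genic" &
                  assign$locus_id %in% trackable, ]
archetypes <- c("up", "down", "up-back", "down-back")
genes <- unique(genic$gene_id)
g_arch <- stats::setNames(sample(archetypes, length(genes), TRUE), genes)
share <- stats::runif(nrow(genic)) < 0.9
t_arch <- ifelse(share, g_arch[genic$gene_id],
                 vapply(g_arch[genic$gene_id], function(a)
                   sample(setdiff(archetypes, a), 1), ""))
feats <- data.frame(
  feature_id = c(genes, genic$locus_id),
  archetype = c(unname(g_arch), t_arch))
cm <- simulate_counts(feats, seed = 14)
write.table(cbind(feature_id = rownames(cm$counts), cm$counts),
            file.path(out, "counts.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(cm$design, file.path(out, "design.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cbind(cm$truth, planted_share = c(rep(NA, length(genes)),
                                              share)),
            file.path(out, "planted_counts.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("counts: %d genes + %d genic TE loci, %d samples, %.0f%% of\n",
            length(genes), nrow(genic), nrow(cm$design),
            100 * mean(share)))
cat("  TE-gene pairs sharing their planted expression archetype\n")
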