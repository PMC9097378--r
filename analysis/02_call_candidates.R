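#!/usr/bin/env Rscript
# Runs the three read-evidence filters over the simulated short-read
# alignments and unites them into the TE expression-candidate pool, then
# summarises trackability, integrity and per-family composition.

suppressMessages(library(teloci))

dat <- "scratch/synthetic_data"
out <- "results"
cl <- read.delim(file.path(dat, "te_canonical_lengths.tsv"))
sf <- read.delim(file.path(dat, "te_sub_features.tsv"))
te <- read_te_annotation(file.path(dat, "te_loci.bed"), cl, sf)
aln <- read_short_read_alignments(file.path(dat, "short_reads.sam"))
lib_hits <- readLines(file.path(dat, "te_library_hits.txt"))

uc <- count_unique_overlaps(aln, te)
cov <- compute_coverage_stats(aln, te)
dg <- find_danglers(aln, lib_hits, te)
calls <- assemble_candidates(te, uc, cov, dg)
write.table(calls, file.path(out, "candidates.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cand <- calls[calls$is_candidate, ]
cat(sprintf("%d of %d annotated loci are expression candidates\n",
            nrow(cand), nrow(calls)))
cat(sprintf("  filters (unique / coverage / dangler): %d / %d / %d\n",
            sum(cand$passed_filter1), sum(cand$passed_filter2),
            sum(cand$passed_filter3)))
cat(sprintf("  trackable: %d (%.1f%%); full-length: %d (%.1f%%)\n",
            sum(cand$trackable),
            proportion_percent(sum(cand$trackable), nrow(cand), 1),
            sum(cand$is_full_length),
            proportion_percent(sum(cand$is_full_length), nrow(cand), 1)))

es <- exclusion_summary(calls)
write.table(es, file.path(out, "exclusion_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("  excluded: %d below threshold, %d without any evidence\n",
            es$n[es$class == "below_threshold"],
            es$n[es$class == "no_evidence"]))

fs <- family_summary(calls)
write.table(fs, file.path(out, "family_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("  %d families contain candidates; largest: %s (%d)\n",
            nrow(fs), fs$family[1], fs$total[1]))

sharing <- read_class_sharing(aln, te, calls)
write.table(sharing, file.path(out, "read_class_sharing.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("  reads hitting candidates fall into %d class combinations\n",
            nrow(sharing)))
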