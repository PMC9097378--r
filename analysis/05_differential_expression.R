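#!/usr/bin/env Rscript
# Calls differentially expressed TE loci and genes on the simulated
# time course, clusters their fold-change patterns jointly, and scores
# expression-pattern concordance across co-localised DETE-DEG pairs.

suppressMessages(library(teloci))

dat <- "scratch/synthetic_data"
out <- "results"
counts <- as.matrix(read.delim(file.path(dat, "counts.tsv"),
                               row.names = 1, check.names = FALSE))
design <- read.delim(file.path(dat, "design.tsv"))
calls <- read.delim(file.path(out, "candidates.tsv"))
assign <- read.delim(file.path(out, "locus_assignments.tsv"))

de <- de_test(counts, design, c("Mock", "T0"))
write.table(de, file.path(out, "de_results.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# the TE universe is restricted to trackable candidates
trackable <- calls$locus_id[calls$trackable]
is_te <- rownames(counts) %in% calls$locus_id
de_calls <- call_de(de, universe = c(rownames(counts)[!is_te], trackable))
dete <- intersect(de_calls$feature_id[de_calls$is_DE], trackable)
deg <- setdiff(de_calls$feature_id[de_calls$is_DE], calls$locus_id)
cat(sprintf("DE calls: %d DETEs, %d DEGs\n", length(dete), length(deg)))

lfc <- vapply(split(de, de$timepoint), function(d)
  d$log2fc[match(rownames(counts), d$feature_id)],
  numeric(nrow(counts)))
rownames(lfc) <- rownames(counts)
cluster <- cluster_patterns(lfc[c(deg, dete), ])
write.table(cluster, file.path(out, "de_clusters.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
pat <- table(cluster$pattern[cluster$feature_id %in% dete])
cat(sprintf("DETE patterns: %s\n",
            paste(sprintf("%s %d", names(pat), pat), collapse = ", ")))

cl_lengths <- read.delim(file.path(dat, "te_canonical_lengths.tsv"))
te <- read_te_annotation(file.path(dat, "te_loci.bed"), cl_lengths)
genes <- read_gene_annotation(file.path(dat, "genes.gff3"))
comp <- build_compartments(genes, 2000)
labels <- stats::setNames(cluster$cluster, cluster$feature_id)
conc <- pair_and_concordance(te, dete, deg, comp, labels)
write.table(conc$pairs, file.path(out, "dete_deg_pairs.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("%d DETE-DEG pairs, %d concordant (%.2f%%)\n",
            nrow(conc$pairs), sum(conc$pairs$concordant),
            concordance_percent(sum(conc$pairs$concordant),
                                nrow(conc$pairs))))

truth <- read.delim(file.path(dat, "planted_counts.tsv"))
planted <- mean(truth$planted_share, na.rm = TRUE)
cat(sprintf("planted sharing rate was %.2f\n", planted))
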