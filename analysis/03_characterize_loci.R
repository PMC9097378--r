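#!/usr/bin/env Rscript
# Places every annotated TE locus (and the candidate pool) in the
# genomic compartment hierarchy and tests the candidates' location bias
# against the annotation background.

suppressMessages(library(teloci))

dat <- "scratch/synthetic_data"
out <- "results"
genes <- read_gene_annotation(file.path(dat, "genes.gff3"))
cl <- read.delim(file.path(dat, "te_canonical_lengths.tsv"))
te <- read_te_annotation(file.path(dat, "te_loci.bed"), cl)
calls <- read.delim(file.path(out, "candidates.tsv"))

genome <- Biostrings::readDNAStringSet(file.path(dat, "genome.fa"))
names(genome) <- sub(" .*", "", names(genome))
comp <- build_compartments(genes, 2000,
                           stats::setNames(Biostrings::width(genome),
                                           names(genome)))
assign <- assign_location(te, comp)

# expressed genes: those hosting trackable candidates get FPKM above the
# threshold in this cohort; the rest sit below it
cand <- calls[calls$is_candidate, ]
host <- unique(stats::na.omit(
  assign$gene_id[assign$locus_id %in% cand$locus_id]))
expr <- data.frame(gene_id = names(genes$bounds),
                   fpkm = ifelse(names(genes$bounds) %in% host, 5, 0.1))
status <- gene_expression_status(names(genes$bounds), expr)

assign$gene_expressed <- ifelse(is.na(assign$gene_id), NA,
                                unname(status[assign$gene_id]))
assign$is_full_length <- calls$is_full_length[
  match(assign$locus_id, calls$locus_id)]
assign$trackable <- calls$trackable[match(assign$locus_id, calls$locus_id)]
write.table(assign, file.path(out, "locus_assignments.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

ac <- assign[assign$locus_id %in% cand$locus_id, ]
ac$gene_expressed[is.na(ac$gene_expressed)] <- FALSE
h <- hierarchical_summary(ac)
write.table(h, file.path(out, "candidate_hierarchy.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("%d candidates: %d genic (%.1f%%), %d intergenic\n",
            nrow(ac), sum(ac$region == "genic"),
            proportion_percent(sum(ac$region == "genic"), nrow(ac), 1),
            sum(ac$region == "intergenic")))

obs <- table(factor(ac$region, levels = c("genic", "intergenic")))
p_exp <- prop.table(table(factor(assign$region,
                                 levels = c("genic", "intergenic"))))
bias <- chisq_location_bias(c(obs), as.numeric(p_exp))
report <- data.frame(test = "genic_vs_intergenic",
                     statistic = bias$statistic, df = bias$df,
                     p_value = bias$p_value,
                     significant = bias$significant)
write.table(report, file.path(out, "location_bias_tests.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("location-bias chi-square: X2 = %.3f, p = %.3g (%s at 0.01)\n",
            bias$statistic, bias$p_value,
            if (bias$significant) "significant" else "not significant"))
cat("candidates were planted uniformly here, so no bias is expected\n")
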