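#!/usr/bin/env Rscript
# Stage 3: population-genetic characterisation of the herd.
#
# Per-locus genotype and allele frequencies, Hardy-Weinberg test,
# heterozygosity, effective allele number and PIC; then two-locus EM
# haplotype frequencies with D' and r-squared.

library(indelscreen)

out_dir <- "results/analysis"
herd <- read_genotype_table(file.path(out_dir, "herd.csv"))

tab <- locus_stats_table(herd, c("P1", "P2"))
print(tab, digits = 3)
write.table(tab, file.path(out_dir, "locus_stats.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

ld <- em_haplotypes(two_locus_counts(herd, "P1", "P2"))
print(ld)
jsonlite::write_json(
  list(haplotype_freqs = as.list(ld$haplotype_freqs), D = ld$D,
       D_prime = ld$D_prime, r2 = ld$r2,
       em_iterations = ld$em_iterations),
  file.path(out_dir, "ld.json"), auto_unbox = TRUE, digits = NA)
cat("Wrote locus_stats.tsv and ld.json under", out_dir, "\n")
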