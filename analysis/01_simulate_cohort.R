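#!/usr/bin/env Rscript
# Build the synthetic reference cohort: three populations (test, sister,
# outgroup), three chromosomes (chr1 carries a hard sweep, s = 0.05, at its
# centre; chr2/chr3 are neutral background), written out as the same file
# types a real study would start from: a phased VCF with INFO/AA, a sample
# panel TSV, an exon BED and the ground-truth table.
library(sweepscan)

seed <- 3
outdir <- "results/cohort"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

sim <- simulate_study(seed, sweep = TRUE)
cat(sprintf("cohort simulated (seed %d): focal %s:%d, sweep deme %s\n",
            seed, "chr1", sim$focal_pos, sim$sweep_deme))
cat(sprintf("final focal frequency per deme: %s\n",
            paste(names(sim$truth$chr1$focal_freq),
                  round(sim$truth$chr1$focal_freq, 3),
                  sep = "=", collapse = ", ")))

emit_vcf(sim$matrices, file.path(outdir, "cohort.vcf"),
         truth = sim$truth$chr1,
         truth_path = file.path(outdir, "truth_chr1.tsv"))

panel <- data.frame(
  sample = unlist(lapply(sim$matrices, `[[`, "sample_ids")),
  population = rep(names(sim$matrices),
                   vapply(sim$matrices, function(m) length(m$sample_ids),
                          integer(1))))
write.table(panel, file.path(outdir, "panel.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE, col.names = FALSE)

ex <- study_exon_model()
write.table(ex$intervals, file.path(outdir, "exons.bed"), sep = "\t",
            quote = FALSE, row.names = FALSE, col.names = FALSE)

cat(sprintf("wrote %s: %d sites x %d samples, %d exon intervals\n",
            file.path(outdir, "cohort.vcf"),
            n_sites(sim$matrices[[1]]), nrow(panel), nrow(ex$intervals)))
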