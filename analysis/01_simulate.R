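#!/usr/bin/env Rscript
# Generate the three study datasets (easy / hard / null profiles) used by the
# downstream analyses.  Each profile writes an aligned FASTA, a species map,
# the true gene tree and a truth summary under results/data/<profile>/.
#
# easy: 5 species x 4 accessions, within/between rate ratio 50, one x20
#       mutation hotspot on columns 801-1600 of a 4000-column alignment.
# hard: 6 species x 3 accessions, ratio 5, with two barely-diverged sister
#       species pairs (the hard case for any barcoding marker).
# null: 20 accessions of a single species -- one branch-length regime, the
#       negative control for the delimitation test.

suppressMessages(library(markerptp))

seed <- 20240601
for (profile in c("easy", "hard", "null")) {
  out <- file.path("results", "data", profile)
  fx <- end_to_end_fixture(profile, seed = seed)
  paths <- write_simulation(fx, out)
  snps <- extract_snps(fx$alignment)
  message(sprintf(
    "[%s] %d tips, %d species, %d/%d SNP columns (%.2f%%) -> %s",
    profile, nrow(fx$species_map), length(fx$truth$species_roots),
    length(snps$positions), aln_length(fx$alignment),
    percent_variable_sites(fx$alignment), out))
}
message("done: study data under results/data/")
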