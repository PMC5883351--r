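#!/usr/bin/env Rscript
# Windowed SNP-density scan of the easy-profile alignment: extract SNP
# columns, bin them into 800-column windows, classify windows by the z-score
# of their SNP count (low / moderate / high), and propose candidate marker
# regions from runs of variable windows.
#
# Writes: results/scan/window_density.tsv, snp_positions.bed,
#         variable_windows.bed, proposed_regions.tsv (+ JSON manifests).

suppressMessages(library(markerptp))

data_dir <- file.path("results", "data", "easy")
if (!file.exists(file.path(data_dir, "alignment.fasta")))
  stop("run analysis/01_simulate.R first")

cfg <- run_config(alignment = file.path(data_dir, "alignment.fasta"),
                  out = file.path("results", "scan"),
                  window_size = 800, seed = 20240601)
run_stage("scan", cfg)
run_stage("propose", cfg)

wd <- utils::read.delim(file.path("results", "scan", "window_density.tsv"))
message(sprintf("windows: %d (%s)", nrow(wd),
                paste(sprintf("%s=%d", names(table(wd$class)),
                              table(wd$class)), collapse = ", ")))
regions <- read_regions(file.path("results", "scan", "proposed_regions.tsv"))
for (i in seq_len(nrow(regions)))
  message(sprintf("proposed region %s: columns %d-%d, %d SNPs",
                  regions$name[i], regions$start[i], regions$end[i],
                  regions$snp_count[i]))
message("the planted hotspot spans columns 801-1600")
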