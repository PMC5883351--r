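# markerptp

Barcoding-marker discovery and Poisson Tree Processes (PTP) species
delimitation for plastome alignments.

Standard plant barcodes (*rbcL*, *matK*, ITS) often cannot separate recently
diverged congeners — the ginsengs being the canonical example — while whole
plastid genomes can.  A usable barcode, however, has to be a short region.
This package implements the workflow that turns a whole-plastome multiple
sequence alignment into ranked candidate markers and then scores each marker
by the question that matters: *does a tree built from this region alone
delimit the species correctly?*

The pipeline:

1. **SNP scan** — extract SNP columns (≥2 distinct A/C/G/T states; gaps and
   ambiguity codes never count), bin them into 800-bp windows, and classify
   each window by the z-score of its SNP count against the mean and SD of
   all windows (`low` z < 1, `moderate` 1 ≤ z < 2, `high` z ≥ 2).
2. **Marker proposal** — runs of variable windows (bridging small gaps)
   become candidate regions, ranked by SNP count; named regions can be
   supplied as a TSV instead.
3. **Trees** — JC69/p distances with pairwise deletion + neighbor joining,
   with column-bootstrap supports; externally built ML trees import via
   Newick at every stage.
4. **Delimitation** — single- and multi-rate PTP: each edge class (speciation
   vs within-species coalescent) is an exponential branch-length process;
   a class with `n` edges of total length `S` contributes `n·ln(n/S) − n`
   at its ML rate.  The ML delimitation (exact-DP + hill-climbing search,
   verified against exhaustive enumeration) is tested against the one-rate
   null by a one-sided LRT (α = 0.01); a two-chain Metropolis sampler gives
   per-node supports and the **Average Support Value** (ASV) — the mean
   support of the ML delimitation's species roots.
5. **Marker scoring** — a species is identified iff some delimited entity
   equals exactly its accession set; markers and concatenated marker
   combinations are reported with percent variable sites, entity counts,
   discrimination and ASV.
6. **Simulator** — Yule-over-species trees with exponential two-regime
   branch lengths, JC69 sequences with rate hotspots, and full ground truth,
   so the entire pipeline is testable without downloads.

## Worked example

```r
library(markerptp)

fx <- end_to_end_fixture("easy", seed = 11)   # 5 species x 4 accessions
snps <- extract_snps(fx$alignment)
wd <- classify_windows(bin_density(snps, window_size = 800))
propose_regions(wd)
#>        name start  end snp_count source
#> 1 R801-1600   801 1600       291   auto

reg <- data.frame(name = c("hot", "cold"),
                  start = c(801, 2401), end = c(1600, 3200))
evaluate_markers(fx$alignment, reg, fx$species_map,
                 combos = list(c("hot", "cold")), seed = 3)
#>       name   type percent_variable_sites n_entities percent_species_identified
#> 1      hot marker                 36.375          8                         80
#> 2     cold marker                  2.875          1                          0
#> 3 hot+cold  combo                 19.625          5                        100
```

The proposal recovers the planted hotspot (columns 801–1600).  The hotspot
marker alone identifies 4 of 5 species (one species is oversplit into two
entities — the same phenomenon that splits over-represented species in real
plastome delimitations); the cold region of equal length identifies none;
concatenating the two identifies all five.  Delimiting the true tree
directly:

```r
ml <- ml_delimitation(fx$truth$tree)          # multi-rate PTP + LRT
mc <- mcmc_delimitation(fx$truth$tree, steps = 20000, seed = 11)
ml$n_entities      # 5
asv(ml, mc)        # 0.9963
```

The numbered scripts under `analysis/` run the same story as a narrated
workflow (simulate → scan → trees → delimit → marker report), writing tables
under `results/`:

```sh
Rscript analysis/01_simulate.R && Rscript analysis/02_snp_scan.R
Rscript analysis/03_trees.R && Rscript analysis/04_delimit.R
Rscript analysis/05_marker_evaluation.R
```

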