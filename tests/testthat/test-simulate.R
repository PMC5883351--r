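test_that("simulated trees have the requested shape and true species clades", {
  sim <- simulate_tree(5, 4, lambda_sp = 1, lambda_coal = 50, seed = 1)
  expect_equal(length(sim$tree$tip.label), 20L)
  expect_equal(length(sim$species_roots), 5L)
  for (sp in names(sim$species_roots)) {
    tips <- ape::extract.clade(sim$tree, sim$species_roots[[sp]])$tip.label
    expect_setequal(tips,
                    sim$species_map$accession[sim$species_map$species == sp])
  }
  # regime bookkeeping: within-species edge count is sum(2*n_i - 2)
  expect_equal(sum(sim$regimes == "coalescent"),
               sum(2 * table(sim$species_map$species) - 2))
  expect_error(simulate_tree(0, 4), "n_species")
  expect_error(simulate_tree(3, 4, lambda_sp = -1), "rates")

  rng <- simulate_tree(6, c(2, 6), seed = 2)
  per <- table(rng$species_map$species)
  expect_true(all(per >= 2 & per <= 6))
})

test_that("simulation is bit-exactly reproducible from the seed", {
  a <- simulate_tree(4, 3, seed = 9)
  b <- simulate_tree(4, 3, seed = 9)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  fx1 <- end_to_end_fixture("easy", seed = 5)
  fx2 <- end_to_end_fixture("easy", seed = 5)
  expect_identical(unclass(fx1$alignment)[, ], unclass(fx2$alignment)[, ])
  expect_identical(ape::write.tree(fx1$truth$tree),
                   ape::write.tree(fx2$truth$tree))
})

test_that("branch-length regimes follow their exponential distributions", {
  set.seed(51)
  coal <- c(); sp <- c()
  for (i in 1:200) {
    s <- simulate_tree(5, 3, lambda_sp = 1, lambda_coal = 50)
    coal <- c(coal, s$tree$edge.length[s$regimes == "coalescent"])
    sp <- c(sp, s$tree$edge.length[s$regimes == "speciation"])
  }
  expect_equal(mean(coal), 1 / 50, tolerance = 0.1)   # CLT band
  expect_equal(mean(sp), 1, tolerance = 0.1)
})

test_that("sequence evolution responds to rate: zero, monotone, saturated", {
  sim <- simulate_tree(3, 2, seed = 3)
  a0 <- simulate_alignment(sim, L = 300, base_rate = 0, seed = 1)
  expect_length(extract_snps(a0)$positions, 0)
  # monotone SNP yield over a rate grid (fixed tree and seed set)
  snps <- vapply(c(0.0005, 0.005, 0.05), function(r) {
    length(extract_snps(simulate_alignment(sim, L = 1500, base_rate = r,
                                           seed = 42))$positions)
  }, 0)
  expect_true(all(diff(snps) > 0))
  # extreme rate drives p-distance to the JC saturation limit 3/4
  tr <- sim$tree; tr$edge.length <- rep(5, length(tr$edge.length))
  sat <- simulate_alignment(tr, L = 20000, base_rate = 10, seed = 2)
  p <- pairwise_distance(sat, "p")
  expect_equal(mean(p[upper.tri(p)]), 0.75, tolerance = 0.02)
})

test_that("hotspots concentrate SNP density in their window", {
  hits <- 0L
  for (s in 1:25) {
    sim <- simulate_tree(5, 4, lambda_sp = 1, lambda_coal = 50,
                         seed = 7000 + s)
    aln <- simulate_alignment(sim, L = 4000, base_rate = 0.002,
                              hotspots = data.frame(start = 801, end = 1600,
                                                    multiplier = 20),
                              seed = 7000 + s)
    wd <- bin_density(extract_snps(aln), window_size = 800)
    if (which.max(wd$snp_count) == 2L) hits <- hits + 1L
  }
  expect_gte(hits / 25, 0.95)
  sim <- simulate_tree(2, 2, seed = 1)
  expect_error(simulate_alignment(sim, L = 100, hotspots = data.frame(
    start = c(1, 30), end = c(50, 60), multiplier = 2)), "overlap")
  expect_error(simulate_alignment(sim, L = 100, hotspots = data.frame(
    start = 90, end = 120, multiplier = 2)), "region")
})

test_that("fixture profiles encode their study conditions", {
  easy <- end_to_end_fixture("easy", seed = 8)
  expect_equal(easy$truth$lambda_coal / easy$truth$lambda_sp, 50)
  expect_equal(nrow(easy$species_map), 20L)

  hard <- end_to_end_fixture("hard", seed = 8)
  expect_equal(hard$truth$lambda_coal / hard$truth$lambda_sp, 5)
  expect_length(hard$truth$sister_pairs, 2L)
  # the two sister-pair stems were redrawn at coalescent scale
  nul <- end_to_end_fixture("null", seed = 8)
  expect_equal(length(unique(nul$species_map$species)), 1L)
  expect_error(end_to_end_fixture("bogus", seed = 1))
})

test_that("simulations write a complete artifact set", {
  fx <- end_to_end_fixture("easy", seed = 13)
  dir <- file.path(tempdir(), "simout")
  paths <- write_simulation(fx, dir)
  expect_true(all(file.exists(paths)))
  back <- read_alignment(paths[["alignment"]])
  expect_identical(unclass(back)[, ], unclass(fx$alignment)[, ])
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_equal(truth$profile, "easy")
  expect_equal(truth$lambda_coal, 50)
})
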