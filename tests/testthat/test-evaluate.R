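sm2 <- data.frame(accession = c("a1", "a2", "b1", "b2"),
                  species = c("A", "A", "B", "B"))

test_that("exact discrimination demands a perfect entity match", {
  d <- species_discrimination(list(c("a1", "a2"), "b1", "b2"), sm2)
  expect_equal(d$n_identified, 1L)
  expect_equal(d$percent, 50)
  expect_true(d$identified[["A"]]); expect_false(d$identified[["B"]])

  perfect <- species_discrimination(list(c("a1", "a2"), c("b1", "b2")), sm2)
  expect_equal(perfect$percent, 100)

  lumped <- species_discrimination(list(c("a1", "a2", "b1", "b2")), sm2)
  expect_equal(lumped$n_identified, 0L)

  expect_error(species_discrimination(list(c("a1", "zz")), sm2), "label")
})

test_that("the loose rule tolerates foreign partial accessions only", {
  sm3 <- data.frame(accession = c("a1", "a2", "b1", "b2", "c1"),
                    species = c("A", "A", "B", "B", "C"))
  ents <- list(c("a1", "a2", "b1"), "b2", "c1")
  strict <- species_discrimination(ents, sm3, mode = "exact")
  loose <- species_discrimination(ents, sm3, mode = "loose")
  expect_false(strict$identified[["A"]])
  expect_true(loose$identified[["A"]])    # only a partial B rides along
  expect_false(loose$identified[["B"]])   # B is split
  lump <- species_discrimination(list(c("a1", "a2", "b1", "b2"), "c1"),
                                 sm3, mode = "loose")
  expect_false(lump$identified[["A"]])    # complete B present: lumped
})

test_that("discrimination is invariant under consistent relabeling", {
  set.seed(61)
  sim <- simulate_tree(4, 3, lambda_sp = 1, lambda_coal = 50)
  ml <- ml_delimitation(sim$tree)
  base <- species_discrimination(ml, sim$species_map)
  relab <- setNames(sprintf("ACC%02d", seq_along(sim$tree$tip.label)),
                    sim$tree$tip.label)
  tr2 <- sim$tree; tr2$tip.label <- unname(relab[tr2$tip.label])
  sm <- sim$species_map
  sm$accession <- unname(relab[sm$accession])
  d2 <- species_discrimination(ml_delimitation(tr2), sm)
  expect_equal(d2$n_identified, base$n_identified)
})

test_that("a marker spanning the whole alignment equals the staged run", {
  fx <- end_to_end_fixture("easy", seed = 19)
  reg <- data.frame(name = "all", start = 1L,
                    end = aln_length(fx$alignment))
  rep <- evaluate_markers(fx$alignment, reg, fx$species_map, seed = 2)
  # by hand: same stages, same settings
  tr <- midpoint_root(nj_tree(pairwise_distance(fx$alignment, "jc69")))
  ml <- ml_delimitation(tr)
  d <- species_discrimination(ml, fx$species_map)
  expect_equal(rep$n_entities, ml$n_entities)
  expect_equal(rep$n_species_identified, d$n_identified)
  expect_equal(rep$percent_variable_sites,
               percent_variable_sites(fx$alignment))
  expect_equal(rep$loglik, ml$loglik, tolerance = 1e-9)
})

test_that("hotspot markers discriminate at least as well as cold regions and
           concatenation does not hurt (seeded study)", {
  hot <- cold <- combo <- numeric(8)
  for (s in seq_len(8)) {
    fx <- end_to_end_fixture("easy", seed = 300 + s)
    reg <- data.frame(name = c("hot", "cold"),
                      start = c(801L, 2401L), end = c(1600L, 3200L))
    rep <- evaluate_markers(fx$alignment, reg, fx$species_map,
                            combos = list(c("hot", "cold")), seed = s)
    hot[s] <- rep$percent_species_identified[rep$name == "hot"]
    cold[s] <- rep$percent_species_identified[rep$name == "cold"]
    combo[s] <- rep$percent_species_identified[rep$name == "hot+cold"]
  }
  expect_gte(mean(hot >= cold), 0.9)
  expect_gte(stats::median(combo), stats::median(hot))
  expect_gte(stats::median(combo), stats::median(cold))
})

test_that("evaluation validates inputs and tags stage errors by marker", {
  fx <- end_to_end_fixture("easy", seed = 23)
  reg <- data.frame(name = "m1", start = 1L, end = 800L)
  expect_error(evaluate_markers(fx$alignment, reg, fx$species_map,
                                combos = list(c("m1", "mX"))), "unknown")
  empty <- reg[0, ]
  expect_error(evaluate_markers(fx$alignment, empty, fx$species_map),
               "no regions")
  # degenerate marker: constant columns -> distance stage fails, named
  const <- msa(setNames(rep(paste(rep("A", 50), collapse = ""),
                            nrow(fx$alignment)), taxa(fx$alignment)))
  expect_error(evaluate_markers(const,
                                data.frame(name = "flat", start = 1L, end = 50L),
                                fx$species_map),
               "flat")
})

test_that("externally supplied trees bypass the NJ engine", {
  fx <- end_to_end_fixture("easy", seed = 29)
  reg <- data.frame(name = "hot", start = 801L, end = 1600L)
  ext <- midpoint_root(nj_tree(pairwise_distance(
    extract_region(fx$alignment, 801, 1600), "jc69")))
  rep1 <- evaluate_markers(fx$alignment, reg, fx$species_map,
                           trees = list(hot = ext), seed = 1)
  rep2 <- evaluate_markers(fx$alignment, reg, fx$species_map, seed = 1)
  expect_equal(rep1$n_entities, rep2$n_entities)
  expect_equal(rep1$percent_species_identified,
               rep2$percent_species_identified)
})

test_that("MCMC-backed evaluation reports an ASV and a run manifest", {
  fx <- end_to_end_fixture("easy", seed = 31)
  reg <- data.frame(name = "hot", start = 801L, end = 1600L)
  rep <- evaluate_markers(fx$alignment, reg, fx$species_map,
                          mcmc_steps = 1000, seed = 4)
  expect_true(rep$asv >= 0 && rep$asv <= 1)
  run <- attr(rep, "run")
  expect_equal(run$seed, 4)
  tmp <- tempfile()
  write_marker_report(rep, tmp)
  expect_named(utils::read.delim(tmp),
               c("name", "type", "start", "end", "n_columns",
                 "percent_variable_sites", "n_entities",
                 "n_species_identified", "percent_species_identified",
                 "asv", "loglik", "p_value"))
})
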