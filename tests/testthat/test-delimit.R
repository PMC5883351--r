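test_that("null model matches its closed form and the single-entity state", {
  t2 <- ape::read.tree(text = "(a:1,b:1);")
  expect_equal(null_loglik(t2)$loglik, -2, tolerance = 1e-12)
  t4 <- ape::read.tree(text = "((a:0.5,b:0.5):0.5,c:0.5);")
  expect_equal(null_loglik(t4)$loglik, 4 * log(2) - 4, tolerance = 1e-12)
  expect_equal(null_loglik(t4)$lambda, 2)

  set.seed(41)
  for (i in 1:25) {
    tr <- rand_mixed_tree(sample(4:15, 1))
    b <- tr$edge.length[tr$edge.length >= 1e-9]
    n <- length(b)
    expect_equal(null_loglik(tr)$loglik, n * log(n / sum(b)) - n,
                 tolerance = 1e-12)
    # single-entity delimitation is the null
    root <- length(tr$tip.label) + 1L
    expect_equal(delimitation_loglik(tr, root, "multi"),
                 null_loglik(tr)$loglik, tolerance = 1e-12)
  }
})

test_that("zero-length branches are excluded from the likelihood", {
  tr <- ape::read.tree(text = "((a:0.5,b:0):0.5,c:0.5);")
  expect_equal(null_loglik(tr)$loglik, 3 * log(3 / 1.5) - 3, tolerance = 1e-12)
  degen <- ape::read.tree(text = "((a:0,b:0):0,c:0);")
  expect_error(null_loglik(degen), "degenerate")
})

test_that("enumeration oracle solves the cherry and star examples", {
  cherry <- ape::read.tree(text = "((A:0.01,B:0.01):1.0,(C:0.01,D:0.01):1.0);")
  for (model in c("multi", "single")) {
    bf <- brute_force_ml(cherry, model)
    expect_equal(bf$n_entities, 2L)
    expect_setequal(vapply(bf$entities, paste, "", collapse = ","),
                    c("A,B", "C,D"))
    expect_gt(bf$loglik, bf$null$loglik)
  }
  # all antichain covers of the 4-tip balanced tree
  expect_length(enumerate_delims(cherry), 5L)

  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1):0;")  # rooted polytomy
  star$root.edge <- 0
  expect_equal(brute_force_ml(star, "multi", alpha = 0.01)$n_entities, 1L)
  expect_error(brute_force_ml(ape::rtree(13)), "size")
})

test_that("delimitation validates its inputs", {
  unr <- ape::unroot(ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);"))
  expect_error(ml_delimitation(unr), "root")
  tr <- ape::read.tree(text = "((a:1,b:1):1,c:1);")
  expect_error(delimitation_loglik(tr, c(4L, 1L)), "partition")
  one <- ape::read.tree(text = "(A:1);")
  expect_equal(ml_delimitation(one)$n_entities, 1L)
})

test_that("heuristic ML search equals the enumeration oracle (spot check)", {
  set.seed(42)
  for (i in 1:30) {
    tr <- rand_mixed_tree(sample(4:12, 1))
    for (model in c("multi", "single")) {
      bf <- brute_force_ml(tr, model, alpha = 0.01)
      ml <- ml_delimitation(tr, model = model, alpha = 0.01)
      expect_equal(ml$loglik, bf$loglik, tolerance = 1e-9)
      expect_identical(ml$species_roots, bf$species_roots)
    }
  }
})

test_that("model nesting: the searched maximum never falls below the null", {
  set.seed(43)
  for (i in 1:20) {
    tr <- rand_mixed_tree(sample(5:25, 1))
    ml <- ml_delimitation(tr, alpha = NULL)
    expect_gte(ml$loglik, ml$null$loglik - 1e-9)
  }
})

test_that("LRT retains the single entity on structureless trees", {
  eq <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  ml <- ml_delimitation(eq, alpha = 0.01)
  expect_equal(ml$n_entities, 1L)
  expect_true(ml$reduced_to_null || ml$lrt$p_value >= 0.01)
})

test_that("type-I error of the LRT is controlled under a single rate", {
  # single-regime trees: the delimitation should be rejected rarely
  rejections <- 0L
  n_rep <- 120L
  for (s in seq_len(n_rep)) {
    sim <- simulate_tree(1, 20, lambda_sp = 1, lambda_coal = 1,
                         seed = 5000 + s)
    ml <- ml_delimitation(sim$tree, alpha = 0.01)
    if (ml$n_entities > 1L) rejections <- rejections + 1L
  }
  expect_lte(rejections / n_rep, 0.03)
})

test_that("species and rate-ratio recovery on two-regime simulations", {
  ratios <- numeric(0)
  perfect <- 0L
  for (s in 1:25) {
    sim <- simulate_tree(10, 4, lambda_sp = 1, lambda_coal = 50,
                         seed = 6000 + s)
    ml <- ml_delimitation(sim$tree, alpha = 0.01)
    d <- species_discrimination(ml, sim$species_map)
    if (d$n_identified >= 9L) perfect <- perfect + 1L
    lc <- ml$rates$lambda_coal
    lc <- mean(lc[is.finite(lc)])
    ratios <- c(ratios, lc / ml$rates$lambda_sp)
  }
  # >= 9 of 10 species recovered in the bulk of replicates
  expect_gte(perfect / 25, 0.9)
  # median estimated coalescent/speciation rate ratio within 2x of truth (50)
  expect_gte(stats::median(ratios), 25)
  expect_lte(stats::median(ratios), 100)
})

test_that("delimitation reports are written as documented", {
  tr <- ape::read.tree(text = "((A:0.01,B:0.01):1.0,(C:0.01,D:0.01):1.0);")
  ml <- ml_delimitation(tr)
  tsv <- tempfile(); js <- tempfile()
  write_entities(ml, tsv)
  ent <- utils::read.delim(tsv)
  expect_named(ent, c("entity_id", "tip"))
  expect_setequal(ent$tip, c("A", "B", "C", "D"))
  write_delim_summary(ml, js, asv = 0.979, seed = 1)
  j <- jsonlite::read_json(js)
  expect_equal(j$n_entities, 2L)
  expect_equal(j$asv, 0.979)
  expect_true(all(c("loglik_null", "loglik_ml", "p_value") %in% names(j)))
})
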