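test_that("pairwise distances: closed forms, pairwise deletion, and errors", {
  aln <- msa(c(x = "AAAA", y = "AAAT"))
  expect_equal(pairwise_distance(aln, "p")[1, 2], 0.25)
  expect_equal(pairwise_distance(aln, "jc69")[1, 2],
               -0.75 * log(1 - (4 / 3) * 0.25), tolerance = 1e-12)
  same <- msa(c(x = "ACGT", y = "ACGT"))
  expect_equal(pairwise_distance(same, "jc69")[1, 2], 0)
  # gap/ambiguity sites are deleted pairwise
  g <- msa(c(x = "A-CN", y = "AACA"))
  expect_equal(pairwise_distance(g, "p")[1, 2], 0)
  expect_error(pairwise_distance(msa(c(x = "A-", y = "-A")), "p"),
               "no comparable sites")
  sat <- msa(c(x = paste(rep("A", 20), collapse = ""),
               y = paste(rep("C", 20), collapse = "")))
  expect_error(pairwise_distance(sat, "jc69"), "saturation")
})

test_that("distances agree with a naive site-loop oracle", {
  set.seed(31)
  aln <- rand_aln(6, 150, gap_frac = 0.1, amb_frac = 0.05)
  d <- pairwise_distance(aln, "p")
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(d[i, j], naive_p_distance(aln, i, j), tolerance = 1e-12)
})

test_that("NJ is exact on additive matrices from random trees", {
  set.seed(32)
  for (i in 1:25) {
    n <- sample(6:10, 1)
    tr <- ape::rtree(n)
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
    d <- ape::cophenetic.phylo(tr)           # path-length oracle
    est <- nj_tree(d)
    expect_true(ape::all.equal.phylo(ape::unroot(tr), est,
                                     use.edge.length = FALSE))
    # branch lengths recovered: pairwise path lengths match to 1e-9
    expect_equal(ape::cophenetic.phylo(est)[rownames(d), colnames(d)], d,
                 tolerance = 1e-9)
  }
})

test_that("NJ handles 2 taxa, rejects bad matrices, clamps negatives", {
  d <- matrix(c(0, 0.3, 0.3, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- nj_tree(d)
  expect_equal(sum(t2$edge.length), 0.3)
  bad <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(nj_tree(bad), "symmetric")
  set.seed(33)
  aln <- rand_aln(8, 60)
  est <- nj_tree(pairwise_distance(aln, "p"))
  expect_true(all(est$edge.length >= 0))
})

test_that("NJ topology is invariant to taxon order", {
  set.seed(34)
  tr <- ape::rtree(7)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
  d <- ape::cophenetic.phylo(tr)
  perm <- sample(7)
  expect_true(ape::all.equal.phylo(
    nj_tree(d), nj_tree(d[perm, perm]), use.edge.length = FALSE))
})

test_that("bootstrap supports are seeded, bounded, and high for clean splits", {
  set.seed(35)
  sim <- simulate_tree(2, 4, lambda_sp = 1, lambda_coal = 50)
  aln <- simulate_alignment(sim, L = 2000, base_rate = 0.01)
  b1 <- bootstrap_support(aln, reps = 30, seed = 7)
  b2 <- bootstrap_support(aln, reps = 30, seed = 7)
  expect_identical(b1$node.label, b2$node.label)
  sup <- b1$node.label[!is.na(b1$node.label)]
  expect_true(all(sup >= 0 & sup <= 1))
  # the two-species split is essentially certain
  expect_gte(max(sup), 0.9)

  const <- msa(c(a = "AAAA", b = "AAAA", c = "AAAA", d = "AAAA"))
  bc <- bootstrap_support(const, reps = 5, seed = 1, model = "p")
  expect_true(all(bc$node.label[!is.na(bc$node.label)] == 1))
})

test_that("outgroup rooting requires monophyly; Newick round-trips", {
  tr <- ape::unroot(ape::read.tree(
    text = "((A:1,B:1):1,(C:1,(D:1,E:1):0.5):1);"))
  rooted <- root_with_outgroup(tr, c("D", "E"))
  expect_true(ape::is.rooted(rooted))
  expect_true(ape::is.monophyletic(rooted, c("A", "B", "C")))
  # single-tip outgroup always works
  expect_true(ape::is.rooted(root_with_outgroup(tr, "C")))
  expect_error(root_with_outgroup(tr, c("A", "D")), "monophyletic")
  expect_error(root_with_outgroup(tr, "Z"), "not in tree")

  # total length is invariant under re-rooting
  expect_equal(sum(rooted$edge.length), sum(tr$edge.length), tolerance = 1e-9)

  tmp <- tempfile(fileext = ".nwk")
  rooted$node.label <- round(seq(0, 1, length.out = rooted$Nnode), 3)
  write_newick(rooted, tmp)
  back <- read_newick(tmp)
  expect_true(ape::all.equal.phylo(rooted, back, use.edge.length = FALSE))
  expect_equal(sort(back$edge.length), sort(rooted$edge.length),
               tolerance = 1e-7)
  # supports stay attached to the same clades (node order may differ)
  clade_support <- function(tr) {
    nt <- length(tr$tip.label)
    keys <- vapply((nt + 1):(nt + tr$Nnode), function(nd)
      paste(sort(ape::extract.clade(tr, nd)$tip.label), collapse = ","), "")
    setNames(as.numeric(tr$node.label), keys)
  }
  a <- clade_support(rooted); b <- clade_support(back)
  expect_mapequal(as.list(b), as.list(a))
})

test_that("midpoint rooting and pruning produce delimitable trees", {
  set.seed(36)
  sim <- simulate_tree(3, 3, lambda_sp = 1, lambda_coal = 50)
  unr <- ape::unroot(sim$tree)
  mid <- midpoint_root(unr)
  expect_true(ape::is.rooted(mid))
  pruned <- prune_taxa(sim$tree, "sp01_1")
  expect_false("sp01_1" %in% pruned$tip.label)
  expect_error(prune_taxa(sim$tree, "nope"), "not in tree")
})
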