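# Distance matrices, neighbor-joining, bootstrap supports, rooting and
# Newick I/O.  Trees are ape "phylo" objects with branch lengths in expected
# substitutions/site; bootstrap supports live in node.label as fractions in
# [0, 1].  These are the carriers for delimitation; externally built ML trees
# can be imported via read_newick() and used in place of the built-in NJ
# engine.

#' Pairwise distances between aligned sequences
#'
#' Computes uncorrected p-distances or Jukes-Cantor (JC69) distances with
#' pairwise deletion: for each pair, only sites where both sequences carry an
#' unambiguous A/C/G/T are compared.
#'
#' @param aln An `msa` alignment with at least 2 taxa.
#' @param model `"jc69"` (default) for \eqn{-\frac{3}{4}\ln(1 - \frac{4}{3}p)}
#'   or `"p"` for the raw mismatch fraction.
#' @return A symmetric numeric matrix with taxa as dimnames.
#' @export
pairwise_distance <- function(aln, model = c("jc69", "p")) {
  model <- match.arg(model)
  if (nrow(aln) < 2L) stop("need >= 2 taxa for distances")
  db <- ape::as.DNAbin(tolower(unclass(aln)))
  p <- as.matrix(ape::dist.dna(db, model = "raw", pairwise.deletion = TRUE))
  if (any(!is.finite(p))) {
    bad <- which(!is.finite(p) & upper.tri(p), arr.ind = TRUE)[1, ]
    stop("distance error: no comparable sites between ",
         rownames(p)[bad[1]], " and ", colnames(p)[bad[2]])
  }
  if (model == "p") return(p)
  if (any(p >= 0.75 - 1e-12)) {
    bad <- which(p >= 0.75 - 1e-12 & upper.tri(p), arr.ind = TRUE)[1, ]
    stop("saturation error: JC69 undefined (p >= 3/4) between ",
         rownames(p)[bad[1]], " and ", colnames(p)[bad[2]])
  }
  d <- -0.75 * log(1 - (4 / 3) * p)
  dimnames(d) <- dimnames(p)
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (exact on additive matrices).  Negative estimated
#' branch lengths are clamped to zero with the deficit moved onto the sister
#' branch, so total path lengths are approximately preserved.
#'
#' @param d Symmetric non-negative distance matrix with taxon dimnames.
#' @return An unrooted `phylo` tree (for 2 taxa: a root with two `d/2`
#'   branches, total length `d`).
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (is.null(rownames(d))) stop("distance matrix needs taxon dimnames")
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("matrix error: distance matrix is not symmetric")
  if (any(!is.finite(d))) stop("matrix error: non-finite distances")
  if (any(abs(diag(d)) > 1e-12)) stop("matrix error: non-zero diagonal")
  n <- nrow(d)
  if (n < 2L) stop("need >= 2 taxa")
  if (n == 2L) {
    tr <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
               edge.length = rep(d[1, 2] / 2, 2),
               tip.label = rownames(d), Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  tr <- ape::nj(d)
  clamp_negative_branches(tr)
}

# zero out negative branch lengths, moving the deficit to a sister branch
clamp_negative_branches <- function(tr) {
  if (is.null(tr$edge.length)) return(tr)
  repeat {
    neg <- which(tr$edge.length < 0)
    if (!length(neg)) break
    e <- neg[1]
    parent <- tr$edge[e, 1]
    sibs <- setdiff(which(tr$edge[, 1] == parent), e)
    if (length(sibs)) {
      s <- sibs[1]
      tr$edge.length[s] <- max(0, tr$edge.length[s] + tr$edge.length[e])
    }
    tr$edge.length[e] <- 0
  }
  tr
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree for each
#' replicate, and records the frequency of each full-data bipartition as a
#' support in `[0, 1]` on the internal nodes of the full-data tree.
#' Reproducible for a fixed seed; resampling is indexed by column, so supports
#' do not depend on taxon order.
#'
#' @param aln An `msa` alignment.
#' @param reps Number of bootstrap replicates (>= 1).
#' @param seed Integer RNG seed.
#' @param model Distance model passed to [pairwise_distance()].
#' @return The full-data NJ `phylo` with `node.label` supports (root `NA`).
#' @export
bootstrap_support <- function(aln, reps = 100, seed = 1, model = "jc69") {
  reps <- as.integer(reps)
  if (is.na(reps) || reps < 1L) stop("invalid `reps`: must be >= 1")
  full <- nj_tree(pairwise_distance(aln, model))
  L <- aln_length(aln)
  mat <- unclass(aln)
  set.seed(seed)
  boots <- vector("list", reps)
  for (r in seq_len(reps)) {
    idx <- sample.int(L, L, replace = TRUE)
    boots[[r]] <- nj_tree(pairwise_distance(new_msa(mat[, idx, drop = FALSE]),
                                            model))
  }
  counts <- ape::prop.clades(full, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  sup <- counts / reps
  sup[1] <- NA_real_  # root of the unrooted representation: trivial split
  full$node.label <- sup
  full
}

#' Root a tree on an outgroup
#'
#' @param tree A `phylo` tree.
#' @param outgroup Character vector of outgroup tip labels; must form one side
#'   of a bipartition of the unrooted tree.
#' @return A rooted `phylo`.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  missing <- setdiff(outgroup, tree$tip.label)
  if (length(missing))
    stop("label error: outgroup taxa not in tree: ",
         paste(missing, collapse = ", "))
  if (length(outgroup) >= length(tree$tip.label))
    stop("rooting error: outgroup cannot contain all tips")
  if (length(outgroup) > 1L) {
    # outgroup must form one side of a split: check monophyly on the tree
    # rooted at an ingroup tip
    ingroup_tip <- setdiff(tree$tip.label, outgroup)[1]
    probe <- ape::root(ape::unroot(tree), outgroup = ingroup_tip,
                       resolve.root = TRUE)
    if (!ape::is.monophyletic(probe, outgroup))
      stop("rooting error: outgroup is not monophyletic")
  }
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Midpoint-root a tree
#'
#' Roots at the midpoint of the longest tip-to-tip path; used when no outgroup
#' is available (e.g. on simulated marker trees).
#'
#' @param tree A `phylo` tree with branch lengths.
#' @return A rooted `phylo`.
#' @export
midpoint_root <- function(tree) {
  phangorn::midpoint(tree)
}

#' Drop taxa from a tree
#'
#' @param tree A `phylo` tree.
#' @param drop Tip labels to remove (e.g. the outgroup before delimitation).
#' @return A `phylo` without the given tips.
#' @export
prune_taxa <- function(tree, drop) {
  missing <- setdiff(drop, tree$tip.label)
  if (length(missing))
    stop("label error: tips not in tree: ", paste(missing, collapse = ", "))
  ape::drop.tip(tree, drop)
}

#' Newick I/O
#'
#' Thin wrappers over ape's Newick reader/writer; branch lengths are written
#' with 10 significant digits and supports round-trip as internal node labels.
#'
#' @param path Newick file path.
#' @return `read_newick()` returns a `phylo`.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("format error: could not parse Newick in ", path)
  tr
}

#' @rdname read_newick
#' @param tree A `phylo` tree.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}
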