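# Coalescent-style synthetic data with the statistical structure the
# delimitation model assumes: a Yule topology over species, a random
# coalescent topology within each species, exponential branch lengths with
# distinct between-species (lambda_sp) and within-species (lambda_coal)
# rates, and Jukes-Cantor sequence evolution with regional mutation-rate
# hotspots.  Everything is reproducible bit-exactly from the seed.

#' Simulate a species/gene tree with two branch-length regimes
#'
#' Species topology is Yule (uniform random tip splitting); within each
#' species the tip topology is a random coalescent join.  Every
#' between-species edge (species-tree internal edges and the stem edge of
#' each species) has length `~ Exponential(lambda_sp)`; every within-species
#' edge has length `~ Exponential(lambda_coal)`.  Branch lengths are in
#' expected substitutions/site.
#'
#' @param n_species Number of species (>= 1).
#' @param tips_per_species Accessions per species: a single count, or a
#'   length-2 range sampled uniformly per species.
#' @param lambda_sp Speciation-edge rate (> 0); mean edge length `1/lambda_sp`.
#' @param lambda_coal Coalescent-edge rate (> 0).
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return An object of class `ptp_sim`: `tree` (rooted `phylo`),
#'   `species_map` (accession/species data.frame), `species_roots` (true
#'   species-root node ids), `regimes` (per tree edge,
#'   `"speciation"`/`"coalescent"`), the rates and the seed.
#' @export
simulate_tree <- function(n_species, tips_per_species = 4, lambda_sp = 1,
                          lambda_coal = 50, seed = NULL) {
  n_species <- as.integer(n_species)
  if (is.na(n_species) || n_species < 1L)
    stop("parameter error: n_species must be >= 1")
  if (!is.numeric(lambda_sp) || lambda_sp <= 0 ||
      !is.numeric(lambda_coal) || lambda_coal <= 0)
    stop("parameter error: rates must be > 0")
  if (!is.null(seed)) set.seed(seed)
  ntips <- tips_count(n_species, tips_per_species)
  sp_names <- sprintf("sp%02d", seq_len(n_species))
  # per-species coalescent subtree as newick (stem length left to the caller)
  sub_nwk <- vapply(seq_len(n_species), function(i)
    coalescent_newick(sprintf("%s_%d", sp_names[i], seq_len(ntips[i])),
                      lambda_coal),
    character(1))
  nwk <- if (n_species == 1L) paste0(sub_nwk, ";")
         else paste0(yule_newick(sub_nwk, lambda_sp), ";")
  tree <- ape::read.tree(text = nwk)
  sm <- data.frame(
    accession = unlist(lapply(seq_len(n_species), function(i)
      sprintf("%s_%d", sp_names[i], seq_len(ntips[i])))),
    species = rep(sp_names, ntips))
  finish_sim(tree, sm, lambda_sp, lambda_coal, seed)
}

tips_count <- function(n_species, tips_per_species) {
  if (length(tips_per_species) == 1L)
    return(rep(as.integer(tips_per_species), n_species))
  if (length(tips_per_species) == 2L) {
    rng <- sort(as.integer(tips_per_species))
    return(sample(rng[1]:rng[2], n_species, replace = TRUE))
  }
  stop("parameter error: tips_per_species must be a count or a range")
}

# random coalescent join of labels; each merged clade gets an Exp(lambda)
# stem edge at merge time
coalescent_newick <- function(labels, lambda) {
  parts <- labels
  while (length(parts) > 1L) {
    pick <- sample.int(length(parts), 2L)
    b <- stats::rexp(2, lambda)
    merged <- sprintf("(%s:%.10g,%s:%.10g)", parts[pick[1]], b[1],
                      parts[pick[2]], b[2])
    parts <- c(parts[-pick], merged)
  }
  parts
}

# Yule topology over pre-built species subtrees: grow by splitting a
# uniformly chosen current tip; every species-tree edge gets Exp(lambda)
yule_newick <- function(subtrees, lambda) {
  n <- length(subtrees)
  # grow topology as parent/children arrays over species-tree nodes
  left <- integer(0); right <- integer(0)
  nodes <- 1L; active <- 1L
  left <- c(left, 0L); right <- c(right, 0L)
  while (length(active) < n) {
    t <- active[sample.int(length(active), 1L)]
    c1 <- nodes + 1L; c2 <- nodes + 2L; nodes <- nodes + 2L
    left <- c(left, 0L, 0L); right <- c(right, 0L, 0L)
    left[t] <- c1; right[t] <- c2
    active <- c(setdiff(active, t), c1, c2)
  }
  # final tips (in id order) carry the species subtrees
  tip_ids <- sort(active)
  tip_sub <- character(nodes)
  tip_sub[tip_ids] <- subtrees
  render <- function(v) {
    if (left[v] == 0L) return(tip_sub[v])
    b <- stats::rexp(2, lambda)
    sprintf("(%s:%.10g,%s:%.10g)", render(left[v]), b[1],
            render(right[v]), b[2])
  }
  render(1L)
}

finish_sim <- function(tree, sm, lambda_sp, lambda_coal, seed) {
  roots <- true_species_roots(tree, sm)
  nt <- length(tree$tip.label)
  # an edge is coalescent iff its parent lies at or below a species root
  desc <- descendants_by_node(tree)
  at_or_below <- logical(nt + tree$Nnode)
  for (r in roots) at_or_below[c(r, desc[[r]])] <- TRUE
  regimes <- ifelse(at_or_below[tree$edge[, 1]], "coalescent", "speciation")
  structure(list(tree = tree, species_map = sm, species_roots = roots,
                 regimes = regimes, lambda_sp = lambda_sp,
                 lambda_coal = lambda_coal, seed = seed),
            class = "ptp_sim")
}

# node ids of each species' MRCA (the tip itself for singletons)
true_species_roots <- function(tree, sm) {
  vapply(split(sm$accession, sm$species), function(acc) {
    ids <- match(acc, tree$tip.label)
    if (length(ids) == 1L) ids else ape::getMRCA(tree, ids)
  }, integer(1))
}

descendants_by_node <- function(tree) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  kids <- vector("list", nn)
  for (e in seq_len(nrow(tree$edge)))
    kids[[tree$edge[e, 1]]] <- c(kids[[tree$edge[e, 1]]], tree$edge[e, 2])
  desc <- rep(list(integer(0)), nn)
  # children-first accumulation (reverse preorder = valid postorder)
  for (u in rev(preorder_nodes(tree))) {
    ch <- kids[[u]]
    if (length(ch)) desc[[u]] <- c(ch, unlist(desc[ch]))
  }
  desc
}

preorder_nodes <- function(tree) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  kids <- vector("list", nn)
  for (e in seq_len(nrow(tree$edge)))
    kids[[tree$edge[e, 1]]] <- c(kids[[tree$edge[e, 1]]], tree$edge[e, 2])
  out <- integer(nn); stack <- nt + 1L; k <- 0L
  while (length(stack)) {
    u <- stack[length(stack)]; stack <- stack[-length(stack)]
    k <- k + 1L; out[k] <- u
    stack <- c(stack, kids[[u]])
  }
  out[seq_len(k)]
}

#' @export
print.ptp_sim <- function(x, ...) {
  cat("PTP simulation:", nrow(x$species_map), "tips,",
      length(x$species_roots), "species; lambda_sp =", x$lambda_sp,
      ", lambda_coal =", x$lambda_coal, "\n")
  invisible(x)
}

#' Simulate an alignment along a tree under Jukes-Cantor with hotspots
#'
#' Sites evolve independently under JC69 along the tree; a site at rate `r`
#' on an edge of length `b` differs from its parent with probability
#' `3/4 * (1 - exp(-4/3 * r * b))`.  Columns inside a hotspot use
#' `base_rate * multiplier`.  The root sequence is uniform over A/C/G/T.
#'
#' @param truth A `ptp_sim` (or a `phylo`) giving the tree.
#' @param L Alignment length in columns.
#' @param base_rate Rate multiplier applied to all branch lengths (>= 0).
#' @param hotspots Optional `data.frame(start, end, multiplier)` of 1-based
#'   inclusive, non-overlapping column ranges with rate multipliers > 0.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return An `msa` alignment over the tree's tips, with the hotspot table in
#'   `attr(, "hotspots")`.
#' @export
simulate_alignment <- function(truth, L = 4000, base_rate = 0.002,
                               hotspots = NULL, seed = NULL) {
  tree <- if (inherits(truth, "ptp_sim")) truth$tree else truth
  if (!inherits(tree, "phylo")) stop("`truth` must be a ptp_sim or phylo")
  L <- as.integer(L)
  if (is.na(L) || L < 1L) stop("parameter error: L must be >= 1")
  if (!is.numeric(base_rate) || base_rate < 0)
    stop("parameter error: base_rate must be >= 0")
  site_rate <- rep(base_rate, L)
  if (!is.null(hotspots) && nrow(hotspots)) {
    h <- hotspots[order(hotspots$start), , drop = FALSE]
    if (any(h$start < 1L) || any(h$end > L) || any(h$start > h$end))
      stop("region error: hotspot outside [1, ", L, "]")
    if (nrow(h) > 1L && any(h$start[-1] <= h$end[-nrow(h)]))
      stop("region error: overlapping hotspots")
    if (any(h$multiplier <= 0)) stop("region error: multipliers must be > 0")
    for (i in seq_len(nrow(h)))
      site_rate[h$start[i]:h$end[i]] <- base_rate * h$multiplier[i]
  }
  if (!is.null(seed)) set.seed(seed)
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  blen <- rep(NA_real_, nn)
  blen[tree$edge[, 2]] <- tree$edge.length
  parent <- rep(NA_integer_, nn)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  seqs <- matrix(0L, nn, L)
  ord <- preorder_nodes(tree)
  root <- nt + 1L
  seqs[root, ] <- sample.int(4L, L, replace = TRUE)
  for (u in ord[-1]) {
    p_change <- 0.75 * (1 - exp(-(4 / 3) * blen[u] * site_rate))
    s <- seqs[parent[u], ]
    hit <- stats::runif(L) < p_change
    if (any(hit)) {
      # new base uniform over the three others
      shift <- sample.int(3L, sum(hit), replace = TRUE)
      s[hit] <- ((s[hit] - 1L + shift) %% 4L) + 1L
    }
    seqs[u, ] <- s
  }
  bases <- c("A", "C", "G", "T")
  mat <- matrix(bases[seqs[seq_len(nt), ]], nt, L)
  rownames(mat) <- tree$tip.label
  out <- new_msa(mat)
  attr(out, "hotspots") <- hotspots
  out
}

#' End-to-end simulation fixtures
#'
#' Named study conditions exercising the full pipeline:
#' \describe{
#'   \item{easy}{5 species x 4 accessions, rate ratio 50
#'     (`lambda_sp = 1`, `lambda_coal = 50`), a 4000-column alignment at
#'     `base_rate = 0.002` with one x20 hotspot on columns 801-1600.}
#'   \item{hard}{6 species x 3 accessions, rate ratio 5, with two sister
#'     pairs of barely diverged species (their stem edges are redrawn at the
#'     coalescent rate), same alignment settings.}
#'   \item{null}{a single 20-accession species: one exponential branch-length
#'     regime, no species structure; 2000 columns, no hotspot.}
#' }
#'
#' @param profile `"easy"`, `"hard"` or `"null"`.
#' @param seed Integer seed.
#' @return List with `alignment` (`msa`), `species_map` and `truth`
#'   (`ptp_sim`).
#' @export
end_to_end_fixture <- function(profile = c("easy", "hard", "null"), seed = 1) {
  profile <- match.arg(profile)
  set.seed(seed)
  if (profile == "easy") {
    truth <- simulate_tree(5, 4, lambda_sp = 1, lambda_coal = 50)
    aln <- simulate_alignment(truth, L = 4000, base_rate = 0.002,
                              hotspots = data.frame(start = 801, end = 1600,
                                                    multiplier = 20))
  } else if (profile == "hard") {
    truth <- hard_profile_tree(n_species = 6, tips = 3,
                               lambda_sp = 1, lambda_coal = 5)
    aln <- simulate_alignment(truth, L = 4000, base_rate = 0.002,
                              hotspots = data.frame(start = 801, end = 1600,
                                                    multiplier = 20))
  } else {
    truth <- simulate_tree(1, 20, lambda_sp = 1, lambda_coal = 1)
    aln <- simulate_alignment(truth, L = 2000, base_rate = 0.002)
  }
  list(alignment = aln, species_map = truth$species_map, truth = truth,
       profile = profile, seed = seed)
}

# rate-ratio-5 tree in which two sister species pairs are barely diverged:
# their stem edges are redrawn from the coalescent regime.  Species
# topologies without two disjoint sister pairs are rejected and redrawn.
hard_profile_tree <- function(n_species, tips, lambda_sp, lambda_coal) {
  for (attempt in 1:200) {
    truth <- simulate_tree(n_species, tips, lambda_sp, lambda_coal)
    pd_parent <- rep(NA_integer_, length(truth$tree$tip.label) +
                       truth$tree$Nnode)
    pd_parent[truth$tree$edge[, 2]] <- truth$tree$edge[, 1]
    par_of_root <- pd_parent[truth$species_roots]
    sib <- split(truth$species_roots, par_of_root)
    pairs <- Filter(function(x) length(x) == 2L, sib)
    if (length(pairs) >= 2L) {
      chosen <- unlist(pairs[1:2])
      ei <- match(chosen, truth$tree$edge[, 2])
      truth$tree$edge.length[ei] <- stats::rexp(length(ei), lambda_coal)
      truth$sister_pairs <- lapply(pairs[1:2], function(r)
        names(truth$species_roots)[match(r, truth$species_roots)])
      return(truth)
    }
  }
  stop("could not draw a species topology with two sister pairs")
}

#' Write a simulation to disk
#'
#' Writes the alignment (FASTA), species map (TSV), tree (Newick) and a truth
#' summary (JSON: rates, seed, profile, hotspots).
#'
#' @param fixture Result of [end_to_end_fixture()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of paths written.
#' @export
write_simulation <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(alignment = file.path(dir, "alignment.fasta"),
             species_map = file.path(dir, "species_map.tsv"),
             tree = file.path(dir, "tree.nwk"),
             truth = file.path(dir, "truth.json"))
  write_alignment(fixture$alignment, paths["alignment"])
  write_species_map(fixture$species_map, paths["species_map"])
  write_newick(fixture$truth$tree, paths["tree"])
  hs <- attr(fixture$alignment, "hotspots")
  jsonlite::write_json(
    list(profile = fixture$profile, seed = fixture$seed,
         lambda_sp = fixture$truth$lambda_sp,
         lambda_coal = fixture$truth$lambda_coal,
         n_species = length(fixture$truth$species_roots),
         n_tips = nrow(fixture$species_map),
         hotspots = hs),
    paths["truth"], auto_unbox = TRUE, digits = NA, na = "null")
  invisible(paths)
}
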