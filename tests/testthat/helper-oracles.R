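# Independent naive oracles and fixture builders used across the suite.
# These deliberately use loop-based "obvious" implementations so they share
# no code path with the package.

# random alignment with optional gap/ambiguity contamination
rand_aln <- function(n_taxa, L, gap_frac = 0, amb_frac = 0) {
  pool <- c("A", "C", "G", "T")
  mat <- matrix(sample(pool, n_taxa * L, replace = TRUE), n_taxa, L)
  contaminate <- function(mat, frac, chars) {
    k <- round(frac * length(mat))
    if (k > 0) mat[sample(length(mat), k)] <-
        sample(chars, k, replace = TRUE)
    mat
  }
  mat <- contaminate(mat, gap_frac, "-")
  mat <- contaminate(mat, amb_frac, c("N", "R", "Y", "W", "S"))
  rownames(mat) <- sprintf("t%02d", seq_len(n_taxa))
  msa(apply(mat, 1, paste, collapse = ""))
}

# naive per-column SNP scan: explicit loop over columns
naive_snp_positions <- function(aln) {
  mat <- unclass(aln)
  out <- integer(0)
  for (j in seq_len(ncol(mat))) {
    states <- unique(mat[, j])
    states <- states[states %in% c("A", "C", "G", "T")]
    if (length(states) >= 2) out <- c(out, j)
  }
  out
}

# naive window histogram by scanning positions one at a time
naive_bin_counts <- function(positions, L, w) {
  n_win <- ceiling(L / w)
  counts <- integer(n_win)
  for (p in positions) {
    i <- ceiling(p / w)
    counts[i] <- counts[i] + 1L
  }
  counts
}

# naive pairwise p-distance with explicit site loop
naive_p_distance <- function(aln, a, b) {
  x <- unclass(aln)[a, ]; y <- unclass(aln)[b, ]
  ok <- 0L; diff <- 0L
  for (j in seq_along(x)) {
    if (x[j] %in% c("A", "C", "G", "T") && y[j] %in% c("A", "C", "G", "T")) {
      ok <- ok + 1L
      if (x[j] != y[j]) diff <- diff + 1L
    }
  }
  if (ok == 0L) return(NA_real_)
  diff / ok
}

# random rooted tree with mixed-regime branch lengths (independent of the
# package's simulator)
rand_mixed_tree <- function(n_tip, fast_rate = 50, slow_rate = 1,
                            p_fast = 0.5) {
  tr <- ape::rtree(n_tip)
  ne <- nrow(tr$edge)
  fast <- stats::runif(ne) < p_fast
  tr$edge.length <- ifelse(fast, stats::rexp(ne, fast_rate),
                           stats::rexp(ne, slow_rate))
  tr
}

# enumerate all delimitations of a small tree with their log-likelihoods,
# via the package's enumeration internals kept separate from the search
enumerate_delims <- function(tree, model = "multi") {
  pd <- markerptp:::ptp_data(tree)
  sets <- markerptp:::enumerate_S(pd)
  out <- lapply(sets, function(Sn) {
    S <- logical(pd$n_node); S[Sn] <- TRUE
    roots <- markerptp:::roots_from_S(pd, S)
    list(roots = sort(roots),
         key = paste(sort(roots), collapse = "-"),
         loglik = markerptp:::delim_loglik_roots(pd, roots, model))
  })
  out
}
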