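# MCMC over PTP delimitations: per-node supports and the Average Support
# Value (ASV).
#
# The chain state is a valid delimitation, carried as the parent-closed
# speciation-node set S (see delimit.R).  The prior is uniform over valid
# delimitations.  Each step proposes toggling a uniformly chosen internal
# node: adding v to S splits the entity rooted at v into its children's
# entities; removing v merges its children's entities into one.  Invalid
# toggles are rejected (the current state is recorded again), which keeps the
# proposal symmetric; acceptance is Metropolis, min(1, exp(delta loglik)).
# Incremental class statistics make each step O(degree).

#' MCMC sampling of PTP delimitations
#'
#' Runs `chains` independent Metropolis chains (chain 1 starts from the
#' single-entity state, chain 2 from the all-singletons state, further chains
#' alternate), discards `burnin` of each, and pools the rest into per-node
#' supports: the fraction of samples in which a node is a species root.
#' Fully reproducible for a fixed seed.
#'
#' @param tree A rooted `phylo`.
#' @param steps Samples per chain (>= 100).
#' @param chains Number of chains (default 2).
#' @param burnin Fraction of each chain discarded (default 0.10).
#' @param seed Integer RNG seed.
#' @param model `"multi"` or `"single"` coalescent-rate model.
#' @param minbr Minimum branch length included in the likelihood.
#' @param keep_states Record the visited delimitation of every post-burn-in
#'   step as a canonical string (species roots, sorted, `-`-joined); useful
#'   for exact small-tree checks.
#' @return An object of class `ptp_mcmc`: `node_support` (named by node id,
#'   pooled), `chain_support` (matrix, one column per chain),
#'   `chain_correlation` (between-chain support correlation), `traces`
#'   (per chain: `loglik`, `n_entities`), `states` (list per chain or `NULL`),
#'   `acceptance`, plus `steps`, `burnin`, `chains`, `seed`, `model`, `tree`.
#' @export
mcmc_delimitation <- function(tree, steps = 50000, chains = 2, burnin = 0.10,
                              seed = 1, model = c("multi", "single"),
                              minbr = PTP_MINBR, keep_states = FALSE) {
  model <- match.arg(model)
  steps <- as.integer(steps)
  if (is.na(steps) || steps < 100L)
    stop("configuration error: `steps` must be >= 100")
  chains <- as.integer(chains)
  if (is.na(chains) || chains < 1L)
    stop("configuration error: `chains` must be >= 1")
  if (!is.numeric(burnin) || burnin < 0 || burnin >= 1)
    stop("configuration error: `burnin` must be in [0, 1)")
  pd <- ptp_data(tree, minbr)
  if (pd$cnt0 == 0L) stop("degenerate tree: no edges of length >= ", minbr)
  n_burn <- floor(burnin * steps)
  n_keep <- steps - n_burn
  set.seed(seed)
  runs <- lapply(seq_len(chains), function(ci) {
    S_init <- logical(pd$n_node)
    if (ci %% 2L == 0L) S_init[pd$internal] <- TRUE
    run_ptp_chain(pd, S_init, steps, n_burn, model, keep_states)
  })
  tally <- Reduce(`+`, lapply(runs, `[[`, "tally"))
  node_support <- tally / (chains * n_keep)
  names(node_support) <- seq_len(pd$n_node)
  chain_support <- vapply(runs, function(r) r$tally / n_keep,
                          numeric(pd$n_node))
  rownames(chain_support) <- seq_len(pd$n_node)
  chain_correlation <- if (chains >= 2L) {
    v <- apply(chain_support[, 1:2, drop = FALSE], 1, stats::var)
    if (all(v == 0, na.rm = TRUE)) 1 else
      suppressWarnings(stats::cor(chain_support[, 1], chain_support[, 2]))
  } else NA_real_
  structure(list(node_support = node_support, chain_support = chain_support,
                 chain_correlation = chain_correlation,
                 traces = lapply(runs, function(r)
                   list(loglik = r$ll_trace, n_entities = r$nent_trace)),
                 states = if (keep_states)
                   lapply(runs, `[[`, "states") else NULL,
                 acceptance = vapply(runs, `[[`, 0, "acc_rate"),
                 steps = steps, burnin = burnin, n_burn = n_burn,
                 chains = chains, seed = seed, model = model,
                 minbr = minbr, tree = tree),
            class = "ptp_mcmc")
}

# one Metropolis chain; returns post-burn-in species-root tallies and traces
run_ptp_chain <- function(pd, S, steps, n_burn, model, keep_states) {
  single <- model == "single"
  # class statistics for the current state
  roots <- roots_from_S(pd, S)
  rootsind <- logical(pd$n_node); rootsind[roots] <- TRUE
  ncoal <- sum(pd$cnt[roots]); scoal <- sum(pd$ssum[roots])
  coalterm <- if (single) fpois(ncoal, scoal) else sum(pd$f_node[roots])
  nsp <- pd$cnt0 - ncoal; ssp <- pd$ssum0 - scoal
  ll <- fpois(nsp, ssp) + coalterm
  internal <- pd$internal
  ki <- length(internal)
  tally <- numeric(pd$n_node)
  ll_trace <- numeric(steps); nent_trace <- integer(steps)
  n_ent <- sum(rootsind)
  states <- if (keep_states) character(steps - n_burn) else NULL
  accepted <- 0L
  picks <- internal[sample.int(ki, steps, replace = TRUE)]
  lograndoms <- log(stats::runif(steps))
  for (i in seq_len(steps)) {
    v <- picks[i]
    valid <- if (S[v]) !any(S[pd$internal_children[[v]]])
             else v == pd$root || S[pd$parent[v]]
    if (valid) {
      ch <- pd$children[[v]]
      d_n <- sum(pd$cnt[ch]) - pd$cnt[v]      # change in coal edge count if
      d_s <- sum(pd$ssum[ch]) - pd$ssum[v]    # v is added to S (split at v)
      if (S[v]) {                              # removing v: merge at v
        ncoal2 <- ncoal - d_n; scoal2 <- scoal - d_s
        coalterm2 <- if (single) fpois(ncoal2, scoal2)
                     else coalterm - sum(pd$f_node[ch]) + pd$f_node[v]
        d_ent <- 1L - length(ch)
      } else {                                 # adding v: split at v
        ncoal2 <- ncoal + d_n; scoal2 <- scoal + d_s
        coalterm2 <- if (single) fpois(ncoal2, scoal2)
                     else coalterm - pd$f_node[v] + sum(pd$f_node[ch])
        d_ent <- length(ch) - 1L
      }
      ll2 <- fpois(pd$cnt0 - ncoal2, pd$ssum0 - scoal2) + coalterm2
      if (lograndoms[i] < ll2 - ll) {
        if (S[v]) { rootsind[v] <- TRUE; rootsind[ch] <- FALSE }
        else { rootsind[v] <- FALSE; rootsind[ch] <- TRUE }
        S[v] <- !S[v]
        ncoal <- ncoal2; scoal <- scoal2; coalterm <- coalterm2
        ll <- ll2; n_ent <- n_ent + d_ent
        accepted <- accepted + 1L
      }
    }
    ll_trace[i] <- ll; nent_trace[i] <- n_ent
    if (i > n_burn) {
      tally <- tally + rootsind
      if (keep_states)
        states[i - n_burn] <- paste(sort(which(rootsind)), collapse = "-")
    }
  }
  list(tally = tally, ll_trace = ll_trace, nent_trace = nent_trace,
       states = states, acc_rate = accepted / steps)
}

#' @export
print.ptp_mcmc <- function(x, ...) {
  cat("PTP MCMC:", x$chains, "chains x", x$steps, "steps (burn-in ",
      x$n_burn, "), model ", x$model, "\n", sep = "")
  cat(sprintf("  acceptance %s; between-chain support correlation %.3f\n",
              paste(sprintf("%.2f", x$acceptance), collapse = "/"),
              x$chain_correlation))
  invisible(x)
}

#' Average Support Value of an ML delimitation
#'
#' The ASV is the mean MCMC support of the ML delimitation's species-root
#' nodes: how strongly the sampler agrees with the point estimate.  For a
#' single-entity ML delimitation it is the support of the tree root.
#'
#' @param ml A `ptp_delim` from [ml_delimitation()] or [brute_force_ml()].
#' @param mcmc A `ptp_mcmc` from [mcmc_delimitation()] on the same tree.
#' @return The ASV as a fraction in `[0, 1]`.
#' @export
asv <- function(ml, mcmc) {
  if (!inherits(ml, "ptp_delim") || !inherits(mcmc, "ptp_mcmc"))
    stop("asv() needs a ptp_delim and a ptp_mcmc")
  if (!identical(ml$tree$tip.label, mcmc$tree$tip.label) ||
      !identical(ml$tree$edge, mcmc$tree$edge))
    stop("tree identity error: ML and MCMC results are from different trees")
  mean(mcmc$node_support[as.character(ml$species_roots)])
}

#' Write per-node MCMC supports as TSV
#'
#' @param mcmc A `ptp_mcmc`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_node_supports <- function(mcmc, path) {
  nt <- length(mcmc$tree$tip.label)
  node <- as.integer(names(mcmc$node_support))
  out <- data.frame(node = node,
                    label = ifelse(node <= nt, mcmc$tree$tip.label[node], ""),
                    support = unname(mcmc$node_support))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
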