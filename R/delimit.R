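# Poisson Tree Processes (PTP) species delimitation.
#
# Model: on a rooted tree, a delimitation is a set of "species-root" nodes,
# pairwise non-ancestral, whose subtrees cover all tips.  Edges strictly
# inside a species subtree are "coalescent" edges; every other edge
# (including the stem edge leading into a species root) is a "speciation"
# edge.  Each edge class is an independent Poisson process on branch length:
# an edge of length b contributes an Exponential(lambda) density, with one
# lambda for the speciation class and either one shared coalescent lambda
# ("single") or one per species ("multi").  For a class with n edges of total
# length S the profile log-likelihood at the MLE lambda = n/S is
# n*log(n/S) - n.  Edges shorter than `minbr` are excluded from every
# likelihood (zero-length branches would force infinite rate estimates).
#
# Internally a delimitation is carried as the parent-closed set S of
# "speciation nodes" (internal nodes strictly above all species roots): the
# species roots are exactly the non-S nodes whose parent is in S, or the tree
# root when S is empty.  This makes enumeration (all parent-closed subsets),
# hill-climbing moves and MCMC toggles simple and exact.

PTP_MINBR <- 1e-9

# profile log-likelihood term for one exponential edge class
fpois <- function(n, s) if (n == 0L) 0 else n * (log(n / s) - 1)

# Precompute tree structure and per-node subtree statistics.
# cnt[u], ssum[u]: number / total length of included edges strictly below u.
ptp_data <- function(tree, minbr = PTP_MINBR) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a phylo object")
  if (!ape::is.rooted(tree)) stop("rooting required: PTP needs a rooted tree")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  root <- nt + 1L
  parent <- rep(NA_integer_, nn)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  blen <- rep(NA_real_, nn)
  blen[tree$edge[, 2]] <- tree$edge.length
  children <- vector("list", nn)
  for (u in seq_len(nn)) children[[u]] <- integer(0)
  for (e in seq_len(nrow(tree$edge)))
    children[[tree$edge[e, 1]]] <- c(children[[tree$edge[e, 1]]],
                                     tree$edge[e, 2])
  incl <- !is.na(blen) & blen >= minbr
  # preorder from root (iterative DFS)
  preord <- integer(nn)
  stack <- root; k <- 0L
  while (length(stack)) {
    u <- stack[length(stack)]; stack <- stack[-length(stack)]
    k <- k + 1L; preord[k] <- u
    stack <- c(stack, children[[u]])
  }
  preord <- preord[seq_len(k)]
  cnt <- integer(nn); ssum <- numeric(nn)
  for (u in rev(preord)) {
    ch <- children[[u]]
    if (length(ch)) {
      cnt[u] <- sum(cnt[ch] + incl[ch])
      ssum[u] <- sum(ssum[ch] + ifelse(incl[ch], blen[ch], 0))
    }
  }
  f_node <- vapply(seq_len(nn), function(u) fpois(cnt[u], ssum[u]), 0)
  internal <- which(seq_len(nn) > nt)
  internal_children <- lapply(children, function(ch) ch[ch > nt])
  list(tree = tree, n_tip = nt, n_node = nn, root = root, parent = parent,
       children = children, internal = internal,
       internal_children = internal_children, blen = blen, incl = incl,
       cnt = cnt, ssum = ssum, f_node = f_node,
       cnt0 = sum(incl), ssum0 = sum(blen[incl]),
       preorder = preord, minbr = minbr)
}

# species roots implied by a speciation-node set S (logical over all nodes)
roots_from_S <- function(pd, S) {
  if (!any(S)) return(pd$root)
  p <- pd$parent
  which(!S & !is.na(p) & S[p])
}

# log-likelihood of the delimitation given by species roots
delim_loglik_roots <- function(pd, roots, model = c("multi", "single")) {
  model <- match.arg(model)
  ncoal <- pd$cnt[roots]; scoal <- pd$ssum[roots]
  nsp <- pd$cnt0 - sum(ncoal); ssp <- pd$ssum0 - sum(scoal)
  ll <- fpois(nsp, ssp)
  ll + if (model == "single") fpois(sum(ncoal), sum(scoal))
       else sum(pd$f_node[roots])
}

# tips covered by each root, as labels
entities_from_roots <- function(pd, roots) {
  tips_under <- function(u) {
    if (u <= pd$n_tip) return(u)
    out <- integer(0); stack <- u
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      ch <- pd$children[[v]]
      if (!length(ch)) out <- c(out, v) else stack <- c(stack, ch)
    }
    out
  }
  lapply(roots, function(r) sort(pd$tree$tip.label[tips_under(r)]))
}

validate_roots <- function(pd, roots) {
  cover <- integer(pd$n_tip)
  for (r in roots) {
    tips <- if (r <= pd$n_tip) r else
      which(vapply(seq_len(pd$n_tip), function(t) {
        u <- t
        while (!is.na(u)) { if (u == r) return(TRUE); u <- pd$parent[u] }
        FALSE
      }, logical(1)))
    cover[tips] <- cover[tips] + 1L
  }
  if (any(cover != 1L))
    stop("invalid delimitation: species roots must partition the tips")
  invisible(TRUE)
}

#' Null (one-rate) model log-likelihood
#'
#' Fits a single exponential rate to all `n` edges of length at least `minbr`:
#' the MLE is `lambda = n / sum(b)` and the maximized log-likelihood is
#' `n*log(n/sum(b)) - n`.  This equals the log-likelihood of the single-entity
#' delimitation.
#'
#' @param tree A rooted `phylo`.
#' @param minbr Minimum branch length for an edge to enter the likelihood.
#' @return List with `loglik` and `lambda`.
#' @export
null_loglik <- function(tree, minbr = PTP_MINBR) {
  pd <- ptp_data(tree, minbr)
  if (pd$cnt0 == 0L)
    stop("degenerate tree: no edges of length >= ", minbr)
  list(loglik = fpois(pd$cnt0, pd$ssum0), lambda = pd$cnt0 / pd$ssum0)
}

#' Log-likelihood of a given delimitation
#'
#' @param tree A rooted `phylo`.
#' @param species_roots Integer node ids (ape numbering: tips `1..n`, then
#'   internals) that are pairwise non-ancestral and cover all tips.
#' @param model `"multi"` (one coalescent rate per species) or `"single"`
#'   (one shared coalescent rate).
#' @param minbr Minimum branch length included in the likelihood.
#' @return The profile log-likelihood at the per-class ML rates.
#' @export
delimitation_loglik <- function(tree, species_roots,
                                model = c("multi", "single"),
                                minbr = PTP_MINBR) {
  pd <- ptp_data(tree, minbr)
  validate_roots(pd, species_roots)
  delim_loglik_roots(pd, species_roots, match.arg(model))
}

# enumerate every parent-closed speciation-node set (as integer vectors of
# node ids); one entry per valid delimitation
enumerate_S <- function(pd) {
  rec <- function(v) {
    kids <- pd$internal_children[[v]]
    combos <- list(integer(0))
    for (k in kids) {
      sub <- rec(k)
      combos <- unlist(lapply(combos, function(a)
        lapply(sub, function(b) c(a, b))), recursive = FALSE)
    }
    c(list(integer(0)), lapply(combos, function(x) c(v, x)))
  }
  if (pd$root > pd$n_node || pd$n_tip < 2L) return(list(integer(0)))
  rec(pd$root)
}

# One-sided LRT statistic: the delimitation hypothesis asserts that
# within-species (coalescent) branching is faster than speciation branching,
# so the test statistic uses the ORDER-CONSTRAINED maximum likelihood of the
# fitted partition: every coalescent class whose unconstrained rate falls at
# or below the speciation rate is pooled into the speciation class (the
# constrained MLE sets its rate equal to the pooled rate), iterating until
# all remaining classes satisfy lambda_coal > lambda_sp.  df = number of
# unpooled coalescent classes.  A fully pooled partition reproduces the null
# exactly (stat 0).
constrained_lrt <- function(pd, roots, model) {
  nsp <- pd$cnt0 - sum(pd$cnt[roots]); ssp <- pd$ssum0 - sum(pd$ssum[roots])
  if (model == "single") {
    n_i <- sum(pd$cnt[roots]); s_i <- sum(pd$ssum[roots])
  } else {
    n_i <- pd$cnt[roots]; s_i <- pd$ssum[roots]
  }
  keep <- n_i > 0L
  n_i <- n_i[keep]; s_i <- s_i[keep]
  pooled_n <- nsp; pooled_s <- ssp
  active <- rep(TRUE, length(n_i))
  repeat {
    lam_sp <- if (pooled_s > 0) pooled_n / pooled_s else 0
    viol <- active & (n_i / s_i <= lam_sp)
    if (!any(viol)) break
    pooled_n <- pooled_n + sum(n_i[viol])
    pooled_s <- pooled_s + sum(s_i[viol])
    active[viol] <- FALSE
  }
  ll_c <- fpois(pooled_n, pooled_s) +
    sum(vapply(which(active), function(j) fpois(n_i[j], s_i[j]), 0))
  list(loglik = ll_c, df = sum(active))
}

# shared finishing step: package a delimitation result
build_delim <- function(pd, roots, model, alpha = NULL) {
  roots <- sort(roots)
  ll <- delim_loglik_roots(pd, roots, model)
  nul <- list(loglik = fpois(pd$cnt0, pd$ssum0),
              lambda = pd$cnt0 / pd$ssum0)
  con <- constrained_lrt(pd, roots, model)
  df <- max(1L, if (model == "single") 1L else length(roots))
  stat <- max(0, 2 * (con$loglik - nul$loglik))
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  reduced <- FALSE
  if (!is.null(alpha) && p >= alpha && !identical(roots, pd$root)) {
    roots <- pd$root
    ll <- nul$loglik
    reduced <- TRUE
  }
  ncoal <- pd$cnt[roots]; scoal <- pd$ssum[roots]
  nsp <- pd$cnt0 - sum(ncoal); ssp <- pd$ssum0 - sum(scoal)
  rates <- list(
    lambda_sp = if (nsp > 0) nsp / ssp else NA_real_,
    lambda_coal = if (model == "single") {
      if (sum(ncoal) > 0) sum(ncoal) / sum(scoal) else NA_real_
    } else ifelse(ncoal > 0, ncoal / scoal, NA_real_))
  entities <- entities_from_roots(pd, roots)
  names(entities) <- sprintf("entity_%d", seq_along(entities))
  structure(list(species_roots = roots, entities = entities,
                 n_entities = length(roots), loglik = ll, model = model,
                 rates = rates, null = nul,
                 lrt = list(stat = stat, df = df, p_value = p),
                 alpha = alpha, reduced_to_null = reduced,
                 minbr = pd$minbr, tree = pd$tree),
            class = "ptp_delim")
}

#' @export
print.ptp_delim <- function(x, ...) {
  cat("PTP delimitation (", x$model, "-rate model): ", x$n_entities,
      " entities over ", length(x$tree$tip.label), " tips\n", sep = "")
  cat(sprintf("  loglik %.4f (null %.4f), LRT p = %.4g (df = %d)\n",
              x$loglik, x$null$loglik, x$lrt$p_value, x$lrt$df))
  if (isTRUE(x$reduced_to_null))
    cat("  LRT not significant: single entity returned\n")
  invisible(x)
}

#' Exhaustive maximum-likelihood delimitation (enumeration oracle)
#'
#' Enumerates every valid delimitation (every antichain of nodes covering the
#' tips), scores each under the PTP likelihood, and returns the maximum; ties
#' are broken toward fewer entities.  Feasible for small trees only and used
#' as the correctness anchor for the heuristic search.
#'
#' @param tree A rooted `phylo` with at most `max_tips` tips.
#' @param model `"multi"` or `"single"` coalescent-rate model.
#' @param alpha Optional likelihood-ratio-test level; when given, the
#'   single-entity delimitation is returned if the test is not significant.
#' @param minbr Minimum branch length included in the likelihood.
#' @param max_tips Enumeration bound (default 12).
#' @return A `ptp_delim` object.
#' @export
brute_force_ml <- function(tree, model = c("multi", "single"), alpha = NULL,
                           minbr = PTP_MINBR, max_tips = 12) {
  model <- match.arg(model)
  pd <- ptp_data(tree, minbr)
  if (pd$n_tip > max_tips)
    stop("size error: enumeration limited to ", max_tips, " tips")
  if (pd$cnt0 == 0L) stop("degenerate tree: no edges of length >= ", minbr)
  sets <- enumerate_S(pd)
  best_ll <- -Inf; best_roots <- NULL; tol <- 1e-12
  for (S_nodes in sets) {
    S <- logical(pd$n_node); S[S_nodes] <- TRUE
    roots <- roots_from_S(pd, S)
    ll <- delim_loglik_roots(pd, roots, model)
    if (ll > best_ll + tol ||
        (abs(ll - best_ll) <= tol && length(roots) < length(best_roots))) {
      best_ll <- ll; best_roots <- roots
    }
  }
  build_delim(pd, best_roots, model, alpha)
}

# Exact optimal partition for FIXED rates, by dynamic programming over the
# antichain lattice: with both class rates held fixed the log-likelihood is
# additive over edges, so each node independently chooses "species root"
# (its subtree becomes one coalescent class; under the multi model that
# class's rate is profiled out via f_node) or "speciation node" (its child
# edges pay the speciation term and the children choose recursively).
# Returns the speciation-node set S.
dp_partition <- function(pd, model, lambda_sp, lambda_coal = NULL) {
  nn <- pd$n_node
  sp_term <- ifelse(pd$incl, log(lambda_sp) - lambda_sp * pd$blen, 0)
  root_score <- if (model == "multi") pd$f_node
                else pd$cnt * log(lambda_coal) - lambda_coal * pd$ssum
  g <- numeric(nn); split <- logical(nn)
  for (u in rev(pd$preorder)) {
    ch <- pd$children[[u]]
    if (!length(ch)) { g[u] <- 0; next }
    opt_split <- sum(sp_term[ch] + g[ch])
    if (opt_split > root_score[u] + 1e-12) {
      g[u] <- opt_split; split[u] <- TRUE
    } else g[u] <- root_score[u]            # tie -> lump
  }
  S <- logical(nn)
  stack <- if (split[pd$root]) pd$root else integer(0)
  while (length(stack)) {
    u <- stack[length(stack)]; stack <- stack[-length(stack)]
    S[u] <- TRUE
    ch <- pd$children[[u]]
    stack <- c(stack, ch[split[ch]])
  }
  S
}

# coordinate ascent: alternate the fixed-rate DP with profile-ML rate
# updates until the partition stabilizes
dp_ascent <- function(pd, model, lambda_sp, lambda_coal) {
  prev <- NULL
  for (it in 1:100) {
    S <- dp_partition(pd, model, lambda_sp, lambda_coal)
    roots <- roots_from_S(pd, S)
    key <- paste(sort(roots), collapse = "-")
    if (identical(key, prev)) break
    prev <- key
    ncoal <- sum(pd$cnt[roots]); scoal <- sum(pd$ssum[roots])
    nsp <- pd$cnt0 - ncoal; ssp <- pd$ssum0 - scoal
    if (nsp == 0L || ssp <= 0) break
    lambda_sp <- nsp / ssp
    if (model == "single") {
      if (ncoal == 0L || scoal <= 0) break
      lambda_coal <- ncoal / scoal
    }
  }
  S
}

# grid of rate initializations from the included branch-length distribution:
# split edges at several quantiles into a putative short (coalescent) and
# long (speciation) fraction
rate_starts <- function(pd, model) {
  b <- pd$blen[!is.na(pd$blen) & pd$incl]
  lam0 <- pd$cnt0 / pd$ssum0
  starts <- list(c(sp = lam0, coal = lam0))
  qs <- c(0.1, 0.25, 0.5, 0.75, 0.9)
  lo_rates <- hi_rates <- numeric(0)
  for (q in qs) {
    cut <- stats::quantile(b, q, names = FALSE)
    lo <- b[b <= cut]; hi <- b[b > cut]
    if (length(lo) && mean(lo) > 0) lo_rates <- c(lo_rates, 1 / mean(lo))
    if (length(hi) && mean(hi) > 0) hi_rates <- c(hi_rates, 1 / mean(hi))
  }
  rates <- unique(c(lo_rates, hi_rates, lam0))
  if (model == "multi") {
    # coalescent rates are profiled out: only lambda_sp matters
    for (sp in rates)
      starts <- c(starts, list(c(sp = sp, coal = lam0)))
  } else {
    # both orientations: the ML speciation class can be the short- or the
    # long-edge class depending on the tree
    for (sp in rates) for (coal in rates)
      starts <- c(starts, list(c(sp = sp, coal = coal)))
  }
  starts
}

# internal nodes strictly inside the subtree of v
subtree_internals <- function(pd, v) {
  out <- integer(0); stack <- pd$internal_children[[v]]
  while (length(stack)) {
    u <- stack[length(stack)]; stack <- stack[-length(stack)]
    out <- c(out, u)
    stack <- c(stack, pd$internal_children[[u]])
  }
  out
}

# best-improvement hill climb over parent-closed sets S, then zero-loss
# merge polishing (ties resolved toward fewer entities)
climb_S <- function(pd, S, model) {
  tol <- 1e-12
  valid_toggle <- function(S, v) {
    if (S[v]) !any(S[pd$internal_children[[v]]])
    else v == pd$root || S[pd$parent[v]]
  }
  ll <- delim_loglik_roots(pd, roots_from_S(pd, S), model)
  repeat {
    # depth 1: best single toggle
    best_delta <- tol; best_v <- 0L
    for (v in pd$internal) {
      if (!valid_toggle(S, v)) next
      S[v] <- !S[v]
      cand <- delim_loglik_roots(pd, roots_from_S(pd, S), model)
      S[v] <- !S[v]
      if (cand - ll > best_delta) { best_delta <- cand - ll; best_v <- v }
    }
    if (best_v != 0L) {
      S[best_v] <- !S[best_v]
      ll <- ll + best_delta
      next
    }
    # macro rescue: collapse a whole subtree to one entity, or shatter it
    # into singletons (coordinated multi-node moves)
    best_delta <- tol; best_S <- NULL
    for (v in pd$internal) {
      sub <- subtree_internals(pd, v)
      if (S[v] || any(S[sub])) {              # collapse subtree(v)
        S2 <- S; S2[c(v, sub)] <- FALSE
        if (v == pd$root || S2[pd$parent[v]] || !any(S2)) {
          cand <- delim_loglik_roots(pd, roots_from_S(pd, S2), model)
          if (cand - ll > best_delta) { best_delta <- cand - ll; best_S <- S2 }
        }
      }
      if (!all(S[c(v, sub)])) {               # shatter subtree(v)
        if (v == pd$root || S[pd$parent[v]]) {
          S2 <- S; S2[c(v, sub)] <- TRUE
          cand <- delim_loglik_roots(pd, roots_from_S(pd, S2), model)
          if (cand - ll > best_delta) { best_delta <- cand - ll; best_S <- S2 }
        }
      }
    }
    if (!is.null(best_S)) {
      S <- best_S
      ll <- ll + best_delta
      next
    }
    # depth 2 rescue: best pair of toggles (ridges the single move cannot see)
    best_delta <- tol; best_pair <- NULL
    for (v in pd$internal) {
      if (!valid_toggle(S, v)) next
      S[v] <- !S[v]
      for (w in pd$internal) {
        if (w == v || !valid_toggle(S, w)) next
        S[w] <- !S[w]
        cand <- delim_loglik_roots(pd, roots_from_S(pd, S), model)
        S[w] <- !S[w]
        if (cand - ll > best_delta) {
          best_delta <- cand - ll; best_pair <- c(v, w)
        }
      }
      S[v] <- !S[v]
    }
    if (is.null(best_pair)) break
    S[best_pair] <- !S[best_pair]
    ll <- ll + best_delta
  }
  # merge entities while the likelihood does not drop (lumping tie-break)
  repeat {
    merged <- FALSE
    for (v in pd$internal) {
      if (!S[v] || any(S[pd$internal_children[[v]]])) next
      S[v] <- FALSE
      cand <- delim_loglik_roots(pd, roots_from_S(pd, S), model)
      if (cand >= ll - tol) { ll <- cand; merged <- TRUE }
      else S[v] <- TRUE
    }
    if (!merged) break
  }
  list(S = S, ll = ll)
}

#' Maximum-likelihood PTP delimitation with LRT
#'
#' Heuristic search for the maximum-likelihood delimitation: best-improvement
#' hill climbing over split/merge moves, started both from the single-entity
#' state and from the all-singletons state, followed by zero-loss merge
#' repair.  The winner is tested against the one-rate null by a likelihood
#' ratio test (chi-squared, df = number of free rate parameters minus one);
#' when `p >= alpha` the single-entity delimitation is returned.
#'
#' @param tree A rooted `phylo`.
#' @param model `"multi"` (default; one coalescent rate per species) or
#'   `"single"`.
#' @param alpha LRT level (default 0.01); `NULL` skips the test and returns
#'   the best delimitation found.
#' @param minbr Minimum branch length included in the likelihood.
#' @return A `ptp_delim` object.
#' @export
ml_delimitation <- function(tree, model = c("multi", "single"), alpha = 0.01,
                            minbr = PTP_MINBR) {
  model <- match.arg(model)
  if (!is.null(alpha) && (!is.numeric(alpha) || alpha <= 0 || alpha > 1))
    stop("invalid `alpha`: must be in (0, 1]")
  pd <- ptp_data(tree, minbr)
  if (pd$cnt0 == 0L) stop("degenerate tree: no edges of length >= ", minbr)
  if (pd$n_tip < 2L)
    return(build_delim(pd, pd$root, model, alpha))
  S0 <- logical(pd$n_node)                       # single entity
  S1 <- logical(pd$n_node); S1[pd$internal] <- TRUE  # all singletons
  starts <- list(S0, S1)
  for (rs in rate_starts(pd, model))
    starts <- c(starts, list(dp_ascent(pd, model, rs[["sp"]], rs[["coal"]])))
  keys <- vapply(starts, function(S) paste(which(S), collapse = "-"),
                 character(1))
  starts <- starts[!duplicated(keys)]
  tol <- 1e-12
  pick <- NULL
  for (S in starts) {
    cand <- climb_S(pd, S, model)
    if (is.null(pick) || cand$ll > pick$ll + tol ||
        (abs(cand$ll - pick$ll) <= tol &&
         length(roots_from_S(pd, cand$S)) < length(roots_from_S(pd, pick$S))))
      pick <- cand
  }
  build_delim(pd, roots_from_S(pd, pick$S), model, alpha)
}

#' Write delimitation reports
#'
#' `write_entities()` writes `entity_id<TAB>tip` rows; `write_delim_summary()`
#' writes a JSON summary (`loglik_null`, `loglik_ml`, `p_value`, `n_entities`,
#' `asv`, `seed`).
#'
#' @param delim A `ptp_delim`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_entities <- function(delim, path) {
  rows <- do.call(rbind, lapply(names(delim$entities), function(id)
    data.frame(entity_id = id, tip = delim$entities[[id]])))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_entities
#' @param asv Average Support Value to record (or `NA`).
#' @param seed Seed to record (or `NA`).
#' @export
write_delim_summary <- function(delim, path, asv = NA_real_, seed = NA) {
  jsonlite::write_json(
    list(loglik_null = delim$null$loglik, loglik_ml = delim$loglik,
         p_value = delim$lrt$p_value, n_entities = delim$n_entities,
         asv = asv, seed = seed, model = delim$model),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
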