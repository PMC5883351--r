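# Marker evaluation: species-discrimination scoring and the per-marker
# report (variable sites, entities, discrimination, optional MCMC/ASV) for
# individual markers and concatenated combinations.

#' Species-discrimination success of a delimitation
#'
#' Under the default `"exact"` rule a species is identified iff some delimited
#' entity's tip set equals exactly that species' accession set (all of its
#' accessions, no foreign ones).  The looser `"loose"` rule requires the
#' species to be neither split (all accessions in one entity) nor lumped
#' (that entity does not also contain another species' complete accession
#' set).  Species with no accession present in the delimitation are excluded
#' from the denominator.
#'
#' @param x A `ptp_delim`, or a list of character vectors of tip labels
#'   (one per entity).
#' @param species_map Accession/species data.frame (see
#'   [read_species_map()]).
#' @param mode `"exact"` (default) or `"loose"`.
#' @return List with `n_identified`, `n_species`, `fraction`, `percent` and
#'   the per-species logical vector `identified`.
#' @export
species_discrimination <- function(x, species_map, mode = c("exact", "loose")) {
  mode <- match.arg(mode)
  entities <- if (inherits(x, "ptp_delim")) x$entities else x
  if (!is.list(entities) || !length(entities))
    stop("`x` must be a ptp_delim or a list of entity tip sets")
  tips <- unlist(entities)
  unmapped <- setdiff(tips, species_map$accession)
  if (length(unmapped))
    stop("label error: tips without species assignment: ",
         paste(unmapped, collapse = ", "))
  sp_sets <- lapply(split(species_map$accession, species_map$species),
                    intersect, tips)
  sp_sets <- Filter(length, sp_sets)
  identified <- vapply(names(sp_sets), function(s) {
    stips <- sp_sets[[s]]
    if (mode == "exact")
      return(any(vapply(entities, setequal, logical(1), stips)))
    holder <- which(vapply(entities, function(e) all(stips %in% e),
                           logical(1)))
    if (!length(holder)) return(FALSE)          # split across entities
    e <- entities[[holder[1]]]
    others <- sp_sets[setdiff(names(sp_sets), s)]
    !any(vapply(others, function(o) all(o %in% e), logical(1)))  # lumped?
  }, logical(1))
  list(n_identified = sum(identified), n_species = length(sp_sets),
       fraction = sum(identified) / length(sp_sets),
       percent = 100 * sum(identified) / length(sp_sets),
       identified = identified)
}

#' Evaluate markers and marker combinations
#'
#' For each region (and each concatenated combination) this extracts the
#' sub-alignment, computes the percentage of variable sites, builds (or
#' imports) a tree, roots it, runs ML PTP delimitation (optionally followed
#' by MCMC for an ASV), and scores species discrimination.  Deterministic for
#' a fixed seed.
#'
#' @param aln Full `msa` alignment.
#' @param regions Region data.frame (`name`, `start`, `end`; see
#'   [propose_regions()] / [read_regions()]).
#' @param species_map Accession/species data.frame covering all ingroup taxa.
#' @param combos List of character vectors of region names to concatenate
#'   (each becomes one extra report row, named by joining the member names
#'   with `+`).
#' @param dist_model Distance model for the NJ engine (`"jc69"` or `"p"`).
#' @param delim_model PTP model (`"multi"` or `"single"`).
#' @param alpha LRT level for [ml_delimitation()].
#' @param mcmc_steps MCMC samples per chain; `0` (default) skips MCMC and
#'   reports `asv = NA`.
#' @param chains,burnin MCMC settings (used when `mcmc_steps > 0`).
#' @param seed Base seed; unit `i` uses `seed + i` for its MCMC.
#' @param outgroup Optional outgroup tip labels: used for rooting, then
#'   pruned before delimitation.  Without an outgroup, trees are
#'   midpoint-rooted.
#' @param trees Optional named list of externally built trees (`phylo`,
#'   rooted or rootable), keyed by region/combo name; bypasses the NJ engine
#'   for those units.
#' @param mode Discrimination rule (see [species_discrimination()]).
#' @return A `marker_report` data.frame: one row per marker and combination
#'   with `name`, `type`, `start`, `end`, `n_columns`,
#'   `percent_variable_sites`, `n_entities`, `n_species_identified`,
#'   `percent_species_identified`, `asv`, `loglik`, `p_value`.
#' @export
evaluate_markers <- function(aln, regions, species_map, combos = list(),
                             dist_model = "jc69", delim_model = "multi",
                             alpha = 0.01, mcmc_steps = 0, chains = 2,
                             burnin = 0.10, seed = 1, outgroup = NULL,
                             trees = NULL, mode = "exact") {
  if (!nrow(regions)) stop("no regions to evaluate")
  if (anyDuplicated(regions$name))
    stop("label error: duplicate region names")
  validate_species_map(species_map)
  for (cb in combos) {
    unknown <- setdiff(cb, regions$name)
    if (length(unknown))
      stop("label error: combo references unknown regions: ",
           paste(unknown, collapse = ", "))
  }
  subs <- lapply(seq_len(nrow(regions)), function(i)
    extract_region(aln, regions[i, ]))
  names(subs) <- regions$name
  units <- c(
    lapply(seq_len(nrow(regions)), function(i)
      list(name = regions$name[i], type = "marker",
           start = regions$start[i], end = regions$end[i],
           aln = subs[[i]])),
    lapply(combos, function(cb)
      list(name = paste(cb, collapse = "+"), type = "combo",
           start = NA_integer_, end = NA_integer_,
           aln = concatenate_alignments(subs[cb]))))
  rows <- lapply(seq_along(units), function(i) {
    u <- units[[i]]
    tryCatch(
      evaluate_one(u, species_map, dist_model, delim_model, alpha,
                   mcmc_steps, chains, burnin, seed + i, outgroup,
                   trees[[u$name]], mode),
      error = function(e)
        stop("marker '", u$name, "': ", conditionMessage(e), call. = FALSE))
  })
  out <- do.call(rbind, rows)
  attr(out, "run") <- list(seed = seed, dist_model = dist_model,
                           delim_model = delim_model, alpha = alpha,
                           mcmc_steps = mcmc_steps, chains = chains,
                           burnin = burnin, mode = mode,
                           outgroup = outgroup)
  class(out) <- c("marker_report", "data.frame")
  out
}

evaluate_one <- function(u, species_map, dist_model, delim_model, alpha,
                         mcmc_steps, chains, burnin, seed, outgroup,
                         ext_tree, mode) {
  pct_var <- percent_variable_sites(u$aln)
  tr <- if (!is.null(ext_tree)) ext_tree
        else nj_tree(pairwise_distance(u$aln, dist_model))
  if (!is.null(outgroup)) {
    tr <- root_with_outgroup(tr, outgroup)
    tr <- prune_taxa(tr, outgroup)
    if (!ape::is.rooted(tr)) tr <- midpoint_root(tr)
  } else if (!ape::is.rooted(tr)) {
    tr <- midpoint_root(tr)
  }
  ml <- ml_delimitation(tr, model = delim_model, alpha = alpha)
  asv_val <- NA_real_
  if (mcmc_steps > 0) {
    mc <- mcmc_delimitation(tr, steps = mcmc_steps, chains = chains,
                            burnin = burnin, seed = seed,
                            model = delim_model)
    asv_val <- asv(ml, mc)
  }
  sm <- species_map[!(species_map$accession %in% outgroup), , drop = FALSE]
  disc <- species_discrimination(ml, sm, mode)
  data.frame(name = u$name, type = u$type, start = u$start, end = u$end,
             n_columns = aln_length(u$aln),
             percent_variable_sites = pct_var,
             n_entities = ml$n_entities,
             n_species_identified = disc$n_identified,
             percent_species_identified = disc$percent,
             asv = asv_val, loglik = ml$loglik,
             p_value = ml$lrt$p_value)
}

#' Write a marker report as TSV
#'
#' @param report A `marker_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_marker_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
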