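# Stage runner: validated run configuration, per-stage artifact writing and
# JSON run manifests.  The analysis/ scripts are thin drivers over these
# functions; `run_stage("evaluate", cfg)` composes the whole workflow
# (scan -> propose -> trees -> delimitation -> discrimination).

RUN_STAGES <- c("simulate", "scan", "propose", "extract", "tree", "delimit",
                "evaluate")

#' Build and validate a run configuration
#'
#' Defaults follow the pipeline's standard settings: 800-column windows,
#' LRT level 0.01, two MCMC chains, 10% burn-in.  Invalid values raise an
#' error naming the offending field.
#'
#' @param alignment,species_map,regions,tree Input paths (stage-dependent).
#' @param out Output directory.
#' @param window_size SNP-density window width in columns.
#' @param alpha LRT level in (0, 1).
#' @param steps MCMC samples per chain.
#' @param chains Number of MCMC chains.
#' @param burnin Burn-in fraction in [0, 1).
#' @param seed Integer RNG seed.
#' @param model PTP model, `"multi"` or `"single"`.
#' @param engine Tree engine: `"nj"` (built-in) or `"external"` (import the
#'   Newick given in `tree`).
#' @param dist_model NJ distance model (`"jc69"` or `"p"`).
#' @param profile Simulation profile for the `simulate` stage.
#' @param combos List of region-name vectors for the `evaluate` stage.
#' @param outgroup Optional outgroup tip labels.
#' @param min_class,merge_gap Region-proposal settings.
#' @param bootstrap Bootstrap replicates for the `tree` stage (0 = none).
#' @param mcmc_steps MCMC samples for `evaluate` (0 skips MCMC there).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(alignment = NULL, species_map = NULL, regions = NULL,
                       tree = NULL, out = ".", window_size = 800,
                       alpha = 0.01, steps = 50000, chains = 2,
                       burnin = 0.10, seed = 1,
                       model = c("multi", "single"),
                       engine = c("nj", "external"), dist_model = "jc69",
                       profile = "easy", combos = list(), outgroup = NULL,
                       min_class = "moderate", merge_gap = 1,
                       bootstrap = 0, mcmc_steps = 0) {
  bad <- function(field, why)
    stop("configuration error: invalid `", field, "`: ", why, call. = FALSE)
  chk_count <- function(x, field, min) {
    x <- suppressWarnings(as.integer(x))
    if (length(x) != 1 || is.na(x) || x < min)
      bad(field, paste("must be an integer >=", min))
    x
  }
  window_size <- chk_count(window_size, "window_size", 1L)
  steps <- chk_count(steps, "steps", 100L)
  chains <- chk_count(chains, "chains", 1L)
  seed <- chk_count(seed, "seed", -.Machine$integer.max)
  merge_gap <- chk_count(merge_gap, "merge_gap", 0L)
  bootstrap <- chk_count(bootstrap, "bootstrap", 0L)
  mcmc_steps <- if (identical(mcmc_steps, 0) || identical(mcmc_steps, 0L)) 0L
                else chk_count(mcmc_steps, "mcmc_steps", 100L)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    bad("alpha", "must be in (0, 1)")
  if (!is.numeric(burnin) || length(burnin) != 1 || burnin < 0 || burnin >= 1)
    bad("burnin", "must be in [0, 1)")
  model <- match.arg(model)
  engine <- match.arg(engine)
  if (!dist_model %in% c("jc69", "p")) bad("dist_model", "must be jc69 or p")
  if (!profile %in% c("easy", "hard", "null"))
    bad("profile", "must be easy, hard or null")
  if (!min_class %in% WINDOW_CLASSES)
    bad("min_class", "must be low, moderate or high")
  if (engine == "external" && is.null(tree))
    bad("tree", "engine 'external' needs a tree path")
  structure(list(alignment = alignment, species_map = species_map,
                 regions = regions, tree = tree, out = out,
                 window_size = window_size, alpha = alpha, steps = steps,
                 chains = chains, burnin = burnin, seed = seed,
                 model = model, engine = engine, dist_model = dist_model,
                 profile = profile, combos = combos, outgroup = outgroup,
                 min_class = min_class, merge_gap = merge_gap,
                 bootstrap = bootstrap, mcmc_steps = mcmc_steps),
            class = "run_config")
}

#' Run a pipeline stage
#'
#' Executes one named stage against the configured inputs, writes its
#' artifacts under `cfg$out`, and records a JSON manifest (configuration,
#' seed, input checksums, package/R versions, stage timing) next to them.
#'
#' @param name One of `"simulate"`, `"scan"`, `"propose"`, `"extract"`,
#'   `"tree"`, `"delimit"`, `"evaluate"`.
#' @param cfg A [run_config()].
#' @return Invisibly, a named character vector of artifact paths.
#' @export
run_stage <- function(name, cfg) {
  if (!inherits(cfg, "run_config")) stop("`cfg` must come from run_config()")
  if (!name %in% RUN_STAGES)
    stop("unknown subcommand '", name, "'; expected one of: ",
         paste(RUN_STAGES, collapse = ", "))
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  paths <- switch(name,
    simulate = stage_simulate(cfg),
    scan = stage_scan(cfg),
    propose = stage_propose(cfg),
    extract = stage_extract(cfg),
    tree = stage_tree(cfg),
    delimit = stage_delimit(cfg),
    evaluate = stage_evaluate(cfg))
  elapsed <- proc.time()[["elapsed"]] - t0
  manifest <- file.path(cfg$out, paste0(name, "_manifest.json"))
  write_manifest(manifest, name, cfg, paths, elapsed)
  message(sprintf("[%s] wrote %d artifact(s) in %.2fs -> %s",
                  name, length(paths), elapsed, cfg$out))
  invisible(c(paths, manifest = manifest))
}

write_manifest <- function(path, stage, cfg, artifacts, elapsed) {
  inputs <- Filter(function(p) is.character(p) && length(p) == 1 &&
                     file.exists(p),
                   cfg[c("alignment", "species_map", "regions", "tree")])
  jsonlite::write_json(
    list(stage = stage,
         config = cfg[setdiff(names(cfg), "combos")],
         combos = lapply(cfg$combos, identity),
         input_md5 = as.list(vapply(inputs, function(p)
           unname(tools::md5sum(p)), character(1))),
         artifacts = as.list(artifacts),
         package = as.character(utils::packageVersion("markerptp")),
         r_version = R.version.string,
         elapsed_seconds = elapsed,
         timestamp = format(Sys.time(), tz = "UTC")),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

stage_simulate <- function(cfg) {
  fx <- end_to_end_fixture(cfg$profile, cfg$seed)
  write_simulation(fx, cfg$out)
}

load_aln <- function(cfg) {
  if (is.null(cfg$alignment)) stop("configuration error: invalid `alignment`: path required")
  read_alignment(cfg$alignment)
}

stage_scan <- function(cfg) {
  aln <- load_aln(cfg)
  wd <- classify_windows(bin_density(extract_snps(aln),
                                     window_size = cfg$window_size))
  paths <- c(density = file.path(cfg$out, "window_density.tsv"),
             snps = file.path(cfg$out, "snp_positions.bed"),
             hot = file.path(cfg$out, "variable_windows.bed"))
  write_window_density(wd, paths["density"])
  write_snp_bed(extract_snps(aln), paths["snps"])
  write_window_bed(wd, paths["hot"], min_class = "high")
  paths
}

stage_propose <- function(cfg) {
  aln <- load_aln(cfg)
  wd <- classify_windows(bin_density(extract_snps(aln),
                                     window_size = cfg$window_size))
  regions <- propose_regions(wd, min_class = cfg$min_class,
                             merge_gap = cfg$merge_gap)
  p <- c(regions = file.path(cfg$out, "proposed_regions.tsv"))
  write_regions(regions, p["regions"])
  p
}

stage_extract <- function(cfg) {
  aln <- load_aln(cfg)
  if (is.null(cfg$regions)) stop("configuration error: invalid `regions`: path required")
  regions <- read_regions(cfg$regions)
  paths <- character(0)
  for (i in seq_len(nrow(regions))) {
    p <- file.path(cfg$out, paste0(regions$name[i], ".fasta"))
    write_alignment(extract_region(aln, regions[i, ]), p)
    paths[regions$name[i]] <- p
  }
  paths
}

stage_tree <- function(cfg) {
  aln <- load_aln(cfg)
  tr <- if (cfg$bootstrap > 0)
    bootstrap_support(aln, reps = cfg$bootstrap, seed = cfg$seed,
                      model = cfg$dist_model)
  else nj_tree(pairwise_distance(aln, cfg$dist_model))
  p <- c(tree = file.path(cfg$out, "nj_tree.nwk"))
  write_newick(tr, p["tree"])
  p
}

stage_delimit <- function(cfg) {
  if (is.null(cfg$tree)) stop("configuration error: invalid `tree`: path required")
  tr <- read_newick(cfg$tree)
  if (!is.null(cfg$outgroup)) {
    tr <- root_with_outgroup(tr, cfg$outgroup)
    tr <- prune_taxa(tr, cfg$outgroup)
  }
  if (!ape::is.rooted(tr)) tr <- midpoint_root(tr)
  ml <- ml_delimitation(tr, model = cfg$model, alpha = cfg$alpha)
  mc <- mcmc_delimitation(tr, steps = cfg$steps, chains = cfg$chains,
                          burnin = cfg$burnin, seed = cfg$seed,
                          model = cfg$model)
  paths <- c(entities = file.path(cfg$out, "entities.tsv"),
             supports = file.path(cfg$out, "node_supports.tsv"),
             summary = file.path(cfg$out, "delimitation.json"))
  write_entities(ml, paths["entities"])
  write_node_supports(mc, paths["supports"])
  write_delim_summary(ml, paths["summary"], asv = asv(ml, mc),
                      seed = cfg$seed)
  paths
}

stage_evaluate <- function(cfg) {
  aln <- load_aln(cfg)
  if (is.null(cfg$species_map)) stop("configuration error: invalid `species_map`: path required")
  sm <- read_species_map(cfg$species_map)
  regions <- if (!is.null(cfg$regions)) read_regions(cfg$regions) else {
    wd <- classify_windows(bin_density(extract_snps(aln),
                                       window_size = cfg$window_size))
    propose_regions(wd, min_class = cfg$min_class,
                    merge_gap = cfg$merge_gap)
  }
  report <- evaluate_markers(aln, regions, sm, combos = cfg$combos,
                             dist_model = cfg$dist_model,
                             delim_model = cfg$model, alpha = cfg$alpha,
                             mcmc_steps = cfg$mcmc_steps,
                             chains = cfg$chains, burnin = cfg$burnin,
                             seed = cfg$seed, outgroup = cfg$outgroup)
  p <- c(report = file.path(cfg$out, "marker_report.tsv"))
  write_marker_report(report, p["report"])
  p
}
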