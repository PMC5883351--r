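# Candidate marker regions: propose from classified windows, extract
# sub-alignments, and read/write region tables.

#' Propose candidate marker regions from classified windows
#'
#' Maximal runs of windows whose class is at least `min_class` become regions;
#' up to `merge_gap` consecutive below-threshold windows are allowed inside a
#' run (so adjacent variable windows separated by a single quiet window merge
#' into one region by default).  Regions are ordered by their total SNP count,
#' descending, and named `R<start>-<end>`.
#'
#' @param wd A classified `window_density` (see [classify_windows()]).
#' @param min_class Minimum window class to seed/extend a region
#'   (default `"moderate"`).
#' @param merge_gap Maximum number of below-threshold windows bridged inside
#'   a region (default 1).
#' @return A data.frame with columns `name`, `start`, `end`, `snp_count`,
#'   `source` (`"auto"`); zero rows when no window qualifies.
#' @export
propose_regions <- function(wd, min_class = "moderate", merge_gap = 1) {
  if (!inherits(wd, "window_density")) stop("`wd` must be a window_density")
  if (anyNA(wd$class)) stop("windows are unclassified; run classify_windows()")
  merge_gap <- as.integer(merge_gap)
  if (is.na(merge_gap) || merge_gap < 0) stop("invalid `merge_gap`")
  qual <- which(class_at_least(wd$class, min_class))
  if (!length(qual)) return(empty_regions())
  grp <- cumsum(c(1L, diff(qual) > merge_gap + 1L))
  regions <- do.call(rbind, lapply(split(qual, grp), function(ix) {
    i1 <- min(ix); i2 <- max(ix)
    data.frame(start = wd$start[i1], end = wd$end[i2],
               snp_count = sum(wd$snp_count[i1:i2]))
  }))
  regions <- regions[order(-regions$snp_count, regions$start), , drop = FALSE]
  data.frame(name = sprintf("R%d-%d", regions$start, regions$end),
             start = regions$start, end = regions$end,
             snp_count = regions$snp_count, source = "auto",
             row.names = NULL)
}

empty_regions <- function() {
  data.frame(name = character(), start = integer(), end = integer(),
             snp_count = integer(), source = character())
}

#' Extract a column region from an alignment
#'
#' @param aln An `msa` alignment.
#' @param start,end 1-based inclusive column bounds; alternatively `start` may
#'   be a one-row region data.frame with `start` and `end` columns.
#' @return The sub-alignment over columns `[start, end]`, all taxa retained.
#' @export
extract_region <- function(aln, start, end = NULL) {
  if (is.data.frame(start)) {
    r <- start
    if (nrow(r) != 1L) stop("pass a single region row")
    start <- r$start; end <- r$end
  }
  start <- as.integer(start); end <- as.integer(end)
  L <- aln_length(aln)
  if (is.na(start) || is.na(end) || start < 1L || end > L || start > end)
    stop("coordinate error: region must satisfy 1 <= start <= end <= ", L)
  new_msa(unclass(aln)[, start:end, drop = FALSE])
}

#' Read or write a marker-region table
#'
#' Region TSVs have a header `name<TAB>start<TAB>end` with 1-based inclusive
#' alignment columns; regions read from file are tagged `source = "user"`
#' (this is how gene-anchored names such as `trnC-rps16` enter the pipeline,
#' since annotation lift-over is out of scope).
#'
#' @param path TSV path.
#' @return `read_regions()` returns a region data.frame.
#' @export
read_regions <- function(path) {
  r <- utils::read.delim(path, header = TRUE, sep = "\t")
  if (!all(c("name", "start", "end") %in% names(r)))
    stop("region table needs columns name, start, end")
  data.frame(name = as.character(r$name), start = as.integer(r$start),
             end = as.integer(r$end),
             snp_count = if ("snp_count" %in% names(r))
               as.integer(r$snp_count) else NA_integer_,
             source = "user")
}

#' @rdname read_regions
#' @param regions Region data.frame.
#' @export
write_regions <- function(regions, path) {
  cols <- intersect(c("name", "start", "end", "snp_count"), names(regions))
  utils::write.table(regions[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
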