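# SNP extraction and windowed density classification.
#
# A column is a SNP iff at least two distinct unambiguous nucleotides
# (A/C/G/T) occur in it; gaps, N and IUPAC ambiguity codes never count as
# states.  Window counts are classified by the z-score of each window's SNP
# count against the mean and sample standard deviation of all window counts:
# z < 1 low, 1 <= z < 2 moderate, z >= 2 high.

WINDOW_CLASSES <- c("low", "moderate", "high")

#' Extract SNP positions from an alignment
#'
#' @param aln An `msa` alignment.
#' @return An object of class `snp_table`: list with `positions` (sorted
#'   1-based column indices), `states` (per position, a table of the
#'   unambiguous nucleotides observed), `L` (alignment length) and `n_taxa`.
#' @examples
#' extract_snps(msa(c(a = "ACGT", b = "ACGA")))$positions
#' @export
extract_snps <- function(aln) {
  if (!inherits(aln, "msa")) stop("`aln` must be an msa alignment")
  mat <- unclass(aln)
  present <- vapply(c("A", "C", "G", "T"),
                    function(b) colSums(mat == b) > 0L,
                    logical(ncol(mat)))
  if (ncol(mat) == 1L) present <- matrix(present, nrow = 1L)
  nstates <- rowSums(present)
  pos <- which(nstates >= 2L)
  states <- lapply(pos, function(j) {
    v <- mat[, j]
    table(v[v %in% c("A", "C", "G", "T")])
  })
  names(states) <- pos
  structure(list(positions = pos, states = states,
                 L = ncol(mat), n_taxa = nrow(mat)),
            class = "snp_table")
}

#' @export
print.snp_table <- function(x, ...) {
  cat("SnpTable:", length(x$positions), "SNP columns out of", x$L,
      "(", x$n_taxa, "taxa )\n")
  invisible(x)
}

#' Bin SNP positions into fixed-width windows
#'
#' Windows tile `[1, L]` as `[1, w]`, `[w+1, 2w]`, ... with a final partial
#' window when `L` is not a multiple of the window size.
#'
#' @param snps An `snp_table`, or an integer vector of 1-based SNP positions.
#' @param L Alignment length in columns (taken from the `snp_table` if
#'   omitted).
#' @param window_size Window width in columns (default 800).
#' @return A `window_density` data.frame with columns `start`, `end`,
#'   `snp_count`, `z`, `class` (`z`/`class` are `NA` until
#'   [classify_windows()] is applied).
#' @export
bin_density <- function(snps, L = NULL, window_size = 800) {
  if (inherits(snps, "snp_table")) {
    if (is.null(L)) L <- snps$L
    pos <- snps$positions
  } else {
    pos <- as.integer(snps)
    if (is.null(L)) stop("`L` is required when passing raw positions")
  }
  window_size <- as.integer(window_size)
  if (is.na(window_size) || window_size < 1L)
    stop("invalid `window_size`: must be >= 1")
  if (length(pos) && (any(pos < 1L) || any(pos > L)))
    stop("coordinate error: SNP positions outside [1, ", L, "]")
  n_win <- as.integer(ceiling(L / window_size))
  starts <- (seq_len(n_win) - 1L) * window_size + 1L
  ends <- pmin(starts + window_size - 1L, L)
  counts <- tabulate((pos - 1L) %/% window_size + 1L, nbins = n_win)
  structure(data.frame(start = starts, end = ends, snp_count = counts,
                       z = NA_real_,
                       class = factor(rep(NA, n_win), levels = WINDOW_CLASSES)),
            window_size = window_size, L = L,
            class = c("window_density", "data.frame"))
}

#' Classify windows by SNP-count z-score
#'
#' Each window's count is standardized against the mean and sample (n-1)
#' standard deviation of all window counts; `z < 1` (including negative z) is
#' `low`, `1 <= z < 2` is `moderate`, `z >= 2` is `high`.  If the counts have
#' zero variance every window is `low`.
#'
#' @param wd A `window_density` from [bin_density()] with at least 2 windows.
#' @return The same `window_density` with `z` and `class` filled in.
#' @export
classify_windows <- function(wd) {
  if (!inherits(wd, "window_density")) stop("`wd` must be a window_density")
  if (nrow(wd) < 2L)
    stop("insufficient data: need >= 2 windows to classify")
  m <- mean(wd$snp_count)
  s <- stats::sd(wd$snp_count)
  z <- if (s > 0) (wd$snp_count - m) / s else rep(0, nrow(wd))
  wd$z <- z
  wd$class <- factor(ifelse(z >= 2, "high", ifelse(z >= 1, "moderate", "low")),
                     levels = WINDOW_CLASSES)
  wd
}

#' Percentage of variable (SNP) sites in an alignment
#'
#' @param aln An `msa` alignment.
#' @return Percentage in `[0, 100]` of columns that are SNPs.
#' @export
percent_variable_sites <- function(aln) {
  100 * length(extract_snps(aln)$positions) / aln_length(aln)
}

#' Write scan reports
#'
#' `write_window_density()` writes the window table as TSV
#' (`window_start`, `window_end`, `snp_count`, `z`, `class`);
#' `write_snp_bed()` writes SNP positions as 0-based half-open BED;
#' `write_window_bed()` writes windows of a minimum class as BED.
#'
#' @param wd A `window_density`.
#' @param path Output path.
#' @param chrom Chromosome/sequence name used in BED output.
#' @return Invisibly, `path`.
#' @export
write_window_density <- function(wd, path) {
  out <- data.frame(window_start = wd$start, window_end = wd$end,
                    snp_count = wd$snp_count, z = wd$z,
                    class = as.character(wd$class))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_window_density
#' @param snps An `snp_table`.
#' @export
write_snp_bed <- function(snps, path, chrom = "alignment") {
  bed <- data.frame(chrom = rep_len(chrom, length(snps$positions)),
                    start = snps$positions - 1L, end = snps$positions)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_window_density
#' @param min_class Minimum class to report (default `"high"`).
#' @export
write_window_bed <- function(wd, path, min_class = "high", chrom = "alignment") {
  keep <- class_at_least(wd$class, min_class)
  bed <- data.frame(chrom = rep_len(chrom, sum(keep)),
                    start = wd$start[keep] - 1L, end = wd$end[keep],
                    name = as.character(wd$class[keep]))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# class comparison on the ordered low < moderate < high scale
class_at_least <- function(cls, min_class) {
  min_class <- match.arg(min_class, WINDOW_CLASSES)
  !is.na(cls) & (match(as.character(cls), WINDOW_CLASSES) >=
                   match(min_class, WINDOW_CLASSES))
}
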