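# Alignment container and I/O.
#
# An alignment is a character matrix (rows = taxa, columns = positions) of
# single uppercase characters, class "msa".  Column coordinates are 1-based
# inclusive everywhere a user sees them; 0-based half-open arithmetic is used
# only internally (window tiling, BED export).  An optional partition table
# lives in attr(x, "partitions") as a data.frame(name, start, end).

ALN_ALPHABET <- c("A", "C", "G", "T",                       # unambiguous
                  "R", "Y", "S", "W", "K", "M",             # two-state IUPAC
                  "B", "D", "H", "V",                       # three-state IUPAC
                  "N", "-", "?")

#' Construct an alignment from sequence strings
#'
#' @param seqs Named character vector of equal-length sequence strings.
#'   Lowercase letters and `U` are accepted and normalized to uppercase `T`.
#' @param partitions Optional `data.frame(name, start, end)` of 1-based
#'   inclusive, non-overlapping column ranges.
#' @return An object of class `msa`: a character matrix with taxa as row
#'   names and one alignment column per matrix column.
#' @examples
#' aln <- msa(c(s1 = "ACGT", s2 = "ACGA"))
#' aln_length(aln)
#' @export
msa <- function(seqs, partitions = NULL) {
  if (!is.character(seqs) || length(seqs) == 0)
    stop("`seqs` must be a non-empty character vector")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be named by taxon")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("alignment shape error: sequences differ in length (",
         paste(unique(lens), collapse = ", "), ")")
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(mat) <- names(seqs)
  new_msa(normalize_bases(mat), partitions)
}

# internal constructor: `mat` already normalized (uppercase, U -> T)
new_msa <- function(mat, partitions = NULL) {
  stopifnot(is.matrix(mat), is.character(mat))
  taxa <- rownames(mat)
  if (is.null(taxa) || any(!nzchar(taxa)))
    stop("alignment rows must be named by taxon")
  if (anyDuplicated(taxa))
    stop("label error: duplicate taxon labels: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  bad <- setdiff(unique(as.vector(mat)), ALN_ALPHABET)
  if (length(bad))
    stop("format error: unsupported characters in alignment: ",
         paste(bad, collapse = " "))
  if (!is.null(partitions))
    partitions <- validate_partitions(partitions, ncol(mat))
  structure(mat, partitions = partitions, class = c("msa", "matrix", "array"))
}

normalize_bases <- function(mat) {
  mat <- toupper(mat)
  mat[mat == "U"] <- "T"
  mat
}

validate_partitions <- function(p, L) {
  p <- as.data.frame(p)
  if (!all(c("name", "start", "end") %in% names(p)))
    stop("partitions need columns name, start, end")
  p$start <- as.integer(p$start)
  p$end <- as.integer(p$end)
  if (any(is.na(p$start)) || any(is.na(p$end)) ||
      any(p$start < 1L) || any(p$end > L) || any(p$start > p$end))
    stop("coordinate error: partition ranges must satisfy 1 <= start <= end <= ", L)
  o <- order(p$start)
  if (any(p$start[o][-1] <= p$end[o][-nrow(p)]))
    stop("coordinate error: partition ranges overlap")
  p[, c("name", "start", "end")]
}

#' @export
print.msa <- function(x, ...) {
  cat("Alignment:", nrow(x), "taxa x", ncol(x), "columns\n")
  p <- attr(x, "partitions")
  if (!is.null(p)) cat("Partitions:", paste(p$name, collapse = ", "), "\n")
  invisible(x)
}

#' Alignment accessors
#'
#' `taxa()` returns the taxon labels, `aln_length()` the number of columns and
#' `partitions()` the partition table (or `NULL`).
#'
#' @param aln An `msa` alignment.
#' @return A character vector, an integer, or a data.frame respectively.
#' @export
taxa <- function(aln) rownames(aln)

#' @rdname taxa
#' @export
aln_length <- function(aln) ncol(aln)

#' @rdname taxa
#' @export
partitions <- function(aln) attr(aln, "partitions")

#' Read a FASTA alignment
#'
#' Reads an aligned FASTA file into an [msa()] object.  Taxon identity is the
#' header up to the first whitespace; sequences are uppercased and `U` is
#' mapped to `T`.  All records must have the same length.
#'
#' @param path Path to a FASTA file with at least two records.
#' @return An `msa` alignment.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  x <- tryCatch(suppressWarnings(ape::read.FASTA(path)),
                error = function(e) stop("format error reading ", path, ": ",
                                         conditionMessage(e)))
  if (is.null(x) || length(x) == 0)
    stop("format error: no FASTA records in ", path)
  if (length(x) < 2)
    stop("alignment needs >= 2 records, found ", length(x))
  labs <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(labs))
    stop("label error: duplicate taxon labels: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  lens <- lengths(x)
  if (length(unique(lens)) != 1L)
    stop("alignment shape error: sequences differ in length (",
         paste(unique(lens), collapse = ", "), ")")
  mat <- do.call(rbind, lapply(as.character(x), identity))
  rownames(mat) <- labs
  new_msa(normalize_bases(mat))
}

#' Write an alignment to FASTA
#'
#' @param aln An `msa` alignment.
#' @param path Output path.
#' @param width Line-wrap width for sequence lines (default 80 columns).
#' @return Invisibly, `path`.
#' @export
write_alignment <- function(aln, path, width = 80) {
  seqs <- apply(unclass(aln), 1L, paste, collapse = "")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read or write an accession-to-species map
#'
#' The species map is a TSV with header `accession<TAB>species` assigning each
#' alignment taxon to a species name.
#'
#' @param path TSV path.
#' @return `read_species_map()` returns a data.frame with character columns
#'   `accession` and `species`.
#' @export
read_species_map <- function(path) {
  sm <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (!all(c("accession", "species") %in% names(sm)))
    stop("species map needs columns accession, species")
  validate_species_map(sm)
}

#' @rdname read_species_map
#' @param sm Species-map data.frame.
#' @export
write_species_map <- function(sm, path) {
  utils::write.table(sm[, c("accession", "species")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_species_map
#' @param aln Optional alignment; when given, every taxon must be mapped
#'   exactly once.
#' @export
validate_species_map <- function(sm, aln = NULL) {
  sm <- as.data.frame(sm)
  if (anyDuplicated(sm$accession))
    stop("label error: accession mapped more than once: ",
         paste(unique(sm$accession[duplicated(sm$accession)]), collapse = ", "))
  if (!is.null(aln)) {
    missing <- setdiff(taxa(aln), sm$accession)
    if (length(missing))
      stop("label error: taxa without species assignment: ",
           paste(missing, collapse = ", "))
  }
  sm
}

#' Subset an alignment by taxa
#'
#' Keeps the requested taxa (in their original row order) and all columns;
#' invariant columns are deliberately retained so that coordinates stay
#' comparable across subsets.
#'
#' @param aln An `msa` alignment.
#' @param keep Character vector of taxon labels to keep.
#' @return An `msa` alignment with the same number of columns.
#' @export
subset_by_taxa <- function(aln, keep) {
  unknown <- setdiff(keep, taxa(aln))
  if (length(unknown))
    stop("label error: unknown taxa: ", paste(unknown, collapse = ", "))
  sel <- taxa(aln) %in% keep
  new_msa(unclass(aln)[sel, , drop = FALSE], partitions(aln))
}

#' Concatenate alignments column-wise
#'
#' All inputs must share the same taxon set (order may differ; the first
#' input's order is used).  The result records each source's column range as a
#' partition.
#'
#' @param alns List of `msa` alignments (names, if present, become partition
#'   names; otherwise `part1`, `part2`, ...).
#' @return An `msa` alignment of length `sum(lengths)` with one partition per
#'   source.
#' @export
concatenate_alignments <- function(alns) {
  if (!is.list(alns) || length(alns) == 0)
    stop("`alns` must be a non-empty list of alignments")
  ref <- taxa(alns[[1]])
  for (a in alns[-1]) {
    if (!setequal(taxa(a), ref))
      stop("taxa error: alignments have different taxon sets")
  }
  mats <- lapply(alns, function(a) unclass(a)[ref, , drop = FALSE])
  lens <- vapply(mats, ncol, integer(1))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  nms <- names(alns)
  if (is.null(nms) || any(!nzchar(nms)))
    nms <- sprintf("part%d", seq_along(alns))
  part <- data.frame(name = nms, start = starts, end = ends)
  new_msa(do.call(cbind, mats), part)
}
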