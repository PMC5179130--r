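#' Taxon count tables
#'
#' A `count_table` holds the classified 16S read counts for one body site:
#' an integer matrix with one row per swab sample and one column per taxon,
#' each column tagged with a seven-rank lineage
#' (kingdom, phylum, class, order, family, genus, species). Lineages may be
#' truncated: ranks below the deepest assignment carry an empty marker, and
#' the invariants are that the kingdom is always assigned and that once a
#' rank is unassigned all deeper ranks are too.
#'
#' @param counts nonnegative integer matrix, samples x taxa. Row names are
#'   sample ids; if absent, `sample_ids` must be given.
#' @param lineages character matrix (taxa x 7) with columns named by rank,
#'   or a character vector of encoded lineage strings
#'   (`"k__X;p__X;c__X;o__X;f__X;g__X;s__X"`).
#' @param site `"ear"` or `"nose"`.
#' @param sample_ids optional character vector of unique sample ids.
#' @param level the taxonomic level of the columns (default `"species"`;
#'   [aggregate_to_level()] maintains it).
#' @return an object of class `count_table`: a list with elements `counts`,
#'   `lineages`, `site`, `level`.
#' @seealso [read_count_table()], [aggregate_to_level()], [normalize_rows()]
#' @export
count_table <- function(counts, lineages, site = c("ear", "nose"),
                        sample_ids = NULL, level = "species") {
  site <- match.arg(site)
  counts <- as.matrix(counts)
  if (is.character(lineages) && is.null(dim(lineages))) {
    lineages <- parse_lineage(lineages)
  }
  if (!is.null(sample_ids)) rownames(counts) <- sample_ids
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("S", seq_len(nrow(counts)))
  }
  storage.mode(counts) <- "double"
  colnames(counts) <- format_lineage(lineages)
  obj <- structure(list(counts = counts, lineages = lineages,
                        site = site, level = level),
                   class = "count_table")
  validate_count_table(obj)
}

validate_count_table <- function(x) {
  counts <- x$counts
  lin <- x$lineages
  if (ncol(counts) != nrow(lin)) {
    stop("counts has ", ncol(counts), " columns but ", nrow(lin),
         " lineages were supplied", call. = FALSE)
  }
  if (anyNA(counts) || any(counts < 0)) {
    stop("counts must be nonnegative and complete", call. = FALSE)
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be integers (read counts)", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate sample id: ",
         rownames(counts)[duplicated(rownames(counts))][1], call. = FALSE)
  }
  if (!identical(colnames(lin), TAXON_RANKS)) {
    stop("lineages must have the 7 rank columns kingdom..species",
         call. = FALSE)
  }
  if (any(is_unclassified(lin[, "kingdom"]))) {
    stop("kingdom rank must always be assigned", call. = FALSE)
  }
  # once unassigned, all deeper ranks unassigned
  for (j in 2:6) {
    bad <- is_unclassified(lin[, j]) & !is_unclassified(lin[, j + 1])
    if (any(bad)) {
      stop("lineage assigned at rank '", TAXON_RANKS[j + 1],
           "' but not at '", TAXON_RANKS[j], "'", call. = FALSE)
    }
  }
  if (anyDuplicated(format_lineage(lin))) {
    stop("duplicate (lineage, site) column", call. = FALSE)
  }
  x
}

#' Parse and format encoded lineage strings
#'
#' Lineages travel on disk as semicolon-joined, rank-prefixed fields,
#' e.g. `"k__Bacteria;p__Firmicutes;c__Bacilli;o__;f__;g__;s__"`. Empty
#' fields mark unassigned ranks.
#'
#' @param x character vector of encoded lineages.
#' @return `parse_lineage`: a character matrix (length(x) x 7) with rank
#'   columns; `format_lineage`: the inverse, a character vector.
#' @export
parse_lineage <- function(x) {
  parts <- strsplit(x, ";", fixed = TRUE)
  out <- matrix(UNCLASSIFIED, nrow = length(x), ncol = 7,
                dimnames = list(NULL, TAXON_RANKS))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) != 7L) {
      stop("malformed lineage '", x[i], "': expected 7 ';'-separated fields",
           call. = FALSE)
    }
    pref <- substr(p, 1, 3)
    if (!identical(pref, RANK_PREFIXES)) {
      stop("malformed lineage '", x[i], "': rank prefixes must be ",
           paste(RANK_PREFIXES, collapse = ","), call. = FALSE)
    }
    out[i, ] <- substring(p, 4)
  }
  out
}

#' @rdname parse_lineage
#' @param lineages a lineage character matrix as produced by
#'   [parse_lineage()].
#' @export
format_lineage <- function(lineages) {
  if (is.null(dim(lineages))) lineages <- matrix(lineages, nrow = 1)
  apply(lineages, 1, function(row) paste0(RANK_PREFIXES, row, collapse = ";"))
}

#' Deepest assigned rank of each lineage
#'
#' @param lineages lineage matrix.
#' @return character vector of rank names.
#' @export
leaf_rank <- function(lineages) {
  if (is.null(dim(lineages))) lineages <- matrix(lineages, nrow = 1)
  apply(lineages, 1, function(row) TAXON_RANKS[max(which(!is_unclassified(row)))])
}

#' Read and write taxon count tables
#'
#' The on-disk format is TSV: first column `sample_id`, remaining column
#' headers encoded lineages (see [parse_lineage()]), cells nonnegative
#' integer read counts. `write_count_table()` and `read_count_table()`
#' round-trip exactly.
#'
#' @param path file path.
#' @param site `"ear"` or `"nose"`.
#' @param level taxonomic level tag for the columns (default `"species"`).
#' @return `read_count_table`: a [count_table()].
#' @export
read_count_table <- function(path, site = c("ear", "nose"),
                             level = "species") {
  site <- match.arg(site)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          colClasses = "character", sep = "\t")
  if (ncol(df) < 2L) stop("count table needs a sample_id column and at least one taxon column", call. = FALSE)
  ids <- df[[1]]
  mat <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(mat), nrow = nrow(mat)))
  if (anyNA(num)) stop("non-numeric count in ", path, call. = FALSE)
  rownames(num) <- ids
  count_table(num, lineages = parse_lineage(colnames(df)[-1]),
              site = site, level = level)
}

#' @rdname read_count_table
#' @param table a [count_table()].
#' @export
write_count_table <- function(table, path) {
  stopifnot(inherits(table, "count_table"))
  df <- data.frame(sample_id = rownames(table$counts),
                   table$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.count_table <- function(x, ...) {
  cat("<count_table> site=", x$site, " level=", x$level, ": ",
      nrow(x$counts), " samples x ", ncol(x$counts), " taxa, ",
      format(sum(x$counts), big.mark = ","), " reads\n", sep = "")
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)
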