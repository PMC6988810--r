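#' OTU count table
#'
#' Construct the validated integer count matrix (rows = OTUs, columns =
#' samples) that every downstream stage transforms.  Counts must be
#' non-negative integers; OTU and sample identifiers must be unique.
#'
#' @param counts numeric matrix of non-negative integral counts, with
#'   rownames (OTU ids) and colnames (sample ids), or a matrix plus
#'   explicit `otu_ids` / `sample_ids`.
#' @param otu_ids,sample_ids optional character vectors overriding
#'   dimnames.
#' @return an object of class `otu_table`: an integer matrix with
#'   unique dimnames.
#' @examples
#' m <- matrix(c(5L, 0L, 2L, 7L), 2, 2,
#'             dimnames = list(c("otu1", "otu2"), c("s1", "s2")))
#' otu_table(m)
#' @export
otu_table <- function(counts, otu_ids = NULL, sample_ids = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (!is.null(otu_ids)) rownames(counts) <- otu_ids
  if (!is.null(sample_ids)) colnames(counts) <- sample_ids
  validate_otu_table(counts)
  storage.mode(counts) <- "integer"
  class(counts) <- c("otu_table", class(counts))
  counts
}

validate_otu_table <- function(counts) {
  if (length(counts) == 0L)
    stop("OTU table is empty", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("OTU table needs OTU ids as rownames and sample ids as colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop("duplicated OTU ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicated sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(counts))
    stop(sprintf(
      "invalid count %s at OTU '%s', sample '%s': counts must be non-negative integers",
      format(counts[bad[1L]]), rownames(counts)[i[1L]], colnames(counts)[i[2L]]),
      call. = FALSE)
  }
  invisible(counts)
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("OTU table: %d OTUs x %d samples, %s reads\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")))
  invisible(x)
}

# keep class on subsetting when the result is still a matrix
#' @export
`[.otu_table` <- function(x, i, j, ..., drop = TRUE) {
  out <- NextMethod()
  if (is.matrix(out)) class(out) <- c("otu_table", "matrix", "array")
  out
}

#' Read an OTU count table from a tab-separated file
#'
#' Expects a header row of sample ids and a first column of OTU ids
#' (canonically named `otu_id`).  All remaining cells must be
#' non-negative integers.  Use `transpose = TRUE` for files with
#' samples as rows.
#'
#' @param path path to a TSV file.
#' @param transpose logical; set `TRUE` when rows are samples.
#' @return an [otu_table].
#' @export
read_otu_table <- function(path, transpose = FALSE) {
  # read.table silently uniquifies duplicate header names; check first
  lines <- readLines(path, n = 50L)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines)) {
    hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]][-1L]
    if (anyDuplicated(hdr))
      stop("duplicated sample ids in header of '", path, "': ",
           paste(unique(hdr[duplicated(hdr)]), collapse = ", "),
           call. = FALSE)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(df) < 2L || nrow(df) < 1L)
    stop("OTU table file '", path, "' is empty or has no count columns",
         call. = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m))
    stop("non-numeric count cell in '", path, "'", call. = FALSE)
  rownames(m) <- ids
  if (transpose) m <- t(m)
  otu_table(m)
}

#' Read sample metadata
#'
#' TSV with columns `sample_id, station, habitat, date, replicate`.
#' Exactly two habitat labels must be present across the dataset.
#'
#' @param path path to a TSV file.
#' @param table optional [otu_table] to validate against (every sample
#'   must have exactly one metadata record).
#' @return a data.frame of class `sample_metadata`.
#' @export
read_sample_metadata <- function(path, table = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  sample_metadata(df, table = table)
}

#' Construct sample metadata
#'
#' @param df data.frame with columns `sample_id, station, habitat,
#'   date, replicate`.
#' @param table optional [otu_table] whose samples must all be covered.
#' @return validated data.frame of class `sample_metadata`.
#' @export
sample_metadata <- function(df, table = NULL) {
  need <- c("sample_id", "station", "habitat", "date", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("metadata is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id in metadata", call. = FALSE)
  if (length(unique(df$habitat)) != 2L)
    stop("habitat must take exactly two values, got: ",
         paste(unique(df$habitat), collapse = ", "), call. = FALSE)
  if (!is.null(table)) {
    absent <- setdiff(colnames(table), df$sample_id)
    if (length(absent))
      stop("samples without metadata: ", paste(absent, collapse = ", "),
           call. = FALSE)
  }
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Read a taxonomy table
#'
#' TSV with `otu_id` and a semicolon-separated lineage string (PR2-style
#' ranks, kingdom to species); an optional `group` column carries the
#' high-level group label, otherwise the deepest informative rank above
#' class level is used.
#'
#' @param path path to a TSV file.
#' @return data.frame with columns `otu_id`, `lineage` (list of
#'   character vectors) and `group`.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("otu_id", "lineage") %in% names(df)))
    stop("taxonomy file needs columns otu_id and lineage", call. = FALSE)
  taxonomy_table(df$otu_id, strsplit(df$lineage, ";", fixed = TRUE),
                 group = if ("group" %in% names(df)) df$group else NULL)
}

#' Construct a taxonomy table
#'
#' @param otu_id character vector of OTU ids.
#' @param lineage list of character vectors (up to 8 PR2 ranks); empty
#'   entries are replaced by the `"unknown"` sentinel.
#' @param group optional high-level group labels; defaults to the third
#'   lineage rank (PR2 division) when absent.
#' @return data.frame with columns `otu_id`, `lineage`, `group`.
#' @export
taxonomy_table <- function(otu_id, lineage, group = NULL) {
  if (anyDuplicated(otu_id))
    stop("duplicated otu_id in taxonomy", call. = FALSE)
  lineage <- lapply(lineage, function(l) {
    l <- trimws(as.character(l))
    l[!nzchar(l) | is.na(l)] <- "unknown"
    l
  })
  if (is.null(group))
    group <- vapply(lineage, function(l)
      if (length(l) >= 3L) l[3L] else "unknown", character(1))
  out <- data.frame(otu_id = as.character(otu_id), group = as.character(group),
                    stringsAsFactors = FALSE)
  out$lineage <- lineage
  class(out) <- c("taxonomy_table", "data.frame")
  out
}
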