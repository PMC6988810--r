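#' Pool replicate samples
#'
#' Sums the columns of an OTU table within replicate groups defined by
#' `(station, date)` in the metadata, mirroring the usual pooling of
#' duplicate filters before normalization (56 samples in duplicate
#' become 28 pooled samples).
#'
#' @param table an [otu_table].
#' @param metadata a [sample_metadata] covering every sample.
#' @return a list with `table` (pooled [otu_table], columns named
#'   `<station>_<date>`) and `metadata` (one row per pooled sample,
#'   `replicate` set to the group size).
#' @export
pool_replicates <- function(table, metadata) {
  metadata <- sample_metadata(as.data.frame(metadata), table = table)
  md <- metadata[match(colnames(table), metadata$sample_id), ]
  grp <- paste(md$station, md$date, sep = "_")
  if (any(is.na(md$station)))
    stop("replicate group with no samples", call. = FALSE)
  glev <- unique(grp)
  pooled <- vapply(glev, function(g)
    rowSums(table[, grp == g, drop = FALSE]), numeric(nrow(table)))
  pooled <- matrix(pooled, nrow = nrow(table),
                   dimnames = list(rownames(table), glev))
  first <- match(glev, grp)
  pmeta <- data.frame(sample_id = glev,
                      station = md$station[first],
                      habitat = md$habitat[first],
                      date = md$date[first],
                      replicate = as.integer(tabulate(factor(grp, glev))),
                      stringsAsFactors = FALSE)
  list(table = otu_table(pooled), metadata = sample_metadata(pmeta))
}

#' Remove singleton OTUs
#'
#' Drops OTUs whose total count across all samples is 1 (the usual
#' metabarcoding singleton filter); OTUs totalling at least 2 reads are
#' kept even when the reads fall in different samples.  Row order is
#' preserved; idempotent.  May return a table with zero rows.
#'
#' @param table an [otu_table].
#' @return the filtered table (plain matrix if empty).
#' @export
remove_singletons <- function(table) {
  keep <- rowSums(table) >= 2
  out <- table[keep, , drop = FALSE]
  if (nrow(out) == 0L) class(out) <- c("matrix", "array")
  out
}

#' Filter OTUs by minimum total abundance
#'
#' Retains OTUs whose total count is at least `min_reads`; an OTU with
#' total abundance *less than* the threshold is excluded, so a total
#' exactly equal to `min_reads` is kept.
#'
#' @param table an [otu_table].
#' @param min_reads positive integer threshold (50 is the conventional
#'   floor before network inference).
#' @return the filtered table.
#' @export
filter_min_total <- function(table, min_reads) {
  stopifnot(min_reads >= 1)
  keep <- rowSums(table) >= min_reads
  out <- table[keep, , drop = FALSE]
  if (nrow(out) == 0L) class(out) <- c("matrix", "array")
  out
}

#' Rarefy an OTU table to even depth
#'
#' Randomly subsamples each column without replacement (a multivariate
#' hypergeometric draw, delegated to [vegan::rrarefy]) so that every
#' retained column sums exactly to `depth`.  Columns whose total is
#' below `depth` are dropped with a warning (set `drop_low = FALSE` to
#' error instead).  With-replacement resampling is available behind
#' `replace = TRUE` but off by default.
#'
#' @param table an [otu_table].
#' @param depth positive integer target depth.
#' @param seed integer seed; the draw is reproducible for a fixed seed.
#' @param drop_low drop columns shallower than `depth` (default) or
#'   raise an error.
#' @param replace subsample with replacement (multinomial) instead.
#' @return rarefied [otu_table]; every column sums to `depth`.
#' @export
rarefy_table <- function(table, depth, seed = 1L, drop_low = TRUE,
                         replace = FALSE) {
  if (length(depth) != 1L || !is.finite(depth) || depth <= 0 ||
      depth != round(depth))
    stop("depth must be a positive integer", call. = FALSE)
  totals <- colSums(table)
  low <- totals < depth
  if (any(low)) {
    if (!drop_low)
      stop("columns below rarefaction depth: ",
           paste(colnames(table)[low], collapse = ", "), call. = FALSE)
    warning(sprintf("dropping %d sample(s) below depth %d: %s",
                    sum(low), depth,
                    paste(colnames(table)[low], collapse = ", ")),
            call. = FALSE)
    table <- table[, !low, drop = FALSE]
  }
  if (ncol(table) == 0L)
    stop("no samples at or above the rarefaction depth", call. = FALSE)
  set.seed(as.integer(seed))
  if (replace) {
    out <- apply(table, 2L, function(col)
      stats::rmultinom(1L, depth, col / sum(col))[, 1L])
  } else {
    out <- t(quiet_rrarefy(t(unclass(table)), depth))
  }
  dimnames(out) <- dimnames(table)
  otu_table(out)
}

# rrarefy warns when counts are larger than typical observed tables
# (e.g. pooled habitat totals); the draw itself is still exact
quiet_rrarefy <- function(x, depth) {
  withCallingHandlers(
    vegan::rrarefy(x, depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

#' Resolve a rarefaction depth policy
#'
#' @param table an [otu_table].
#' @param policy `"second_lowest"`, `"lowest"`, or a fixed positive
#'   integer.  The second-lowest column total is the conventional choice
#'   when one sample is an outlier in depth and is meant to be dropped.
#' @return integer depth.
#' @export
resolve_depth <- function(table, policy = "second_lowest") {
  if (is.numeric(policy)) {
    stopifnot(length(policy) == 1L, policy >= 1)
    return(as.integer(policy))
  }
  totals <- sort(colSums(table))
  switch(match.arg(policy, c("second_lowest", "lowest")),
         second_lowest = as.integer(if (length(totals) >= 2L) totals[2L]
                                    else totals[1L]),
         lowest = as.integer(totals[1L]))
}

#' Pool counts by habitat and equalize depths
#'
#' Sums counts over the selected stations within each habitat, then
#' rarefies the deeper of the two pooled count vectors down to the
#' shallower one (single-column rarefying semantics), so the two-habitat
#' comparison in [clam_classify] sees equal totals.
#'
#' @param table an [otu_table] (unnormalized counts).
#' @param metadata a [sample_metadata].
#' @param stations optional character vector restricting the samples to
#'   a subset of stations (default: all).
#' @param seed integer seed for the equalizing subsample.
#' @return list with integer vectors `count_A` and `count_B` (named by
#'   OTU), the habitat labels `habitats`, and the common `depth`.
#' @export
pool_by_habitat <- function(table, metadata, stations = NULL, seed = 1L) {
  metadata <- sample_metadata(as.data.frame(metadata), table = table)
  md <- metadata[match(colnames(table), metadata$sample_id), ]
  if (!is.null(stations)) {
    sel <- md$station %in% stations
    table <- table[, sel, drop = FALSE]
    md <- md[sel, , drop = FALSE]
  }
  habs <- sort(unique(metadata$habitat))
  cols_a <- md$habitat == habs[1L]
  cols_b <- md$habitat == habs[2L]
  if (!any(cols_a) || !any(cols_b))
    stop("a habitat has no selected samples (stations: ",
         paste(stations, collapse = ", "), ")", call. = FALSE)
  a <- rowSums(table[, cols_a, drop = FALSE])
  b <- rowSums(table[, cols_b, drop = FALSE])
  depth <- min(sum(a), sum(b))
  set.seed(as.integer(seed))
  equalize <- function(v) {
    if (sum(v) == depth) return(as.integer(v))
    as.integer(quiet_rrarefy(matrix(v, nrow = 1L), depth)[1L, ])
  }
  a <- stats::setNames(equalize(a), rownames(table))
  b <- stats::setNames(equalize(b), rownames(table))
  list(count_A = a, count_B = b, habitats = habs, depth = depth)
}

#' Hellinger transformation
#'
#' Each cell becomes the square root of its sample-relative abundance,
#' `sqrt(count / column total)`, so every transformed column has unit
#' squared norm.  The standard pre-transform before Euclidean-embedding
#' ordinations.
#'
#' @param table an [otu_table].
#' @return a real-valued matrix of the same shape.
#' @export
hellinger_transform <- function(table) {
  totals <- colSums(table)
  if (any(totals == 0))
    stop("all-zero sample column(s): ",
         paste(colnames(table)[totals == 0], collapse = ", "),
         call. = FALSE)
  t(vegan::decostand(t(unclass(table)), method = "hellinger"))
}
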