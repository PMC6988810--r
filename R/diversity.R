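#' Shannon diversity (natural log)
#'
#' H = -sum(p_i * ln p_i) over positive counts.  Natural log, matching
#' the convention of reporting H on the nat scale for OTU tables.
#'
#' @param counts non-negative count vector with at least one positive
#'   entry.
#' @return Shannon H in nats.
#' @export
shannon <- function(counts) {
  if (all(counts == 0))
    stop("all-zero count vector", call. = FALSE)
  as.numeric(vegan::diversity(counts, index = "shannon", base = exp(1)))
}

#' Per-sample diversity summary
#'
#' @param table an [otu_table].
#' @return data.frame with `sample_id`, observed `richness`, and
#'   `shannon_H` (nats).
#' @export
diversity_summary <- function(table) {
  data.frame(
    sample_id = colnames(table),
    richness = as.integer(colSums(table > 0)),
    shannon_H = apply(table, 2L, shannon),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Analytic rarefaction curve
#'
#' Expected observed richness when subsampling `d` reads without
#' replacement from a count vector:
#' `E[S(d)] = sum_i (1 - choose(N - N_i, d) / choose(N, d))`
#' (hypergeometric expectation, computed via [vegan::rarefy]).
#' Deterministic and monotone non-decreasing in depth; a Monte-Carlo
#' resampling mode exists for cross-checking.
#'
#' @param counts non-negative count vector.
#' @param depths increasing positive integers, each at most
#'   `sum(counts)`.
#' @param method `"analytic"` (default) or `"resample"`.
#' @param n_draws number of Monte-Carlo draws for `"resample"`.
#' @param seed seed for `"resample"`.
#' @return numeric vector of expected richness, one per depth.
#' @export
rarefaction_curve <- function(counts, depths, method = c("analytic", "resample"),
                              n_draws = 1000L, seed = 1L) {
  method <- match.arg(method)
  total <- sum(counts)
  if (any(depths > total))
    stop("depth exceeds the total count (", total, ")", call. = FALSE)
  if (any(depths <= 0) || any(depths != round(depths)))
    stop("depths must be positive integers", call. = FALSE)
  if (method == "analytic") {
    # vegan nags when counts do not look like a raw observed vector;
    # the expectation formula is unaffected
    out <- withCallingHandlers(
      vegan::rarefy(counts, sample = depths),
      warning = function(w) {
        if (grepl("observed count", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    return(as.numeric(out))
  }
  set.seed(as.integer(seed))
  pool <- rep.int(seq_along(counts), counts)
  vapply(depths, function(d)
    mean(vapply(seq_len(n_draws), function(i)
      length(unique(sample(pool, d))), numeric(1))), numeric(1))
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(j,k) = sum_i |x_ij - x_ik| / sum_i (x_ij + x_ik)` between sample
#' columns; symmetric, zero diagonal, values in `[0, 1]`.
#'
#' @param table an [otu_table] (or numeric matrix), samples as columns.
#' @return a symmetric base matrix of dissimilarities with sample
#'   dimnames.
#' @export
bray_curtis <- function(table) {
  if (any(colSums(table) == 0))
    stop("all-zero sample column(s)", call. = FALSE)
  as.matrix(vegan::vegdist(t(unclass(table)), method = "bray"))
}

#' Shared/exclusive partition of OTUs and reads between two habitats
#'
#' An OTU is shared when it has a positive total in both habitats;
#' read fractions are computed over the whole table, so the three
#' fractions sum to 1.
#'
#' @param table an [otu_table].
#' @param metadata a [sample_metadata].
#' @return object of class `venn_partition`: list with OTU counts
#'   (`shared_otus`, `exclusive_A_otus`, `exclusive_B_otus`, plus
#'   `absent_otus` for all-zero rows), read fractions, and the habitat
#'   labels mapped to A and B.
#' @export
venn_partition <- function(table, metadata) {
  metadata <- sample_metadata(as.data.frame(metadata), table = table)
  md <- metadata[match(colnames(table), metadata$sample_id), ]
  habs <- sort(unique(metadata$habitat))
  in_a <- md$habitat == habs[1L]
  in_b <- md$habitat == habs[2L]
  if (!any(in_a) || !any(in_b))
    stop("both habitats must be present among the samples", call. = FALSE)
  tot_a <- rowSums(table[, in_a, drop = FALSE])
  tot_b <- rowSums(table[, in_b, drop = FALSE])
  shared <- tot_a > 0 & tot_b > 0
  excl_a <- tot_a > 0 & tot_b == 0
  excl_b <- tot_b > 0 & tot_a == 0
  total_reads <- sum(tot_a) + sum(tot_b)
  out <- list(
    habitats = stats::setNames(habs, c("A", "B")),
    shared_otus = sum(shared),
    exclusive_A_otus = sum(excl_a),
    exclusive_B_otus = sum(excl_b),
    absent_otus = sum(!shared & !excl_a & !excl_b),
    shared_read_fraction = sum(tot_a[shared] + tot_b[shared]) / total_reads,
    exclusive_A_read_fraction = sum(tot_a[excl_a]) / total_reads,
    exclusive_B_read_fraction = sum(tot_b[excl_b]) / total_reads)
  class(out) <- "venn_partition"
  out
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf("Habitat partition (A = %s, B = %s)\n",
              x$habitats["A"], x$habitats["B"]))
  cat(sprintf("  shared:      %d OTUs, %.1f%% of reads\n",
              x$shared_otus, 100 * x$shared_read_fraction))
  cat(sprintf("  exclusive A: %d OTUs, %.1f%% of reads\n",
              x$exclusive_A_otus, 100 * x$exclusive_A_read_fraction))
  cat(sprintf("  exclusive B: %d OTUs, %.1f%% of reads\n",
              x$exclusive_B_otus, 100 * x$exclusive_B_read_fraction))
  invisible(x)
}
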