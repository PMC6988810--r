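#' Parameters for MIC association inference
#'
#' @param b_exponent grid-budget exponent in (0, 1); the number of grid
#'   cells searched is `B(n) = max(4, floor(n^b_exponent))` so the
#'   minimal 2x2 grid is always available at the supported `n >= 8`.
#' @param clumps_factor superclump cap `c`: at most `c * kx` candidate
#'   cut points per axis optimization.
#' @param n_permutations permutations for the significance null.
#' @param p_threshold retain pairs with `p < p_threshold`.
#' @param min_total_reads abundance floor applied before inference.
#' @param seed integer seed for the permutation null.
#' @return list of class `mic_params`.
#' @export
mic_params <- function(b_exponent = 0.6, clumps_factor = 15L,
                       n_permutations = 1000L, p_threshold = 0.01,
                       min_total_reads = 50L, seed = 1L) {
  if (!(b_exponent > 0 && b_exponent < 1))
    stop("b_exponent must lie in (0, 1)", call. = FALSE)
  if (clumps_factor < 1) stop("clumps_factor must be >= 1", call. = FALSE)
  if (n_permutations < 1) stop("n_permutations must be >= 1", call. = FALSE)
  if (!(p_threshold > 0 && p_threshold <= 1))
    stop("p_threshold must lie in (0, 1]", call. = FALSE)
  structure(list(b_exponent = b_exponent,
                 clumps_factor = as.integer(clumps_factor),
                 n_permutations = as.integer(n_permutations),
                 p_threshold = p_threshold,
                 min_total_reads = as.integer(min_total_reads),
                 seed = as.integer(seed)),
            class = "mic_params")
}

check_pair <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y differ in length", call. = FALSE)
  if (length(x) < 8L)
    stop("MIC needs at least 8 paired observations", call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("MIC input contains missing values", call. = FALSE)
}

#' Maximal information coefficient of one pair
#'
#' MIC is the maximum over grid shapes `(kx, ky)` with
#' `kx * ky <= B(n)` of the maximal mutual information over axis
#' partitions, normalized by `log2(min(kx, ky))`.  One axis is
#' equipartitioned, the other optimized by the ApproxMaxMI dynamic
#' program over tie-respecting clumps; both orientations are searched.
#' Constant input returns 0 by convention; the statistic depends only
#' on ranks, so it is invariant to strictly monotone transforms.
#'
#' @param x,y numeric vectors of equal length `n >= 8`.
#' @param params a [mic_params].
#' @return list with `mic`, `pearson_r`, and `nonlinearity`
#'   (`mic - pearson_r^2`).
#' @export
compute_mic <- function(x, y, params = mic_params()) {
  check_pair(x, y)
  mic <- mic_cpp(as.numeric(x), as.numeric(y),
                 params$b_exponent, params$clumps_factor)
  r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) 0
       else stats::cor(x, y)
  list(mic = mic, pearson_r = r, nonlinearity = mic - r^2)
}

#' Permutation p-value for a MIC
#'
#' `p = (1 + #(permuted MIC >= observed)) / (1 + n_permutations)`,
#' shuffling `y` under the stage seed; this replaces table lookups of
#' precomputed null quantiles with an explicit null constructed from
#' the data at hand.
#'
#' @inheritParams compute_mic
#' @return p-value in `(0, 1]`.
#' @export
permutation_pvalue <- function(x, y, params = mic_params()) {
  check_pair(x, y)
  set.seed(params$seed)
  mic_perm_pvalue_cpp(as.numeric(x), as.numeric(y), params$b_exponent,
                      params$clumps_factor, params$n_permutations)
}

#' Sign of an association from its nonlinearity
#'
#' Nonlinearity (MIC minus squared Pearson r) strictly above 0.5 marks
#' a non-linear relationship, treated as a negative connection; all
#' others are positive.
#'
#' @param result a list or data.frame row with a `nonlinearity` field,
#'   or a bare numeric nonlinearity.
#' @return `"negative"` or `"positive"` (vectorized).
#' @export
edge_sign <- function(result) {
  nl <- if (is.numeric(result)) result else result$nonlinearity
  ifelse(nl > 0.5, "negative", "positive")
}

#' All-pairs MIC edge set
#'
#' Computes MIC, Pearson r, nonlinearity, permutation p-value and sign
#' for every unordered OTU pair of a normalized, abundance-filtered
#' table, and keeps pairs with `p < p_threshold`.  Deterministic for a
#' fixed `params$seed`.
#'
#' @param table an [otu_table], already rarefied; rows failing
#'   `params$min_total_reads` are removed here (with a message) if any
#'   remain.
#' @param params a [mic_params].
#' @param keep_all return all pairs regardless of significance
#'   (diagnostics).
#' @return data.frame of class `mic_edge_set` with columns `otu_a`,
#'   `otu_b`, `mic`, `pearson_r`, `nonlinearity`, `p_value`, `sign`.
#' @export
build_edge_set <- function(table, params = mic_params(), keep_all = FALSE) {
  low <- rowSums(table) < params$min_total_reads
  if (any(low)) {
    message(sprintf("build_edge_set: dropping %d OTU(s) below %d total reads",
                    sum(low), params$min_total_reads))
    table <- table[!low, , drop = FALSE]
  }
  if (nrow(table) < 2L)
    stop("need at least 2 OTUs to build an edge set", call. = FALSE)
  if (ncol(table) < 8L)
    stop("need at least 8 samples for MIC", call. = FALSE)
  set.seed(params$seed)
  res <- mic_all_pairs_cpp(unclass(table) * 1.0, params$b_exponent,
                           params$clumps_factor, params$n_permutations)
  ids <- rownames(table)
  out <- data.frame(otu_a = ids[res$i], otu_b = ids[res$j],
                    mic = res$mic, pearson_r = res$pearson_r,
                    nonlinearity = res$mic - res$pearson_r^2,
                    p_value = res$p_value, stringsAsFactors = FALSE)
  out$sign <- edge_sign(out)
  n_total <- nrow(out)
  if (!keep_all && params$p_threshold < 1)
    out <- out[out$p_value < params$p_threshold, , drop = FALSE]
  rownames(out) <- NULL
  message(sprintf("build_edge_set: %d of %d pairs significant at p < %g",
                  sum(out$p_value < params$p_threshold), n_total,
                  params$p_threshold))
  attr(out, "params") <- params
  class(out) <- c("mic_edge_set", "data.frame")
  out
}
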