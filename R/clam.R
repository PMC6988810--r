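#' Parameters for the CLAM generalist/specialist classification
#'
#' @param K specialization threshold in (0.5, 1); the supermajority
#'   rule K = 2/3 says a specialist's true proportional abundance in
#'   its preferred habitat exceeds two-thirds.
#' @param alpha per-side significance level in (0, 0.5); the
#'   conventional conservative choice is 0.005.  No multiplicity
#'   correction is applied (the classification is descriptive).
#' @param ci_method `"exact_binomial"` (Clopper-Pearson, default) or
#'   `"poisson_normal"` (normal approximation to the log Poisson
#'   ratio, for cross-checking).
#' @return list of class `clam_params`.
#' @export
clam_params <- function(K = 2 / 3, alpha = 0.005,
                        ci_method = c("exact_binomial", "poisson_normal")) {
  if (!(K > 0.5 && K < 1)) stop("K must lie in (0.5, 1)", call. = FALSE)
  if (!(alpha > 0 && alpha < 0.5)) stop("alpha must lie in (0, 0.5)",
                                        call. = FALSE)
  structure(list(K = K, alpha = alpha, ci_method = match.arg(ci_method)),
            class = "clam_params")
}

clam_ci <- function(a, t, alpha, ci_method) {
  if (ci_method == "exact_binomial") {
    # Clopper-Pearson bounds at two-sided level 1 - 2*alpha
    lo <- ifelse(a == 0, 0, stats::qbeta(alpha, a, t - a + 1))
    hi <- ifelse(a == t, 1, stats::qbeta(1 - alpha, a + 1, t - a))
  } else {
    # normal approx to log(a/b) treating the two counts as Poisson;
    # half-integer continuity correction keeps zero counts finite
    z <- stats::qnorm(1 - alpha)
    ac <- a + 0.5
    bc <- t - a + 0.5
    se <- sqrt(1 / ac + 1 / bc)
    lr <- log(ac / bc)
    lo <- stats::plogis(lr - z * se)
    hi <- stats::plogis(lr + z * se)
  }
  cbind(lo = pmax(0, lo), hi = pmin(1, hi))
}

#' CLAM classification of OTUs into habitat classes
#'
#' For each OTU with habitat counts `(a, b)` (totals equalized upstream
#' by [pool_by_habitat]), conditions on `t = a + b` and treats `a` as
#' `Binomial(t, pi)` where `pi` is the OTU's preference for habitat A.
#' Two-sided `1 - 2*alpha` confidence bounds on `pi` drive the call:
#' specialist of A when the lower bound exceeds `K`; specialist of B
#' when the upper bound is below `1 - K`; generalist when the interval
#' lies inside `[1 - K, K]`; otherwise too rare to classify.  Ties at a
#' threshold resolve toward the less specific class.  OTUs with
#' `a + b = 0` are reported `too_rare`, never dropped.
#'
#' @param count_A,count_B non-negative integer vectors aligned on OTU
#'   id (names, when present, must agree).
#' @param params a [clam_params].
#' @return data.frame of class `clam_result` with columns `otu_id`,
#'   `count_A`, `count_B`, `pi_hat`, `ci_low`, `ci_high`, `class`
#'   (factor: generalist, specialist_A, specialist_B, too_rare).
#' @export
clam_classify <- function(count_A, count_B, params = clam_params()) {
  if (length(count_A) != length(count_B))
    stop("count vectors have different lengths", call. = FALSE)
  na <- names(count_A); nb <- names(count_B)
  if (!is.null(na) && !is.null(nb) && !identical(na, nb))
    stop("count vectors are not aligned on otu_id", call. = FALSE)
  ids <- if (!is.null(na)) na else sprintf("otu%d", seq_along(count_A))
  a <- as.numeric(count_A); b <- as.numeric(count_B)
  if (any(a < 0) || any(b < 0) || any(a != round(a)) || any(b != round(b)))
    stop("counts must be non-negative integers", call. = FALSE)
  t <- a + b
  ci <- clam_ci(a, pmax(t, 1), params$alpha, params$ci_method)
  lo <- ci[, "lo"]; hi <- ci[, "hi"]
  K <- params$K
  cls <- rep("too_rare", length(a))
  cls[lo > K] <- "specialist_A"
  cls[hi < 1 - K] <- "specialist_B"
  cls[lo >= 1 - K & hi <= K] <- "generalist"
  cls[t == 0] <- "too_rare"
  lo[t == 0] <- 0; hi[t == 0] <- 1
  out <- data.frame(
    otu_id = ids,
    count_A = as.integer(a), count_B = as.integer(b),
    pi_hat = ifelse(t > 0, a / t, NA_real_),
    ci_low = lo, ci_high = hi,
    class = factor(cls, levels = c("generalist", "specialist_A",
                                   "specialist_B", "too_rare")),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "params") <- params
  class(out) <- c("clam_result", "data.frame")
  out
}

#' @export
print.clam_result <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("CLAM classification (K = %.4g, alpha = %.4g, %s) of %d OTUs\n",
              p$K, p$alpha, p$ci_method, nrow(x)))
  print(table(x$class))
  invisible(x)
}

#' Summary tallies of a CLAM result
#'
#' @param object a `clam_result`.
#' @param ... unused.
#' @return list with per-class OTU tallies and read fractions.
#' @export
summary.clam_result <- function(object, ...) {
  reads <- object$count_A + object$count_B
  tot <- sum(reads)
  list(
    n_otus = nrow(object),
    class_counts = as.list(table(object$class)),
    class_read_fraction = as.list(tapply(reads, object$class,
                                         function(r) sum(r) / tot,
                                         default = 0)))
}

#' Minimum evidence needed to escape the too-rare class
#'
#' Smallest total `t` such that an OTU with counts `(t, 0)` is called a
#' specialist of habitat A under `params` -- the implied detectability
#' boundary of the classification.
#'
#' @param params a [clam_params].
#' @return integer total count.
#' @export
clam_min_abundance <- function(params = clam_params()) {
  for (t in 1:10000) {
    cls <- clam_classify(t, 0, params)$class
    if (cls == "specialist_A") return(t)
  }
  stop("no specialist call up to t = 10000", call. = FALSE)
}
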