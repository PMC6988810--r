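# Independent brute-force oracles.  Each reimplements the quantity it
# checks from its definition, sharing no code with the package
# internals (the equipartition scheme is part of the statistic's
# definition and is therefore re-stated here in plain R).

# even row assignment of sorted values, ties never split
equipartition_r <- function(vsorted, k) {
  n <- length(vsorted)
  row <- integer(n)
  i <- 1L; curr <- 1L; row_size <- 0
  desired <- n / k
  while (i <= n) {
    j <- i
    while (j <= n && vsorted[j] == vsorted[i]) j <- j + 1L
    run <- j - i
    if (row_size != 0 &&
        abs(row_size + run - desired) >= abs(row_size - desired) &&
        curr < k) {
      curr <- curr + 1L
      row_size <- 0
      desired <- (n - i + 1) / (k - curr + 1)
    }
    row[i:(j - 1L)] <- curr
    row_size <- row_size + run
    i <- j
  }
  row
}

mi_bits <- function(tab) {
  n <- sum(tab)
  p <- tab / n
  px <- rowSums(p); py <- colSums(p)
  s <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab)))
    if (p[i, j] > 0) s <- s + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
  s
}

# exhaustive MIC: enumerate every cut-point subset on the optimized
# axis (clump boundaries only, i.e. tied values never split), rows
# equipartitioned on the other axis; both orientations; normalize by
# log2(min(columns, rows)).  Feasible for small grid budgets.
mic_exhaustive <- function(x, y, B) {
  stopifnot(length(x) == length(y))
  one_orientation <- function(xx, yy, ky, kxmax) {
    n <- length(xx)
    oy <- order(yy)
    rows <- integer(n)
    rows[oy] <- equipartition_r(yy[oy], ky)
    if (length(unique(rows)) < 2L) return(0)
    ox <- order(xx)
    xs <- xx[ox]
    clump <- cumsum(c(1L, as.integer(diff(xs) != 0)))
    T <- max(clump)
    if (T < 2L) return(0)
    row_sorted <- rows[ox]
    best <- 0
    for (l in 2:min(kxmax, T)) {
      for (cut in if (l == 2L) as.list(1:(T - 1L))
           else asplit(utils::combn(T - 1L, l - 1L), 2L)) {
        col <- findInterval(clump, c(unlist(cut)) + 0.5) + 1L
        tab <- table(factor(col, levels = 1:l),
                     factor(row_sorted, levels = sort(unique(rows))))
        val <- mi_bits(tab) / log2(min(l, ky))
        if (val > best) best <- val
      }
    }
    best
  }
  best <- 0
  ky <- 2L
  while (2L * ky <= B) {
    kxmax <- B %/% ky
    if (kxmax < 2L) break
    best <- max(best,
                one_orientation(x, y, ky, kxmax),
                one_orientation(y, x, ky, kxmax))
    ky <- ky + 1L
  }
  best
}

# Bray-Curtis by direct double loop
bray_oracle <- function(m) {
  k <- ncol(m)
  d <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    d[i, j] <- sum(abs(m[, i] - m[, j])) / sum(m[, i] + m[, j])
  d
}

# mean local clustering via explicit neighbor-pair counting,
# degree < 2 contributing zero
clustering_oracle <- function(adj) {
  n <- nrow(adj)
  loc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] > 0)
    k <- length(nb)
    if (k < 2) next
    links <- sum(adj[nb, nb]) / 2
    loc[v] <- links / choose(k, 2)
  }
  mean(loc)
}

# characteristic path length via all-pairs BFS over connected pairs
path_length_oracle <- function(adj) {
  n <- nrow(adj)
  tot <- 0; cnt <- 0
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in which(adj[v, ] > 0)) if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        queue <- c(queue, w)
      }
    }
    reach <- which(!is.na(dist) & seq_len(n) != s)
    tot <- tot + sum(dist[reach]); cnt <- cnt + length(reach)
  }
  if (cnt == 0) NA_real_ else tot / cnt
}

# analytic expected richness under subsampling, from the definition
rarefaction_oracle <- function(counts, d) {
  N <- sum(counts)
  sum(1 - exp(lchoose(N - counts, d) - lchoose(N, d)))
}
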