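test_that("reading a well-formed TSV round-trips and validation catches bad cells", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("otu_id\ts1\ts2", "o1\t3\t0", "o2\t1\t5", "o3\t0\t2"), tf)
  t <- read_otu_table(tf)
  expect_identical(dim(t), c(3L, 2L))
  expect_identical(unname(t["o2", "s2"]), 5L)

  writeLines(c("otu_id\ts1\ts1", "o1\t3\t0"), tf)
  expect_error(read_otu_table(tf), "duplicated sample")

  writeLines(c("otu_id\ts1\ts2", "o1\t3\t-4"), tf)
  expect_error(read_otu_table(tf), "'o1', sample 's2'")

  writeLines("otu_id\ts1", tf)
  expect_error(read_otu_table(tf), "empty")

  expect_error(otu_table(matrix(1.5, 1, 1,
                                dimnames = list("a", "s"))),
               "non-negative integers")
})

test_that("replicate pooling sums within (station, date) and conserves reads", {
  meta <- toy_design()
  tab <- toy_counts_for(meta)
  pooled <- pool_replicates(tab, meta)
  expect_identical(ncol(pooled$table), 8L)  # 4 stations x 2 dates
  expect_identical(sum(pooled$table), sum(tab))
  # explicit addition on one group
  g <- pooled$metadata$sample_id[1]
  members <- meta$sample_id[paste(meta$station, meta$date, sep = "_") == g]
  expect_equal(pooled$table[, g],
               rowSums(tab[, members, drop = FALSE]))
  # single-replicate groups pass through unchanged
  one <- meta[meta$replicate == 1L, ]
  p1 <- pool_replicates(tab[, one$sample_id], one)
  expect_identical(unname(unclass(p1$table)),
                   unname(unclass(tab[, one$sample_id])))
})

test_that("singleton removal drops rowsum-1 OTUs only and is idempotent", {
  m <- otu_table(matrix(c(1L, 0L,
                          1L, 1L,
                          0L, 1L), 3, 2, byrow = TRUE,
                        dimnames = list(c("single", "split", "single2"),
                                        c("s1", "s2"))))
  out <- remove_singletons(m)
  expect_identical(rownames(out), "split")
  expect_identical(remove_singletons(out), out)
  all_single <- m[c(1, 3), ]
  expect_identical(nrow(remove_singletons(all_single)), 0L)
})

test_that("abundance filter keeps totals at the threshold and drops below", {
  m <- otu_table(matrix(c(49L, 0L, 25L, 25L, 60L, 0L), 3, 2, byrow = TRUE,
                        dimnames = list(c("at49", "at50", "at60"),
                                        c("s1", "s2"))))
  out <- filter_min_total(m, 50L)
  expect_identical(rownames(out), c("at50", "at60"))
  expect_identical(rownames(filter_min_total(m, 1L)), rownames(m))
})

test_that("rarefying yields exact column sums, never exceeds input, and is seed-reproducible", {
  meta <- toy_design()
  tab <- toy_counts_for(meta, n_otus = 30L, lambda = 25)
  depth <- min(colSums(tab))
  r1 <- rarefy_table(tab, depth, seed = 9L)
  expect_true(all(colSums(r1) == depth))
  expect_true(all(r1 <= tab))
  expect_identical(unclass(r1), unclass(rarefy_table(tab, depth, seed = 9L)))
  r2 <- rarefy_table(tab, depth, seed = 10L)
  expect_true(all(colSums(r2) == depth))
  expect_false(identical(unclass(r1), unclass(r2)))
  # identity when depth equals the column total
  one <- tab[, 1, drop = FALSE]
  expect_identical(unclass(rarefy_table(one, sum(one), seed = 1L)),
                   unclass(one))
  expect_error(rarefy_table(tab, 0L), "positive")
  # shallow columns are dropped with a warning
  expect_warning(r3 <- rarefy_table(tab, depth + 1L, seed = 1L),
                 "below depth")
  expect_lt(ncol(r3), ncol(tab))
})

test_that("rarefied cell means match the hypergeometric expectation", {
  col <- otu_table(matrix(c(8000L, 2000L), 2, 1,
                          dimnames = list(c("big", "small"), "s")))
  draws <- vapply(1:4000, function(s)
    rarefy_table(col, 1000L, seed = s)["big", 1], numeric(1))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 800), 3 * se)
})

test_that("depth policies resolve to sorted column totals", {
  meta <- toy_design()
  tab <- toy_counts_for(meta, n_otus = 10L)
  tot <- sort(colSums(tab))
  expect_identical(resolve_depth(tab, "lowest"), as.integer(tot[1]))
  expect_identical(resolve_depth(tab, "second_lowest"), as.integer(tot[2]))
  expect_identical(resolve_depth(tab, 500), 500L)
})

test_that("habitat pooling equalizes the two depths by subsampling", {
  meta <- toy_design()
  tab <- toy_counts_for(meta, n_otus = 15L)
  pools <- pool_by_habitat(tab, meta, seed = 4L)
  expect_identical(sum(pools$count_A), sum(pools$count_B))
  expect_identical(sum(pools$count_A), as.integer(pools$depth))
  tot_a <- rowSums(tab[, meta$sample_id[meta$habitat == "A"]])
  tot_b <- rowSums(tab[, meta$sample_id[meta$habitat == "B"]])
  expect_identical(pools$depth, min(sum(tot_a), sum(tot_b)))
  # the shallower pool passes through unchanged
  shallow <- if (sum(tot_a) <= sum(tot_b)) pools$count_A else pools$count_B
  ref <- if (sum(tot_a) <= sum(tot_b)) tot_a else tot_b
  expect_identical(shallow, setNames(as.integer(ref), rownames(tab)))
  # an OTU absent everywhere stays in the output as (0, 0)
  tab0 <- otu_table(rbind(unclass(tab),
                          zero = rep(0L, ncol(tab))))
  p0 <- pool_by_habitat(tab0, meta, seed = 4L)
  expect_identical(unname(p0$count_A["zero"]), 0L)
  expect_identical(unname(p0$count_B["zero"]), 0L)
  expect_error(pool_by_habitat(tab, meta, stations = c("StA1", "StA2")),
               "no selected samples")
})

test_that("Hellinger transform yields unit squared column norms", {
  m <- otu_table(matrix(c(1L, 1L, 1L, 1L,
                          4L, 0L, 0L, 0L), 4, 2,
                        dimnames = list(paste0("o", 1:4), c("s1", "s2"))))
  h <- hellinger_transform(m)
  expect_equal(unname(h[, "s1"]), rep(0.5, 4))
  expect_equal(unname(h[, "s2"]), c(1, 0, 0, 0))
  expect_equal(unname(colSums(h^2)), c(1, 1), tolerance = 1e-12)
  bad <- otu_table(matrix(c(1L, 0L), 1, 2,
                          dimnames = list("o", c("s1", "s2"))))
  expect_error(hellinger_transform(bad), "all-zero")
})
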