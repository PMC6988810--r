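test_that("MIC analytic anchors: perfect line, constant, degenerate input", {
  expect_identical(compute_mic(1:50, 1:50)$mic, 1)
  expect_identical(compute_mic(1:50, 50:1)$mic, 1)
  expect_identical(compute_mic(1:50, rep(3, 50))$mic, 0)
  expect_error(compute_mic(1:5, 1:5), "at least 8")
  expect_error(compute_mic(1:10, 1:9), "length")
})

test_that("MIC is symmetric and invariant to monotone transforms", {
  set.seed(17)
  for (i in 1:40) {
    x <- rnorm(28); y <- rnorm(28)
    m <- compute_mic(x, y)$mic
    expect_equal(compute_mic(y, x)$mic, m, tolerance = 1e-12)
    expect_equal(compute_mic(exp(x), y)$mic, m, tolerance = 1e-12)
    expect_equal(compute_mic(x, rank(y))$mic, m, tolerance = 1e-12)
    expect_equal(compute_mic(x^3, atan(y))$mic, m, tolerance = 1e-12)
  }
})

test_that("the dynamic program equals exhaustive partition search at small n", {
  set.seed(23)
  for (i in 1:60) {
    n <- sample(8:12, 1)
    B <- sample(4:6, 1)
    tied <- runif(1) < 0.4
    x <- if (tied) sample(1:4, n, TRUE) else rnorm(n)
    y <- if (tied) sample(1:5, n, TRUE) else rnorm(n)
    expect_equal(protistnet:::mic_budget_cpp(as.numeric(x), as.numeric(y),
                                             as.integer(B), 15L),
                 mic_exhaustive(x, y, B), tolerance = 1e-10)
  }
})

test_that("permutation p-values behave as a valid exact test", {
  # a perfect relationship is never beaten by a permutation
  p <- permutation_pvalue(1:30, 1:30, mic_params(n_permutations = 500L))
  expect_equal(p, 1 / 501, tolerance = 1e-12)
  # reproducible under the stage seed
  set.seed(5)
  x <- rnorm(28); y <- rnorm(28)
  p1 <- permutation_pvalue(x, y, mic_params(n_permutations = 200L, seed = 7L))
  p2 <- permutation_pvalue(x, y, mic_params(n_permutations = 200L, seed = 7L))
  expect_identical(p1, p2)
  expect_error(mic_params(n_permutations = 0L), ">= 1")
})

test_that("edge sign follows the strict nonlinearity rule", {
  expect_identical(edge_sign(list(nonlinearity = 0.9 - 0.95^2)), "positive")
  expect_identical(edge_sign(list(nonlinearity = 0.9 - 0.1^2)), "negative")
  expect_identical(edge_sign(0.5), "positive")  # boundary: strictly above
  expect_identical(edge_sign(0.5 + 1e-9), "negative")
})

test_that("edge sets recover a planted correlated block against independent OTUs", {
  set.seed(77)
  n <- 28
  z <- rnorm(n)
  block <- t(vapply(1:5, function(i)
    rpois(n, exp(1.2 * z + 0.3 * rnorm(n)) * 40), numeric(n)))
  indep <- t(vapply(1:20, function(i) rpois(n, 40), numeric(n)))
  tab <- otu_table(matrix(as.integer(rbind(block, indep)), 25, n,
                          dimnames = list(c(sprintf("blk%d", 1:5),
                                            sprintf("ind%02d", 1:20)),
                                          sprintf("s%02d", 1:n))))
  params <- mic_params(n_permutations = 999L, min_total_reads = 1L, seed = 3L)
  edges <- suppressMessages(build_edge_set(tab, params))
  in_block <- grepl("^blk", edges$otu_a) & grepl("^blk", edges$otu_b)
  expect_gte(sum(in_block), 8)
  # independent OTUs pick up at most sporadic edges
  ind_ids <- sprintf("ind%02d", 1:20)
  per_otu <- vapply(ind_ids, function(id)
    sum(edges$otu_a == id | edges$otu_b == id), numeric(1))
  expect_identical(unname(median(per_otu)), 0)
})

test_that("edge set plumbing: thresholds, identical rows, degenerate tables", {
  set.seed(41)
  tab <- otu_table(matrix(rpois(4 * 12, 30), 4, 12,
                          dimnames = list(paste0("o", 1:4), paste0("s", 1:12))))
  params <- mic_params(n_permutations = 49L, p_threshold = 1,
                       min_total_reads = 1L)
  all_pairs <- suppressMessages(build_edge_set(tab, params))
  expect_identical(nrow(all_pairs), 6L)
  # duplicated rows give MIC 1 at the minimal attainable p
  dup <- otu_table(rbind(unclass(tab), o1copy = unclass(tab)[1, ]))
  e <- suppressMessages(build_edge_set(dup, params))
  pair <- e[(e$otu_a == "o1" & e$otu_b == "o1copy") |
              (e$otu_a == "o1copy" & e$otu_b == "o1"), ]
  expect_equal(pair$mic, 1)
  expect_equal(pair$p_value, min(e$p_value))
  one <- tab[1, , drop = FALSE]
  expect_error(suppressMessages(build_edge_set(one, params)), "at least 2")
})
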