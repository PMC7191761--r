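toy_gcm <- function(counts, level = "family") {
  if (is.null(rownames(counts))) {
    rownames(counts) <- LETTERS[seq_len(nrow(counts))]
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("g", seq_len(ncol(counts)))
  }
  structure(list(level = level, cyp_names = rownames(counts),
                 genome_ids = colnames(counts), counts = counts,
                 G_ci = rowSums(counts > 0), G_t = ncol(counts)),
            class = "GCM")
}

test_that("pan/core curve matches hand enumeration on the 3-genome toy", {
  g <- toy_gcm(rbind(A = c(1, 1, 1), B = c(1, 0, 0), C = c(0, 1, 1)))
  cv <- pan_core_curve(g, samples = 300, seed = 1)
  # n = 2 exhaustive: pans (3,3,2), cores (1,1,2)
  expect_equal(cv$pan_mean[2], 8 / 3)
  expect_equal(cv$core_mean[2], 4 / 3)
  # n = 1: pan = core = CYPs per genome, averaged
  expect_equal(cv$pan_mean[1], mean(c(2, 2, 2)))
  expect_equal(cv$core_mean[1], cv$pan_mean[1])
  # n = N: pan = all rows, core = rows positive everywhere, every sample
  expect_equal(cv$pan_mean[3], 3)
  expect_equal(cv$core_mean[3], 1)
  expect_equal(cv$pan_median[3], 3)
  expect_error(pan_core_curve(g, samples = 0), "samples")
})

test_that("single-genome GCM collapses pan and core", {
  g <- toy_gcm(matrix(c(2, 0, 5), ncol = 1))
  cv <- pan_core_curve(g, samples = 10, seed = 1)
  expect_equal(nrow(cv), 1L)
  expect_equal(cv$pan_mean, 2)
  expect_equal(cv$core_mean, 2)
})

test_that("sampled means equal exhaustive enumeration when saturated", {
  set.seed(6)
  for (rep in 1:5) {
    N <- sample(3:6, 1)
    counts <- matrix(rpois(8 * N, 0.8), nrow = 8)
    counts <- counts[rowSums(counts) > 0, , drop = FALSE]
    if (nrow(counts) < 2) next
    g <- toy_gcm(counts)
    cv <- pan_core_curve(g, samples = 2^N, seed = rep)
    oracle <- pancore_oracle(counts)
    expect_equal(cv$pan_mean, oracle$pan_mean)
    expect_equal(cv$core_mean, oracle$core_mean)
    expect_equal(cv$pan_median, oracle$pan_median)
    expect_equal(cv$core_median, oracle$core_median)
  }
})

test_that("pan is non-decreasing and core non-increasing in n", {
  set.seed(77)
  for (rep in 1:20) {
    N <- sample(2:7, 1)
    counts <- matrix(rpois(6 * N, 0.7), nrow = 6)
    counts <- counts[rowSums(counts) > 0, , drop = FALSE]
    if (nrow(counts) < 1) next
    cv <- pan_core_curve(toy_gcm(counts), samples = 50, seed = rep)
    expect_true(all(diff(cv$pan_mean) >= -1e-9))
    expect_true(all(diff(cv$core_mean) <= 1e-9))
  }
})

test_that("sampled means converge to exhaustive means", {
  set.seed(55)
  counts <- matrix(rpois(10 * 8, 0.9), nrow = 10)
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  g <- toy_gcm(counts)
  exact <- pancore_oracle(counts)
  err <- vapply(c(20, 250), function(s) {
    cv <- pan_core_curve(g, samples = s, seed = 101)
    max(abs(cv$pan_mean - exact$pan_mean))
  }, numeric(1))
  expect_lte(err[2], err[1] + 1e-9)
})

test_that("power-law fit recovers exact and noisy parameters", {
  n <- 1:10
  cv <- data.frame(n = n, pan_mean = 2.5 * n^0.8, pan_median = 2.5 * n^0.8)
  fit <- fit_power_law(cv)
  expect_equal(fit$sigma, 2.5, tolerance = 1e-9)
  expect_equal(fit$gamma, 0.8, tolerance = 1e-9)

  const <- data.frame(n = 1:8, pan_mean = rep(7, 8), pan_median = rep(7, 8))
  fit0 <- fit_power_law(const)
  expect_equal(fit0$gamma, 0, tolerance = 1e-12)
  expect_equal(fit0$sigma, 7, tolerance = 1e-12)

  set.seed(11)
  n <- 1:30
  noisy <- data.frame(n = n,
                      pan_mean = 2.5 * n^0.8 * exp(rnorm(30, 0, 0.05)),
                      pan_median = NA)
  fitn <- fit_power_law(noisy)
  expect_lt(abs(fitn$gamma - 0.8), 0.05)

  expect_error(fit_power_law(data.frame(n = 1:3, pan_mean = c(1, 0, 2))),
               "positive")
  # median target is available
  expect_equal(fit_power_law(cv, fit_target = "median")$gamma, 0.8,
               tolerance = 1e-9)
})

test_that("co-occurrence matches hand counts on the toy matrices", {
  # one genome with three CYPs: complete triangle, all weights 1
  g1 <- toy_gcm(matrix(c(1, 2, 1), ncol = 1))
  net1 <- cooccurrence(g1)
  expect_equal(nrow(net1$edges), 3L)
  expect_true(all(net1$edges$weight == 1))
  expect_true(all(diag(net1$adjacency) == 0))

  # A(2,1,0), B(1,0,3), C(0,4,0): w(A,B)=1, w(A,C)=1, w(B,C)=0
  g2 <- toy_gcm(rbind(A = c(2, 1, 0), B = c(1, 0, 3), C = c(0, 4, 0)))
  net2 <- cooccurrence(g2)
  expect_equal(net2$weighted["A", "B"], 1)
  expect_equal(net2$weighted["A", "C"], 1)
  expect_equal(net2$weighted["B", "C"], 0)
  expect_equal(nrow(net2$edges), 2L)
  expect_equal(net2$nodes$occurrence, c(2, 2, 1))
  expect_equal(net2$nodes$total_count, c(3, 4, 4))
})

test_that("co-occurrence equals brute-force pair counting on random GCMs", {
  set.seed(14)
  for (rep in 1:10) {
    counts <- matrix(rpois(100, 0.6), nrow = 10,
                     dimnames = list(paste0("C", 1:10), paste0("g", 1:10)))
    net <- cooccurrence(toy_gcm(counts))
    W <- cooccurrence_oracle(counts)
    expect_equal(unname(net$weighted), unname(W))
    expect_identical(net$weighted, t(net$weighted))
    expect_true(all(diag(net$adjacency) == 0))
    expect_equal(net$adjacency, (net$weighted >= 1) * 1L)
    occ <- rowSums(counts > 0)
    for (e in seq_len(nrow(net$edges))) {
      expect_lte(net$edges$weight[e],
                 min(occ[net$edges$cyp_a[e]], occ[net$edges$cyp_b[e]]))
    }
  }
})

test_that("genome clustering orders leaves sensibly", {
  counts <- cbind(a1 = c(5, 4, 0, 0), a2 = c(5, 4, 0, 0),
                  b1 = c(0, 0, 6, 3), b2 = c(0, 1, 6, 3))
  rownames(counts) <- paste0("C", 1:4)
  g <- toy_gcm(counts)
  cl <- cluster_heatmap(g)
  expect_setequal(cl$genome_order, colnames(counts))
  # identical columns merge at height 0 and sit adjacent
  h <- cl$genome_hclust
  expect_equal(min(h$height), 0)
  pos <- match(c("a1", "a2"), cl$genome_order)
  expect_equal(abs(diff(pos)), 1L)
  # the two engineered groups form the two top-level subtrees
  top <- stats::cutree(h, k = 2)
  expect_length(unique(top[c("a1", "a2")]), 1L)
  expect_length(unique(top[c("b1", "b2")]), 1L)
  expect_false(top[["a1"]] == top[["b1"]])

  expect_warning(cluster_heatmap(toy_gcm(matrix(1:3, ncol = 1))),
                 "2 genomes")
})

test_that("cloud frequencies rank row totals with name tie-breaks", {
  g1 <- toy_gcm(matrix(c(2, 3), nrow = 1, dimnames = list("C1", NULL)))
  c1 <- cloud_frequencies(g1)
  expect_equal(c1$frequency, 5)
  expect_equal(c1$rank, 1L)

  g2 <- toy_gcm(rbind(A = c(2, 1, 0), B = c(1, 0, 3), C = c(0, 4, 0)))
  c2 <- cloud_frequencies(g2)
  expect_identical(c2$cyp, c("B", "C", "A"))   # B=4, C=4 tie by name, A=3
  expect_equal(sum(c2$frequency), sum(g2$counts))

  p <- file.path(tempdir(), "cloud.tsv")
  cloud_frequencies(g2, out_path = p)
  expect_identical(read.delim(p)$cyp, c2$cyp)
})
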