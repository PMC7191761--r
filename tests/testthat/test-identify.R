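test_that("build_profile gives consensus residues maximal scores", {
  set.seed(2)
  s <- random_aa_seq(20)
  prof <- build_profile(c(s, s), name = "p")
  expect_equal(prof$length, 20L)
  v <- strsplit(s, "")[[1]]
  for (j in 1:20) {
    expect_identical(names(which.max(prof$scores[j, ])), v[j])
  }
  expect_error(build_profile(s), "at least 2")
})

test_that("majority-gap columns are dropped", {
  aln <- c("AC-D", "AC-D", "A--D")
  prof <- build_profile(aln)
  expect_equal(prof$length, 3L)  # the all/majority-gap column is gone
  aln_all_gap <- c("----", "----")
  expect_error(build_profile(aln_all_gap), "no columns")
})

test_that("the consensus outscores every individual input sequence", {
  set.seed(9)
  anc <- random_aa_seq(30)
  inputs <- vapply(1:5, function(i) mutate_seq(anc, 4), character(1))
  prof <- build_profile(inputs, name = "fix")
  consensus <- paste(colnames(prof$scores)[apply(prof$scores, 1, which.max)],
                     collapse = "")
  cons_score <- scan_sequence(consensus, prof)$score
  for (s in inputs) {
    expect_gte(cons_score, scan_sequence(s, prof)$score)
  }
})

test_that("scan_sequence matches the brute-force all-window oracle", {
  set.seed(13)
  anc <- random_aa_seq(60)
  prof <- build_profile(vapply(1:4, function(i) mutate_seq(anc, 6),
                               character(1)))
  q <- random_aa_seq(200)
  got <- scan_sequence(q, prof)
  # oracle: score every one of the 141 windows independently
  v <- strsplit(q, "")[[1]]
  win <- vapply(1:141, function(s) {
    sum(vapply(1:60, function(j) prof$scores[j, v[s + j - 1]], numeric(1)))
  }, numeric(1))
  expect_equal(got$score, max(win))
  expect_equal(got$start, which.max(win))
  expect_equal(got$end, got$start + 59L)

  # consensus query: maximal score at start 1
  consensus <- paste(colnames(prof$scores)[apply(prof$scores, 1, which.max)],
                     collapse = "")
  cg <- scan_sequence(consensus, prof)
  expect_equal(cg$start, 1L)
  expect_equal(cg$score, sum(apply(prof$scores, 1, max)))

  # all-X query scores 0 (background expectation), short query no-hit
  xq <- strrep("X", 80)
  expect_equal(scan_sequence(xq, prof)$score, 0)
  expect_identical(scan_sequence("MKLV", prof)$score, -Inf)
})

test_that("E-values behave like K m n exp(-lambda S)", {
  cal <- structure(list(lambda = 0.3, K = 0.01), class = "ProfileCalibration")
  e1 <- estimate_evalue(50, 200, 60, cal)
  expect_equal(estimate_evalue(50, 200, 120, cal), 2 * e1)  # linear in n
  expect_equal(estimate_evalue(50, 400, 60, cal), 2 * e1)   # linear in m
  expect_lt(estimate_evalue(60, 200, 60, cal), e1)          # monotone in S
  expect_equal(estimate_evalue(1e6, 200, 60, cal), 0)       # S -> Inf
  expect_error(estimate_evalue(50, 200, 60, list()), "calibration")
})

test_that("calibrated tail predictions track hold-out decoys", {
  set.seed(4)
  anc <- random_aa_seq(60)
  prof <- build_profile(vapply(1:5, function(i) mutate_seq(anc, 8),
                               character(1)), name = "fix")
  cal <- calibrate_profile(prof, n_decoys = 500, decoy_length = 200,
                           seed = 7)
  expect_gt(cal$lambda, 0)
  expect_gt(cal$K, 0)
  # hold-out decoys, fresh seed
  set.seed(1234)
  hold <- vapply(1:400, function(i) {
    scan_sequence(random_aa_seq(200), prof)$score
  }, numeric(1))
  s95 <- unname(quantile(cal$scores, 0.95))
  emp <- mean(hold >= s95)
  pred <- estimate_evalue(s95, 200, prof$length, cal)
  expect_gt(emp, pred / 3)
  expect_lt(emp, pred * 3)
})

test_that("identify_cyps separates engineered CYPs from decoys", {
  ds <- shared_dataset()
  ref <- ds$reference
  prof <- build_profile(unname(ref$domain_alignment), name = "CYP_domain")
  prof$calibration <- calibrate_profile(prof, n_decoys = 500,
                                        decoy_length = 340, seed = 7)
  set.seed(99)
  cyps <- setNames(vapply(1:20, function(i) {
    r <- ref$references[sample(nrow(ref$references), 1), ]
    mutate_seq(r$sequence, round(0.1 * nchar(r$sequence)))
  }, character(1)), sprintf("g|c%02d", 1:20))
  decoys <- setNames(vapply(1:20, function(i) random_aa_seq(300),
                            character(1)), sprintf("g|d%02d", 1:20))
  hits <- identify_cyps(c(cyps, decoys), list(prof), evalue_cutoff = 1e-5)
  expect_setequal(hits$query, names(cyps))
  # margins: every decoy at least 1e3 above the cutoff
  all_ev <- vapply(names(decoys), function(id) {
    sc <- scan_sequence(decoys[[id]], prof)
    estimate_evalue(sc$score, nchar(decoys[[id]]), prof$length,
                    prof$calibration)
  }, numeric(1))
  expect_true(all(all_ev >= 1e-2))

  # identification is order-invariant and monotone in the cutoff
  shuf <- c(decoys, cyps)[sample(40)]
  hits2 <- identify_cyps(shuf, list(prof), evalue_cutoff = 1e-5)
  expect_equal(hits2, hits)
  relaxed <- identify_cyps(c(cyps, decoys), list(prof),
                           evalue_cutoff = 1e-3)
  expect_true(all(hits$query %in% relaxed$query))
  none <- identify_cyps(c(cyps, decoys), list(prof), evalue_cutoff = 0)
  expect_equal(nrow(none), 0L)
  empty <- identify_cyps(setNames(character(0), character(0)), list(prof))
  expect_equal(nrow(empty), 0L)
})

test_that("profiles round-trip through the text serialization", {
  set.seed(21)
  anc <- random_aa_seq(25)
  prof <- build_profile(vapply(1:3, function(i) mutate_seq(anc, 3),
                               character(1)), name = "rt")
  p <- file.path(tempdir(), "prof.tsv")
  write_profile(prof, p)
  back <- read_profile(p)
  expect_identical(back$name, "rt")
  expect_equal(back$length, prof$length)
  expect_equal(unname(back$scores), unname(prof$scores), tolerance = 1e-4)
})
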