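test_that("CYP names parse into family and subfamily", {
  p <- parse_cyp_name(c("CYP51F1", "CYP141A1", "CYP102", "CYP5150AB12"))
  expect_identical(p$family, c("CYP51", "CYP141", "CYP102", "CYP5150"))
  expect_identical(p$subfamily,
                   c("CYP51F", "CYP141A", NA, "CYP5150AB"))
  expect_identical(p$allele, c(1L, 1L, NA_integer_, 12L))
  expect_error(parse_cyp_name("P450foo"), "not a valid CYP name")
})

make_refs <- function(seqs, names) {
  parsed <- parse_cyp_name(names)
  parsed$subfamily[is.na(parsed$subfamily)] <- parsed$family
  parsed$sequence <- seqs
  parsed$allele <- NULL
  parsed
}

test_that("an exact reference match inherits family and subfamily", {
  set.seed(1)
  ref <- random_aa_seq(100)
  refs <- make_refs(ref, "CYP51F1")
  a <- best_hit_classify(ref, refs, query_id = "g|q")
  expect_identical(a$family, "CYP51")
  expect_identical(a$subfamily, "CYP51F")
  expect_equal(a$best_identity, 1)
  expect_false(a$family_is_new)
  expect_false(a$subfamily_is_new)
  expect_error(best_hit_classify(ref, refs[0, ]), "empty reference")
})

test_that("the 40%/55% rule boundaries are inclusive", {
  set.seed(8)
  ref <- random_aa_seq(100)
  refs <- make_refs(ref, "CYP51F1")
  cases <- list(
    list(id = 0.39, fam_new = TRUE,  sub_new = TRUE),
    list(id = 0.40, fam_new = FALSE, sub_new = TRUE),
    list(id = 0.54, fam_new = FALSE, sub_new = TRUE),
    list(id = 0.55, fam_new = FALSE, sub_new = FALSE),
    list(id = 0.56, fam_new = FALSE, sub_new = FALSE))
  for (cs in cases) {
    q <- query_at_identity(ref, cs$id)
    a <- best_hit_classify(q, refs)
    expect_equal(a$best_identity, cs$id, tolerance = 1e-12)
    expect_identical(a$family_is_new, cs$fam_new)
    expect_identical(a$subfamily_is_new, cs$sub_new)
    if (!cs$fam_new) expect_identical(a$family, "CYP51")
    if (!cs$sub_new) expect_identical(a$subfamily, "CYP51F")
  }
})

test_that("a ~31.7%-identity best hit founds a new family", {
  set.seed(50)
  ref <- random_aa_seq(120)
  refs <- make_refs(ref, "CYP141A1")
  q <- query_at_identity(ref, 38 / 120)   # ~31.7%
  a <- best_hit_classify(q, refs)
  expect_identical(a$best_hit, "CYP141A1")
  expect_lt(a$best_identity, 0.40)
  expect_true(a$family_is_new)
  expect_true(a$subfamily_is_new)
})

test_that("ties are broken by the lexicographically smallest name", {
  set.seed(3)
  ref <- random_aa_seq(80)
  refs <- make_refs(c(ref, ref), c("CYP9B1", "CYP10A1"))
  a <- best_hit_classify(ref, refs)
  expect_identical(a$best_hit, "CYP10A1")  # "CYP10A1" < "CYP9B1"
  # reference file order is irrelevant
  a2 <- best_hit_classify(ref, refs[2:1, ])
  expect_identical(a2$best_hit, a$best_hit)
})

test_that("novel groups get deterministic NF / NS working names", {
  set.seed(17)
  base <- random_aa_seq(100)
  refs <- make_refs(random_aa_seq(100), "CYP51F1")

  # one novel sequence -> NF1 / NF1.1
  seqs <- setNames(base, "g|a")
  a <- classify_centroids(seqs, refs)
  expect_identical(a$family, "NF1")
  expect_identical(a$subfamily, "NF1.1")

  # two novels at ~80% mutual identity share family and subfamily
  pair <- setNames(c(base, query_at_identity(base, 0.80)),
                   c("g|a", "g|b"))
  a2 <- classify_centroids(pair, refs)
  expect_identical(a2$family, c("NF1", "NF1"))
  expect_identical(a2$subfamily, c("NF1.1", "NF1.1"))

  # two novels at ~10% mutual identity split into NF1 and NF2
  far <- setNames(c(base, random_aa_seq(100)), c("g|a", "g|b"))
  stopifnot(pairwise_identity(far[[1]], far[[2]]) < 0.2)
  a3 <- classify_centroids(far, refs)
  expect_setequal(a3$family, c("NF1", "NF2"))

  # novel subfamily inside a known family
  mid <- setNames(query_at_identity(refs$sequence[1], 0.47), "g|m")
  a4 <- classify_centroids(mid, refs)
  expect_identical(a4$family, "CYP51")
  expect_identical(a4$subfamily, "CYP51-NS1")
})

test_that("centroid labels propagate to all cluster members", {
  clusters <- structure(list(threshold = 0.55, clusters = list(
    list(index = 0L, centroid = "g1|c1",
         members = data.frame(id = c("g1|m1", "g2|m2", "g2|m3"),
                              identity = c(0.9, 0.58, 0.75))),
    list(index = 1L, centroid = "g1|c2",
         members = data.frame(id = character(0), identity = numeric(0))),
    list(index = 2L, centroid = "g2|d1",
         members = data.frame(id = character(0), identity = numeric(0)))
  )), class = "ClusterSet")
  assignments <- data.frame(
    query = c("g1|c1", "g1|c2"), family = c("CYP51", "CYP102"),
    subfamily = c("CYP51F", "CYP102A"), best_hit = c("CYP51F1", "CYP102A1"),
    best_identity = c(0.9, 0.8), family_is_new = FALSE,
    subfamily_is_new = FALSE, stringsAsFactors = FALSE)
  tab <- propagate_to_members(assignments, clusters)
  expect_equal(nrow(tab), 5L)               # d1 cluster is unlabelled
  expect_setequal(tab$tagged_id[tab$family == "CYP51"],
                  c("g1|c1", "g1|m1", "g2|m2", "g2|m3"))
  expect_identical(tab$genome_id[tab$tagged_id == "g2|m2"], "g2")
  # member at 0.58 to its centroid is flagged near the 0.55 boundary
  expect_true(tab$near_boundary[tab$tagged_id == "g2|m2"])
  expect_false(tab$near_boundary[tab$tagged_id == "g1|m1"])

  bad <- assignments
  bad$query[1] <- "g9|nope"
  expect_error(propagate_to_members(bad, clusters), "non-centroid")
})
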