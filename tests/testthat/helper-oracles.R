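# Independent oracles used across the suite. These deliberately avoid the
# package's implementation paths: the aligner is a pure-R affine
# Needleman-Wunsch, pan/core and co-occurrence are plain loops.

.oracle_blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

# Global affine-gap alignment (gap of length k costs open + k * ext,
# end gaps penalised) returning the aligned strings.
nw_align <- function(a, b, open = 10, ext = 1) {
  S <- .oracle_blosum62()
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  n <- length(va)
  m <- length(vb)
  NEG <- -1e9
  M <- Ix <- Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- -(open + i * ext)
  for (j in seq_len(m)) Iy[1, j + 1] <- -(open + j * ext)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- S[va[i], vb[j]]
      M[i + 1, j + 1] <- s + max(M[i, j], Ix[i, j], Iy[i, j])
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                              Ix[i, j + 1] - ext,
                              Iy[i, j + 1] - open - ext)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                              Iy[i + 1, j] - ext,
                              Ix[i + 1, j] - open - ext)
    }
  }
  # traceback
  state <- which.max(c(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1]))
  i <- n; j <- m
  ra <- rb <- character(0)
  while (i > 0 || j > 0) {
    if (state == 1L) {
      ra <- c(va[i], ra); rb <- c(vb[j], rb)
      prev <- c(M[i, j], Ix[i, j], Iy[i, j])
      target <- M[i + 1, j + 1] - S[va[i], vb[j]]
      state <- which.max(ifelse(abs(prev - target) < 1e-6, prev, NEG))
      i <- i - 1; j <- j - 1
    } else if (state == 2L) {
      ra <- c(va[i], ra); rb <- c("-", rb)
      cur <- Ix[i + 1, j + 1]
      cand <- c(M[i, j + 1] - open - ext, Ix[i, j + 1] - ext,
                Iy[i, j + 1] - open - ext)
      state <- which.max(ifelse(abs(cand - cur) < 1e-6, cand, NEG))
      i <- i - 1
    } else {
      ra <- c("-", ra); rb <- c(vb[j], rb)
      cur <- Iy[i + 1, j + 1]
      cand <- c(M[i + 1, j] - open - ext, Iy[i + 1, j] - ext,
                Ix[i + 1, j] - open - ext)
      state <- which.max(ifelse(abs(cand - cur) < 1e-6, cand, NEG))
      state <- c(1L, 3L, 2L)[state]
      j <- j - 1
    }
    if (i == 0 && j > 0) state <- 3L
    if (j == 0 && i > 0) state <- 2L
  }
  list(a = paste(ra, collapse = ""), b = paste(rb, collapse = ""))
}

# identity = matches / columns excluding terminal-gap runs
nw_identity <- function(a, b, open = 10, ext = 1) {
  al <- nw_align(a, b, open, ext)
  va <- strsplit(al$a, "")[[1]]
  vb <- strsplit(al$b, "")[[1]]
  gap <- va == "-" | vb == "-"
  first <- match(FALSE, gap)
  if (is.na(first)) return(0)
  last <- length(gap) + 1L - match(FALSE, rev(gap))
  sum(va[first:last] == vb[first:last] & va[first:last] != "-") /
    (last - first + 1L)
}

# brute-force replay of the greedy clustering discipline (no prefilter,
# no vectorisation): returns member -> centroid map
greedy_oracle <- function(records, threshold = 0.55) {
  ord <- order(-nchar(records$sequence), records$tagged_id)
  ids <- records$tagged_id[ord]
  seqs <- records$sequence[ord]
  centroids <- character(0)
  cen_seq <- character(0)
  map <- character(length(ids))
  for (i in seq_along(ids)) {
    hit <- NA_character_
    for (k in seq_along(centroids)) {
      if (pairwise_identity(seqs[i], cen_seq[k]) >= threshold) {
        hit <- centroids[k]
        break
      }
    }
    if (is.na(hit)) {
      centroids <- c(centroids, ids[i])
      cen_seq <- c(cen_seq, seqs[i])
      hit <- ids[i]
    }
    map[i] <- hit
  }
  setNames(map, ids)
}

# exhaustive pan/core enumeration by plain loops over all subsets
pancore_oracle <- function(counts) {
  N <- ncol(counts)
  out <- NULL
  for (n in seq_len(N)) {
    subsets <- utils::combn(N, n, simplify = FALSE)
    pan <- core <- numeric(length(subsets))
    for (s in seq_along(subsets)) {
      sub <- counts[, subsets[[s]], drop = FALSE]
      pan[s] <- sum(apply(sub, 1, function(r) any(r > 0)))
      core[s] <- sum(apply(sub, 1, function(r) all(r > 0)))
    }
    out <- rbind(out, data.frame(n = n, pan_mean = mean(pan),
                                 core_mean = mean(core),
                                 pan_median = stats::median(pan),
                                 core_median = stats::median(core)))
  }
  out
}

# brute-force per-genome pair counting for the co-occurrence weights
cooccurrence_oracle <- function(counts) {
  p <- nrow(counts)
  W <- matrix(0L, p, p, dimnames = dimnames(counts)[c(1, 1)])
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j) next
      W[i, j] <- sum(counts[i, ] > 0 & counts[j, ] > 0)
    }
  }
  W
}

# --- fixture construction helpers -------------------------------------

random_aa_seq <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
               n, replace = TRUE), collapse = "")
}

# most-conservative substitution partner per residue (argmax off-diagonal
# BLOSUM62 score): substitutions score >= 0 so gapless alignments stay
# strictly optimal and realized identity = matches / length exactly
.conservative_partner <- local({
  p <- NULL
  function() {
    if (is.null(p)) {
      aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
              "K", "M", "F", "P", "S", "T", "W", "Y", "V")
      S <- .oracle_blosum62()[aa, aa]
      diag(S) <- -100
      p <<- setNames(aa[apply(S, 1, which.max)], aa)
    }
    p
  }
})

# query at an exact identity fraction to ref (equal length, engineered
# gapless optimum)
query_at_identity <- function(ref, identity) {
  L <- nchar(ref)
  k <- L - round(identity * L)
  stopifnot(abs((L - k) / L - identity) < 1e-9)
  v <- strsplit(ref, "")[[1]]
  pos <- round(seq(1, L, length.out = k))   # spread, deterministic
  v[pos] <- .conservative_partner()[v[pos]]
  paste(v, collapse = "")
}

# substitution-only mutant at k random positions (always to a different
# residue)
mutate_seq <- function(s, k) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
          "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  v <- strsplit(s, "")[[1]]
  pos <- sample(length(v), k)
  for (p in pos) v[p] <- sample(setdiff(aa, v[p]), 1)
  paste(v, collapse = "")
}

# small multi-family record set with known true partition
random_family_records <- function(n_fam = 3, members = 3, len = 60) {
  fams <- lapply(seq_len(n_fam), function(f) {
    anc <- random_aa_seq(len)
    vapply(seq_len(members), function(m) {
      mutate_seq(anc, max(1, round(0.1 * len)))
    }, character(1))
  })
  seqs <- unlist(fams)
  data.frame(
    tagged_id = sprintf("g1|f%02d_m%02d",
                        rep(seq_len(n_fam), each = members),
                        rep(seq_len(members), n_fam)),
    sequence = seqs,
    true_family = rep(seq_len(n_fam), each = members),
    stringsAsFactors = FALSE)
}

# --- shared expensive fixtures (built once per test run) ---------------

.shared <- new.env(parent = emptyenv())

shared_dataset <- function() {
  if (is.null(.shared$ds)) {
    .shared$ds <- write_synth_dataset(
      file.path(tempdir(), "cypome-synth42"), synth_config(seed = 42L))
  }
  .shared$ds
}

shared_run <- function() {
  if (is.null(.shared$run)) {
    ds <- shared_dataset()
    out <- file.path(tempdir(), "cypome-run42")
    cfg <- run_config(ds$paths$genomes_dir, ds$paths$ref_cyps,
                      ds$paths$ref_domains, out_dir = out, seed = 42L,
                      plots = TRUE)
    .shared$run <- suppressMessages(run_pipeline(cfg))
  }
  .shared$run
}
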