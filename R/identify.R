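#' Build a position-specific scoring matrix from an ungapped-ish alignment
#'
#' Constructs a log-odds profile of a conserved protein domain from a
#' multiple alignment. Columns with more than 50% gaps are dropped. Each
#' surviving column scores residue `a` as
#' `2 * log2((count_a + 1) / (n_obs + 20) / background_a)` (half-bit
#' units, +1 pseudocount). `X` and any non-standard residue score 0
#' (background expectation) when scanned.
#'
#' @param aligned_sequences Character vector of equal-length gapped
#'   sequences (`-` for gaps), at least 2.
#' @param name Profile name.
#' @param background Either `"uniform"` (each residue 0.05) or
#'   `"estimate"` (frequencies pooled from the alignment), or a named
#'   numeric vector over the 20 amino acids summing to 1.
#' @return A `DomainProfile`: list with `name`, `length`, `scores`
#'   (length x 20 matrix, half-bits, columns named by residue) and
#'   `background`.
#' @export
build_profile <- function(aligned_sequences, name = "CYP_domain",
                          background = "uniform") {
  if (length(aligned_sequences) < 2L) stop("need at least 2 sequences")
  aligned_sequences <- toupper(aligned_sequences)
  w <- unique(nchar(aligned_sequences))
  if (length(w) != 1L) stop("aligned sequences must all have equal length")
  m <- do.call(rbind, strsplit(aligned_sequences, "", fixed = TRUE))

  gap_frac <- colMeans(m == "-" | m == ".")
  keep <- gap_frac <= 0.5
  if (!any(keep)) stop("no columns survive the gap filter")
  m <- m[, keep, drop = FALSE]

  bg <- .resolve_background(background, m)
  L <- ncol(m)
  scores <- matrix(0, nrow = L, ncol = 20L,
                   dimnames = list(NULL, AA_ALPHABET20))
  for (j in seq_len(L)) {
    col <- m[, j]
    col <- col[col %in% AA_ALPHABET20]
    n_obs <- length(col)
    cnt <- table(factor(col, levels = AA_ALPHABET20))
    freq <- (as.numeric(cnt) + 1) / (n_obs + 20)
    scores[j, ] <- 2 * log2(freq / bg)
  }
  structure(list(name = name, length = L, scores = scores, background = bg),
            class = "DomainProfile")
}

.resolve_background <- function(background, m = NULL) {
  if (is.numeric(background)) {
    stopifnot(all(AA_ALPHABET20 %in% names(background)))
    bg <- background[AA_ALPHABET20]
    return(bg / sum(bg))
  }
  if (identical(background, "estimate")) {
    res <- m[m %in% AA_ALPHABET20]
    cnt <- table(factor(res, levels = AA_ALPHABET20))
    bg <- (as.numeric(cnt) + 1) / (length(res) + 20)
    names(bg) <- AA_ALPHABET20
    return(bg / sum(bg))
  }
  setNames(rep(0.05, 20L), AA_ALPHABET20)
}

#' Scan a query sequence with a domain profile
#'
#' Ungapped sliding-window scan: every window of the query the width of
#' the profile is scored by summing per-column residue scores, and the
#' maximum-scoring window is returned (ties broken by the smallest
#' start). `X` and other non-standard residues contribute 0.
#'
#' @param query Protein sequence.
#' @param profile A `DomainProfile` from [build_profile()].
#' @return List with `score` (half-bits; `-Inf` if the query is shorter
#'   than the profile), `start`, `end` (1-based inclusive).
#' @export
scan_sequence <- function(query, profile) {
  L <- profile$length
  n <- nchar(query)
  if (n < L) return(list(score = -Inf, start = NA_integer_, end = NA_integer_))
  res <- strsplit(toupper(query), "", fixed = TRUE)[[1]]
  idx <- match(res, AA_ALPHABET20)          # NA for X and friends -> 0
  nw <- n - L + 1L
  total <- numeric(nw)
  for (j in seq_len(L)) {
    v <- unname(profile$scores[j, ])[idx[j:(j + nw - 1L)]]
    v[is.na(v)] <- 0
    total <- total + v
  }
  best <- unname(which.max(total))  # first index on ties
  list(score = total[best], start = best, end = best + L - 1L)
}

#' Calibrate the E-value model of a profile on shuffled decoys
#'
#' Fits the Karlin-Altschul-shaped model `E = K * m * n * exp(-lambda * S)`
#' empirically: `n_decoys` random sequences are drawn from the profile
#' background, each is scanned, and a Gumbel distribution is fitted to
#' the maximum window scores by maximum likelihood. `lambda` is the
#' inverse Gumbel scale; `K` is set so that the expected hit count for a
#' decoy-sized query against a database of `profile$length` residues
#' reproduces the fitted tail.
#'
#' @param profile A `DomainProfile`.
#' @param n_decoys Number of decoy sequences (>= 500 recommended).
#' @param decoy_length Length of each decoy.
#' @param seed Integer seed; calibration is deterministic given it.
#' @return A `ProfileCalibration`: list with `lambda`, `K`,
#'   `decoy_length`, `n_decoys`, `seed`, `scores` (the decoy maxima).
#' @export
calibrate_profile <- function(profile, n_decoys = 500L, decoy_length = 300L,
                              seed = 1L) {
  if (n_decoys < 2L) stop("need at least 2 decoys")
  if (decoy_length < profile$length) {
    stop("decoy_length must be >= profile length")
  }
  set.seed(seed)
  maxima <- vapply(seq_len(n_decoys), function(i) {
    s <- paste(sample(AA_ALPHABET20, decoy_length, replace = TRUE,
                      prob = profile$background), collapse = "")
    scan_sequence(s, profile)$score
  }, numeric(1))

  fit <- .fit_gumbel(maxima)
  lambda <- 1 / fit$beta
  # P(max <= s) = exp(-K * m0 * n0 * exp(-lambda s)) with m0 = decoy
  # length, n0 = profile residues  =>  K * m0 * n0 = exp(mu / beta)
  K <- exp(lambda * fit$mu) / (decoy_length * profile$length)
  structure(list(lambda = lambda, K = K, mu = fit$mu, beta = fit$beta,
                 decoy_length = decoy_length, n_decoys = n_decoys,
                 seed = seed, scores = maxima),
            class = "ProfileCalibration")
}

# Gumbel (max) maximum-likelihood fit; moment estimates as start values.
.fit_gumbel <- function(x) {
  beta0 <- stats::sd(x) * sqrt(6) / pi
  mu0 <- mean(x) - 0.5772156649 * beta0
  nll <- function(p) {
    beta <- exp(p[2])
    z <- (x - p[1]) / beta
    sum(log(beta) + z + exp(-z))
  }
  opt <- optim(c(mu0, log(beta0)), nll, method = "Nelder-Mead")
  list(mu = opt$par[1], beta = exp(opt$par[2]))
}

#' E-value of a profile hit
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of chance
#' windows scoring `S` or better for a query of `m` residues against a
#' profile database of `n` residues. Monotonically decreasing in `S` and
#' linear in both sizes.
#'
#' @param score Window score in half-bits.
#' @param query_length Query length m (residues).
#' @param database_size Total profile-database residues n.
#' @param calibration A `ProfileCalibration`.
#' @return Positive E-value (0 only in the limit of infinite score).
#' @export
estimate_evalue <- function(score, query_length, database_size, calibration) {
  if (!inherits(calibration, "ProfileCalibration")) {
    stop("missing calibration: run calibrate_profile() for this profile")
  }
  calibration$K * query_length * database_size *
    exp(-calibration$lambda * score)
}

#' Identify CYP centroids by domain-profile scanning
#'
#' Scans every centroid against every profile; a centroid is identified
#' as a CYP when its best (lowest) E-value over the profiles does not
#' exceed `evalue_cutoff`. One best hit is retained per centroid:
#' multi-domain proteins count once.
#'
#' @param centroids Named character vector: tagged id -> sequence.
#' @param profiles List of `DomainProfile` objects, each carrying its
#'   calibration in `$calibration` (see [calibrate_profile()]).
#' @param evalue_cutoff Maximum E-value; default 1e-5.
#' @return Data frame (one row per identified CYP) with columns `query`,
#'   `profile`, `score`, `evalue`, `start`, `end`, sorted by query.
#' @export
identify_cyps <- function(centroids, profiles, evalue_cutoff = 1e-5) {
  if (length(profiles) < 1L) stop("need at least one profile")
  for (p in profiles) {
    if (is.null(p$calibration)) {
      stop("profile '", p$name,
           "' has no calibration: run calibrate_profile()")
    }
  }
  db_size <- sum(vapply(profiles, function(p) p$length, numeric(1)))
  hits <- lapply(names(centroids), function(id) {
    q <- centroids[[id]]
    best <- NULL
    for (p in profiles) {
      sc <- scan_sequence(q, p)
      if (!is.finite(sc$score)) next
      ev <- estimate_evalue(sc$score, nchar(q), db_size, p$calibration)
      if (is.null(best) || ev < best$evalue) {
        best <- data.frame(query = id, profile = p$name, score = sc$score,
                           evalue = ev, start = sc$start, end = sc$end,
                           stringsAsFactors = FALSE)
      }
    }
    if (!is.null(best) && best$evalue <= evalue_cutoff) best else NULL
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(query = character(0), profile = character(0),
                      score = numeric(0), evalue = numeric(0),
                      start = integer(0), end = integer(0))
  }
  out <- out[order(out$query), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a domain profile as a plain-text matrix
#'
#' One header line (`name`, length, tab, then the 20 residue letters),
#' followed by `length` rows of 20 tab-separated half-bit scores.
#'
#' @param profile A `DomainProfile`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(profile$name, profile$length, AA_ALPHABET20),
                   collapse = "\t"), con)
  write.table(format(profile$scores, digits = 6, trim = TRUE), con,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a domain profile written by [write_profile()]
#' @param path Path to a profile text file.
#' @return A `DomainProfile` (uniform background).
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  name <- hdr[1]
  L <- as.integer(hdr[2])
  alpha <- hdr[-(1:2)]
  scores <- do.call(rbind, lapply(lines[-1], function(l) {
    as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]])
  }))
  colnames(scores) <- alpha
  scores <- scores[, AA_ALPHABET20, drop = FALSE]
  stopifnot(nrow(scores) == L)
  structure(list(name = name, length = L, scores = scores,
                 background = setNames(rep(0.05, 20), AA_ALPHABET20)),
            class = "DomainProfile")
}
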