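#' Greedy incremental centroid clustering of protein sequences
#'
#' UCLUST-style greedy clustering: records are processed in decreasing
#' length order (ties broken by lexicographic tagged id); each record is
#' compared against existing centroids in centroid-creation order and
#' joins the first cluster whose centroid it matches at `threshold`
#' identity or better, otherwise it founds a new cluster. A length-5
#' amino-acid word prefilter skips centroids sharing no word with the
#' query; `exact = TRUE` disables it so every centroid is aligned
#' against (used by the brute-force oracle tests).
#'
#' @param records Data frame with columns `tagged_id` and `sequence`
#'   (as produced by [pool_and_tag()]).
#' @param threshold Identity threshold in (0, 1]; default 0.55.
#' @param exact Disable the k-mer prefilter.
#' @param best_match Assign to the best-identity centroid above the
#'   threshold instead of the first acceptable one.
#' @param word_size Prefilter word length.
#' @param identity_def Identity definition passed to the alignment engine.
#' @return A `ClusterSet`: list with `threshold` and `clusters`, an
#'   ordered list of clusters, each with `index` (0-based), `centroid`
#'   (tagged id) and `members` (data frame `id`, `identity`; the centroid
#'   itself is not listed — cluster size is `1 + nrow(members)`).
#' @export
greedy_cluster <- function(records, threshold = 0.55, exact = FALSE,
                           best_match = FALSE, word_size = 5L,
                           identity_def = "internal") {
  if (nrow(records) < 1L) stop("need at least one record")
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")

  lens <- nchar(records$sequence)
  ord <- order(-lens, records$tagged_id)
  ids <- records$tagged_id[ord]
  seqs <- records$sequence[ord]

  cen_ids <- character(0)
  cen_seqs <- character(0)
  cen_words <- list()        # set of k-mer words per centroid
  assignment <- integer(length(ids))    # 1-based cluster index per record
  identity <- numeric(length(ids))

  for (i in seq_along(ids)) {
    q <- seqs[i]
    cand <- seq_along(cen_ids)
    if (!exact && length(cand) > 0L) {
      qw <- .seq_words(q, word_size)
      share <- vapply(cen_words, function(w) any(qw %in% w), logical(1))
      cand <- cand[share]
    }
    hit <- 0L
    hit_id <- NA_real_
    if (length(cand) > 0L) {
      idents <- identity_to_subject(cen_seqs[cand], q,
                                    definition = identity_def)
      pass <- which(idents >= threshold)
      if (length(pass) > 0L) {
        j <- if (best_match) pass[which.max(idents[pass])] else pass[1L]
        hit <- cand[j]
        hit_id <- idents[j]
      }
    }
    if (hit > 0L) {
      assignment[i] <- hit
      identity[i] <- hit_id
    } else {
      cen_ids <- c(cen_ids, ids[i])
      cen_seqs <- c(cen_seqs, q)
      if (!exact) cen_words[[length(cen_ids)]] <- .seq_words(q, word_size)
      assignment[i] <- length(cen_ids)
      identity[i] <- 1
    }
  }

  clusters <- lapply(seq_along(cen_ids), function(k) {
    mem <- which(assignment == k & ids != cen_ids[k])
    list(index = k - 1L, centroid = cen_ids[k],
         members = data.frame(id = ids[mem], identity = identity[mem],
                              stringsAsFactors = FALSE))
  })
  structure(list(clusters = clusters, threshold = threshold),
            class = "ClusterSet")
}

# k-mer word set of a sequence (unique words)
.seq_words <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(s)
  unique(substring(s, 1:(n - k + 1L), k:n))
}

#' Membership table of a cluster set
#'
#' @param clusters A `ClusterSet`.
#' @return Data frame with columns `cluster` (0-based), `member`,
#'   `centroid`, `identity`.
#' @export
cluster_membership <- function(clusters) {
  out <- do.call(rbind, lapply(clusters$clusters, function(cl) {
    rbind(data.frame(cluster = cl$index, member = cl$centroid,
                     centroid = cl$centroid, identity = 1,
                     stringsAsFactors = FALSE),
          if (nrow(cl$members) > 0L)
            data.frame(cluster = cl$index, member = cl$members$id,
                       centroid = cl$centroid,
                       identity = cl$members$identity,
                       stringsAsFactors = FALSE))
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.ClusterSet <- function(x, ...) {
  sizes <- vapply(x$clusters, function(cl) 1L + nrow(cl$members), integer(1))
  cat(sprintf("ClusterSet: %d clusters at %.0f%% identity (%d records)\n",
              length(x$clusters), 100 * x$threshold, sum(sizes)))
  invisible(x)
}
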