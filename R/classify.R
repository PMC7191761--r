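#' Parse CYP nomenclature names
#'
#' Splits names such as `CYP51F1` into family (`CYP51`), subfamily
#' (`CYP51F`) and allele number, following the standard nomenclature
#' pattern `CYP<digits><letters><digits>` (subfamily letters and allele
#' number optional).
#'
#' @param names Character vector of CYP names.
#' @return Data frame with columns `name`, `family`, `subfamily`,
#'   `allele` (NA when absent).
#' @export
parse_cyp_name <- function(names) {
  m <- regmatches(names, regexec("^(CYP[0-9]+)([A-Za-z]+)?([0-9]+)?$", names))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad)) {
    stop("not a valid CYP name: ", paste(names[bad], collapse = ", "))
  }
  fam <- vapply(m, `[`, character(1), 2L)
  sub_letters <- vapply(m, `[`, character(1), 3L)
  allele <- vapply(m, `[`, character(1), 4L)
  data.frame(name = names, family = fam,
             subfamily = ifelse(nzchar(sub_letters),
                                paste0(fam, sub_letters), NA_character_),
             allele = suppressWarnings(as.integer(allele)),
             stringsAsFactors = FALSE)
}

#' Read a named reference CYP FASTA
#'
#' Record headers must be CYP names (e.g. `CYP51F1`); family and
#' subfamily are parsed from them.
#'
#' @param path Path to the reference FASTA.
#' @return Data frame with columns `name`, `family`, `subfamily`,
#'   `sequence`.
#' @export
read_reference_cyps <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  if (length(ss) == 0L) stop("no sequences in reference file ", path)
  ids <- vapply(strsplit(names(ss), "[ \t]"), `[`, character(1), 1L)
  parsed <- parse_cyp_name(ids)
  parsed$subfamily[is.na(parsed$subfamily)] <- parsed$family[is.na(parsed$subfamily)]
  parsed$sequence <- toupper(as.character(ss))
  parsed$allele <- NULL
  parsed
}

#' Classify one query against the reference CYP set by best identity
#'
#' Finds the best-identity reference (ties broken by lexicographically
#' smallest reference name) and applies the nomenclature rules:
#' identity >= 0.55 inherits family and subfamily; 0.40 <= identity <
#' 0.55 inherits the family with a novel subfamily; identity < 0.40 is a
#' novel family (and therefore novel subfamily). Both thresholds are
#' inclusive.
#'
#' @param query Protein sequence.
#' @param refs Reference data frame from [read_reference_cyps()].
#' @param query_id Tagged id recorded in the assignment.
#' @param family_id,subfamily_id Identity thresholds (defaults 0.40 and
#'   0.55).
#' @return One-row data frame (a `CypAssignment`): `query`, `family`,
#'   `subfamily`, `best_hit`, `best_identity`, `family_is_new`,
#'   `subfamily_is_new`. Novel levels are left `NA` until
#'   [name_novel_groups()] labels them.
#' @export
best_hit_classify <- function(query, refs, query_id = "query",
                              family_id = 0.40, subfamily_id = 0.55) {
  if (nrow(refs) < 1L) stop("empty reference set")
  ord <- order(refs$name)
  refs <- refs[ord, , drop = FALSE]
  idents <- identity_to_subject(refs$sequence, query)
  best <- which.max(idents)  # first (smallest name) on ties
  bid <- idents[best]
  fam_new <- bid < family_id
  sub_new <- fam_new || bid < subfamily_id
  data.frame(query = query_id,
             family = if (fam_new) NA_character_ else refs$family[best],
             subfamily = if (sub_new) NA_character_ else refs$subfamily[best],
             best_hit = refs$name[best],
             best_identity = bid,
             family_is_new = fam_new,
             subfamily_is_new = sub_new,
             stringsAsFactors = FALSE)
}

#' Classify many centroid sequences
#'
#' Applies [best_hit_classify()] to each identified CYP centroid and
#' then labels novel groups with [name_novel_groups()].
#'
#' @param sequences Named character vector: tagged id -> sequence.
#' @param refs Reference data frame.
#' @inheritParams best_hit_classify
#' @return Data frame of assignments, one row per sequence.
#' @export
classify_centroids <- function(sequences, refs, family_id = 0.40,
                               subfamily_id = 0.55) {
  if (length(sequences) == 0L) {
    return(data.frame(query = character(0), family = character(0),
                      subfamily = character(0), best_hit = character(0),
                      best_identity = numeric(0),
                      family_is_new = logical(0),
                      subfamily_is_new = logical(0)))
  }
  out <- do.call(rbind, lapply(names(sequences), function(id) {
    best_hit_classify(sequences[[id]], refs, query_id = id,
                      family_id = family_id, subfamily_id = subfamily_id)
  }))
  name_novel_groups(out, sequences, family_id = family_id,
                    subfamily_id = subfamily_id)
}

#' Label novel families and subfamilies
#'
#' Sequences flagged as novel are clustered among themselves, greedily
#' and deterministically (processing order = lexicographic tagged id),
#' with the same 40%/55% identity thresholds. Sequences co-clustering at
#' the family threshold share a new family label `NF<k>` (k = 1-based
#' discovery order) and, inside each new family, co-clustering at the
#' subfamily threshold yields `NF<k>.<j>` subfamily labels. Novel
#' subfamilies inside a known family are labelled `<family>-NS<j>`.
#' These labels are run-scoped working names, not nomenclature-committee
#' assignments.
#'
#' @param assignments Assignment data frame (rows with novelty flags).
#' @param sequences Named character vector covering all novel queries.
#' @inheritParams best_hit_classify
#' @return The assignment data frame with `family`/`subfamily` filled in.
#' @export
name_novel_groups <- function(assignments, sequences, family_id = 0.40,
                              subfamily_id = 0.55) {
  # --- novel families ---
  nf <- which(assignments$family_is_new)
  if (length(nf) > 0L) {
    qids <- sort(assignments$query[nf])
    fam_centroids <- character(0)   # sequences founding NF families
    fam_of <- integer(length(qids))
    for (i in seq_along(qids)) {
      s <- sequences[[qids[i]]]
      k <- 0L
      if (length(fam_centroids) > 0L) {
        idents <- identity_to_subject(fam_centroids, s)
        pass <- which(idents >= family_id)
        if (length(pass) > 0L) k <- pass[1L]
      }
      if (k == 0L) {
        fam_centroids <- c(fam_centroids, s)
        k <- length(fam_centroids)
      }
      fam_of[i] <- k
    }
    # subfamilies inside each new family
    sub_label <- character(length(qids))
    for (k in seq_along(fam_centroids)) {
      in_k <- which(fam_of == k)
      sub_of <- .greedy_label(sequences[qids[in_k]], subfamily_id)
      sub_label[in_k] <- paste0("NF", k, ".", sub_of)
    }
    idx <- match(qids, assignments$query)
    assignments$family[idx] <- paste0("NF", fam_of)
    assignments$subfamily[idx] <- sub_label
  }

  # --- novel subfamilies within known families ---
  ns <- which(assignments$subfamily_is_new & !assignments$family_is_new)
  if (length(ns) > 0L) {
    for (fam in unique(assignments$family[ns])) {
      rows <- ns[assignments$family[ns] == fam]
      qids <- sort(assignments$query[rows])
      sub_of <- .greedy_label(sequences[qids], subfamily_id)
      idx <- match(qids, assignments$query)
      assignments$subfamily[idx] <- paste0(fam, "-NS", sub_of)
    }
  }
  assignments
}

# Greedy single-linkage-to-centroid labelling: returns a 1-based group
# index per sequence, discovery order = input order.
.greedy_label <- function(seqs, threshold) {
  centroids <- character(0)
  out <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    k <- 0L
    if (length(centroids) > 0L) {
      idents <- identity_to_subject(centroids, seqs[[i]])
      pass <- which(idents >= threshold)
      if (length(pass) > 0L) k <- pass[1L]
    }
    if (k == 0L) {
      centroids <- c(centroids, seqs[[i]])
      k <- length(centroids)
    }
    out[i] <- k
  }
  out
}

#' Propagate centroid assignments to all cluster members
#'
#' Every member of a cluster whose centroid was identified and
#' classified as a CYP inherits the centroid's family and subfamily;
#' members of non-CYP centroids are dropped (unlabelled). A
#' `near_boundary` column flags members whose identity to their centroid
#' lies within 5 percentage points of a classification rule boundary
#' (0.40 or 0.55), where inherited labels are least certain.
#'
#' @param assignments Centroid-level assignment data frame.
#' @param clusters A `ClusterSet`; every assigned query must be one of
#'   its centroids.
#' @return Per-sequence assignment table: `tagged_id`, `genome_id`,
#'   `id`, `family`, `subfamily`, `best_hit`, `best_identity`,
#'   `centroid`, `identity_to_centroid`, `is_centroid`, `near_boundary`.
#' @export
propagate_to_members <- function(assignments, clusters) {
  cen_ids <- vapply(clusters$clusters, function(cl) cl$centroid, character(1))
  unknown <- setdiff(assignments$query, cen_ids)
  if (length(unknown) > 0L) {
    stop("assignment for non-centroid id(s): ",
         paste(unknown, collapse = ", "))
  }
  rows <- lapply(clusters$clusters, function(cl) {
    a <- assignments[assignments$query == cl$centroid, , drop = FALSE]
    if (nrow(a) == 0L) return(NULL)
    members <- rbind(data.frame(id = cl$centroid, identity = 1,
                                stringsAsFactors = FALSE), cl$members)
    data.frame(tagged_id = members$id,
               family = a$family, subfamily = a$subfamily,
               best_hit = a$best_hit, best_identity = a$best_identity,
               centroid = cl$centroid,
               identity_to_centroid = members$identity,
               is_centroid = members$id == cl$centroid,
               near_boundary = abs(members$identity - 0.40) < 0.05 |
                 abs(members$identity - 0.55) < 0.05,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(tagged_id = character(0), family = character(0),
                      subfamily = character(0), best_hit = character(0),
                      best_identity = numeric(0), centroid = character(0),
                      identity_to_centroid = numeric(0),
                      is_centroid = logical(0), near_boundary = logical(0))
  }
  split_ids <- split_tagged_id(out$tagged_id)
  out <- cbind(out[, "tagged_id", drop = FALSE], split_ids,
               out[, setdiff(names(out), "tagged_id"), drop = FALSE])
  rownames(out) <- NULL
  out
}
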