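#' Read one genome's protein FASTA
#'
#' Reads a protein FASTA file (`.fasta`/`.faa`) into a genome proteome:
#' a data frame of records tagged with a genome identifier derived from the
#' filename stem. Sequences are uppercased; a terminal stop character
#' (`*`) is stripped silently; records containing any other character
#' outside the 20 amino acids plus `X` are skipped with a warning.
#' Duplicate record ids within one file are disambiguated by appending an
#' ordinal suffix (`_2`, `_3`, ...).
#'
#' @param path Path to a protein FASTA file.
#' @param genome_id Genome identifier; defaults to the filename stem.
#' @return An object of class `GenomeProteome`: a list with `genome_id`
#'   and `records`, a data frame with columns `id` and `sequence`.
#' @export
read_fasta <- function(path, genome_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(genome_id)) {
    genome_id <- sub("\\.(fasta|faa|fa)$", "", basename(path),
                     ignore.case = TRUE)
  }
  ss <- Biostrings::readAAStringSet(path)
  if (length(ss) == 0L) stop("no sequences in ", path)
  # keep only the first whitespace-delimited token of each header
  ids <- vapply(strsplit(names(ss), "[ \t]"), `[`, character(1), 1L)
  seqs <- toupper(as.character(ss))
  seqs <- sub("\\*+$", "", seqs)  # terminal stop codons

  ok_chars <- paste0("^[", paste(AA_ALPHABET20, collapse = ""), "X]+$")
  keep <- grepl(ok_chars, seqs) & nchar(seqs) >= 1L
  if (any(!keep)) {
    for (bad in ids[!keep]) {
      .log_warn("record '%s' in %s contains non-amino-acid characters; skipped",
                bad, basename(path))
    }
    ids <- ids[keep]
    seqs <- seqs[keep]
  }
  if (length(seqs) == 0L) stop("no valid sequences in ", path)

  # disambiguate duplicate ids in file order
  if (anyDuplicated(ids)) {
    tab <- table(ids)
    for (d in names(tab[tab > 1L])) {
      idx <- which(ids == d)
      # second copy gets _2, third _3, ...
      ids[idx[-1L]] <- paste0(d, "_", 1L + seq_len(length(idx) - 1L))
      .log_warn("duplicate record id '%s' in %s disambiguated", d,
                basename(path))
    }
  }
  structure(list(genome_id = genome_id,
                 records = data.frame(id = ids, sequence = seqs,
                                      stringsAsFactors = FALSE)),
            class = "GenomeProteome")
}

#' Write protein sequences to FASTA
#'
#' @param sequences Named character vector of protein sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return The path, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 70L) {
  ss <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(ss, filepath = path, width = width)
  invisible(path)
}

#' Pool genomes into one tagged record set
#'
#' Concatenates the proteomes of several genomes into a single ordered
#' record table whose `tagged_id` (`genome_id|id`) is globally unique. A
#' `|` occurring inside an input record id is replaced by `_` so the tag
#' stays parseable.
#'
#' @param genomes List of `GenomeProteome` objects.
#' @return Data frame with columns `tagged_id`, `genome_id`, `id`,
#'   `sequence`.
#' @export
pool_and_tag <- function(genomes) {
  if (length(genomes) < 1L) stop("need at least one genome")
  gids <- vapply(genomes, function(g) g$genome_id, character(1))
  if (anyDuplicated(gids)) {
    stop("duplicate genome_id: ",
         paste(unique(gids[duplicated(gids)]), collapse = ", "))
  }
  out <- do.call(rbind, lapply(genomes, function(g) {
    ids <- g$records$id
    if (any(grepl(GENOME_SEP, ids, fixed = TRUE))) {
      .log_warn("record ids in genome '%s' contain '%s'; replaced by '_'",
                g$genome_id, GENOME_SEP)
      ids <- gsub(GENOME_SEP, "_", ids, fixed = TRUE)
    }
    data.frame(tagged_id = paste0(g$genome_id, GENOME_SEP, ids),
               genome_id = g$genome_id, id = ids,
               sequence = g$records$sequence, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  stopifnot(!anyDuplicated(out$tagged_id))
  out
}

#' Split a tagged id back into genome and record id
#' @param tagged_id Character vector of `genome|record` ids.
#' @return Data frame with columns `genome_id`, `id`.
#' @export
split_tagged_id <- function(tagged_id) {
  pos <- regexpr(GENOME_SEP, tagged_id, fixed = TRUE)
  data.frame(genome_id = substr(tagged_id, 1L, pos - 1L),
             id = substr(tagged_id, pos + 1L, nchar(tagged_id)),
             stringsAsFactors = FALSE)
}

#' Write a cluster set in UCLUST's uc format
#'
#' Emits the 10-column tab-separated uc format: `S` lines for centroid
#' seeds, `H` lines for cluster members (with percent identity to the
#' centroid), and `C` summary lines carrying the cluster size. The
#' alignment column is emitted as `*`; downstream steps only consume
#' cluster membership.
#'
#' @param clusters A `ClusterSet` (see [greedy_cluster()]).
#' @param path Output path.
#' @param lengths Named integer vector of sequence lengths indexed by
#'   tagged id (used for the length column of S/H lines).
#' @return The path, invisibly.
#' @export
write_uc <- function(clusters, path, lengths) {
  lines <- character(0)
  for (cl in clusters$clusters) {
    cen_len <- unname(lengths[[cl$centroid]])
    lines <- c(lines, paste("S", cl$index, cen_len, "*", "*", "*", "*", "*",
                            cl$centroid, "*", sep = "\t"))
    if (nrow(cl$members) > 0L) {
      lines <- c(lines, paste("H", cl$index,
                              unname(lengths[cl$members$id]),
                              sprintf("%.1f", 100 * cl$members$identity),
                              "*", "*", "*", "*",
                              cl$members$id, cl$centroid, sep = "\t"))
    }
    lines <- c(lines, paste("C", cl$index, 1L + nrow(cl$members), "*", "*",
                            "*", "*", "*", cl$centroid, "*", sep = "\t"))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Parse a uc cluster file back into a membership table
#'
#' @param path Path to a uc file written by [write_uc()] (or UCLUST).
#' @return Data frame with columns `cluster` (0-based), `member`,
#'   `centroid`, `identity` (fraction; 1 for the centroid itself).
#' @export
read_uc <- function(path) {
  uc <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (ncol(uc) != 10L) stop("uc file must have 10 columns")
  names(uc) <- c("type", "cluster", "size", "pctid", "strand", "p1", "p2",
                 "aln", "query", "target")
  s <- uc[uc$type == "S", ]
  h <- uc[uc$type == "H", ]
  out <- rbind(
    data.frame(cluster = as.integer(s$cluster), member = s$query,
               centroid = s$query, identity = 1, stringsAsFactors = FALSE),
    if (nrow(h) > 0L)
      data.frame(cluster = as.integer(h$cluster), member = h$query,
                 centroid = h$target, identity = as.numeric(h$pctid) / 100,
                 stringsAsFactors = FALSE)
  )
  out[order(out$cluster, out$member != out$centroid, out$member), ,
      drop = FALSE]
}
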