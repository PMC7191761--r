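#' Build the Genome-CYP Matrix (GCM)
#'
#' Counts classified sequences per CYP name and genome at the family or
#' subfamily level: rows are CYP names, columns genomes, elements the
#' number of sequences of that genome carrying the name. Rows are sorted
#' lexicographically with novel (`NF`) groups after known families;
#' columns sorted by genome id.
#'
#' @param assignments Per-sequence assignment table (see
#'   [propagate_to_members()]): must carry `genome_id` and the level
#'   column (`family` or `subfamily`).
#' @param level `"family"` or `"subfamily"`.
#' @param genome_ids Optional character vector of all genomes in the
#'   run; genomes without any CYP then appear as all-zero columns.
#' @return A `GCM`: list with `level`, `cyp_names`, `genome_ids`,
#'   `counts` (integer matrix with dimnames) and the derived `G_ci`
#'   (genomes containing each CYP) and `G_t` (total genomes).
#' @export
build_gcm <- function(assignments, level = c("family", "subfamily"),
                      genome_ids = NULL) {
  level <- match.arg(level)
  labels <- assignments[[level]]
  if (is.null(genome_ids)) genome_ids <- unique(assignments$genome_id)
  genome_ids <- sort(genome_ids)
  cyp_names <- .sort_cyp_names(unique(labels))
  counts <- matrix(0L, nrow = length(cyp_names), ncol = length(genome_ids),
                   dimnames = list(cyp_names, genome_ids))
  if (nrow(assignments) > 0L) {
    tab <- table(factor(labels, levels = cyp_names),
                 factor(assignments$genome_id, levels = genome_ids))
    counts[] <- as.integer(tab)
  }
  structure(list(level = level, cyp_names = cyp_names,
                 genome_ids = genome_ids, counts = counts,
                 G_ci = rowSums(counts > 0), G_t = length(genome_ids)),
            class = "GCM")
}

# lexicographic, but run-scoped novel families (NF...) after known ones
.sort_cyp_names <- function(x) {
  x <- x[!is.na(x)]
  is_nf <- startsWith(x, "NF")
  c(sort(x[!is_nf]), sort(x[is_nf]))
}

#' @export
print.GCM <- function(x, ...) {
  cat(sprintf("GCM (%s level): %d CYP names x %d genomes, %d sequences\n",
              x$level, nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Export a GCM as a numeric CSV table
#'
#' Layout: header row (`CYP`, then genome ids), one row per CYP name,
#' unquoted integer counts — the `panTable_<level>_numeric.csv` format.
#'
#' @param gcm A `GCM`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
export_numeric_csv <- function(gcm, path) {
  df <- data.frame(CYP = rownames(gcm$counts), gcm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a GCM back from its numeric CSV export
#' @param path Path to a csv written by [export_numeric_csv()].
#' @param level Level recorded on the result.
#' @return A `GCM`.
#' @export
read_numeric_csv <- function(path, level = "family") {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  mode(counts) <- "integer"
  rownames(counts) <- df[[1]]
  structure(list(level = level, cyp_names = rownames(counts),
                 genome_ids = colnames(counts), counts = counts,
                 G_ci = rowSums(counts > 0), G_t = ncol(counts)),
            class = "GCM")
}
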