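#' Pairwise global percent identity between two protein sequences
#'
#' Aligns two sequences globally (Needleman-Wunsch with affine gaps,
#' BLOSUM62, gap opening 10, gap extension 1) and returns the fraction of
#' identical alignment columns. Under the default `"internal"` definition
#' the denominator excludes terminal-gap columns (the USEARCH-like
#' convention); `"all-columns"` divides by the full alignment length.
#'
#' @param a,b Protein sequences (character scalars).
#' @param definition `"internal"` (default) or `"all-columns"`.
#' @param gap_opening,gap_extension Affine gap penalties (positive costs).
#' @param substitution_matrix Scoring matrix name or matrix; default
#'   BLOSUM62.
#' @return Identity fraction in \[0, 1\]; symmetric in its arguments.
#' @examples
#' pairwise_identity("ACDEFGHIK", "ACDEFGHIR")  # 8/9
#' @export
pairwise_identity <- function(a, b, definition = c("internal", "all-columns"),
                              gap_opening = 10, gap_extension = 1,
                              substitution_matrix = "BLOSUM62") {
  definition <- match.arg(definition)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  identity_to_subject(a, b, definition = definition,
                      gap_opening = gap_opening,
                      gap_extension = gap_extension,
                      substitution_matrix = substitution_matrix)
}

#' Global identity of many patterns against one subject
#'
#' Vectorised backend for [pairwise_identity()]: aligns each pattern
#' globally against the single subject and returns identity fractions.
#'
#' @inheritParams pairwise_identity
#' @param patterns Character vector of protein sequences.
#' @param subject Single protein sequence.
#' @return Numeric vector of identities, one per pattern.
#' @keywords internal
identity_to_subject <- function(patterns, subject,
                                definition = "internal",
                                gap_opening = 10, gap_extension = 1,
                                substitution_matrix = "BLOSUM62") {
  if (length(patterns) == 0L) return(numeric(0))
  mat <- .get_submat(substitution_matrix)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(patterns), Biostrings::AAString(subject),
    substitutionMatrix = mat, gapOpening = gap_opening,
    gapExtension = gap_extension, type = "global")
  pa <- as.character(Biostrings::alignedPattern(aln))
  sa <- as.character(Biostrings::alignedSubject(aln))
  vapply(seq_along(pa), function(i) {
    .aligned_identity(pa[i], sa[i], definition)
  }, numeric(1))
}

.submat_cache <- new.env(parent = emptyenv())

.get_submat <- function(name) {
  if (is.matrix(name)) return(name)
  if (!is.null(.submat_cache[[name]])) return(.submat_cache[[name]])
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  .submat_cache[[name]] <- get(name, envir = e)
  .submat_cache[[name]]
}

# Identity from a pair of aligned (gapped) strings.
.aligned_identity <- function(pa, sa, definition = "internal") {
  va <- strsplit(pa, "", fixed = TRUE)[[1]]
  vb <- strsplit(sa, "", fixed = TRUE)[[1]]
  n <- length(va)
  stopifnot(length(vb) == n)
  matches <- sum(va == vb & va != "-")
  if (definition == "all-columns") return(matches / n)
  # terminal-gap columns: leading/trailing runs where either row is a gap
  gap_either <- va == "-" | vb == "-"
  first <- match(FALSE, gap_either)
  if (is.na(first)) return(0)  # degenerate: all columns have a gap
  last <- n + 1L - match(FALSE, rev(gap_either))
  denom <- last - first + 1L
  matches / denom
}
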