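#' Configuration for the synthetic CYP dataset generator
#'
#' The generator builds a named reference CYP set, a conserved-domain
#' alignment, and multi-genome proteomes with a ground-truth manifest,
#' so the whole pipeline can be exercised offline. Pairwise identities
#' are engineered into disjoint bands that keep a safety margin of at
#' least 5 percentage points from both classification rule boundaries
#' (0.40 and 0.55): members of one subfamily stay at >= 0.70 mutual
#' identity, subfamily references within a family fall in 0.45--0.54,
#' and references of different families stay at <= 0.30.
#'
#' @param seed Master seed; all outputs are byte-deterministic given it.
#' @param n_families Number of reference CYP families.
#' @param subfamilies_per_family Subfamily references per family (one
#'   reference sequence each).
#' @param n_genomes Number of synthetic genomes.
#' @param cyps_per_genome CYP sequences drawn per genome.
#' @param decoys_per_genome Non-CYP decoy sequences per genome.
#' @param length_range Protein length range (residues).
#' @param core_length Length of the conserved domain core embedded in
#'   every CYP and in no decoy.
#' @param member_mut_range Per-member substitution fraction range
#'   relative to its subfamily reference (keeps members at 0.85--0.95
#'   identity to the reference and >= 0.70 to each other).
#' @param subfamily_divergence Substitution fraction applied (on
#'   disjoint position sets) to derive each subfamily reference from its
#'   family ancestor; two references then sit at
#'   `1 - 2 * subfamily_divergence` mutual identity.
#' @param within_family_band,between_family_max,within_subfamily_min
#'   Identity bands the realized sequences are verified against.
#' @param family_pool Optional integer vector restricting which families
#'   genomes draw from (used to engineer overlapping populations).
#' @param max_retries Regeneration attempts before giving up on a band.
#' @return A `SynthConfig` list.
#' @export
synth_config <- function(seed = 42L, n_families = 4L,
                         subfamilies_per_family = 2L, n_genomes = 6L,
                         cyps_per_genome = 8L, decoys_per_genome = 6L,
                         length_range = c(280L, 340L), core_length = 60L,
                         member_mut_range = c(0.05, 0.15),
                         subfamily_divergence = 0.25,
                         within_family_band = c(0.45, 0.54),
                         between_family_max = 0.30,
                         within_subfamily_min = 0.70,
                         family_pool = NULL, max_retries = 20L) {
  structure(as.list(environment()), class = "SynthConfig")
}

#' Generate the synthetic reference CYP database
#'
#' One random ancestor per family (with a shared conserved core
#' embedded); subfamily references are derived by substitutions at
#' disjoint position sets so their mutual identity lands in the
#' within-family band. Realized pairwise identities are verified against
#' the configured bands by direct alignment and offending families are
#' regenerated (bounded retries).
#'
#' @param config A `SynthConfig`.
#' @return A `SynthReference`: list with `references` (data frame
#'   `name`, `family`, `subfamily`, `sequence`), `domain_alignment`
#'   (named character vector of the per-reference core region, aligned
#'   and ungapped), `core` (the canonical core sequence) and `config`.
#' @export
generate_reference_db <- function(config) {
  set.seed(config$seed)
  core <- .random_aa(config$core_length)
  fams <- list()
  f <- 1L
  tries <- 0L
  while (f <= config$n_families) {
    cand <- .make_family(config, core, f)
    if (.family_band_ok(cand, fams, config)) {
      fams[[f]] <- cand
      f <- f + 1L
      tries <- 0L
    } else {
      tries <- tries + 1L
      if (tries > config$max_retries) {
        stop("identity band unattainable after ", config$max_retries,
             " retries for family ", f,
             " (realized identities keep leaving the configured bands)")
      }
    }
  }
  refs <- do.call(rbind, lapply(fams, `[[`, "refs"))
  rownames(refs) <- NULL
  domain <- setNames(
    unlist(lapply(fams, function(fm) {
      substr(fm$refs$sequence, fm$core_start,
             fm$core_start + config$core_length - 1L)
    })),
    refs$name)
  structure(list(references = refs, domain_alignment = domain,
                 core = core, config = config),
            class = "SynthReference")
}

# One synthetic family: ancestor + subfamily references.
.make_family <- function(config, core, fam_index) {
  L <- sample(seq(config$length_range[1], config$length_range[2]), 1L)
  core_start <- sample.int(L - config$core_length + 1L, 1L)
  anc <- .random_aa(L)
  substr(anc, core_start, core_start + config$core_length - 1L) <- core
  s <- config$subfamilies_per_family
  k <- round(L * config$subfamily_divergence)
  pos <- sample.int(L, s * k)           # disjoint mutation sets
  fam_name <- paste0("CYP", 100L + fam_index)
  refs <- do.call(rbind, lapply(seq_len(s), function(j) {
    pj <- pos[((j - 1L) * k + 1L):(j * k)]
    data.frame(name = paste0(fam_name, LETTERS[j], 1L),
               family = fam_name,
               subfamily = paste0(fam_name, LETTERS[j]),
               sequence = .mutate_positions(anc, pj),
               stringsAsFactors = FALSE)
  }))
  list(refs = refs, ancestor = anc, core_start = core_start, L = L)
}

# verify within-family band and between-family ceiling for a candidate
.family_band_ok <- function(cand, existing, config) {
  seqs <- cand$refs$sequence
  if (length(seqs) > 1L) {
    for (i in seq_len(length(seqs) - 1L)) {
      idents <- identity_to_subject(seqs[(i + 1L):length(seqs)], seqs[i])
      if (any(idents < config$within_family_band[1] |
              idents > config$within_family_band[2])) return(FALSE)
    }
  }
  for (fm in existing) {
    for (s in seqs) {
      if (any(identity_to_subject(fm$refs$sequence, s) >
              config$between_family_max)) return(FALSE)
    }
  }
  TRUE
}

#' Generate synthetic genome proteomes with ground truth
#'
#' Each genome draws `cyps_per_genome` subfamily references (with
#' replacement, from `family_pool` if set), derives one member sequence
#' per draw inside the within-subfamily identity band, and adds
#' `decoys_per_genome` random decoys verified to share no 10-mer with
#' the conserved core. The manifest records the truth for every
#' sequence.
#'
#' @param config A `SynthConfig`.
#' @param reference A `SynthReference` from the same config.
#' @param genome_prefix Prefix of the generated genome ids.
#' @return A `SynthGenomes`: list with `genomes` (list of
#'   `GenomeProteome`), `manifest` (data frame `genome_id`, `id`,
#'   `is_cyp`, `family`, `subfamily`) and `config`.
#' @export
generate_genomes <- function(config, reference, genome_prefix = "genome") {
  set.seed(config$seed + 1L)
  refs <- reference$references
  pool <- if (is.null(config$family_pool)) {
    seq_len(config$n_families)
  } else config$family_pool
  fam_names <- unique(refs$family)[pool]
  pool_rows <- which(refs$family %in% fam_names)

  genomes <- list()
  manifest <- list()
  for (g in seq_len(config$n_genomes)) {
    gid <- sprintf("%s%02d", genome_prefix, g)
    ids <- character(0)
    seqs <- character(0)
    fams <- character(0)
    subs <- character(0)
    draws <- sample(pool_rows, config$cyps_per_genome, replace = TRUE)
    for (j in seq_along(draws)) {
      r <- refs[draws[j], ]
      member <- .derive_member(r$sequence, config)
      ids <- c(ids, sprintf("p%03d", j))
      seqs <- c(seqs, member)
      fams <- c(fams, r$family)
      subs <- c(subs, r$subfamily)
    }
    for (j in seq_len(config$decoys_per_genome)) {
      ids <- c(ids, sprintf("d%03d", j))
      seqs <- c(seqs, .make_decoy(config, reference$core))
      fams <- c(fams, NA_character_)
      subs <- c(subs, NA_character_)
    }
    genomes[[g]] <- structure(
      list(genome_id = gid,
           records = data.frame(id = ids, sequence = seqs,
                                stringsAsFactors = FALSE)),
      class = "GenomeProteome")
    manifest[[g]] <- data.frame(genome_id = gid, id = ids,
                                is_cyp = !is.na(fams), family = fams,
                                subfamily = subs, stringsAsFactors = FALSE)
  }
  structure(list(genomes = genomes, manifest = do.call(rbind, manifest),
                 config = config),
            class = "SynthGenomes")
}

# member within the within-subfamily band of its reference, verified
.derive_member <- function(ref_seq, config) {
  L <- nchar(ref_seq)
  for (try in seq_len(config$max_retries)) {
    rate <- runif(1, config$member_mut_range[1], config$member_mut_range[2])
    k <- max(1L, round(L * rate))
    member <- .mutate_positions(ref_seq, sample.int(L, k))
    ident <- pairwise_identity(member, ref_seq)
    if (ident >= 0.80 && ident <= 0.97) return(member)
  }
  stop("could not derive member inside the within-subfamily band")
}

.make_decoy <- function(config, core) {
  core_words <- .seq_words(core, 10L)
  for (try in seq_len(config$max_retries)) {
    d <- .random_aa(sample(seq(config$length_range[1],
                               config$length_range[2]), 1L))
    if (!any(.seq_words(d, 10L) %in% core_words)) return(d)
  }
  stop("could not generate a core-free decoy")
}

.random_aa <- function(n) {
  paste(sample(AA_ALPHABET20, n, replace = TRUE), collapse = "")
}

# substitute the given positions, each to a different residue drawn from
# the BLOSUM62-conditional distribution P(b | a) ~ 2^(score(a,b)/2)
.mutate_positions <- function(seq, positions) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  cond <- .blosum_conditional()
  for (p in positions) {
    v[p] <- sample(AA_ALPHABET20, 1L, prob = cond[v[p], ])
  }
  paste(v, collapse = "")
}

.blosum_cond_cache <- new.env(parent = emptyenv())

.blosum_conditional <- function() {
  if (!is.null(.blosum_cond_cache$m)) return(.blosum_cond_cache$m)
  b <- .get_submat("BLOSUM62")[AA_ALPHABET20, AA_ALPHABET20]
  w <- 2^(b / 2)
  diag(w) <- 0                      # never "mutate" to the same residue
  m <- w / rowSums(w)
  .blosum_cond_cache$m <- m
  m
}

#' Expected Genome-CYP Matrix from a truth manifest
#'
#' Recomputes the GCM a perfect pipeline would produce by counting the
#' manifest directly — the ground-truth oracle for end-to-end tests.
#'
#' @param manifest Manifest data frame from [generate_genomes()].
#' @param level `"family"` or `"subfamily"`.
#' @param genome_ids Optional full genome set (zero columns included).
#' @return A `GCM`.
#' @export
expected_gcm <- function(manifest, level = c("family", "subfamily"),
                         genome_ids = NULL) {
  level <- match.arg(level)
  cyp <- manifest[manifest$is_cyp, , drop = FALSE]
  if (is.null(genome_ids)) genome_ids <- unique(manifest$genome_id)
  build_gcm(cyp, level = level, genome_ids = genome_ids)
}

#' Write a complete synthetic dataset to disk
#'
#' Emits the directory layout the pipeline consumes: one protein FASTA
#' per genome under `genomes/`, the named reference FASTA
#' (`reference_cyps.faa`), the domain alignment
#' (`domain_alignment.afa`) and the ground truth
#' (`truth_manifest.tsv`).
#'
#' @param dir Output directory (created if needed).
#' @param config A `SynthConfig`.
#' @return List with `paths` (named: `genomes_dir`, `ref_cyps`,
#'   `ref_domains`, `manifest`), `reference` and `genomes` objects.
#' @export
write_synth_dataset <- function(dir, config = synth_config()) {
  reference <- generate_reference_db(config)
  synth <- generate_genomes(config, reference)
  gdir <- file.path(dir, "genomes")
  dir.create(gdir, recursive = TRUE, showWarnings = FALSE)
  for (g in synth$genomes) {
    write_fasta(setNames(g$records$sequence, g$records$id),
                file.path(gdir, paste0(g$genome_id, ".faa")))
  }
  ref_path <- file.path(dir, "reference_cyps.faa")
  write_fasta(setNames(reference$references$sequence,
                       reference$references$name), ref_path)
  dom_path <- file.path(dir, "domain_alignment.afa")
  write_fasta(reference$domain_alignment, dom_path)
  man_path <- file.path(dir, "truth_manifest.tsv")
  write.table(synth$manifest, man_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  list(paths = list(genomes_dir = gdir, ref_cyps = ref_path,
                    ref_domains = dom_path, manifest = man_path),
       reference = reference, genomes = synth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
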