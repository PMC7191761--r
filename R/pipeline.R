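#' Pipeline run configuration
#'
#' Collects inputs, output directory, thresholds and switches for a full
#' run. Defaults mirror the pipeline's standard operating point:
#' clustering at 55% identity, family/subfamily rules at 40%/55%,
#' domain-scan E-value cutoff 1e-5, 300 subsets per pan-CYPome point.
#'
#' @param input_dir Directory containing one protein FASTA
#'   (`.fasta`/`.faa`) per genome.
#' @param ref_cyps Reference CYP FASTA (headers = CYP names).
#' @param ref_domains Aligned FASTA of reference CYP domain sequences
#'   (used to build the scan profile).
#' @param out_dir Output directory.
#' @param seed Integer seed controlling subset sampling and E-value
#'   calibration.
#' @param cluster_id,family_id,subfamily_id Identity thresholds.
#' @param evalue E-value cutoff for CYP identification.
#' @param pan_samples Subsets per pan-CYPome point.
#' @param plots Render PNG figures in addition to tables.
#' @param exact Disable the clustering k-mer prefilter.
#' @param fit_target `"mean"` or `"median"` pan summary for the
#'   power-law fit.
#' @param identity_def Identity definition (`"internal"` or
#'   `"all-columns"`).
#' @return A `RunConfig` list.
#' @export
run_config <- function(input_dir, ref_cyps, ref_domains, out_dir,
                       seed = 1L, cluster_id = 0.55, family_id = 0.40,
                       subfamily_id = 0.55, evalue = 1e-5,
                       pan_samples = 300L, plots = TRUE, exact = FALSE,
                       fit_target = "mean", identity_def = "internal") {
  stopifnot(cluster_id > 0, cluster_id <= 1, family_id > 0, family_id <= 1,
            subfamily_id > 0, subfamily_id <= 1, evalue > 0,
            pan_samples >= 1)
  structure(as.list(environment()), class = "RunConfig")
}

#' Run the full pipeline
#'
#' Executes the four pipeline stages on every genome FASTA in the input
#' directory: (1) pooling and greedy centroid clustering, (2) CYP
#' identification by calibrated domain-profile scanning of the
#' centroids, (3) family/subfamily classification of CYP centroids with
#' propagation to cluster members, (4) GCM construction at both levels
#' followed by pan/core-CYPome + power-law, co-occurrence-network,
#' genome-clustering and CYP-cloud analyses. All tables, a run log and
#' a checksummed output manifest are written to `out_dir`; the output
#' catalog is fixed and never exceeds 32 files.
#'
#' @param config A `RunConfig` from [run_config()].
#' @return Invisibly, a list with every intermediate (`pooled`,
#'   `clusters`, `hits`, `assignments`, `per_sequence`, `gcm`
#'   (per level), `pancore`, `powerlaw`, `network`, `clustering`,
#'   `cloud`, `files`).
#' @export
run_pipeline <- function(config) {
  t0 <- Sys.time()
  for (p in c(config$ref_cyps, config$ref_domains)) {
    if (!file.exists(p)) stop("missing reference file: ", p)
  }
  fa <- list.files(config$input_dir, pattern = "\\.(fasta|faa|fa)$",
                   full.names = TRUE, ignore.case = TRUE)
  if (length(fa) == 0L) stop("no .fasta/.faa files in ", config$input_dir)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  log_lines <- c(
    sprintf("# pipeline run %s", format(t0, "%Y-%m-%d %H:%M:%S")),
    sprintf("R %s.%s; package cypome %s", R.version$major, R.version$minor,
            as.character(utils::packageVersion("cypome"))),
    sprintf("seed=%d cluster_id=%g family_id=%g subfamily_id=%g evalue=%g pan_samples=%d",
            config$seed, config$cluster_id, config$family_id,
            config$subfamily_id, config$evalue, config$pan_samples))
  files <- character(0)
  emit <- function(path) { files <<- c(files, path); path }

  ## Step 1: pool and cluster -------------------------------------------
  genomes <- lapply(fa, read_fasta)
  pooled <- pool_and_tag(genomes)
  log_lines <- c(log_lines, sprintf("step1: %d genomes, %d sequences",
                                    length(genomes), nrow(pooled)))
  clusters <- greedy_cluster(pooled, threshold = config$cluster_id,
                             exact = config$exact,
                             identity_def = config$identity_def)
  cen_ids <- vapply(clusters$clusters, `[[`, character(1), "centroid")
  cen_seqs <- setNames(pooled$sequence[match(cen_ids, pooled$tagged_id)],
                       cen_ids)
  write_fasta(cen_seqs, emit(file.path(config$out_dir, "R_centroids.faa")))
  lens <- setNames(nchar(pooled$sequence), pooled$tagged_id)
  write_uc(clusters, emit(file.path(config$out_dir, "R_clusters.uc")), lens)
  log_lines <- c(log_lines, sprintf("step1: %d clusters at %g%% identity",
                                    length(clusters$clusters),
                                    100 * config$cluster_id))

  ## Step 2: identify CYP centroids -------------------------------------
  dom <- Biostrings::readAAStringSet(config$ref_domains)
  profile <- build_profile(as.character(dom), name = "CYP_domain")
  profile$calibration <- calibrate_profile(
    profile, n_decoys = 500L,
    decoy_length = max(300L, max(nchar(cen_seqs))),
    seed = config$seed + 17L)
  hits <- identify_cyps(cen_seqs, list(profile),
                        evalue_cutoff = config$evalue)
  write.table(hits, emit(file.path(config$out_dir, "I_cyp_hits.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  log_lines <- c(log_lines,
                 sprintf("step2: %d of %d centroids identified as CYP (E <= %g)",
                         nrow(hits), length(cen_seqs), config$evalue))

  ## Step 3: classify and propagate -------------------------------------
  refs <- read_reference_cyps(config$ref_cyps)
  assignments <- classify_centroids(cen_seqs[hits$query], refs,
                                    family_id = config$family_id,
                                    subfamily_id = config$subfamily_id)
  per_sequence <- propagate_to_members(assignments, clusters)
  write.table(per_sequence,
              emit(file.path(config$out_dir, "C_classification.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  n_new_fam <- length(unique(assignments$family[assignments$family_is_new]))
  n_new_sub <- length(unique(assignments$subfamily[assignments$subfamily_is_new]))
  if (n_new_fam + n_new_sub > 0) {
    log_lines <- c(log_lines, sprintf(
      "step3: NOTE %d novel families / %d novel subfamilies carry run-scoped working names (NF/NS), not committee assignments",
      n_new_fam, n_new_sub))
  }
  log_lines <- c(log_lines,
                 sprintf("step3: %d CYP sequences classified into %d families / %d subfamilies",
                         nrow(per_sequence),
                         length(unique(per_sequence$family)),
                         length(unique(per_sequence$subfamily))))

  ## Step 4: GCMs and analyses ------------------------------------------
  gids <- vapply(genomes, `[[`, character(1), "genome_id")
  result <- list(pooled = pooled, clusters = clusters, hits = hits,
                 assignments = assignments, per_sequence = per_sequence,
                 gcm = list(), pancore = list(), powerlaw = list(),
                 network = list(), clustering = list(), cloud = list())
  for (level in c("family", "subfamily")) {
    Lv <- tools::toTitleCase(level)
    gcm <- build_gcm(per_sequence, level = level, genome_ids = gids)
    export_numeric_csv(gcm, emit(file.path(
      config$out_dir, sprintf("panTable_%s_numeric.csv", Lv))))

    curve <- pan_core_curve(gcm, samples = config$pan_samples,
                            seed = config$seed)
    write.table(as.data.frame(curve),
                emit(file.path(config$out_dir,
                               sprintf("R_pancore_%s.tsv", Lv))),
                sep = "\t", quote = FALSE, row.names = FALSE)
    pl <- tryCatch(fit_power_law(curve, fit_target = config$fit_target),
                   error = function(e) {
                     .log_warn("power-law fit skipped (%s level): %s",
                               level, conditionMessage(e))
                     NULL
                   })
    net <- cooccurrence(gcm)
    write_network(net,
                  emit(file.path(config$out_dir,
                                 sprintf("N_network_%s.tsv", Lv))),
                  emit(file.path(config$out_dir,
                                 sprintf("N_nodes_%s.tsv", Lv))))
    clus <- NULL
    if (length(gids) >= 2L && nrow(gcm$counts) > 0L) {
      clus <- cluster_heatmap(
        gcm, out_prefix = emit_prefix(config$out_dir, Lv, emit),
        plot_file = if (config$plots)
          emit(file.path(config$out_dir,
                         sprintf("R_heatmap_%s.png", Lv))) else NULL)
    }
    cloud <- cloud_frequencies(
      gcm, out_path = emit(file.path(config$out_dir,
                                     sprintf("R_cloud_%s.tsv", Lv))),
      plot_file = if (config$plots && nrow(gcm$counts) > 0L)
        emit(file.path(config$out_dir,
                       sprintf("R_cloud_%s.png", Lv))) else NULL)
    result$gcm[[level]] <- gcm
    result$pancore[[level]] <- curve
    result$powerlaw[[level]] <- pl
    result$network[[level]] <- net
    result$clustering[[level]] <- clus
    result$cloud[[level]] <- cloud
    log_lines <- c(log_lines,
                   sprintf("step4 (%s): %d CYP names; pan at N = %g; gamma = %s",
                           level, nrow(gcm$counts),
                           utils::tail(curve$pan_mean, 1),
                           if (is.null(pl)) "NA" else sprintf("%.4f", pl$gamma)))
  }
  pl_df <- do.call(rbind, lapply(names(result$powerlaw), function(lv) {
    pl <- result$powerlaw[[lv]]
    if (is.null(pl)) return(NULL)
    data.frame(level = lv, sigma = pl$sigma, gamma = pl$gamma,
               fit_target = pl$fit_target, r_squared = pl$r_squared)
  }))
  if (!is.null(pl_df)) {
    write.table(pl_df, emit(file.path(config$out_dir, "R_powerlaw.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## log + manifest ------------------------------------------------------
  log_lines <- c(log_lines, sprintf("done in %.1f s",
                                    as.numeric(Sys.time() - t0, units = "secs")))
  writeLines(log_lines, emit(log_path))
  files <- unique(files[file.exists(files)])
  manifest <- data.frame(file = basename(files),
                         bytes = file.size(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  man_path <- file.path(config$out_dir, "output_manifest.tsv")
  write.table(manifest, man_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  result$files <- c(files, man_path)
  stopifnot(length(result$files) <= 32L)
  invisible(result)
}

# register the leaf-order text file produced by cluster_heatmap
emit_prefix <- function(out_dir, Lv, emit) {
  prefix <- file.path(out_dir, sprintf("R_heatmap_%s", Lv))
  emit(paste0(prefix, "_leaforder.txt"))
  prefix
}
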