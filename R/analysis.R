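#' Pan- and core-CYPome rarefaction curve
#'
#' For every subset size `n` in `1..N` (N = number of genomes), draws up
#' to `samples` distinct genome subsets (exhaustive enumeration when
#' `choose(N, n) <= samples`, i.e. sampling is without replacement among
#' subsets). For each subset the pan-CYPome size is the number of GCM
#' rows present in at least one subset genome and the core-CYPome size
#' the number of rows present in every subset genome. Per-`n` means and
#' medians of both are reported.
#'
#' @param gcm A `GCM`.
#' @param samples Maximum number of subsets per `n` (default 300).
#' @param seed Integer seed making the subset draw deterministic.
#' @return A `PanCoreCurve`: data frame with columns `n`, `n_subsets`,
#'   `pan_mean`, `pan_median`, `core_mean`, `core_median`, plus the raw
#'   per-subset sizes in `attr(, "samples")` (list indexed by `n` with
#'   matrices `pan`/`core`).
#' @export
pan_core_curve <- function(gcm, samples = 300L, seed = 1L) {
  if (samples < 1L) stop("samples must be >= 1")
  N <- ncol(gcm$counts)
  if (N < 1L) stop("GCM has no genomes")
  present <- gcm$counts > 0
  set.seed(seed)
  per_n <- vector("list", N)
  rows <- vector("list", N)
  for (n in seq_len(N)) {
    n_total <- choose(N, n)
    if (n_total <= samples) {
      subsets <- combn(N, n, simplify = FALSE)
    } else {
      subsets <- list()
      seen <- character(0)
      while (length(subsets) < samples) {
        s <- sort(sample.int(N, n))
        key <- paste(s, collapse = ",")
        if (!(key %in% seen)) {
          seen <- c(seen, key)
          subsets[[length(subsets) + 1L]] <- s
        }
      }
    }
    pan <- vapply(subsets, function(s) {
      sum(rowSums(present[, s, drop = FALSE]) >= 1L)
    }, numeric(1))
    core <- vapply(subsets, function(s) {
      sum(rowSums(present[, s, drop = FALSE]) == length(s))
    }, numeric(1))
    per_n[[n]] <- list(pan = pan, core = core)
    rows[[n]] <- data.frame(n = n, n_subsets = length(subsets),
                            pan_mean = mean(pan), pan_median = median(pan),
                            core_mean = mean(core),
                            core_median = median(core))
  }
  out <- do.call(rbind, rows)
  attr(out, "samples") <- per_n
  class(out) <- c("PanCoreCurve", class(out))
  out
}

#' Fit the pan-CYPome power law n = sigma * N^gamma
#'
#' Ordinary least squares of `log(pan size)` on `log(N)`: `gamma` is the
#' slope and `sigma = exp(intercept)`. `gamma` near 0 indicates a closed
#' (saturating) pan-CYPome; substantially positive `gamma`, an open one.
#'
#' @param curve A `PanCoreCurve`, or a data frame with columns `n` and
#'   the chosen summary column.
#' @param fit_target `"mean"` (default) or `"median"` pan summary.
#' @return A `PowerLawFit`: list with `sigma`, `gamma`, `N` (number of
#'   points), `fit_target`, `r_squared`.
#' @export
fit_power_law <- function(curve, fit_target = c("mean", "median")) {
  fit_target <- match.arg(fit_target)
  ycol <- paste0("pan_", fit_target)
  y <- curve[[ycol]]
  x <- curve$n
  if (length(unique(x)) < 2L) stop("need >= 2 distinct subset sizes")
  if (any(y <= 0)) stop("pan summaries must be positive for a log-log fit")
  fit <- lm(log(y) ~ log(x))
  structure(list(sigma = unname(exp(coef(fit)[1])),
                 gamma = unname(coef(fit)[2]),
                 N = length(x), fit_target = fit_target,
                 r_squared = suppressWarnings(summary(fit)$r.squared)),
            class = "PowerLawFit")
}

#' @export
print.PowerLawFit <- function(x, ...) {
  cat(sprintf("Power law n = sigma * N^gamma: sigma = %.4g, gamma = %.4g (%s, %d points, R^2 = %.3f)\n",
              x$sigma, x$gamma, x$fit_target, x$N, x$r_squared))
  invisible(x)
}

#' CYP co-occurrence network from a GCM
#'
#' Two CYPs co-occur when they are present together in at least one
#' genome. With `B = indicator(M > 0)`, the weighted co-occurrence
#' matrix is `B %*% t(B)` with a zeroed diagonal (entry = number of
#' genomes sharing the pair) and the unweighted adjacency replaces every
#' non-zero entry by 1. Node occurrence counts are the number of genomes
#' containing each CYP; total sequence counts are exported alongside.
#'
#' @param gcm A `GCM`.
#' @return A `CooccurrenceNetwork`: list with `nodes` (data frame `cyp`,
#'   `occurrence`, `total_count`), `weighted` and `adjacency` matrices,
#'   and `edges` (data frame `cyp_a`, `cyp_b`, `weight`; `cyp_a < cyp_b`,
#'   weight > 0).
#' @export
cooccurrence <- function(gcm) {
  B <- (gcm$counts > 0) * 1L
  W <- B %*% t(B)
  diag(W) <- 0L
  A <- (W >= 1L) * 1L
  nodes <- data.frame(cyp = rownames(B), occurrence = rowSums(B),
                      total_count = rowSums(gcm$counts),
                      stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  edges <- NULL
  if (nrow(W) > 1L) {
    ut <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
    edges <- data.frame(cyp_a = rownames(W)[ut[, 1]],
                        cyp_b = colnames(W)[ut[, 2]],
                        weight = W[ut], stringsAsFactors = FALSE)
    edges <- edges[order(edges$cyp_a, edges$cyp_b), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(cyp_a = character(0), cyp_b = character(0),
                        weight = integer(0))
  }
  structure(list(nodes = nodes, weighted = W, adjacency = A, edges = edges),
            class = "CooccurrenceNetwork")
}

#' Hierarchical clustering of genomes (and CYPs) on the GCM
#'
#' Clusters genome columns (and CYP rows) of the count matrix with
#' [stats::hclust()]. A text summary (leaf orders plus the merge tree)
#' is written when `out_prefix` is given, and a clustered-heatmap image
#' when `plot_file` is given and a rendering backend is available.
#'
#' @param gcm A `GCM` with at least 2 genomes.
#' @param metric Distance metric for [stats::dist()] (default
#'   `"euclidean"`).
#' @param linkage Agglomeration method (default `"average"`).
#' @param out_prefix Optional path prefix for the text summary
#'   (`<prefix>_leaforder.txt`).
#' @param plot_file Optional path of a heatmap image (PNG).
#' @return A `GenomeClustering`: list with `genome_hclust`,
#'   `cyp_hclust` (NULL when < 2 rows), `genome_order`, `cyp_order`,
#'   `metric`, `linkage`.
#' @export
cluster_heatmap <- function(gcm, metric = "euclidean", linkage = "average",
                            out_prefix = NULL, plot_file = NULL) {
  if (ncol(gcm$counts) < 2L) {
    warning("need >= 2 genomes for clustering; skipped")
    return(NULL)
  }
  gh <- hclust(dist(t(gcm$counts), method = metric), method = linkage)
  ch <- if (nrow(gcm$counts) >= 2L) {
    hclust(dist(gcm$counts, method = metric), method = linkage)
  } else NULL
  res <- structure(list(genome_hclust = gh, cyp_hclust = ch,
                        genome_order = gh$labels[gh$order],
                        cyp_order = if (is.null(ch)) rownames(gcm$counts)
                                    else ch$labels[ch$order],
                        metric = metric, linkage = linkage),
                   class = "GenomeClustering")
  if (!is.null(out_prefix)) {
    con <- file(paste0(out_prefix, "_leaforder.txt"), "w")
    writeLines(c(paste0("# metric=", metric, " linkage=", linkage),
                 paste0("genome_order\t",
                        paste(res$genome_order, collapse = ",")),
                 paste0("cyp_order\t", paste(res$cyp_order, collapse = ",")),
                 "# genome merge tree (hclust merge; heights below)",
                 apply(cbind(gh$merge, round(gh$height, 6)), 1,
                       paste, collapse = "\t")), con)
    close(con)
  }
  if (!is.null(plot_file)) {
    .try_plot(plot_file, function() {
      if (requireNamespace("pheatmap", quietly = TRUE)) {
        pheatmap::pheatmap(gcm$counts, clustering_method = linkage,
                           clustering_distance_rows = metric,
                           clustering_distance_cols = metric,
                           cluster_rows = !is.null(ch),
                           main = paste0("Genome-CYP matrix (",
                                         gcm$level, ")"),
                           filename = plot_file, silent = TRUE)
        return(TRUE)   # pheatmap manages its own device
      }
      FALSE
    })
  }
  res
}

#' CYP cloud: population-wide CYP frequencies
#'
#' Total sequence count per CYP name (row sums of the GCM), ranked in
#' decreasing frequency with ties broken by name — the tabular form of a
#' CYP word cloud. A simple text-cloud image is rendered when
#' `plot_file` is given.
#'
#' @param gcm A `GCM`.
#' @param out_path Optional path of a tab-separated table (`cyp`,
#'   `frequency`, `rank`).
#' @param plot_file Optional PNG path.
#' @return A `CypCloud` data frame: `cyp`, `frequency`, `rank`.
#' @export
cloud_frequencies <- function(gcm, out_path = NULL, plot_file = NULL) {
  freq <- rowSums(gcm$counts)
  ord <- order(-freq, names(freq))
  out <- data.frame(cyp = names(freq)[ord], frequency = unname(freq[ord]),
                    rank = seq_along(freq), stringsAsFactors = FALSE)
  class(out) <- c("CypCloud", class(out))
  if (!is.null(out_path)) {
    write.table(out, out_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(plot_file) && nrow(out) > 0L) {
    .try_plot(plot_file, function() {
      png(plot_file, width = 800, height = 600)
      on.exit(dev.off())
      op <- par(mar = c(0, 0, 2, 0))
      on.exit(par(op), add = TRUE)
      n <- nrow(out)
      cex <- 0.8 + 3 * out$frequency / max(out$frequency)
      # deterministic golden-angle spiral, most frequent in the centre
      th <- 2.39996 * seq_len(n)
      r <- 0.45 * sqrt((seq_len(n) - 1) / max(1, n - 1))
      plot.new()
      title(main = paste0("CYP cloud (", gcm$level, ")"))
      text(0.5 + r * cos(th), 0.5 + r * sin(th), out$cyp,
           cex = cex, col = hcl.colors(n, "Dark 2"))
      TRUE
    })
  }
  out
}

#' Write an edge list and node table of a co-occurrence network
#'
#' Plain tab-separated exports importable by Gephi or Cytoscape.
#'
#' @param network A `CooccurrenceNetwork`.
#' @param edge_path,node_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_network <- function(network, edge_path, node_path) {
  write.table(network$edges, edge_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(network$nodes, node_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(edge_path, node_path))
}

# Run a plotting closure; warn instead of failing when no graphics
# backend is usable (images are an optional output).
.try_plot <- function(path, fun) {
  ok <- tryCatch(fun(), error = function(e) {
    .log_warn("could not render %s: %s", basename(path),
              conditionMessage(e))
    FALSE
  })
  invisible(isTRUE(ok))
}
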