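#' Configure a synthetic pooled screen simulation
#'
#' Assembles and validates the parameters of the synthetic screen generator.
#' The defaults emulate an in vivo pooled fate screen in embryonic tissue:
#' 14 fate clusters of uneven size, a 25-gene by 4-guide library plus two
#' scramble controls (102 guides), multi-guide cells with up to 29 guides,
#' low-UMI ambient guide contamination, partial knockdown of the target gene
#' in guide-bearing cells, and optional per-(gene, cluster) fate-shift
#' effects that tilt cluster membership of perturbed cells.
#'
#' @param n_cells Number of cells to simulate.
#' @param n_clusters Number of fate clusters.
#' @param cluster_proportions Baseline cluster probabilities (sum to 1).
#'   Default: uneven proportions proportional to `(n_clusters:1)^0.7`.
#' @param n_target_genes,guides_per_gene,n_scramble Guide library design.
#' @param guides_per_cell List with elements `mean` (rate of the
#'   zero-truncated Poisson guide-uptake component), `max` (cap on guides per
#'   cell) and `zero_prob` (fraction of cells receiving no guide, i.e. not
#'   electroporated or with no captured guide).
#' @param ambient_rate Expected number of ambient (spurious) guide
#'   assignments per cell.
#' @param true_guide_umi_mean,ambient_umi_mean Poisson means (truncated at
#'   >= 1) for capture UMI counts of true and ambient assignments. The
#'   ambient mean must be well below the true mean.
#' @param knockdown_fraction Multiplier in `[0, 1]` applied to the target
#'   gene's expected expression in cells bearing one of its guides. Either a
#'   scalar or a vector named by target gene. `1` means no knockdown (null
#'   screen).
#' @param fate_effect `NULL`, or a data frame with columns `gene`, `cluster`
#'   (integer index) and `factor` (multiplicative tilt, >= 0) applied to the
#'   cluster probability of cells bearing a guide for `gene`, followed by
#'   renormalization.
#' @param n_background_genes Non-target genes added to the expression matrix.
#' @param baseline_expression Optional genes x clusters matrix of negative
#'   binomial means. Default: per-gene lognormal baselines with mild
#'   cluster-specific modulation.
#' @param dispersion Negative binomial dispersion (`size = 1/dispersion`).
#' @param seed Integer seed; identical seeds give identical datasets.
#'
#' @return A validated list of class `SimulationConfig`.
#' @seealso [simulate_screen()]
#' @export
simulation_config <- function(n_cells = 6000,
                              n_clusters = 14,
                              cluster_proportions = NULL,
                              n_target_genes = 25,
                              guides_per_gene = 4,
                              n_scramble = 2,
                              guides_per_cell = list(mean = 2, max = 29,
                                                     zero_prob = 0.8),
                              ambient_rate = 0.5,
                              true_guide_umi_mean = 50,
                              ambient_umi_mean = 1,
                              knockdown_fraction = 0.2,
                              fate_effect = NULL,
                              n_background_genes = 25,
                              baseline_expression = NULL,
                              dispersion = 0.5,
                              seed = 1L) {
  if (is.null(cluster_proportions)) {
    w <- (n_clusters:1)^0.7
    cluster_proportions <- w / sum(w)
  }
  cfg <- list(
    n_cells = as.integer(n_cells), n_clusters = as.integer(n_clusters),
    cluster_proportions = cluster_proportions,
    n_target_genes = as.integer(n_target_genes),
    guides_per_gene = as.integer(guides_per_gene),
    n_scramble = as.integer(n_scramble),
    guides_per_cell = guides_per_cell,
    ambient_rate = ambient_rate,
    true_guide_umi_mean = true_guide_umi_mean,
    ambient_umi_mean = ambient_umi_mean,
    knockdown_fraction = knockdown_fraction,
    fate_effect = fate_effect,
    n_background_genes = as.integer(n_background_genes),
    baseline_expression = baseline_expression,
    dispersion = dispersion,
    seed = as.integer(seed)
  )
  class(cfg) <- "SimulationConfig"
  validate_simulation_config(cfg)
}

validate_simulation_config <- function(cfg) {
  p <- cfg$cluster_proportions
  if (length(p) != cfg$n_clusters || any(p < 0) ||
      abs(sum(p) - 1) > 1e-9) {
    stop_input("cluster_proportions must be a length-", cfg$n_clusters,
               " probability vector summing to 1")
  }
  gpc <- cfg$guides_per_cell
  if (!is.list(gpc) || is.null(gpc$mean) || is.null(gpc$max)) {
    stop_input("guides_per_cell must supply mean and max")
  }
  if (is.null(gpc$zero_prob)) gpc$zero_prob <- 0
  if (gpc$mean <= 0 || gpc$max < 1 || gpc$zero_prob < 0 || gpc$zero_prob > 1) {
    stop_input("invalid guides_per_cell distribution spec")
  }
  cfg$guides_per_cell <- gpc
  if (cfg$ambient_rate < 0) stop_input("ambient_rate must be >= 0")
  if (cfg$true_guide_umi_mean <= 0 || cfg$ambient_umi_mean <= 0) {
    stop_input("UMI means must be positive")
  }
  if (cfg$ambient_umi_mean >= cfg$true_guide_umi_mean) {
    stop_input("ambient_umi_mean must be well below true_guide_umi_mean")
  }
  kd <- cfg$knockdown_fraction
  if (any(kd < 0 | kd > 1)) stop_input("knockdown_fraction must be in [0, 1]")
  if (cfg$dispersion <= 0) stop_input("dispersion must be positive")
  fe <- cfg$fate_effect
  if (!is.null(fe)) {
    if (!all(c("gene", "cluster", "factor") %in% names(fe))) {
      stop_input("fate_effect needs columns gene, cluster, factor")
    }
    genes <- sprintf("gene%02d", seq_len(cfg$n_target_genes))
    if (!all(fe$gene %in% genes)) {
      stop_input("fate_effect references unknown gene(s): ",
                 paste(setdiff(fe$gene, genes), collapse = ", "))
    }
    if (!all(fe$cluster %in% seq_len(cfg$n_clusters))) {
      stop_input("fate_effect references unknown cluster(s)")
    }
    if (any(fe$factor < 0)) stop_input("fate_effect factors must be >= 0")
  }
  cfg
}

# Default baseline: per-gene lognormal grand mean, modulated per cluster so
# clusters are distinguishable without being degenerate.
default_baseline <- function(n_genes, n_clusters) {
  base <- exp(stats::rnorm(n_genes, mean = log(5), sd = 0.6))
  mod <- matrix(exp(stats::rnorm(n_genes * n_clusters, 0, 0.3)),
                n_genes, n_clusters)
  base * mod
}

#' Simulate a pooled CRISPR screen with planted ground truth
#'
#' Generates a complete synthetic screen dataset: a genes x cells negative
#' binomial count matrix with cluster structure, a cells x guides capture UMI
#' matrix containing true assignments (high UMI) plus ambient contamination
#' (low UMI), per-cell cluster labels sampled from the baseline proportions
#' tilted by any planted fate effects, and target-gene knockdown in
#' guide-bearing cells. Every planted effect is recorded in the returned
#' ground truth so downstream stages can be scored against it.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `dataset` (class `ScreenDataset`: `counts`
#'   genes x cells sparse matrix, `guide_umis` cells x guides sparse matrix,
#'   `library`, `clusters` named cluster labels, `cell_ids`, `gene_ids`) and
#'   `truth` (class `GroundTruth`: `true_assignments`, `ambient_assignments`,
#'   `planted_fate_effects`, `planted_knockdowns`).
#' @examples
#' sim <- simulate_screen(simulation_config(n_cells = 300, n_clusters = 4,
#'   n_target_genes = 3, n_background_genes = 5, seed = 7))
#' dim(sim$dataset$counts)
#' @export
simulate_screen <- function(config) {
  config <- validate_simulation_config(config)
  with_seed_(config$seed, simulate_screen_impl(config))
}

simulate_screen_impl <- function(cfg) {
  lib <- guide_library(cfg$n_target_genes, cfg$guides_per_gene,
                       cfg$n_scramble)
  n_guides <- nrow(lib)
  genes <- sprintf("gene%02d",
                   seq_len(cfg$n_target_genes + cfg$n_background_genes))
  target_genes <- genes[seq_len(cfg$n_target_genes)]
  cells <- sprintf("cell%05d", seq_len(cfg$n_cells))

  # --- guide uptake -------------------------------------------------------
  gpc <- cfg$guides_per_cell
  has_guide <- stats::runif(cfg$n_cells) >= gpc$zero_prob
  n_per_cell <- integer(cfg$n_cells)
  n_per_cell[has_guide] <- pmin(rztpois(sum(has_guide), gpc$mean),
                                min(gpc$max, n_guides))
  cell_idx <- rep.int(seq_len(cfg$n_cells), n_per_cell)
  guide_idx <- unlist(lapply(n_per_cell[n_per_cell > 0L], function(k) {
    sample.int(n_guides, k)
  }), use.names = FALSE)
  if (is.null(guide_idx)) guide_idx <- integer(0)

  # --- ambient contamination ---------------------------------------------
  p_amb <- min(1, cfg$ambient_rate / n_guides)
  amb <- which(stats::runif(cfg$n_cells * n_guides) < p_amb)
  amb_cell <- ((amb - 1L) %% cfg$n_cells) + 1L
  amb_guide <- ((amb - 1L) %/% cfg$n_cells) + 1L
  # ambient pairs must not duplicate true assignments
  true_key <- paste(cell_idx, guide_idx)
  keep <- !(paste(amb_cell, amb_guide) %in% true_key)
  amb_cell <- amb_cell[keep]; amb_guide <- amb_guide[keep]

  umi_true <- rztpois(length(cell_idx), cfg$true_guide_umi_mean)
  umi_amb <- rztpois(length(amb_cell), cfg$ambient_umi_mean)
  guide_umis <- Matrix::sparseMatrix(
    i = c(cell_idx, amb_cell), j = c(guide_idx, amb_guide),
    x = as.numeric(c(umi_true, umi_amb)),
    dims = c(cfg$n_cells, n_guides),
    dimnames = list(cells, lib$guide_id)
  )

  # --- cluster assignment with fate tilts --------------------------------
  # genes perturbed in each cell (true assignments only)
  kd <- cfg$knockdown_fraction
  if (length(kd) == 1L) kd <- setNames(rep(kd, cfg$n_target_genes), target_genes)
  cell_genes <- split(lib$target_gene[guide_idx], cell_idx)
  cell_genes <- lapply(cell_genes, function(g) unique(g[!is.na(g)]))

  probs <- matrix(cfg$cluster_proportions, cfg$n_cells, cfg$n_clusters,
                  byrow = TRUE)
  fe <- cfg$fate_effect
  if (!is.null(fe) && nrow(fe)) {
    affected <- vapply(cell_genes, function(g) any(g %in% fe$gene),
                       logical(1))
    for (cell_s in names(cell_genes)[affected]) {
      gset <- cell_genes[[cell_s]]
      if (!length(gset)) next
      rows <- fe[fe$gene %in% gset, , drop = FALSE]
      if (!nrow(rows)) next
      ci <- as.integer(cell_s)
      for (r in seq_len(nrow(rows))) {
        probs[ci, rows$cluster[r]] <- probs[ci, rows$cluster[r]] * rows$factor[r]
      }
      probs[ci, ] <- probs[ci, ] / sum(probs[ci, ])
    }
  }
  u <- stats::runif(cfg$n_cells)
  cum <- t(apply(probs, 1, cumsum))
  cluster <- rowSums(u > cum) + 1L
  cluster_labels <- setNames(paste0("C", cluster), cells)

  # --- expression with knockdown -----------------------------------------
  n_genes <- length(genes)
  baseline <- cfg$baseline_expression
  if (is.null(baseline)) baseline <- default_baseline(n_genes, cfg$n_clusters)
  if (!all(dim(baseline) == c(n_genes, cfg$n_clusters))) {
    stop_input("baseline_expression must be ", n_genes, " x ", cfg$n_clusters)
  }
  mu <- baseline[, cluster, drop = FALSE]
  for (cell_s in names(cell_genes)) {
    gset <- cell_genes[[cell_s]]
    if (!length(gset)) next
    gi <- match(gset, genes)
    mu[gi, as.integer(cell_s)] <- mu[gi, as.integer(cell_s)] * kd[gset]
  }
  counts <- matrix(stats::rnbinom(n_genes * cfg$n_cells,
                                  mu = as.vector(mu),
                                  size = 1 / cfg$dispersion),
                   n_genes, cfg$n_cells, dimnames = list(genes, cells))

  dataset <- structure(list(
    counts = as_dgc(Matrix::Matrix(counts, sparse = TRUE)),
    guide_umis = as_dgc(guide_umis),
    library = lib,
    clusters = cluster_labels,
    cell_ids = cells,
    gene_ids = genes
  ), class = "ScreenDataset")

  truth <- structure(list(
    true_assignments = data.frame(
      cell_id = cells[cell_idx], guide_id = lib$guide_id[guide_idx],
      stringsAsFactors = FALSE),
    ambient_assignments = data.frame(
      cell_id = cells[amb_cell], guide_id = lib$guide_id[amb_guide],
      stringsAsFactors = FALSE),
    planted_fate_effects = if (is.null(fe)) {
      data.frame(gene = character(0), cluster = integer(0),
                 factor = numeric(0))
    } else fe,
    planted_knockdowns = data.frame(gene = target_genes,
                                    fraction = unname(kd[target_genes]),
                                    stringsAsFactors = FALSE)
  ), class = "GroundTruth")

  list(dataset = dataset, truth = truth)
}

#' @exportS3Method base::print
print.ScreenDataset <- function(x, ...) {
  cat("ScreenDataset:", ncol(x$counts), "cells,", nrow(x$counts), "genes,",
      ncol(x$guide_umis), "guides,",
      length(unique(x$clusters)), "clusters\n")
  invisible(x)
}

#' Simulate a per-cell HCR measurement table
#'
#' Emulates the per-cell output of an HCR image quantification pipeline: cell
#' centre coordinates on a 2-D embryo-like domain, a strictly positive DAPI
#' channel, and per-channel "hood" (dilated nuclear neighborhood) averages in
#' which a designated fraction of cells is drawn from a higher-mean signal
#' distribution. Planted positive/negative labels are kept alongside the
#' measurements so threshold-based positivity calls can be scored.
#'
#' @param n_cells Number of cells.
#' @param channel_means Named positive numeric vector: mean DAPI-normalized
#'   signal of the positive population per channel.
#' @param positive_fraction Probability, per channel (recycled), that a cell
#'   belongs to the positive population. `0` gives a unimodal null channel.
#' @param negative_level Mean of the negative population relative to
#'   `channel_means` (default 0.3).
#' @param noise_sd Within-population SD relative to `channel_means`.
#' @param seed Integer seed.
#' @return A data frame of class `CellMeasurementTable` with columns
#'   `cell_id`, `x`, `y`, `dapi`, one `<channel>_hood` column per channel
#'   (and matching `<channel>_nuclear`, `<channel>_cyto` columns), plus
#'   logical `<channel>_true_positive` ground-truth columns.
#' @examples
#' tab <- simulate_hcr_table(100, c(TBXT = 0.8, SOX2 = 0.6),
#'                           positive_fraction = 0.3, seed = 1)
#' head(tab)
#' @export
simulate_hcr_table <- function(n_cells, channel_means,
                               positive_fraction = 0.3,
                               negative_level = 0.3,
                               noise_sd = 0.08,
                               seed = 1L) {
  if (any(channel_means <= 0)) stop_input("channel means must be positive")
  if (is.null(names(channel_means))) {
    names(channel_means) <- paste0("ch", seq_along(channel_means))
  }
  positive_fraction <- rep_len(positive_fraction, length(channel_means))
  if (any(positive_fraction < 0 | positive_fraction > 1)) {
    stop_input("positive_fraction must be in [0, 1]")
  }
  with_seed_(seed, {
    tab <- data.frame(
      cell_id = sprintf("cell%05d", seq_len(n_cells)),
      x = stats::runif(n_cells, 0, 500),
      y = stats::runif(n_cells, 0, 1000),
      dapi = exp(stats::rnorm(n_cells, mean = 0, sd = 0.2)),
      stringsAsFactors = FALSE
    )
    for (k in seq_along(channel_means)) {
      ch <- names(channel_means)[k]
      m <- channel_means[k]
      pos <- stats::runif(n_cells) < positive_fraction[k]
      level <- ifelse(pos, m, m * negative_level)
      norm_val <- pmax(stats::rnorm(n_cells, level, m * noise_sd), 0)
      tab[[paste0(ch, "_hood")]] <- norm_val * tab$dapi
      tab[[paste0(ch, "_nuclear")]] <- norm_val * tab$dapi * 0.9
      tab[[paste0(ch, "_cyto")]] <- norm_val * tab$dapi * 0.4
      tab[[paste0(ch, "_true_positive")]] <- pos
    }
    class(tab) <- c("CellMeasurementTable", "data.frame")
    tab
  })
}
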