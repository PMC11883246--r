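#' Cells required per guide for a detectable fate shift
#'
#' Two-sample difference-of-means sample size: the number of cells that must
#' receive each guide so that a difference of `delta` cells in guide
#' detection is detectable at significance `alpha` with the target power,
#' given the per-gene SD of guide detection and the average SD across
#' target genes:
#' \deqn{n = (Z_{1-\alpha/2} + Z_{power})^2 (\sigma^2 + \sigma_{AVG}^2) /
#'   \Delta^2}
#'
#' @param alpha Two-sided significance level (default 0.05).
#' @param power Target power (default 0.8).
#' @param delta Difference in guide-detection cells to detect (must be > 0).
#' @param sigma Per-gene SD of guide detection.
#' @param sigma_avg Average SD of guide detection across target genes.
#' @return List of class `PowerDesign`: inputs, the standard-normal
#'   quantiles `z_alpha` and `z_power`, `n_per_guide` (real) and
#'   `n_rounded` (nearest integer).
#' @examples
#' cells_per_guide(delta = 50, sigma = 100, sigma_avg = 100)$n_per_guide
#' @export
cells_per_guide <- function(alpha = 0.05, power = 0.8, delta, sigma,
                            sigma_avg) {
  if (alpha <= 0 || alpha >= 1) stop_input("alpha must be in (0, 1)")
  if (power <= 0 || power >= 1) stop_input("power must be in (0, 1)")
  if (delta <= 0) stop_input("delta must be > 0 (n undefined at delta = 0)")
  if (sigma < 0 || sigma_avg < 0) stop_input("SDs must be >= 0")
  z_alpha <- stats::qnorm(1 - alpha / 2)
  z_power <- stats::qnorm(power)
  n <- (z_alpha + z_power)^2 * (sigma^2 + sigma_avg^2) / delta^2
  structure(list(alpha = alpha, power = power, delta = delta,
                 sigma = sigma, sigma_avg = sigma_avg,
                 z_alpha = z_alpha, z_power = z_power,
                 n_per_guide = n, n_rounded = round(n)),
            class = "PowerDesign")
}

#' Number of guides that can be electroporated into one embryo
#'
#' Given the number of cells in the targeted tissue, the expected
#' electroporation efficacy, and the cells required per guide, the guide
#' capacity is `floor(tissue_cells * efficacy / cells_per_guide)` (a
#' fractional guide cannot be electroporated).
#'
#' @param tissue_cells Cells in the target tissue (> 0).
#' @param efficacy Electroporation efficacy in (0, 1].
#' @param cells_per_guide Cells required per guide (> 0), e.g. the rounded
#'   output of [cells_per_guide()].
#' @return Integer maximum number of guides.
#' @examples
#' guide_capacity(6000, 0.8, 240)  # 20
#' guide_capacity(9000, 0.8, 240)  # 30
#' @export
guide_capacity <- function(tissue_cells, efficacy, cells_per_guide) {
  if (tissue_cells <= 0) stop_input("tissue_cells must be > 0")
  if (efficacy <= 0 || efficacy > 1) stop_input("efficacy must be in (0, 1]")
  if (cells_per_guide <= 0) stop_input("cells_per_guide must be > 0")
  as.integer(floor(tissue_cells * efficacy / cells_per_guide))
}

#' Per-gene guide-detection SDs from a screen dataset
#'
#' Helper for plugging pilot data into [cells_per_guide()]: for each target
#' gene, the SD across its guides of the number of cells in which each guide
#' was detected, plus the average SD across genes.
#'
#' @param assignments A `GuideAssignmentSet`.
#' @param library A `GuideLibrary`.
#' @return List: `per_gene` (named SDs), `sigma_avg`.
#' @export
guide_detection_sd <- function(assignments, library) {
  a <- assignments$assignments
  counts <- table(factor(a$guide_id, levels = library$guide_id))
  targeting <- library[!library$scramble, , drop = FALSE]
  per_gene <- vapply(split(targeting$guide_id, targeting$target_gene),
                     function(g) stats::sd(as.integer(counts[g])),
                     numeric(1))
  list(per_gene = per_gene, sigma_avg = mean(per_gene, na.rm = TRUE))
}
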