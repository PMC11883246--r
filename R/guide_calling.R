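#' Filter ambient guide capture by the log10-UMI 2 SD rule
#'
#' Guide capture in droplet data contains spurious low-UMI "ambient"
#' assignments in cells that never received the guide. For each guide, over
#' the cells with at least one UMI, the mean `m` and sample SD `s` of
#' `log10(UMI)` are computed and an assignment is retained iff
#' `log10(UMI) >= m - sd_multiplier * s`; everything below is discarded as
#' ambient amplification. With `pooled = TRUE` a single mean/SD is computed
#' over all nonzero entries of the matrix instead of per guide.
#'
#' Guides with no nonzero cell have an undefined threshold and are flagged
#' `undetected` (guide dropout), with no error. Note that re-filtering an
#' already filtered matrix recomputes the thresholds on the retained counts
#' and may therefore discard additional assignments; the rule is a
#' single-pass contract.
#'
#' @param umi_matrix Cells x guides matrix of nonnegative integer UMI counts
#'   (dense or sparse), with dimnames.
#' @param library A `GuideLibrary` matching the matrix columns.
#' @param sd_multiplier Number of SDs below the mean to cut at (default 2).
#' @param pooled Compute the log10-UMI statistics pooled over all guides
#'   rather than per guide.
#' @return A list of class `GuideAssignmentSet`: `assignments` and
#'   `discarded` data frames (`cell_id`, `guide_id`, `umi`), and `thresholds`
#'   (per guide: `n_cells`, `mean_log10`, `sd_log10`, `threshold`,
#'   `undetected`). The full cell universe is kept in attribute `cells`.
#' @examples
#' lib <- guide_library(1, guides_per_gene = 1, n_scramble = 1)
#' m <- matrix(c(1, rep(100, 9), rep(2, 10)), ncol = 2,
#'             dimnames = list(sprintf("c%02d", 1:10), lib$guide_id))
#' aset <- filter_ambient(m, lib)
#' aset$discarded     # the single 1-UMI ambient assignment
#' @export
filter_ambient <- function(umi_matrix, library, sd_multiplier = 2,
                           pooled = FALSE) {
  if (sd_multiplier < 0) stop_input("sd_multiplier must be >= 0")
  if (ncol(umi_matrix) != nrow(library) ||
      !identical(colnames(umi_matrix), library$guide_id)) {
    stop_input("umi_matrix columns must match the guide library")
  }
  if (is.null(rownames(umi_matrix))) stop_input("umi_matrix needs cell ids")
  if (any(umi_matrix < 0)) stop_input("negative UMI counts")

  m <- as_dgc(Matrix::Matrix(umi_matrix, sparse = TRUE))
  sm <- Matrix::summary(m)
  sm <- sm[sm$x > 0, , drop = FALSE]
  lg <- log10(sm$x)
  gid <- colnames(umi_matrix)

  if (pooled) {
    mu <- rep(mean(lg), length(gid))
    s <- rep(stats::sd(lg), length(gid))
    n <- rep(length(lg), length(gid))
    detected <- tabulate(sm$j, nbins = length(gid)) > 0
    n[!detected] <- 0L
  } else {
    jf <- factor(sm$j, levels = seq_along(gid))
    n <- as.integer(table(jf))
    mu <- tapply(lg, jf, mean)
    s <- tapply(lg, jf, stats::sd)
    mu <- as.numeric(mu); s <- as.numeric(s)
    detected <- n > 0
  }
  s[n == 1] <- 0  # single observation: zero spread, retained
  thr <- mu - sd_multiplier * s
  thr[!detected] <- NA_real_

  keep <- detected[sm$j] & lg >= thr[sm$j]
  mk <- function(idx) data.frame(
    cell_id = rownames(umi_matrix)[sm$i[idx]],
    guide_id = gid[sm$j[idx]],
    umi = sm$x[idx],
    stringsAsFactors = FALSE
  )
  res <- structure(list(
    assignments = mk(which(keep)),
    discarded = mk(which(!keep)),
    thresholds = data.frame(
      guide_id = gid, n_cells = n, mean_log10 = mu, sd_log10 = s,
      threshold = thr, undetected = !detected, stringsAsFactors = FALSE)
  ), class = "GuideAssignmentSet")
  attr(res, "cells") <- rownames(umi_matrix)
  res
}

#' Number of distinct retained guides per cell
#'
#' @param assignments A `GuideAssignmentSet` from [filter_ambient()].
#' @param cell_ids Cell universe; defaults to the cells of the filtered
#'   matrix. Cells without retained guides map to 0.
#' @return Named integer vector, cell -> guide count.
#' @export
guides_per_cell <- function(assignments, cell_ids = attr(assignments, "cells")) {
  a <- assignments$assignments
  tab <- table(factor(a$cell_id, levels = cell_ids))
  setNames(as.integer(tab), cell_ids)
}

#' Cells retained for a given guide
#'
#' @param assignments A `GuideAssignmentSet`.
#' @param guide_id A single guide id present in the filtered matrix.
#' @return Character vector of cell ids (possibly empty).
#' @export
cells_with_guide <- function(assignments, guide_id) {
  known <- assignments$thresholds$guide_id
  if (!guide_id %in% known) stop_input("unknown guide: ", guide_id)
  a <- assignments$assignments
  unique(a$cell_id[a$guide_id == guide_id])
}

# Cells carrying >= 1 retained guide from a set of guide ids.
cells_with_any_guide <- function(assignments, guide_ids) {
  a <- assignments$assignments
  unique(a$cell_id[a$guide_id %in% guide_ids])
}
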