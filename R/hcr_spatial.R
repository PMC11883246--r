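#' DAPI-normalize HCR channel measurements
#'
#' Divides each channel's per-cell hood average (the dilated nuclear
#' neighborhood used as a proxy for transcript detection) by the cell's DAPI
#' signal, correcting per-cell imaging artefacts. The result is invariant to
#' a common rescaling of hood and DAPI.
#'
#' @param table A `CellMeasurementTable` (data frame with a positive `dapi`
#'   column and `<channel>_hood` columns).
#' @param channels Channel names; default: every `*_hood` column.
#' @return Cells x channels matrix of normalized values, rownames from
#'   `cell_id`.
#' @export
normalize_to_dapi <- function(table, channels = NULL) {
  if (is.null(channels)) {
    channels <- sub("_hood$", "", grep("_hood$", names(table), value = TRUE))
  }
  bad <- which(!(table$dapi > 0))
  if (length(bad)) {
    stop_input("nonpositive DAPI for cell(s): ",
               paste(utils::head(table$cell_id[bad], 5), collapse = ", "))
  }
  out <- vapply(channels, function(ch) {
    col <- paste0(ch, "_hood")
    if (is.null(table[[col]])) stop_input("missing channel column: ", col)
    table[[col]] / table$dapi
  }, numeric(nrow(table)))
  out <- matrix(out, nrow = nrow(table),
                dimnames = list(table$cell_id, channels))
  out
}

#' Mean-threshold positivity calls
#'
#' A cell is called positive for a channel when its DAPI-normalized value is
#' strictly larger than the sample mean of that channel's normalized
#' distribution. With all values equal, no cell is positive.
#'
#' @param normalized Cells x channels matrix from [normalize_to_dapi()], or
#'   a numeric vector for a single channel.
#' @return Logical matrix (or vector) of the same shape.
#' @examples
#' call_positive(c(1, 2, 3))  # FALSE FALSE TRUE
#' @export
call_positive <- function(normalized) {
  if (is.null(dim(normalized))) {
    if (length(normalized) < 2) stop_input("need >= 2 cells")
    return(normalized > mean(normalized))
  }
  if (nrow(normalized) < 2) stop_input("need >= 2 cells")
  sweep(normalized, 2, colMeans(normalized), ">")
}

#' Classify TBXT expression level
#'
#' Maps DAPI-normalized TBXT values to the three-level class used to
#' distinguish notochord (high), caudal epiblast / primitive streak
#' (medium), and negative cells: high if strictly `> high_cut`, medium if
#' `> medium_cut` and `<= high_cut`, else negative. A value exactly at the
#' high cutoff is medium.
#'
#' @param values Numeric vector of normalized TBXT.
#' @param high_cut,medium_cut Class boundaries (defaults 0.4 and 0.3).
#' @return Factor with levels `high`, `medium`, `negative`.
#' @examples
#' classify_tbxt(c(0.35, 0.4, 0.41, 0.1))
#' @export
classify_tbxt <- function(values, high_cut = 0.4, medium_cut = 0.3) {
  cls <- ifelse(values > high_cut, "high",
                ifelse(values > medium_cut, "medium", "negative"))
  factor(cls, levels = c("high", "medium", "negative"))
}

#' Co-expression overlap between two positive populations
#'
#' Fraction of the reference population (e.g. a TBXT level class) that is
#' also positive for a second channel, with the co-positive cells returned
#' for mapping back onto the imaged tissue.
#'
#' @param reference_positive Logical vector: membership in the reference
#'   (denominator) population.
#' @param other_positive Logical vector: positivity in the other channel.
#' @param coordinates Optional data frame (same cells) with `x`, `y`
#'   columns for map export.
#' @return List: `fraction` (`|A & B| / |A|`; `NA` with empty reference),
#'   `co_positive` (indices), `coordinates` (subset, if given).
#' @export
coexpression_overlap <- function(reference_positive, other_positive,
                                 coordinates = NULL) {
  if (length(reference_positive) != length(other_positive)) {
    stop_input("call vectors differ in length")
  }
  n_ref <- sum(reference_positive)
  co <- which(reference_positive & other_positive)
  frac <- if (n_ref == 0) NA_real_ else length(co) / n_ref
  out <- list(fraction = frac, co_positive = co)
  if (!is.null(coordinates)) out$coordinates <- coordinates[co, , drop = FALSE]
  out
}

#' Hierarchical clustering of per-cell channel profiles
#'
#' Average-linkage Euclidean hierarchical clustering of the cells x channels
#' normalized matrix, producing the dendrogram ordering and flat groups at a
#' configurable height cut. Ordering is deterministic: input rows are first
#' sorted by cell id so ties merge identically regardless of input order.
#'
#' @param normalized Cells x channels numeric matrix with rownames.
#' @param cut_height Height of the flat cut (default: half the maximum
#'   merge height).
#' @return List: `hclust` (the fitted tree), `order` (cell ids in dendrogram
#'   order), `groups` (named integer vector of flat groups).
#' @export
cluster_profiles <- function(normalized, cut_height = NULL) {
  if (nrow(normalized) < 2) stop_input("need >= 2 cells")
  if (is.null(rownames(normalized))) {
    rownames(normalized) <- sprintf("cell%05d", seq_len(nrow(normalized)))
  }
  normalized <- normalized[order(rownames(normalized)), , drop = FALSE]
  hc <- stats::hclust(stats::dist(normalized), method = "average")
  if (is.null(cut_height)) cut_height <- max(hc$height) / 2
  groups <- stats::cutree(hc, h = cut_height)
  list(hclust = hc, order = rownames(normalized)[hc$order], groups = groups)
}

#' Tortuosity of a binary region mask
#'
#' Perimeter divided by area of the foreground region: area is the
#' foreground pixel count and the perimeter is the number of foreground
#' pixel edges adjacent to background or to the grid boundary
#' (4-connectivity edge count). A solid k x k square has tortuosity `4/k`;
#' sinuous boundaries of equal area score higher.
#'
#' @param mask Logical (or 0/1) matrix; must contain foreground.
#' @return Perimeter / area.
#' @examples
#' mask_tortuosity(matrix(TRUE, 10, 10))  # 0.4
#' @export
mask_tortuosity <- function(mask) {
  m <- (as.matrix(mask) != 0)
  if (!any(m)) stop_input("empty mask")
  pad <- matrix(FALSE, nrow(m) + 2, ncol(m) + 2)
  pad[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  core <- pad[2:(nrow(m) + 1), 2:(ncol(m) + 1), drop = FALSE]
  up    <- pad[1:nrow(m),       2:(ncol(m) + 1), drop = FALSE]
  down  <- pad[3:(nrow(m) + 2), 2:(ncol(m) + 1), drop = FALSE]
  left  <- pad[2:(nrow(m) + 1), 1:ncol(m),       drop = FALSE]
  right <- pad[2:(nrow(m) + 1), 3:(ncol(m) + 2), drop = FALSE]
  perimeter <- sum(core & !up) + sum(core & !down) +
    sum(core & !left) + sum(core & !right)
  perimeter / sum(m)
}

#' Fraction of positive cells within a region mask
#'
#' Proportion of cells inside a masked region (e.g. the neural tube) that
#' are positive for a channel.
#'
#' @param positive Logical vector of positivity calls.
#' @param in_mask Logical vector of mask membership (same cells); must
#'   include at least one cell.
#' @return Positives within the mask / cells within the mask.
#' @export
positive_fraction_in_mask <- function(positive, in_mask) {
  if (length(positive) != length(in_mask)) {
    stop_input("call and mask vectors differ in length")
  }
  if (!any(in_mask)) stop_input("no cells within the mask")
  sum(positive & in_mask) / sum(in_mask)
}
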