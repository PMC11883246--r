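#' Library-size normalize and log-transform a count matrix
#'
#' Scales each cell to a common total count and applies `log1p`, the
#' standard preprocessing ahead of fold-change comparisons. Cells with zero
#' total count are left as all-zero columns with a warning.
#'
#' @param counts Genes x cells matrix of nonnegative counts (dense or
#'   sparse; cells in columns).
#' @param scale Common per-cell total after scaling (default 10000).
#' @return A genes x cells matrix of `log1p`-normalized expression.
#' @export
normalize_expression <- function(counts, scale = 1e4) {
  if (any(counts < 0)) stop_input("counts must be nonnegative")
  tot <- Matrix::colSums(counts)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " cell(s) with zero total count left all-zero")
  }
  sf <- ifelse(tot > 0, scale / tot, 0)
  norm <- counts %*% Matrix::Diagonal(x = sf)
  dimnames(norm) <- dimnames(counts)
  log1p(norm)
}

#' Two-sided rank-sum test with exact small-sample null
#'
#' Wilcoxon rank-sum comparison of two samples. When the smaller group has
#' at most 8 observations (and the enumeration is tractable) the null is
#' computed exactly by enumerating all assignments of the pooled midranks to
#' the two groups, which handles ties exactly; otherwise the tie-corrected
#' normal approximation of [stats::wilcox.test()] is used.
#'
#' @param x,y Numeric samples.
#' @param max_combos Enumeration cap on `choose(n, n_x)` (default 20000).
#' @return Two-sided p-value.
#' @examples
#' rank_sum_test(c(0, 0, 0, 0), c(5, 6, 7, 8))  # 2/70
#' @export
rank_sum_test <- function(x, y, max_combos = 20000) {
  n1 <- length(x)
  n <- n1 + length(y)
  if (min(n1, length(y)) <= 8 && choose(n, n1) <= max_combos) {
    r <- rank(c(x, y))
    W <- sum(r[seq_len(n1)])
    E <- n1 * mean(r)
    combos <- utils::combn(n, n1)
    Wnull <- colSums(matrix(r[combos], nrow = n1))
    mean(abs(Wnull - E) >= abs(W - E) - 1e-9)
  } else {
    suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
  }
}

# Rank-sum p plus the pseudocounted log2 FC of group means on the
# de-logged scale.
guide_de_test <- function(x_guide, x_comp) {
  list(p_value = rank_sum_test(x_guide, x_comp),
       log_fold_change = log2((mean(expm1(x_guide)) + 1) /
                                (mean(expm1(x_comp)) + 1)))
}

#' Test whether one guide knocked down its target gene
#'
#' Compares the normalized expression of a guide's target gene between the
#' cells that received the guide and a comparator population, by a two-sided
#' Wilcoxon rank-sum test, together with the log2 fold change of group means
#' (pseudocount 1 on the de-logged scale). A guide is a knockdown candidate
#' when expression is reduced (negative fold change) at an acceptable FDR;
#' the FDR adjustment across all guides of a run is applied by
#' [qc_guides()].
#'
#' @param dataset A `ScreenDataset` (its `counts` are normalized internally
#'   unless `normalized` is supplied).
#' @param assignments A `GuideAssignmentSet`.
#' @param guide_id A targeting guide id.
#' @param comparator `"scramble"` (cells bearing a scramble guide, the
#'   default) or `"guide_free"` (cells without any guide targeting the
#'   gene under test). Cells bearing both the tested gene's guide and a
#'   scramble count in the guide group only.
#' @param min_cells Minimum group size; below it the result is
#'   indeterminate (`successful = NA`), not an error.
#' @param normalized Optional precomputed [normalize_expression()] matrix.
#' @return A one-row data frame (`guide_id`, `target_gene`,
#'   `log_fold_change`, `p_value`, `fdr_q`, `n_guide_cells`,
#'   `n_comparator_cells`, `successful`). `fdr_q` equals `p_value` for a
#'   single test.
#' @export
test_guide_success <- function(dataset, assignments, guide_id,
                               comparator = c("scramble", "guide_free"),
                               min_cells = 3, normalized = NULL) {
  comparator <- match.arg(comparator)
  lib <- dataset$library
  row <- lib[lib$guide_id == guide_id, , drop = FALSE]
  if (!nrow(row)) stop_input("unknown guide: ", guide_id)
  if (row$scramble) stop_input("scramble guides have no target")
  gene <- row$target_gene
  if (!gene %in% dataset$gene_ids) {
    stop_input("target gene ", gene, " absent from expression matrix")
  }
  if (is.null(normalized)) normalized <- normalize_expression(dataset$counts)

  guide_cells <- cells_with_guide(assignments, guide_id)
  gene_guides <- guides_for_gene(lib, gene)
  comp_cells <- if (comparator == "scramble") {
    setdiff(cells_with_any_guide(assignments, scramble_ids(lib)),
            cells_with_any_guide(assignments, gene_guides))
  } else {
    setdiff(dataset$cell_ids, cells_with_any_guide(assignments, gene_guides))
  }
  out <- data.frame(
    guide_id = guide_id, target_gene = gene,
    log_fold_change = NA_real_, p_value = NA_real_, fdr_q = NA_real_,
    n_guide_cells = length(guide_cells),
    n_comparator_cells = length(comp_cells),
    successful = NA, stringsAsFactors = FALSE
  )
  if (length(guide_cells) < min_cells || length(comp_cells) < min_cells) {
    return(out)  # indeterminate
  }
  de <- guide_de_test(as.numeric(normalized[gene, guide_cells]),
                      as.numeric(normalized[gene, comp_cells]))
  out$log_fold_change <- de$log_fold_change
  out$p_value <- de$p_value
  out$fdr_q <- de$p_value
  out
}

#' Knockdown QC of every targeting guide in a screen
#'
#' Runs [test_guide_success()] for each targeting guide, applies
#' Benjamini-Hochberg adjustment across all testable guides of the run, and
#' calls a guide "successful" when its target expression is reduced
#' (`log_fold_change < 0`) at `fdr_q < fdr_threshold`.
#'
#' @inheritParams test_guide_success
#' @param fdr_threshold FDR level for the success call (default 0.05).
#' @return Data frame with one row per targeting guide; `successful` is
#'   `NA` for indeterminate guides (group below `min_cells`).
#' @export
qc_guides <- function(dataset, assignments,
                      comparator = c("scramble", "guide_free"),
                      fdr_threshold = 0.05, min_cells = 3) {
  comparator <- match.arg(comparator)
  lib <- dataset$library
  normalized <- normalize_expression(dataset$counts)
  recs <- lapply(lib$guide_id[!lib$scramble], function(g) {
    test_guide_success(dataset, assignments, g, comparator = comparator,
                       min_cells = min_cells, normalized = normalized)
  })
  res <- do.call(rbind, recs)
  res$fdr_q <- bh_adjust(res$p_value)
  res$successful <- ifelse(is.na(res$p_value), NA,
                           res$log_fold_change < 0 &
                             res$fdr_q < fdr_threshold)
  res
}

#' Summarize guide success per target gene
#'
#' Counts successful / failed / indeterminate guides per target gene and
#' flags genes with no successful guide for exclusion from downstream
#' enrichment analysis.
#'
#' @param records Data frame of guide QC records from [qc_guides()].
#' @return Data frame with one row per target gene: `n_guides`,
#'   `n_successful`, `n_failed`, `n_indeterminate`, `excluded`.
#' @export
summarize_success <- function(records) {
  if (!nrow(records)) {
    return(data.frame(target_gene = character(0), n_guides = integer(0),
                      n_successful = integer(0), n_failed = integer(0),
                      n_indeterminate = integer(0), excluded = logical(0)))
  }
  by_gene <- split(records, records$target_gene)
  out <- do.call(rbind, lapply(by_gene, function(d) {
    data.frame(
      target_gene = d$target_gene[1],
      n_guides = nrow(d),
      n_successful = sum(d$successful %in% TRUE),
      n_failed = sum(d$successful %in% FALSE),
      n_indeterminate = sum(is.na(d$successful)),
      stringsAsFactors = FALSE
    )
  }))
  out$excluded <- out$n_successful == 0
  rownames(out) <- NULL
  out
}
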