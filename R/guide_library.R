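#' Construct a CRISPR guide library table
#'
#' Builds the guide library data frame used throughout the pipeline: one row
#' per guide, mapping guide ids to target genes, with non-targeting scramble
#' controls flagged. The default layout mirrors a pooled fate screen design
#' with several guides per target gene plus a small number of scramble
#' controls whose cluster distribution defines the null expectation for
#' enrichment analysis.
#'
#' @param target_genes Character vector of target gene symbols, or a single
#'   count (genes are then named `gene01`, `gene02`, ...).
#' @param guides_per_gene Number of guides designed against each target gene.
#' @param n_scramble Number of non-targeting scramble control guides.
#'
#' @return A data frame of class `GuideLibrary` with columns `guide_id`,
#'   `target_gene` (`NA` for scrambles) and `scramble` (logical).
#' @examples
#' lib <- guide_library(25, guides_per_gene = 4, n_scramble = 2)
#' nrow(lib)            # 102 guides
#' sum(!lib$scramble)   # 100 targeting
#' @export
guide_library <- function(target_genes, guides_per_gene = 4, n_scramble = 2) {
  if (is.numeric(target_genes) && length(target_genes) == 1L) {
    target_genes <- sprintf("gene%02d", seq_len(target_genes))
  }
  target_genes <- as.character(target_genes)
  if (anyDuplicated(target_genes)) stop_input("duplicate target genes")
  if (guides_per_gene < 1) stop_input("guides_per_gene must be >= 1")
  if (n_scramble < 1) {
    stop_input("at least one scramble guide is required by downstream comparisons")
  }
  gid <- c(
    unlist(lapply(target_genes, function(g) {
      paste0(g, "_g", seq_len(guides_per_gene))
    })),
    paste0("scramble_", seq_len(n_scramble))
  )
  lib <- data.frame(
    guide_id = gid,
    target_gene = c(rep(target_genes, each = guides_per_gene),
                    rep(NA_character_, n_scramble)),
    scramble = c(rep(FALSE, length(target_genes) * guides_per_gene),
                 rep(TRUE, n_scramble)),
    stringsAsFactors = FALSE
  )
  validate_guide_library(lib)
}

#' Validate a guide library table
#'
#' Checks the `GuideLibrary` invariants: unique guide ids, scramble guides
#' (and only scramble guides) without a target gene, and at least one
#' scramble control.
#'
#' @param lib A data frame with columns `guide_id`, `target_gene`, `scramble`.
#' @return The validated library, classed `GuideLibrary`.
#' @export
validate_guide_library <- function(lib) {
  req <- c("guide_id", "target_gene", "scramble")
  if (!all(req %in% names(lib))) {
    stop_input("guide library needs columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(lib$guide_id)) stop_input("guide_id values must be unique")
  if (any(lib$scramble != is.na(lib$target_gene))) {
    stop_input("scramble flag must match absence of a target gene")
  }
  if (!any(lib$scramble)) stop_input("library must contain a scramble guide")
  class(lib) <- c("GuideLibrary", "data.frame")
  lib
}

scramble_ids <- function(lib) lib$guide_id[lib$scramble]

guides_for_gene <- function(lib, gene) {
  lib$guide_id[!lib$scramble & lib$target_gene == gene]
}
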