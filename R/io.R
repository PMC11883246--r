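#' Write a screen dataset to a directory of standard files
#'
#' Exports the dataset in the layout produced by droplet scRNA-seq pipelines
#' with feature barcoding: `matrix.mtx` (genes x cells counts),
#' `guide_umis.mtx` (cells x guides capture UMIs), `barcodes.tsv`,
#' `features.tsv`, `guides.csv` (the guide library) and `clusters.csv`.
#' If ground truth is supplied it is written as `ground_truth.json`.
#'
#' @param dataset A `ScreenDataset`.
#' @param dir Output directory (created if needed).
#' @param truth Optional `GroundTruth` to serialize alongside.
#' @return `dir`, invisibly.
#' @seealso [read_screen_dataset()]
#' @export
write_screen_dataset <- function(dataset, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(dataset$counts, file.path(dir, "matrix.mtx"))
  Matrix::writeMM(dataset$guide_umis, file.path(dir, "guide_umis.mtx"))
  writeLines(dataset$cell_ids, file.path(dir, "barcodes.tsv"))
  writeLines(dataset$gene_ids, file.path(dir, "features.tsv"))
  write.csv(as.data.frame(dataset$library), file.path(dir, "guides.csv"),
            row.names = FALSE)
  write.csv(data.frame(cell_id = names(dataset$clusters),
                       cluster = unname(dataset$clusters)),
            file.path(dir, "clusters.csv"), row.names = FALSE)
  if (!is.null(truth)) {
    jsonlite::write_json(unclass(truth), file.path(dir, "ground_truth.json"),
                         dataframe = "columns", auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a screen dataset written by [write_screen_dataset()]
#'
#' @param dir Directory containing `matrix.mtx`, `guide_umis.mtx`,
#'   `barcodes.tsv`, `features.tsv`, `guides.csv` and `clusters.csv`.
#' @return A `ScreenDataset`.
#' @export
read_screen_dataset <- function(dir) {
  counts <- as_dgc(Matrix::readMM(file.path(dir, "matrix.mtx")))
  guide_umis <- as_dgc(Matrix::readMM(file.path(dir, "guide_umis.mtx")))
  cells <- readLines(file.path(dir, "barcodes.tsv"))
  genes <- readLines(file.path(dir, "features.tsv"))
  lib <- validate_guide_library(
    read.csv(file.path(dir, "guides.csv"), stringsAsFactors = FALSE))
  cl <- read.csv(file.path(dir, "clusters.csv"), stringsAsFactors = FALSE)
  dimnames(counts) <- list(genes, cells)
  dimnames(guide_umis) <- list(cells, lib$guide_id)
  structure(list(
    counts = counts, guide_umis = guide_umis, library = lib,
    clusters = setNames(cl$cluster, cl$cell_id)[cells],
    cell_ids = cells, gene_ids = genes
  ), class = "ScreenDataset")
}

#' Read a cells x guides capture UMI table in long CSV format
#'
#' Converts a long-format table with columns `cell_id`, `guide_id`, `umi`
#' into the sparse cells x guides matrix consumed by [filter_ambient()].
#'
#' @param path CSV file path.
#' @param library A `GuideLibrary` naming the guide columns.
#' @param cell_ids Optional full cell universe (cells with no guide capture
#'   are kept as all-zero rows).
#' @return A sparse cells x guides matrix.
#' @export
read_guide_umis_csv <- function(path, library, cell_ids = NULL) {
  long <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("cell_id", "guide_id", "umi")
  if (!all(req %in% names(long))) {
    stop_input("long-format guide table needs columns: ",
               paste(req, collapse = ", "))
  }
  if (!all(long$guide_id %in% library$guide_id)) {
    stop_input("guide ids not present in library: ",
               paste(unique(setdiff(long$guide_id, library$guide_id)),
                     collapse = ", "))
  }
  if (is.null(cell_ids)) cell_ids <- sort(unique(long$cell_id))
  Matrix::sparseMatrix(
    i = match(long$cell_id, cell_ids),
    j = match(long$guide_id, library$guide_id),
    x = as.numeric(long$umi),
    dims = c(length(cell_ids), nrow(library)),
    dimnames = list(cell_ids, library$guide_id)
  )
}

#' Read a GMT gene-set annotation file
#'
#' Thin wrapper over `fgsea::gmtPathways()` returning a named list of gene
#' sets, the annotation format consumed by [fisher_ora()].
#'
#' @param path GMT file path.
#' @return Named list: term -> character vector of genes.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write a named list of gene sets as a GMT file
#'
#' @param sets Named list: term -> character vector of genes.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
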