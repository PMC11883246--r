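#' Center and scale expression per gene
#'
#' Standardizes each gene (row) to zero mean and unit variance across cells,
#' the preprocessing assumed by the regression-based perturbation scoring.
#' Genes with zero variance become all-zero rows.
#'
#' @param normalized Genes x cells matrix of normalized expression (e.g.
#'   from [normalize_expression()]).
#' @return A dense genes x cells matrix of scaled expression.
#' @export
scale_expression <- function(normalized) {
  m <- as.matrix(normalized)
  mu <- rowMeans(m)
  s <- apply(m, 1, stats::sd)
  s[s == 0] <- Inf  # constant genes -> all-zero rows
  out <- (m - mu) / s
  dimnames(out) <- dimnames(m)
  out
}

# Build the cells x [intercept | targeting-guide indicators] design matrix.
# Scramble-only cells are the all-zero reference rows.
guide_design_matrix <- function(assignments, library, cells) {
  targeting <- library$guide_id[!library$scramble]
  X <- matrix(0, length(cells), length(targeting),
              dimnames = list(cells, targeting))
  a <- assignments$assignments
  a <- a[a$cell_id %in% cells & a$guide_id %in% targeting, , drop = FALSE]
  X[cbind(match(a$cell_id, cells), match(a$guide_id, targeting))] <- 1
  cbind(`(Intercept)` = 1, X)
}

#' Regularized-regression perturbation scores with permutation p-values
#'
#' Scores transcriptome-wide expression changes for every targeting guide by
#' ridge-penalized least squares: scaled expression of each feature is
#' regressed on an intercept plus one indicator column per targeting guide,
#' with scramble-bearing cells as the all-zero reference. Cells carrying
#' several guides contribute to each of their guide columns. The coefficient
#' of a guide indicator (the "lr score") is its corrected differential
#' expression readout. Significance comes from permuting the cell-to-guide
#' labels: `p = (1 + #{|coef_perm| >= |coef_obs|}) / (n_permutations + 1)`,
#' with BH adjustment across features within each guide. Features with
#' permutation `p < 0.05` form the guide's misregulated gene set.
#'
#' @param expression Scaled features x cells matrix ([scale_expression()]),
#'   already restricted to the feature list of interest.
#' @param assignments A `GuideAssignmentSet`.
#' @param library A `GuideLibrary`.
#' @param feature_list Optional character vector restricting the feature
#'   universe; unknown features are dropped with a warning.
#' @param ridge_penalty Nonnegative ridge penalty on the guide columns
#'   (intercept unpenalized). Zero requires a nonsingular design.
#' @param n_permutations Permutation replicates (default 999).
#' @param seed Integer seed.
#' @return A list of class `PerturbationSignature`: `lr_score`, `p`,
#'   `fdr_q` (guides x features matrices), `misregulated` (named list of
#'   feature sets), `feature_list`, `cells` (cells used in the fit).
#' @export
lr_scores <- function(expression, assignments, library, feature_list = NULL,
                      ridge_penalty = 0.1, n_permutations = 999, seed = 1L) {
  if (ridge_penalty < 0) stop_input("ridge_penalty must be >= 0")
  if (!is.null(feature_list)) {
    unknown <- setdiff(feature_list, rownames(expression))
    if (length(unknown)) {
      warning(length(unknown), " feature(s) absent from expression, dropped")
    }
    feature_list <- intersect(feature_list, rownames(expression))
    expression <- expression[feature_list, , drop = FALSE]
  } else {
    feature_list <- rownames(expression)
  }
  # cells carrying >= 1 retained guide (targeting or scramble)
  cells <- intersect(colnames(expression),
                     cells_with_any_guide(assignments, library$guide_id))
  if (length(cells) < 2) stop_input("need >= 2 guide- or scramble-bearing cells")
  X <- guide_design_matrix(assignments, library, cells)
  Y <- Matrix::t(expression[, cells, drop = FALSE])  # cells x features
  Y <- as.matrix(Y)
  p_cols <- ncol(X)
  D <- diag(c(0, rep(1, p_cols - 1L)), p_cols)
  A <- crossprod(X) + ridge_penalty * D
  ok <- tryCatch({solve(A); TRUE}, error = function(e) FALSE)
  if (!ok) {
    stop_input("singular design; use a positive ridge_penalty")
  }
  C <- solve(A, t(X))            # p x n projector
  B_obs <- C %*% Y               # p x features
  coef_obs <- B_obs[-1, , drop = FALSE]
  guides <- colnames(X)[-1]

  exceed <- matrix(0L, length(guides), length(feature_list),
                   dimnames = list(guides, feature_list))
  abs_obs <- abs(coef_obs)
  n <- nrow(Y)
  with_seed_(seed, {
    for (b in seq_len(n_permutations)) {
      perm <- sample.int(n)
      B_perm <- C %*% Y[perm, , drop = FALSE]
      exceed <- exceed + (abs(B_perm[-1, , drop = FALSE]) >= abs_obs)
    }
  })
  p_mat <- (1 + exceed) / (n_permutations + 1)
  q_mat <- p_mat
  for (i in seq_len(nrow(q_mat))) q_mat[i, ] <- bh_adjust(p_mat[i, ])
  dimnames(p_mat) <- dimnames(q_mat) <- list(guides, feature_list)
  lr <- coef_obs
  dimnames(lr) <- list(guides, feature_list)
  mis <- lapply(guides, function(g) feature_list[p_mat[g, ] < 0.05])
  names(mis) <- guides
  structure(list(
    lr_score = lr, p = p_mat, fdr_q = q_mat,
    misregulated = mis, feature_list = feature_list, cells = cells
  ), class = "PerturbationSignature")
}

#' Pairwise Jaccard overlap matrix of labeled sets
#'
#' Computes `|A intersect B| / |A union B|` for every pair of sets. The
#' reported number is the overlap fraction (1 for identical nonempty sets,
#' 0 for disjoint ones). Two empty sets have an undefined ratio and are
#' reported as 0 with a warning.
#'
#' @param sets Named list of character vectors.
#' @return A symmetric matrix of class `SetComparisonMatrix` with unit
#'   diagonal for nonempty sets.
#' @examples
#' jaccard_matrix(list(a = c("x", "y", "z"), b = c("y", "z", "w")))
#' @export
jaccard_matrix <- function(sets) {
  sets <- lapply(sets, unique)
  n <- length(sets)
  J <- matrix(0, n, n, dimnames = list(names(sets), names(sets)))
  warned <- FALSE
  for (i in seq_len(n)) {
    for (j in i:n) {
      u <- length(union(sets[[i]], sets[[j]]))
      if (u == 0) {
        if (!warned && i != j) {
          warning("empty-vs-empty set pair(s): Jaccard reported as 0")
          warned <- TRUE
        }
        J[i, j] <- J[j, i] <- 0
      } else {
        J[i, j] <- J[j, i] <-
          length(intersect(sets[[i]], sets[[j]])) / u
      }
    }
  }
  structure(J, class = c("SetComparisonMatrix", class(J)))
}

#' Fisher over-representation analysis against a local annotation
#'
#' One-sided Fisher exact test of a gene set against each term of a local
#' annotation (term -> gene set, e.g. from [read_gmt()]) over a fixed gene
#' universe, with BH adjustment over terms. A local replacement for online
#' enrichment services.
#'
#' @param gene_set Genes of interest (must lie in `universe`).
#' @param annotation Named list of term gene sets; each is intersected with
#'   the universe.
#' @param universe Character vector, the gene universe.
#' @param alpha Adjusted-p significance level (default 0.05).
#' @return Data frame per term: `term`, `n_overlap`, `n_set`, `n_term`,
#'   `odds_ratio`, `p_value`, `adj_p`, `significant`.
#' @export
fisher_ora <- function(gene_set, annotation, universe, alpha = 0.05) {
  universe <- unique(universe)
  if (!length(universe)) stop_input("empty universe")
  gene_set <- intersect(unique(gene_set), universe)
  rows <- lapply(names(annotation), function(term) {
    ann <- intersect(unique(annotation[[term]]), universe)
    k <- length(intersect(gene_set, ann))
    tab <- matrix(c(k,
                    length(gene_set) - k,
                    length(ann) - k,
                    length(universe) - length(gene_set) - length(ann) + k),
                  2, 2)
    ft <- stats::fisher.test(tab, alternative = "greater")
    data.frame(term = term, n_overlap = k, n_set = length(gene_set),
               n_term = length(ann),
               odds_ratio = unname(ft$estimate), p_value = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p_value)
  out$significant <- out$adj_p < alpha
  rownames(out) <- NULL
  out
}

#' Compare perturbations by their misregulated gene and term sets
#'
#' Builds the two Jaccard overlap matrices used to relate perturbations: one
#' over each guide's misregulated gene set, one over each guide's set of
#' significant annotation terms (from [fisher_ora()]). Guides are grouped by
#' the elbow-selected K-means of [kmeans_enrichment_patterns()] applied to
#' the gene-set Jaccard rows, and an average-linkage hierarchical ordering
#' is returned for heatmap export.
#'
#' @param signature A `PerturbationSignature` from [lr_scores()].
#' @param annotation Named list of term gene sets.
#' @param universe Gene universe for the ORA (default: the signature's
#'   feature list).
#' @param alpha Term-level adjusted-p threshold (default 0.05).
#' @param k_max,seed Passed to the K-means grouping.
#' @return List: `jaccard_genes`, `jaccard_terms`, `term_sets`, `groups`
#'   (K-means labels and chosen k), `hclust_order`.
#' @export
compare_perturbations <- function(signature, annotation,
                                  universe = signature$feature_list,
                                  alpha = 0.05, k_max = 10, seed = 1L) {
  mis <- signature$misregulated
  empty <- vapply(mis, function(s) length(s) == 0, logical(1))
  if (all(empty)) stop_input("no signal to compare: all misregulated sets empty")
  if (any(empty)) {
    warning("excluding guide(s) with empty misregulated sets: ",
            paste(names(mis)[empty], collapse = ", "))
    mis <- mis[!empty]
  }
  if (length(mis) < 2) stop_input("need >= 2 guides with nonempty sets")
  J_genes <- jaccard_matrix(mis)
  term_sets <- lapply(mis, function(s) {
    ora <- fisher_ora(s, annotation, universe, alpha = alpha)
    ora$term[ora$significant]
  })
  J_terms <- suppressWarnings(jaccard_matrix(term_sets))
  groups <- kmeans_enrichment_patterns(unclass(J_genes),
                                       k_max = min(k_max, nrow(J_genes)),
                                       seed = seed)
  hc <- stats::hclust(stats::dist(unclass(J_genes)), method = "average")
  list(jaccard_genes = J_genes, jaccard_terms = J_terms,
       term_sets = term_sets, groups = groups,
       hclust_order = rownames(J_genes)[hc$order])
}
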