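#' Guide representation per cluster
#'
#' Guide representation is the basic quantity behind fate enrichment: for
#' each guide and cluster, the number of cluster cells carrying the guide
#' divided by the total number of cells in the cluster.
#'
#' @param assignments A `GuideAssignmentSet` from [filter_ambient()].
#' @param clusters Named vector mapping cell id -> cluster label; must cover
#'   every assigned cell. Cluster sizes are taken over all labeled cells.
#' @return A list of class `RepresentationTable`: `counts` (guides x
#'   clusters integer matrix), `r` (representation fractions) and
#'   `cluster_sizes`.
#' @export
guide_representation <- function(assignments, clusters) {
  a <- assignments$assignments
  missing <- setdiff(unique(a$cell_id), names(clusters))
  if (length(missing)) {
    stop_input("assigned cell(s) without cluster label: ",
               paste(utils::head(missing, 5), collapse = ", "))
  }
  guides <- assignments$thresholds$guide_id
  lev <- sort(unique(as.character(clusters)))
  sizes <- table(factor(as.character(clusters), levels = lev))
  counts <- table(factor(a$guide_id, levels = guides),
                  factor(as.character(clusters[a$cell_id]), levels = lev))
  counts <- matrix(as.integer(counts), nrow = length(guides),
                   dimnames = list(guides, lev))
  r <- sweep(counts, 2, as.integer(sizes), "/")
  structure(list(counts = counts, r = r,
                 cluster_sizes = setNames(as.integer(sizes), lev)),
            class = "RepresentationTable")
}

# Cluster-stratified fold labels over the cells of `clusters`.
stratified_folds <- function(clusters, n_folds) {
  fold <- integer(length(clusters))
  names(fold) <- names(clusters)
  for (cl in unique(clusters)) {
    idx <- which(clusters == cl)
    fold[idx[sample.int(length(idx))]] <-
      rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Cross-validated guide enrichment scores against the scramble reference
#'
#' Cells are partitioned into `n_folds` folds stratified by cluster. Within
#' each fold the representation of every guide per cluster is computed and
#' the enrichment of guide `g` in cluster `c` is
#' `log2((r[g,c] + eps) / (mean over scramble guides of r[s,c] + eps))`,
#' with `eps = 1/(fold cluster size + 1)` guarding zeros. The score reported
#' per guide and cluster is the mean over folds, with its SD quantifying
#' fold-to-fold stability. With `n_folds = 1` this reduces to the whole-data
#' log ratio.
#'
#' @inheritParams guide_representation
#' @param scramble_guides Character vector of scramble guide ids (the
#'   reference distribution); must be nonempty.
#' @param n_folds Number of CV folds (default 5).
#' @param seed Integer seed for the fold partition.
#' @return List of class `EnrichmentResult` with matrices `enrichment` and
#'   `cv_sd` (guides x clusters) and the fold assignment in `folds`.
#' @export
cv_enrichment <- function(assignments, clusters, scramble_guides,
                          n_folds = 5, seed = 1L) {
  if (!length(scramble_guides)) stop_input("scramble reference required")
  guides <- assignments$thresholds$guide_id
  if (!all(scramble_guides %in% guides)) {
    stop_input("scramble guide(s) not in assignment set")
  }
  clusters <- setNames(as.character(clusters), names(clusters))
  if (length(clusters) < n_folds) stop_input("fewer cells than folds")
  fold <- with_seed_(seed, stratified_folds(clusters, n_folds))
  lev <- sort(unique(clusters))
  a <- assignments$assignments
  per_fold <- array(NA_real_, c(length(guides), length(lev), n_folds),
                    dimnames = list(guides, lev, NULL))
  for (f in seq_len(n_folds)) {
    cells_f <- names(fold)[fold == f]
    sizes <- table(factor(clusters[cells_f], levels = lev))
    af <- a[a$cell_id %in% cells_f, , drop = FALSE]
    cnt <- table(factor(af$guide_id, levels = guides),
                 factor(clusters[af$cell_id], levels = lev))
    cnt <- matrix(as.numeric(cnt), nrow = length(guides))
    sz <- pmax(as.numeric(sizes), 1)
    r <- sweep(cnt, 2, sz, "/")
    eps <- 1 / (sz + 1)
    scr <- colMeans(r[match(scramble_guides, guides), , drop = FALSE])
    per_fold[, , f] <- log2(sweep(r, 2, eps, "+")) -
      matrix(log2(scr + eps), length(guides), length(lev), byrow = TRUE)
  }
  structure(list(
    enrichment = apply(per_fold, c(1, 2), mean),
    cv_sd = apply(per_fold, c(1, 2), stats::sd),
    folds = fold
  ), class = "EnrichmentResult")
}

#' Chi-square test of one guide's cluster distribution against a reference
#'
#' Forms the 2 x K contingency table of a guide's per-cluster cell counts
#' against a reference count row (typically scramble guide 1, or the average
#' across all guides), computes the Pearson chi-square statistic and p-value
#' and, per cluster, the adjusted standardized residual of the guide row.
#' Under independence these residuals are standard normal, so `|z| > 2`
#' classifies the guide as enriched (`z > 2`) or depleted (`z < -2`) in a
#' cluster. Clusters whose expected guide-row count falls below
#' `pool_threshold` are pooled into a remainder category that contributes to
#' the statistic but receives no per-cluster call.
#'
#' @param guide_counts Named numeric vector: guide cells per cluster.
#' @param reference_counts Named numeric vector over the same clusters;
#'   nonnegative with positive total (may be non-integer, e.g. an average).
#' @param pool_threshold Minimum expected guide-row count for a cluster to
#'   receive its own call (default 1).
#' @param residual `"adjusted"` (default; null-standard-normal) or
#'   `"pearson"` raw residuals.
#' @return List: `chi2_stat`, `df`, `p_value`, `z` (named, `NA` for pooled
#'   clusters), `call` (`"enriched"`, `"depleted"`, `"none"`, or `NA`),
#'   `pooled` (cluster names pooled), `untestable` (all-zero guide row).
#' @examples
#' chi2_guide_test(c(A = 10, B = 30), c(A = 30, B = 30))
#' @export
chi2_guide_test <- function(guide_counts, reference_counts,
                            pool_threshold = 1,
                            residual = c("adjusted", "pearson")) {
  residual <- match.arg(residual)
  if (length(guide_counts) < 2) stop_input("need at least 2 clusters")
  if (!identical(names(guide_counts), names(reference_counts))) {
    reference_counts <- reference_counts[names(guide_counts)]
  }
  if (any(reference_counts < 0) || sum(reference_counts) <= 0) {
    stop_input("reference counts must be nonnegative with positive total")
  }
  clusters <- names(guide_counts)
  if (sum(guide_counts) == 0) {
    return(list(chi2_stat = NA_real_, df = NA_integer_, p_value = NA_real_,
                z = setNames(rep(NA_real_, length(clusters)), clusters),
                call = setNames(rep(NA_character_, length(clusters)), clusters),
                pooled = character(0), untestable = TRUE))
  }
  O <- rbind(guide = guide_counts, reference = reference_counts)
  N <- sum(O)
  expected_guide <- sum(O[1, ]) * colSums(O) / N
  pooled <- clusters[expected_guide < pool_threshold]
  keep <- setdiff(clusters, pooled)
  if (length(pooled) > 0 && length(keep) >= 1) {
    Ok <- cbind(O[, keep, drop = FALSE],
                .pooled = rowSums(O[, pooled, drop = FALSE]))
  } else {
    Ok <- O
    pooled <- character(0)
    keep <- clusters
  }
  E <- outer(rowSums(Ok), colSums(Ok)) / N
  chi2 <- sum((Ok - E)^2 / E)
  df <- ncol(Ok) - 1L
  p <- stats::pchisq(chi2, df = df, lower.tail = FALSE)
  # residuals of the guide row
  raw <- (Ok[1, ] - E[1, ]) / sqrt(E[1, ])
  if (residual == "adjusted") {
    adj <- raw / sqrt((1 - rowSums(Ok)[1] / N) * (1 - colSums(Ok) / N))
  } else {
    adj <- raw
  }
  z <- setNames(rep(NA_real_, length(clusters)), clusters)
  z[keep] <- adj[keep]
  call <- ifelse(is.na(z), NA_character_,
                 ifelse(z > 2, "enriched", ifelse(z < -2, "depleted", "none")))
  list(chi2_stat = chi2, df = df, p_value = p, z = z,
       call = setNames(call, clusters), pooled = pooled, untestable = FALSE)
}

#' Chi-square z-scores for every guide in a representation table
#'
#' Applies [chi2_guide_test()] to each guide against either the scramble
#' guide 1 counts or the average counts across all guides, returning the
#' guides x clusters matrix of adjusted residual z-scores together with the
#' per-guide statistics and the enriched/depleted/none calls.
#'
#' @param rep_table A `RepresentationTable` from [guide_representation()].
#' @param reference `"scramble1"` or `"average"`.
#' @param scramble_guides Scramble guide ids (needed for `"scramble1"`).
#' @param ... Passed to [chi2_guide_test()].
#' @return List: `z` and `call` matrices (guides x clusters), `stats` data
#'   frame (`guide_id`, `chi2_stat`, `df`, `p_value`, `untestable`).
#' @export
chi2_all_guides <- function(rep_table, reference = c("average", "scramble1"),
                            scramble_guides = NULL, ...) {
  reference <- match.arg(reference)
  cnt <- rep_table$counts
  guides <- rownames(cnt)
  res_z <- matrix(NA_real_, nrow(cnt), ncol(cnt), dimnames = dimnames(cnt))
  res_call <- matrix(NA_character_, nrow(cnt), ncol(cnt),
                     dimnames = dimnames(cnt))
  st <- vector("list", length(guides))
  for (i in seq_along(guides)) {
    ref <- if (reference == "scramble1") {
      if (is.null(scramble_guides) || !length(scramble_guides)) {
        stop_input("scramble_guides required for reference = 'scramble1'")
      }
      cnt[scramble_guides[1], ]
    } else {
      colMeans(cnt)
    }
    t_i <- chi2_guide_test(cnt[i, ], ref, ...)
    res_z[i, ] <- t_i$z
    res_call[i, ] <- t_i$call
    st[[i]] <- data.frame(guide_id = guides[i], chi2_stat = t_i$chi2_stat,
                          df = t_i$df, p_value = t_i$p_value,
                          untestable = t_i$untestable,
                          stringsAsFactors = FALSE)
  }
  list(z = res_z, call = res_call, stats = do.call(rbind, st))
}

#' Kullback-Leibler divergence between two discrete distributions
#'
#' `D_KL(p || q) = sum_k p_k log(p_k / q_k)`, in nats by default. Zero
#' entries of `p` contribute zero; zero entries of `q` with positive `p`
#' give `Inf` (callers smooth first).
#'
#' @param p,q Probability vectors over the same support (renormalized).
#' @param base Logarithm base; `exp(1)` for nats (default), `2` for bits.
#' @return Nonnegative divergence (0 iff `p == q` on the support).
#' @examples
#' kl_divergence(c(0.5, 0.5), c(0.9, 0.1))  # 0.5 * log(25/9)
#' @export
kl_divergence <- function(p, q, base = exp(1)) {
  p <- p / sum(p); q <- q / sum(q)
  nz <- p > 0
  sum(p[nz] * (log(p[nz] / q[nz]) / log(base)))
}

smooth_dist <- function(counts, k = length(counts)) {
  p <- counts / max(sum(counts), 1)
  p <- p + 1 / k
  p / sum(p)
}

# mean-over-folds KLD of a guide's cells against a fixed scramble dist
mean_fold_kld <- function(guide_cl, q, lev, fold_id, base) {
  vapply(unique(fold_id), function(f) {
    cnt <- tabulate(match(guide_cl[fold_id == f], lev), nbins = length(lev))
    kl_divergence(smooth_dist(cnt), q, base = base)
  }, numeric(1)) |> mean()
}

#' KLD cross-validation test of a guide distribution against scramble
#'
#' Compares the cluster distribution of a guide's cells to the scramble
#' reference distribution by Kullback-Leibler divergence, cross-validated:
#' the guide's cells are split into `n_folds` random folds and the reported
#' divergence is the mean over folds of `D_KL(fold distribution || scramble
#' distribution)`, both distributions smoothed by adding `1/K` to each
#' cluster mass and renormalizing. Significance comes from a permutation
#' null that randomly relabels which of the pooled guide + scramble cells
#' are "guide", with `p = (1 + #{permutation KLD >= observed}) /
#' (n_permutations + 1)`.
#'
#' @param guide_clusters Cluster labels of the guide's cells.
#' @param scramble_clusters Cluster labels of the scramble reference cells.
#' @param cluster_levels Full cluster set (default: union observed).
#' @param n_folds CV folds (default 5). Guides with fewer cells than folds
#'   return an indeterminate result (`NA`s), not an error.
#' @param n_permutations Permutation replicates (default 999).
#' @param base KLD logarithm base (default nats).
#' @param seed Integer seed.
#' @return List: `kld` (mean-fold divergence), `p_value`, `significant`
#'   (at 0.05), `n_guide_cells`, `indeterminate`.
#' @export
kld_cv_test <- function(guide_clusters, scramble_clusters,
                        cluster_levels = NULL, n_folds = 5,
                        n_permutations = 999, base = exp(1), seed = 1L) {
  guide_clusters <- as.character(guide_clusters)
  scramble_clusters <- as.character(scramble_clusters)
  if (is.null(cluster_levels)) {
    cluster_levels <- sort(unique(c(guide_clusters, scramble_clusters)))
  }
  n_g <- length(guide_clusters)
  if (n_g < n_folds || !length(scramble_clusters)) {
    return(list(kld = NA_real_, p_value = NA_real_, significant = NA,
                n_guide_cells = n_g, indeterminate = TRUE))
  }
  lev <- cluster_levels
  K <- length(lev)
  with_seed_(seed, {
    fold_id <- sample(rep_len(seq_len(n_folds), n_g))
    q_obs <- smooth_dist(tabulate(match(scramble_clusters, lev), nbins = K))
    obs <- mean_fold_kld(guide_clusters, q_obs, lev, fold_id, base)
    pool <- c(guide_clusters, scramble_clusters)
    n_pool <- length(pool)
    perm <- vapply(seq_len(n_permutations), function(b) {
      idx <- sample.int(n_pool, n_g)
      qb <- smooth_dist(tabulate(match(pool[-idx], lev), nbins = K))
      mean_fold_kld(pool[idx], qb, lev, fold_id, base)
    }, numeric(1))
    p <- (1 + sum(perm >= obs)) / (n_permutations + 1)
    list(kld = obs, p_value = p, significant = p < 0.05,
         n_guide_cells = n_g, indeterminate = FALSE)
  })
}

#' K-means grouping of guide enrichment patterns with elbow selection
#'
#' Clusters the guides x clusters enrichment matrix with K-means for
#' `k = 1..k_max` (multiple restarts, fixed seed) and selects the number of
#' groups at the elbow of the total within-cluster sum of squares, taken as
#' the maximizer of its second difference. Degenerate inputs (all rows
#' identical, or no interior elbow) fall back to `k = 1`.
#'
#' @param enrichment Guides x clusters numeric matrix.
#' @param k_max Largest k tried (capped at the number of guides, with a
#'   warning).
#' @param nstart Random restarts per k (default 10).
#' @param seed Integer seed.
#' @return List: `labels` (named guide -> group), `chosen_k`, `withinss`
#'   (total within-cluster SS per k).
#' @export
kmeans_enrichment_patterns <- function(enrichment, k_max = 10, nstart = 10,
                                       seed = 1L) {
  n <- nrow(enrichment)
  if (n < 2) stop_input("need at least 2 guides")
  n_distinct <- nrow(unique(round(enrichment, 12)))
  if (k_max > n) {
    warning("k_max capped at the number of guides (", n, ")")
    k_max <- n
  }
  # k = n is never an elbow candidate and breaks center sampling
  k_max <- max(1L, min(k_max, n - 1L, n_distinct))
  with_seed_(seed, {
    W <- vapply(seq_len(k_max), function(k) {
      if (k == 1) {
        sum(scale(enrichment, scale = FALSE)^2)
      } else {
        stats::kmeans(enrichment, centers = k, nstart = nstart,
                      iter.max = 50)$tot.withinss
      }
    }, numeric(1))
    chosen_k <- 1L
    if (k_max >= 3 && W[1] > 1e-12) {
      d2 <- W[seq_len(k_max - 2)] - 2 * W[seq(2, k_max - 1)] +
        W[seq(3, k_max)]
      chosen_k <- which.max(d2) + 1L
    } else if (k_max == 2 && W[1] > 1e-12 && W[2] < 0.5 * W[1]) {
      chosen_k <- 2L
    }
    labels <- if (chosen_k == 1) {
      setNames(rep(1L, n), rownames(enrichment))
    } else {
      fit <- stats::kmeans(enrichment, centers = chosen_k, nstart = nstart,
                           iter.max = 50)
      setNames(fit$cluster, rownames(enrichment))
    }
    list(labels = labels, chosen_k = chosen_k, withinss = W)
  })
}

#' PCA of the guide enrichment matrix
#'
#' Column-centered principal component analysis of the guides x clusters
#' enrichment matrix. The loadings expose which clusters drive each
#' component of variation between perturbations, and the explained variance
#' fractions quantify how much of the enrichment structure each component
#' captures.
#'
#' @param enrichment Guides x clusters numeric matrix (>= 2 guides and
#'   clusters).
#' @return List: `scores` (guides x components), `loadings` (clusters x
#'   components), `explained` (variance fractions, nonincreasing, summing
#'   to <= 1). A constant matrix yields empty components.
#' @export
pca_enrichment <- function(enrichment) {
  if (nrow(enrichment) < 2 || ncol(enrichment) < 2) {
    stop_input("need >= 2 guides and >= 2 clusters")
  }
  fit <- stats::prcomp(enrichment, center = TRUE, scale. = FALSE)
  keep <- fit$sdev > 1e-10
  if (!any(keep)) {
    return(list(scores = fit$x[, 0, drop = FALSE],
                loadings = fit$rotation[, 0, drop = FALSE],
                explained = numeric(0)))
  }
  ev <- fit$sdev[keep]^2
  list(scores = fit$x[, keep, drop = FALSE],
       loadings = fit$rotation[, keep, drop = FALSE],
       explained = ev / sum(fit$sdev^2))
}
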