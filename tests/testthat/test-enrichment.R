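make_assignments <- function(pairs, lib, cells) {
  manual_assignments(pairs, lib, cells)
}

test_that("guide representation equals cells-with-guide over cluster size", {
  lib <- guide_library(1, guides_per_gene = 1, n_scramble = 1)
  cells <- paste0("c", 1:20)
  clusters <- setNames(rep(c("A", "B"), each = 10), cells)
  pairs <- data.frame(cell_id = c("c1", "c2", paste0("c", 11:20)),
                      guide_id = c(rep(lib$guide_id[1], 2),
                                   rep(lib$guide_id[2], 10)))
  aset <- make_assignments(pairs, lib, cells)
  tab <- guide_representation(aset, clusters)
  expect_equal(tab$r[lib$guide_id[1], "A"], 0.2)
  expect_equal(tab$r[lib$guide_id[2], "B"], 1)
  expect_equal(tab$counts[lib$guide_id[1], "B"], 0L)
  # unlabeled assigned cell is an input error naming the cell
  expect_error(guide_representation(aset, clusters[-1]), "c1")
})

test_that("representation matches an explicit double-loop oracle", {
  withr::local_seed(55)
  lib <- guide_library(4, guides_per_gene = 1, n_scramble = 1)
  cells <- paste0("c", 1:60)
  clusters <- setNames(sample(c("A", "B", "C"), 60, replace = TRUE), cells)
  pairs <- data.frame(
    cell_id = sample(cells, 80, replace = TRUE),
    guide_id = sample(lib$guide_id, 80, replace = TRUE))
  pairs <- unique(pairs)
  aset <- make_assignments(pairs, lib, cells)
  tab <- guide_representation(aset, clusters)
  for (g in lib$guide_id) {
    for (cl in c("A", "B", "C")) {
      in_cl <- names(clusters)[clusters == cl]
      with_g <- unique(pairs$cell_id[pairs$guide_id == g])
      expect_equal(tab$counts[g, cl], length(intersect(in_cl, with_g)))
      expect_equal(tab$r[g, cl],
                   length(intersect(in_cl, with_g)) / length(in_cl))
    }
  }
})

test_that("single-fold CV enrichment equals the whole-data log ratio", {
  lib <- guide_library(1, guides_per_gene = 1, n_scramble = 1)
  cells <- paste0("c", 1:30)
  clusters <- setNames(rep(c("A", "B", "C"), each = 10), cells)
  pairs <- data.frame(
    cell_id = c(paste0("c", 1:6), paste0("c", 11:13), paste0("c", 21:22),
                paste0("c", c(1, 2, 11, 21, 22, 23))),
    guide_id = rep(lib$guide_id, c(11, 6)))
  aset <- make_assignments(pairs, lib, cells)
  enr <- cv_enrichment(aset, clusters, scramble_guides = lib$guide_id[2],
                       n_folds = 1, seed = 1)
  tab <- guide_representation(aset, clusters)
  eps <- 1 / (10 + 1)
  manual <- log2((tab$r[1, ] + eps) / (tab$r[2, ] + eps))
  expect_equal(enr$enrichment[1, ], manual)
  expect_true(all(is.na(enr$cv_sd) | enr$cv_sd == 0))
})

test_that("a guide duplicating the scramble distribution scores near zero", {
  withr::local_seed(66)
  lib <- validate_guide_library(data.frame(
    guide_id = c("twin", "scr"), target_gene = c("geneX", NA),
    scramble = c(FALSE, TRUE)))
  cells <- paste0("c", 1:300)
  clusters <- setNames(sample(c("A", "B", "C", "D"), 300, TRUE), cells)
  chosen <- sample(cells, 150)
  pairs <- rbind(data.frame(cell_id = chosen, guide_id = "twin"),
                 data.frame(cell_id = chosen, guide_id = "scr"))
  aset <- make_assignments(pairs, lib, cells)
  enr <- cv_enrichment(aset, clusters, scramble_guides = "scr",
                       n_folds = 5, seed = 2)
  expect_true(all(abs(enr$enrichment["twin", ]) < 1e-9))
  expect_error(cv_enrichment(aset, clusters, character(0)),
               "scramble reference")
})

test_that("chi-square guide test matches the hand-worked 2x2 example", {
  res <- chi2_guide_test(c(A = 10, B = 30), c(A = 30, B = 30))
  # expected guide counts 16 / 24; adjusted residuals -2.5 / +2.5
  expect_equal(unname(res$z["A"]), -2.5)
  expect_equal(unname(res$z["B"]), 2.5)
  expect_equal(unname(res$call["A"]), "depleted")
  expect_equal(unname(res$call["B"]), "enriched")
  # chi2 equals the brute-force cell-wise sum
  O <- rbind(c(10, 30), c(30, 30))
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(res$chi2_stat, sum((O - E)^2 / E))
})

test_that("chi-square and adjusted residuals match brute force on random tables", {
  withr::local_seed(77)
  for (i in 1:20) {
    K <- sample(3:8, 1)
    guide <- rpois(K, 20) + 5
    ref <- rpois(K, 30) + 5
    names(guide) <- names(ref) <- paste0("cl", seq_len(K))
    res <- chi2_guide_test(guide, ref, pool_threshold = 0)
    O <- rbind(guide, ref)
    N <- sum(O)
    E <- outer(rowSums(O), colSums(O)) / N
    expect_equal(res$chi2_stat, sum((O - E)^2 / E))
    adj <- (O[1, ] - E[1, ]) /
      sqrt(E[1, ] * (1 - rowSums(O)[1] / N) * (1 - colSums(O) / N))
    expect_equal(unname(res$z), unname(adj))
    # cross-check statistic and p against stats::chisq.test
    ct <- suppressWarnings(chisq.test(O, correct = FALSE))
    expect_equal(res$chi2_stat, unname(ct$statistic))
    expect_equal(res$p_value, ct$p.value)
    expect_equal(unname(res$z), unname(ct$stdres[1, ]))
  }
})

test_that("proportional rows give chi2 = 0 and degenerate rows are flagged", {
  res <- chi2_guide_test(c(A = 10, B = 20, C = 30),
                         c(A = 20, B = 40, C = 60))
  expect_equal(res$chi2_stat, 0)
  expect_true(all(res$z == 0))
  expect_true(all(res$call == "none"))
  res0 <- chi2_guide_test(c(A = 0, B = 0), c(A = 5, B = 5))
  expect_true(res0$untestable)
  expect_true(all(is.na(res0$z)))
})

test_that("low-expectation clusters are pooled out of per-cluster calls", {
  guide <- c(A = 40, B = 30, C = 0)
  ref <- c(A = 40, B = 30, C = 1)   # expected guide count in C is ~0.5
  res <- chi2_guide_test(guide, ref, pool_threshold = 1)
  expect_true("C" %in% res$pooled)
  expect_true(is.na(res$z["C"]))
  expect_false(is.na(res$z["A"]))
})

test_that("KLD formula, nonnegativity, and smoothing zero-iff-equal hold", {
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.9, 0.1)), 0.5 * log(25 / 9))
  expect_equal(kl_divergence(c(0.2, 0.8), c(0.2, 0.8)), 0)
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.9, 0.1), base = 2),
               0.5 * log2(25 / 9))
  withr::local_seed(88)
  for (i in 1:10) {
    p <- crisprfate:::smooth_dist(rpois(5, 10))
    q <- crisprfate:::smooth_dist(rpois(5, 10))
    expect_gte(kl_divergence(p, q), 0)
  }
})

test_that("KLD CV test is seeded, indeterminate below fold count, and detects shifts", {
  withr::local_seed(99)
  g <- sample(c("A", "B", "C"), 100, TRUE, prob = c(0.7, 0.2, 0.1))
  s <- sample(c("A", "B", "C"), 200, TRUE, prob = c(1, 1, 1) / 3)
  r1 <- kld_cv_test(g, s, n_permutations = 199, seed = 5)
  r2 <- kld_cv_test(g, s, n_permutations = 199, seed = 5)
  expect_identical(r1, r2)
  expect_lt(r1$p_value, 0.05)
  expect_gt(r1$kld, 0)
  few <- kld_cv_test(c("A", "B"), s, n_folds = 5, n_permutations = 99)
  expect_true(few$indeterminate)
  expect_true(is.na(few$p_value))
})

test_that("elbow K-means recovers planted groups and degenerates to k = 1", {
  withr::local_seed(111)
  grp1 <- matrix(rnorm(5 * 6, mean = 0, sd = 0.1), 5, 6)
  grp2 <- matrix(rnorm(5 * 6, mean = 5, sd = 0.1), 5, 6)
  E <- rbind(grp1, grp2)
  rownames(E) <- paste0("g", 1:10)
  fit <- kmeans_enrichment_patterns(E, k_max = 6, seed = 3)
  expect_equal(fit$chosen_k, 2L)
  # perfect agreement with the planted partition
  expect_equal(length(unique(fit$labels[1:5])), 1)
  expect_equal(length(unique(fit$labels[6:10])), 1)
  expect_false(fit$labels[1] == fit$labels[6])
  # identical rows: fall back to a single cluster
  flat <- matrix(1, 4, 3, dimnames = list(paste0("g", 1:4), NULL))
  expect_equal(kmeans_enrichment_patterns(flat, k_max = 4,
                                          seed = 1)$chosen_k, 1L)
  expect_warning(kmeans_enrichment_patterns(E, k_max = 50, seed = 1),
                 "capped")
})

test_that("enrichment PCA matches a brute-force eigendecomposition", {
  withr::local_seed(123)
  E <- matrix(rnorm(24), 6, 4,
              dimnames = list(paste0("g", 1:6), paste0("cl", 1:4)))
  res <- pca_enrichment(E)
  expect_true(all(diff(res$explained) <= 1e-12))
  expect_lte(sum(res$explained), 1 + 1e-9)
  ev <- eigen(cov(E))
  for (j in seq_along(res$explained)) {
    # loadings equal eigenvectors up to sign
    expect_equal(abs(unname(res$loadings[, j])), abs(ev$vectors[, j]),
                 tolerance = 1e-8)
  }
  expect_equal(res$explained, ev$values[seq_along(res$explained)] /
                 sum(ev$values), tolerance = 1e-8)
  # rank-1 matrix: first component carries all variance
  r1 <- outer(1:5, c(1, 2, 3))
  rownames(r1) <- paste0("g", 1:5)
  expect_equal(pca_enrichment(r1)$explained[1], 1, tolerance = 1e-9)
})
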