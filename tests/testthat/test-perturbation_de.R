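# Tiny designs for closed-form regression checks.
two_group_setup <- function(guide_vals, scr_vals, gene = "geneX") {
  lib <- validate_guide_library(data.frame(
    guide_id = c("g_target", "scr"), target_gene = c(gene, NA),
    scramble = c(FALSE, TRUE)))
  cells <- paste0("c", seq_len(length(guide_vals) + length(scr_vals)))
  pairs <- data.frame(
    cell_id = cells,
    guide_id = rep(c("g_target", "scr"),
                   c(length(guide_vals), length(scr_vals))))
  aset <- manual_assignments(pairs, lib, cells)
  expr <- matrix(c(guide_vals, scr_vals), nrow = 1,
                 dimnames = list(gene, cells))
  list(lib = lib, aset = aset, expr = expr)
}

test_that("zero-penalty single-guide coefficients equal group-mean differences", {
  su <- two_group_setup(c(1, 3), c(5, 7))
  sig <- lr_scores(su$expr, su$aset, su$lib, ridge_penalty = 0,
                   n_permutations = 9, seed = 1)
  expect_equal(unname(sig$lr_score["g_target", "geneX"]), -4)
  # closed-form limit on a larger random instance
  withr::local_seed(7)
  gv <- rnorm(40, 1)
  sv <- rnorm(60, 3)
  su2 <- two_group_setup(gv, sv)
  sig2 <- lr_scores(su2$expr, su2$aset, su2$lib, ridge_penalty = 0,
                    n_permutations = 9, seed = 1)
  expect_equal(unname(sig2$lr_score["g_target", "geneX"]),
               mean(gv) - mean(sv), tolerance = 1e-10)
})

test_that("a dominating observed statistic gives the minimal permutation p", {
  su <- two_group_setup(rep(10, 10), rep(0, 10))
  sig <- lr_scores(su$expr, su$aset, su$lib, ridge_penalty = 0,
                   n_permutations = 99, seed = 2)
  expect_equal(unname(sig$p["g_target", "geneX"]), 1 / 100)
  expect_equal(sig$misregulated$g_target, "geneX")
})

test_that("permutation p is invariant to adding a constant to a gene", {
  withr::local_seed(17)
  su <- two_group_setup(rnorm(15, 0.5), rnorm(15))
  s1 <- lr_scores(su$expr, su$aset, su$lib, ridge_penalty = 0.1,
                  n_permutations = 99, seed = 3)
  su$expr <- su$expr + 100
  s2 <- lr_scores(su$expr, su$aset, su$lib, ridge_penalty = 0.1,
                  n_permutations = 99, seed = 3)
  expect_equal(s1$p, s2$p)
})

test_that("no-effect nulls give approximately uniform permutation p-values", {
  withr::local_seed(19)
  n_genes <- 200
  lib <- validate_guide_library(data.frame(
    guide_id = c("gA", "scr"), target_gene = c("t1", NA),
    scramble = c(FALSE, TRUE)))
  cells <- paste0("c", 1:60)
  pairs <- data.frame(cell_id = cells,
                      guide_id = rep(c("gA", "scr"), each = 30))
  aset <- manual_assignments(pairs, lib, cells)
  expr <- matrix(rnorm(n_genes * 60), n_genes, 60,
                 dimnames = list(paste0("f", 1:n_genes), cells))
  sig <- lr_scores(scale_expression(expr), aset, lib, ridge_penalty = 0.1,
                   n_permutations = 199, seed = 4)
  p <- sort(as.numeric(sig$p))
  ks <- max(abs(p - seq_along(p) / length(p)))
  expect_lt(ks, 0.1)
})

test_that("singular zero-penalty designs advise a positive penalty", {
  # two guides always co-occurring make collinear indicator columns
  lib <- validate_guide_library(data.frame(
    guide_id = c("g1", "g2", "scr"), target_gene = c("t1", "t2", NA),
    scramble = c(FALSE, FALSE, TRUE)))
  cells <- paste0("c", 1:8)
  pairs <- rbind(
    data.frame(cell_id = cells[1:4], guide_id = "g1"),
    data.frame(cell_id = cells[1:4], guide_id = "g2"),
    data.frame(cell_id = cells[5:8], guide_id = "scr"))
  aset <- manual_assignments(pairs, lib, cells)
  expr <- matrix(rnorm(8), 1, 8, dimnames = list("f1", cells))
  expect_error(lr_scores(expr, aset, lib, ridge_penalty = 0,
                         n_permutations = 9),
               "ridge_penalty")
  # and the ridge fix runs
  sig <- lr_scores(expr, aset, lib, ridge_penalty = 0.5, n_permutations = 9)
  expect_true(all(is.finite(sig$lr_score)))
})

test_that("scaling standardizes genes and zero-variance genes collapse to 0", {
  withr::local_seed(23)
  m <- matrix(rnorm(50, 5, 2), 5, 10,
              dimnames = list(paste0("g", 1:5), paste0("c", 1:10)))
  m[3, ] <- 7  # constant gene
  s <- scale_expression(m)
  expect_equal(unname(rowMeans(s)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(s[-3, ], 1, sd)), rep(1, 4), tolerance = 1e-12)
  expect_true(all(s[3, ] == 0))
})

test_that("jaccard matrix follows the overlap-fraction convention", {
  J <- jaccard_matrix(list(a = c("x", "y", "z"), b = c("y", "z", "w"),
                           c = c("q")))
  expect_equal(J["a", "b"], 0.5)
  expect_equal(J["a", "c"], 0)
  expect_equal(unname(diag(J)), c(1, 1, 1))
  expect_true(isSymmetric(unclass(J)))
  expect_warning(J0 <- jaccard_matrix(list(a = character(0),
                                           b = character(0))),
                 "empty")
  expect_equal(unname(J0["a", "b"]), 0)
})

test_that("Fisher ORA matches exhaustive hypergeometric tail sums", {
  hyper_tail <- function(k, n_set, n_term, N) {
    # P(overlap >= k) by direct enumeration
    i <- k:min(n_set, n_term)
    sum(choose(n_term, i) * choose(N - n_term, n_set - i) / choose(N, n_set))
  }
  universe <- paste0("g", 1:20)
  annotation <- list(T1 = universe[1:10], T2 = universe[8:14],
                     T3 = universe[15:20])
  gene_set <- universe[1:10]
  ora <- fisher_ora(gene_set, annotation, universe)
  expect_equal(ora$p_value[ora$term == "T1"], hyper_tail(10, 10, 10, 20))
  expect_equal(ora$p_value[ora$term == "T2"], hyper_tail(3, 10, 7, 20))
  expect_equal(ora$p_value[ora$term == "T3"], hyper_tail(0, 10, 6, 20))
  # zero overlap with a small term: p = 1 (no enrichment side)
  expect_equal(ora$p_value[ora$term == "T3"], 1)
  expect_error(fisher_ora(gene_set, annotation, character(0)), "universe")
})

test_that("random gene sets rarely produce significant terms", {
  withr::local_seed(29)
  universe <- paste0("g", 1:100)
  annotation <- lapply(1:8, function(i) sample(universe, 20))
  names(annotation) <- paste0("T", 1:8)
  hits <- 0
  for (i in 1:50) {
    ora <- fisher_ora(sample(universe, 15), annotation, universe)
    hits <- hits + sum(ora$significant)
  }
  expect_lte(hits / (50 * 8), 0.07)
})

test_that("perturbation comparison relates shared-effect guides", {
  sets <- list(gA = paste0("g", 1:20), gB = paste0("g", c(1:18, 30, 31)),
               gC = paste0("g", 40:55))
  sig <- structure(list(misregulated = sets,
                        feature_list = paste0("g", 1:60)),
                   class = "PerturbationSignature")
  annotation <- list(T1 = paste0("g", 1:25), T2 = paste0("g", 35:60))
  cmp <- compare_perturbations(sig, annotation, alpha = 0.05, seed = 1)
  J <- cmp$jaccard_genes
  expect_gt(J["gA", "gB"], J["gA", "gC"])
  expect_equal(unname(diag(unclass(J))), rep(1, 3))
  expect_setequal(cmp$hclust_order, names(sets))
  # empty sets are excluded with a warning; all-empty errors
  sig$misregulated$gC <- character(0)
  expect_warning(cmp2 <- compare_perturbations(sig, annotation, seed = 1),
                 "empty")
  expect_equal(nrow(cmp2$jaccard_genes), 2)
  sig$misregulated <- list(gA = character(0), gB = character(0))
  expect_error(compare_perturbations(sig, annotation), "no signal")
})

test_that("GMT files round-trip through read and write", {
  sets <- list(TermA = c("g1", "g2", "g3"), TermB = c("g2", "g5"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_equal(back[order(names(back))], sets[order(names(sets))])
})
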