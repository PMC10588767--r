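# quantification toy with a complex whose members co-vary only in one group
cohesionToy <- function(nPerBatch = 8, nMembers = 5, nNoise = 5,
                        loadOld = 1, loadYoung = 0, noiseSd = 0.3,
                        seed = 1) {
  ann <- toyAnnotation(nPerBatch = nPerBatch)
  ann_s <- ann[!ann$is_bridge, ]
  n <- nrow(ann_s)
  set.seed(seed)
  f <- rnorm(n)
  load <- ifelse(ann_s$age == "old", loadOld, loadYoung)
  members <- sprintf("CPLX_P%02d", seq_len(nMembers))
  noise <- sprintf("FREE_P%02d", seq_len(nNoise))
  vals <- rbind(
    t(sapply(members, function(p) load * f + rnorm(n, 0, noiseSd))),
    t(sapply(noise, function(p) rnorm(n, 0, noiseSd))))
  colnames(vals) <- ann_s$sample_id
  list(ann = ann, ann_s = ann_s,
       pq = makeProteinQuant(vals, ann), members = members)
}

test_that("catalog filtering keeps complexes with enough observed members", {
  toy <- cohesionToy()
  cat <- complexCatalog(list(
    big = toy$members,                        # all 5 observed
    partial = c(toy$members[1:3], "GHOST1"),  # 3 observed
    free = sprintf("FREE_P%02d", 1:4)))
  expect_message(obs <- filterComplexes(cat, toy$pq, minMembers = 4),
                 "not observed")
  expect_setequal(names(obs), c("big", "free"))
  expect_setequal(obs$big, toy$members)
  obs3 <- suppressMessages(filterComplexes(cat, toy$pq, minMembers = 3))
  expect_true("partial" %in% names(obs3))
  expect_setequal(obs3$partial, toy$members[1:3])
})

test_that("cohesiveness is 1 for perfectly correlated members and ~0 for noise", {
  ann <- toyAnnotation(nPerBatch = 6)
  ann_s <- ann[!ann$is_bridge, ]
  set.seed(5)
  f <- rnorm(nrow(ann_s))
  perfect <- outer(c(1, 2, 0.5, 3), f)  # positive multiples of one factor
  rownames(perfect) <- paste0("P", 1:4); colnames(perfect) <- ann_s$sample_id
  expect_equal(as.numeric(complexCohesiveness(perfect, paste0("P", 1:4))), 1,
               tolerance = 1e-12)
  indep <- matrix(rnorm(4 * nrow(ann_s)), 4,
                  dimnames = list(paste0("P", 1:4), ann_s$sample_id))
  expect_lt(abs(as.numeric(complexCohesiveness(indep, paste0("P", 1:4)))), 0.6)
})

test_that("cohesiveness equals a literal median-of-medians transcription", {
  set.seed(9)
  mat <- matrix(rnorm(6 * 12), 6, 12,
                dimnames = list(sprintf("P%d", 1:6), NULL))
  val <- complexCohesiveness(mat, sprintf("P%d", 1:6))
  # independent oracle: explicit loops over members
  ids <- sprintf("P%d", 1:6)
  per <- vapply(ids, function(m) {
    median(vapply(setdiff(ids, m), function(n)
      cor(mat[m, ], mat[n, ]), numeric(1)))
  }, numeric(1))
  expect_equal(as.numeric(val), median(per), tolerance = 1e-12)
  expect_equal(attr(val, "perProtein")[ids], per, tolerance = 1e-12)
})

test_that("cohesiveness is invariant to per-member affine rescaling", {
  set.seed(2)
  mat <- matrix(rnorm(5 * 10), 5, 10, dimnames = list(paste0("P", 1:5), NULL))
  v1 <- complexCohesiveness(mat, paste0("P", 1:5))
  mat2 <- mat * c(2, 10, 0.1, 5, 1) + c(-3, 0, 7, 1, 100)
  v2 <- complexCohesiveness(mat2, paste0("P", 1:5))
  expect_equal(as.numeric(v1), as.numeric(v2), tolerance = 1e-12)
})

test_that("zero-variance members are excluded; too few leads to NA with reason", {
  set.seed(3)
  mat <- matrix(rnorm(5 * 10), 5, 10, dimnames = list(paste0("P", 1:5), NULL))
  mat["P3", ] <- 4  # flat member
  v <- complexCohesiveness(mat, paste0("P", 1:5))
  expect_equal(attr(v, "nMembers"), 4)
  mat["P4", ] <- 0; mat["P5", ] <- -1
  v2 <- complexCohesiveness(mat, paste0("P", 1:5))
  expect_true(is.na(v2))
  expect_match(attr(v2, "reason"), "variance")
})

test_that("complex-wide abundance test finds a coherent shift and not a split one", {
  toy <- cohesionToy(loadOld = 0, loadYoung = 0, seed = 7)
  pq <- toy$pq
  old <- SummarizedExperiment::colData(pq)$age == "old"
  Y <- SummarizedExperiment::assay(pq, "log2ratio")
  Y[toy$members, old] <- Y[toy$members, old] + 0.8
  pq_up <- makeProteinQuant(Y, toy$ann)
  r <- testComplexAbundanceEffect(pq_up, toy$members, "age")
  expect_equal(r$coefficient, 0.8, tolerance = 0.2)
  expect_lt(r$p, 1e-4)
  # members split half up, half down cancel at the complex level
  Y2 <- SummarizedExperiment::assay(pq, "log2ratio")
  Y2[toy$members[1:2], old] <- Y2[toy$members[1:2], old] + 0.8
  Y2[toy$members[3:4], old] <- Y2[toy$members[3:4], old] - 0.8
  r2 <- testComplexAbundanceEffect(makeProteinQuant(Y2, toy$ann),
                                   toy$members[1:4], "age")
  expect_lt(abs(r2$coefficient), 0.25)
  expect_gt(r2$p, 0.05)
})

test_that("cohesiveness-change t-test matches a hand-built paired t oracle", {
  toy <- cohesionToy(loadOld = 1, loadYoung = 0, seed = 11)
  mat <- SummarizedExperiment::assay(toy$pq, "log2ratio")
  res <- testCohesivenessChange(mat, toy$members, toy$ann_s$age)
  # oracle: correlations per level computed member-pair by member-pair
  ids <- sort(toy$members)
  pairs <- combn(ids, 2)
  rlev <- function(lv) apply(pairs, 2, function(pp)
    cor(mat[pp[1], toy$ann_s$age == lv], mat[pp[2], toy$ann_s$age == lv]))
  tt <- t.test(rlev("young"), rlev("old"), paired = TRUE)
  expect_false(res$degenerate)
  expect_equal(res$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
  expect_lt(res$p, 0.01)  # the planted change is found
  # levels are sorted ("old" first), so effect = r_young - r_old < 0
  expect_lt(res$effect, -0.3)
})

test_that("degenerate cohesiveness differences are flagged, not tested", {
  ann <- toyAnnotation(nPerBatch = 4)
  ann_s <- ann[!ann$is_bridge, ]
  set.seed(21)
  f <- rnorm(nrow(ann_s))
  # members perfectly collinear in both groups: all pairwise r = 1
  mat <- outer(1:4, f) + 0
  rownames(mat) <- paste0("P", 1:4); colnames(mat) <- ann_s$sample_id
  res <- testCohesivenessChange(mat, paste0("P", 1:4), ann_s$age)
  expect_true(res$degenerate)
  expect_true(is.na(res$p))
})

test_that("stratified permutations preserve within-stratum label counts", {
  test_lab <- c("y", "y", "o", "o", "y", "o", "o", "y")
  stratum <- c("F", "F", "F", "F", "M", "M", "M", "M")
  sp <- stratifiedPermutations(test_lab, stratum, P = 100000)
  expect_true(sp$exact)
  expect_equal(ncol(sp$perms), choose(4, 2) * choose(4, 2))
  for (s in c("F", "M")) {
    idx <- stratum == s
    counts <- colSums(sp$perms[idx, , drop = FALSE] == "y")
    expect_true(all(counts == sum(test_lab[idx] == "y")))
  }
  expect_equal(anyDuplicated(apply(sp$perms, 2, paste, collapse = "")), 0)
  # Monte-Carlo branch (arrangements exceed P) also preserves counts
  test_lab2 <- rep(c("y", "o"), times = 8)
  stratum2 <- rep(c("F", "M"), each = 8)
  set.seed(6)
  sp2 <- stratifiedPermutations(test_lab2, stratum2, P = 150)
  expect_false(sp2$exact)
  expect_equal(ncol(sp2$perms), 150)
  for (s in c("F", "M")) {
    idx <- stratum2 == s
    expect_true(all(colSums(sp2$perms[idx, , drop = FALSE] == "y") ==
                      sum(test_lab2[idx] == "y")))
  }
  expect_error(stratifiedPermutations(c("y", "y", "o", "o"),
                                      c("a", "a", "b", "b"), 100),
               "no stratum is permutable")
})

test_that("vectorized permutation statistics equal a literal loop", {
  set.seed(13)
  n <- 16
  xm <- rnorm(n); xn <- rnorm(n)
  test_lab <- rep(c("o", "y"), each = n / 2)
  stratum <- rep(c("F", "M"), times = n / 2)
  sp <- stratifiedPermutations(test_lab, stratum, P = 500)
  fast <- permStatistics(xm, xn, sp$perms, sort(unique(test_lab)))
  slow <- apply(sp$perms, 2, function(lab) {
    g <- lab == "o"
    abs(abs(cor(xm[g], xn[g])) - abs(cor(xm[!g], xn[!g])))
  })
  expect_equal(fast, unname(slow), tolerance = 1e-12)
})

test_that("permutation p-values use the add-one rule and never reach zero", {
  toy <- cohesionToy(loadOld = 2, loadYoung = 0, noiseSd = 0.05, seed = 17)
  mat <- SummarizedExperiment::assay(toy$pq, "log2ratio")
  res <- permutationTestPair(mat[toy$members[1], ], mat[toy$members[2], ],
                             toy$ann_s$age, toy$ann_s$sex,
                             P = 400, seed = 99)
  expect_gt(res$p, 0)
  if (!res$exact) expect_gte(res$p, 1 / (res$P + 1))
  expect_lt(res$p, 0.02)  # extreme planted difference
  expect_equal(unname(res$r["old"]), 1, tolerance = 0.05)
  # determinism under the same seed
  res2 <- permutationTestPair(mat[toy$members[1], ], mat[toy$members[2], ],
                              toy$ann_s$age, toy$ann_s$sex,
                              P = 400, seed = 99)
  expect_identical(res$p, res2$p)
})

test_that("the permutation test is symmetric in the level labels", {
  toy <- cohesionToy(seed = 23)
  mat <- SummarizedExperiment::assay(toy$pq, "log2ratio")
  age <- toy$ann_s$age
  swapped <- ifelse(age == "old", "young", "old")
  r1 <- permutationTestPair(mat[toy$members[1], ], mat[toy$members[3], ],
                            age, toy$ann_s$sex, P = 300, seed = 5)
  r2 <- permutationTestPair(mat[toy$members[1], ], mat[toy$members[3], ],
                            swapped, toy$ann_s$sex, P = 300, seed = 5)
  expect_equal(r1$t_obs, r2$t_obs, tolerance = 1e-12)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
})

test_that("complexAnalysis assembles all result tables deterministically", {
  toy <- cohesionToy(seed = 29)
  cat <- complexCatalog(list(cplx = toy$members,
                             free = sprintf("FREE_P%02d", 1:5)))
  res <- complexAnalysis(toy$pq, cat, permutations = 120, seed = 42)
  expect_setequal(unique(res$cohesiveness$complex_id), c("cplx", "free"))
  # groups: all + 2 ages + 2 sexes
  expect_setequal(unique(res$cohesiveness$group),
                  c("all", "young", "old", "F", "M"))
  expect_equal(nrow(res$abundance), 2 * 2)
  expect_setequal(unique(res$cohesivenessChange$factor), c("age", "sex"))
  expect_equal(nrow(res$pairTests), 2 * 2 * choose(5, 2))
  expect_true(all(res$pairTests$perm_p > 0))
  res2 <- complexAnalysis(toy$pq, cat, permutations = 120, seed = 42)
  expect_identical(res$pairTests$perm_p, res2$pairTests$perm_p)
})

test_that("family-wise adjustment spans complexes and tissues per effect", {
  toy1 <- cohesionToy(seed = 31)
  toy2 <- cohesionToy(seed = 33)
  # give the second toy a different tissue label
  ann2 <- toy2$ann; ann2$tissue <- "kidney"
  ann2$sample_id <- sub("liver", "kidney", ann2$sample_id)
  vals2 <- SummarizedExperiment::assay(toy2$pq, "log2ratio")
  colnames(vals2) <- sub("liver", "kidney", colnames(vals2))
  pq2 <- makeProteinQuant(vals2, ann2, tissue = "kidney")
  cat <- complexCatalog(list(cplx = toy1$members))
  res <- adjustComplexFamilies(list(
    complexAnalysis(toy1$pq, cat), complexAnalysis(pq2, cat)))
  expect_setequal(unique(res$abundance$tissue), c("liver", "kidney"))
  for (e in c("age", "sex")) {
    i <- res$abundance$effect_type == e
    expect_equal(res$abundance$q[i], bhFdr(res$abundance$p[i]))
  }
  for (e in c("age", "sex")) {
    i <- res$cohesivenessChange$factor == e & !res$cohesivenessChange$degenerate
    expect_equal(res$cohesivenessChange$q[i],
                 bhFdr(res$cohesivenessChange$p[i]))
  }
  # degenerate rows keep NA q
  if (any(res$cohesivenessChange$degenerate))
    expect_true(all(is.na(
      res$cohesivenessChange$q[res$cohesivenessChange$degenerate])))
})
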