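# stacked multi-tissue toy data with known structure
stackedToy <- function(nMice = 12, nTissues = 3, mouseSd = 0.4,
                       residSd = 0.3, betaAge = 0.5, betaSex = -0.3,
                       seed = 1) {
  set.seed(seed)
  mice <- data.frame(
    mouse_id = sprintf("M%02d", seq_len(nMice)),
    old = rep(c(0, 1), each = nMice / 2),
    female = rep(c(0, 1), times = nMice / 2))
  u <- rnorm(nMice, 0, mouseSd)
  meta <- do.call(rbind, lapply(seq_len(nTissues), function(t)
    data.frame(mice, tissue = paste0("t", t))))
  tshift <- rep(seq_len(nTissues) * 0.2, each = nMice)
  y <- betaAge * meta$old + betaSex * meta$female + tshift +
    u[match(meta$mouse_id, mice$mouse_id)] +
    rnorm(nrow(meta), 0, residSd)
  list(y = y, meta = meta)
}

test_that("profiled-REML fit matches the lme4 oracle on random data", {
  for (seed in c(1, 2, 3)) {
    d <- stackedToy(seed = seed)
    fit <- fitCrossTissueLMM(d$y, d$meta)
    df <- data.frame(y = d$y, old = d$meta$old, female = d$meta$female,
                     tissue = factor(d$meta$tissue),
                     mouse = d$meta$mouse_id)
    oracle <- lme4::lmer(y ~ old + female + tissue + (1 | mouse), data = df,
                         REML = TRUE)
    expect_equal(unname(fit$beta), unname(lme4::fixef(oracle)),
                 tolerance = 1e-5)
    expect_equal(unname(fit$se),
                 unname(sqrt(diag(as.matrix(stats::vcov(oracle))))),
                 tolerance = 1e-5)
    vc <- as.data.frame(lme4::VarCorr(oracle))
    expect_equal(fit$tau2, vc$vcov[vc$grp == "mouse"], tolerance = 1e-4)
    expect_equal(fit$sigma2, vc$vcov[vc$grp == "Residual"], tolerance = 1e-4)
  }
})

test_that("Satterthwaite df and p agree with the lmerTest oracle", {
  d <- stackedToy(seed = 7)
  fit <- fitCrossTissueLMM(d$y, d$meta)
  s <- lmmSatterthwaite(fit, "old")
  df <- data.frame(y = d$y, old = d$meta$old, female = d$meta$female,
                   tissue = factor(d$meta$tissue), mouse = d$meta$mouse_id)
  oracle <- lmerTest::lmer(y ~ old + female + tissue + (1 | mouse), data = df)
  ct <- summary(oracle)$coefficients["old", ]
  expect_equal(s$estimate, unname(ct["Estimate"]), tolerance = 1e-5)
  expect_equal(s$se, unname(ct["Std. Error"]), tolerance = 1e-5)
  expect_equal(s$df, unname(ct["df"]), tolerance = 0.05)
  expect_equal(s$p, unname(ct["Pr(>|t|)"]), tolerance = 1e-3)
  expect_equal(s$method, "Satterthwaite")
})

test_that("with no mouse variance the fit collapses to OLS and is flagged", {
  d <- stackedToy(mouseSd = 0, seed = 11)
  fit <- fitCrossTissueLMM(d$y, d$meta)
  X <- cbind(1, d$meta$old, d$meta$female,
             stats::model.matrix(~factor(d$meta$tissue))[, -1])
  ols <- stats::lm.fit(X, d$y)
  # tau2 estimate should be at/near the boundary and beta near OLS
  expect_lt(fit$tau2 / fit$sigma2, 0.3)
  expect_equal(unname(fit$beta), unname(ols$coefficients), tolerance = 0.02)
  # exact boundary: refit at lambda = 0 equals OLS to float precision
  fit0 <- lmmFit(d$y, crossTissueDesign(
    data.frame(tissue = d$meta$tissue, old = d$meta$old,
               female = d$meta$female)), d$meta$mouse_id)
  expect_true(is.finite(fit0$logLik))
})

test_that("variance components are recovered from a large balanced design", {
  d <- stackedToy(nMice = 40, nTissues = 8, mouseSd = 0.5, residSd = 0.25,
                  seed = 5)
  fit <- fitCrossTissueLMM(d$y, d$meta)
  expect_equal(fit$tau2, 0.25, tolerance = 0.4)   # tau2 = 0.5^2, 40 mice
  expect_equal(fit$sigma2, 0.0625, tolerance = 0.15)
  expect_false(fit$singular)
})

test_that("ML LRT matches the lme4 anova oracle and is null-calibrated", {
  d <- stackedToy(seed = 9)
  X0 <- crossTissueDesign(d$meta)
  main <- d$meta$old
  Td <- X0[, grep("^tissue", colnames(X0)), drop = FALSE]
  X1 <- cbind(X0, Td * main)
  res <- lmmLRT(d$y, X1, X0, d$meta$mouse_id)
  df <- data.frame(y = d$y, old = d$meta$old, female = d$meta$female,
                   tissue = factor(d$meta$tissue), mouse = d$meta$mouse_id)
  m1 <- lme4::lmer(y ~ old + female + tissue + old:tissue + (1 | mouse),
                   data = df, REML = FALSE)
  m0 <- lme4::lmer(y ~ old + female + tissue + (1 | mouse),
                   data = df, REML = FALSE)
  a <- anova(m1, m0)
  expect_equal(res$chisq, a$Chisq[2], tolerance = 1e-3)
  expect_equal(res$df, a$Df[2])
  expect_equal(res$p, a$`Pr(>Chisq)`[2], tolerance = 1e-3)
})

test_that("a planted tissue-specific age effect is detected by the LRT", {
  d <- stackedToy(seed = 15, betaAge = 0)
  # strong age effect in tissue 1 only
  idx <- d$meta$tissue == "t1" & d$meta$old == 1
  d$y[idx] <- d$y[idx] + 1.5
  res <- testEffectByTissue(d$y, d$meta, "age")
  expect_lt(res$p, 1e-4)
  expect_equal(res$method, "LRT(ML)")
  # while a purely consistent effect does not trigger it
  d2 <- stackedToy(seed = 16, betaAge = 1.5)
  res2 <- testEffectByTissue(d2$y, d2$meta, "age")
  expect_gt(res2$p, 0.01)
})

test_that("an inestimable interaction is skipped, not mis-tested", {
  d <- stackedToy(nMice = 8, nTissues = 2, seed = 3)
  # make age perfectly aliased with tissue: old only measured in t2
  keep <- !(d$meta$old == 1 & d$meta$tissue == "t1") &
    !(d$meta$old == 0 & d$meta$tissue == "t2")
  res <- testEffectByTissue(d$y[keep], d$meta[keep, ], "age")
  expect_true(is.na(res$p))
  expect_match(res$method, "skipped")
})

test_that("stacking pads unobserved proteins with NA and tracks batches", {
  sim <- simulateStudy(smallConfig(seed = 19))
  pqs <- lapply(names(sim$peptides), function(t)
    quantifyTissue(sim$peptides[[t]], sim$annotation, t))
  st <- stackTissues(pqs)
  expect_equal(ncol(st$Y), sum(vapply(pqs, ncol, integer(1))))
  expect_equal(nrow(st$meta), ncol(st$Y))
  expect_setequal(unique(st$meta$batch_global),
                  as.vector(outer(names(sim$peptides), 1:2,
                                  function(t, b) paste0(t, "_b", b))))
  # a protein dropped in one tissue is NA exactly in that tissue's columns
  only1 <- setdiff(rownames(pqs[[1]]), rownames(pqs[[2]]))
  if (length(only1)) {
    p <- only1[1]
    expect_true(all(is.na(st$Y[p, st$meta$tissue == tissueName(pqs[[2]])])))
    expect_true(all(!is.na(st$Y[p, st$meta$tissue == tissueName(pqs[[1]])])))
  }
  # observed values match the per-tissue assays
  expect_equal(unname(st$Y[rownames(pqs[[1]]), st$meta$tissue ==
                             tissueName(pqs[[1]])]),
               unname(SummarizedExperiment::assay(pqs[[1]], "log2ratio")))
})

test_that("cross-tissue effects recover a consistent planted age effect", {
  sim <- simulateStudy(smallConfig(nTissues = 3, nProteins = 30,
                                   propAffected = 0, seed = 23))
  pqs <- lapply(names(sim$peptides), function(t)
    quantifyTissue(sim$peptides[[t]], sim$annotation, t))
  # plant a +1 age shift on one protein in every tissue
  target <- Reduce(intersect, lapply(pqs, rownames))[1]
  pqs <- lapply(pqs, function(pq) {
    old <- SummarizedExperiment::colData(pq)$age == "old"
    SummarizedExperiment::assay(pq, "log2ratio")[target, old] <-
      SummarizedExperiment::assay(pq, "log2ratio")[target, old] + 1
    pq
  })
  res <- crossTissueEffects(pqs)
  row <- res[res$protein_id == target, ]
  expect_equal(row$consistent_age_coef, 1, tolerance = 0.25)
  expect_lt(row$consistent_age_p, 1e-4)
  expect_equal(row$n_tissues_observed, 3)
  # q columns are BH within each family
  expect_equal(res$consistent_age_q, bhFdr(res$consistent_age_p))
  expect_equal(res$age_by_tissue_q, bhFdr(res$age_by_tissue_p))
  # proteins observed in a single tissue are excluded
  expect_true(all(res$n_tissues_observed >= 2))
})

test_that("variance decomposition fractions sum to one and rank the planted component", {
  sim <- simulateStudy(smallConfig(nTissues = 3, nProteins = 25,
                                   mouseSd = 0.6, tagSd = 0.05,
                                   batchSd = 0.05, residualSd = 0.15,
                                   propAffected = 0, seed = 27))
  pqs <- lapply(names(sim$peptides), function(t)
    quantifyTissue(sim$peptides[[t]], sim$annotation, t))
  vd <- varianceDecomposition(pqs)
  expect_gt(nrow(vd$varp), 5)
  sums <- vd$varp$varp_mouse + vd$varp$varp_tag + vd$varp$varp_batch +
    vd$varp$varp_residual
  expect_equal(sums, rep(1, nrow(vd$varp)), tolerance = 1e-8)
  # with mouseSd dominant, the mouse fraction should dominate on median
  expect_gt(median(vd$varp$varp_mouse), median(vd$varp$varp_tag))
  expect_gt(median(vd$varp$varp_mouse), median(vd$varp$varp_batch))
  expect_gt(median(vd$varp$varp_mouse), 0.3)
})

test_that("BLUPs are shrunken mouse means with finite intervals", {
  sim <- simulateStudy(smallConfig(nTissues = 3, nProteins = 20,
                                   mouseSd = 0.5, propAffected = 0,
                                   seed = 31))
  pqs <- lapply(names(sim$peptides), function(t)
    quantifyTissue(sim$peptides[[t]], sim$annotation, t))
  vd <- varianceDecomposition(pqs)
  b <- vd$blups[vd$blups$factor == "mouse", ]
  expect_gt(nrow(b), 0)
  expect_true(all(is.finite(b$estimate) & b$lower <= b$estimate &
                    b$estimate <= b$upper))
  # BLUPs per protein are centered (random effects sum to ~0)
  cent <- tapply(b$estimate, b$protein_id, mean)
  expect_lt(max(abs(cent)), 0.2)
  # shrinkage: BLUP magnitude does not exceed the raw mouse-mean deviation
  # (checked on a protein whose mouse component is away from the boundary)
  st <- stackTissues(pqs)
  p0 <- vd$varp$protein_id[!vd$varp$singular & vd$varp$varp_mouse > 0.2][1]
  expect_false(is.na(p0))
  raw <- tapply(st$Y[p0, ] - mean(st$Y[p0, ]), st$meta$mouse_id, mean)
  bl <- b[b$protein_id == p0, ]
  raw <- raw[bl$level]
  # shrinkage in aggregate: the BLUP spread is below the raw-mean spread
  # (raw mouse means also carry tag/batch noise, so the comparison is
  # aggregate, not element-wise), and the two track each other
  expect_lt(stats::sd(bl$estimate), stats::sd(raw))
  expect_gt(stats::cor(bl$estimate, raw), 0.7)
})
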