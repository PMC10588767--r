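#' Restrict a complex catalog to members observed in a tissue
#'
#' Keeps, per tissue, the complexes with at least `minMembers` member
#' proteins present in the quantification object (members without a match
#' are dropped with a warning the first time they are seen).
#'
#' @param catalog a [ComplexCatalog-class].
#' @param x a [ProteinQuant-class].
#' @param minMembers minimum observed members (default 4, i.e. "more than
#'   three").
#' @return named list: complex id -> observed member ids.
#' @export
filterComplexes <- function(catalog, x, minMembers = 4) {
  obs <- lapply(members(catalog), intersect, y = rownames(x))
  dropped <- sum(lengths(members(catalog)) - lengths(obs))
  if (dropped > 0)
    message(dropped, " catalog member(s) not observed in ", tissueName(x))
  obs[lengths(obs) >= minMembers]
}

pairwiseCor <- function(mat, samples = NULL) {
  sub <- if (is.null(samples)) mat else mat[, samples, drop = FALSE]
  cor(t(sub))
}

#' Complex cohesiveness: median of member-wise median correlations
#'
#' For each member protein, the median Pearson correlation between it and
#' every other member across the selected samples; the complex summary is
#' the median of those per-member medians. Members with zero variance in
#' the subset carry no correlation information and are excluded; if fewer
#' than `minMembers` remain, `NA` is returned with the reason as an
#' attribute.
#'
#' @param mat proteins x samples abundance matrix (typically the
#'   batch-adjusted assay).
#' @param memberIds member protein ids (rows of `mat`).
#' @param samples optional column subset (e.g. one age group).
#' @param minMembers minimum usable members (default 4).
#' @return single numeric in `[-1, 1]`; attributes `perProtein` (the
#'   member-wise medians) and `nMembers`.
#' @examples
#' m <- matrix(rnorm(40), 4, 10, dimnames = list(paste0("P", 1:4), NULL))
#' complexCohesiveness(m, paste0("P", 1:4))
#' @export
complexCohesiveness <- function(mat, memberIds, samples = NULL,
                                minMembers = 4) {
  memberIds <- intersect(memberIds, rownames(mat))
  sub <- mat[memberIds, , drop = FALSE]
  if (!is.null(samples)) sub <- sub[, samples, drop = FALSE]
  keep <- apply(sub, 1, function(v) var(v) > 0)
  if (sum(keep) < minMembers)
    return(structure(NA_real_, reason = "fewer than minMembers members with variance",
                     nMembers = sum(keep)))
  cc <- cor(t(sub[keep, , drop = FALSE]))
  diag(cc) <- NA
  per <- apply(cc, 1, median, na.rm = TRUE)
  structure(median(per), perProtein = per, nMembers = sum(keep))
}

#' Complex-wide abundance effect (joint mixed model)
#'
#' Stacks all member proteins' abundances and fits (REML, lmerTest)
#' `abundance ~ age + sex + (1 | mouse) + (1 | protein)`; the age or sex
#' fixed effect is tested with Satterthwaite degrees of freedom. This
#' targets shifts that are consistent across the complex: members moving in
#' opposite directions cancel.
#'
#' @param x a [ProteinQuant-class].
#' @param memberIds observed member protein ids.
#' @param effect `"age"` or `"sex"`.
#' @param assayName assay to model (default `"log2ratio"`, the normalized
#'   but not batch-adjusted values).
#' @return list with `coefficient`, `se`, `p`, `df`, `singular`.
#' @export
testComplexAbundanceEffect <- function(x, memberIds,
                                       effect = c("age", "sex"),
                                       assayName = "log2ratio") {
  effect <- match.arg(effect)
  memberIds <- intersect(memberIds, rownames(x))
  stopifnot(length(memberIds) >= 4)
  Y <- SummarizedExperiment::assay(x, assayName)[memberIds, , drop = FALSE]
  ann <- as.data.frame(SummarizedExperiment::colData(x))
  ind <- designIndicators(ann)
  d <- data.frame(y = as.vector(t(Y)),
                  old = rep(ind$old, length(memberIds)),
                  female = rep(ind$female, length(memberIds)),
                  mouse = factor(rep(ann$mouse_id, length(memberIds))),
                  protein = factor(rep(memberIds, each = ncol(Y))))
  m <- suppressMessages(lmerTest::lmer(
    y ~ old + female + (1 | mouse) + (1 | protein), data = d,
    control = lme4::lmerControl(check.conv.singular = "ignore")))
  co <- stats::coef(summary(m))
  term <- if (effect == "age") "old" else "female"
  list(coefficient = unname(co[term, "Estimate"]),
       se = unname(co[term, "Std. Error"]),
       p = unname(co[term, "Pr(>|t|)"]), df = unname(co[term, "df"]),
       singular = lme4::isSingular(m))
}

memberPairs <- function(memberIds) {
  cb <- combn(sort(memberIds), 2)
  data.frame(protein_m = cb[1, ], protein_n = cb[2, ])
}

#' Paired t-test for a change in complex correlation structure
#'
#' Computes all unique pairwise Pearson correlations between members within
#' each level of the factor (age groups pool both sexes; sex groups pool
#' both ages) and compares the two sets with a paired t-test across pairs
#' (second level minus first). If every pairwise difference is identical
#' the t-statistic is undefined; the result is flagged degenerate and must
#' be excluded from the FDR family by the caller.
#'
#' @param mat proteins x samples matrix (typically the batch-adjusted
#'   assay).
#' @param memberIds observed member ids (>= 4).
#' @param fac per-sample factor values (e.g. age), aligned with `mat`
#'   columns.
#' @param levels the two factor levels to compare, in order (difference =
#'   level 2 - level 1).
#' @return list with `t`, `p`, `effect` (mean difference), `degenerate`,
#'   and `pairs` (per-pair correlations in both levels).
#' @export
testCohesivenessChange <- function(mat, memberIds, fac,
                                   levels = sort(unique(as.character(fac)))) {
  stopifnot(length(memberIds) >= 4, length(levels) == 2)
  fac <- as.character(fac)
  idx1 <- which(fac == levels[1]); idx2 <- which(fac == levels[2])
  stopifnot(length(idx1) >= 4, length(idx2) >= 4)
  c1 <- pairwiseCor(mat[memberIds, , drop = FALSE], idx1)
  c2 <- pairwiseCor(mat[memberIds, , drop = FALSE], idx2)
  lower <- lower.tri(c1)
  pairs <- memberPairs(memberIds)
  r1 <- c1[lower]; r2 <- c2[lower]
  pairs$r_level1 <- r1; pairs$r_level2 <- r2
  diffs <- r2 - r1
  if (sd(diffs) < 1e-12 || anyNA(diffs))
    return(list(t = NA_real_, p = NA_real_, effect = mean(diffs),
                degenerate = TRUE, pairs = pairs))
  tt <- t.test(r2, r1, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       effect = unname(tt$estimate), degenerate = FALSE, pairs = pairs)
}

# stratified label permutations at the mouse level: the tested factor's
# labels are shuffled within each stratum of the other factor
stratifiedPermutations <- function(test_lab, stratum, P) {
  n <- length(test_lab)
  strata <- split(seq_len(n), stratum)
  counts <- vapply(strata, function(ix) {
    k <- sum(test_lab[ix] == sort(unique(test_lab))[1]); length(ix)
  }, numeric(1))
  n_arr <- prod(vapply(strata, function(ix)
    choose(length(ix), sum(test_lab[ix] == unique(test_lab)[1])), numeric(1)))
  if (!any(vapply(strata, function(ix) length(unique(test_lab[ix])) > 1,
                  logical(1))))
    stop("no stratum is permutable: the tested factor is constant within every stratum")
  if (is.finite(n_arr) && n_arr <= P) {
    # exhaustive enumeration of within-stratum label arrangements
    per_stratum <- lapply(strata, function(ix) {
      lv1 <- sort(unique(test_lab))[1]
      k <- sum(test_lab[ix] == lv1)
      ch <- combn(length(ix), k)
      lapply(seq_len(ncol(ch)), function(j) {
        lab <- rep(sort(unique(test_lab))[min(2, length(unique(test_lab)))],
                   length(ix))
        lab[ch[, j]] <- lv1
        lab
      })
    })
    grid <- expand.grid(lapply(per_stratum, seq_along))
    perms <- matrix(NA_character_, n, nrow(grid))
    for (r in seq_len(nrow(grid))) {
      lab <- character(n)
      for (s in seq_along(strata))
        lab[strata[[s]]] <- per_stratum[[s]][[grid[r, s]]]
      perms[, r] <- lab
    }
    list(perms = perms, exact = TRUE)
  } else {
    perms <- matrix(NA_character_, n, P)
    for (r in seq_len(P)) {
      lab <- character(n)
      for (s in seq_along(strata)) {
        ix <- strata[[s]]
        lab[ix] <- test_lab[ix][sample.int(length(ix))]
      }
      perms[, r] <- lab
    }
    list(perms = perms, exact = FALSE)
  }
}

#' Stratified permutation test for a change in pairwise correlation
#'
#' Tests whether the correlation between two proteins differs between the
#' two levels of a factor (age or sex) using label permutations stratified
#' by the other factor: when testing age, mouse labels are swapped among
#' males and among females separately (and vice versa), preserving the
#' untested factor's effect. The statistic is
#' `T = | |r(level 1)| - |r(level 2)| |` on absolute Pearson correlations.
#' The Monte-Carlo p-value uses the add-one convention
#' `p = (1 + #{T_perm >= T_obs}) / (P + 1)` and is therefore never 0; when
#' the stratified arrangements number at most `P` they are enumerated
#' exhaustively and the p-value is exact.
#'
#' @param xm,xn numeric abundances of proteins m and n across samples.
#' @param testFac per-sample values of the tested factor (two levels, each
#'   with >= 4 samples).
#' @param stratumFac per-sample values of the stratifying factor.
#' @param P number of permutations (default 100000; at least 100).
#' @param seed optional integer seed recorded with the result.
#' @return list with `p`, `t_obs`, `r` (named observed correlations per
#'   level), `exact`, `P`, `seed`.
#' @export
permutationTestPair <- function(xm, xn, testFac, stratumFac, P = 100000,
                                seed = NULL) {
  stopifnot(P >= 100, length(xm) == length(xn))
  testFac <- as.character(testFac)
  levs <- sort(unique(testFac))
  stopifnot(length(levs) == 2, all(table(testFac) >= 4))
  if (!is.null(seed)) set.seed(seed)
  corAbsByGroup <- function(lab) {
    g1 <- lab == levs[1]
    c(abs(cor(xm[g1], xn[g1])), abs(cor(xm[!g1], xn[!g1])))
  }
  obs <- corAbsByGroup(testFac)
  t_obs <- abs(obs[1] - obs[2])
  sp <- stratifiedPermutations(testFac, stratumFac, P)
  t_perm <- permStatistics(xm, xn, sp$perms, levs)
  p <- if (sp$exact) mean(t_perm >= t_obs - 1e-12)
       else (1 + sum(t_perm >= t_obs - 1e-12)) / (ncol(sp$perms) + 1)
  list(p = p, t_obs = t_obs, r = setNames(obs, levs), exact = sp$exact,
       P = ncol(sp$perms), seed = seed)
}

# vectorized | |r1| - |r2| | over permutation columns
permStatistics <- function(xm, xn, perms, levs) {
  M1 <- perms == levs[1]
  corGroup <- function(M) {
    k <- colSums(M)
    sx <- crossprod(M, xm); sy <- crossprod(M, xn)
    sxx <- crossprod(M, xm^2); syy <- crossprod(M, xn^2)
    sxy <- crossprod(M, xm * xn)
    num <- sxy - sx * sy / k
    den <- sqrt(pmax(sxx - sx^2 / k, 0) * pmax(syy - sy^2 / k, 0))
    drop(num / den)
  }
  abs(abs(corGroup(M1)) - abs(corGroup(!M1)))
}

#' Full complex analysis for one tissue
#'
#' Runs the complex pipeline in one tissue: member filtering, cohesiveness
#' in all samples and per group (age and sex strata), complex-wide
#' abundance tests, cohesiveness-change paired t-tests, and (optionally)
#' stratified permutation tests for every member pair. q-values for the
#' abundance and cohesiveness families are computed by the caller across
#' tissues ([adjustComplexFamilies()]).
#'
#' @param x a [ProteinQuant-class] (with `"adjusted"` assay for
#'   correlations).
#' @param catalog a [ComplexCatalog-class].
#' @param permutations permutations per pair (0 disables pair tests).
#' @param seed master seed for the per-pair permutation substreams (derived
#'   from pair identity, so results do not depend on execution order).
#' @param useAdjusted correlate batch-adjusted abundances (default TRUE);
#'   set FALSE to use the raw normalized values.
#' @return list of data.frames: `cohesiveness`, `abundance`,
#'   `cohesivenessChange`, `pairTests`.
#' @export
complexAnalysis <- function(x, catalog, permutations = 0, seed = 1,
                            useAdjusted = TRUE) {
  assayCor <- if (useAdjusted && "adjusted" %in%
                  SummarizedExperiment::assayNames(x)) "adjusted" else "log2ratio"
  mat <- SummarizedExperiment::assay(x, assayCor)
  ann <- as.data.frame(SummarizedExperiment::colData(x))
  obs <- filterComplexes(catalog, x)
  tis <- tissueName(x)
  groups <- list(all = rep(TRUE, ncol(mat)))
  for (lv in unique(ann$age)) groups[[lv]] <- ann$age == lv
  for (lv in unique(ann$sex)) groups[[lv]] <- ann$sex == lv

  coh <- do.call(rbind, lapply(names(obs), function(cid) {
    do.call(rbind, lapply(names(groups), function(gname) {
      val <- complexCohesiveness(mat, obs[[cid]], which(groups[[gname]]))
      data.frame(complex_id = cid, tissue = tis, group = gname,
                 n_members_observed = attr(val, "nMembers"),
                 cohesiveness = as.numeric(val))
    }))
  }))

  abund <- do.call(rbind, lapply(names(obs), function(cid) {
    do.call(rbind, lapply(c("age", "sex"), function(eff) {
      r <- testComplexAbundanceEffect(x, obs[[cid]], eff)
      data.frame(complex_id = cid, tissue = tis, effect_type = eff,
                 coefficient = r$coefficient, se = r$se, p = r$p,
                 singular = r$singular)
    }))
  }))

  chg <- do.call(rbind, lapply(names(obs), function(cid) {
    do.call(rbind, lapply(c("age", "sex"), function(eff) {
      fac <- if (eff == "age") ann$age else ann$sex
      r <- tryCatch(testCohesivenessChange(mat, obs[[cid]], fac),
                    error = function(e) NULL)
      if (is.null(r)) return(NULL)
      data.frame(complex_id = cid, tissue = tis, factor = eff,
                 t_statistic = r$t, effect = r$effect, p = r$p,
                 degenerate = r$degenerate)
    }))
  }))

  pairs <- NULL
  if (permutations > 0 && length(obs)) {
    pairs <- do.call(rbind, lapply(names(obs), function(cid) {
      pr <- memberPairs(obs[[cid]])
      do.call(rbind, lapply(c("age", "sex"), function(eff) {
        testFac <- if (eff == "age") ann$age else ann$sex
        stratum <- if (eff == "age") ann$sex else ann$age
        res <- lapply(seq_len(nrow(pr)), function(k) {
          pseed <- substreamSeed(seed, paste("pair", tis, cid, eff,
                                             pr$protein_m[k], pr$protein_n[k]))
          permutationTestPair(mat[pr$protein_m[k], ], mat[pr$protein_n[k], ],
                              testFac, stratum, P = permutations,
                              seed = pseed)
        })
        data.frame(complex_id = cid, tissue = tis, factor = eff,
                   protein_m = pr$protein_m, protein_n = pr$protein_n,
                   r_level1 = vapply(res, function(r) r$r[1], numeric(1)),
                   r_level2 = vapply(res, function(r) r$r[2], numeric(1)),
                   t_obs = vapply(res, function(r) r$t_obs, numeric(1)),
                   perm_p = vapply(res, function(r) r$p, numeric(1)),
                   exact = vapply(res, function(r) r$exact, logical(1)))
      }))
    }))
  }
  list(cohesiveness = coh, abundance = abund, cohesivenessChange = chg,
       pairTests = pairs)
}

#' Benjamini-Hochberg adjustment across complexes and tissues
#'
#' Abundance tests are adjusted across complexes x tissues per effect type;
#' cohesiveness-change t-tests likewise per factor, with degenerate rows
#' (undefined t) excluded from the family. Pair permutation p-values are
#' reported unadjusted.
#'
#' @param results list of per-tissue results from [complexAnalysis()].
#' @return list with combined `abundance` (with `q`), `cohesivenessChange`
#'   (with `q`), `cohesiveness` and `pairTests` tables.
#' @export
adjustComplexFamilies <- function(results) {
  abund <- do.call(rbind, lapply(results, `[[`, "abundance"))
  chg <- do.call(rbind, lapply(results, `[[`, "cohesivenessChange"))
  coh <- do.call(rbind, lapply(results, `[[`, "cohesiveness"))
  pairs <- do.call(rbind, lapply(results, `[[`, "pairTests"))
  if (!is.null(abund)) {
    abund$q <- NA_real_
    for (e in unique(abund$effect_type)) {
      i <- abund$effect_type == e
      abund$q[i] <- bhFdr(abund$p[i])
    }
  }
  if (!is.null(chg)) {
    chg$q <- NA_real_
    for (e in unique(chg$factor)) {
      i <- chg$factor == e & !chg$degenerate
      chg$q[i] <- bhFdr(chg$p[i])
    }
  }
  list(abundance = abund, cohesivenessChange = chg, cohesiveness = coh,
       pairTests = pairs)
}
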