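# Linear mixed model with a single random intercept, fit by profiled REML.
#
# The cross-tissue model (abundance ~ age + sex + tissue + mouse random
# intercept) is fit for thousands of proteins, so the per-fit cost matters.
# With one grouping factor the covariance is V = sigma2 (I + lambda Z Z'),
# and (I + lambda Z Z')^-1 has the closed group-wise form
# v - lambda/(1 + lambda n_g) * groupsum(v), which reduces each criterion
# evaluation to one rowsum and one p x p Cholesky. REML (or ML) is then a
# 1-D optimization over log(lambda). Satterthwaite denominator df for a
# fixed-effect contrast come from the delta method: the asymptotic
# covariance of (sigma2, tau2) is twice the inverse hessian of the REML
# -2 log-likelihood, and df = 2 g^2 / (grad' Vcov grad) with
# g = Var(c'beta). Cross-checked against lmerTest in the test suite.

lmmCriterion <- function(lambda, y, X, g, ng, reml) {
  n <- length(y); p <- ncol(X)
  A <- cbind(y, X)
  GS <- rowsum(A, g)                       # m x (p+1) group sums
  shrink <- lambda / (1 + lambda * ng)
  WA <- A - GS[g, , drop = FALSE] * shrink[g]
  M <- crossprod(A, WA)
  XtWX <- M[-1, -1, drop = FALSE]; XtWy <- M[-1, 1]; ytWy <- M[1, 1]
  R <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(R)) return(list(value = Inf))
  b <- forwardsolve(t(R), XtWy)
  quad <- max(ytWy - sum(b^2), 1e-300)
  logdetV0 <- sum(log1p(lambda * ng))
  if (reml) {
    s2 <- quad / (n - p)
    val <- (n - p) * (log(2 * pi * s2) + 1) + logdetV0 +
      2 * sum(log(diag(R)))
  } else {
    s2 <- quad / n
    val <- n * (log(2 * pi * s2) + 1) + logdetV0
  }
  list(value = val, s2 = s2, R = R, beta = backsolve(R, b), quad = quad,
       XtWX = XtWX)
}

# full (unprofiled) REML -2 log-likelihood in (sigma2, tau2)
lmmNeg2REML <- function(sigma2, tau2, y, X, g, ng) {
  n <- length(y); p <- ncol(X)
  cr <- lmmCriterion(tau2 / sigma2, y, X, g, ng, reml = TRUE)
  if (!is.finite(cr$value)) return(Inf)
  (n - p) * log(2 * pi) + (n - p) * log(sigma2) +
    sum(log1p(tau2 / sigma2 * ng)) + 2 * sum(log(diag(cr$R))) +
    cr$quad / sigma2
}

#' Fit a linear mixed model with one random intercept
#'
#' Profiled (RE)ML over the variance ratio for the model
#' `y = X beta + Z u + e`, `u ~ N(0, tau2)` per level of `group`,
#' `e ~ N(0, sigma2)`. Used for the cross-tissue protein model; the
#' boundary fit `tau2 = 0` is retained and flagged `singular`.
#'
#' @param y numeric response.
#' @param X design matrix (full column rank).
#' @param group grouping factor for the random intercept.
#' @param reml REML (default) or ML.
#' @return object of class `lmm1` with elements `beta`, `se`, `vcovBeta`,
#'   `sigma2`, `tau2`, `logLik` (-2 log-likelihood), `singular`, `n`, `p`.
#' @export
lmmFit <- function(y, X, group, reml = TRUE) {
  g <- as.integer(factor(group))
  ng <- tabulate(g)
  n <- length(y); p <- ncol(X)
  stopifnot(n == nrow(X), n > p)
  if (qr(X)$rank < p) stop("fixed-effect design is rank deficient")
  obj <- function(ll) lmmCriterion(exp(ll), y, X, g, ng, reml)$value
  opt <- optimize(obj, interval = c(-15, 15), tol = 1e-9)
  cand <- list(c(exp(opt$minimum), opt$objective),
               c(0, lmmCriterion(0, y, X, g, ng, reml)$value))
  best <- cand[[which.min(vapply(cand, `[`, numeric(1), 2))]]
  lambda <- best[1]
  cr <- lmmCriterion(lambda, y, X, g, ng, reml)
  XtWXinv <- chol2inv(cr$R)
  vcovBeta <- cr$s2 * XtWXinv
  beta <- drop(cr$beta); names(beta) <- colnames(X)
  structure(list(beta = beta, se = sqrt(diag(vcovBeta)),
                 vcovBeta = vcovBeta, sigma2 = cr$s2,
                 tau2 = lambda * cr$s2, lambda = lambda,
                 logLik = cr$value, singular = lambda < 1e-8,
                 n = n, p = p, reml = reml,
                 y = y, X = X, g = g, ng = ng),
            class = "lmm1")
}

#' Satterthwaite test of a fixed-effect contrast in an `lmm1` fit
#'
#' Two-sided t-test of `c' beta = 0` with denominator degrees of freedom
#' from Satterthwaite's approximation: `df = 2 g^2 / Var(g)` where
#' `g = Var(c' beta)` as a function of the variance components and
#' `Var(g)` comes from the delta method with the asymptotic covariance of
#' `(sigma2, tau2)` (twice the inverse numeric hessian of the REML
#' -2 log-likelihood). Falls back to a normal reference (flagged) if the
#' approximation yields a non-finite or non-positive df.
#'
#' @param fit an `lmm1` object from [lmmFit()] (REML).
#' @param contrast coefficient name or numeric contrast vector.
#' @return list with `estimate`, `se`, `t`, `df`, `p`, `method`.
#' @export
lmmSatterthwaite <- function(fit, contrast) {
  if (is.character(contrast)) {
    cvec <- as.numeric(names(fit$beta) == contrast)
    if (sum(cvec) != 1) stop("unknown coefficient: ", contrast)
  } else cvec <- contrast
  est <- sum(cvec * fit$beta)
  gfun <- function(s2, t2) {
    cr <- lmmCriterion(t2 / s2, fit$y, fit$X, fit$g, fit$ng, reml = TRUE)
    s2 * drop(crossprod(cvec, chol2inv(cr$R) %*% cvec))
  }
  theta <- c(fit$sigma2, fit$tau2)
  h <- pmax(1e-8, 1e-4 * pmax(theta, fit$sigma2))
  f <- function(th) lmmNeg2REML(th[1], max(th[2], 0), fit$y, fit$X,
                                fit$g, fit$ng)
  H <- numericHessian(f, theta, h)
  grad <- numericGradient(function(th) gfun(th[1], max(th[2], 0)), theta, h)
  g0 <- gfun(theta[1], theta[2])
  vcov_th <- tryCatch(2 * solve(H), error = function(e) NULL)
  df <- if (is.null(vcov_th)) NA_real_ else {
    denom <- drop(crossprod(grad, vcov_th %*% grad))
    if (denom <= 0) NA_real_ else 2 * g0^2 / denom
  }
  tval <- est / sqrt(g0)
  if (!is.finite(df) || df <= 1e-6) {
    p <- 2 * stats::pnorm(-abs(tval)); method <- "z"
  } else {
    p <- 2 * pt(-abs(tval), df); method <- "Satterthwaite"
  }
  list(estimate = est, se = sqrt(g0), t = tval, df = df, p = p,
       method = method)
}

numericHessian <- function(f, x, h) {
  k <- length(x)
  H <- matrix(NA_real_, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) for (j in i:k) {
    ei <- ej <- numeric(k); ei[i] <- h[i]; ej[j] <- h[j]
    # forward-biased stencil keeps tau2 >= 0 at the boundary
    if (i == j) {
      H[i, i] <- (f(x + 2 * ei) - 2 * f(x + ei) + f0) / h[i]^2
    } else {
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei) - f(x + ej) + f0) / (h[i] * h[j])
    }
  }
  H
}

numericGradient <- function(f, x, h) {
  vapply(seq_along(x), function(i) {
    ei <- numeric(length(x)); ei[i] <- h[i]
    (f(x + ei) - f(x)) / h[i]
  }, numeric(1))
}

#' ML likelihood-ratio test between nested `lmm1` designs
#'
#' Both models are (re)fit by maximum likelihood; the statistic is referred
#' to a chi-square with df equal to the difference in fixed-effect columns.
#' Used for the multi-df age-by-tissue and sex-by-tissue tests.
#'
#' @param y,group response and grouping factor shared by both models.
#' @param Xfull,Xreduced nested design matrices.
#' @return list with `chisq`, `df`, `p`, `method = "LRT(ML)"`.
#' @export
lmmLRT <- function(y, Xfull, Xreduced, group) {
  f1 <- lmmFit(y, Xfull, group, reml = FALSE)
  f0 <- lmmFit(y, Xreduced, group, reml = FALSE)
  stat <- max(f0$logLik - f1$logLik, 0)
  df <- ncol(Xfull) - ncol(Xreduced)
  list(chisq = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE),
       method = "LRT(ML)")
}

crossTissueDesign <- function(meta) {
  tis <- factor(meta$tissue)
  X <- cbind(`(Intercept)` = 1, old = meta$old, female = meta$female)
  if (nlevels(tis) > 1) {
    Td <- stats::model.matrix(~tis)[, -1, drop = FALSE]
    colnames(Td) <- paste0("tissue", levels(tis)[-1])
    X <- cbind(X, Td)
  }
  X
}

#' Fit the cross-tissue model for one protein
#'
#' REML fit of `abundance ~ age + sex + tissue (fixed) + mouse (random
#' intercept)` over the tissues in which the protein was observed. Batch is
#' deliberately absent: batches are nested in tissues, so the tissue term
#' absorbs their marginal effect.
#'
#' @param values numeric abundances (stacked across tissues).
#' @param meta data.frame with `tissue`, `mouse_id`, `old`, `female` (0/1)
#'   aligned with `values`.
#' @return an `lmm1` fit with an attribute `meta`.
#' @export
fitCrossTissueLMM <- function(values, meta) {
  stopifnot(length(unique(meta$tissue)) >= 2)
  fit <- lmmFit(values, crossTissueDesign(meta), meta$mouse_id, reml = TRUE)
  attr(fit, "meta") <- meta
  fit
}

#' Test a consistent (cross-tissue) age or sex effect
#'
#' Single-df Satterthwaite t-test of the age (or sex) coefficient of a
#' [fitCrossTissueLMM()] fit; equivalent to the F-test comparing the model
#' with and without that term.
#'
#' @param fit an `lmm1` from [fitCrossTissueLMM()].
#' @param effect `"age"` or `"sex"`.
#' @return list with `coefficient`, `se`, `p`, `df`, `method`.
#' @export
testConsistentEffect <- function(fit, effect = c("age", "sex")) {
  effect <- match.arg(effect)
  term <- if (effect == "age") "old" else "female"
  s <- lmmSatterthwaite(fit, term)
  list(coefficient = s$estimate, se = s$se, p = s$p, df = s$df,
       method = s$method)
}

#' Test tissue-specific (interaction) age or sex effects
#'
#' Compares the cross-tissue model plus an age-by-tissue (or sex-by-tissue)
#' interaction against the base model by an ML likelihood-ratio test with a
#' chi-square reference on #tissues - 1 df.
#'
#' @param values,meta as in [fitCrossTissueLMM()].
#' @param effect `"age"` or `"sex"`.
#' @return list with `p`, `chisq`, `df`, `method`.
#' @export
testEffectByTissue <- function(values, meta, effect = c("age", "sex")) {
  effect <- match.arg(effect)
  X0 <- crossTissueDesign(meta)
  main <- if (effect == "age") meta$old else meta$female
  Td <- X0[, grep("^tissue", colnames(X0)), drop = FALSE]
  Xi <- Td * main
  colnames(Xi) <- paste0(if (effect == "age") "old:" else "female:",
                         colnames(Td))
  X1 <- cbind(X0, Xi)
  if (qr(X1)$rank < ncol(X1))
    return(list(p = NA_real_, chisq = NA_real_, df = NA_integer_,
                method = "skipped: interaction inestimable"))
  lmmLRT(values, X1, X0, meta$mouse_id)
}

# stack per-tissue assays into one proteins x (tissue, sample) matrix
stackTissues <- function(pqList, assayName = "log2ratio") {
  proteins <- sort(unique(unlist(lapply(pqList, rownames))))
  metas <- lapply(pqList, function(pq) {
    cd <- as.data.frame(SummarizedExperiment::colData(pq))
    ind <- designIndicators(cd)
    data.frame(sample_id = cd$sample_id, tissue = tissueName(pq),
               mouse_id = cd$mouse_id, tag = cd$tag,
               batch_global = paste0(tissueName(pq), "_b", cd$batch),
               old = ind$old, female = ind$female)
  })
  meta <- do.call(rbind, metas)
  rownames(meta) <- NULL
  Y <- matrix(NA_real_, length(proteins), nrow(meta),
              dimnames = list(proteins, paste0(meta$tissue, ":", meta$sample_id)))
  off <- 0
  for (pq in pqList) {
    k <- ncol(pq)
    Y[rownames(pq), off + seq_len(k)] <-
      SummarizedExperiment::assay(pq, assayName)
    off <- off + k
  }
  list(Y = Y, meta = meta)
}

#' Cross-tissue consistent and tissue-specific effects for all proteins
#'
#' For every protein observed in at least two tissues: the consistent age
#' and sex effects (REML + Satterthwaite) and the age-by-tissue /
#' sex-by-tissue interaction tests (ML LRT). Benjamini-Hochberg q-values
#' are computed across proteins within each test family.
#'
#' @param pqList list of per-tissue [ProteinQuant-class] objects.
#' @return data.frame, one row per eligible protein: coefficients, p- and
#'   q-values per test, `n_tissues_observed`, `singular`, and the test
#'   method actually used.
#' @export
crossTissueEffects <- function(pqList) {
  st <- stackTissues(pqList)
  rows <- vector("list", nrow(st$Y))
  for (i in seq_len(nrow(st$Y))) {
    obs <- which(!is.na(st$Y[i, ]))
    meta <- st$meta[obs, ]
    if (length(unique(meta$tissue)) < 2) next
    vals <- st$Y[i, obs]
    fit <- fitCrossTissueLMM(vals, meta)
    a <- testConsistentEffect(fit, "age")
    s <- testConsistentEffect(fit, "sex")
    abt <- testEffectByTissue(vals, meta, "age")
    sbt <- testEffectByTissue(vals, meta, "sex")
    rows[[i]] <- data.frame(
      protein_id = rownames(st$Y)[i],
      consistent_age_coef = a$coefficient, consistent_age_p = a$p,
      age_by_tissue_p = abt$p,
      consistent_sex_coef = s$coefficient, consistent_sex_p = s$p,
      sex_by_tissue_p = sbt$p,
      n_tissues_observed = length(unique(meta$tissue)),
      singular = fit$singular,
      consistent_method = a$method, interaction_method = abt$method)
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) return(res)
  res$consistent_age_q <- bhFdr(res$consistent_age_p)
  res$age_by_tissue_q <- bhFdr(res$age_by_tissue_p)
  res$consistent_sex_q <- bhFdr(res$consistent_sex_p)
  res$sex_by_tissue_q <- bhFdr(res$sex_by_tissue_p)
  rownames(res) <- NULL
  res
}

#' Variance-component decomposition for proteins observed in all tissues
#'
#' For each protein present in every tissue, fits (REML, lme4)
#' `abundance ~ age + sex + (1 | mouse) + (1 | tag) + (1 | batch)` over all
#' tissues and reports each factor's share of the summed variance,
#' `VarP_f = tau2_f / (tau2_mouse + tau2_tag + tau2_batch + sigma2)`
#' (fractions sum to one by construction), plus BLUPs of every random-effect
#' level with 95% predictive intervals (+-1.96 conditional SD). Proteins
#' sharing the complete observation pattern are refit from one model
#' structure, which keeps the per-protein cost low. A random factor with a
#' single level is dropped (its component reported as 0 and flagged).
#'
#' @param pqList list of per-tissue [ProteinQuant-class] objects.
#' @param blups also return BLUP tables (default TRUE).
#' @return list with `varp` (one row per protein: `varp_mouse`, `varp_tag`,
#'   `varp_batch`, `varp_residual`, `singular`) and `blups` (long format:
#'   `protein_id`, `factor`, `level`, `estimate`, `lower`, `upper`).
#' @export
varianceDecomposition <- function(pqList, blups = TRUE) {
  st <- stackTissues(pqList)
  full <- rowSums(is.na(st$Y)) == 0
  if (!any(full))
    return(list(varp = NULL, blups = NULL))
  Yf <- st$Y[full, , drop = FALSE]
  meta <- st$meta
  d <- data.frame(y = Yf[1, ], old = meta$old, female = meta$female,
                  mouse = factor(meta$mouse_id), tag = factor(meta$tag),
                  batch = factor(meta$batch_global))
  terms <- c(mouse = nlevels(d$mouse) > 1, tag = nlevels(d$tag) > 1,
             batch = nlevels(d$batch) > 1)
  if (!any(terms)) stop("no random factor has more than one level")
  form <- paste("y ~ old + female",
                paste(sprintf("(1 | %s)", names(terms)[terms]), collapse = " + "),
                sep = " + ")
  template <- lme4::lmer(as.formula(form), data = d, REML = TRUE,
                         control = lme4::lmerControl(
                           check.conv.singular = "ignore",
                           calc.derivs = FALSE))
  varp_rows <- vector("list", nrow(Yf))
  blup_rows <- if (blups) vector("list", nrow(Yf)) else NULL
  for (i in seq_len(nrow(Yf))) {
    m <- if (i == 1) template else
      suppressMessages(lme4::refit(template, newresp = Yf[i, ]))
    vc <- as.data.frame(lme4::VarCorr(m))
    tau2 <- setNames(rep(0, 3), c("mouse", "tag", "batch"))
    tau2[vc$grp[vc$grp %in% names(tau2)]] <-
      vc$vcov[vc$grp %in% names(tau2)]
    sigma2 <- vc$vcov[vc$grp == "Residual"]
    tot <- sum(tau2) + sigma2
    varp_rows[[i]] <- data.frame(
      protein_id = rownames(Yf)[i],
      varp_mouse = tau2[["mouse"]] / tot, varp_tag = tau2[["tag"]] / tot,
      varp_batch = tau2[["batch"]] / tot, varp_residual = sigma2 / tot,
      singular = lme4::isSingular(m),
      dropped = paste(names(terms)[!terms], collapse = ","))
    if (blups) {
      re <- lme4::ranef(m, condVar = TRUE)
      blup_rows[[i]] <- do.call(rbind, lapply(names(re), function(f) {
        est <- re[[f]][, 1]
        sdv <- sqrt(drop(attr(re[[f]], "postVar")))
        data.frame(protein_id = rownames(Yf)[i], factor = f,
                   level = rownames(re[[f]]), estimate = est,
                   lower = est - 1.96 * sdv, upper = est + 1.96 * sdv)
      }))
    }
  }
  varp <- do.call(rbind, varp_rows)
  rownames(varp) <- NULL
  stopifnot(all(abs(varp$varp_mouse + varp$varp_tag + varp$varp_batch +
                    varp$varp_residual - 1) < 1e-8))
  out_blups <- if (blups) do.call(rbind, blup_rows) else NULL
  if (!is.null(out_blups)) rownames(out_blups) <- NULL
  list(varp = varp, blups = out_blups)
}
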