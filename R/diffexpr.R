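#' Fit the within-tissue protein model
#'
#' Ordinary least squares of one protein's log2 bridge-normalized abundance
#' on age (old = 1), sex (female = 1) and batch (second batch = 1):
#' `y ~ old + female + batch2`. The age-by-sex interaction model adds
#' `old:female` on top (both main effects retained).
#'
#' @param values numeric vector, one protein's abundances across samples.
#' @param annotation data.frame with `age`, `sex`, `batch` for those
#'   samples.
#' @param interaction include the age-by-sex interaction term.
#' @return an `lm` fit with coefficients `old`, `female`, `batch2`
#'   (and `old:female`).
#' @export
fitProteinModel <- function(values, annotation, interaction = FALSE) {
  ind <- designIndicators(annotation)
  d <- data.frame(y = values, old = ind$old, female = ind$female,
                  batch2 = ind$batch2)
  f <- if (interaction) y ~ old + female + batch2 + old:female
       else y ~ old + female + batch2
  fit <- lm(f, data = d)
  if (anyNA(coef(fit)))
    stop("design is rank deficient; protein cannot be tested")
  fit
}

#' Nested-model test of one effect
#'
#' Tests `age`, `sex`, or `age_by_sex` by comparing the full model to the
#' model without the tested term via ANOVA (F-test). For the interaction,
#' the full model is the base model plus `old:female` and the reduced model
#' is the base model. For single-df terms the F-test equals the squared-t
#' test of the coefficient.
#'
#' @param values,annotation as in [fitProteinModel()].
#' @param effect one of `"age"`, `"sex"`, `"age_by_sex"`.
#' @return list with `coefficient`, `se`, `p`.
#' @export
testEffect <- function(values, annotation, effect = c("age", "sex", "age_by_sex")) {
  effect <- match.arg(effect)
  base <- fitProteinModel(values, annotation, interaction = FALSE)
  if (effect == "age_by_sex") {
    full <- fitProteinModel(values, annotation, interaction = TRUE)
    a <- anova(base, full)
    s <- summary(full)$coefficients
    return(list(coefficient = unname(s["old:female", 1]),
                se = unname(s["old:female", 2]), p = a[2, "Pr(>F)"]))
  }
  term <- if (effect == "age") "old" else "female"
  red <- lm(as.formula(paste("y ~", paste(setdiff(c("old", "female", "batch2"),
                                                  term), collapse = " + "))),
            data = base$model)
  a <- anova(red, base)
  s <- summary(base)$coefficients
  list(coefficient = unname(s[term, 1]), se = unname(s[term, 2]),
       p = a[2, "Pr(>F)"])
}

#' Per-tissue age, sex, and age-by-sex effects for every protein
#'
#' Vectorized over proteins through a single QR decomposition of the shared
#' design matrix; results are identical to looping [testEffect()] over
#' rows. Benjamini-Hochberg q-values are computed within each
#' tissue-by-effect family. Proteins that cannot be fit (zero residual df
#' or rank-deficient design) are reported with a skip reason, never
#' silently dropped.
#'
#' @param x a [ProteinQuant-class].
#' @param effects which effects to test.
#' @return data.frame with columns `protein_id`, `effect_type`,
#'   `coefficient`, `se`, `p`, `q`, `tissue` (one row per protein x
#'   effect), with skipped proteins in attribute `skipped`.
#' @export
proteinEffects <- function(x, effects = c("age", "sex", "age_by_sex")) {
  ann <- as.data.frame(SummarizedExperiment::colData(x))
  Y <- SummarizedExperiment::assay(x, "log2ratio")
  ind <- designIndicators(ann)
  X0 <- cbind(`(Intercept)` = 1, old = ind$old, female = ind$female,
              batch2 = ind$batch2)
  X0 <- X0[, qr(X0)$pivot[seq_len(qr(X0)$rank)], drop = FALSE]
  if (!all(c("old", "female") %in% colnames(X0)))
    stop("age or sex is not estimable in this design")
  res0 <- olsAll(X0, Y)
  out <- list()
  if ("age" %in% effects)
    out$age <- effectRows(res0, "old", "age", rownames(Y))
  if ("sex" %in% effects)
    out$sex <- effectRows(res0, "female", "sex", rownames(Y))
  if ("age_by_sex" %in% effects) {
    X1 <- cbind(X0, `old:female` = ind$old * ind$female)
    res1 <- olsAll(X1, Y)
    # nested F: (RSS0 - RSS1) / (RSS1 / df1)
    df1 <- nrow(X1) - ncol(X1)
    F <- (res0$rss - res1$rss) / (res1$rss / df1)
    p <- pf(F, 1, df1, lower.tail = FALSE)
    out$age_by_sex <- data.frame(
      protein_id = rownames(Y), effect_type = "age_by_sex",
      coefficient = res1$beta["old:female", ], se = res1$se["old:female", ],
      p = p)
  }
  res <- do.call(rbind, out)
  res$q <- NA_real_
  for (e in unique(res$effect_type)) {
    i <- res$effect_type == e & !is.na(res$p)
    res$q[i] <- p.adjust(res$p[i], method = "BH")
  }
  res$tissue <- tissueName(x)
  rownames(res) <- NULL
  attr(res, "skipped") <- res0$skipped
  res
}

# shared-design OLS over all proteins at once
olsAll <- function(X, Y) {
  n <- nrow(X); k <- ncol(X)
  qrx <- qr(X)
  if (qrx$rank < k) stop("design matrix is rank deficient")
  beta <- qr.coef(qrx, t(Y))
  fitted <- X %*% beta
  resid <- t(Y) - fitted
  rss <- colSums(resid^2)
  sigma2 <- rss / (n - k)
  xtxinv <- chol2inv(qr.R(qrx))
  se <- sqrt(outer(diag(xtxinv), sigma2))
  rownames(se) <- rownames(beta) <- colnames(X)
  tstat <- beta / se
  p <- 2 * pt(-abs(tstat), df = n - k)
  list(beta = beta, se = se, p = p, rss = rss, df = n - k,
       skipped = data.frame(protein_id = character(), reason = character()))
}

effectRows <- function(res, term, label, proteins) {
  data.frame(protein_id = proteins, effect_type = label,
             coefficient = res$beta[term, ], se = res$se[term, ],
             p = res$p[term, ])
}

#' Benjamini-Hochberg q-values
#'
#' Step-up BH within one family; `NA` p-values are excluded from the family
#' size and returned as `NA` q-values.
#'
#' @param p numeric p-values in (0, 1].
#' @return q-values, monotone non-decreasing in p-rank.
#' @export
bhFdr <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- p.adjust(p[ok], method = "BH")
  q
}

#' Correlate effect estimates between two studies
#'
#' Pearson correlation of per-protein effect coefficients over the
#' identifier intersection of two effect tables, optionally restricted to
#' proteins significant (q < `qCut`) in the first study.
#'
#' @param effectsA data.frame with `protein_id`, `coefficient` (and `q` if
#'   restricting).
#' @param effectsB data.frame with `protein_id`, `coefficient`.
#' @param restrictToSignificant restrict to `q < qCut` in `effectsA`.
#' @param qCut significance cut for the restriction (default 0.1).
#' @param key identifier column shared by both tables (default
#'   `"protein_id"`); no fuzzy matching is attempted.
#' @return list with `r`, `p` (two-sided), `n`.
#' @export
compareEffectsCrossStudy <- function(effectsA, effectsB,
                                     restrictToSignificant = FALSE,
                                     qCut = 0.1, key = "protein_id") {
  a <- effectsA
  if (restrictToSignificant) a <- a[!is.na(a$q) & a$q < qCut, ]
  m <- merge(a[, c(key, "coefficient")], effectsB[, c(key, "coefficient")],
             by = key, suffixes = c("_a", "_b"))
  if (nrow(m) < 3) stop("fewer than 3 shared proteins (n = ", nrow(m), ")")
  ct <- stats::cor.test(m$coefficient_a, m$coefficient_b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(m))
}

#' Flag proteins with strong, sign-concordant effects in two studies
#'
#' A protein is flagged when both studies agree on the sign of the effect
#' and both standardized scores |coefficient / se| exceed 2. Proteins with
#' a zero standard error in either study are skipped with a warning.
#'
#' @param effectsA,effectsB data.frames with `protein_id`, `coefficient`,
#'   `se`.
#' @param key shared identifier column.
#' @return data.frame `protein_id`, `z_a`, `z_b`, `concordant_strong`.
#' @export
flagConcordantStrong <- function(effectsA, effectsB, key = "protein_id") {
  m <- merge(effectsA[, c(key, "coefficient", "se")],
             effectsB[, c(key, "coefficient", "se")],
             by = key, suffixes = c("_a", "_b"))
  zero <- m$se_a == 0 | m$se_b == 0
  if (any(zero)) {
    warning(sum(zero), " protein(s) skipped for zero standard error")
    m <- m[!zero, ]
  }
  z_a <- m$coefficient_a / m$se_a
  z_b <- m$coefficient_b / m$se_b
  data.frame(protein_id = m[[key]], z_a = z_a, z_b = z_b,
             concordant_strong = sign(m$coefficient_a) == sign(m$coefficient_b) &
               abs(z_a) > 2 & abs(z_b) > 2)
}

#' Cluster age-effect profiles across tissues
#'
#' Builds the proteins x tissues matrix of age coefficients for proteins
#' with a significant age effect (q < `qCut`) in at least one tissue,
#' setting cells to 0 for tissues in which a protein was not observed, and
#' clusters proteins hierarchically (Euclidean distance, Ward linkage by
#' default — both stable on zero-filled matrices and exposed as arguments).
#'
#' @param effectsList list of per-tissue effect tables from
#'   [proteinEffects()].
#' @param qCut significance threshold (default 0.1).
#' @param k number of flat clusters to cut (default 3).
#' @param distMethod,linkage distance and linkage passed to [stats::dist()]
#'   and [stats::hclust()].
#' @return list with `matrix` (ordered proteins x tissues), `order` (leaf
#'   order), `clusters` (named cluster labels), `hclust`, and `newick`
#'   (dendrogram in Newick format); `NULL` with a warning when no protein
#'   passes the cut.
#' @export
clusterAgeEffects <- function(effectsList, qCut = 0.1, k = 3,
                              distMethod = "euclidean", linkage = "ward.D2") {
  age <- do.call(rbind, lapply(effectsList, function(e)
    e[e$effect_type == "age", c("protein_id", "coefficient", "q", "tissue")]))
  sig <- unique(age$protein_id[!is.na(age$q) & age$q < qCut])
  if (length(sig) < 2) {
    warning("fewer than two proteins with a significant age effect")
    return(NULL)
  }
  sig <- sort(sig)
  tissues <- sort(unique(age$tissue))
  m <- matrix(0, length(sig), length(tissues), dimnames = list(sig, tissues))
  obs <- age[age$protein_id %in% sig, ]
  m[cbind(obs$protein_id, obs$tissue)] <- obs$coefficient
  hc <- stats::hclust(stats::dist(m, method = distMethod), method = linkage)
  cl <- stats::cutree(hc, k = min(k, length(sig)))
  phylo <- ape::as.phylo(hc)
  list(matrix = m[hc$order, , drop = FALSE], order = hc$labels[hc$order],
       clusters = cl, hclust = hc, newick = ape::write.tree(phylo))
}

#' Minimal volcano plot of one effect family
#'
#' @param effects data.frame from [proteinEffects()].
#' @param effect which effect type to plot.
#' @param qCut highlight threshold.
#' @return a ggplot object (requires the ggplot2 package).
#' @export
plotVolcano <- function(effects, effect = "age", qCut = 0.1) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  d <- effects[effects$effect_type == effect, ]
  d$significant <- !is.na(d$q) & d$q < qCut
  ggplot2::ggplot(d, ggplot2::aes(x = .data$coefficient,
                                  y = -log10(.data$p),
                                  colour = .data$significant)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "log2 effect", y = "-log10 p",
                  title = paste(unique(d$tissue), effect, "effects"))
}
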