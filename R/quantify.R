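#' Within-batch scaling factors
#'
#' For each sample of a batch, theta = (sum of all peptide intensities of
#' the sample) / (maximum such sum over the samples of the batch, bridge
#' included). Exactly one sample per batch (the batch maximum) has
#' theta = 1; dividing by theta equalizes total peptide loading within the
#' batch before protein rollup.
#'
#' @param peptides long-format peptide table (`peptide_id`, `protein_id`,
#'   `sample_id`, `intensity`), one tissue.
#' @param annotation sample annotation covering the peptide table's samples
#'   (`sample_id`, `batch`, `is_bridge`, ...).
#' @param tissue optional tissue id to subset `annotation`.
#' @return data.frame with columns `sample_id`, `batch`, `theta`.
#' @examples
#' ann <- data.frame(sample_id = c("A", "B", "Br"), tissue = "t",
#'                   batch = 1, is_bridge = c(FALSE, FALSE, TRUE))
#' pep <- data.frame(peptide_id = "p1", protein_id = "P1",
#'                   sample_id = c("A", "B", "Br"),
#'                   intensity = c(100, 200, 150))
#' computeScalingFactors(pep, ann)  # theta = 0.5, 1.0, 0.75
#' @export
computeScalingFactors <- function(peptides, annotation, tissue = NULL) {
  if (!is.null(tissue)) annotation <- annotation[annotation$tissue == tissue, ]
  checkPeptideTable(peptides, annotation)
  totals <- tapply(peptides$intensity, peptides$sample_id, sum)
  out <- data.frame(sample_id = annotation$sample_id,
                    batch = annotation$batch,
                    total = as.numeric(totals[annotation$sample_id]))
  if (anyNA(out$total) || any(out$total <= 0))
    stop("every sample must have positive total peptide intensity; offending: ",
         paste(out$sample_id[is.na(out$total) | out$total <= 0], collapse = ", "))
  for (b in unique(out$batch)) {
    idx <- out$batch == b
    out$theta[idx] <- out$total[idx] / max(out$total[idx])
  }
  out$total <- NULL
  out
}

#' Roll peptides up to raw protein abundances
#'
#' The abundance of protein j in sample i is the sum of the intensities of
#' its observed peptides, divided by the sample's within-batch scaling
#' factor theta. Peptides absent from a sample contribute nothing; a protein
#' with no observed peptide in a sample gets abundance 0 there.
#'
#' @param peptides long-format peptide table, one tissue.
#' @param factors scaling factors from [computeScalingFactors()].
#' @return numeric matrix, proteins x samples (all samples in `factors`,
#'   bridge included), raw scaled-sum abundances.
#' @export
rollupProteins <- function(peptides, factors) {
  prot <- factor(peptides$protein_id)
  smp <- factor(peptides$sample_id, levels = factors$sample_id)
  if (anyNA(smp))
    stop("peptide table contains samples missing from the scaling factors")
  y <- matrix(0, nlevels(prot), nlevels(smp),
              dimnames = list(levels(prot), levels(smp)))
  sums <- rowsum(peptides$intensity,
                 group = (as.integer(smp) - 1L) * nlevels(prot) + as.integer(prot))
  y[as.integer(rownames(sums))] <- sums[, 1]
  sweep(y, 2, factors$theta, "/")
}

#' Bridge (pooled-sample) ratio normalization
#'
#' Standardizes quantities across the two batches of a tissue by taking,
#' per protein, log2((y + 1) / (y_bridge + 1)) against the bridge sample of
#' the sample's own batch. The +1 pseudo-count (raw scale) keeps the ratio
#' finite when a protein is absent; a sample identical to its bridge maps
#' to 0. Bridge columns are consumed and dropped from the output.
#'
#' @param raw proteins x samples matrix from [rollupProteins()].
#' @param annotation sample annotation for those samples (must flag exactly
#'   one bridge per batch).
#' @param tissue tissue id recorded in the result (default: from
#'   annotation).
#' @return a [ProteinQuant-class] with assay `"log2ratio"` and the
#'   per-batch observation mask (observed = any peptide signal in any
#'   sample of the batch, i.e. raw abundance > 0).
#' @export
bridgeNormalize <- function(raw, annotation, tissue = NULL) {
  annotation <- annotation[match(colnames(raw), annotation$sample_id), ]
  if (anyNA(annotation$sample_id))
    stop("annotation does not cover all columns of the abundance matrix")
  if (is.null(tissue)) tissue <- unique(annotation$tissue)
  stopifnot(length(tissue) == 1)
  batches <- sort(unique(annotation$batch))
  obs <- vapply(batches, function(b) {
    rowSums(raw[, annotation$batch == b, drop = FALSE] > 0) > 0
  }, logical(nrow(raw)))
  colnames(obs) <- paste0("batch", batches)

  norm <- raw
  for (b in batches) {
    br <- which(annotation$batch == b & annotation$is_bridge)
    if (length(br) != 1)
      stop("batch ", b, " must have exactly one bridge sample, found ",
           length(br))
    idx <- annotation$batch == b
    norm[, idx] <- log2((raw[, idx, drop = FALSE] + 1) / (raw[, br] + 1))
  }
  # internal check: a bridge normalized against itself is identically 0
  stopifnot(all(abs(norm[, annotation$is_bridge]) < 1e-12))

  keep <- !annotation$is_bridge
  ann <- annotation[keep, c("sample_id", "mouse_id", "tissue", "batch",
                            "tag", "age", "sex")]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2ratio = norm[, keep, drop = FALSE]),
    colData = S4Vectors::DataFrame(ann, row.names = ann$sample_id),
    metadata = list(tissue = tissue, observed = obs,
                    qc = list(removed_single_batch = character(),
                              flagged_samples = character())))
  new("ProteinQuant", se)
}

#' Remove proteins observed in only one batch
#'
#' Proteins quantified in a single batch of a tissue cannot be compared
#' across the full sample set and are dropped; the removed identifiers are
#' recorded in `metadata(x)$qc$removed_single_batch`.
#'
#' @param x a [ProteinQuant-class].
#' @return the filtered [ProteinQuant-class].
#' @export
filterSingleBatch <- function(x) {
  obs <- observedMask(x)
  keep <- rowSums(obs) == ncol(obs)
  removed <- rownames(x)[!keep]
  out <- x[keep, ]
  md <- S4Vectors::metadata(out)
  md$observed <- obs[keep, , drop = FALSE]
  md$qc$removed_single_batch <- removed
  S4Vectors::metadata(out) <- md
  out
}

#' Flag outlier samples on robust PCA score distances
#'
#' Projects samples onto the first `nComponents` principal axes of the
#' complete-case protein matrix (proteins observed in every batch; values
#' centered per protein, not scaled) and flags samples whose robust
#' distance, max over axes of |score - median| / MAD, exceeds `kMad`.
#' Flags are advisory: nothing is removed here. Axes with zero MAD are
#' treated as carrying no outlier information unless a sample deviates from
#' the axis median at all.
#'
#' @param x a [ProteinQuant-class] (post [filterSingleBatch()]).
#' @param kMad robust-distance threshold (default 5).
#' @param nComponents number of principal axes (default 2).
#' @return character vector of flagged sample ids, with the score matrix
#'   and per-sample distances as attributes `scores` and `distance`.
#' @export
detectOutlierSamples <- function(x, kMad = 5, nComponents = 2) {
  stopifnot(ncol(x) >= 4)
  obs <- observedMask(x)
  mat <- SummarizedExperiment::assay(x, "log2ratio")
  mat <- mat[rowSums(obs) == ncol(obs), , drop = FALSE]
  if (nrow(mat) < nComponents)
    stop("fewer complete-case proteins (", nrow(mat),
         ") than components (", nComponents, ")")
  pc <- prcomp(t(mat), center = TRUE, scale. = FALSE)
  sc <- pc$x[, seq_len(min(nComponents, ncol(pc$x))), drop = FALSE]
  z <- apply(sc, 2, function(s) {
    m <- median(s); d <- abs(s - m); md <- mad(s)
    if (md < 1e-12) ifelse(d < 1e-8, 0, Inf) else d / md
  })
  z <- matrix(z, nrow = nrow(sc))
  dist <- apply(z, 1, max)
  flagged <- colnames(x)[dist > kMad]
  structure(flagged, scores = sc,
            distance = setNames(dist, colnames(x)))
}

#' Remove samples from a quantification object
#'
#' Explicit removal of flagged (or manually listed) outlier samples;
#' removals are recorded in `metadata(x)$qc$flagged_samples`.
#'
#' @param x a [ProteinQuant-class].
#' @param samples character vector of sample ids to drop.
#' @return the reduced [ProteinQuant-class].
#' @export
removeSamples <- function(x, samples) {
  if (!length(samples)) return(x)
  missing <- setdiff(samples, colnames(x))
  if (length(missing))
    stop("unknown sample(s): ", paste(missing, collapse = ", "))
  out <- x[, setdiff(colnames(x), samples)]
  md <- S4Vectors::metadata(out)
  md$qc$flagged_samples <- union(md$qc$flagged_samples, samples)
  S4Vectors::metadata(out) <- md
  out
}

#' Regress the batch effect out of the abundance matrix
#'
#' Per protein, fits the within-tissue linear model
#' (intercept + old + female + batch) and subtracts the estimated batch
#' term, leaving age and sex structure untouched. The adjusted values are
#' stored as an additional assay `"adjusted"`; they are intended for
#' visualization and co-abundance analysis, while effect inference always
#' uses the unadjusted model fit.
#'
#' @param x a [ProteinQuant-class].
#' @return `x` with an `"adjusted"` assay added.
#' @export
regressOutBatch <- function(x) {
  ann <- as.data.frame(SummarizedExperiment::colData(x))
  ind <- designIndicators(ann)
  Y <- SummarizedExperiment::assay(x, "log2ratio")
  if (length(unique(ann$batch)) < 2) {
    warning("all samples are in one batch; returning values unchanged")
    SummarizedExperiment::assays(x)$adjusted <- Y
    return(x)
  }
  X <- cbind(1, ind$old, ind$female, ind$batch2)
  beta_batch <- qr.coef(qr(X), t(Y))[4, ]
  adj <- Y - outer(beta_batch, ind$batch2)
  SummarizedExperiment::assays(x)$adjusted <- adj
  x
}

#' Quantify one tissue from peptides to normalized protein abundances
#'
#' Chains [computeScalingFactors()], [rollupProteins()],
#' [bridgeNormalize()], the single-batch protein filter, outlier flagging,
#' and batch regression into the standard per-tissue quantification.
#'
#' @param peptides long-format peptide table for one tissue.
#' @param annotation sample annotation (all tissues fine; subset by
#'   `tissue`).
#' @param tissue tissue id.
#' @param filterSingle drop single-batch proteins (default TRUE).
#' @param kMad,nComponents outlier-flagging parameters, see
#'   [detectOutlierSamples()].
#' @param removeOutliers `"none"` (default, flags are advisory), `"auto"`
#'   (drop flagged samples), or a character vector of sample ids to drop.
#' @return a [ProteinQuant-class] with assays `"log2ratio"` and
#'   `"adjusted"`; QC details in `metadata(x)$qc`.
#' @export
quantifyTissue <- function(peptides, annotation, tissue,
                           filterSingle = TRUE, kMad = 5, nComponents = 2,
                           removeOutliers = "none") {
  ann <- annotation[annotation$tissue == tissue, ]
  sf <- computeScalingFactors(peptides, ann)
  raw <- rollupProteins(peptides, sf)
  pq <- bridgeNormalize(raw, ann, tissue)
  if (filterSingle) pq <- filterSingleBatch(pq)
  flagged <- tryCatch(detectOutlierSamples(pq, kMad, nComponents),
                      error = function(e) character())
  md <- S4Vectors::metadata(pq)
  md$qc$flagged_samples <- as.character(flagged)
  S4Vectors::metadata(pq) <- md
  drop <- if (identical(removeOutliers, "auto")) as.character(flagged)
          else if (is.character(removeOutliers) &&
                   !identical(removeOutliers, "none")) removeOutliers
          else character()
  if (length(drop)) pq <- removeSamples(pq, drop)
  regressOutBatch(pq)
}

checkPeptideTable <- function(peptides, annotation) {
  need <- c("peptide_id", "protein_id", "sample_id", "intensity")
  if (!all(need %in% colnames(peptides)))
    stop("peptide table must have columns: ", paste(need, collapse = ", "))
  if (any(peptides$intensity <= 0))
    stop("peptide intensities must be strictly positive")
  if (anyDuplicated(peptides[, c("peptide_id", "sample_id")]))
    stop("(peptide_id, sample_id) pairs must be unique")
  unknown <- setdiff(peptides$sample_id, annotation$sample_id)
  if (length(unknown))
    stop("peptide table references unknown samples: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  invisible(TRUE)
}
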