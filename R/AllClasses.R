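#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames colData
#' @importFrom S4Vectors metadata "metadata<-" DataFrame
#' @importFrom stats anova as.formula coef cor lm logLik mad median optimize
#'   p.adjust pchisq pf pnorm prcomp pt qnorm quantile rbinom rnorm runif sd
#'   setNames t.test var
#' @importFrom utils read.delim write.table combn packageVersion
NULL

#' Simulation configuration for the multi-tissue study design
#'
#' Holds every tunable parameter of the synthetic-data generator, which
#' emulates a 20-mouse (two ages x two sexes, five animals per group),
#' 10-tissue TMT study in which each tissue is run as two 11-plex batches
#' (10 mice plus one pooled bridge sample per batch).
#'
#' All effect sizes and standard deviations are on the log2 scale of protein
#' abundance. Age/sex/interaction effects are planted on a random subset of
#' proteins (`propAffected`) with magnitude `ageEffect` (etc.) and random
#' sign. Protein complexes receive a per-mouse latent factor whose
#' group-specific loading (`complexLoading`) controls within-complex
#' co-abundance ("cohesiveness") separately in young and old animals.
#'
#' @slot nMicePerGroup mice per age-by-sex group (default 5, i.e. 20 mice).
#' @slot ageLevels,sexLevels factor labels, first level is the reference.
#' @slot nTissues number of tissues (default 10).
#' @slot nProteins number of simulated proteins.
#' @slot peptidesPerProtein integer range (min, max) of peptides per protein.
#' @slot nComplexes number of protein complexes.
#' @slot complexSize integer range (min, max) of complex sizes.
#' @slot ageEffect,sexEffect,interactionEffect log2 effect magnitudes for
#'   affected proteins (sign randomized per protein).
#' @slot propAffected fraction of proteins with a nonzero age (and,
#'   independently, sex) effect.
#' @slot mouseSd,tagSd,batchSd,residualSd standard deviations of the mouse,
#'   TMT-tag, batch random effects and the residual, log2 scale.
#' @slot complexLoading named numeric, latent-factor loading per age group
#'   (names must match `ageLevels`).
#' @slot detectProb probability that a peptide is detected in a batch.
#' @slot peptideNoiseSd log2-scale multiplicative peptide noise.
#' @slot peptideEfficiencySd natural-log sd of the fixed per-peptide
#'   ionization efficiency (log-normal, median 1).
#' @slot baselineMean,baselineSd mean/sd of per-protein baseline log2
#'   abundance.
#' @slot seed integer master seed; all stage substreams derive from it.
#'
#' @seealso [simConfig()] for the user-facing constructor,
#'   [generateDesign()], [simulateStudy()].
#' @export
setClass("SimConfig", representation(
  nMicePerGroup = "integer",
  ageLevels = "character",
  sexLevels = "character",
  nTissues = "integer",
  nProteins = "integer",
  peptidesPerProtein = "integer",
  nComplexes = "integer",
  complexSize = "integer",
  ageEffect = "numeric",
  sexEffect = "numeric",
  interactionEffect = "numeric",
  propAffected = "numeric",
  mouseSd = "numeric",
  tagSd = "numeric",
  batchSd = "numeric",
  residualSd = "numeric",
  complexLoading = "numeric",
  detectProb = "numeric",
  peptideNoiseSd = "numeric",
  peptideEfficiencySd = "numeric",
  baselineMean = "numeric",
  baselineSd = "numeric",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  chkpos <- function(x, nm) if (length(x) != 1 || is.na(x) || x < 0)
    sprintf("'%s' must be a single nonnegative number", nm) else character()
  msg <- c(msg,
    chkpos(object@mouseSd, "mouseSd"), chkpos(object@tagSd, "tagSd"),
    chkpos(object@batchSd, "batchSd"), chkpos(object@residualSd, "residualSd"),
    chkpos(object@peptideNoiseSd, "peptideNoiseSd"),
    chkpos(object@peptideEfficiencySd, "peptideEfficiencySd"),
    chkpos(object@ageEffect, "ageEffect"), chkpos(object@sexEffect, "sexEffect"))
  if (object@propAffected < 0 || object@propAffected > 1)
    msg <- c(msg, "'propAffected' must be in [0, 1]")
  if (object@detectProb < 0 || object@detectProb > 1)
    msg <- c(msg, "'detectProb' must be in [0, 1]")
  if (length(object@ageLevels) != 2 || length(object@sexLevels) != 2)
    msg <- c(msg, "'ageLevels' and 'sexLevels' must each have two levels")
  for (nm in c("peptidesPerProtein", "complexSize")) {
    r <- slot(object, nm)
    if (length(r) != 2 || any(r < 1) || r[1] > r[2])
      msg <- c(msg, sprintf("'%s' must be an ascending positive range", nm))
  }
  if (!all(object@ageLevels %in% names(object@complexLoading)))
    msg <- c(msg, "'complexLoading' must be named by age levels")
  if (object@nMicePerGroup < 1 || object@nTissues < 1 || object@nProteins < 1)
    msg <- c(msg, "counts must be >= 1")
  if (object@complexSize[2] * object@nComplexes > object@nProteins)
    msg <- c(msg, "complexes cannot use more proteins than simulated (members drawn without replacement)")
  if (length(msg)) msg else TRUE
})

#' Construct a [SimConfig-class] with study-design defaults
#'
#' Defaults reproduce the study conditions: 5 mice per age-by-sex group,
#' 10 tissues, two 11-plex batches per tissue, 2000 proteins, peptide-level
#' log-normal intensity spread and per-batch detection at probability 0.8,
#' planted age/sex effects of 0.6 log2 units on 10% of proteins (roughly
#' twice the per-observation noise), and equal complex loadings in both age
#' groups (no cohesiveness change unless requested).
#'
#' @param nMicePerGroup,ageLevels,sexLevels,nTissues,nProteins see
#'   [SimConfig-class].
#' @param peptidesPerProtein,nComplexes,complexSize,ageEffect,sexEffect see
#'   [SimConfig-class].
#' @param interactionEffect,propAffected,mouseSd,tagSd,batchSd,residualSd see
#'   [SimConfig-class].
#' @param complexLoading,detectProb,peptideNoiseSd,peptideEfficiencySd see
#'   [SimConfig-class].
#' @param baselineMean,baselineSd,seed see [SimConfig-class].
#' @return a validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nTissues = 2, nProteins = 50, seed = 1)
#' @export
simConfig <- function(nMicePerGroup = 5L,
                      ageLevels = c("young", "old"),
                      sexLevels = c("F", "M"),
                      nTissues = 10L,
                      nProteins = 2000L,
                      peptidesPerProtein = c(2L, 8L),
                      nComplexes = 20L,
                      complexSize = c(4L, 12L),
                      ageEffect = 0.6,
                      sexEffect = 0.6,
                      interactionEffect = 0,
                      propAffected = 0.1,
                      mouseSd = 0.1,
                      tagSd = 0.1,
                      batchSd = 0.2,
                      residualSd = 0.2,
                      complexLoading = c(young = 0.5, old = 0.5),
                      detectProb = 0.8,
                      peptideNoiseSd = 0.3,
                      peptideEfficiencySd = 0.5,
                      baselineMean = 12,
                      baselineSd = 1,
                      seed = 1L) {
  new("SimConfig",
      nMicePerGroup = as.integer(nMicePerGroup), ageLevels = ageLevels,
      sexLevels = sexLevels, nTissues = as.integer(nTissues),
      nProteins = as.integer(nProteins),
      peptidesPerProtein = as.integer(peptidesPerProtein),
      nComplexes = as.integer(nComplexes), complexSize = as.integer(complexSize),
      ageEffect = ageEffect, sexEffect = sexEffect,
      interactionEffect = interactionEffect, propAffected = propAffected,
      mouseSd = mouseSd, tagSd = tagSd, batchSd = batchSd,
      residualSd = residualSd, complexLoading = complexLoading,
      detectProb = detectProb, peptideNoiseSd = peptideNoiseSd,
      peptideEfficiencySd = peptideEfficiencySd, baselineMean = baselineMean,
      baselineSd = baselineSd, seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:",
      4L * object@nMicePerGroup, "mice x", object@nTissues, "tissues,",
      object@nProteins, "proteins,", object@nComplexes, "complexes\n")
  cat("  effects: age", object@ageEffect, "sex", object@sexEffect,
      "interaction", object@interactionEffect,
      "on", sprintf("%.0f%%", 100 * object@propAffected), "of proteins\n")
  cat("  sds (log2): mouse", object@mouseSd, "tag", object@tagSd,
      "batch", object@batchSd, "residual", object@residualSd, "\n")
  cat("  detectProb", object@detectProb, " seed", object@seed, "\n")
})

#' Protein abundance container for one tissue
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] holding the
#' log2 bridge-normalized protein-by-sample abundance matrix for a single
#' tissue (assay `"log2ratio"`), the sample annotation in `colData`
#' (`mouse_id`, `batch`, `tag`, `age`, `sex`), and the per-protein,
#' per-batch observation mask in `metadata(x)$observed` (a logical matrix,
#' proteins x batches: was at least one peptide of the protein quantified
#' in at least one sample of the batch). Bridge samples are already
#' consumed by the normalization and do not appear as columns.
#'
#' After [regressOutBatch()] an additional assay `"adjusted"` carries the
#' batch-adjusted values used for plotting and co-abundance analysis.
#'
#' @seealso [quantifyTissue()], [tissueName()], [observedMask()]
#' @export
setClass("ProteinQuant", contains = "SummarizedExperiment")

setValidity("ProteinQuant", function(object) {
  msg <- character()
  if (!"log2ratio" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'log2ratio' is required")
  need <- c("sample_id", "mouse_id", "batch", "tag", "age", "sex")
  if (!all(need %in% colnames(SummarizedExperiment::colData(object))))
    msg <- c(msg, paste("colData must contain:", paste(need, collapse = ", ")))
  obs <- S4Vectors::metadata(object)$observed
  if (is.null(obs) || !is.matrix(obs) || !is.logical(obs))
    msg <- c(msg, "metadata(x)$observed must be a logical proteins x batches matrix")
  else if (!identical(rownames(obs), rownames(object)))
    msg <- c(msg, "rownames of observed mask must match proteins")
  if (is.null(S4Vectors::metadata(object)$tissue))
    msg <- c(msg, "metadata(x)$tissue is required")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ProteinQuant", function(object) {
  callNextMethod()
  obs <- S4Vectors::metadata(object)$observed
  cat("tissue:", S4Vectors::metadata(object)$tissue, "|",
      sum(rowSums(obs) < ncol(obs)), "proteins not observed in every batch\n")
})

#' Protein complex membership catalog
#'
#' Maps complex identifiers to member protein identifiers (unique within a
#' complex, at least two members). Read/written in a GMT-like tab format:
#' `complex_id <TAB> description <TAB> member1 <TAB> member2 ...`.
#'
#' @slot members named list of character vectors of member protein ids.
#' @slot description named character vector, free-text per complex.
#' @seealso [complexCatalog()], [readComplexCatalog()], [filterComplexes()]
#' @export
setClass("ComplexCatalog", representation(
  members = "list", description = "character"))

setValidity("ComplexCatalog", function(object) {
  msg <- character()
  if (is.null(names(object@members)) || anyDuplicated(names(object@members)))
    msg <- c(msg, "complex ids must be unique and named")
  bad <- vapply(object@members,
                function(m) anyDuplicated(m) > 0 || length(m) < 2, logical(1))
  if (any(bad))
    msg <- c(msg, paste("complexes with duplicated or <2 members:",
                        paste(names(object@members)[bad], collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' @param members named list of character vectors (complex id -> members).
#' @param description optional named character vector of descriptions.
#' @rdname ComplexCatalog-class
#' @export
complexCatalog <- function(members, description = NULL) {
  if (is.null(description))
    description <- setNames(rep("", length(members)), names(members))
  new("ComplexCatalog", members = members, description = description)
}

#' @describeIn ComplexCatalog-class number of complexes.
#' @param x a `ComplexCatalog`.
#' @export
setMethod("length", "ComplexCatalog", function(x) length(x@members))

#' @describeIn ComplexCatalog-class complex identifiers.
#' @export
setMethod("names", "ComplexCatalog", function(x) names(x@members))

setMethod("show", "ComplexCatalog", function(object) {
  sz <- lengths(object@members)
  cat("ComplexCatalog with", length(sz), "complexes; sizes",
      min(sz), "-", max(sz), "\n")
})
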