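#' Pipeline run configuration
#'
#' Bundles the inputs, stage list, thresholds and seed of one pipeline run.
#' Either `sim` (a [SimConfig-class]; data are generated) or `inputs` (a
#' named list with `annotation`, `peptides` — named per-tissue TSV paths —
#' and optionally `catalog`) must be given.
#'
#' @param sim a [SimConfig-class], or NULL when reading files.
#' @param inputs named list of input paths, or NULL when simulating.
#' @param stages stages to run, in pipeline order.
#' @param outdir output directory.
#' @param seed master seed; every stochastic stage draws from a named
#'   substream of it.
#' @param fdrAbundance FDR threshold for abundance effect families
#'   (default 0.1).
#' @param fdrCohesiveness stricter FDR threshold for cohesiveness-change
#'   t-tests (default 0.01).
#' @param permutations permutations per protein pair (default 100000).
#' @param kMad outlier-flagging threshold (default 5).
#' @param removeOutliers `"none"`, `"auto"`, or sample ids to drop.
#' @param configFile optional YAML or JSON file whose keys provide any of
#'   the above (explicit arguments win).
#' @return validated list of class `RunConfig`.
#' @export
runConfig <- function(sim = NULL, inputs = NULL,
                      stages = c("simulate", "quantify", "effects",
                                 "cross_tissue", "complexes"),
                      outdir = "pipeline_out", seed = 1,
                      fdrAbundance = 0.1, fdrCohesiveness = 0.01,
                      permutations = 100000, kMad = 5,
                      removeOutliers = "none", configFile = NULL) {
  cfg <- list(sim = sim, inputs = inputs, stages = stages, outdir = outdir,
              seed = as.integer(seed), fdrAbundance = fdrAbundance,
              fdrCohesiveness = fdrCohesiveness,
              permutations = as.integer(permutations), kMad = kMad,
              removeOutliers = removeOutliers)
  if (!is.null(configFile)) {
    file_cfg <- if (grepl("[.]json$", configFile))
      jsonlite::read_json(configFile, simplifyVector = TRUE)
    else yaml::read_yaml(configFile)
    explicit <- names(as.list(match.call()))
    for (k in setdiff(names(file_cfg), explicit)) cfg[[k]] <- file_cfg[[k]]
  }
  if (is.null(cfg$sim) && is.null(cfg$inputs))
    stop("either 'sim' or 'inputs' must be provided")
  stopifnot(cfg$fdrAbundance > 0, cfg$fdrAbundance < 1,
            cfg$fdrCohesiveness > 0, cfg$fdrCohesiveness < 1,
            cfg$permutations >= 100)
  if (!is.null(cfg$inputs)) {
    paths <- c(cfg$inputs$annotation, unlist(cfg$inputs$peptides),
               cfg$inputs$catalog)
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("input path(s) do not exist: ", paste(missing, collapse = ", "))
  }
  class(cfg) <- "RunConfig"
  cfg
}

stageFail <- function(outdir, stage, err) {
  writeLines(paste("FAILED at stage:", stage, "-", conditionMessage(err)),
             file.path(outdir, "FAILED"))
  stop("pipeline failed in stage '", stage, "': ", conditionMessage(err),
       call. = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order — simulate (or load), quantify,
#' per-tissue effects, cross-tissue models, complex analysis — writing
#' every result table as TSV under `config$outdir` plus a JSON manifest
#' (package version, seed, effective configuration, per-stage row counts,
#' skipped entities with reasons, and the named RNG substream seeds).
#' Identical configurations produce byte-identical outputs; a stage failure
#' aborts with the failing stage named and a `FAILED` marker next to the
#' partial outputs.
#'
#' @param config a `RunConfig` from [runConfig()].
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(outdir, "FAILED"))
  manifest <- list(
    package = "AgeProteomics",
    version = as.character(packageVersion("AgeProteomics")),
    seed = config$seed,
    config = list(stages = config$stages, fdrAbundance = config$fdrAbundance,
                  fdrCohesiveness = config$fdrCohesiveness,
                  permutations = config$permutations, kMad = config$kMad,
                  removeOutliers = config$removeOutliers),
    substreams = list(), stages = list(), skipped = list())

  annotation <- NULL; peptides <- NULL; catalog <- NULL
  if ("simulate" %in% config$stages && !is.null(config$sim)) {
    manifest$substreams$simulate <- substreamSeed(config$seed, "proteins")
    res <- tryCatch({
      simcfg <- config$sim
      simcfg@seed <- config$seed
      sim <- simulateStudy(simcfg)
      writeStudy(sim, file.path(outdir, "simulated"))
      sim
    }, error = function(e) stageFail(outdir, "simulate", e))
    annotation <- res$annotation; peptides <- res$peptides
    catalog <- res$catalog
    manifest$stages$simulate <- list(
      status = "complete",
      n_peptide_rows = sum(vapply(peptides, nrow, numeric(1))),
      n_samples = nrow(annotation))
  } else {
    res <- tryCatch({
      annotation <- readSampleAnnotation(config$inputs$annotation)
      peptides <- lapply(config$inputs$peptides, readPeptideTable)
      if (is.null(names(peptides)) || any(!nzchar(names(peptides))))
        stop("inputs$peptides must be a named (per-tissue) list of paths")
      if (!is.null(config$inputs$catalog))
        catalog <- readComplexCatalog(config$inputs$catalog)
      NULL
    }, error = function(e) stageFail(outdir, "load", e))
    manifest$stages$load <- list(status = "complete",
                                 tissues = names(peptides))
  }
  tissues <- names(peptides)

  pqs <- NULL
  if ("quantify" %in% config$stages) {
    pqs <- tryCatch({
      out <- lapply(tissues, function(tis) {
        pq <- quantifyTissue(peptides[[tis]], annotation, tis,
                             kMad = config$kMad,
                             removeOutliers = config$removeOutliers)
        writeProteinMatrix(pq, file.path(outdir, paste0("protein_matrix_",
                                                        tis, ".tsv")))
        qc <- S4Vectors::metadata(pq)$qc
        writeTsv(data.frame(
          entity = c(qc$removed_single_batch, qc$flagged_samples),
          reason = c(rep("single_batch", length(qc$removed_single_batch)),
                     rep("pca_outlier_flag", length(qc$flagged_samples)))),
          file.path(outdir, paste0("qc_", tis, ".tsv")))
        pq
      })
      names(out) <- tissues
      out
    }, error = function(e) stageFail(outdir, "quantify", e))
    manifest$stages$quantify <- list(
      status = "complete",
      n_proteins = vapply(pqs, nrow, numeric(1)),
      removed_single_batch = vapply(pqs, function(p)
        length(S4Vectors::metadata(p)$qc$removed_single_batch), numeric(1)),
      flagged_samples = lapply(pqs, function(p)
        S4Vectors::metadata(p)$qc$flagged_samples))
  }

  effectsList <- NULL
  if ("effects" %in% config$stages) {
    if (is.null(pqs)) stop("the 'effects' stage requires 'quantify'")
    effectsList <- tryCatch({
      out <- lapply(pqs, proteinEffects)
      for (tis in tissues)
        writeTsv(out[[tis]][, c("protein_id", "effect_type", "coefficient",
                                "se", "p", "q")],
                 file.path(outdir, paste0("effects_", tis, ".tsv")))
      cl <- suppressWarnings(clusterAgeEffects(out, qCut = config$fdrAbundance))
      if (!is.null(cl)) {
        writeTsv(data.frame(protein_id = cl$order,
                            cluster = cl$clusters[cl$order]),
                 file.path(outdir, "age_effect_clusters.tsv"))
        writeLines(cl$newick, file.path(outdir, "age_effect_dendrogram.nwk"))
      }
      out
    }, error = function(e) stageFail(outdir, "effects", e))
    manifest$stages$effects <- list(
      status = "complete",
      n_tests = sum(vapply(effectsList, nrow, numeric(1))),
      n_significant_age = sum(vapply(effectsList, function(e)
        sum(e$effect_type == "age" & !is.na(e$q) &
            e$q < config$fdrAbundance), numeric(1))))
  }

  if ("cross_tissue" %in% config$stages) {
    if (is.null(pqs)) stop("the 'cross_tissue' stage requires 'quantify'")
    ct <- tryCatch({
      res <- crossTissueEffects(pqs)
      if (!is.null(res))
        writeTsv(res, file.path(outdir, "cross_tissue_effects.tsv"))
      vd <- varianceDecomposition(pqs)
      if (!is.null(vd$varp))
        writeTsv(vd$varp, file.path(outdir, "variance_decomposition.tsv"))
      if (!is.null(vd$blups))
        writeTsv(vd$blups, file.path(outdir, "blups.tsv"))
      list(res = res, vd = vd)
    }, error = function(e) stageFail(outdir, "cross_tissue", e))
    manifest$stages$cross_tissue <- list(
      status = "complete",
      n_proteins_multitissue = if (is.null(ct$res)) 0 else nrow(ct$res),
      n_proteins_all_tissues = if (is.null(ct$vd$varp)) 0 else
        nrow(ct$vd$varp))
  }

  if ("complexes" %in% config$stages) {
    if (is.null(pqs)) stop("the 'complexes' stage requires 'quantify'")
    if (is.null(catalog))
      stop("the 'complexes' stage requires a complex catalog ",
           "(inputs$catalog or simulated)")
    cx <- tryCatch({
      per_tissue <- lapply(pqs, complexAnalysis, catalog = catalog,
                           permutations = config$permutations,
                           seed = config$seed)
      adj <- adjustComplexFamilies(per_tissue)
      for (nm in c("cohesiveness", "abundance", "cohesivenessChange",
                   "pairTests"))
        if (!is.null(adj[[nm]]))
          writeTsv(adj[[nm]], file.path(outdir, paste0("complex_", nm, ".tsv")))
      adj
    }, error = function(e) stageFail(outdir, "complexes", e))
    manifest$stages$complexes <- list(
      status = "complete",
      n_complex_tissue = if (is.null(cx$abundance)) 0 else
        length(unique(paste(cx$abundance$complex_id, cx$abundance$tissue))),
      n_cohesiveness_hits = if (is.null(cx$cohesivenessChange)) 0 else
        sum(!is.na(cx$cohesivenessChange$q) &
            cx$cohesivenessChange$q < config$fdrCohesiveness))
  }

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Validate pipeline input files
#'
#' Schema checks on the annotation, peptide and catalog files: required
#' columns, positive intensities, uniqueness of (peptide_id, sample_id),
#' known samples, and exactly one bridge per (tissue, batch). Reports every
#' violation instead of stopping at the first.
#'
#' @param annotation path to the sample annotation TSV.
#' @param peptides character vector of peptide TSV paths.
#' @param catalog optional complex catalog path.
#' @return data.frame with columns `file`, `rule`, `detail` (zero rows when
#'   everything is valid).
#' @export
validateInputs <- function(annotation, peptides = character(),
                           catalog = NULL) {
  v <- list()
  note <- function(file, rule, detail)
    v[[length(v) + 1]] <<- data.frame(file = file, rule = rule,
                                      detail = detail)
  ann <- tryCatch(readSampleAnnotation(annotation), error = function(e) {
    note(annotation, "annotation_schema", conditionMessage(e)); NULL
  })
  if (!is.null(ann)) {
    if (anyDuplicated(ann$sample_id))
      note(annotation, "duplicate_sample_id",
           paste(unique(ann$sample_id[duplicated(ann$sample_id)]),
                 collapse = ", "))
    tb <- ann[ann$is_bridge, ]
    counts <- table(paste(tb$tissue, tb$batch))
    all_tb <- unique(paste(ann$tissue, ann$batch))
    for (b in all_tb) {
      k <- if (b %in% names(counts)) counts[[b]] else 0
      if (k != 1)
        note(annotation, "bridge_per_batch",
             sprintf("tissue/batch %s has %d bridge samples (need 1)", b, k))
    }
  }
  for (p in peptides) {
    pep <- tryCatch(readPeptideTable(p), error = function(e) {
      note(p, "peptide_schema", conditionMessage(e)); NULL
    })
    if (is.null(pep)) next
    if (any(pep$intensity <= 0))
      note(p, "nonpositive_intensity",
           sprintf("%d rows with intensity <= 0", sum(pep$intensity <= 0)))
    dup <- duplicated(pep[, c("peptide_id", "sample_id")])
    if (any(dup)) {
      first <- which(dup)[1]
      other <- which(pep$peptide_id == pep$peptide_id[first] &
                     pep$sample_id == pep$sample_id[first])[1]
      note(p, "duplicate_peptide_sample",
           sprintf("%d duplicated (peptide_id, sample_id) rows, e.g. rows %d and %d (%s, %s)",
                   sum(dup), other, first, pep$peptide_id[first],
                   pep$sample_id[first]))
    }
    if (!is.null(ann)) {
      unknown <- setdiff(pep$sample_id, ann$sample_id)
      if (length(unknown))
        note(p, "unknown_sample",
             paste(utils::head(unknown, 5), collapse = ", "))
    }
  }
  if (!is.null(catalog)) {
    tryCatch(readComplexCatalog(catalog), error = function(e)
      note(catalog, "catalog_schema", conditionMessage(e)))
  }
  if (length(v)) do.call(rbind, v) else
    data.frame(file = character(), rule = character(), detail = character())
}
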