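#' Generate the sample annotation for the full study design
#'
#' Lays out the TMT design: each tissue is run as two batches, each holding
#' half of the mice plus one pooled bridge sample. Mice are split into
#' batches so that age-by-sex groups are balanced across batches as far as
#' group sizes allow (odd groups split n/2 vs n/2 + 1 with alternating
#' direction so batch totals stay equal). Every mouse appears in exactly one
#' batch per tissue; the batch split and the within-batch TMT tag of a mouse
#' are identical across tissues, as in a multi-tissue TMT study where each
#' animal keeps its channel.
#'
#' @param config a [SimConfig-class].
#' @return data.frame with columns `sample_id`, `mouse_id`, `tissue`,
#'   `batch` (1/2), `tag`, `age`, `sex`, `is_bridge`.
#' @examples
#' ann <- generateDesign(simConfig(nTissues = 2))
#' table(ann$batch, ann$is_bridge)
#' @export
generateDesign <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  n <- config@nMicePerGroup
  groups <- expand.grid(sex = config@sexLevels, age = config@ageLevels,
                        stringsAsFactors = FALSE)
  mice <- do.call(rbind, lapply(seq_len(nrow(groups)), function(g) {
    data.frame(age = groups$age[g], sex = groups$sex[g],
               member = seq_len(n), group = g)
  }))
  mice$mouse_id <- sprintf("M%02d", seq_len(nrow(mice)))
  # balanced 2x2 start pattern keeps batches balanced for any group size,
  # including n = 1 (then batch1 = {ref-sex/ref-age, alt-sex/alt-age})
  start <- c(0L, 1L, 1L, 0L)[(mice$group - 1L) %% 4L + 1L]
  mice$batch <- 1L + (mice$member - 1L + start) %% 2L
  if (abs(sum(mice$batch == 1L) - sum(mice$batch == 2L)) > 1L)
    warning("batch sizes differ by more than one animal; proceeding with near-balance")
  # within-batch tag assignment, stable across tissues
  mice$tag <- NA_character_
  for (b in 1:2) {
    idx <- which(mice$batch == b)
    mice$tag[idx] <- sprintf("tag%02d", seq_along(idx))
  }
  bridge_tag <- sprintf("tag%02d", max(sum(mice$batch == 1), sum(mice$batch == 2)) + 1L)

  tissues <- tissueNames(config@nTissues)
  per_tissue <- function(tis) {
    smp <- data.frame(
      sample_id = paste0(tis, "_b", mice$batch, "_", mice$mouse_id),
      mouse_id = mice$mouse_id, tissue = tis, batch = mice$batch,
      tag = mice$tag, age = mice$age, sex = mice$sex, is_bridge = FALSE)
    bridge <- data.frame(
      sample_id = paste0(tis, "_b", 1:2, "_bridge"),
      mouse_id = "bridge", tissue = tis, batch = 1:2, tag = bridge_tag,
      age = "pooled", sex = "pooled", is_bridge = TRUE)
    rbind(smp, bridge)
  }
  ann <- do.call(rbind, lapply(tissues, per_tissue))
  rownames(ann) <- NULL
  ann[order(ann$tissue, ann$batch, ann$is_bridge, ann$mouse_id), , drop = FALSE]
}

# draw n values uniformly from an inclusive integer range; safe for
# degenerate ranges (sample(4, ...) would otherwise draw from 1:4)
sampleRange <- function(range, n) {
  if (range[1] == range[2]) rep(as.integer(range[1]), n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

tissueNames <- function(n) {
  organs <- c("kidney", "liver", "fat", "spleen", "lung", "heart",
              "muscle", "striatum", "cerebellum", "hippocampus")
  if (n <= length(organs)) organs[seq_len(n)] else
    c(organs, sprintf("tissue%02d", seq_len(n - length(organs))))
}

#' Simulate latent protein log2 abundances with known ground truth
#'
#' For every tissue, draws a proteins x samples matrix of latent log2
#' abundances following the additive model used throughout the analysis:
#' baseline + age + sex + age-by-sex + batch offset + mouse, tag and batch
#' random effects + a per-complex latent factor with group-specific loading
#' (which creates within-complex co-abundance, differing between age groups
#' when the loadings differ) + residual noise. The bridge sample of each
#' batch carries the per-protein mean over all in-study samples of the
#' tissue, mirroring a pool built from equal amounts of every mouse.
#'
#' Mouse and tag effects are drawn once per protein and shared across
#' tissues (the same animal and channel underlie each tissue's measurement);
#' batch effects, complex factors and residuals are drawn per tissue from a
#' tissue-named RNG substream, so adding tissues never perturbs existing
#' ones.
#'
#' @param design annotation from [generateDesign()].
#' @param config the same [SimConfig-class] used for the design.
#' @return list with elements `latent` (named list of proteins x samples
#'   matrices, one per tissue, bridge columns included), `truth` (ground
#'   truth: per-protein effects per tissue, complex membership and loadings,
#'   realized random effects), and `catalog` (a [ComplexCatalog-class]).
#' @export
simulateProteins <- function(design, config) {
  stopifnot(is(config, "SimConfig"))
  mice <- unique(design[!design$is_bridge,
                        c("mouse_id", "batch", "tag", "age", "sex")])
  mice <- mice[order(mice$mouse_id), ]
  nm <- nrow(mice); np <- config@nProteins
  tags <- sort(unique(mice$tag))
  proteins <- sprintf("P%04d", seq_len(np))

  gl <- withSubstream(config@seed, "proteins", {
    mu <- rnorm(np, config@baselineMean, config@baselineSd)
    beta_age <- ifelse(runif(np) < config@propAffected,
                       sample(c(-1, 1), np, replace = TRUE), 0) * config@ageEffect
    beta_sex <- ifelse(runif(np) < config@propAffected,
                       sample(c(-1, 1), np, replace = TRUE), 0) * config@sexEffect
    beta_int <- if (config@interactionEffect != 0)
      ifelse(runif(np) < config@propAffected,
             sample(c(-1, 1), np, replace = TRUE), 0) * config@interactionEffect
      else rep(0, np)
    u_mouse <- matrix(rnorm(np * nm, 0, config@mouseSd), np, nm,
                      dimnames = list(proteins, mice$mouse_id))
    u_tag <- matrix(rnorm(np * length(tags), 0, config@tagSd), np, length(tags),
                    dimnames = list(proteins, tags))
    sizes <- sampleRange(config@complexSize, config@nComplexes)
    memb <- sample(proteins, sum(sizes))
    cx <- split(memb, rep(seq_len(config@nComplexes), sizes))
    names(cx) <- sprintf("CPX%03d", seq_len(config@nComplexes))
    list(mu = mu, beta_age = beta_age, beta_sex = beta_sex,
         beta_int = beta_int, u_mouse = u_mouse, u_tag = u_tag, cx = cx)
  })

  # protein -> complex index (0 = none); members drawn without replacement
  cx_of <- integer(np); names(cx_of) <- proteins
  for (ci in seq_along(gl$cx)) cx_of[gl$cx[[ci]]] <- ci

  old <- levelIndicator(mice$age, config@ageLevels[2])
  fem <- levelIndicator(mice$sex, "F")
  agegrp <- as.character(mice$age)
  loading <- config@complexLoading[agegrp]  # per-mouse loading by age group

  tissues <- unique(design$tissue)
  latent <- list(); batch_eff <- list()
  for (tis in tissues) {
    tl <- withSubstream(config@seed, paste0("tissue:", tis), {
      u_batch <- matrix(rnorm(np * 2, 0, config@batchSd), np, 2)
      f <- if (length(gl$cx))
        matrix(rnorm(length(gl$cx) * nm), length(gl$cx), nm)
      else matrix(0, 0, nm)
      eps <- matrix(rnorm(np * nm, 0, config@residualSd), np, nm)
      list(u_batch = u_batch, f = f, eps = eps)
    })
    fixed <- gl$mu +
      outer(gl$beta_age, old) + outer(gl$beta_sex, fem) +
      outer(gl$beta_int, old * fem)
    lat <- fixed + gl$u_mouse +
      gl$u_tag[, match(mice$tag, tags), drop = FALSE] +
      tl$u_batch[, mice$batch, drop = FALSE] + tl$eps
    if (length(gl$cx)) {
      has_cx <- cx_of > 0
      lat[has_cx, ] <- lat[has_cx, , drop = FALSE] +
        tl$f[cx_of[has_cx], , drop = FALSE] *
        matrix(loading, sum(has_cx), nm, byrow = TRUE)
    }
    dimnames(lat) <- list(proteins, mice$mouse_id)
    # bridge = per-protein mean over all in-study samples of this tissue
    bridge <- rowMeans(lat)
    ann_t <- design[design$tissue == tis, ]
    full <- matrix(NA_real_, np, nrow(ann_t),
                   dimnames = list(proteins, ann_t$sample_id))
    for (i in seq_len(nrow(ann_t)))
      full[, i] <- if (ann_t$is_bridge[i]) bridge else lat[, ann_t$mouse_id[i]]
    latent[[tis]] <- full
    batch_eff[[tis]] <- tl$u_batch
  }

  effects <- do.call(rbind, lapply(tissues, function(tis) {
    data.frame(protein_id = proteins, tissue = tis,
               beta_age = gl$beta_age, beta_sex = gl$beta_sex,
               beta_interaction = gl$beta_int,
               beta_batch = batch_eff[[tis]][, 2] - batch_eff[[tis]][, 1])
  }))
  loadings <- do.call(rbind, lapply(names(gl$cx), function(cid) {
    data.frame(complex_id = cid, group = config@ageLevels,
               loading = unname(config@complexLoading[config@ageLevels]))
  }))
  truth <- list(
    effects = effects,
    membership = data.frame(
      complex_id = rep(names(gl$cx), lengths(gl$cx)),
      protein_id = unlist(gl$cx, use.names = FALSE)),
    loadings = loadings,
    randomEffects = list(mouse = gl$u_mouse, tag = gl$u_tag,
                         batch = batch_eff))
  catalog <- complexCatalog(gl$cx,
    setNames(rep("simulated complex", length(gl$cx)), names(gl$cx)))
  list(latent = latent, truth = truth, catalog = catalog)
}

#' Emit quantified peptides from latent protein abundances
#'
#' Each protein emits K peptides (K drawn from the configured range) with a
#' fixed per-peptide ionization efficiency (log-normal, median 1, shared
#' across tissues and samples). The raw intensity of peptide m in sample i
#' is `e_m * 2^(latent + noise)` with independent log2-scale Gaussian noise
#' per (peptide, sample); intensities are therefore strictly positive. Each
#' peptide is detected independently per batch with probability
#' `detectProb`; an undetected peptide is absent from every sample of that
#' batch, which is what drives the downstream single-batch protein filter.
#'
#' @param latent named list of latent matrices from [simulateProteins()].
#' @param design annotation from [generateDesign()].
#' @param config the [SimConfig-class].
#' @return named list (per tissue) of long-format data.frames with columns
#'   `peptide_id`, `protein_id`, `sample_id`, `intensity`.
#' @export
simulatePeptides <- function(latent, design, config) {
  proteins <- rownames(latent[[1]])
  np <- length(proteins)
  st <- withSubstream(config@seed, "peptides", {
    k <- sampleRange(config@peptidesPerProtein, np)
    pep_prot <- rep(seq_len(np), k)
    pep_id <- paste0(proteins[pep_prot], "_pep",
                     unlist(lapply(k, seq_len), use.names = FALSE))
    eff <- exp(rnorm(length(pep_id), 0, config@peptideEfficiencySd))
    list(pep_prot = pep_prot, pep_id = pep_id, eff = eff)
  })
  npep <- length(st$pep_id)

  out <- list()
  for (tis in names(latent)) {
    ann_t <- design[design$tissue == tis, ]
    lat <- latent[[tis]]
    tab <- withSubstream(config@seed, paste0("peptides:", tis), {
      detect <- matrix(rbinom(npep * 2, 1, config@detectProb) == 1, npep, 2)
      parts <- list()
      for (b in 1:2) {
        det <- which(detect[, b])
        if (!length(det)) next
        smp <- ann_t$sample_id[ann_t$batch == b]
        pep_idx <- rep(det, each = length(smp))
        smp_idx <- rep(match(smp, colnames(lat)), times = length(det))
        noise <- rnorm(length(pep_idx), 0, config@peptideNoiseSd)
        parts[[b]] <- data.frame(
          peptide_id = st$pep_id[pep_idx],
          protein_id = proteins[st$pep_prot[pep_idx]],
          sample_id = colnames(lat)[smp_idx],
          intensity = st$eff[pep_idx] *
            2^(lat[cbind(st$pep_prot[pep_idx], smp_idx)] + noise))
      }
      do.call(rbind, parts)
    })
    rownames(tab) <- NULL
    out[[tis]] <- tab
  }
  out
}

#' Simulate a complete study
#'
#' Convenience wrapper chaining [generateDesign()], [simulateProteins()],
#' and [simulatePeptides()]. Identical configurations (including the seed)
#' give byte-identical results.
#'
#' @param config a [SimConfig-class].
#' @return list with `annotation`, `peptides` (per-tissue list of long
#'   tables), `latent`, `truth`, and `catalog`.
#' @examples
#' sim <- simulateStudy(simConfig(nTissues = 1, nProteins = 30,
#'                                nComplexes = 2, seed = 7))
#' head(sim$peptides[[1]])
#' @export
simulateStudy <- function(config) {
  design <- generateDesign(config)
  pr <- simulateProteins(design, config)
  peps <- simulatePeptides(pr$latent, design, config)
  list(annotation = design, peptides = peps, latent = pr$latent,
       truth = pr$truth, catalog = pr$catalog)
}

#' Write a simulated study to disk as plain-text tables
#'
#' Writes the sample annotation, one peptide table per tissue, the ground
#' truth effect table, and the complex catalog (GMT-like format) under
#' `dir`.
#'
#' @param sim result of [simulateStudy()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named character vector of written paths.
#' @export
writeStudy <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(annotation = file.path(dir, "annotation.tsv"))
  writeTsv(sim$annotation, paths[["annotation"]])
  for (tis in names(sim$peptides)) {
    p <- file.path(dir, paste0("peptides_", tis, ".tsv"))
    writeTsv(sim$peptides[[tis]], p)
    paths[[paste0("peptides_", tis)]] <- p
  }
  paths[["truth_effects"]] <- file.path(dir, "truth_effects.tsv")
  writeTsv(sim$truth$effects, paths[["truth_effects"]])
  paths[["catalog"]] <- file.path(dir, "complexes.gmt")
  writeComplexCatalog(sim$catalog, paths[["catalog"]])
  invisible(paths)
}
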