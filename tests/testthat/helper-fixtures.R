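# Fixtures are generated in code; nothing is read from disk.

# small simulation config for fast module tests
smallConfig <- function(...) {
  defaults <- list(nTissues = 2L, nProteins = 40L, nComplexes = 2L,
                   complexSize = c(4L, 5L), seed = 11L)
  args <- utils::modifyList(defaults, list(...))
  do.call(simConfig, args)
}

# noise-free configuration: peptide chain becomes deterministic
noiselessConfig <- function(...) {
  base <- list(mouseSd = 0, tagSd = 0, batchSd = 0, residualSd = 0,
               peptideNoiseSd = 0, peptideEfficiencySd = 0,
               baselineSd = 0, detectProb = 1, propAffected = 0,
               complexLoading = c(young = 0, old = 0))
  do.call(smallConfig, utils::modifyList(base, list(...)))
}

# annotation for a single-tissue toy with nb samples + 1 bridge per batch
toyAnnotation <- function(nPerBatch = 4, tissue = "liver") {
  rows <- list()
  mouse <- 0
  for (b in 1:2) {
    for (i in seq_len(nPerBatch)) {
      mouse <- mouse + 1
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = sprintf("%s_b%d_M%02d", tissue, b, mouse),
        mouse_id = sprintf("M%02d", mouse), tissue = tissue, batch = b,
        tag = sprintf("tag%02d", i),
        age = if (i <= nPerBatch / 2) "young" else "old",
        sex = if (mouse %% 2 == 0) "M" else "F", is_bridge = FALSE)
    }
    rows[[length(rows) + 1]] <- data.frame(
      sample_id = sprintf("%s_b%d_bridge", tissue, b), mouse_id = "bridge",
      tissue = tissue, batch = b, tag = "tag99", age = "pooled",
      sex = "pooled", is_bridge = TRUE)
  }
  do.call(rbind, rows)
}

# random toy peptide table over a toy annotation
toyPeptides <- function(annotation, nProteins = 5, nPeptides = 12,
                        seed = 1) {
  set.seed(seed)
  prot <- sprintf("P%02d", sort(sample(seq_len(nProteins), nPeptides,
                                       replace = TRUE)))
  pep <- sprintf("%s_pep%02d", prot, seq_len(nPeptides))
  do.call(rbind, lapply(annotation$sample_id, function(s) {
    data.frame(peptide_id = pep, protein_id = prot, sample_id = s,
               intensity = exp(rnorm(nPeptides, 8, 1)))
  }))
}

# build a ProteinQuant directly from a value matrix (bypasses peptides)
makeProteinQuant <- function(values, annotation, tissue = "liver") {
  ann <- annotation[!annotation$is_bridge, ]
  obs <- matrix(TRUE, nrow(values), 2,
                dimnames = list(rownames(values), c("batch1", "batch2")))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2ratio = values[, ann$sample_id, drop = FALSE]),
    colData = S4Vectors::DataFrame(
      ann[, c("sample_id", "mouse_id", "tissue", "batch", "tag", "age", "sex")],
      row.names = ann$sample_id),
    metadata = list(tissue = tissue, observed = obs,
                    qc = list(removed_single_batch = character(),
                              flagged_samples = character())))
  new("ProteinQuant", se)
}

# literal transcription of the three quantification formulas, used as the
# independent oracle: theta = sum / batch max; y = sum(peptides)/theta;
# ytilde = log2((y+1)/(y_bridge+1))
oracleQuantify <- function(peptides, annotation) {
  theta <- numeric(nrow(annotation))
  names(theta) <- annotation$sample_id
  for (s in annotation$sample_id) {
    tot_s <- sum(peptides$intensity[peptides$sample_id == s])
    batch_samples <- annotation$sample_id[annotation$batch ==
                                            annotation$batch[annotation$sample_id == s]]
    tot_max <- max(vapply(batch_samples, function(ss)
      sum(peptides$intensity[peptides$sample_id == ss]), numeric(1)))
    theta[s] <- tot_s / tot_max
  }
  proteins <- sort(unique(peptides$protein_id))
  y <- matrix(0, length(proteins), nrow(annotation),
              dimnames = list(proteins, annotation$sample_id))
  for (j in proteins) for (s in annotation$sample_id) {
    rows <- peptides$protein_id == j & peptides$sample_id == s
    y[j, s] <- sum(peptides$intensity[rows]) / theta[s]
  }
  yt <- y
  for (s in annotation$sample_id) {
    b <- annotation$batch[annotation$sample_id == s]
    br <- annotation$sample_id[annotation$batch == b & annotation$is_bridge]
    yt[, s] <- log2((y[, s] + 1) / (y[, br] + 1))
  }
  list(theta = theta, y = y, ytilde = yt)
}
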