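#' Read a long-format peptide table
#'
#' Expects tab-separated columns `peptide_id`, `protein_id`, `sample_id`,
#' `intensity`.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readPeptideTable <- function(path) {
  df <- readTsv(path)
  need <- c("peptide_id", "protein_id", "sample_id", "intensity")
  if (!all(need %in% colnames(df)))
    stop(path, " must have columns: ", paste(need, collapse = ", "))
  df
}

#' Read a sample annotation table
#'
#' Expects tab-separated columns `sample_id`, `mouse_id`, `tissue`,
#' `batch`, `tag`, `age`, `sex`, `is_bridge`.
#'
#' @param path TSV path.
#' @return data.frame with `is_bridge` as logical.
#' @export
readSampleAnnotation <- function(path) {
  df <- readTsv(path)
  need <- c("sample_id", "mouse_id", "tissue", "batch", "tag", "age",
            "sex", "is_bridge")
  if (!all(need %in% colnames(df)))
    stop(path, " must have columns: ", paste(need, collapse = ", "))
  df$is_bridge <- as.logical(df$is_bridge)
  df
}

#' Read a complex catalog in GMT-like format
#'
#' Each line: `complex_id <TAB> description <TAB> member1 <TAB> member2 ...`
#'
#' @param path file path.
#' @return a [ComplexCatalog-class].
#' @export
readComplexCatalog <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, character(1), 1)
  desc <- vapply(parts, `[`, character(1), 2)
  memb <- lapply(parts, function(p) p[-(1:2)])
  names(memb) <- ids
  complexCatalog(memb, setNames(desc, ids))
}

#' Write a complex catalog in GMT-like format
#'
#' @param catalog a [ComplexCatalog-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeComplexCatalog <- function(catalog, path) {
  lines <- vapply(names(catalog), function(cid) {
    paste(c(cid, catalog@description[[cid]], members(catalog, cid)),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a per-tissue protein matrix as TSV
#'
#' Proteins x samples, first column `protein_id`, floats at 6 significant
#' digits.
#'
#' @param x a [ProteinQuant-class].
#' @param path output path.
#' @param assayName assay to write (default `"log2ratio"`).
#' @return invisibly, the path.
#' @export
writeProteinMatrix <- function(x, path, assayName = "log2ratio") {
  writeMatrixTsv(SummarizedExperiment::assay(x, assayName), path)
}
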