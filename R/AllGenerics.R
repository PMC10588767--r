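#' Tissue of a quantification object
#' @param x a [ProteinQuant-class] object.
#' @return single character, the tissue identifier.
#' @export
setGeneric("tissueName", function(x) standardGeneric("tissueName"))

#' @rdname tissueName
#' @export
setMethod("tissueName", "ProteinQuant",
          function(x) S4Vectors::metadata(x)$tissue)

#' Per-protein, per-batch observation mask
#' @param x a [ProteinQuant-class] object.
#' @return logical matrix, proteins x batches; `TRUE` when at least one
#'   peptide of the protein was quantified in at least one sample of the
#'   batch.
#' @export
setGeneric("observedMask", function(x) standardGeneric("observedMask"))

#' @rdname observedMask
#' @export
setMethod("observedMask", "ProteinQuant",
          function(x) S4Vectors::metadata(x)$observed)

#' Complex members
#' @param x a [ComplexCatalog-class].
#' @param complex optional complex id(s); default all.
#' @return named list of member protein id vectors (or a single character
#'   vector when one complex is requested).
#' @export
setGeneric("members", function(x, complex = NULL) standardGeneric("members"))

#' @rdname members
#' @export
setMethod("members", "ComplexCatalog", function(x, complex = NULL) {
  if (is.null(complex)) return(x@members)
  if (length(complex) == 1L) x@members[[complex]] else x@members[complex]
})
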