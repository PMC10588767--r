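# Internal helpers: named RNG substreams and TSV conventions.

# Deterministic 31-bit seed for a named substream of a master seed.
# A simple polynomial string hash keeps substreams stable across sessions
# and independent of evaluation order; adding tissues or stages never
# perturbs the draws of existing ones.
substreamSeed <- function(seed, name) {
  stopifnot(length(seed) == 1, is.finite(seed))
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483647
  as.integer((h + (as.numeric(seed) %% 2147483647) * 48271) %% 2147483647)
}

withSubstream <- function(seed, name, expr) {
  set.seed(substreamSeed(seed, name))
  expr
}

# All pipeline TSVs share one dialect: tab-separated, header, no quotes,
# floats at 6 significant digits.
writeTsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 6))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readTsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

writeMatrixTsv <- function(mat, path, rowlab = "protein_id") {
  df <- data.frame(rownames(mat), signif(mat, 6), check.names = FALSE)
  colnames(df) <- c(rowlab, colnames(mat))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readMatrixTsv <- function(path) {
  df <- readTsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

# Factor coding used throughout the models: old = 1 / young = 0,
# female = 1 / male = 0, second batch = 1 / first batch = 0.
# For non-default labels the second level of factor() is coded 1.
levelIndicator <- function(x, one = NULL) {
  x <- as.character(x)
  lev <- sort(unique(x))
  if (!is.null(one) && one %in% lev) return(as.numeric(x == one))
  if (length(lev) == 1L) return(rep(0, length(x)))
  as.numeric(x == lev[2])
}

designIndicators <- function(annotation) {
  list(old    = levelIndicator(annotation$age, "old"),
       female = levelIndicator(annotation$sex, "F"),
       batch2 = {
         b <- as.character(annotation$batch)
         as.numeric(b == sort(unique(b))[min(2, length(unique(b)))] & length(unique(b)) > 1)
       })
}
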