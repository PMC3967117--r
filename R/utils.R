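## Internal helpers shared across modules.

riskFactor <- function(x) factor(x, levels = RISK_LEVELS, ordered = TRUE)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

## MD5 of an arbitrary R object for report provenance: serialize to a
## temporary file and hash that (tools::md5sum is file-based).
hashObject <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  con <- file(tf, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(tf))
}

hashFile <- function(path) {
  if (is.null(path) || !file.exists(path)) return(NA_character_)
  unname(tools::md5sum(path))
}

## Hardy-Weinberg genotype probabilities for effect-allele frequency p.
hweProbs <- function(p) c((1 - p)^2, 2 * p * (1 - p), p^2)

## Strand-ambiguous allele pair (A/T or C/G): indistinguishable under a
## strand flip, so excluded from genotype matching by default.
isStrandAmbiguous <- function(a1, a2) {
  pair <- paste(pmin(toupper(a1), toupper(a2)), pmax(toupper(a1), toupper(a2)))
  pair %in% c("A T", "C G")
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readTsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = NA, check.names = FALSE)
}
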