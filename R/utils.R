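#' @import data.table
#' @importFrom stats chisq.test phyper rbinom runif setNames aggregate
#'   hclust cutree dist pchisq
#' @importFrom utils head tail write.table
#' @importFrom methods as
NULL

#' The 12 ordered reference-to-variant mismatch types
#'
#' In the conventional display order (reference base major, variant base
#' minor). Mismatch spectra and transform schemes are indexed by these.
#'
#' @export
MISMATCH_TYPES <- c("AC", "AG", "AT",
                    "CA", "CG", "CT",
                    "GA", "GC", "GT",
                    "TA", "TC", "TG")

BASES <- c("A", "C", "G", "T")

comp_base <- function(x) {
  chartr("ACGTN", "TGCAN", x)
}

#' Reverse-complement DNA strings
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    comp_base(paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Canonical site key
#'
#' Builds the unique identifier used throughout the package for an editing
#' site: contig, 1-based position, strand and mismatch type.
#'
#' @param contig,pos,strand,type vectors of equal length (recycled).
#' @return character vector of keys.
#' @keywords internal
site_key <- function(contig, pos, strand, type) {
  paste(contig, pos, strand, type, sep = ":")
}

assert_cols <- function(df, cols, what = "table") {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stopf("%s is missing required column(s): %s", what,
          paste(miss, collapse = ", "))
  invisible(df)
}

# Empty CandidateSite table with the canonical column set.
empty_sites <- function() {
  data.table(contig = character(), pos = integer(), strand = character(),
             type = character(), coverage = integer(), variant = integer(),
             rate = numeric(), study = character(), sample = character(),
             pipeline = character())
}

# Empty PositionCounts table.
empty_counts <- function() {
  data.table(contig = character(), pos = integer(), strand = character(),
             ref = character(), nA = integer(), nC = integer(),
             nG = integer(), nT = integer(), total = integer())
}

as_counts_dt <- function(df) {
  dt <- if (data.table::is.data.table(df)) data.table::copy(df)
        else as.data.table(df)
  assert_cols(dt, c("contig", "pos", "strand", "ref", "nA", "nC", "nG", "nT"),
              "position-counts table")
  if (!"total" %in% names(dt)) dt[, total := nA + nC + nG + nT]
  dt
}
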