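# Internal helpers shared across modules.

.karyotype <- paste0("chr", c(1:22, "X", "Y"))

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Normalize chromosome labels
#'
#' Chromosome labels are compared as exact strings after normalizing the
#' optional `"chr"` prefix: `"4"`, `"chr4"` and `"CHR4"` all become `"chr4"`.
#'
#' @param x character vector of chromosome labels.
#' @return character vector with a canonical `"chr"` prefix.
#' @export
#' @examples
#' normalize_chrom(c("4", "chrX", "CHR17"))
normalize_chrom <- function(x) {
  x <- trimws(as.character(x))
  if (any(is.na(x) | x == ""))
    stopf("chromosome labels must be non-empty")
  has <- grepl("^chr", x, ignore.case = TRUE)
  x[has] <- paste0("chr", substring(x[has], 4L))
  x[!has] <- paste0("chr", x[!has])
  x
}

# Karyotype-first ordering of chromosome labels (chr1..chr22, chrX, chrY,
# then anything else alphabetically).
chrom_levels <- function(chroms) {
  u <- unique(as.character(chroms))
  c(intersect(.karyotype, u), sort(setdiff(u, .karyotype)))
}

order_genomic <- function(chrom, start, end) {
  order(match(chrom, chrom_levels(chrom)), start, end)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a reproducible 31-bit sub-seed from a parent seed and an index.
sub_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 16807) %% 2147483647)
}

# Strip thousands separators from printed coordinates ("143,211,964").
strip_thousands <- function(x) gsub(",", "", trimws(as.character(x)), fixed = TRUE)

parse_coord <- function(x, what, lines) {
  out <- suppressWarnings(as.numeric(strip_thousands(x)))
  bad <- which(is.na(out) | out != floor(out))
  if (length(bad))
    stopf("cannot parse %s at line %d: '%s'", what, lines[bad[1]], x[bad[1]])
  out
}

as_flag <- function(x, what, lines) {
  x0 <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x0))
  out[x0 %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[x0 %in% c("false", "f", "0", "no", "n")] <- FALSE
  bad <- which(is.na(out))
  if (length(bad))
    stopf("cannot parse flag %s at line %d: '%s'", what, lines[bad[1]], x[bad[1]])
  out
}

require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stopf("%s is missing column(s): %s", what, paste(miss, collapse = ", "))
  invisible(df)
}

interval_key <- function(chrom, start, end) {
  sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end))
}
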