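# Domain types and tabular readers/writers.
#
# Coordinates are 1-based and inclusive on both ends throughout the package,
# matching the convention in which printed intervals such as
# chr4:143,211,964-146,188,881 name their first and last base. Converters to
# and from 0-based half-open coordinates live at the I/O boundary only.

#' Construct a table of genomic intervals
#'
#' @param chromosome character vector of chromosome labels; an optional
#'   `"chr"` prefix is normalized.
#' @param start,end 1-based inclusive coordinates with `1 <= start <= end`.
#' @return a `data.frame` with columns `chrom`, `start`, `end`.
#' @export
#' @examples
#' genomic_interval("4", 143211964, 146188881)
genomic_interval <- function(chromosome, start, end) {
  chrom <- normalize_chrom(chromosome)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(!is.finite(start)) || any(!is.finite(end)))
    stopf("interval coordinates must be finite")
  if (any(start < 1)) stopf("interval start must be >= 1")
  if (any(end < start)) stopf("interval end must be >= start")
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             stringsAsFactors = FALSE)
}

#' Convert intervals between 1-based inclusive and 0-based half-open
#'
#' The package works in 1-based inclusive coordinates; these helpers convert
#' at the boundary with BED-style tools.
#'
#' @param intervals a data.frame with `chrom`, `start`, `end`.
#' @return a data.frame in the other convention.
#' @export
to_zero_based <- function(intervals) {
  require_columns(intervals, c("chrom", "start", "end"), "interval table")
  transform(intervals, start = start - 1L)
}

#' @rdname to_zero_based
#' @export
from_zero_based <- function(intervals) {
  require_columns(intervals, c("chrom", "start", "end"), "interval table")
  genomic_interval(intervals$chrom, intervals$start + 1L, intervals$end)
}

# Validate a segment table: column presence, coordinate invariants, and the
# within-sample non-overlap rule. `lines` maps rows to file lines for error
# messages from readers; defaults to row numbers.
validate_segments <- function(seg, lines = NULL, what = "segment table") {
  require_columns(seg, c("sample", "chrom", "start", "end", "value"), what)
  if (is.null(lines)) lines <- seq_len(nrow(seg))
  if (nrow(seg) == 0) return(invisible(seg))
  if (any(!is.finite(seg$value)))
    stopf("%s: non-finite segment value at line %d", what,
          lines[which(!is.finite(seg$value))[1]])
  bad <- which(seg$start < 1 | seg$end < seg$start)
  if (length(bad))
    stopf("%s: invalid interval at line %d (%s:%s-%s)", what, lines[bad[1]],
          seg$chrom[bad[1]], seg$start[bad[1]], seg$end[bad[1]])
  key <- paste(seg$sample, seg$chrom)
  for (k in unique(key)) {
    i <- which(key == k)
    if (length(i) < 2) next
    o <- i[order(seg$start[i])]
    ov <- which(seg$start[o][-1] <= seg$end[o][-length(o)])
    if (length(ov)) {
      a <- o[ov[1]]; b <- o[ov[1] + 1]
      stopf(paste0("%s: overlapping segments within sample '%s': ",
                   "%s:%d-%d (line %d) and %s:%d-%d (line %d)"),
            what, seg$sample[a], seg$chrom[a], seg$start[a], seg$end[a],
            lines[a], seg$chrom[b], seg$start[b], seg$end[b], lines[b])
    }
  }
  invisible(seg)
}

#' Read segmented copy-number calls (SEG dialect)
#'
#' Reads a tab-delimited file with header
#' `sample  chrom  start  end  value` holding one copy-number segment per
#' row, where `value` is the segment statistic on the log2 scale (0 =
#' copy-neutral). Thousands separators in coordinates are tolerated and
#' stripped. Within each sample, segments on one chromosome must not
#' overlap; violations are rejected, never repaired.
#'
#' @param path path to the tab-delimited file.
#' @return a `data.frame` with columns `sample`, `chrom`, `start`, `end`,
#'   `value`, one row per segment.
#' @seealso [write_seg()], [build_regions()]
#' @export
read_seg <- function(path) {
  raw <- read.delim(path, colClasses = "character", check.names = FALSE,
                    stringsAsFactors = FALSE)
  require_columns(raw, c("sample", "chrom", "start", "end", "value"),
                  sprintf("SEG file '%s'", path))
  lines <- seq_len(nrow(raw)) + 1L  # header is line 1
  if (nrow(raw) == 0) {
    return(data.frame(sample = character(), chrom = character(),
                      start = integer(), end = integer(), value = numeric(),
                      stringsAsFactors = FALSE))
  }
  val <- suppressWarnings(as.numeric(raw$value))
  if (any(is.na(val)))
    stopf("SEG file '%s': cannot parse value at line %d: '%s'", path,
          lines[which(is.na(val))[1]], raw$value[which(is.na(val))[1]])
  seg <- data.frame(
    sample = raw$sample,
    chrom = normalize_chrom(raw$chrom),
    start = as.integer(parse_coord(raw$start, "start", lines)),
    end = as.integer(parse_coord(raw$end, "end", lines)),
    value = val,
    stringsAsFactors = FALSE)
  validate_segments(seg, lines = lines, what = sprintf("SEG file '%s'", path))
  seg
}

#' Write segments to a SEG-dialect TSV
#'
#' @param segments a segment `data.frame` as returned by [read_seg()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_seg <- function(segments, path) {
  validate_segments(segments)
  write.table(segments[, c("sample", "chrom", "start", "end", "value")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.mutation_columns <- c("sample", "gene", "chrom", "position", "ref", "alt",
                       "region_class", "allele_frequency", "coverage",
                       "alt_reads", "in_dbsnp", "in_germline")

# Validate a mutation table against the MutationCall invariants.
validate_mutations <- function(mut, lines = NULL, what = "mutation table") {
  require_columns(mut, .mutation_columns, what)
  if (is.null(lines)) lines <- seq_len(nrow(mut))
  if (nrow(mut) == 0) return(invisible(mut))
  bad <- which(mut$allele_frequency < 0 | mut$allele_frequency > 1)
  if (length(bad))
    stopf("%s: allele_frequency outside [0,1] at line %d (%s)", what,
          lines[bad[1]], mut$allele_frequency[bad[1]])
  bad <- which(mut$alt_reads > mut$coverage)
  if (length(bad))
    stopf("%s: alt_reads (%d) exceeds coverage (%d) at line %d", what,
          mut$alt_reads[bad[1]], mut$coverage[bad[1]], lines[bad[1]])
  bad <- which(mut$coverage < 0 | mut$alt_reads < 0)
  if (length(bad))
    stopf("%s: negative read count at line %d", what, lines[bad[1]])
  bad <- which(!mut$region_class %in% c("exon", "non-exon"))
  if (length(bad))
    stopf("%s: region_class must be 'exon' or 'non-exon' at line %d", what,
          lines[bad[1]])
  invisible(mut)
}

#' Read a somatic mutation table
#'
#' Reads a tab-delimited table of candidate somatic substitutions/indels with
#' columns `sample`, `gene`, `chrom`, `position`, `ref`, `alt`,
#' `region_class` (`exon`/`non-exon`), `allele_frequency`, `coverage`,
#' `alt_reads`, `in_dbsnp`, `in_germline`. Flag columns are coerced to
#' logical (`true/false`, `1/0`, `yes/no` accepted). Records violating the
#' call invariants (allele frequency outside \[0,1\], more supporting reads
#' than coverage) are rejected with the offending line number.
#'
#' @param path path to the tab-delimited file.
#' @return a validated mutation `data.frame`.
#' @seealso [filter_mutations()]
#' @export
read_mutation_table <- function(path) {
  raw <- read.delim(path, colClasses = "character", check.names = FALSE,
                    stringsAsFactors = FALSE)
  what <- sprintf("mutation table '%s'", path)
  require_columns(raw, .mutation_columns, what)
  lines <- seq_len(nrow(raw)) + 1L
  if (nrow(raw) == 0) {
    mut <- data.frame(sample = character(), gene = character(),
                      chrom = character(), position = integer(),
                      ref = character(), alt = character(),
                      region_class = character(), allele_frequency = numeric(),
                      coverage = integer(), alt_reads = integer(),
                      in_dbsnp = logical(), in_germline = logical(),
                      stringsAsFactors = FALSE)
    return(mut)
  }
  mut <- data.frame(
    sample = raw$sample,
    gene = raw$gene,
    chrom = normalize_chrom(raw$chrom),
    position = as.integer(parse_coord(raw$position, "position", lines)),
    ref = raw$ref,
    alt = raw$alt,
    region_class = trimws(raw$region_class),
    allele_frequency = suppressWarnings(as.numeric(raw$allele_frequency)),
    coverage = as.integer(parse_coord(raw$coverage, "coverage", lines)),
    alt_reads = as.integer(parse_coord(raw$alt_reads, "alt_reads", lines)),
    in_dbsnp = as_flag(raw$in_dbsnp, "in_dbsnp", lines),
    in_germline = as_flag(raw$in_germline, "in_germline", lines),
    stringsAsFactors = FALSE)
  if (any(is.na(mut$allele_frequency)))
    stopf("%s: cannot parse allele_frequency at line %d", what,
          lines[which(is.na(mut$allele_frequency))[1]])
  validate_mutations(mut, lines = lines, what = what)
  mut
}

#' @rdname read_mutation_table
#' @param mutations a validated mutation `data.frame`.
#' @export
write_mutation_table <- function(mutations, path) {
  validate_mutations(mutations)
  write.table(mutations[, .mutation_columns], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-level CNV event table
#'
#' Columns: `sample`, `gene`, `direction` (`gain`/`loss`) and optionally
#' `log2_ratio`. When `log2_ratio` is present its sign is checked against the
#' stated direction.
#'
#' @param path path to the tab-delimited file.
#' @return a `data.frame` of gene CNV events.
#' @export
read_gene_cnv_table <- function(path) {
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  what <- sprintf("gene CNV table '%s'", path)
  require_columns(raw, c("sample", "gene", "direction"), what)
  if (nrow(raw) && any(!raw$direction %in% c("gain", "loss")))
    stopf("%s: direction must be 'gain' or 'loss' (line %d)", what,
          which(!raw$direction %in% c("gain", "loss"))[1] + 1L)
  if ("log2_ratio" %in% names(raw) && nrow(raw)) {
    bad <- which((raw$direction == "gain" & raw$log2_ratio <= 0) |
                 (raw$direction == "loss" & raw$log2_ratio >= 0))
    if (length(bad))
      stopf("%s: direction contradicts log2_ratio sign at line %d", what,
            bad[1] + 1L)
  }
  raw
}

#' Read a cohort label table
#'
#' Columns: `sample_id`, `cancer_type`. Duplicate sample ids are rejected.
#'
#' @param path path to the tab-delimited file.
#' @return a `data.frame` mapping sample id to cancer-type label.
#' @export
read_cohort_labels <- function(path) {
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  what <- sprintf("cohort label table '%s'", path)
  require_columns(raw, c("sample_id", "cancer_type"), what)
  dup <- raw$sample_id[duplicated(raw$sample_id)]
  if (length(dup))
    stopf("%s: duplicated sample id '%s'", what, dup[1])
  raw
}

#' Write and read a region-by-sample copy-number matrix
#'
#' The on-disk format is tab-delimited with columns `chrom`, `start`, `end`
#' followed by one column per sample; it round-trips losslessly through
#' [read_region_matrix()].
#'
#' @param x a `region_matrix` (see [fill_matrix()]).
#' @param path output path.
#' @return `path` (writer) or a `region_matrix` (reader).
#' @export
write_region_matrix <- function(x, path) {
  stopifnot(inherits(x, "region_matrix"))
  if (nrow(x$regions) == 0) stopf("refusing to write an empty region matrix")
  out <- cbind(x$regions[, c("chrom", "start", "end")],
               as.data.frame(x$values, optional = TRUE))
  names(out) <- c("chrom", "start", "end", x$samples)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_region_matrix
#' @export
read_region_matrix <- function(path) {
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  require_columns(raw, c("chrom", "start", "end"),
                  sprintf("region matrix '%s'", path))
  samples <- setdiff(names(raw), c("chrom", "start", "end"))
  regions <- genomic_interval(raw$chrom, raw$start, raw$end)
  values <- as.matrix(raw[, samples, drop = FALSE])
  rownames(values) <- interval_key(regions$chrom, regions$start, regions$end)
  colnames(values) <- samples
  new_region_matrix(regions, samples, values, labels = NULL, fill = 0)
}
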