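# Alignment of multi-sample segmented copy-number data into disjoint
# regions, and construction of the region x sample value matrix.
#
# Breakpoints are the union of all samples' segment boundaries; the emitted
# regions are the maximal intervals between consecutive breakpoints that are
# covered by at least one sample's segment. By construction every region is
# covered all-or-none by any given segment, so the matrix fill is exact.

segments_to_granges <- function(segments) {
  lv <- chrom_levels(segments$chrom)
  gr <- GenomicRanges::GRanges(
    factor(segments$chrom, levels = lv),
    IRanges::IRanges(segments$start, segments$end))
  S4Vectors::mcols(gr)$sample <- segments$sample
  S4Vectors::mcols(gr)$value <- segments$value
  gr
}

new_region_matrix <- function(regions, samples, values, labels, fill) {
  structure(list(regions = regions, samples = samples, values = values,
                 labels = labels, fill = fill),
            class = "region_matrix")
}

empty_regions <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             stringsAsFactors = FALSE)
}

#' Align segment boundaries into disjoint regions
#'
#' Collects, per chromosome, the union of all samples' segment boundaries
#' and emits the maximal disjoint intervals between consecutive breakpoints
#' that are covered by at least one sample's segment (footprint-union
#' semantics: stretches covered by no sample are not emitted; set
#' `emit_gaps = TRUE` with a `genome` to include them). Output is sorted by
#' karyotype order then start; every region boundary coincides with a
#' boundary of some input segment.
#'
#' @param segments a validated segment `data.frame` (see [read_seg()]). A
#'   zero-row table yields an empty region set.
#' @param emit_gaps also emit regions covered by no sample (default `FALSE`).
#' @param genome named vector of chromosome lengths, required when
#'   `emit_gaps = TRUE`.
#' @return a `data.frame` of class `region_set` with columns `chrom`,
#'   `start`, `end`, pairwise disjoint and sorted.
#' @export
#' @examples
#' seg <- data.frame(sample = c("A", "B"), chrom = "chr1",
#'                   start = c(1, 51), end = c(100, 150), value = c(0.8, -0.9))
#' build_regions(seg)
build_regions <- function(segments, emit_gaps = FALSE, genome = NULL) {
  if (is.null(segments)) stopf("build_regions: segment table is missing")
  validate_segments(segments)
  if (nrow(segments) == 0) {
    out <- empty_regions()
    class(out) <- c("region_set", "data.frame")
    return(out)
  }
  gr <- segments_to_granges(segments)
  dj <- GenomicRanges::disjoin(gr)
  if (emit_gaps) {
    if (is.null(genome)) stopf("emit_gaps = TRUE requires a genome")
    lv <- GenomicRanges::seqlevels(dj)
    covered <- GenomicRanges::reduce(dj)
    bounds <- GenomicRanges::GRanges(
      factor(names(genome), levels = lv),
      IRanges::IRanges(1L, as.integer(genome)))
    gaps <- GenomicRanges::setdiff(bounds, covered)
    dj <- sort(c(dj, gaps))
  }
  dj <- sort(dj)
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(dj)),
                    start = GenomicRanges::start(dj),
                    end = GenomicRanges::end(dj),
                    stringsAsFactors = FALSE)
  class(out) <- c("region_set", "data.frame")
  out
}

#' Fill the region-by-sample copy-number matrix
#'
#' Entry (r, s) is the value of sample s's segment covering region r; for
#' region sets from [build_regions()] coverage is all-or-none, and a
#' partially covering segment is reported as an internal-consistency error.
#' Regions not covered by a sample receive `fill` (default 0, i.e.
#' log2-neutral: segment absence is read as no detected deviation).
#'
#' @param segments a validated segment `data.frame`.
#' @param regions a `region_set` from [build_regions()] (or any table of
#'   disjoint intervals whose boundaries refine the segments).
#' @param samples sample ids forming the matrix columns; defaults to the
#'   sorted unique samples in `segments`. Samples without segments are
#'   legal and yield all-`fill` columns.
#' @param fill value for uncovered (region, sample) entries (default 0).
#' @param labels optional named vector of class labels (names = sample ids),
#'   or a cohort label `data.frame` (`sample_id`, `cancer_type`).
#' @return an object of class `region_matrix`: list with `regions`,
#'   `samples`, `values` (region x sample matrix with `chrom:start-end`
#'   rownames), `labels`, `fill`.
#' @export
fill_matrix <- function(segments, regions, samples = NULL, fill = 0,
                        labels = NULL) {
  validate_segments(segments)
  require_columns(regions, c("chrom", "start", "end"), "region set")
  if (is.null(samples)) samples <- sort(unique(segments$sample))
  labels <- normalize_labels(labels, samples)
  values <- matrix(fill, nrow = nrow(regions), ncol = length(samples),
                   dimnames = list(
                     interval_key(regions$chrom, regions$start, regions$end),
                     samples))
  if (nrow(regions) > 0 && nrow(segments) > 0) {
    extra <- setdiff(unique(segments$sample), samples)
    if (length(extra))
      stopf("segments carry sample '%s' absent from the sample list", extra[1])
    lv <- chrom_levels(c(regions$chrom, segments$chrom))
    rg <- GenomicRanges::GRanges(factor(regions$chrom, levels = lv),
                                 IRanges::IRanges(regions$start, regions$end))
    sg <- GenomicRanges::GRanges(factor(segments$chrom, levels = lv),
                                 IRanges::IRanges(segments$start, segments$end))
    h <- GenomicRanges::findOverlaps(rg, sg)
    qi <- S4Vectors::queryHits(h); si <- S4Vectors::subjectHits(h)
    partial <- which(segments$start[si] > regions$start[qi] |
                     segments$end[si] < regions$end[qi])
    if (length(partial)) {
      p <- partial[1]
      stopf(paste0("internal consistency: segment %s:%d-%d (sample '%s') ",
                   "partially overlaps region %s:%d-%d; rebuild regions ",
                   "with build_regions()"),
            segments$chrom[si[p]], segments$start[si[p]], segments$end[si[p]],
            segments$sample[si[p]],
            regions$chrom[qi[p]], regions$start[qi[p]], regions$end[qi[p]])
    }
    values[cbind(qi, match(segments$sample[si], samples))] <-
      segments$value[si]
  }
  new_region_matrix(as.data.frame(regions), samples, values, labels, fill)
}

# Accept labels as NULL, a named vector, or a cohort label data.frame, and
# return a named vector aligned with `samples` (or NULL).
normalize_labels <- function(labels, samples) {
  if (is.null(labels)) return(NULL)
  if (is.data.frame(labels)) {
    require_columns(labels, c("sample_id", "cancer_type"), "label table")
    labels <- setNames(labels$cancer_type, labels$sample_id)
  }
  miss <- setdiff(samples, names(labels))
  if (length(miss))
    stopf("no class label for sample '%s'", miss[1])
  labels[samples]
}

#' Build a labelled region matrix from cohort segments in one step
#'
#' Convenience wrapper: [build_regions()] then [fill_matrix()]. When
#' `labels` is given, the matrix columns are the labelled samples (so
#' samples with no segments still appear, all-fill).
#'
#' @inheritParams fill_matrix
#' @return a `region_matrix`.
#' @export
region_matrix <- function(segments, labels = NULL, samples = NULL, fill = 0) {
  if (is.null(samples)) {
    labelled <- if (is.data.frame(labels)) labels$sample_id
                else if (!is.null(labels)) names(labels)
    # keep label order first; segment-only samples surface the missing-label
    # error in normalize_labels rather than being dropped silently
    samples <- union(labelled, sort(unique(segments$sample)))
  }
  if (length(samples) == 0) stopf("cohort contains no samples")
  regions <- build_regions(segments)
  fill_matrix(segments, regions, samples = samples, fill = fill,
              labels = labels)
}

#' Project segments of new samples onto an existing region set
#'
#' For classifying lesions against a cohort-derived region set, each
#' (region, sample) value is the coverage-weighted mean of the sample's
#' segment values over the region, with uncovered bases contributing `fill`.
#' Segments of the new samples need not align to the cohort breakpoints;
#' when they do (e.g. identical segmentation), projection reduces to the
#' exact [fill_matrix()] values.
#'
#' @param segments segment `data.frame` for the new samples.
#' @param regions a `region_set` (the cohort's).
#' @param samples column order; defaults to sorted unique segment samples.
#' @param fill value for uncovered bases (default 0).
#' @return a region x sample numeric matrix with `chrom:start-end` rownames.
#' @export
project_segments <- function(segments, regions, samples = NULL, fill = 0) {
  validate_segments(segments)
  require_columns(regions, c("chrom", "start", "end"), "region set")
  if (is.null(samples)) samples <- sort(unique(segments$sample))
  values <- matrix(fill, nrow = nrow(regions), ncol = length(samples),
                   dimnames = list(
                     interval_key(regions$chrom, regions$start, regions$end),
                     samples))
  if (nrow(regions) == 0 || nrow(segments) == 0) return(values)
  lv <- chrom_levels(c(regions$chrom, segments$chrom))
  rg <- GenomicRanges::GRanges(factor(regions$chrom, levels = lv),
                               IRanges::IRanges(regions$start, regions$end))
  sg <- GenomicRanges::GRanges(factor(segments$chrom, levels = lv),
                               IRanges::IRanges(segments$start, segments$end))
  h <- GenomicRanges::findOverlaps(rg, sg)
  if (length(h) == 0) return(values)
  qi <- S4Vectors::queryHits(h); si <- S4Vectors::subjectHits(h)
  w <- GenomicRanges::width(GenomicRanges::pintersect(rg[qi], sg[si]))
  region_w <- GenomicRanges::width(rg)
  # accumulate sum(value * overlap) and sum(overlap) per (region, sample)
  col <- match(segments$sample[si], samples)
  idx <- paste(qi, col)
  sv <- tapply(segments$value[si] * w, idx, sum)
  sw <- tapply(as.numeric(w), idx, sum)
  parts <- strsplit(names(sv), " ", fixed = TRUE)
  ri <- as.integer(vapply(parts, `[`, "", 1L))
  ci <- as.integer(vapply(parts, `[`, "", 2L))
  values[cbind(ri, ci)] <-
    (sv + fill * (region_w[ri] - sw)) / region_w[ri]
  values
}

#' @export
print.region_matrix <- function(x, ...) {
  cat(sprintf("Region matrix: %d regions x %d samples (fill = %g)\n",
              nrow(x$regions), length(x$samples), x$fill))
  if (!is.null(x$labels)) {
    tb <- table(x$labels)
    cat("  classes:", paste(sprintf("%s (%d)", names(tb), tb),
                            collapse = ", "), "\n")
  }
  invisible(x)
}

#' Total genomic length of a region set
#'
#' Equals the length of the union of all samples' segment footprints when
#' the regions come from [build_regions()].
#'
#' @param regions a `region_set`.
#' @return total base count.
#' @export
region_width <- function(regions) {
  require_columns(regions, c("chrom", "start", "end"), "region set")
  if (nrow(regions) == 0) return(0)
  sum(regions$end - regions$start + 1)
}
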