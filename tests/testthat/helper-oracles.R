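# Independent brute-force oracles and small fixture builders used across the
# suite. The oracles deliberately avoid the package's interval machinery:
# they expand segments to per-base value vectors and use plain set algebra.

# Random small genome (two chromosomes, <= 10 kb total).
random_tiny_genome <- function() {
  c(chrA = sample(2000:6000, 1), chrB = sample(1000:4000, 1))
}

# Random non-overlapping segments for `n_samples` samples: each sample's
# chromosome is cut at random breakpoints and each block is kept with
# probability 1/2. Values are bounded away from 0 so coverage is always
# distinguishable from fill.
random_tiny_segments <- function(genome, n_samples) {
  rows <- list()
  for (s in seq_len(n_samples)) {
    sid <- sprintf("S%02d", s)
    for (chrom in names(genome)) {
      L <- genome[[chrom]]
      n_cuts <- sample(0:6, 1)
      bounds <- sort(unique(c(1L, sample.int(L - 1, n_cuts) + 1L, L + 1L)))
      for (b in seq_len(length(bounds) - 1)) {
        if (runif(1) < 0.5) next
        rows[[length(rows) + 1]] <- data.frame(
          sample = sid, chrom = chrom,
          start = bounds[b], end = bounds[b + 1] - 1L,
          value = sample(c(-1, 1), 1) * runif(1, 0.1, 2),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(sample = character(), chrom = character(),
                      start = integer(), end = integer(), value = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# Per-base value map implied by raw segments: list chrom -> base x sample
# matrix, `fill` where no segment covers the base.
per_base_map <- function(segments, samples, genome, fill = 0) {
  maps <- lapply(genome, function(L)
    matrix(fill, nrow = L, ncol = length(samples),
           dimnames = list(NULL, samples)))
  for (i in seq_len(nrow(segments))) {
    maps[[segments$chrom[i]]][segments$start[i]:segments$end[i],
                              segments$sample[i]] <- segments$value[i]
  }
  maps
}

# Expand a region_matrix back to a per-base map.
region_matrix_to_map <- function(rm, genome) {
  maps <- lapply(genome, function(L)
    matrix(rm$fill, nrow = L, ncol = length(rm$samples),
           dimnames = list(NULL, rm$samples)))
  for (r in seq_len(nrow(rm$regions))) {
    maps[[rm$regions$chrom[r]]][rm$regions$start[r]:rm$regions$end[r], ] <-
      matrix(rm$values[r, ], rm$regions$end[r] - rm$regions$start[r] + 1L,
             length(rm$samples), byrow = TRUE)
  }
  maps
}

# TRUE iff region construction + fill reproduce the raw per-base map
# exactly, regions are disjoint, their union equals the covered footprint,
# and every region boundary is a segment boundary.
check_region_matrix_oracle <- function(segments, samples, genome) {
  regions <- build_regions(segments)
  rm <- fill_matrix(segments, regions, samples = samples)
  raw <- per_base_map(segments, samples, genome)
  rebuilt <- region_matrix_to_map(rm, genome)
  if (!isTRUE(all.equal(raw, rebuilt))) return(FALSE)
  for (chrom in unique(regions$chrom)) {
    rr <- regions[regions$chrom == chrom, ]
    o <- order(rr$start)
    if (any(rr$start[o][-1] <= rr$end[o][-nrow(rr)])) return(FALSE)
  }
  for (chrom in names(genome)) {
    covered <- rowSums(raw[[chrom]] != 0) > 0
    in_regions <- rep(FALSE, genome[[chrom]])
    rr <- regions[regions$chrom == chrom, ]
    for (r in seq_len(nrow(rr))) in_regions[rr$start[r]:rr$end[r]] <- TRUE
    if (!identical(covered, in_regions)) return(FALSE)
    ss <- segments[segments$chrom == chrom, ]
    if (nrow(rr) &&
        !all(rr$start %in% c(ss$start, ss$end + 1L) &
             rr$end %in% c(ss$end, ss$start - 1L))) return(FALSE)
  }
  TRUE
}

# Minimal mutation row(s) passing validation; fields overridable.
make_mutations <- function(n = 1, sample = "L1", gene = "TP53",
                           chrom = "chr17", position = 7577538,
                           ref = "C", alt = "T", region_class = "exon",
                           allele_frequency = 0.156, coverage = 576,
                           alt_reads = NULL, in_dbsnp = FALSE,
                           in_germline = FALSE) {
  if (is.null(alt_reads)) alt_reads <- round(allele_frequency * coverage)
  df <- data.frame(sample = sample, gene = gene, chrom = chrom,
                   position = position, ref = ref, alt = alt,
                   region_class = region_class,
                   allele_frequency = allele_frequency,
                   coverage = coverage, alt_reads = alt_reads,
                   in_dbsnp = in_dbsnp, in_germline = in_germline,
                   stringsAsFactors = FALSE)
  if (nrow(df) == 1 && n > 1) df <- df[rep(1, n), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Lesion profile whose mutations sit at the given integer site keys on one
# chromosome (used to compare Venn counts against plain set algebra).
lesion_from_sites <- function(id, sites, cnv_keys = integer(),
                              gene_keys = integer()) {
  muts <- if (length(sites)) make_mutations(
    n = length(sites), sample = id, gene = paste0("G", sites %% 17),
    position = sites, allele_frequency = 0.1, coverage = 500)
  else NULL
  if (!is.null(muts)) muts$position <- sites
  cnvs <- if (length(cnv_keys)) data.frame(
    chrom = "chr2", start = cnv_keys * 1000L, end = cnv_keys * 1000L + 500L)
  else NULL
  genes <- if (length(gene_keys)) data.frame(
    gene = paste0("CN", gene_keys), direction = "gain")
  else NULL
  lesion_profile(id, mutations = muts, cnv_intervals = cnvs,
                 gene_cnvs = genes)
}

# Small cohort spec used by unit tests (fast; not the study-scale default).
tiny_cohort_spec <- function(seed, n_signature_regions_per_class = 5,
                             samples_per_class = 10,
                             n_passenger_segments = 5) {
  cohort_spec(samples_per_class = samples_per_class,
              genome = setNames(rep(2e6, 2), c("chr1", "chr2")),
              n_signature_regions_per_class = n_signature_regions_per_class,
              n_passenger_segments = n_passenger_segments,
              signature_length_range = c(2e4, 6e4),
              passenger_length_range = c(1e4, 3e4),
              seed = seed)
}

# Small patient spec matched to tiny cohorts (fewer private CNVs so the
# 4 Mb genome can host all lesions' intervals disjointly).
tiny_patient_spec <- function(seed, ...) {
  patient_spec(n_private_cnvs = c(pancreas = 8, biliary_duct = 16,
                                  omentum = 12),
               seed = seed, ...)
}
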