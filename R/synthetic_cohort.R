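# Synthetic labelled CNV cohorts and clonally structured multi-lesion
# patients with known ground truth.
#
# The cohort generator emulates a labelled multi-cancer training set of
# segmented copy-number profiles: each cancer type carries a fixed set of
# planted signature regions (class-specific gains/losses) on top of
# passenger segments placed uniformly at random. The patient generator
# emulates a multifocal patient under single clonal evolution: founder
# (truncal) events shared by every lesion, lineage events shared along a
# branch, and private events per lesion.

#' Specification of a synthetic labelled CNV cohort
#'
#' Defaults describe a three-class cohort (TCGA-style study codes CHOL,
#' LIHC, PAAD) of 40 samples per class on a compact 8-chromosome synthetic
#' genome, with 30 planted signature regions per class of mean log2 shift
#' +/-0.8 over a noise floor of sd 0.1, plus 15 passenger segments per
#' sample.
#'
#' @param n_classes number of cancer types.
#' @param samples_per_class samples per type.
#' @param genome named integer vector of chromosome lengths.
#' @param n_signature_regions_per_class planted signature regions per class;
#'   planted regions are disjoint across classes.
#' @param signature_effect mean |log2| shift of a planted region
#'   (default 0.8); the sign per region is fixed at planting time.
#' @param n_passenger_segments passenger segments per sample.
#' @param segment_value_noise_sd Gaussian noise sd on segment values
#'   (default 0.1).
#' @param passenger_inflate_prob probability that a passenger is a real
#'   CNV-like event pushed past the calling threshold (default 0.1).
#' @param cnv_log2_threshold magnitude used to inflate passengers past the
#'   calling threshold (default 0.7).
#' @param signature_length_range,passenger_length_range interval length
#'   ranges in bases.
#' @param class_labels optional class label vector (length `n_classes`).
#' @param seed RNG seed; the same spec and seed reproduce the cohort
#'   byte-for-byte.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_classes = 3, samples_per_class = 40,
                        genome = setNames(rep(10e6, 8), paste0("chr", 1:8)),
                        n_signature_regions_per_class = 30,
                        signature_effect = 0.8,
                        n_passenger_segments = 15,
                        segment_value_noise_sd = 0.1,
                        passenger_inflate_prob = 0.1,
                        cnv_log2_threshold = 0.7,
                        signature_length_range = c(5e4, 2e5),
                        passenger_length_range = c(2e4, 1e5),
                        class_labels = NULL, seed = 1) {
  if (n_classes < 1 || samples_per_class < 0 ||
      n_signature_regions_per_class < 0 || n_passenger_segments < 0)
    stopf("all counts must be >= 0 (and n_classes >= 1)")
  if (!is.finite(signature_effect) || !is.finite(segment_value_noise_sd))
    stopf("effect and noise must be finite")
  if (is.null(names(genome)) || any(genome < 1))
    stopf("genome must be a named vector of positive chromosome lengths")
  if (is.null(class_labels))
    class_labels <- c("CHOL", "LIHC", "PAAD",
                      paste0("CLASS", seq_len(max(0, n_classes - 3))))[
                        seq_len(n_classes)]
  if (length(class_labels) != n_classes)
    stopf("class_labels must have length n_classes")
  structure(list(n_classes = n_classes, samples_per_class = samples_per_class,
                 genome = genome,
                 n_signature_regions_per_class = n_signature_regions_per_class,
                 signature_effect = signature_effect,
                 n_passenger_segments = n_passenger_segments,
                 segment_value_noise_sd = segment_value_noise_sd,
                 passenger_inflate_prob = passenger_inflate_prob,
                 cnv_log2_threshold = cnv_log2_threshold,
                 signature_length_range = signature_length_range,
                 passenger_length_range = passenger_length_range,
                 class_labels = class_labels, seed = seed),
            class = "cohort_spec")
}

# Draw `n` intervals uniformly over the genome, rejecting overlap with
# `existing` (a data.frame chrom/start/end) and among themselves.
place_intervals <- function(n, genome, length_range, existing = NULL,
                            max_tries = 10000) {
  chroms <- names(genome)
  placed <- if (is.null(existing) || nrow(existing) == 0) empty_regions()
            else existing[, c("chrom", "start", "end")]
  out <- vector("list", n)
  got <- 0L; tries <- 0L
  while (got < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stopf("could not place %d non-overlapping intervals (genome too small?)",
            n)
    len <- round(runif(1, length_range[1], length_range[2]))
    chrom <- sample(chroms, 1, prob = as.numeric(genome))
    if (genome[[chrom]] <= len) next
    start <- sample.int(genome[[chrom]] - len, 1)
    end <- start + len - 1L
    same <- placed$chrom == chrom
    if (any(same & placed$start <= end & placed$end >= start)) next
    got <- got + 1L
    cand <- data.frame(chrom = chrom, start = as.integer(start),
                       end = as.integer(end), stringsAsFactors = FALSE)
    out[[got]] <- cand
    placed <- rbind(placed, cand)
  }
  do.call(rbind, out)
}

#' Generate a labelled synthetic CNV cohort
#'
#' Each sample carries its class's planted signature segments (value =
#' planted sign x effect + Gaussian noise) plus passenger segments placed
#' uniformly at random (value ~ Normal(0, noise), inflated past the calling
#' threshold with small probability). Deterministic given the spec's seed;
#' per-sample sub-seeds make generation order-independent.
#'
#' @param spec a [cohort_spec()].
#' @return an object of class `synthetic_cohort`: list with `segments`
#'   (SEG-style data.frame), `labels` (`sample_id`, `cancer_type`), and
#'   `truth` (planted signature regions per class with signs, plus the
#'   spec).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_sig_total <- spec$n_classes * spec$n_signature_regions_per_class
  if (max(spec$signature_length_range) * n_sig_total > sum(spec$genome))
    stopf("planted regions exceed the genome size")
  truth_regions <- with_seed(spec$seed, {
    if (n_sig_total == 0) {
      tr <- empty_regions()
      tr$class <- character(0); tr$sign <- numeric(0)
      tr
    } else {
      tr <- place_intervals(n_sig_total, spec$genome,
                            spec$signature_length_range)
      tr$class <- rep(spec$class_labels,
                      each = spec$n_signature_regions_per_class)
      tr$sign <- rep_len(c(1, -1), n_sig_total)
      tr
    }
  })
  seg_list <- list()
  labels <- data.frame(sample_id = character(), cancer_type = character(),
                       stringsAsFactors = FALSE)
  for (ci in seq_len(spec$n_classes)) {
    cls <- spec$class_labels[ci]
    for (si in seq_len(spec$samples_per_class)) {
      sid <- sprintf("%s_%03d", cls, si)
      labels <- rbind(labels, data.frame(sample_id = sid, cancer_type = cls,
                                         stringsAsFactors = FALSE))
      seg_list[[sid]] <- with_seed(
        sub_seed(spec$seed, (ci - 1) * spec$samples_per_class + si), {
          sig <- truth_regions[truth_regions$class == cls, , drop = FALSE]
          segs <- empty_regions(); segs$value <- numeric(0)
          if (nrow(sig)) {
            segs <- data.frame(
              chrom = sig$chrom, start = sig$start, end = sig$end,
              value = sig$sign * spec$signature_effect +
                rnorm(nrow(sig), 0, spec$segment_value_noise_sd),
              stringsAsFactors = FALSE)
          }
          if (spec$n_passenger_segments > 0) {
            pas <- place_intervals(spec$n_passenger_segments, spec$genome,
                                   spec$passenger_length_range,
                                   existing = segs)
            val <- rnorm(nrow(pas), 0, spec$segment_value_noise_sd)
            inflate <- runif(nrow(pas)) < spec$passenger_inflate_prob
            val[inflate] <- sign(val[inflate] + 1e-12) *
              (spec$cnv_log2_threshold + abs(val[inflate]) + 0.1)
            pas$value <- val
            segs <- rbind(segs, pas)
          }
          if (nrow(segs)) {
            segs <- data.frame(sample = sid, segs, stringsAsFactors = FALSE)
            segs[order_genomic(segs$chrom, segs$start, segs$end), ,
                 drop = FALSE]
          } else {
            data.frame(sample = character(), chrom = character(),
                       start = integer(), end = integer(), value = numeric(),
                       stringsAsFactors = FALSE)
          }
        })
    }
  }
  segments <- do.call(rbind, seg_list)
  rownames(segments) <- NULL
  validate_segments(segments, what = "generated cohort")
  structure(list(segments = segments, labels = labels,
                 truth = list(signature_regions = truth_regions, spec = spec)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d samples, %d classes, %d segments, %d planted signature regions\n",
              nrow(x$labels), length(unique(x$labels$cancer_type)),
              nrow(x$segments), nrow(x$truth$signature_regions)))
  invisible(x)
}

#' Specification of a synthetic multifocal patient
#'
#' Defaults emulate a three-lesion patient (pancreas, biliary duct, omentum)
#' whose cancer originated in the pancreas and whose biliary-duct and
#' omentum lesions form a later branch: 29 truncal mutations, 1 truncal CNV
#' interval and 5 truncal gene CNVs shared by all lesions; 17 mutations,
#' 6 CNV intervals and 2 gene CNVs shared by the branch only; and private
#' events per lesion scaled so that the pancreas lesion carries the fewest
#' alterations. Allele frequencies are drawn from Beta(1, 20) (clamped to a
#' minimum of 0.01) so that roughly two thirds of calls fall below 0.05, as
#' seen in deep-sequenced tumor tissue.
#'
#' @param n_lesions number of lesions (>= 2; the defaults describe 3).
#' @param lesion_ids lesion identifiers.
#' @param origin_class cancer-type label of the tissue of origin; must exist
#'   in the cohort truth passed to [generate_patient()].
#' @param n_truncal_mutations,n_truncal_cnvs,n_truncal_gene_cnvs founder
#'   events shared by every lesion. Truncal CNV intervals are drawn from the
#'   origin class's planted signature regions.
#' @param lineage list of branches; each branch is a list with `lesions`
#'   (ids, a strict subset of `lesion_ids` with >= 2 members) and event
#'   counts `n_mutations`, `n_cnvs`, `n_gene_cnvs` shared by exactly that
#'   branch.
#' @param n_private_mutations,n_private_cnvs,n_private_gene_cnvs named (or
#'   positional) per-lesion private event counts.
#' @param n_artifacts per-lesion count of planted non-somatic candidates
#'   (dbSNP/germline-flagged or low-support) that the inclusion filter
#'   should remove.
#' @param af_shape1,af_shape2 Beta parameters of the allele-frequency
#'   distribution.
#' @param coverage_mean,coverage_sd Gaussian parameters for per-call read
#'   depth (floored at 120).
#' @param seed RNG seed.
#' @return an object of class `patient_spec`.
#' @export
patient_spec <- function(n_lesions = 3,
                         lesion_ids = c("pancreas", "biliary_duct", "omentum"),
                         origin_class = "PAAD",
                         n_truncal_mutations = 29, n_truncal_cnvs = 1,
                         n_truncal_gene_cnvs = 5,
                         lineage = list(list(
                           lesions = c("biliary_duct", "omentum"),
                           n_mutations = 17, n_cnvs = 6, n_gene_cnvs = 2)),
                         n_private_mutations = c(pancreas = 34,
                                                 biliary_duct = 38,
                                                 omentum = 42),
                         n_private_cnvs = c(pancreas = 83, biliary_duct = 178,
                                            omentum = 138),
                         n_private_gene_cnvs = c(pancreas = 0,
                                                 biliary_duct = 1,
                                                 omentum = 1),
                         n_artifacts = 5,
                         af_shape1 = 1, af_shape2 = 20,
                         coverage_mean = 450, coverage_sd = 150, seed = 1) {
  if (n_lesions < 2) stopf("a patient case needs >= 2 lesions")
  if (length(lesion_ids) != n_lesions || anyDuplicated(lesion_ids))
    stopf("lesion_ids must be %d distinct ids", n_lesions)
  fix <- function(x, what) {
    if (is.null(names(x))) {
      if (length(x) != n_lesions) stopf("%s must have one entry per lesion", what)
      names(x) <- lesion_ids
    }
    miss <- setdiff(lesion_ids, names(x))
    if (length(miss)) stopf("%s missing for lesion '%s'", what, miss[1])
    if (any(x < 0)) stopf("%s must be >= 0", what)
    x[lesion_ids]
  }
  n_private_mutations <- fix(n_private_mutations, "n_private_mutations")
  n_private_cnvs <- fix(n_private_cnvs, "n_private_cnvs")
  n_private_gene_cnvs <- fix(n_private_gene_cnvs, "n_private_gene_cnvs")
  for (br in lineage) {
    if (!all(c("lesions", "n_mutations", "n_cnvs", "n_gene_cnvs") %in%
             names(br)))
      stopf("each lineage branch needs lesions and event counts")
    if (length(br$lesions) < 2 || length(br$lesions) >= n_lesions ||
        !all(br$lesions %in% lesion_ids))
      stopf("lineage branch lesions must be a strict subset (>= 2) of lesion_ids")
  }
  structure(list(n_lesions = n_lesions, lesion_ids = lesion_ids,
                 origin_class = origin_class,
                 n_truncal_mutations = n_truncal_mutations,
                 n_truncal_cnvs = n_truncal_cnvs,
                 n_truncal_gene_cnvs = n_truncal_gene_cnvs,
                 lineage = lineage,
                 n_private_mutations = n_private_mutations,
                 n_private_cnvs = n_private_cnvs,
                 n_private_gene_cnvs = n_private_gene_cnvs,
                 n_artifacts = n_artifacts,
                 af_shape1 = af_shape1, af_shape2 = af_shape2,
                 coverage_mean = coverage_mean, coverage_sd = coverage_sd,
                 seed = seed),
            class = "patient_spec")
}

#' Generate a synthetic multifocal patient case
#'
#' Generates one lesion profile per lesion under the clonal structure of the
#' spec: truncal events appear in every lesion (with lesion-specific allele
#' frequency and depth for mutations), lineage events in their branch's
#' lesions only, private events in one lesion each. Mutation coordinates are
#' drawn without replacement genome-wide, so no two distinct planted events
#' collide. Each lesion also receives a segmented copy-number profile
#' carrying the origin class's signature regions (so the case can be
#' classified against a cohort) plus segments for its CNV intervals.
#'
#' @param spec a [patient_spec()].
#' @param cohort a [generate_cohort()] result (or its `truth` element)
#'   providing the genome, the planted signature regions and the origin
#'   class's segment value model.
#' @return an object of class `patient_case`: list with `lesions` (named
#'   list of [lesion_profile()]), `segments` (SEG-style data.frame across
#'   lesions), and `truth` (origin lesion, branches, per-category planted
#'   key sets and counts).
#' @export
generate_patient <- function(spec, cohort) {
  stopifnot(inherits(spec, "patient_spec"))
  truth <- if (inherits(cohort, "synthetic_cohort")) cohort$truth else cohort
  cspec <- truth$spec
  genome <- cspec$genome
  sig <- truth$signature_regions
  if (!spec$origin_class %in% cspec$class_labels)
    stopf("origin_class '%s' is not a cohort class", spec$origin_class)
  origin_sig <- sig[sig$class == spec$origin_class, , drop = FALSE]
  if (spec$n_truncal_cnvs > nrow(origin_sig))
    stopf("n_truncal_cnvs exceeds the origin class's %d signature regions",
          nrow(origin_sig))
  ids <- spec$lesion_ids

  with_seed(spec$seed, {
    # ---- event pools ------------------------------------------------------
    n_mut_total <- spec$n_truncal_mutations +
      sum(vapply(spec$lineage, `[[`, 0, "n_mutations")) +
      sum(spec$n_private_mutations) + spec$n_artifacts * length(ids)
    mut_pool <- draw_mutation_sites(n_mut_total, genome)
    pool_at <- 0L
    take_sites <- function(n) {
      if (n == 0) return(mut_pool[0, , drop = FALSE])
      out <- mut_pool[pool_at + seq_len(n), , drop = FALSE]
      pool_at <<- pool_at + n
      out
    }

    gene_cnv_pool <- data.frame(
      gene = sprintf("CNVGENE%03d", seq_len(200)),
      direction = sample(c("gain", "loss"), 200, replace = TRUE),
      stringsAsFactors = FALSE)
    gene_at <- 0L
    take_gene_cnvs <- function(n) {
      if (n == 0) return(gene_cnv_pool[0, , drop = FALSE])
      out <- gene_cnv_pool[gene_at + seq_len(n), , drop = FALSE]
      gene_at <<- gene_at + n
      out
    }

    # truncal CNV intervals come from the origin class's signature regions
    truncal_cnvs <- origin_sig[sample.int(nrow(origin_sig),
                                          spec$n_truncal_cnvs), ,
                               drop = FALSE]
    truncal_cnvs <- data.frame(chrom = truncal_cnvs$chrom,
                               start = truncal_cnvs$start,
                               end = truncal_cnvs$end,
                               direction = ifelse(truncal_cnvs$sign > 0,
                                                  "gain", "loss"),
                               stringsAsFactors = FALSE)
    used_intervals <- rbind(origin_sig[, c("chrom", "start", "end")],
                            sig[, c("chrom", "start", "end")])
    draw_cnvs <- function(n) {
      if (n == 0) {
        out <- empty_regions(); out$direction <- character(0)
        return(out)
      }
      iv <- place_intervals(n, genome, cspec$passenger_length_range,
                            existing = used_intervals)
      used_intervals <<- rbind(used_intervals, iv)
      iv$direction <- sample(c("gain", "loss"), n, replace = TRUE)
      iv
    }

    truncal_mut <- take_sites(spec$n_truncal_mutations)
    branch_events <- lapply(spec$lineage, function(br) {
      list(lesions = br$lesions,
           mutations = take_sites(br$n_mutations),
           cnvs = draw_cnvs(br$n_cnvs),
           gene_cnvs = take_gene_cnvs(br$n_gene_cnvs))
    })
    truncal_gene <- take_gene_cnvs(spec$n_truncal_gene_cnvs)

    # ---- assemble lesions -------------------------------------------------
    lesions <- list()
    segments <- list()
    for (les in ids) {
      mut_sites <- truncal_mut
      cnvs <- truncal_cnvs
      genes <- truncal_gene
      for (br in branch_events) {
        if (les %in% br$lesions) {
          mut_sites <- rbind(mut_sites, br$mutations)
          cnvs <- rbind(cnvs, br$cnvs)
          genes <- rbind(genes, br$gene_cnvs)
        }
      }
      mut_sites <- rbind(mut_sites, take_sites(spec$n_private_mutations[les]))
      cnvs <- rbind(cnvs, draw_cnvs(spec$n_private_cnvs[les]))
      genes <- rbind(genes, take_gene_cnvs(spec$n_private_gene_cnvs[les]))

      muts <- realize_mutations(mut_sites, les, spec)
      arts <- realize_artifacts(take_sites(spec$n_artifacts), les, spec)
      muts <- rbind(muts, arts)

      lesions[[les]] <- lesion_profile(les, mutations = muts,
                                       cnv_intervals = cnvs,
                                       gene_cnvs = genes)

      # segmented profile: origin-class signature segments + CNV-interval
      # segments (truncal intervals are signature regions; emitted once)
      extra <- cnvs[!interval_key(cnvs$chrom, cnvs$start, cnvs$end) %in%
                      interval_key(origin_sig$chrom, origin_sig$start,
                                   origin_sig$end), , drop = FALSE]
      seg <- data.frame(
        sample = les,
        chrom = c(origin_sig$chrom, extra$chrom),
        start = c(origin_sig$start, extra$start),
        end = c(origin_sig$end, extra$end),
        value = c(origin_sig$sign * cspec$signature_effect +
                    rnorm(nrow(origin_sig), 0, cspec$segment_value_noise_sd),
                  ifelse(extra$direction == "gain", 1, -1) *
                    (cspec$cnv_log2_threshold + 0.1 +
                       abs(rnorm(nrow(extra), 0,
                                 cspec$segment_value_noise_sd)))),
        stringsAsFactors = FALSE)
      segments[[les]] <- seg[order_genomic(seg$chrom, seg$start, seg$end), ,
                             drop = FALSE]
    }
    segments <- do.call(rbind, segments)
    rownames(segments) <- NULL
    validate_segments(segments, what = "generated patient segments")

    # ---- planted truth ----------------------------------------------------
    burdens <- vapply(ids, function(les) {
      in_branches <- vapply(branch_events, function(br) les %in% br$lesions,
                            TRUE)
      spec$n_truncal_mutations + spec$n_truncal_cnvs +
        spec$n_truncal_gene_cnvs +
        sum(vapply(branch_events[in_branches], function(br)
          nrow(br$mutations) + nrow(br$cnvs) + nrow(br$gene_cnvs), 0)) +
        spec$n_private_mutations[les] + spec$n_private_cnvs[les] +
        spec$n_private_gene_cnvs[les] + spec$n_artifacts
    }, 0)
    truth_out <- list(
      origin_class = spec$origin_class,
      origin_lesion = ids[which.min(burdens)],
      branches = lapply(spec$lineage, `[[`, "lesions"),
      planted_burdens = burdens,
      truncal = list(mutations = spec$n_truncal_mutations,
                     cnvs = spec$n_truncal_cnvs,
                     gene_cnvs = spec$n_truncal_gene_cnvs),
      spec = spec)
    structure(list(lesions = lesions, segments = segments,
                   truth = truth_out),
              class = "patient_case")
  })
}

# Draw n distinct genomic sites with gene annotations and alleles.
draw_mutation_sites <- function(n, genome) {
  if (n == 0)
    return(data.frame(gene = character(), chrom = character(),
                      position = integer(), ref = character(),
                      alt = character(), region_class = character(),
                      stringsAsFactors = FALSE))
  chrom <- sample(names(genome), n, replace = TRUE,
                  prob = as.numeric(genome))
  pos <- vapply(chrom, function(ch) sample.int(genome[[ch]], 1), 0L)
  key <- paste(chrom, pos)
  while (anyDuplicated(key)) {  # genome >> n, so this terminates promptly
    dup <- which(duplicated(key))
    pos[dup] <- vapply(chrom[dup], function(ch) sample.int(genome[[ch]], 1), 0L)
    key <- paste(chrom, pos)
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  data.frame(gene = sprintf("MUTGENE%04d", sample.int(390, n, replace = TRUE)),
             chrom = chrom, position = as.integer(pos), ref = ref, alt = alt,
             region_class = ifelse(runif(n) < 0.46, "exon", "non-exon"),
             stringsAsFactors = FALSE)
}

# Give planted sites lesion-specific allele frequencies and depths that pass
# the default inclusion filter.
realize_mutations <- function(sites, lesion_id, spec) {
  n <- nrow(sites)
  if (n == 0)
    return(data.frame(sample = character(), sites,
                      allele_frequency = numeric(), coverage = integer(),
                      alt_reads = integer(), in_dbsnp = logical(),
                      in_germline = logical(), stringsAsFactors = FALSE))
  af <- pmin(pmax(rbeta(n, spec$af_shape1, spec$af_shape2), 0.01), 0.999)
  coverage <- pmax(round(rnorm(n, spec$coverage_mean, spec$coverage_sd)), 120)
  alt_reads <- rbinom(n, coverage, af)
  data.frame(sample = lesion_id, sites,
             allele_frequency = af, coverage = as.integer(coverage),
             alt_reads = as.integer(alt_reads),
             in_dbsnp = FALSE, in_germline = FALSE,
             stringsAsFactors = FALSE)
}

# Non-somatic candidates the filter should remove: dbSNP- or germline-
# flagged, or below the coverage floor.
realize_artifacts <- function(sites, lesion_id, spec) {
  out <- realize_mutations(sites, lesion_id, spec)
  n <- nrow(out)
  if (n == 0) return(out)
  kind <- sample(c("dbsnp", "germline", "lowcov"), n, replace = TRUE)
  out$in_dbsnp <- kind == "dbsnp"
  out$in_germline <- kind == "germline"
  low <- kind == "lowcov"
  out$coverage[low] <- as.integer(sample(20:99, sum(low), replace = TRUE))
  out$alt_reads[low] <- pmin(out$alt_reads[low], out$coverage[low])
  out
}

#' @export
print.patient_case <- function(x, ...) {
  cat(sprintf("Patient case: %d lesions (%s); origin lesion '%s' (class %s)\n",
              length(x$lesions), paste(names(x$lesions), collapse = ", "),
              x$truth$origin_lesion, x$truth$origin_class))
  invisible(x)
}
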