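# End-to-end orchestration: filtering -> concordance -> route, and
# region matrix -> signatures -> discriminant -> origin calls. Both entry
# points are deterministic given their inputs and seed, and optionally write
# machine-readable JSON reports whose header records the seed and
# configuration.

pipeline_header <- function(config, seed) {
  list(tool = "clonotrace",
       version = as.character(utils::packageVersion("clonotrace")),
       seed = if (is.null(seed)) NA else seed,
       config = config)
}

write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Run the clonality analysis on a set of lesions
#'
#' Applies the somatic inclusion filter to every lesion's mutation
#' candidates, computes the shared-event Venn decomposition across lesions,
#' and infers a relatedness ordering / metastatic route. Alternatively, when
#' only published Venn counts are available (no underlying event tables),
#' pass `venn_tabulated` to evaluate the inclusion-exclusion union from the
#' printed per-lesion, pairwise and triple counts.
#'
#' @param lesions list of >= 2 [lesion_profile()] objects (ignored when
#'   `venn_tabulated` is given).
#' @param policy a [filter_policy()] applied to each lesion's mutations.
#' @param match_alleles mutation identity includes ref/alt alleles
#'   (default `TRUE`); set `FALSE` to match on gene + coordinate only.
#' @param venn_tabulated optional list with `per_lesion` (3 counts),
#'   `pairwise` (3 counts), `triple` (1 count) of shared mutations.
#' @param output_dir optional directory for `clonality_report.json`.
#' @param seed recorded in the report header (the analysis itself is
#'   deterministic).
#' @return a list with `report` (a [venn_counts()] result), `route`
#'   (an [infer_route()] result), `filtered` (per-lesion retained/candidate
#'   mutation counts), or -- in pre-tabulated mode -- `union_size` and the
#'   input counts.
#' @export
run_clonality <- function(lesions = NULL, policy = filter_policy(),
                          match_alleles = TRUE, venn_tabulated = NULL,
                          output_dir = NULL, seed = NULL) {
  if (!is.null(venn_tabulated)) {
    u <- union_from_venn(venn_tabulated$per_lesion, venn_tabulated$pairwise,
                         venn_tabulated$triple)
    out <- list(mode = "pretabulated", union_size = u,
                counts = venn_tabulated)
    if (!is.null(output_dir)) {
      dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
      write_report_json(
        c(pipeline_header(list(mode = "pretabulated"), seed), out),
        file.path(output_dir, "clonality_report.json"))
    }
    return(out)
  }
  if (is.null(lesions) || length(lesions) < 2)
    stopf("run_clonality needs at least two lesions")
  filtered <- lapply(lesions, function(l) {
    kept <- filter_mutations(l$mutations, policy)
    out <- l
    out$mutations <- kept
    attr(out, "attrition") <- c(candidates = nrow(l$mutations),
                                retained = nrow(kept))
    out
  })
  attrition <- t(vapply(filtered, attr, c(candidates = 0, retained = 0),
                        "attrition"))
  rownames(attrition) <- vapply(filtered, `[[`, "", "lesion_id")
  report <- venn_counts(filtered, match_alleles = match_alleles)
  route <- infer_route(filtered, match_alleles = match_alleles)
  out <- list(mode = "lesions", report = report, route = route,
              filtered = attrition)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    config <- list(mode = "lesions", match_alleles = match_alleles,
                   policy = unclass(policy))
    json <- c(pipeline_header(config, seed),
              list(filtered = as.data.frame(attrition),
                   venn = report[c("mutations", "cnv_intervals",
                                   "gene_cnvs")],
                   route = list(route = route$route, origin = route$origin,
                                closest_pair = route$closest_pair,
                                burdens = as.list(route$burdens),
                                flags = route$flags)))
    write_report_json(json, file.path(output_dir, "clonality_report.json"))
  }
  out
}

#' Run the tissue-of-origin analysis
#'
#' Builds the disjoint-region matrix from the labelled cohort segments
#' (cohort samples only -- new lesions never contribute breakpoints or enter
#' signature selection), selects cancer-type signature regions, trains the
#' diagonal discriminant model, reports stratified cross-validated per-class
#' accuracy, and classifies the patient lesions after projecting their
#' segments onto the cohort's region set (0 fill for uncovered regions).
#'
#' @param cohort_segments SEG-style `data.frame` for the labelled cohort.
#' @param cohort_labels cohort label `data.frame` (`sample_id`,
#'   `cancer_type`) or named vector.
#' @param patient_segments optional SEG-style `data.frame` of lesions to
#'   classify.
#' @param alpha signature selection cutoff (default 1e-12). `alpha = 0`
#'   selects nothing and training refuses to run.
#' @param folds cross-validation folds (default 5).
#' @param seed seed for the fold assignment.
#' @param method association scorer (`"logistic"` or `"anova"`).
#' @param include_resubstitution also report resubstitution accuracy,
#'   clearly labelled (default `FALSE`).
#' @param priors,var_floor passed to [train_discriminant()].
#' @param output_dir optional directory for `origin_report.json`.
#' @return a list with `matrix` (the labelled `region_matrix`),
#'   `signatures`, `model`, `cv` (a `classification_report`),
#'   `resubstitution` (or `NULL`), and `patient_calls` (data.frame
#'   lesion/predicted, or `NULL`).
#' @export
run_origin <- function(cohort_segments, cohort_labels,
                       patient_segments = NULL, alpha = 1e-12, folds = 5,
                       seed = 1, method = c("logistic", "anova"),
                       include_resubstitution = FALSE, priors = "empirical",
                       var_floor = 1e-6, output_dir = NULL) {
  method <- match.arg(method)
  if (is.data.frame(cohort_labels))
    require_columns(cohort_labels, c("sample_id", "cancer_type"),
                    "cohort labels")
  rm_labelled <- region_matrix(cohort_segments, labels = cohort_labels)
  if (length(unique(rm_labelled$labels)) < 2)
    stopf("cohort label table must declare at least two classes")
  signatures <- select_signatures(rm_labelled, alpha = alpha, method = method)
  model <- train_discriminant(rm_labelled, signatures = signatures,
                              priors = priors, var_floor = var_floor)
  cv <- cross_validate(rm_labelled, alpha = alpha, k = folds, seed = seed,
                       mode = "cv", method = method, priors = priors,
                       var_floor = var_floor)
  resub <- if (include_resubstitution)
    cross_validate(rm_labelled, alpha = alpha, mode = "resubstitution",
                   method = method, priors = priors, var_floor = var_floor)
  patient_calls <- NULL
  if (!is.null(patient_segments) && nrow(patient_segments) > 0) {
    proj <- project_segments(patient_segments, rm_labelled$regions,
                             fill = rm_labelled$fill)
    pred <- classify(model, proj)
    patient_calls <- data.frame(lesion = colnames(proj),
                                predicted = pred$class,
                                tie = pred$tie, stringsAsFactors = FALSE)
  }
  out <- list(matrix = rm_labelled, signatures = signatures, model = model,
              cv = cv, resubstitution = resub,
              patient_calls = patient_calls)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    config <- list(alpha = alpha, folds = folds, method = method,
                   priors = if (is.character(priors)) priors else "custom",
                   var_floor = var_floor,
                   n_regions = nrow(rm_labelled$regions),
                   n_samples = length(rm_labelled$samples))
    json <- c(pipeline_header(config, seed), list(
      n_signatures = length(signatures$index),
      cv = list(mode = cv$mode, k = cv$k,
                per_class_accuracy = as.list(cv$per_class_accuracy),
                overall_accuracy = cv$overall_accuracy),
      resubstitution = if (!is.null(resub)) list(
        mode = resub$mode,
        per_class_accuracy = as.list(resub$per_class_accuracy),
        overall_accuracy = resub$overall_accuracy),
      patient_calls = patient_calls))
    write_report_json(json, file.path(output_dir, "origin_report.json"))
  }
  out
}
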