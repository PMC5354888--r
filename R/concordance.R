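# Shared-event analysis between tumor lesions: Venn decompositions,
# relatedness scores, and metastatic-route inference.
#
# Under single clonal evolution, lesions descending from one ancestral cell
# population share the founder (truncal) alterations; later divergence shows
# up as lineage-restricted and private events. Counting exactly matched
# events between lesions therefore measures relatedness.

#' Assemble a lesion profile
#'
#' A lesion profile bundles the (filtered) somatic events observed in one
#' tumor mass: point mutations, chromosome-level CNV intervals, and
#' gene-level CNV events. Member records are stamped with the lesion id.
#'
#' @param lesion_id unique lesion identifier (e.g. `"pancreas"`).
#' @param tissue_label free-text sampled-tissue label (defaults to the id).
#' @param mutations mutation `data.frame` (may be `NULL`).
#' @param cnv_intervals `data.frame` with `chrom`, `start`, `end` and
#'   optionally `direction` (may be `NULL`).
#' @param gene_cnvs `data.frame` with `gene`, `direction` (may be `NULL`).
#' @return an object of class `lesion_profile`.
#' @export
lesion_profile <- function(lesion_id, tissue_label = lesion_id,
                           mutations = NULL, cnv_intervals = NULL,
                           gene_cnvs = NULL) {
  if (length(lesion_id) != 1 || is.na(lesion_id) || lesion_id == "")
    stopf("lesion_id must be a single non-empty string")
  if (is.null(mutations)) {
    mutations <- data.frame(sample = character(), gene = character(),
                            chrom = character(), position = integer(),
                            ref = character(), alt = character(),
                            region_class = character(),
                            allele_frequency = numeric(),
                            coverage = integer(), alt_reads = integer(),
                            in_dbsnp = logical(), in_germline = logical(),
                            stringsAsFactors = FALSE)
  } else {
    validate_mutations(mutations, what = sprintf("lesion '%s'", lesion_id))
    mutations$sample <- lesion_id
  }
  if (is.null(cnv_intervals)) {
    cnv_intervals <- data.frame(chrom = character(), start = integer(),
                                end = integer(), direction = character(),
                                stringsAsFactors = FALSE)
  } else {
    require_columns(cnv_intervals, c("chrom", "start", "end"),
                    sprintf("lesion '%s' cnv_intervals", lesion_id))
    ival <- genomic_interval(cnv_intervals$chrom, cnv_intervals$start,
                             cnv_intervals$end)
    ival$direction <- if ("direction" %in% names(cnv_intervals))
      cnv_intervals$direction else NA_character_
    cnv_intervals <- ival
  }
  if (is.null(gene_cnvs)) {
    gene_cnvs <- data.frame(gene = character(), direction = character(),
                            stringsAsFactors = FALSE)
  } else {
    require_columns(gene_cnvs, c("gene", "direction"),
                    sprintf("lesion '%s' gene_cnvs", lesion_id))
  }
  structure(list(lesion_id = lesion_id, tissue_label = tissue_label,
                 mutations = mutations, cnv_intervals = cnv_intervals,
                 gene_cnvs = gene_cnvs),
            class = "lesion_profile")
}

#' @export
print.lesion_profile <- function(x, ...) {
  cat(sprintf("Lesion '%s' (%s): %d mutations, %d CNV intervals, %d gene CNVs\n",
              x$lesion_id, x$tissue_label, nrow(x$mutations),
              nrow(x$cnv_intervals), nrow(x$gene_cnvs)))
  invisible(x)
}

# Identity keys for matched-event counting. In strict mode a mutation is
# identified by gene + coordinate + alleles; in gene+coordinate mode the
# alleles are ignored (two different substitutions at one site merge).
mutation_keys <- function(lesion, match_alleles = TRUE) {
  m <- lesion$mutations
  if (nrow(m) == 0) return(character())
  base <- paste(m$gene, m$chrom, m$position, sep = "|")
  if (match_alleles) paste(base, m$ref, m$alt, sep = "|") else base
}

cnv_interval_keys <- function(lesion) {
  ci <- lesion$cnv_intervals
  if (nrow(ci) == 0) return(character())
  interval_key(ci$chrom, ci$start, ci$end)
}

gene_cnv_keys <- function(lesion) {
  g <- lesion$gene_cnvs
  if (nrow(g) == 0) return(character())
  paste(g$gene, g$direction, sep = "|")
}

#' Shared somatic mutations between two lesions
#'
#' A mutation is shared when it lies in the same gene and at the same genomic
#' coordinate in both lesions. By default the reference and alternate
#' alleles must also match (`match_alleles = TRUE`); switch it off to match
#' on gene + coordinate only, which can merge distinct substitutions at one
#' site.
#'
#' @param a,b `lesion_profile` objects.
#' @param match_alleles require identical ref/alt alleles (default `TRUE`).
#' @return character vector of matched mutation keys
#'   (`gene|chrom|position[|ref|alt]`).
#' @export
shared_mutations <- function(a, b, match_alleles = TRUE) {
  stopifnot(inherits(a, "lesion_profile"), inherits(b, "lesion_profile"))
  intersect(unique(mutation_keys(a, match_alleles)),
            unique(mutation_keys(b, match_alleles)))
}

#' Shared CNV intervals between two lesions
#'
#' Only CNVs occupying *identical* intervals -- equal chromosome, start and
#' end -- count as overlapping; an interval off by a single base does not
#' match. An optional reciprocal-overlap mode relaxes this: intervals match
#' when their reciprocal overlap fraction reaches `min_reciprocal` in both
#' directions.
#'
#' @param a,b `lesion_profile` objects.
#' @param min_reciprocal `NULL` (default) for exact-interval matching, or a
#'   fraction in (0, 1\] for reciprocal-overlap matching.
#' @return a `data.frame` of shared intervals (`chrom`, `start`, `end`),
#'   using `a`'s coordinates in reciprocal mode.
#' @export
shared_cnv_intervals <- function(a, b, min_reciprocal = NULL) {
  stopifnot(inherits(a, "lesion_profile"), inherits(b, "lesion_profile"))
  ia <- a$cnv_intervals; ib <- b$cnv_intervals
  if (is.null(min_reciprocal)) {
    keys <- intersect(unique(cnv_interval_keys(a)),
                      unique(cnv_interval_keys(b)))
    out <- ia[match(keys, cnv_interval_keys(a)), c("chrom", "start", "end"),
              drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  if (!(min_reciprocal > 0 && min_reciprocal <= 1))
    stopf("min_reciprocal must lie in (0, 1]")
  if (nrow(ia) == 0 || nrow(ib) == 0)
    return(ia[0, c("chrom", "start", "end"), drop = FALSE])
  ga <- GenomicRanges::GRanges(ia$chrom, IRanges::IRanges(ia$start, ia$end))
  gb <- GenomicRanges::GRanges(ib$chrom, IRanges::IRanges(ib$start, ib$end))
  h <- GenomicRanges::findOverlaps(ga, gb)
  if (length(h) == 0)
    return(ia[0, c("chrom", "start", "end"), drop = FALSE])
  ov <- GenomicRanges::pintersect(ga[S4Vectors::queryHits(h)],
                                  gb[S4Vectors::subjectHits(h)])
  w <- GenomicRanges::width(ov)
  ok <- w / GenomicRanges::width(ga[S4Vectors::queryHits(h)]) >= min_reciprocal &
        w / GenomicRanges::width(gb[S4Vectors::subjectHits(h)]) >= min_reciprocal
  idx <- unique(S4Vectors::queryHits(h)[ok])
  out <- ia[idx, c("chrom", "start", "end"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Shared gene-level CNV events between two lesions
#'
#' Events match on gene symbol and direction (gain/loss).
#'
#' @param a,b `lesion_profile` objects.
#' @return a `data.frame` with `gene`, `direction`.
#' @export
shared_gene_cnvs <- function(a, b) {
  stopifnot(inherits(a, "lesion_profile"), inherits(b, "lesion_profile"))
  keys <- intersect(unique(gene_cnv_keys(a)), unique(gene_cnv_keys(b)))
  parts <- strsplit(keys, "|", fixed = TRUE)
  data.frame(gene = vapply(parts, `[`, "", 1L),
             direction = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

# Venn decomposition of one event category given per-lesion key sets.
venn_decompose <- function(key_sets) {
  ids <- names(key_sets)
  k <- length(key_sets)
  per_lesion <- vapply(key_sets, length, 0L)
  pairs <- utils::combn(ids, 2, simplify = FALSE)
  pairwise <- vapply(pairs, function(p)
    length(intersect(key_sets[[p[1]]], key_sets[[p[2]]])), 0L)
  names(pairwise) <- vapply(pairs, paste, "", collapse = "|")
  all_shared <- Reduce(intersect, key_sets)
  union_keys <- Reduce(union, key_sets)
  list(per_lesion = per_lesion, pairwise = pairwise,
       all_shared = length(all_shared), union_size = length(union_keys))
}

#' Venn decomposition of shared events across lesions
#'
#' Computes, for each event category (mutations, CNV intervals, gene CNVs),
#' the per-lesion totals, all pairwise intersection sizes, the size of the
#' intersection across all lesions, and the union size by explicit set
#' union. For three lesions the inclusion-exclusion identity
#' `|A u B u C| = sum singles - sum pairwise + triple` is verified and the
#' function fails if it does not hold (it cannot, for honest set algebra).
#'
#' @param lesions a list of >= 2 `lesion_profile` objects with distinct ids.
#' @param match_alleles passed to [shared_mutations()] key construction.
#' @return an object of class `shared_event_report`: a list with elements
#'   `mutations`, `cnv_intervals`, `gene_cnvs`, each holding `per_lesion`,
#'   `pairwise`, `all_shared`, `union_size`.
#' @export
venn_counts <- function(lesions, match_alleles = TRUE) {
  if (length(lesions) < 2) stopf("venn_counts needs at least two lesions")
  ok <- vapply(lesions, inherits, TRUE, "lesion_profile")
  if (!all(ok)) stopf("all inputs must be lesion_profile objects")
  ids <- vapply(lesions, `[[`, "", "lesion_id")
  if (anyDuplicated(ids))
    stopf("duplicate lesion id '%s'", ids[duplicated(ids)][1])
  names(lesions) <- ids
  categories <- list(
    mutations = lapply(lesions, mutation_keys, match_alleles = match_alleles),
    cnv_intervals = lapply(lesions, cnv_interval_keys),
    gene_cnvs = lapply(lesions, gene_cnv_keys))
  out <- lapply(categories, function(ks) {
    ks <- lapply(ks, unique)
    d <- venn_decompose(ks)
    if (length(ks) == 3) {
      ie <- sum(d$per_lesion) - sum(d$pairwise) + d$all_shared
      stopifnot(ie == d$union_size)
    }
    d
  })
  structure(c(out, list(lesion_ids = ids)), class = "shared_event_report")
}

#' @export
print.shared_event_report <- function(x, ...) {
  cat("Shared-event report for lesions:", paste(x$lesion_ids, collapse = ", "),
      "\n")
  for (cat_name in c("mutations", "cnv_intervals", "gene_cnvs")) {
    d <- x[[cat_name]]
    cat(sprintf("  %s: per-lesion [%s]; pairwise [%s]; all-shared %d; union %d\n",
                cat_name, paste(d$per_lesion, collapse = ", "),
                paste(sprintf("%s=%d", names(d$pairwise), d$pairwise),
                      collapse = ", "),
                d$all_shared, d$union_size))
  }
  invisible(x)
}

#' Union size from printed Venn counts
#'
#' Inclusion-exclusion for three sets: given per-lesion totals, the three
#' pairwise intersection sizes and the triple intersection, returns
#' `sum(singles) - sum(pairwise) + triple`. Useful for checking published
#' Venn diagrams whose underlying sets are not available.
#'
#' @param per_lesion numeric vector of 3 per-lesion totals.
#' @param pairwise numeric vector of 3 pairwise intersection sizes.
#' @param triple size of the triple intersection.
#' @return the union size.
#' @export
#' @examples
#' union_from_venn(c(63, 84, 88), c(38, 37, 46), 29)
union_from_venn <- function(per_lesion, pairwise, triple) {
  per_lesion <- unlist(per_lesion)
  pairwise <- unlist(pairwise)
  triple <- unlist(triple)
  if (length(per_lesion) != 3 || length(pairwise) != 3 || length(triple) != 1)
    stopf("union_from_venn expects 3 singles, 3 pairwise counts, 1 triple")
  if (any(triple > pairwise))
    stopf("triple intersection cannot exceed a pairwise intersection")
  sum(per_lesion) - sum(pairwise) + triple
}

#' Total event burden of a lesion
#'
#' Filtered mutation count plus CNV interval count plus gene CNV count. The
#' lesion sampling the ancestral population is expected to carry the fewest
#' acquired alterations.
#'
#' @param lesion a `lesion_profile`.
#' @return a non-negative count.
#' @export
event_burden <- function(lesion) {
  stopifnot(inherits(lesion, "lesion_profile"))
  nrow(lesion$mutations) + nrow(lesion$cnv_intervals) + nrow(lesion$gene_cnvs)
}

#' Pairwise relatedness score between two lesions
#'
#' An unweighted count of exactly matched events: shared mutations + shared
#' identical CNV intervals + shared gene CNV events. Symmetric;
#' `relatedness_score(a, a)` equals `a`'s total (unique-key) event count.
#' Category weights are exposed for sensitivity analyses but default to 1.
#'
#' @param a,b `lesion_profile` objects.
#' @param match_alleles passed to [shared_mutations()].
#' @param weights numeric length-3 weights for (mutations, cnv_intervals,
#'   gene_cnvs).
#' @return a non-negative score.
#' @export
relatedness_score <- function(a, b, match_alleles = TRUE,
                              weights = c(1, 1, 1)) {
  stopifnot(length(weights) == 3, all(weights >= 0))
  n_mut <- length(shared_mutations(a, b, match_alleles))
  n_cnv <- nrow(shared_cnv_intervals(a, b))
  n_gene <- nrow(shared_gene_cnvs(a, b))
  sum(weights * c(n_mut, n_cnv, n_gene))
}

#' Infer a metastatic route from relatedness and burden
#'
#' The lesion with the smallest total event burden is taken as sampling the
#' ancestral (origin) population -- cells acquire further alterations as they
#' disseminate. Remaining lesions are chained by descending relatedness to
#' the current chain tail. Ties are broken lexicographically by lesion id and
#' flagged; an all-zero score matrix yields an ordering flagged
#' `"unresolved"`.
#'
#' @param lesions list of >= 2 `lesion_profile` objects (>= 3 for a
#'   meaningful route).
#' @param match_alleles passed to [relatedness_score()].
#' @param weights passed to [relatedness_score()].
#' @return an object of class `relatedness_ordering`: list with `route`
#'   (lesion ids from origin outward), `origin`, `closest_pair`, `burdens`,
#'   `score_matrix`, and `flags` (character vector, possibly empty, with
#'   `"tie"` and/or `"unresolved"`).
#' @export
infer_route <- function(lesions, match_alleles = TRUE, weights = c(1, 1, 1)) {
  if (length(lesions) < 2) stopf("infer_route needs at least two lesions")
  ids <- unname(vapply(lesions, `[[`, "", "lesion_id"))
  if (anyDuplicated(ids)) stopf("duplicate lesion ids")
  names(lesions) <- ids
  k <- length(ids)
  burdens <- vapply(lesions, event_burden, 0)
  scores <- matrix(0, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    s <- relatedness_score(lesions[[i]], lesions[[j]], match_alleles, weights)
    scores[i, j] <- scores[j, i] <- s
  }
  flags <- character()
  if (all(scores == 0)) flags <- c(flags, "unresolved")

  pick_min <- function(v) {  # lexicographic tie-break, flag ties
    m <- names(v)[v == min(v)]
    if (length(m) > 1) flags <<- unique(c(flags, "tie"))
    sort(m)[1]
  }
  pick_max <- function(v) {
    m <- names(v)[v == max(v)]
    if (length(m) > 1) flags <<- unique(c(flags, "tie"))
    sort(m)[1]
  }

  origin <- pick_min(burdens)
  route <- origin
  remaining <- setdiff(ids, origin)
  while (length(remaining)) {
    tail_id <- route[length(route)]
    nxt <- pick_max(setNames(scores[tail_id, remaining], remaining))
    route <- c(route, nxt)
    remaining <- setdiff(remaining, nxt)
  }

  upper <- scores
  upper[lower.tri(upper, diag = TRUE)] <- -Inf
  best <- which(upper == max(upper), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
  closest_pair <- sort(c(ids[best[1, 1]], ids[best[1, 2]]))

  structure(list(route = route, origin = origin, closest_pair = closest_pair,
                 burdens = burdens,
                 burden_ranking = names(sort(burdens)),
                 score_matrix = scores, flags = flags),
            class = "relatedness_ordering")
}

#' @export
print.relatedness_ordering <- function(x, ...) {
  cat("Inferred route:", paste(x$route, collapse = " -> "), "\n")
  cat("  origin:", x$origin, " closest pair:",
      paste(x$closest_pair, collapse = " & "), "\n")
  cat("  burdens:", paste(sprintf("%s=%d", names(x$burdens), x$burdens),
                          collapse = ", "), "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
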