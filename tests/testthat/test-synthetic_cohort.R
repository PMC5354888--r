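test_that("cohort generation is deterministic and respects invariants", {
  spec <- tiny_cohort_spec(21)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  # planted regions disjoint across classes; per-sample segments never overlap
  tr <- a$truth$signature_regions
  expect_true(check_disjoint <- all(!duplicated(
    paste(tr$chrom, tr$start, tr$end))))
  expect_silent(clonotrace:::validate_segments(a$segments))
  expect_equal(nrow(a$labels), 30)
  expect_equal(sort(unique(a$labels$cancer_type)),
               c("CHOL", "LIHC", "PAAD"))
})

test_that("cohort generation rejects planted regions exceeding the genome", {
  spec <- cohort_spec(genome = c(chr1 = 1e5),
                      n_signature_regions_per_class = 50,
                      signature_length_range = c(5e4, 5e4))
  expect_error(generate_cohort(spec), "exceed")
})

test_that("patient venn counts equal the generator bookkeeping exactly", {
  co <- generate_cohort(tiny_cohort_spec(22))
  spec <- tiny_patient_spec(22)
  pat <- generate_patient(spec, co)
  v <- venn_counts(pat$lesions)
  branch <- spec$lineage[[1]]
  in_branch <- function(l) l %in% branch$lesions
  for (les in spec$lesion_ids) {
    expected <- spec$n_truncal_mutations + spec$n_private_mutations[les] +
      spec$n_artifacts + if (in_branch(les)) branch$n_mutations else 0
    expect_equal(unname(v$mutations$per_lesion[les]), unname(expected))
  }
  pw <- function(a, b) {
    both <- in_branch(a) && in_branch(b)
    spec$n_truncal_mutations + if (both) branch$n_mutations else 0
  }
  expect_equal(unname(v$mutations$pairwise["pancreas|biliary_duct"]),
               pw("pancreas", "biliary_duct"))
  expect_equal(unname(v$mutations$pairwise["biliary_duct|omentum"]),
               pw("biliary_duct", "omentum"))
  expect_equal(v$mutations$all_shared, spec$n_truncal_mutations)
  # CNV intervals: truncal + branch + private, all collision-free
  expect_equal(v$cnv_intervals$all_shared, spec$n_truncal_cnvs)
  expect_equal(unname(v$cnv_intervals$pairwise["biliary_duct|omentum"]),
               spec$n_truncal_cnvs + branch$n_cnvs)
  expect_equal(unname(v$cnv_intervals$per_lesion["omentum"]),
               unname(spec$n_truncal_cnvs + branch$n_cnvs +
                        spec$n_private_cnvs["omentum"]))
  expect_equal(v$gene_cnvs$all_shared, spec$n_truncal_gene_cnvs)
})

test_that("same patient seed reproduces the case; specs are validated", {
  co <- generate_cohort(tiny_cohort_spec(23))
  s <- tiny_patient_spec(23)
  expect_identical(generate_patient(s, co), generate_patient(s, co))
  expect_error(patient_spec(lineage = list(list(
    lesions = c("pancreas", "nope"), n_mutations = 1, n_cnvs = 0,
    n_gene_cnvs = 0))), "strict subset")
  expect_error(generate_patient(tiny_patient_spec(1, origin_class = "BRCA"),
                                co), "not a cohort class")
})

test_that("more truncal events monotonically increase pairwise relatedness", {
  co <- generate_cohort(tiny_cohort_spec(24))
  lo <- generate_patient(tiny_patient_spec(24, n_truncal_mutations = 5), co)
  hi <- generate_patient(tiny_patient_spec(24, n_truncal_mutations = 40), co)
  for (pair in list(c("pancreas", "biliary_duct"),
                    c("pancreas", "omentum"),
                    c("biliary_duct", "omentum"))) {
    expect_gt(relatedness_score(hi$lesions[[pair[1]]], hi$lesions[[pair[2]]]),
              relatedness_score(lo$lesions[[pair[1]]], lo$lesions[[pair[2]]]))
  }
})

test_that("no private or lineage events makes all lesions equally related", {
  co <- generate_cohort(tiny_cohort_spec(25))
  spec <- patient_spec(n_truncal_mutations = 12, n_truncal_cnvs = 2,
                       lineage = list(),
                       n_private_mutations = c(0, 0, 0),
                       n_private_cnvs = c(0, 0, 0),
                       n_private_gene_cnvs = c(0, 0, 0),
                       n_artifacts = 0, seed = 25)
  pat <- generate_patient(spec, co)
  scores <- combn(names(pat$lesions), 2, function(p)
    relatedness_score(pat$lesions[[p[1]]], pat$lesions[[p[2]]]))
  expect_equal(length(unique(scores)), 1)
})

test_that("generated allele frequencies concentrate below 0.05", {
  co <- generate_cohort(tiny_cohort_spec(26))
  pat <- generate_patient(tiny_patient_spec(26), co)
  af <- unlist(lapply(pat$lesions, function(l) l$mutations$allele_frequency))
  frac <- mean(af < 0.05)
  expect_gt(frac, 0.5)
  expect_lt(frac, 0.8)
})

test_that("artifacts are planted so the inclusion filter removes them", {
  co <- generate_cohort(tiny_cohort_spec(27))
  pat <- generate_patient(tiny_patient_spec(27), co)
  les <- pat$lesions$omentum
  kept <- filter_mutations(les$mutations)
  dropped <- nrow(les$mutations) - nrow(kept)
  expect_gte(dropped, pat$truth$spec$n_artifacts)
})
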