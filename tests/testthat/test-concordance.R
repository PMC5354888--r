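test_that("mutations shared across lesions match on gene and coordinate", {
  a <- lesion_profile("bile_duct",
                      mutations = make_mutations(sample = "bile_duct",
                                                 allele_frequency = 0.156))
  b <- lesion_profile("pancreas",
                      mutations = make_mutations(sample = "pancreas",
                                                 allele_frequency = 0.06))
  expect_equal(shared_mutations(a, b), "TP53|chr17|7577538|C|T")
  # same gene, different position: not shared
  m2 <- make_mutations(sample = "pancreas", position = 7577600)
  b2 <- lesion_profile("pancreas", mutations = m2)
  expect_length(shared_mutations(a, b2), 0)
  # identical lesions share their full mutation set
  expect_length(shared_mutations(a, a), nrow(a$mutations))
})

test_that("allele-strict matching separates distinct substitutions at one site", {
  a <- lesion_profile("a", mutations = make_mutations(alt = "T"))
  b <- lesion_profile("b", mutations = make_mutations(alt = "G"))
  expect_length(shared_mutations(a, b, match_alleles = TRUE), 0)
  expect_length(shared_mutations(a, b, match_alleles = FALSE), 1)
})

test_that("CNV intervals only match when identical, not off by one base", {
  mk <- function(id, ends) lesion_profile(id, cnv_intervals = data.frame(
    chrom = c("chrX", "chr4"), start = c(177942, 143211964),
    end = c(2686899, ends)))
  a <- mk("a", 146188881)
  b <- mk("b", 146188880)  # end off by one on chr4
  sh <- shared_cnv_intervals(a, b)
  expect_equal(nrow(sh), 1)
  expect_equal(sh$chrom, "chrX")
  expect_equal(nrow(shared_cnv_intervals(a, lesion_profile("c"))), 0)
  # reciprocal-overlap mode recovers the near-identical pair
  expect_equal(nrow(shared_cnv_intervals(a, b, min_reciprocal = 0.99)), 2)
})

test_that("venn counts equal brute-force set algebra on random lesions", {
  set.seed(202)
  for (rep in 1:25) {
    sets <- lapply(1:3, function(i) sample.int(40, sample(0:15, 1)))
    names(sets) <- c("L1", "L2", "L3")
    lesions <- lapply(names(sets), function(id)
      lesion_from_sites(id, sets[[id]],
                        cnv_keys = sample.int(20, sample(0:5, 1)),
                        gene_keys = sample.int(10, sample(0:4, 1))))
    v <- venn_counts(lesions)
    expect_equal(unname(v$mutations$per_lesion), unname(lengths(sets)))
    expect_equal(unname(v$mutations$pairwise),
                 c(length(intersect(sets$L1, sets$L2)),
                   length(intersect(sets$L1, sets$L3)),
                   length(intersect(sets$L2, sets$L3))))
    expect_equal(v$mutations$all_shared,
                 length(Reduce(intersect, sets)))
    expect_equal(v$mutations$union_size, length(Reduce(union, sets)))
    # inclusion-exclusion holds exactly for every category
    for (catg in c("mutations", "cnv_intervals", "gene_cnvs")) {
      d <- v[[catg]]
      expect_equal(sum(d$per_lesion) - sum(d$pairwise) + d$all_shared,
                   d$union_size)
    }
  }
})

test_that("venn counts reject duplicate lesion ids and single lesions", {
  a <- lesion_from_sites("x", 1:3)
  expect_error(venn_counts(list(a, a)), "duplicate")
  expect_error(venn_counts(list(a)), "at least two")
})

test_that("three identical lesions give all-equal venn entries", {
  lesions <- lapply(c("a", "b", "c"), lesion_from_sites, sites = 1:7)
  v <- venn_counts(lesions)
  expect_true(all(v$mutations$per_lesion == 7))
  expect_true(all(v$mutations$pairwise == 7))
  expect_equal(v$mutations$all_shared, 7)
  expect_equal(v$mutations$union_size, 7)
})

test_that("published-style venn counts give the inclusion-exclusion union", {
  expect_equal(union_from_venn(c(63, 84, 88), c(38, 37, 46), 29), 143)
  expect_error(union_from_venn(c(10, 10, 10), c(3, 3, 3), 5),
               "cannot exceed")
})

test_that("relatedness scores are symmetric counts of matched events", {
  a <- lesion_from_sites("a", 1:10, cnv_keys = 1:6, gene_keys = 1:7)
  b <- lesion_from_sites("b", 5:14, cnv_keys = 4:9, gene_keys = 5:11)
  expect_equal(relatedness_score(a, b), 6 + 3 + 3)
  expect_equal(relatedness_score(a, b), relatedness_score(b, a))
  expect_equal(relatedness_score(a, a), event_burden(a))
  disjoint <- lesion_from_sites("c", 100:105)
  expect_equal(relatedness_score(a, disjoint), 0)
})

test_that("relatedness is monotone under superset growth of a lesion", {
  a <- lesion_from_sites("a", 1:10)
  small <- lesion_from_sites("b", 3:6)
  big <- lesion_from_sites("b", 3:9)
  expect_gte(relatedness_score(a, big), relatedness_score(a, small))
})

test_that("routes order two lesions by burden and flag unresolved cases", {
  a <- lesion_from_sites("alpha", 1:4)
  b <- lesion_from_sites("beta", 1:9)
  r <- infer_route(list(a, b))
  expect_equal(r$route, c("alpha", "beta"))
  x <- lesion_from_sites("x", 1:3)
  y <- lesion_from_sites("y", 11:14)
  z <- lesion_from_sites("z", 21:26)
  r0 <- infer_route(list(x, y, z))
  expect_true("unresolved" %in% r0$flags)
})

test_that("planted clonal lineages are recovered from raw lesion profiles", {
  co <- generate_cohort(tiny_cohort_spec(8))
  for (seed in c(2, 4, 6)) {
    pat <- generate_patient(tiny_patient_spec(seed), co)
    r <- infer_route(pat$lesions)
    expect_equal(r$origin, pat$truth$origin_lesion)
    expect_equal(sort(r$closest_pair), sort(pat$truth$branches[[1]]))
    expect_setequal(r$route[2:3], pat$truth$branches[[1]])
  }
})
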