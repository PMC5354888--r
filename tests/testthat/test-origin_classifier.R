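# Permutation oracle for a region's association p-value: permute labels,
# recompute the logistic LRT statistic, and count exceedances.
permutation_pvalue <- function(values, labels, cls, n_perm = 999) {
  obs <- clonotrace:::logistic_lrt(values, labels == cls)$stat
  hits <- 0
  for (i in seq_len(n_perm)) {
    stat <- clonotrace:::logistic_lrt(values, sample(labels) == cls)$stat
    if (stat >= obs) hits <- hits + 1
  }
  (hits + 1) / (n_perm + 1)
}

test_that("constant regions score p = 1 and are flagged degenerate", {
  labels <- rep(c("A", "B"), each = 10)
  sc <- score_region_association(rep(0.3, 20), labels)
  expect_equal(sc$p_value, 1)
  expect_true(sc$degenerate)
})

test_that("strongly separated two-class regions pass the 1e-12 cutoff", {
  set.seed(7)
  labels <- rep(c("A", "B"), each = 40)
  values <- c(rnorm(40, 0.9, 0.1), rnorm(40, -0.9, 0.1))
  sc <- score_region_association(values, labels)
  expect_lt(sc$p_value, 1e-12)
  expect_true(any(sc$per_class$separated))
  # permutation oracle agrees at its resolution
  expect_lte(permutation_pvalue(values, labels, "A"), 1e-3)
})

test_that("weak and null effects agree with the permutation oracle", {
  set.seed(8)
  labels <- rep(c("A", "B"), each = 25)
  null_vals <- rnorm(50, 0, 0.3)
  sc_null <- score_region_association(null_vals, labels)
  p_perm <- permutation_pvalue(null_vals, labels, "A")
  expect_gt(sc_null$p_value, 0.01)
  expect_gt(p_perm, 0.01)
  weak <- null_vals + ifelse(labels == "A", 0.25, -0.25)
  sc_weak <- score_region_association(weak, labels)
  p_perm_weak <- permutation_pvalue(weak, labels, "A")
  # both routes call a clear but non-extreme association
  expect_lt(sc_weak$p_value, 0.01)
  expect_lt(p_perm_weak, 0.01)
})

test_that("the internal logistic LRT matches stats::glm away from separation", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(30:80, 1)
    x <- rnorm(n, 0, 0.5)
    y <- runif(n) < plogis(0.3 + runif(1, -2, 2) * x)
    if (sum(y) < 2 || sum(!y) < 2) next
    mine <- clonotrace:::logistic_lrt(x, y)
    if (mine$separated) next
    fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
    p_glm <- stats::pchisq(fit$null.deviance - fit$deviance, df = 1,
                           lower.tail = FALSE)
    expect_equal(mine$p_value, p_glm, tolerance = 1e-6)
    expect_equal(mine$slope, unname(stats::coef(fit)["x"]),
                 tolerance = 1e-4)
  }
})

test_that("null p-values are approximately uniform (two-class KS check)", {
  set.seed(9)
  labels <- rep(c("A", "B"), each = 30)
  p <- replicate(400, score_region_association(rnorm(60, 0, 0.1),
                                               labels)$p_value)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.001)
})

test_that("the ANOVA scorer is offered and agrees on a strong effect", {
  set.seed(10)
  labels <- rep(c("A", "B", "C"), each = 20)
  values <- rnorm(60, 0, 0.1) + ifelse(labels == "B", 0.8, 0)
  sc <- score_region_association(values, labels, method = "anova")
  expect_lt(sc$p_value, 1e-12)
})

test_that("signature selection is strict in alpha and deterministic", {
  co <- generate_cohort(tiny_cohort_spec(12))
  rm1 <- region_matrix(co$segments, labels = co$labels)
  all_sel <- select_signatures(rm1, alpha = 1)
  degenerate <- sum(all_sel$p_values == 1)
  expect_equal(length(all_sel$index), nrow(rm1$regions) - degenerate)
  expect_warning(none <- select_signatures(rm1, alpha = 0), "no region")
  expect_length(none$index, 0)
  again <- select_signatures(rm1, alpha = 1)
  expect_equal(again$p_values, all_sel$p_values)
})

test_that("discriminant training enforces class sizes and is duplication-invariant", {
  set.seed(13)
  x <- matrix(rnorm(40), ncol = 2)
  labels <- rep(c("A", "B"), each = 10)
  m1 <- train_discriminant(x, labels = labels)
  m2 <- train_discriminant(rbind(x, x), labels = c(labels, labels))
  expect_equal(m1$means, m2$means)
  expect_equal(m1$priors, m2$priors)
  # pooled variance uses the n - K divisor; duplication doubles the sums of
  # squares while the divisor goes from 20 - 2 to 40 - 2
  expect_equal(m2$pooled_var, m1$pooled_var * 2 * (20 - 2) / (40 - 2))
  expect_error(train_discriminant(x[c(1, 11:20), ],
                                  labels = labels[c(1, 11:20)]),
               "fewer than 2")
})

test_that("variance floor keeps scores finite for constant features", {
  x <- cbind(rep(0.5, 20), rnorm(20))
  labels <- rep(c("A", "B"), each = 10)
  m <- train_discriminant(x, labels = labels, var_floor = 1e-6)
  expect_gte(min(m$pooled_var), 1e-6)
  pred <- classify(m, x)
  expect_true(all(is.finite(pred$scores)))
})

test_that("classification picks class means and flags midpoint ties", {
  m <- train_discriminant(matrix(c(rnorm(10, 1, 0.2), rnorm(10, -1, 0.2))),
                          labels = rep(c("up", "down"), each = 10),
                          priors = "uniform")
  at_mean <- classify(m, matrix(m$means["up", ]))
  expect_equal(at_mean$class, "up")
  mid <- classify(m, matrix(mean(m$means[, 1])))
  expect_true(mid$tie)
  expect_equal(mid$class, "down")  # tie broken by class label order
})

test_that("predictions are invariant to feature permutation and sample order", {
  set.seed(14)
  x <- matrix(rnorm(60 * 4), ncol = 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  x[, 1] <- x[, 1] + rep(c(2, 0, -2), each = 20)
  labels <- rep(c("A", "B", "C"), each = 20)
  m <- train_discriminant(x, labels = labels)
  p1 <- classify(m, x)
  p2 <- classify(m, x[, c(3, 1, 4, 2)])
  expect_equal(p1$class, p2$class)
  ord <- sample(60)
  p3 <- classify(m, x[ord, ])
  expect_equal(p3$class, p1$class[ord])
})

test_that("one-feature two-class model matches the closed-form LDA boundary", {
  set.seed(15)
  n1 <- 30; n2 <- 50
  x <- matrix(c(rnorm(n1, 1, 0.7), rnorm(n2, -1, 0.7)))
  labels <- rep(c("hi", "lo"), c(n1, n2))
  m <- train_discriminant(x, labels = labels)
  # independent closed form from sample moments
  mu <- tapply(x, labels, mean)
  pooled <- (sum((x[labels == "hi"] - mu["hi"])^2) +
             sum((x[labels == "lo"] - mu["lo"])^2)) / (n1 + n2 - 2)
  pri <- c(hi = n1, lo = n2) / (n1 + n2)
  boundary <- (mu["hi"] + mu["lo"]) / 2 -
    pooled * (log(pri["hi"]) - log(pri["lo"])) / (mu["hi"] - mu["lo"])
  f <- function(v) {
    s <- classify(m, matrix(v))$scores
    s[1, "hi"] - s[1, "lo"]
  }
  root <- stats::uniroot(f, c(-3, 3), tol = 1e-14)$root
  expect_lt(abs(root - boundary), 1e-9)
  # and the model agrees with lda() predictions away from the boundary
  skip_if_not_installed("MASS")
  fit <- MASS::lda(x, grouping = labels)
  grid <- matrix(seq(-2.5, 2.5, length.out = 41))
  keep <- abs(grid - boundary) > 0.05
  expect_equal(classify(m, grid)$class[keep],
               as.character(predict(fit, grid)$class)[keep])
})

test_that("cross-validation is perfect on separable data and chance on noise", {
  co <- generate_cohort(tiny_cohort_spec(16))
  rm1 <- region_matrix(co$segments, labels = co$labels)
  # the LRT statistic is bounded by the null deviance (~2 n H(1/3)), so a
  # 30-sample test cohort needs a cutoff scaled to its size
  cv <- cross_validate(rm1, alpha = 1e-3, k = 5, seed = 1)
  expect_true(all(cv$per_class_accuracy == 1))
  expect_equal(unname(rowSums(cv$confusion)),
               unname(as.vector(table(rm1$labels))))
  # no planted signal: in-fold selection at a loose alpha, chance accuracy
  null_co <- generate_cohort(tiny_cohort_spec(17,
                                              n_signature_regions_per_class = 0,
                                              n_passenger_segments = 12))
  null_rm <- region_matrix(null_co$segments, labels = null_co$labels)
  cv0 <- cross_validate(null_rm, alpha = 0.3, k = 5, seed = 2)
  expect_lt(abs(cv0$overall_accuracy - 1 / 3), 0.25)
})

test_that("cross-validation validates stratification and supports resubstitution", {
  co <- generate_cohort(tiny_cohort_spec(18, samples_per_class = 4))
  rm1 <- region_matrix(co$segments, labels = co$labels)
  expect_error(cross_validate(rm1, k = 5, seed = 1), "fewer samples")
  resub <- cross_validate(rm1, alpha = 0.01, mode = "resubstitution")
  expect_equal(resub$mode, "resubstitution")
  expect_true(all(resub$per_class_accuracy == 1))
})

test_that("fold assignment is reproducible given the seed", {
  co <- generate_cohort(tiny_cohort_spec(19))
  rm1 <- region_matrix(co$segments, labels = co$labels)
  cv1 <- cross_validate(rm1, alpha = 1e-3, k = 3, seed = 77)
  cv2 <- cross_validate(rm1, alpha = 1e-3, k = 3, seed = 77)
  expect_equal(cv1$predictions, cv2$predictions)
  expect_error(cross_validate(rm1, k = 3, seed = NULL), "seed")
})
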