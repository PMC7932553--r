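test_that("Sidak adjustment satisfies its closed form", {
  a <- sidak_alpha(0.05, 78)
  expect_equal(a, 1 - 0.95^(1 / 78))
  expect_equal(a, 6.576e-4, tolerance = 1e-3)
  for (m in c(1, 5, 78, 500))
    expect_equal((1 - sidak_alpha(0.05, m))^m, 0.95)
})

test_that("per-slice comparison flags nothing for identical groups", {
  prof <- data.frame(slice_index = 1:20, depth_um = (1:20) * 2.8,
                     crystal_area_um2 = 0, analyzed_area_um2 = 100,
                     normalized_area = seq(0, 0.19, by = 0.01))
  res <- per_slice_comparison(list(prof, prof), list(prof, prof))
  expect_true(all(res$mean_diff == 0))
  expect_false(any(res$significant))
  expect_true(all(res$p_value == 1))
  expect_equal(attr(res, "alpha_adjusted"), sidak_alpha(0.05, 20))
  expect_error(per_slice_comparison(list(prof), list(prof, prof)),
               "at least 2")
})

test_that("group comparison handles the standard and degenerate cases", {
  x <- c(1.1, 0.9, 1.0, 1.3); y <- c(1.1, 0.9, 1.0, 1.3)
  same <- group_t_test(x, y)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  flat <- group_t_test(c(0, 0, 0, 0), c(0, 0, 0, 0))
  expect_true(flat$degenerate)
  expect_equal(flat$p, 1)

  sep <- group_t_test(c(0, 0, 0, 0), c(1, 1, 1, 1))
  expect_true(sep$degenerate)
  expect_equal(sep$p, 0)

  # agreement with the textbook Welch test on a 4-point input
  a <- c(1, 2, 3, 4); b <- c(2, 4, 6, 8)
  got <- group_t_test(a, b)
  want <- t.test(a, b)
  expect_equal(got$t, unname(want$statistic))
  expect_equal(got$p, want$p.value)
  pooled <- group_t_test(a, b, var_equal = TRUE)
  expect_equal(pooled$p, t.test(a, b, var.equal = TRUE)$p.value)
})

test_that("empirical rejection rate matches analytic power for a unit shift", {
  hits <- 0L
  for (seed in 1:100) {
    set.seed(seed)
    p <- group_t_test(rnorm(30, 1, 1), rnorm(30, 0, 1))$p
    hits <- hits + (p < 0.001)
  }
  want <- power.t.test(n = 30, delta = 1, sd = 1,
                       sig.level = 0.001)$power
  expect_lt(abs(hits / 100 - want), 0.15)
  expect_gt(hits, 40L)
})

test_that("AUC matches hand-computed and brute-force values", {
  expect_equal(roc_auc(c(5, 6, 7, 1, 2), c(TRUE, TRUE, TRUE, FALSE, FALSE),
                       n_boot = 10)$auc, 1.0)
  # positives {1,2,3} vs negatives {0,1,2}: 6 wins + 2 half-ties of 9 pairs
  r <- roc_auc(c(1, 2, 3, 0, 1, 2),
               c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), n_boot = 10)
  expect_equal(r$auc, 7 / 9)
  expect_equal(r$auc, auc_brute(c(1, 2, 3, 0, 1, 2), rep(c(TRUE, FALSE),
                                                         each = 3)))

  # oracle equivalence over random inputs up to n = 50, with ties
  set.seed(5)
  for (i in 1:25) {
    n <- sample(4:50, 1)
    labels <- c(TRUE, FALSE, runif(n - 2) > 0.5)
    scores <- sample(0:8, n, replace = TRUE)  # many ties
    expect_equal(roc_auc(scores, labels, n_boot = 2)$auc,
                 auc_brute(scores, labels))
  }
})

test_that("AUC agrees with an independent ROC package", {
  skip_if_not_installed("pROC")
  set.seed(21)
  for (i in 1:5) {
    scores <- rnorm(40)
    labels <- rep(c(TRUE, FALSE), each = 20)
    want <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                           direction = "<")))
    expect_equal(roc_auc(scores, labels, n_boot = 2)$auc, want)
  }
})

test_that("AUC near 0.5 for permuted labels, bootstrap CI behaves", {
  set.seed(11)
  scores <- rnorm(60)
  labels <- rep(c(TRUE, FALSE), 30)
  r <- roc_auc(scores, labels, seed = 3)
  expect_lt(abs(r$auc - 0.5), 0.2)
  expect_gte(0.5, r$ci_low)
  expect_lte(0.5, r$ci_high)
  expect_lte(r$ci_low, r$auc)
  expect_gte(r$ci_high, r$auc)
  # deterministic given the seed
  expect_identical(roc_auc(scores, labels, seed = 3), r)
  expect_error(roc_auc(scores, rep(TRUE, 60)), "both classes")
})

test_that("perfect separation gives a clear AUC from the pipeline scale", {
  expect_equal(roc_auc(c(1900, 2100, 1700, 300, 400, 350),
                       c(1, 1, 1, 0, 0, 0), n_boot = 10)$auc, 1.0)
})

test_that("correlations match closed-form examples", {
  x <- c(1, 2, 3, 4)
  expect_equal(correlation(x, x)$estimate, 1)
  expect_equal(correlation(x, -x, method = "spearman")$estimate, -1)
  expect_equal(correlation(x, c(2, 1, 4, 3), method = "spearman")$estimate,
               0.6)
  got <- correlation(x, c(1.2, 1.9, 3.4, 3.8))
  want <- cor.test(x, c(1.2, 1.9, 3.4, 3.8))
  expect_equal(got$estimate, unname(want$estimate))
  expect_equal(got$p, want$p.value)
  expect_error(correlation(x, rep(1, 4)), "zero-variance")
  expect_error(correlation(1:2, 1:2), "length")
})

test_that("repeatability CV matches direct arithmetic", {
  expect_equal(repeatability_cv(c(10, 10, 10)), 0)
  expect_equal(repeatability_cv(c(90, 100, 110)), 10)
  expect_error(repeatability_cv(c(-2, 2)), "non-positive")
  expect_error(repeatability_cv(5), "length")
})

test_that("clinical unit conversions are exact", {
  expect_equal(granulocyte_from_leukocyte(0), 0)
  expect_equal(granulocyte_from_leukocyte(1.0), 1.95)
  expect_equal(granulocyte_from_leukocyte(2.0), 3.90)
  expect_equal(granulocyte_from_leukocyte(c(1, 2)), c(1.95, 3.90))
  expect_error(granulocyte_from_leukocyte(-1), "nonnegative")

  expect_equal(egfr_schwartz(100, 0.413), 100)
  expect_equal(egfr_schwartz(120, 1) / egfr_schwartz(120, 2), 2)
  expect_equal(round(egfr_schwartz(141.6, 1.0), 1), 58.5)
  expect_error(egfr_schwartz(0, 1), "positive")
  expect_error(egfr_schwartz(100, 0), "positive")
})

sim_records <- function(n, beta = 0, seed = 1, binary = TRUE) {
  set.seed(seed)
  nccv <- abs(rnorm(n, 1500, 800))
  z <- as.numeric(scale(nccv))
  if (binary) {
    pr <- plogis(-0.5 + beta * z)
    out <- rbinom(n, 1, pr)
  } else {
    out <- 2 + beta * z + rnorm(n)
  }
  data.frame(subject_id = seq_len(n), nccv_um3 = nccv, outcome = out,
             age_years = runif(n, 1, 50))
}

test_that("logistic association recovers a known odds ratio per SD", {
  ors <- vapply(1:100, function(seed) {
    rec <- sim_records(200, beta = log(3), seed = seed)
    association(rec, "outcome", kind = "binary")$effect
  }, numeric(1))
  expect_gte(median(ors), 2.4)
  expect_lte(median(ors), 3.75)
})

test_that("null association CIs cover the null and errors are informative", {
  rec <- sim_records(120, beta = 0, seed = 7)
  a <- association(rec, "outcome", kind = "binary")
  expect_true(a$ci_low <= 1 && 1 <= a$ci_high || a$p_value > 0.05)
  expect_s3_class(a, "nccv_association")
  expect_output(print(a), "OR")

  cont <- sim_records(80, beta = 0.8, seed = 3, binary = FALSE)
  ac <- association(cont, "outcome", kind = "continuous",
                    covariates = "age_years")
  expect_equal(ac$kind, "continuous")
  expect_true(ac$ci_low <= ac$effect && ac$effect <= ac$ci_high)
  expect_gt(ac$effect, 0.5)

  expect_error(association(rec, "nope", kind = "binary"), "unknown field")
  expect_error(association(rec[1:5, ], "outcome", kind = "binary"),
               "fewer than 10")
})

test_that("complete separation is flagged, not silently divergent", {
  rec <- sim_records(40, beta = 0, seed = 9)
  rec$outcome <- as.integer(rec$nccv_um3 > median(rec$nccv_um3))
  expect_warning(a <- association(rec, "outcome", kind = "binary"),
                 "separation")
  expect_true(a$separation)

  rec$outcome <- 0L
  expect_warning(a0 <- association(rec, "outcome", kind = "binary"),
                 "separation")
  expect_true(a0$separation)
})

test_that("restriction and listwise deletion shape the analyzed set", {
  rec <- sim_records(60, beta = 0.5, seed = 11)
  rec$age_years[1:10] <- NA
  suppressMessages(
    a <- association(rec, "outcome", kind = "binary",
                     covariates = "age_years",
                     restrict = function(d) d$age_years >= 9 |
                                            is.na(d$age_years)))
  expect_lte(a$n, 50)
  expect_identical(a$covariates, "age_years")
})
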