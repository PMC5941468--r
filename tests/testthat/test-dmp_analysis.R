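make_delta <- function(n, p, effect = 0, sd = 0.03, seed = 1) {
  set.seed(seed)
  d <- matrix(rnorm(n * p, mean = effect, sd = sd), n,
              dimnames = list(sprintf("I%02d", 1:n), sprintf("cg%04d", 1:p)))
  d
}

test_that("paired_delta pairs individuals and is order-invariant", {
  co <- simulate_cohort(small_config(seed = 91))
  d <- paired_delta(co$beta_pre, co$beta_post, co$sheet)
  expect_equal(nrow(d), 27)
  # post = pre -> zeros
  d0 <- paired_delta(co$beta_pre, co$beta_pre, within(co$sheet, {
    sample_id <- sub("_post", "_pre", sample_id)
  }))
  expect_true(all(d0 == 0))
  # shuffled sample order gives the identical matrix
  perm <- sample(nrow(co$beta_pre))
  d2 <- paired_delta(co$beta_pre[perm, ], co$beta_post, co$sheet)
  expect_identical(d, d2)
  # unpaired individual is named in the error
  sheet_bad <- co$sheet[co$sheet$sample_id != "F001_post", ]
  expect_error(paired_delta(co$beta_pre, co$beta_post, sheet_bad), "F001")
})

test_that("estimate_prior recovers simulated scaled-inv-chisq parameters", {
  set.seed(101)
  d0_true <- 4; s02_true <- 0.01; df <- 29
  # s^2 ~ s0^2 * d0 / chisq_{d0} * chisq_d / d  (scaled inverse chi-square
  # prior on the true variance, then a chi-square sampling draw)
  sigma2 <- s02_true * d0_true / rchisq(1e4, d0_true)
  s2 <- sigma2 * rchisq(1e4, df) / df
  pr <- estimate_prior(s2, df)
  expect_gte(pr$d0, 3); expect_lte(pr$d0, 5)
  expect_gte(pr$s02, 0.008); expect_lte(pr$s02, 0.012)
  # scale equivariance: doubling s^2 doubles s0^2, leaves d0 unchanged
  pr2 <- estimate_prior(2 * s2, df)
  expect_equal(pr2$d0, pr$d0, tolerance = 1e-8)
  expect_equal(pr2$s02, 2 * pr$s02, tolerance = 1e-8)
  # degenerate: identical variances -> infinite prior df
  pr3 <- estimate_prior(rep(0.01, 100), 10)
  expect_true(is.infinite(pr3$d0))
  expect_error(estimate_prior(rep(0, 5), 10), "zero")
})

test_that("moderated test with d0 = 0 equals the classical paired t-test", {
  d <- make_delta(12, 50, effect = 0.01, seed = 3)
  prior0 <- structure(list(d0 = 0, s02 = 1), class = "moderation_prior")
  res <- moderated_paired_test(d, prior0)
  for (j in c(1, 17, 50)) {
    tt <- t.test(d[, j])
    expect_lt(abs(res$p[j] - tt$p.value), 1e-12)
    expect_lt(abs(res$t[j] - unname(tt$statistic)), 1e-10)
  }
  expect_error(moderated_paired_test(d[1:2, ]), "at least 3")
})

test_that("moderated test matches limma on the same one-sample design", {
  skip_if_not_installed("limma")
  d <- make_delta(20, 300, effect = 0, sd = 0.05, seed = 4)
  d[, 1:20] <- d[, 1:20] + 0.04
  fit <- limma::eBayes(limma::lmFit(t(d), matrix(1, nrow(d))))
  pr <- estimate_prior(apply(d, 2, var), nrow(d) - 1)
  expect_equal(pr$d0, fit$df.prior, tolerance = 1e-6)
  expect_equal(pr$s02, fit$s2.prior, tolerance = 1e-6)
  res <- moderated_paired_test(d, pr)
  expect_equal(res$t, unname(fit$t[, 1]), tolerance = 1e-8)
  expect_equal(res$p, unname(fit$p.value[, 1]), tolerance = 1e-8)
})

test_that("with d0 = Inf every probe uses the common prior variance", {
  d <- make_delta(10, 40, seed = 5)
  prior <- structure(list(d0 = Inf, s02 = 9e-4), class = "moderation_prior")
  res <- moderated_paired_test(d, prior)
  expect_true(all(res$s2_tilde == 9e-4))
})

test_that("null simulation holds its type-I error near nominal", {
  # 200 reps x 500 probes, 30 pairs; rejection rate at alpha = 0.05
  set.seed(202)
  rates <- replicate(200, {
    d <- matrix(rnorm(30 * 500, sd = 0.03), 30)
    colnames(d) <- sprintf("p%03d", 1:500)
    res <- moderated_paired_test(d)
    mean(res$p < 0.05)
  })
  expect_gte(mean(rates), 0.04)
  expect_lte(mean(rates), 0.06)
})

test_that("planted effects are detected with high power at FDR 5%", {
  set.seed(203)
  powers <- replicate(5, {
    d <- matrix(rnorm(30 * 1000, sd = 0.03), 30)
    colnames(d) <- sprintf("p%04d", 1:1000)
    d[, 1:50] <- d[, 1:50] + 0.05
    res <- moderated_paired_test(d)
    mean(res$sig_05[1:50])
  })
  expect_gt(mean(powers), 0.9)
})

test_that("interaction test: symmetry, null uniformity, detection", {
  df_ <- make_delta(15, 400, seed = 6)
  dm_ <- make_delta(12, 400, seed = 7)
  res <- interaction_test(df_, dm_)
  swapped <- interaction_test(dm_, df_)
  expect_equal(res$t, -swapped$t, tolerance = 1e-12)
  expect_equal(res$p, swapped$p, tolerance = 1e-12)
  # null: p approximately uniform
  ks <- suppressWarnings(stats::ks.test(res$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  # female-only planted effect -> small interaction q
  df2 <- df_; df2[, 1:40] <- df2[, 1:40] + 0.05
  res2 <- interaction_test(df2, dm_)
  expect_lt(median(res2$q[1:40]), 0.05)
  expect_error(interaction_test(df_[1:2, ], dm_), "at least 3")
})

test_that("bh_fdr reproduces the hand-computed step-up example", {
  r <- bh_fdr(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(r$q, rep(0.04, 4))
  r1 <- bh_fdr(rep(1, 5))
  expect_equal(r1$q, rep(1, 5))
  expect_true(all(!r1$flags))
  # monotone in sorted p; FDR-10 flags superset of FDR-5 flags
  set.seed(8)
  p <- runif(200)^2
  r2 <- bh_fdr(p)
  expect_true(all(diff(r2$q[order(p)]) >= -1e-15))
  expect_true(all(r2$flags[r2$flags[, 1], 2]))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("classify_dmps implements the set definitions", {
  mk <- function(probes, sig) {
    data.frame(probe = probes, sig_05 = sig, sig_10 = sig,
               stringsAsFactors = FALSE)
  }
  probes <- paste0("p", 1:5)
  res_f <- mk(probes, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  res_m <- mk(probes, c(FALSE, TRUE, TRUE, FALSE, FALSE))
  res_c <- mk(probes, c(FALSE, FALSE, FALSE, TRUE, FALSE))
  sets <- classify_dmps(res_f, res_m, res_c)
  expect_equal(sets$female_specific, "p1")
  expect_equal(sets$male_specific, "p3")
  expect_equal(sets$shared, "p4")
  expect_equal(unname(sets$counts["female_male_overlap"]), 1L)
  empty <- classify_dmps(mk(probes, rep(FALSE, 5)),
                         mk(probes, rep(FALSE, 5)),
                         mk(probes, rep(FALSE, 5)))
  expect_length(empty$female_specific, 0)
  expect_length(empty$shared, 0)
})

test_that("classification recovers truth classes on strong effects", {
  cfg <- small_config(seed = 110, n_probes = 1000L, effect_low = 0.08,
                      effect_median = 0.1, effect_high = 0.15,
                      n_dmp_female = 40L, n_dmp_male = 20L,
                      n_dmp_shared = 0L)
  co <- simulate_cohort(cfg)
  d <- paired_delta(co$beta_pre, co$beta_post, co$sheet)
  sex <- attr(d, "sex")
  res_f <- moderated_paired_test(d[sex == "F", ], group = "female")
  res_m <- moderated_paired_test(d[sex == "M", ], group = "male")
  res_c <- moderated_paired_test(d, group = "combined")
  sets <- classify_dmps(res_f, res_m, res_c)
  truth_f <- co$truth$probe[co$truth$class == "female_specific"]
  truth_m <- co$truth$probe[co$truth$class == "male_specific"]
  agree <- c(truth_f %in% sets$female_specific,
             truth_m %in% sets$male_specific)
  expect_gte(mean(agree), 0.9)
})

test_that("summarize_dmps computes the printed-percentage arithmetic", {
  # 155 hyper of 347 -> 44.7% (the published worked example shape)
  set.seed(9)
  n <- 347
  delta <- matrix(0, 4, n, dimnames = list(NULL, paste0("p", 1:n)))
  delta[, 1:155] <- 0.03
  delta[, 156:347] <- -0.03
  s <- summarize_dmps(colnames(delta), delta)
  expect_equal(s$pct_hyper, 44.7)
  expect_equal(s$pct_hypo, 55.3)
  # all positive -> 100% hyper
  s2 <- summarize_dmps(colnames(delta)[1:10], delta[, 1:10] + 1)
  expect_equal(s2$pct_hyper, 100)
  # empty set -> zero-count summary
  s3 <- summarize_dmps(character(0), delta)
  expect_equal(s3$n, 0L)
  # median |delta| matches truth-side computation on simulation
  co <- simulate_cohort(small_config(seed = 111))
  d <- paired_delta(co$beta_pre, co$beta_post, co$sheet)
  sex <- attr(d, "sex")
  dmpf <- co$truth$probe[co$truth$class == "female_specific"]
  s4 <- summarize_dmps(dmpf, d[sex == "F", ])
  truth_med <- median(abs(co$truth$true_delta[match(dmpf, co$truth$probe)]))
  expect_lt(abs(s4$median_abs_delta - truth_med), 0.01)
})

test_that("estimated effects are nearly unbiased at n = 30", {
  errs <- vapply(1:5, function(s) {
    co <- simulate_cohort(small_config(seed = 300 + s, n_female = 30L))
    d <- paired_delta(co$beta_pre, co$beta_post, co$sheet)
    sex <- attr(d, "sex")
    dmpf <- co$truth$probe[co$truth$class == "female_specific"]
    est <- colMeans(d[sex == "F", dmpf])
    mean(est - co$truth$true_delta[match(dmpf, co$truth$probe)])
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.002)
})
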