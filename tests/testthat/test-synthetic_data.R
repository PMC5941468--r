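test_that("config validation rejects impossible settings", {
  expect_error(small_config(n_dmp_female = 700L), "exceed n_probes")
  expect_error(small_config(effect_median = 0.2), "effect_low")
  expect_error(small_config(rho_pair = 1), "rho_pair")
  expect_error(small_config(expr_modules = list(list(size = 500,
                                                     loading = 0.5))),
               "larger than n_genes")
})

test_that("all-null config gives a null cohort", {
  cfg <- small_config(n_dmp_female = 0L, n_dmp_male = 0L, n_dmp_shared = 0L,
                      seed = 21)
  co <- simulate_cohort(cfg)
  expect_true(all(co$truth$class == "null"))
  d <- co$beta_post[paste0(co$sheet$individual[1:27], "_post"), ] -
    co$beta_pre[paste0(co$sheet$individual[1:27], "_pre"), ]
  md <- colMeans(d)
  se <- apply(d, 2, sd) / sqrt(nrow(d))
  expect_gte(mean(abs(md) <= 3 * se), 0.99)
})

test_that("planted effect sizes match the stated magnitude regime", {
  co <- simulate_cohort(sim_config(seed = 5))
  td <- co$truth$true_delta[co$truth$class == "female_specific"]
  expect_length(td, 347)
  expect_gte(median(abs(td)), 0.02)
  expect_lte(median(abs(td)), 0.035)
  expect_true(all(abs(td) >= 0.016 & abs(td) <= 0.105))
  # planted post-pre mean difference tracks the truth
  d <- paired_delta(co$beta_pre, co$beta_post, co$sheet)
  sexes <- attr(d, "sex")
  dmpf <- co$truth$probe[co$truth$class == "female_specific"]
  est <- colMeans(d[sexes == "F", dmpf])
  expect_lt(max(abs(est - co$truth$true_delta[match(dmpf, co$truth$probe)])),
            0.06)
  expect_gt(cor(est, co$truth$true_delta[match(dmpf, co$truth$probe)]), 0.9)
})

test_that("rho_pair controls within- vs between-individual correlation", {
  co <- simulate_cohort(small_config(rho_pair = 0.9, seed = 31,
                                     n_dmp_female = 0L, n_dmp_male = 0L,
                                     n_dmp_shared = 0L))
  pre_ids <- co$sheet$sample_id[co$sheet$timepoint == "pre"]
  post_ids <- co$sheet$sample_id[co$sheet$timepoint == "post"]
  n <- length(pre_ids)
  within <- mean(vapply(seq_len(n), function(i)
    cor(co$beta_pre[pre_ids[i], ], co$beta_post[post_ids[i], ]),
    numeric(1)))
  set.seed(1)
  other <- vapply(seq_len(n), function(i) {
    j <- sample(setdiff(seq_len(n), i), 1)
    cor(co$beta_pre[pre_ids[i], ], co$beta_post[post_ids[j], ])
  }, numeric(1))
  expect_gt(within, mean(other))
})

test_that("invariants: range, cell sums, determinism, truth counts", {
  cfg <- small_config(seed = 41)
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co1$beta_pre, co2$beta_pre)
  expect_identical(co1$truth, co2$truth)
  co3 <- simulate_cohort(small_config(seed = 42))
  expect_false(identical(co1$beta_pre, co3$beta_pre))
  expect_true(all(co1$beta_pre >= 0 & co1$beta_pre <= 1))
  expect_true(all(co1$beta_post >= 0 & co1$beta_post <= 1))
  sums <- rowSums(co1$sheet[, c("lymphocyte", "monocyte", "eosinophil")])
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_identical(unname(table(co1$truth$class)[c("female_specific",
                                                   "male_specific",
                                                   "shared")]),
                   table(factor(rep(c("f", "m", "s"),
                                    c(cfg$n_dmp_female, cfg$n_dmp_male,
                                      cfg$n_dmp_shared)))) |> unname())
  # each individual paired across timepoints
  tt <- table(co1$sheet$individual)
  expect_true(all(tt == 2))
})

test_that("simulated intensities round-trip through compute_beta", {
  cfg <- small_config(seed = 51, det_fail_frac = 0.01,
                      det_fail_sample_frac = 0.8)
  si <- simulate_intensities(cfg)
  beta <- compute_beta(si$meth, si$unmeth)
  expect_lt(max(abs(beta - si$beta)), 1e-6)
  # planted detection failures are caught by the 75% rule
  ann <- data.frame(probe = colnames(beta),
                    sex_chromosome = FALSE, multi_map = FALSE,
                    snp_overlap = FALSE, stringsAsFactors = FALSE)
  rep_ <- filter_probes(beta, si$detp, ann)
  expect_true(all(!rep_$kept[rep_$probe %in% si$failed_probes]))
  expect_setequal(rep_$probe[rep_$detection_fail], si$failed_probes)
})

test_that("M = U gives beta one-half everywhere", {
  m <- matrix(500, 3, 4)
  expect_true(all(compute_beta(m, m) == 0.5))
})

test_that("expression: modules and cis effects are planted as configured", {
  cfg <- small_config(seed = 61, frac_cis = 0)
  co <- simulate_cohort(cfg)
  # no modules, no cis -> near-independent noise
  cfg0 <- small_config(seed = 61, frac_cis = 0, expr_modules = list())
  e0 <- simulate_expression(co$sheet, co$truth, cfg0)
  cc <- cor(e0[, 1:80])
  expect_lt(mean(abs(cc[upper.tri(cc)])), 0.2)
  # one 50-gene module with loading 0.8 -> intra > inter correlation
  e1 <- simulate_expression(co$sheet, co$truth, cfg)
  mod <- attr(e1, "module")
  cc1 <- abs(cor(e1))
  in_m <- which(mod == 1)
  out_m <- which(mod == 0)[1:50]
  intra <- mean(cc1[in_m, in_m][upper.tri(cc1[in_m, in_m])])
  inter <- mean(cc1[in_m, out_m])
  expect_gt(intra, inter)
  expect_gt(intra, 0.4)
  # cis genes correlate with their probe's methylation
  cfg2 <- small_config(seed = 62, frac_cis = 0.1)
  co2 <- simulate_cohort(cfg2)
  e2 <- simulate_expression(co2$sheet, co2$truth, cfg2,
                            beta_post = co2$beta_post)
  cg <- attr(e2, "cis_genes")
  expect_gt(length(cg), 0)
  g <- cg[1]
  p <- co2$truth$probe[match(g, co2$truth$gene)]
  r <- cor(e2[, g], co2$beta_post[rownames(e2), p])
  expect_gt(abs(r), 0.5)
  expect_error(simulate_expression(co2$sheet, co2$truth, cfg2),
               "beta_post")
})
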