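cell_sheet <- function(n = 30, shift = 0, noise = 0.01, seed = 1) {
  set.seed(seed)
  ind <- sprintf("I%02d", 1:n)
  base <- cbind(lymphocyte = 0.75, monocyte = 0.18, eosinophil = 0.07)
  pre <- pmax(base[rep(1, n), ] + matrix(rnorm(3 * n, 0, noise), n), 0.001)
  post <- pre
  post[, "monocyte"] <- post[, "monocyte"] + shift +
    if (shift > 0) rnorm(n, 0, noise) else 0
  data.frame(sample_id = c(paste0(ind, "_pre"), paste0(ind, "_post")),
             individual = rep(ind, 2),
             timepoint = rep(c("pre", "post"), each = n),
             lymphocyte = c(pre[, 1], post[, 1]),
             monocyte = c(pre[, 2], post[, 2]),
             eosinophil = c(pre[, 3], post[, 3]),
             stringsAsFactors = FALSE)
}

test_that("paired_cell_test detects planted shifts and handles degenerate input", {
  for (s in 1:5) {
    sh <- cell_sheet(shift = 0.05, seed = s)
    r <- paired_cell_test(sh, "monocyte")
    expect_lt(r$p, 0.001)
    expect_equal(r$direction, "increase")
  }
  # post = pre -> degenerate branch
  sh0 <- cell_sheet(shift = 0, seed = 6)
  r0 <- paired_cell_test(sh0, "eosinophil")   # differences exactly 0
  expect_equal(r0$p, 1)
  expect_equal(r0$note, "all differences zero")
  # sign flip leaves p unchanged
  sh1 <- cell_sheet(shift = 0.03, seed = 7)
  r1 <- paired_cell_test(sh1, "monocyte")
  sh2 <- sh1
  sh2$timepoint <- ifelse(sh1$timepoint == "pre", "post", "pre")
  r2 <- paired_cell_test(sh2, "monocyte")
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
  expect_error(paired_cell_test(sh1, "neutrophil"), "unknown cell type")
  expect_error(paired_cell_test(sh1[c(1, 2, 31, 32), ], "monocyte"),
               ">= 6")
})

test_that("delta_cell_correlation: null flag rate, perfect monotone probe, ties", {
  # independence -> few BH flags
  fracs <- vapply(1:10, function(s) {
    sh <- cell_sheet(n = 25, shift = 0.03, seed = 600 + s)
    set.seed(700 + s)
    delta <- matrix(rnorm(25 * 100, sd = 0.02), 25,
                    dimnames = list(sprintf("I%02d", 1:25),
                                    sprintf("cg%03d", 1:100)))
    res <- delta_cell_correlation(delta, sh, cell_types = "monocyte")
    mean(res$flagged)
  }, numeric(1))
  expect_lte(mean(fracs), 0.05)
  # planted monotone dependence -> rho 1 and flagged
  sh <- cell_sheet(n = 20, shift = 0.04, seed = 8)
  dmono <- sh$monocyte[sh$timepoint == "post"] -
    sh$monocyte[sh$timepoint == "pre"]
  delta <- matrix(rnorm(20 * 30, sd = 0.02), 20,
                  dimnames = list(sprintf("I%02d", 1:20),
                                  sprintf("cg%03d", 1:30)))
  delta[, 1] <- dmono * 2 + 0.01     # strictly monotone function
  res <- delta_cell_correlation(delta, sh, cell_types = "monocyte")
  expect_equal(res$rho[1], 1)
  expect_true(res$flagged[1])
  # tie-heavy input matches brute-force average-rank correlation
  delta[, 2] <- rep(c(0.01, -0.01), 10)
  res2 <- delta_cell_correlation(delta, sh, cell_types = "monocyte")
  brute <- cor(rank(delta[, 2]), rank(dmono))
  expect_equal(res2$rho[2], brute, tolerance = 1e-12)
  # constant cell change -> not testable
  sh_const <- sh
  sh_const$monocyte <- 0.2
  res3 <- delta_cell_correlation(delta, sh_const, cell_types = "monocyte")
  expect_true(all(!res3$testable))
})

test_that("correlation p-values agree with a permutation null on a small instance", {
  set.seed(14)
  n <- 15
  x <- rnorm(n); y <- 0.6 * x + rnorm(n, sd = 0.8)
  p_param <- suppressWarnings(cor.test(x, y, method = "spearman",
                                       exact = FALSE))$p.value
  obs <- abs(cor(x, y, method = "spearman"))
  perm <- replicate(1e4, abs(cor(x, sample(y), method = "spearman")))
  p_mc <- (sum(perm >= obs) + 1) / (1e4 + 1)
  mc_se <- sqrt(p_mc * (1 - p_mc) / 1e4)
  expect_lt(abs(p_param - p_mc), 3 * mc_se + 0.01)
})

test_that("cis_correlation finds planted affine dependence and counts exclusions", {
  cfg <- small_config(seed = 130, frac_cis = 0.1)
  co <- simulate_cohort(cfg)
  expr <- simulate_expression(co$sheet, co$truth, cfg,
                              beta_post = co$beta_post)
  # perfect affine pair
  probe1 <- co$truth$probe[1]
  g1 <- co$truth$gene[1]
  expr[, g1] <- 2 * co$beta_post[rownames(expr), probe1] + 1
  res <- cis_correlation(co$beta_post, expr, co$annotation,
                         c(probe1, co$truth$probe[2:40]))
  expect_equal(abs(res$r[res$probe == probe1]), 1, tolerance = 1e-12)
  # planted cis genes show excess flagged fraction over the null rate
  cisg <- attr(expr, "cis_genes")
  cis_probes <- co$truth$probe[match(cisg, co$truth$gene)]
  res_cis <- cis_correlation(co$beta_post, expr, co$annotation, cis_probes)
  expect_gt(attr(res_cis, "frac_flagged"), 0.5)
  # gene absent from expression -> excluded and tallied
  expr2 <- expr[, setdiff(colnames(expr), co$truth$gene[2]), drop = FALSE]
  res2 <- cis_correlation(co$beta_post, expr2, co$annotation,
                          co$truth$probe[1:5])
  expect_gte(attr(res2, "n_excluded"), 1)
  expect_error(cis_correlation(co$beta_post[0, , drop = FALSE], expr,
                               co$annotation, probe1), "matched samples")
})

test_that("subset_sensitivity: identity, ancestry regime, degenerate input", {
  co <- simulate_cohort(small_config(seed = 131))
  d <- paired_delta(co$beta_pre, co$beta_post, co$sheet)
  dmps <- co$truth$probe[co$truth$class != "null"]
  r0 <- subset_sensitivity(d, character(0), dmps)
  expect_equal(r0$r, 1)
  expect_error(subset_sensitivity(d, character(0), character(0)), "empty")
  expect_error(subset_sensitivity(d, rownames(d)[-(1:2)], dmps),
               "fewer than 3")
  # excluding 5 of ~30 female individuals keeps estimates correlated
  ok <- vapply(1:10, function(s) {
    co2 <- simulate_cohort(small_config(seed = 800 + s, n_female = 30L))
    d2 <- paired_delta(co2$beta_pre, co2$beta_post, co2$sheet)
    dmp2 <- co2$truth$probe[co2$truth$class != "null"]
    set.seed(900 + s)
    ex <- sample(rownames(d2), 5)
    subset_sensitivity(d2, ex, dmp2)$r > 0.8
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})
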