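#' Within-individual methylation differences (delta-beta matrix)
#'
#' Computes delta = beta(post) - beta(pre) per individual over the probe set
#' common to both matrices. The paired "random individual effect" design for
#' two timepoints is exactly equivalent to testing these within-individual
#' differences, which is how all downstream tests operate.
#'
#' @param pre,post beta matrices (samples x probes) for the two timepoints.
#' @param sheet sample sheet linking \code{sample_id} to \code{individual},
#'   \code{sex} and \code{timepoint}.
#' @return individuals x probes matrix of differences with attribute
#'   \code{sex} (named by individual).
#' @export
paired_delta <- function(pre, post, sheet) {
  probes <- intersect(colnames(pre), colnames(post))
  if (length(probes) == 0) stop("no common probes between timepoints")
  sh_pre <- sheet[sheet$timepoint == "pre", ]
  sh_post <- sheet[sheet$timepoint == "post", ]
  ind <- sort(unique(sheet$individual))
  miss <- ind[!(ind %in% sh_pre$individual) | !(ind %in% sh_post$individual)]
  if (length(miss))
    stop("unpaired individuals: ", paste(miss, collapse = ", "))
  pre_ids <- sh_pre$sample_id[match(ind, sh_pre$individual)]
  post_ids <- sh_post$sample_id[match(ind, sh_post$individual)]
  if (!all(pre_ids %in% rownames(pre)) || !all(post_ids %in% rownames(post)))
    stop("sample sheet references samples absent from the beta matrices")
  delta <- post[post_ids, probes, drop = FALSE] -
    pre[pre_ids, probes, drop = FALSE]
  rownames(delta) <- ind
  attr(delta, "sex") <- setNames(sh_pre$sex[match(ind, sh_pre$individual)],
                                 ind)
  delta
}

## Invert the trigamma function by Newton iteration (monotone decreasing).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

#' Empirical-Bayes moderation prior for per-probe variances
#'
#' Fits a scaled inverse-chi-square prior (d0, s0^2) to the observed
#' per-probe sample variances by the method of moments on the log scale:
#' log s^2 is distributed as log s0^2 plus log F(d, d0) under the model, so
#' the prior degrees of freedom solve
#' trigamma(d0/2) = var(log s^2) - trigamma(d/2) and s0^2 follows from the
#' mean. When the empirical variance of log s^2 does not exceed its
#' theoretical null value, d0 is infinite and all probes share s0^2.
#'
#' @param s2 per-probe sample variances (zeros are excluded from the fit).
#' @param df residual degrees of freedom of each variance (scalar).
#' @return list of class \code{moderation_prior} with \code{d0} and
#'   \code{s02}.
#' @export
estimate_prior <- function(s2, df) {
  if (all(s2 == 0)) stop("all variances are zero")
  s2 <- s2[s2 > 0]
  if (df < 1) stop("residual df must be >= 1")
  z <- log(s2)
  evar <- var(z) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    d0 <- Inf
    s02 <- exp(mean(z) - digamma(df / 2) + log(df / 2))
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(mean(z) - digamma(df / 2) + log(df / 2) +
               digamma(d0 / 2) - log(d0 / 2))
  }
  structure(list(d0 = d0, s02 = s02), class = "moderation_prior")
}

moderated_stats <- function(mean_eff, s2, df, se_factor, prior) {
  d0 <- prior$d0; s02 <- prior$s02
  if (d0 == 0) {
    s2_tilde <- s2
  } else if (is.infinite(d0)) {
    s2_tilde <- rep(s02, length(s2))
  } else {
    s2_tilde <- (d0 * s02 + df * s2) / (d0 + df)
  }
  tt <- mean_eff / (sqrt(s2_tilde) * se_factor)
  df_total <- d0 + df
  p <- 2 * pt(abs(tt), df = df_total, lower.tail = FALSE)
  list(s2_tilde = s2_tilde, t = tt, df_total = df_total, p = p)
}

#' Moderated one-sample (paired) t-test per probe
#'
#' For each probe, tests whether the mean within-individual difference is
#' zero using a t statistic whose variance estimate is shrunk toward the
#' prior: s~^2 = (d0 s0^2 + d s^2) / (d0 + d) with d = n - 1, and p-values
#' from t on d0 + d degrees of freedom. With \code{prior = NULL} the prior is
#' estimated from the data; a prior with d0 = 0 reduces exactly to the
#' classical paired t-test.
#'
#' @param delta individuals x probes difference matrix
#'   (see \code{\link{paired_delta}}).
#' @param prior a \code{\link{estimate_prior}} result, or \code{NULL}.
#' @param group label stored in the result (e.g. "female").
#' @param fdr_levels FDR thresholds for significance flags.
#' @return data.frame of class \code{dmp_result}: probe, group, mean_delta,
#'   s2, s2_tilde, t, df_total, p, q, sig_05, sig_10, direction.
#' @export
moderated_paired_test <- function(delta, prior = NULL, group = "combined",
                                  fdr_levels = c(0.05, 0.10)) {
  n <- nrow(delta)
  if (n < 3) stop("need at least 3 individuals, got ", n)
  df <- n - 1
  mean_d <- colMeans(delta)
  s2 <- (colSums(delta^2) - n * mean_d^2) / df
  s2[s2 < 0] <- 0
  if (is.null(prior)) prior <- estimate_prior(s2, df)
  ms <- moderated_stats(mean_d, s2, df, 1 / sqrt(n), prior)
  build_dmp_result(colnames(delta), group, mean_d, s2, ms, fdr_levels)
}

#' Moderated two-sample interaction test (sex x age)
#'
#' Compares the within-individual differences between sexes probe by probe:
#' a two-sample moderated t on the delta matrices, i.e. the sex-by-timepoint
#' interaction of the 2 x 2 paired design. Pooled variances are moderated by
#' the supplied or estimated prior.
#'
#' @param delta_f,delta_m delta matrices for the two groups.
#' @param prior moderation prior or \code{NULL} to estimate from the pooled
#'   variances.
#' @param fdr_levels FDR thresholds for significance flags.
#' @return \code{dmp_result} data.frame; \code{mean_delta} holds the
#'   female-minus-male difference in mean delta.
#' @export
interaction_test <- function(delta_f, delta_m, prior = NULL,
                             fdr_levels = c(0.05, 0.10)) {
  nf <- nrow(delta_f); nm <- nrow(delta_m)
  if (nf < 3 || nm < 3) stop("need at least 3 individuals per sex")
  probes <- intersect(colnames(delta_f), colnames(delta_m))
  delta_f <- delta_f[, probes, drop = FALSE]
  delta_m <- delta_m[, probes, drop = FALSE]
  df <- nf + nm - 2
  mf <- colMeans(delta_f); mm <- colMeans(delta_m)
  s2 <- ((colSums(delta_f^2) - nf * mf^2) +
         (colSums(delta_m^2) - nm * mm^2)) / df
  s2[s2 < 0] <- 0
  if (is.null(prior)) prior <- estimate_prior(s2, df)
  ms <- moderated_stats(mf - mm, s2, df, sqrt(1 / nf + 1 / nm), prior)
  build_dmp_result(probes, "interaction", mf - mm, s2, ms, fdr_levels)
}

build_dmp_result <- function(probes, group, mean_d, s2, ms, fdr_levels) {
  fdr <- bh_fdr(ms$p, levels = fdr_levels)
  out <- data.frame(probe = probes, group = group, mean_delta = mean_d,
                    s2 = s2, s2_tilde = ms$s2_tilde, t = ms$t,
                    df_total = ms$df_total, p = ms$p, q = fdr$q,
                    sig_05 = fdr$flags[, 1], sig_10 = fdr$flags[, 2],
                    direction = ifelse(mean_d > 0, "hyper", "hypo"),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("dmp_result", "data.frame")
  out
}

#' Benjamini-Hochberg q-values with significance flags
#'
#' Step-up BH adjusted p-values plus logical flags at the requested FDR
#' levels.
#'
#' @param p p-values in [0, 1].
#' @param levels FDR thresholds to flag (default 0.05 and 0.10).
#' @return list with \code{q} and a logical matrix \code{flags}
#'   (one column per level).
#' @export
bh_fdr <- function(p, levels = c(0.05, 0.10)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  q <- p.adjust(p, method = "BH")
  flags <- vapply(levels, function(l) !is.na(q) & q <= l,
                  logical(length(p)))
  if (is.null(dim(flags))) flags <- matrix(flags, nrow = length(p))
  colnames(flags) <- paste0("fdr_", levels)
  list(q = q, flags = flags)
}

#' Classify significant probes into sex-specific and shared DMP sets
#'
#' Operationalizes "unique to girls/boys" as significant in that sex's
#' stratified analysis and not in the other's; "shared" as significant in
#' the combined analysis.
#'
#' @param res_f,res_m,res_combined \code{dmp_result} tables on a common
#'   probe set.
#' @param fdr_level 0.05 or 0.10 (selects the flag column).
#' @return list with \code{female_specific}, \code{male_specific},
#'   \code{shared} (probe id vectors) and \code{counts}.
#' @export
classify_dmps <- function(res_f, res_m, res_combined, fdr_level = 0.05) {
  col <- if (fdr_level <= 0.05) "sig_05" else "sig_10"
  sf <- res_f$probe[res_f[[col]]]
  sm <- res_m$probe[res_m[[col]]]
  sc <- res_combined$probe[res_combined[[col]]]
  out <- list(female_specific = setdiff(sf, sm),
              male_specific = setdiff(sm, sf),
              shared = sc)
  out$counts <- c(female_specific = length(out$female_specific),
                  male_specific = length(out$male_specific),
                  shared = length(out$shared),
                  female_male_overlap = length(intersect(sf, sm)))
  out
}

#' Summary statistics for a DMP set
#'
#' Counts and percentages of hyper-/hypomethylated probes, the median and
#' range of |delta-beta|, the number with |delta-beta| > 0.05, and region
#' category fractions when annotation is supplied. Percentages are rounded
#' to one decimal at the reporting layer.
#'
#' @param probes DMP probe ids (may be empty).
#' @param delta individuals x probes difference matrix used to estimate mean
#'   delta per probe.
#' @param ann optional probe annotation with a \code{region} column.
#' @return list of summary fields.
#' @export
summarize_dmps <- function(probes, delta, ann = NULL) {
  if (length(probes) == 0)
    return(list(n = 0L, n_hyper = 0L, n_hypo = 0L, pct_hyper = NA_real_,
                pct_hypo = NA_real_, median_abs_delta = NA_real_,
                range_abs_delta = c(NA_real_, NA_real_), n_gt_05 = 0L,
                region_fractions = NULL))
  md <- colMeans(delta[, probes, drop = FALSE])
  n <- length(probes)
  n_hyper <- sum(md > 0)
  out <- list(n = n, n_hyper = n_hyper, n_hypo = n - n_hyper,
              pct_hyper = round(100 * n_hyper / n, 1),
              pct_hypo = round(100 * (n - n_hyper) / n, 1),
              median_abs_delta = median(abs(md)),
              range_abs_delta = range(abs(md)),
              n_gt_05 = sum(abs(md) > 0.05))
  if (!is.null(ann)) {
    reg <- ann$region[match(probes, ann$probe)]
    out$region_fractions <- round(100 * table(reg) / n, 1)
  }
  out
}
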