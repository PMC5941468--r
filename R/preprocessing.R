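#' Beta values from methylated/unmethylated intensities
#'
#' beta = M / (M + U + offset), elementwise. The default offset is 0, i.e.
#' the plain methylated-signal fraction; array pipelines commonly add 100,
#' which is supported via \code{offset}.
#'
#' @param meth,unmeth conformable nonnegative intensity matrices
#'   (samples x probes).
#' @param offset nonnegative scalar added to the denominator.
#' @param on_zero what to do where \code{M + U + offset == 0}: \code{"error"}
#'   (default) or \code{"na"}.
#' @return matrix of beta values in [0, 1] with the input dimnames.
#' @export
compute_beta <- function(meth, unmeth, offset = 0, on_zero = c("error", "na")) {
  on_zero <- match.arg(on_zero)
  if (!all(dim(meth) == dim(unmeth)))
    stop("meth and unmeth must be conformable")
  if (any(meth < 0) || any(unmeth < 0) || offset < 0)
    stop("intensities and offset must be nonnegative")
  den <- meth + unmeth + offset
  if (any(den == 0)) {
    if (on_zero == "error")
      stop("M + U + offset is zero at ", sum(den == 0), " cell(s)")
    den[den == 0] <- NA_real_
  }
  beta <- meth / den
  dimnames(beta) <- dimnames(meth)
  beta
}

#' Apply the probe-level quality filters
#'
#' A probe is removed when it (i) maps to a sex chromosome, (ii) is flagged
#' as multi-mapping, (iii) overlaps a known SNP, or (iv) has detection
#' p-value above \code{detp_threshold} in at least \code{sample_fraction} of
#' samples. The detection rule is a removal criterion with an inclusive
#' boundary: a failing-sample fraction of exactly \code{sample_fraction}
#' removes the probe.
#'
#' @param beta beta matrix (samples x probes); only its probe set is used.
#' @param detp detection p-value matrix conformable with \code{beta}, or
#'   \code{NULL} to skip the detection filter.
#' @param ann probe annotation covering all probes, with columns
#'   \code{probe}, \code{sex_chromosome} (or \code{chrom}), \code{multi_map},
#'   \code{snp_overlap}.
#' @param detp_threshold detection p-value cutoff (default 0.01).
#' @param sample_fraction failing-sample fraction at or above which the probe
#'   is removed (default 0.75).
#' @return a \code{filter_report} data.frame: one row per probe with logical
#'   flag columns and \code{kept}; attribute \code{counts} holds per-reason
#'   totals.
#' @export
filter_probes <- function(beta, detp = NULL, ann,
                          detp_threshold = 0.01, sample_fraction = 0.75) {
  probes <- colnames(beta)
  m <- match(probes, ann$probe)
  if (anyNA(m))
    stop("annotation missing for probes: ",
         paste(head(probes[is.na(m)], 10), collapse = ", "))
  a <- ann[m, , drop = FALSE]
  sex_chr <- if ("sex_chromosome" %in% names(a)) a$sex_chromosome
             else a$chrom %in% c("chrX", "chrY")
  det_fail <- rep(FALSE, length(probes))
  if (!is.null(detp)) {
    if (!all(dim(detp) == dim(beta)))
      stop("detp must be conformable with beta")
    frac_fail <- colMeans(detp > detp_threshold)
    det_fail <- frac_fail >= sample_fraction
  }
  rep_df <- data.frame(probe = probes,
                       sex_chromosome = sex_chr,
                       multi_map = a$multi_map,
                       snp_overlap = a$snp_overlap,
                       detection_fail = det_fail,
                       stringsAsFactors = FALSE)
  rep_df$kept <- !(rep_df$sex_chromosome | rep_df$multi_map |
                   rep_df$snp_overlap | rep_df$detection_fail)
  attr(rep_df, "counts") <- c(
    total = nrow(rep_df),
    sex_chromosome = sum(rep_df$sex_chromosome),
    multi_map = sum(rep_df$multi_map),
    snp_overlap = sum(rep_df$snp_overlap),
    detection_fail = sum(rep_df$detection_fail),
    kept = sum(rep_df$kept))
  class(rep_df) <- c("filter_report", "data.frame")
  rep_df
}

#' Subset a beta matrix to the probes kept by a filter report
#' @param beta beta matrix (samples x probes).
#' @param report a \code{filter_report} from \code{\link{filter_probes}}.
#' @return the beta matrix restricted to kept probes.
#' @export
apply_filter <- function(beta, report) {
  beta[, report$probe[report$kept], drop = FALSE]
}

#' Logit2 (M-value) transform of beta values
#'
#' M = log2((beta + eps) / (1 - beta + eps)); strictly increasing in beta.
#' With \code{eps = 0} (the default) beta values of exactly 0 or 1 map to
#' -Inf/Inf; simulated and clamped data never hit those bounds.
#'
#' @param beta beta values in [0, 1].
#' @param eps small nonnegative stabilizer.
#' @return M-values, same shape as the input.
#' @export
mvalue <- function(beta, eps = 0) {
  log2((beta + eps) / (1 - beta + eps))
}

#' Inverse of \code{\link{mvalue}} at eps = 0
#' @param m M-values.
#' @return beta values.
#' @export
beta_from_mvalue <- function(m) {
  x <- 2^m
  x / (1 + x)
}

#' PCA screen for technical and biological covariates
#'
#' Runs PCA on the (column-centered) data matrix and tests each covariate
#' against each of the top principal components: one-way ANOVA for factors,
#' Pearson correlation for numeric covariates. A covariate is flagged as a
#' potential confounder when it associates with any screened PC at
#' \code{alpha}. Constant covariates are reported as not testable rather
#' than raising an error.
#'
#' @param x data matrix, samples x features.
#' @param sheet sample sheet with one row per row of \code{x} (matched on
#'   \code{sample_id} when present, otherwise by order).
#' @param covariates names of sheet columns to screen.
#' @param n_components number of leading PCs to test.
#' @param alpha flagging threshold (applied per covariate with a Bonferroni
#'   correction across the screened PCs).
#' @return data.frame with \code{pc}, \code{covariate}, \code{p},
#'   \code{testable}; attribute \code{flagged} lists covariates with any
#'   p < alpha.
#' @export
pca_screen <- function(x, sheet, covariates = c("batch", "sex", "timepoint"),
                       n_components = 5, alpha = 0.05) {
  if (nrow(x) < 2) stop("need at least 2 samples")
  if (!is.null(rownames(x)) && "sample_id" %in% names(sheet))
    sheet <- sheet[match(rownames(x), sheet$sample_id), , drop = FALSE]
  n_components <- min(n_components, nrow(x) - 1)
  pcs <- prcomp(x, center = TRUE, scale. = FALSE)$x[, seq_len(n_components),
                                                    drop = FALSE]
  rows <- list()
  for (cv in covariates) {
    v <- sheet[[cv]]
    testable <- length(unique(v[!is.na(v)])) > 1
    for (k in seq_len(n_components)) {
      p <- NA_real_
      if (testable) {
        if (is.numeric(v)) {
          p <- cor.test(pcs[, k], v)$p.value
        } else {
          fit <- aov(pcs[, k] ~ factor(v))
          p <- summary(fit)[[1]][["Pr(>F)"]][1]
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        pc = paste0("PC", k), covariate = cv, p = p, testable = testable,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  ## Bonferroni across the screened PCs so the per-covariate false-flag
  ## rate stays near alpha regardless of n_components
  flagged <- unique(out$covariate[out$testable & !is.na(out$p) &
                                  out$p < alpha / n_components])
  attr(out, "flagged") <- flagged
  out
}

#' Remove batch effects from a data matrix
#'
#' Two modes. \code{meancenter}: per feature, shift each batch's mean to the
#' grand mean (location only). \code{eb_location_scale}: an empirical-Bayes
#' location-scale correction in the ComBat spirit -- per-feature batch means
#' and variances are estimated on standardized data, shrunk toward their
#' across-feature pooled values by method-of-moments priors (normal prior on
#' locations, inverse-gamma on scales), and removed; the grand mean and
#' pooled scale are restored afterwards. Both modes preserve the per-feature
#' grand mean.
#'
#' @param x data matrix, samples x features.
#' @param batch batch label per sample.
#' @param mode \code{"meancenter"} or \code{"eb_location_scale"}.
#' @return adjusted matrix, same shape.
#' @export
adjust_batch <- function(x, batch,
                         mode = c("meancenter", "eb_location_scale")) {
  mode <- match.arg(mode)
  batch <- as.character(batch)
  if (length(batch) != nrow(x)) stop("one batch label per sample required")
  tab <- table(batch)
  if (length(tab) < 2) stop("need at least 2 batches")
  if (any(tab < 2)) {
    if (mode == "eb_location_scale")
      stop("batch with a single sample: ",
           paste(names(tab)[tab < 2], collapse = ", "))
    warning("batch with a single sample; mean-centering only")
  }
  grand <- colMeans(x)
  if (mode == "meancenter") {
    out <- x
    for (b in names(tab)) {
      idx <- batch == b
      out[idx, ] <- sweep(x[idx, , drop = FALSE], 2,
                          colMeans(x[idx, , drop = FALSE]) - grand, `-`)
    }
    return(out)
  }
  ## eb_location_scale
  pooled_var <- apply(x, 2, var)
  pooled_var[pooled_var == 0] <- min(pooled_var[pooled_var > 0], 1e-12)
  z <- sweep(sweep(x, 2, grand, `-`), 2, sqrt(pooled_var), `/`)
  out <- z
  for (b in names(tab)) {
    idx <- batch == b
    nb <- sum(idx)
    gb <- colMeans(z[idx, , drop = FALSE])               # batch locations
    db <- apply(z[idx, , drop = FALSE], 2, var)          # batch scales
    db[is.na(db) | db == 0] <- 1
    ## MoM priors across features
    g_bar <- mean(gb); t2 <- max(var(gb) - mean(db) / nb, 1e-8)
    m_d <- mean(db); v_d <- var(db)
    a_prior <- if (v_d > 0) (2 * v_d + m_d^2) / v_d else Inf
    b_prior <- if (is.finite(a_prior)) (m_d * v_d + m_d^3) / v_d else NA
    g_star <- (nb * t2 * gb + db * g_bar) / (nb * t2 + db)
    d_star <- if (is.finite(a_prior)) {
      (b_prior + 0.5 * (nb - 1) * db) / (a_prior + (nb - 1) / 2 - 1)
    } else rep(m_d, length(db))
    d_star[d_star <= 0] <- m_d
    out[idx, ] <- sweep(sweep(z[idx, , drop = FALSE], 2, g_star, `-`),
                        2, sqrt(d_star), `/`)
  }
  ## restore original location/scale; re-center globally so the per-feature
  ## grand mean is preserved exactly (batch means only equalized up to the
  ## EB shrinkage, by design)
  out <- sweep(sweep(out, 2, sqrt(pooled_var), `*`), 2, grand, `+`)
  sweep(out, 2, colMeans(out) - grand, `-`)
}
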