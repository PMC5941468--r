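#' Paired Wilcoxon signed-rank test of a cell-type proportion change
#'
#' Tests whether a blood-cell proportion differs between the pre and post
#' timepoints within individuals. "Wilcoxon Rank Test" on paired data is
#' interpreted as the signed-rank test. When every within-individual
#' difference is zero the test is degenerate and p = 1 is reported with a
#' note.
#'
#' @param sheet sample sheet (both timepoints) with \code{individual},
#'   \code{timepoint} and a column named after \code{cell_type}.
#' @param cell_type column name, e.g. "monocyte".
#' @return data.frame row: cell_type, statistic, p, direction
#'   ("increase"/"decrease"/"none"), note.
#' @export
paired_cell_test <- function(sheet, cell_type) {
  if (!cell_type %in% names(sheet)) stop("unknown cell type: ", cell_type)
  pre <- sheet[sheet$timepoint == "pre", ]
  post <- sheet[sheet$timepoint == "post", ]
  ind <- intersect(pre$individual, post$individual)
  if (length(ind) < 6) stop("need paired proportions for >= 6 individuals")
  d <- post[[cell_type]][match(ind, post$individual)] -
    pre[[cell_type]][match(ind, pre$individual)]
  if (all(d == 0))
    return(data.frame(cell_type = cell_type, statistic = NA_real_, p = 1,
                      direction = "none", note = "all differences zero",
                      stringsAsFactors = FALSE))
  wt <- suppressWarnings(wilcox.test(d, exact = FALSE))
  data.frame(cell_type = cell_type, statistic = unname(wt$statistic),
             p = wt$p.value,
             direction = if (median(d) > 0) "increase"
                         else if (median(d) < 0) "decrease" else "none",
             note = NA_character_, stringsAsFactors = FALSE)
}

#' Probe-wise correlation of methylation change with cell-composition change
#'
#' Spearman correlation (average ranks for ties, normal-approximation p)
#' between each probe's within-individual delta-beta and the
#' within-individual change in each cell-type proportion, with BH FDR flags
#' per cell type. Constant cell-proportion changes are reported as not
#' testable.
#'
#' @param delta individuals x probes difference matrix.
#' @param sheet sample sheet with both timepoints.
#' @param cell_types columns to test.
#' @param fdr_level FDR flag threshold (default 0.05).
#' @return data.frame: probe, cell_type, rho, p, q, flagged, testable.
#' @export
delta_cell_correlation <- function(delta, sheet,
                                   cell_types = c("lymphocyte", "monocyte",
                                                  "eosinophil"),
                                   fdr_level = 0.05) {
  ind <- rownames(delta)
  if (length(ind) < 6) stop("need >= 6 individuals")
  pre <- sheet[sheet$timepoint == "pre", ]
  post <- sheet[sheet$timepoint == "post", ]
  out <- list()
  for (ct in cell_types) {
    dcell <- post[[ct]][match(ind, post$individual)] -
      pre[[ct]][match(ind, pre$individual)]
    testable <- length(unique(dcell)) > 1
    if (!testable) {
      out[[ct]] <- data.frame(probe = colnames(delta), cell_type = ct,
                              rho = NA_real_, p = NA_real_, q = NA_real_,
                              flagged = FALSE, testable = FALSE,
                              stringsAsFactors = FALSE)
      next
    }
    res <- apply(delta, 2, function(v) {
      ct_ <- suppressWarnings(cor.test(v, dcell, method = "spearman",
                                       exact = FALSE))
      c(ct_$estimate, ct_$p.value)
    })
    q <- p.adjust(res[2, ], method = "BH")
    out[[ct]] <- data.frame(probe = colnames(delta), cell_type = ct,
                            rho = unname(res[1, ]), p = unname(res[2, ]),
                            q = q, flagged = q <= fdr_level, testable = TRUE,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Methylation-expression (cis) correlation at DMPs
#'
#' Pearson correlation between post-timepoint beta at each DMP and the
#' expression of its nearest gene, over matched samples. Pairs whose gene is
#' not in the expression matrix are excluded and counted.
#'
#' @param beta_post post-timepoint beta matrix (samples x probes).
#' @param expr post-timepoint expression matrix (samples x genes).
#' @param ann probe annotation with \code{probe}, \code{nearest_gene}.
#' @param dmp_probes DMP probe ids to test.
#' @param alpha flagging threshold on the unadjusted p (default 0.05).
#' @return data.frame of class \code{cis_correlation}: probe, gene, r, p,
#'   flagged; attributes \code{n_excluded} (gene not expressed) and
#'   \code{frac_flagged}.
#' @export
cis_correlation <- function(beta_post, expr, ann, dmp_probes, alpha = 0.05) {
  samples <- intersect(rownames(beta_post), rownames(expr))
  if (length(samples) == 0) stop("no matched samples between matrices")
  genes <- ann$nearest_gene[match(dmp_probes, ann$probe)]
  ok <- !is.na(genes) & genes %in% colnames(expr)
  rows <- lapply(which(ok), function(i) {
    ct <- cor.test(beta_post[samples, dmp_probes[i]],
                   expr[samples, genes[i]])
    data.frame(probe = dmp_probes[i], gene = genes[i],
               r = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(probe = character(0), gene = character(0),
               r = numeric(0), p = numeric(0), stringsAsFactors = FALSE)
  out$flagged <- out$p < alpha
  attr(out, "n_excluded") <- sum(!ok)
  attr(out, "frac_flagged") <- if (nrow(out)) mean(out$flagged) else NA_real_
  class(out) <- c("cis_correlation", "data.frame")
  out
}

#' Sensitivity of DMP effect estimates to excluding individuals
#'
#' Recomputes per-probe mean delta-beta over the DMP set after dropping the
#' given individuals and correlates (Pearson) the subset estimates with the
#' full-sample estimates. Used for the ancestry sensitivity check (excluding
#' the non-European individuals).
#'
#' @param delta individuals x probes difference matrix.
#' @param exclude individual ids to drop (may be empty).
#' @param dmp_probes probe ids over which to correlate (non-empty).
#' @return list: r, n_full, n_subset, excluded.
#' @export
subset_sensitivity <- function(delta, exclude, dmp_probes) {
  if (length(dmp_probes) == 0) stop("empty DMP probe list")
  keep <- setdiff(rownames(delta), exclude)
  if (length(keep) < 3) stop("exclusion leaves fewer than 3 individuals")
  full <- colMeans(delta[, dmp_probes, drop = FALSE])
  sub <- colMeans(delta[keep, dmp_probes, drop = FALSE])
  r <- if (length(dmp_probes) > 1 && sd(full) > 0 && sd(sub) > 0)
    cor(full, sub) else NA_real_
  list(r = r, n_full = nrow(delta), n_subset = length(keep),
       excluded = intersect(rownames(delta), exclude))
}
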