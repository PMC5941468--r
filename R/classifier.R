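#' Unsupervised 2-group clustering of samples on a CpG panel
#'
#' Agglomerative hierarchical clustering of samples on the beta values of a
#' CpG predictor panel, cut at k = 2. Deterministic given inputs. Panel
#' probes absent from the matrix are dropped (the intersection size is
#' reported via an attribute); clustering proceeds on the rest.
#'
#' @param beta beta matrix (samples x probes), typically both timepoints
#'   stacked.
#' @param panel character vector of panel probe ids.
#' @param linkage linkage method for \code{hclust} (default "complete").
#' @param metric distance metric for \code{dist} (default "euclidean").
#' @return integer cluster labels (1/2) named by sample; attribute
#'   \code{panel_used} gives the probes actually used.
#' @export
hclust_classify <- function(beta, panel, linkage = "complete",
                            metric = "euclidean") {
  if (nrow(beta) < 4) stop("need at least 4 samples")
  used <- intersect(panel, colnames(beta))
  if (length(used) < 2)
    stop("fewer than 2 panel probes present in the beta matrix")
  hc <- hclust(dist(beta[, used, drop = FALSE], method = metric),
               method = linkage)
  cl <- cutree(hc, k = 2)
  attr(cl, "panel_used") <- used
  cl
}

#' Orient 2 clusters to pre/post-puberty labels
#'
#' Chooses the cluster-to-status mapping that maximizes balanced accuracy
#' against the known status; exact ties are broken by mapping the cluster
#' with higher mean age (when ages are given) to "post", otherwise cluster 2
#' to "post".
#'
#' @param clusters integer labels (1/2) named by sample.
#' @param truth known status per sample ("pre"/"post"), same order.
#' @param ages optional numeric ages for tie-breaking.
#' @return named character vector, e.g. \code{c("1" = "pre", "2" = "post")}.
#' @export
assign_cluster_labels <- function(clusters, truth, ages = NULL) {
  stopifnot(length(clusters) == length(truth))
  bal_acc <- function(pred) {
    sens <- mean(pred[truth == "post"] == "post")
    spec <- mean(pred[truth == "pre"] == "pre")
    mean(c(sens, spec))
  }
  m1 <- c("1" = "pre", "2" = "post")
  m2 <- c("1" = "post", "2" = "pre")
  a1 <- bal_acc(unname(m1[as.character(clusters)]))
  a2 <- bal_acc(unname(m2[as.character(clusters)]))
  if (a1 > a2) return(m1)
  if (a2 > a1) return(m2)
  if (!is.null(ages)) {
    post_cl <- if (mean(ages[clusters == 2]) >= mean(ages[clusters == 1]))
      "2" else "1"
    return(if (post_cl == "2") m1 else m2)
  }
  m1
}

#' Confusion counts and sensitivity/specificity
#'
#' Positive class is post-puberty by convention: sensitivity = TP/(TP+FN)
#' on post samples, specificity = TN/(TN+FP) on pre samples. Percentages
#' are reported to one decimal. If a class is absent from the truth the
#' corresponding metric is NA.
#'
#' @param predicted,truth status vectors ("pre"/"post") of equal length.
#' @param positive the positive class (default "post").
#' @return list of class \code{classifier_result}: TP, FP, TN, FN,
#'   sensitivity, specificity (percent, one decimal).
#' @export
confusion_metrics <- function(predicted, truth, positive = "post") {
  stopifnot(length(predicted) == length(truth))
  pos <- truth == positive
  tp <- sum(predicted == positive & pos)
  fn <- sum(predicted != positive & pos)
  tn <- sum(predicted != positive & !pos)
  fp <- sum(predicted == positive & !pos)
  sens <- if (tp + fn > 0) round(100 * tp / (tp + fn), 1) else NA_real_
  spec <- if (tn + fp > 0) round(100 * tn / (tn + fp), 1) else NA_real_
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn,
                 sensitivity = sens, specificity = spec),
            class = "classifier_result")
}

#' End-to-end puberty-status classification
#'
#' Clusters samples on the panel, orients the clusters against the known
#' status, and scores the result. Optionally restricts to a sex.
#'
#' @param beta stacked beta matrix (both timepoints).
#' @param panel panel probe ids.
#' @param sheet sample sheet with \code{sample_id}, \code{puberty_status},
#'   \code{age}, \code{sex}.
#' @param sex optional "F" or "M" to restrict the sample set.
#' @param linkage,metric passed to \code{\link{hclust_classify}}.
#' @return \code{classifier_result} with an added \code{predicted} vector
#'   and \code{n_panel_used}.
#' @export
classify_puberty <- function(beta, panel, sheet, sex = NULL,
                             linkage = "complete", metric = "euclidean") {
  sheet <- sheet[match(rownames(beta), sheet$sample_id), , drop = FALSE]
  if (!is.null(sex)) {
    keep <- sheet$sex == sex
    beta <- beta[keep, , drop = FALSE]
    sheet <- sheet[keep, , drop = FALSE]
  }
  cl <- hclust_classify(beta, panel, linkage = linkage, metric = metric)
  mapping <- assign_cluster_labels(cl, sheet$puberty_status, sheet$age)
  pred <- unname(mapping[as.character(cl)])
  res <- confusion_metrics(pred, sheet$puberty_status)
  res$predicted <- setNames(pred, rownames(beta))
  res$n_panel_used <- length(attr(cl, "panel_used"))
  res
}

#' Overlap of a CpG panel with DMP sets
#'
#' @param panel panel probe ids.
#' @param sets named list of probe-id vectors (e.g. output of
#'   \code{\link{classify_dmps}} without the counts element).
#' @return data.frame with set name, overlap count, panel size, and percent
#'   of panel (one decimal).
#' @export
panel_overlap <- function(panel, sets) {
  panel <- unique(panel)
  rows <- lapply(names(sets), function(nm) {
    ov <- length(intersect(panel, sets[[nm]]))
    data.frame(set = nm, overlap = ov, panel_size = length(panel),
               percent = round(100 * ov / length(panel), 1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
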