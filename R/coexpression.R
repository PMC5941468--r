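#' Detect co-expression modules among a gene subset
#'
#' Simplified weighted correlation network stage: adjacency is
#' |Pearson correlation|^power between genes, dissimilarity 1 - adjacency,
#' clustered by average-linkage hierarchical clustering and cut at a static
#' height (default 0.98 of the maximum merge height). Clusters smaller than
#' \code{min_size} are dissolved to label 0 (unassigned). Surviving modules
#' are relabeled 1, 2, ... in decreasing size order.
#'
#' @param expr samples x genes expression matrix (>= 3 samples).
#' @param genes gene subset to analyze (default: all columns).
#' @param power soft-threshold exponent on |correlation| (default 6).
#' @param min_size minimum module size (default 30).
#' @param cut_height static tree-cut height; default 0.98 of the maximum
#'   merge height.
#' @return data.frame of class \code{module_assignment} with columns
#'   \code{gene}, \code{module}; attributes \code{sizes} and
#'   \code{intra_cor} (mean intra-module |correlation| per module).
#' @export
detect_modules <- function(expr, genes = colnames(expr), power = 6,
                           min_size = 30, cut_height = NULL) {
  if (nrow(expr) < 3) stop("need at least 3 samples")
  missing_g <- setdiff(genes, colnames(expr))
  if (length(missing_g))
    stop("genes absent from expression matrix: ",
         paste(head(missing_g, 10), collapse = ", "))
  x <- expr[, genes, drop = FALSE]
  if (length(genes) < min_size) {
    warning("gene subset smaller than min_size; all genes unassigned")
    out <- data.frame(gene = genes, module = 0L, stringsAsFactors = FALSE)
    attr(out, "sizes") <- integer(0)
    attr(out, "intra_cor") <- numeric(0)
    class(out) <- c("module_assignment", "data.frame")
    return(out)
  }
  cc <- cor(x)
  adj <- abs(cc)^power
  diss <- as.dist(1 - adj)
  hc <- hclust(diss, method = "average")
  if (is.null(cut_height)) cut_height <- 0.98 * max(hc$height)
  raw <- cutree(hc, h = cut_height)
  ## dissolve small clusters, relabel by decreasing size
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_size]
  module <- integer(length(raw))
  if (length(keep)) {
    ord <- keep[order(-sizes[keep], as.integer(keep))]
    for (i in seq_along(ord)) module[raw == ord[i]] <- i
  }
  out <- data.frame(gene = genes, module = module, stringsAsFactors = FALSE)
  msz <- table(factor(module[module > 0]))
  intra <- vapply(as.integer(names(msz)), function(m) {
    idx <- which(module == m)
    cm <- abs(cc[idx, idx])
    mean(cm[upper.tri(cm)])
  }, numeric(1))
  attr(out, "sizes") <- as.integer(msz)
  attr(out, "intra_cor") <- intra
  class(out) <- c("module_assignment", "data.frame")
  out
}

#' Gene-set enrichment of each detected module
#'
#' Runs \code{\link{permutation_enrichment}} once per module, with the
#' expressed-gene universe.
#'
#' @param modules a \code{\link{detect_modules}} result.
#' @param er_set a \code{\link{gene_set}}.
#' @param universe expressed gene universe.
#' @param n_perm,mode,seed passed to \code{\link{permutation_enrichment}}.
#' @return named list of \code{enrichment_result}, one per module.
#' @export
module_enrichment <- function(modules, er_set, universe, n_perm = 500000L,
                              mode = c("literal", "universe"), seed = NULL) {
  mode <- match.arg(mode)
  labs <- sort(unique(modules$module[modules$module > 0]))
  out <- list()
  for (m in labs) {
    gs <- modules$gene[modules$module == m]
    out[[paste0("module", m)]] <- permutation_enrichment(
      gs, er_set, universe, n_perm = n_perm, mode = mode,
      seed = if (is.null(seed)) NULL else seed + m)
  }
  out
}
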