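#' Construct a gene set
#'
#' Gene ids are uppercased and deduplicated; matching everywhere in the
#' package is exact string comparison after this normalization.
#'
#' @param name set name.
#' @param genes character vector of member gene ids.
#' @return list of class \code{gene_set} with \code{name} and \code{genes}.
#' @export
gene_set <- function(name, genes) {
  genes <- unique(toupper(as.character(genes)))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0) stop("gene set must be non-empty")
  structure(list(name = name, genes = genes), class = "gene_set")
}

#' Read a gene set from a text file
#'
#' Accepts one-gene-per-line files or single-line GMT records
#' (name, description, members, tab-separated).
#'
#' @param path file path.
#' @param name set name for one-per-line files (defaults to the file name).
#' @return a \code{\link{gene_set}}.
#' @export
read_gene_set <- function(path, name = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 1 && grepl("\t", lines)) {
    parts <- strsplit(lines, "\t")[[1]]
    return(gene_set(parts[1], parts[-(1:2)]))
  }
  gene_set(name %||% basename(path), trimws(lines))
}

#' 2x2 contingency table of an observed gene list against a gene set
#'
#' Rows: observed vs not-observed (within the universe); columns: in-set vs
#' out-of-set. All ids are matched after uppercase normalization.
#'
#' @param observed observed gene list (e.g. genes near DMPs); must lie in
#'   the universe.
#' @param er_set a \code{\link{gene_set}}.
#' @param universe all genes under consideration.
#' @return 2x2 integer matrix with dimnames, plus attributes \code{k_obs},
#'   \code{x_obs}, \code{K}, \code{N}.
#' @export
build_contingency <- function(observed, er_set, universe) {
  observed <- unique(toupper(observed))
  universe <- unique(toupper(universe))
  outside <- setdiff(observed, universe)
  if (length(outside))
    stop("observed genes outside universe: ",
         paste(head(outside, 10), collapse = ", "))
  set_in_univ <- intersect(er_set$genes, universe)
  a <- length(intersect(observed, set_in_univ))
  b <- length(observed) - a
  c_ <- length(set_in_univ) - a
  d <- length(universe) - length(observed) - c_
  tab <- matrix(as.integer(c(a, c_, b, d)), 2,
                dimnames = list(c("observed", "not_observed"),
                                c("in_set", "out_of_set")))
  attr(tab, "k_obs") <- length(observed)
  attr(tab, "x_obs") <- a
  attr(tab, "K") <- length(set_in_univ)
  attr(tab, "N") <- length(universe)
  tab
}

#' Exact hypergeometric upper-tail probability
#'
#' P(X >= x_obs) for X ~ Hypergeometric(N, K, k_obs): drawing \code{k_obs}
#' genes from a universe of \code{N} containing \code{K} set members.
#' Computed in a numerically stable way (log-space pmf accumulation via
#' \code{phyper}).
#'
#' @param x_obs observed overlap.
#' @param K set size in the universe.
#' @param k_obs draw (observed list) size.
#' @param N universe size.
#' @return upper-tail probability.
#' @export
hypergeom_tail <- function(x_obs, K, k_obs, N) {
  if (K > N || k_obs > N || x_obs < 0 || x_obs > min(K, k_obs) + 1)
    stop("inconsistent hypergeometric counts")
  if (x_obs == 0) return(1.0)
  phyper(x_obs - 1, K, N - K, k_obs, lower.tail = FALSE)
}

#' Permutation test for gene-set over-representation
#'
#' Two resampling frames are provided because the underlying procedure is
#' ambiguous between them and they differ drastically in stringency:
#' \describe{
#'   \item{literal}{each iteration draws \code{length(observed)} genes
#'     without replacement \emph{from the set itself} and counts how many
#'     fall in the observed gene list; the tail tallies overlap >= the
#'     observed in-set count \code{x_obs}. This is the frame used for
#'     reproduction of the published bound.}
#'   \item{universe}{each iteration draws \code{length(observed)} genes from
#'     the whole universe and counts set members; its null is exactly
#'     hypergeometric, which \code{\link{hypergeom_tail}} provides as an
#'     oracle.}
#' }
#' The permutation p-value is reported as (r + 1) / (n_perm + 1), where r is
#' the exceedance count, so it is never exactly zero; when r = 0 the
#' conventional bound "< 1/n_perm" is also recorded.
#'
#' @param observed observed gene list.
#' @param er_set a \code{\link{gene_set}}.
#' @param universe gene universe (required in universe mode and for the
#'   bookkeeping table; defaults to observed union set).
#' @param n_perm number of permutations (default 500000).
#' @param mode \code{"literal"} or \code{"universe"}.
#' @param seed RNG seed for reproducibility.
#' @return list of class \code{enrichment_result}: contingency table, counts,
#'   exceedance count \code{r}, \code{p_perm}, \code{p_bound} (string or NA),
#'   exact \code{p_hyper}, Fisher p and odds ratio, mode, n_perm, seed.
#' @export
permutation_enrichment <- function(observed, er_set, universe = NULL,
                                   n_perm = 500000L,
                                   mode = c("literal", "universe"),
                                   seed = NULL) {
  mode <- match.arg(mode)
  if (n_perm < 1) stop("n_perm must be >= 1")
  observed <- unique(toupper(observed))
  if (is.null(universe)) universe <- union(observed, er_set$genes)
  tab <- build_contingency(observed, er_set, universe)
  k_obs <- attr(tab, "k_obs"); x_obs <- attr(tab, "x_obs")
  K <- attr(tab, "K"); N <- attr(tab, "N")
  if (x_obs > k_obs) stop("observed overlap exceeds list size")
  if (!is.null(seed)) set.seed(seed)

  r <- 0L
  if (mode == "literal") {
    if (K < k_obs)
      stop("literal mode requires set size >= draw size (", K, " < ",
           k_obs, ")")
    set_in_univ <- intersect(er_set$genes, toupper(universe))
    in_obs <- as.integer(set_in_univ %in% observed)
    nK <- length(set_in_univ)
    for (i in seq_len(n_perm))
      r <- r + (sum(in_obs[sample.int(nK, k_obs)]) >= x_obs)
  } else {
    in_set <- as.integer(toupper(universe) %in% er_set$genes)
    for (i in seq_len(n_perm))
      r <- r + (sum(in_set[sample.int(N, k_obs)]) >= x_obs)
  }
  p_perm <- (r + 1) / (n_perm + 1)
  p_bound <- if (r == 0L) sprintf("< %.3g", 1 / n_perm) else NA_character_
  ph <- hypergeom_tail(x_obs, K, k_obs, N)
  fe <- fisher_exact(tab, alternative = "greater")
  structure(list(table = tab, k_obs = k_obs, x_obs = x_obs, K = K, N = N,
                 n_perm = as.integer(n_perm), r = r, p_perm = p_perm,
                 p_bound = p_bound, p_hyper = ph,
                 p_fisher = fe$p, odds_ratio = fe$odds_ratio,
                 mode = mode, seed = seed),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Gene-set enrichment (", x$mode, " mode, ", x$n_perm,
      " permutations)\n", sep = "")
  print(matrix(x$table, 2, dimnames = dimnames(x$table)))
  cat(sprintf("overlap %d/%d (%.1f%%), set %d, universe %d\n",
              x$x_obs, x$k_obs, 100 * x$x_obs / x$k_obs, x$K, x$N))
  cat(sprintf("exceedances r = %d; permutation p = %.3g%s\n", x$r, x$p_perm,
              if (!is.na(x$p_bound)) paste0(" (bound ", x$p_bound, ")")
              else ""))
  cat(sprintf("exact hypergeometric tail p = %.3g; Fisher (right) p = %.3g\n",
              x$p_hyper, x$p_fisher))
  invisible(x)
}

#' Fisher's exact test on a 2x2 table
#'
#' Conditional exact test; the right-tailed option mirrors over-representation
#' scoring. With a zero margin the odds ratio is undefined and returned as NA.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @param alternative \code{"two.sided"} or \code{"greater"} (right tail).
#' @return list with \code{odds_ratio} (conditional MLE) and \code{p}.
#' @export
fisher_exact <- function(tab, alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  tab <- matrix(as.numeric(tab), 2)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("cells must be nonnegative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(odds_ratio = NA_real_, p = 1.0))
  ft <- fisher.test(tab, alternative = alternative)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value)
}
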