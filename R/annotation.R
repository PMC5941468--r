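#' Nearest transcription start site for each probe
#'
#' For every probe, finds the gene on the same chromosome whose TSS is
#' closest in absolute genomic distance (strand is ignored for the distance
#' itself). The returned distance is signed relative to the gene's strand:
#' negative means the probe lies upstream of the TSS. Ties at exactly equal
#' distance are broken toward the lexicographically smaller gene id. Probes
#' on chromosomes with no gene get \code{NA} gene and distance.
#'
#' @param chrom,pos probe chromosome and 1-based position vectors (recycled
#'   against each other).
#' @param genes gene model data.frame with columns \code{gene}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand}, \code{tss}.
#' @return data.frame with columns \code{gene} and \code{distance} (signed).
#' @export
nearest_tss <- function(chrom, pos, genes) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  out_gene <- rep(NA_character_, n)
  out_dist <- rep(NA_real_, n)
  for (ch in unique(chrom)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    pi <- which(chrom == ch)
    if (nrow(g) == 0) next
    ## min gene id per unique TSS, sorted by TSS
    g <- g[order(g$tss, g$gene), , drop = FALSE]
    keep <- !duplicated(g$tss)
    tss <- g$tss[keep]; gid <- g$gene[keep]
    idx <- findInterval(pos[pi], tss)
    left <- pmax(idx, 1L)
    right <- pmin(idx + 1L, length(tss))
    dl <- abs(pos[pi] - tss[left])
    dr <- abs(pos[pi] - tss[right])
    dl[idx < 1L] <- Inf
    ## pick side; on exact distance tie, smaller gene id
    use_left <- dl < dr | (dl == dr & gid[left] <= gid[right])
    best <- ifelse(use_left, left, right)
    out_gene[pi] <- gid[best]
    out_dist[pi] <- pos[pi] - tss[best]
  }
  ## sign relative to strand: negative = upstream
  sgn <- ifelse(genes$strand[match(out_gene, genes$gene)] == "-", -1, 1)
  data.frame(gene = out_gene, distance = out_dist * sgn,
             stringsAsFactors = FALSE)
}

#' Genic region category of a probe relative to its nearest gene
#'
#' Simplified 450K-style categories: \code{TSS200} when the probe is at most
#' 200 bp upstream of the TSS, \code{TSS1500} when 201--1500 bp upstream,
#' \code{Body} when inside the gene's [start, end] interval, otherwise
#' \code{Intergenic}. Upstream is strand-aware. Probes without a nearest gene
#' are \code{Intergenic}.
#'
#' @param chrom,pos probe coordinates.
#' @param gene nearest gene id per probe (e.g. from \code{\link{nearest_tss}}).
#' @param genes gene model table (see \code{\link{nearest_tss}}).
#' @return character vector of categories.
#' @export
region_category <- function(chrom, pos, gene, genes) {
  n <- max(length(chrom), length(pos), length(gene))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  gene <- rep_len(gene, n)
  m <- match(gene, genes$gene)
  out <- rep("Intergenic", n)
  ok <- !is.na(m) & chrom == genes$chrom[m]
  d <- ifelse(genes$strand[m] == "-", genes$tss[m] - pos, pos - genes$tss[m])
  upstream <- ok & d < 0
  out[ok & pos >= genes$start[m] & pos <= genes$end[m]] <- "Body"
  out[upstream & -d <= 1500] <- "TSS1500"
  out[upstream & -d <= 200] <- "TSS200"
  out
}

#' Unique genes nearest to a set of DMPs
#'
#' Deduplicated list of nearest genes for the given probes, in order of first
#' appearance. Errors on probes missing from the annotation.
#'
#' @param probes character vector of probe ids (may be empty).
#' @param ann probe annotation with columns \code{probe}, \code{nearest_gene}.
#' @return character vector of unique gene ids (intergenic probes with no
#'   gene are dropped).
#' @export
genes_near_dmps <- function(probes, ann) {
  if (length(probes) == 0) return(character(0))
  m <- match(probes, ann$probe)
  if (anyNA(m))
    stop("unannotated probes: ", paste(probes[is.na(m)], collapse = ", "))
  g <- ann$nearest_gene[m]
  unique(g[!is.na(g)])
}
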