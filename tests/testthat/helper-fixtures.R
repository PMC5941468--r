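# Shared small fixtures, built in code at test time.

small_config <- function(seed = 11, ...) {
  defaults <- list(n_female = 15L, n_male = 12L, n_probes = 600L,
                   n_genes = 300L, n_dmp_female = 30L, n_dmp_male = 10L,
                   n_dmp_shared = 8L, seed = seed,
                   expr_modules = list(list(size = 50, loading = 0.8)))
  override <- list(...)
  defaults[names(override)] <- override
  do.call(sim_config, defaults)
}

# Deterministic tiny gene model for annotation tests.
toy_genes <- function() {
  data.frame(
    gene = c("GA", "GB", "GC"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(1000L, 5000L, 2000L),
    end = c(3000L, 7000L, 4000L),
    strand = c("+", "-", "+"),
    tss = c(1000L, 7000L, 2000L),
    stringsAsFactors = FALSE)
}

# Brute-force nearest-TSS oracle: O(probes x genes) exhaustive search with
# the same tie-break (min |distance|, then min gene id).
brute_nearest <- function(chrom, pos, genes) {
  out <- data.frame(gene = NA_character_, distance = NA_real_)
  out <- out[rep(1, length(chrom)), ]
  for (i in seq_along(chrom)) {
    g <- genes[genes$chrom == chrom[i], , drop = FALSE]
    if (nrow(g) == 0) next
    d <- abs(pos[i] - g$tss)
    cand <- which(d == min(d))
    best <- cand[order(g$gene[cand])][1]
    sgn <- if (g$strand[best] == "-") -1 else 1
    out$gene[i] <- g$gene[best]
    out$distance[i] <- (pos[i] - g$tss[best]) * sgn
  }
  rownames(out) <- NULL
  out
}

random_gene_model <- function(n_genes, n_chrom = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chrom <- sample(paste0("chr", seq_len(n_chrom)), n_genes, replace = TRUE)
  start <- sample.int(1e6, n_genes)
  len <- sample(500:20000, n_genes, replace = TRUE)
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  g <- data.frame(gene = sprintf("G%03d", seq_len(n_genes)), chrom = chrom,
                  start = start, end = start + len, strand = strand,
                  stringsAsFactors = FALSE)
  g$tss <- ifelse(g$strand == "+", g$start, g$end)
  g
}
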