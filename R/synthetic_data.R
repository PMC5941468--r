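#' Configuration for the synthetic cohort generator
#'
#' Builds and validates the parameter set for \code{\link{simulate_cohort}}
#' and friends. Defaults emulate the study design the pipeline targets:
#' 30 girls and 25 boys sampled at two timepoints (ages 8 and 14), 347
#' female-specific, 50 male-specific and 48 shared differentially methylated
#' probes (DMPs), with absolute effect sizes drawn so that the median
#' |delta-beta| is about 0.026 on a 0.016--0.105 range for females, and
#' bimodal background methylation typical of 450K arrays.
#'
#' @param n_female,n_male numbers of paired individuals per sex.
#' @param n_probes,n_genes numbers of CpG probes and genes simulated.
#' @param n_dmp_female,n_dmp_male,n_dmp_shared planted DMP counts per class.
#' @param effect_low,effect_high,effect_median bounds and target median of the
#'   planted |delta-beta| distribution (beta-value scale).
#' @param effect_sdlog log-scale spread of the (truncated log-normal) effect
#'   magnitude distribution.
#' @param frac_hyper_female,frac_hyper_male probability that a planted effect
#'   is a methylation gain (hypermethylation) in each sex-specific class.
#' @param rho_pair within-individual correlation of null-probe methylation
#'   across the two timepoints, in [0, 1). Free parameter (not reported for a
#'   6-year interval in blood); default 0.7.
#' @param logit_sd total per-probe sample-to-sample s.d. on the logit scale;
#'   split between the individual random effect and residual noise by
#'   \code{rho_pair}.
#' @param beta_mix list with elements \code{weight} (probability of the
#'   low-methylation mode) and \code{low}, \code{high} (shape pairs of the two
#'   Beta components giving probe baseline means).
#' @param n_batches,batch_sd number of array batches and the s.d. of the
#'   per-batch, per-probe logit-scale offsets.
#' @param cell_means_pre named means (lymphocyte, monocyte, eosinophil) of the
#'   pre-puberty cell-composition Dirichlet; must sum to 1.
#' @param cell_shift named additive change in mean composition from pre to
#'   post; must sum to 0.
#' @param cell_conc Dirichlet concentration (larger = less variable).
#' @param frac_sex_probes,frac_multimap,frac_snp fractions of probes planted
#'   on sex chromosomes / flagged multi-mapping / flagged SNP-overlapping.
#' @param det_fail_frac fraction of probes planted as detection failures by
#'   \code{\link{simulate_intensities}}.
#' @param det_fail_sample_frac fraction of samples in which a planted
#'   detection-failure probe has detection p > 0.01.
#' @param expr_modules list of co-expression modules to plant, each a list
#'   with \code{size} and \code{loading} (correlation of member genes with
#'   the module's latent factor). Defaults mirror two modules of 198 and 86
#'   genes with loading 0.8.
#' @param frac_cis fraction of genes whose post-puberty expression depends
#'   linearly on methylation at their assigned probe.
#' @param cis_strength standardised slope of the cis methylation effect.
#' @param er_frac fraction of genes carrying predicted high-affinity estrogen
#'   response elements (ER set); default matches 3497/23629.
#' @param seed RNG seed recorded in the config; all \code{simulate_*}
#'   functions reseed from it, making outputs reproducible.
#' @return a validated list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_female = 30L, n_male = 25L,
                       n_probes = 5000L, n_genes = 2000L,
                       n_dmp_female = 347L, n_dmp_male = 50L,
                       n_dmp_shared = 48L,
                       effect_low = 0.016, effect_high = 0.105,
                       effect_median = 0.026, effect_sdlog = 0.55,
                       frac_hyper_female = 0.447, frac_hyper_male = 0.58,
                       rho_pair = 0.7, logit_sd = 0.35,
                       beta_mix = list(weight = 0.5, low = c(2, 18),
                                       high = c(18, 4)),
                       n_batches = 2L, batch_sd = 0.05,
                       cell_means_pre = c(lymphocyte = 0.75,
                                          monocyte = 0.18,
                                          eosinophil = 0.07),
                       cell_shift = c(lymphocyte = -0.05,
                                      monocyte = 0.05,
                                      eosinophil = 0),
                       cell_conc = 200,
                       frac_sex_probes = 0.02, frac_multimap = 0.01,
                       frac_snp = 0.02,
                       det_fail_frac = 0.005, det_fail_sample_frac = 0.9,
                       expr_modules = list(list(size = 198, loading = 0.8),
                                           list(size = 86, loading = 0.8)),
                       frac_cis = 0.05, cis_strength = 0.8,
                       er_frac = 3497 / 23629,
                       seed = NULL) {
  cfg <- list(n_female = as.integer(n_female), n_male = as.integer(n_male),
              n_probes = as.integer(n_probes), n_genes = as.integer(n_genes),
              n_dmp_female = as.integer(n_dmp_female),
              n_dmp_male = as.integer(n_dmp_male),
              n_dmp_shared = as.integer(n_dmp_shared),
              effect_low = effect_low, effect_high = effect_high,
              effect_median = effect_median, effect_sdlog = effect_sdlog,
              frac_hyper_female = frac_hyper_female,
              frac_hyper_male = frac_hyper_male,
              rho_pair = rho_pair, logit_sd = logit_sd,
              beta_mix = beta_mix, n_batches = as.integer(n_batches),
              batch_sd = batch_sd, cell_means_pre = cell_means_pre,
              cell_shift = cell_shift, cell_conc = cell_conc,
              frac_sex_probes = frac_sex_probes,
              frac_multimap = frac_multimap, frac_snp = frac_snp,
              det_fail_frac = det_fail_frac,
              det_fail_sample_frac = det_fail_sample_frac,
              expr_modules = expr_modules, frac_cis = frac_cis,
              cis_strength = cis_strength, er_frac = er_frac, seed = seed)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  n_dmp <- cfg$n_dmp_female + cfg$n_dmp_male + cfg$n_dmp_shared
  if (n_dmp > cfg$n_probes)
    stop("configuration error: planted DMP counts (", n_dmp,
         ") exceed n_probes (", cfg$n_probes, ")")
  if (!(cfg$effect_low <= cfg$effect_median &&
        cfg$effect_median <= cfg$effect_high))
    stop("configuration error: need effect_low <= effect_median <= effect_high")
  if (cfg$rho_pair < 0 || cfg$rho_pair >= 1)
    stop("configuration error: rho_pair must be in [0, 1)")
  if (abs(sum(cfg$cell_means_pre) - 1) > 1e-9)
    stop("configuration error: cell_means_pre must sum to 1")
  if (abs(sum(cfg$cell_shift)) > 1e-9)
    stop("configuration error: cell_shift must sum to 0")
  sizes <- vapply(cfg$expr_modules, function(m) m$size, numeric(1))
  if (length(sizes) && sum(sizes) > cfg$n_genes)
    stop("configuration error: expression modules larger than n_genes")
  invisible(cfg)
}

## |delta-beta| magnitudes: log-normal with median `effect_median`, truncated
## by rejection to [effect_low, effect_high].
sample_effect_sizes <- function(n, cfg) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rlnorm(2L * n, meanlog = log(cfg$effect_median),
                sdlog = cfg$effect_sdlog)
    out <- c(out, x[x >= cfg$effect_low & x <= cfg$effect_high])
  }
  out[seq_len(n)]
}

## Dirichlet rows via normalized gammas.
rdirichlet_rows <- function(n, alpha) {
  x <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  sw <- x / rowSums(x)
  colnames(sw) <- names(alpha)
  sw
}

#' Simulate a paired two-timepoint methylation cohort with ground truth
#'
#' Generates pre- and post-timepoint beta matrices for paired individuals of
#' both sexes, a sample sheet, probe annotation, a synthetic estrogen-response
#' gene set and a truth table recording every planted effect.
#'
#' Probe baseline means come from a 50/50 two-component Beta mixture (one
#' low-, one high-methylation mode) to reproduce 450K bimodality. Pairing is
#' an additive per-individual, per-probe Gaussian random effect on the logit
#' scale whose share of the total variance is \code{rho_pair}. Sex-specific
#' effects are added (on the beta scale, then clamped to [0.001, 0.999]) only
#' to the designated sex's post-timepoint samples; shared effects to both
#' sexes' post samples. Batch offsets are per-batch, per-probe logit-scale
#' shifts; cell compositions are Dirichlet draws whose means move from pre to
#' post by \code{cell_shift}.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with components \code{beta_pre}, \code{beta_post}
#'   (samples x probes), \code{sheet} (sample sheet covering both timepoints),
#'   \code{annotation} (probe annotation), \code{genes} (gene model table),
#'   \code{er_set} (a \code{\link{gene_set}}), and \code{truth} (truth table:
#'   probe, class, signed true delta, assigned gene, ER membership).
#' @export
simulate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  n_ind <- config$n_female + config$n_male
  probes <- sprintf("cg%07d", seq_len(config$n_probes))

  ind <- data.frame(
    individual = c(sprintf("F%03d", seq_len(config$n_female)),
                   sprintf("M%03d", seq_len(config$n_male))),
    sex = rep(c("F", "M"), c(config$n_female, config$n_male)),
    stringsAsFactors = FALSE)
  ## ancestry: 5 non-European individuals (1 + 2 among girls, 2 among boys),
  ## matching the cohort composition the pipeline is designed around
  ind$ancestry <- "European"
  if (config$n_female >= 3)
    ind$ancestry[1:3] <- c("AfricanAmerican", "Hispanic", "Hispanic")
  if (config$n_male >= 2)
    ind$ancestry[config$n_female + 1:2] <- "AfricanAmerican"
  ind$batch <- sprintf("B%d", 1L + (seq_len(n_ind) %% config$n_batches))

  genes <- simulate_gene_model(config)
  ann <- simulate_probe_annotation(config, probes, genes)
  er_genes <- genes$gene[runif(config$n_genes) < config$er_frac]
  er_set <- gene_set("ER_synthetic", er_genes)

  ## truth: assign effect classes to clean autosomal probes
  clean <- which(!ann$sex_chromosome & !ann$multi_map & !ann$snp_overlap)
  n_dmp <- config$n_dmp_female + config$n_dmp_male + config$n_dmp_shared
  if (n_dmp > length(clean))
    stop("configuration error: not enough clean probes to plant DMPs")
  dmp_idx <- sample(clean, n_dmp)
  cls <- rep("null", config$n_probes)
  cls[dmp_idx] <- rep(c("female_specific", "male_specific", "shared"),
                      c(config$n_dmp_female, config$n_dmp_male,
                        config$n_dmp_shared))
  true_delta <- numeric(config$n_probes)
  if (n_dmp > 0) {
    mag <- sample_effect_sizes(n_dmp, config)
    p_hyper <- rep(c(config$frac_hyper_female, config$frac_hyper_male, 0.5),
                   c(config$n_dmp_female, config$n_dmp_male,
                     config$n_dmp_shared))
    sgn <- ifelse(runif(n_dmp) < p_hyper, 1, -1)
    true_delta[dmp_idx] <- sgn * mag
  }
  truth <- data.frame(probe = probes, class = cls, true_delta = true_delta,
                      gene = ann$nearest_gene,
                      in_er_set = toupper(ann$nearest_gene) %in% er_set$genes,
                      stringsAsFactors = FALSE)

  ## baseline probe means from the bimodal mixture, kept away from 0/1
  bm <- config$beta_mix
  low <- runif(config$n_probes) < bm$weight
  mu <- ifelse(low, rbeta(config$n_probes, bm$low[1], bm$low[2]),
               rbeta(config$n_probes, bm$high[1], bm$high[2]))
  mu <- clamp(mu, 0.02, 0.98)
  lmu <- qlogis(mu)

  tau <- config$logit_sd * sqrt(config$rho_pair)        # individual effect
  sig <- config$logit_sd * sqrt(1 - config$rho_pair)    # residual

  u <- matrix(rnorm(n_ind * config$n_probes, sd = tau), n_ind)
  batch_eff <- matrix(rnorm(config$n_batches * config$n_probes,
                            sd = config$batch_sd), config$n_batches)
  rownames(batch_eff) <- sprintf("B%d", seq_len(config$n_batches))

  make_tp <- function() {
    e <- matrix(rnorm(n_ind * config$n_probes, sd = sig), n_ind)
    lin <- sweep(u + e, 2, lmu, `+`) + batch_eff[ind$batch, , drop = FALSE]
    plogis(lin)
  }
  beta_pre <- make_tp()
  beta_post <- make_tp()

  ## plant effects on the beta scale, post timepoint only
  for (j in dmp_idx) {
    rows <- switch(cls[j],
                   female_specific = ind$sex == "F",
                   male_specific = ind$sex == "M",
                   shared = rep(TRUE, n_ind))
    beta_post[rows, j] <- beta_post[rows, j] + true_delta[j]
  }
  beta_pre <- clamp(beta_pre, 0.001, 0.999)
  beta_post <- clamp(beta_post, 0.001, 0.999)
  dimnames(beta_pre) <- dimnames(beta_post) <- NULL

  pre_ids <- paste0(ind$individual, "_pre")
  post_ids <- paste0(ind$individual, "_post")
  rownames(beta_pre) <- pre_ids
  rownames(beta_post) <- post_ids
  colnames(beta_pre) <- colnames(beta_post) <- probes

  cells_pre <- rdirichlet_rows(n_ind, config$cell_conc * config$cell_means_pre)
  mean_post <- config$cell_means_pre + config$cell_shift
  cells_post <- rdirichlet_rows(n_ind, config$cell_conc * mean_post)

  sheet <- data.frame(
    sample_id = c(pre_ids, post_ids),
    individual = rep(ind$individual, 2),
    sex = rep(ind$sex, 2),
    timepoint = rep(c("pre", "post"), each = n_ind),
    age = rep(c(8, 14), each = n_ind) + round(runif(2 * n_ind, -0.5, 0.5), 1),
    batch = rep(ind$batch, 2),
    lymphocyte = c(cells_pre[, "lymphocyte"], cells_post[, "lymphocyte"]),
    monocyte = c(cells_pre[, "monocyte"], cells_post[, "monocyte"]),
    eosinophil = c(cells_pre[, "eosinophil"], cells_post[, "eosinophil"]),
    ancestry = rep(ind$ancestry, 2),
    puberty_status = rep(c("pre", "post"), each = n_ind),
    stringsAsFactors = FALSE)

  list(beta_pre = beta_pre, beta_post = beta_post, sheet = sheet,
       annotation = ann, genes = genes, er_set = er_set, truth = truth,
       config = config)
}

## Gene model on 22 autosomes: uniform TSS placement, random strand,
## gamma-distributed gene lengths (median ~20 kb).
simulate_gene_model <- function(config) {
  n <- config$n_genes
  chrom <- sample(paste0("chr", 1:22), n, replace = TRUE,
                  prob = 23 - (1:22))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  len <- pmax(200L, as.integer(rgamma(n, shape = 2, scale = 12000)))
  start <- as.integer(runif(n, 1e4, 2e8))
  g <- data.frame(gene = sprintf("GENE%05d", seq_len(n)), chrom = chrom,
                  start = start, end = start + len, strand = strand,
                  stringsAsFactors = FALSE)
  g$tss <- ifelse(g$strand == "+", g$start, g$end)
  g
}

## Probes placed relative to genes: promoter-proximal, genic, or far
## intergenic; a small fraction parked on chrX/chrY or flagged.
simulate_probe_annotation <- function(config, probes, genes) {
  n <- config$n_probes
  host <- sample(nrow(genes), n, replace = TRUE)
  zone <- sample(c("tss", "body", "far"), n, replace = TRUE,
                 prob = c(0.35, 0.40, 0.25))
  off_tss <- -as.integer(runif(n, 1, 1500))
  dirsgn <- ifelse(genes$strand[host] == "+", 1L, -1L)
  pos <- integer(n)
  pos[zone == "tss"] <- genes$tss[host[zone == "tss"]] +
    dirsgn[zone == "tss"] * off_tss[zone == "tss"]
  frac <- runif(n)
  pos[zone == "body"] <- as.integer(
    genes$start[host[zone == "body"]] +
      frac[zone == "body"] * (genes$end[host[zone == "body"]] -
                              genes$start[host[zone == "body"]]))
  pos[zone == "far"] <- genes$tss[host[zone == "far"]] +
    as.integer(sample(c(-1, 1), sum(zone == "far"), TRUE) *
               runif(sum(zone == "far"), 2e4, 2e5))
  pos <- pmax(pos, 1L)
  chrom <- genes$chrom[host]

  n_sex <- round(config$frac_sex_probes * n)
  sex_idx <- sample(n, n_sex)
  chrom[sex_idx] <- sample(c("chrX", "chrY"), n_sex, replace = TRUE,
                           prob = c(0.8, 0.2))
  ann <- data.frame(probe = probes, chrom = chrom, pos = pos,
                    multi_map = runif(n) < config$frac_multimap,
                    snp_overlap = runif(n) < config$frac_snp,
                    stringsAsFactors = FALSE)
  ann$sex_chromosome <- ann$chrom %in% c("chrX", "chrY")
  ## nearest-gene truth by exhaustive search per chromosome
  nt <- nearest_tss(ann$chrom, ann$pos, genes)
  ann$nearest_gene <- nt$gene
  ann$tss_distance <- nt$distance
  ann$region <- region_category(ann$chrom, ann$pos, nt$gene, genes)
  ann
}

#' Simulate raw methylated/unmethylated intensities with detection p-values
#'
#' Produces single-timepoint intensity matrices whose implied beta values
#' (\code{M / (M + U)}) equal an internally generated bimodal beta matrix to
#' machine precision, plus a detection p-value matrix in which a configurable
#' fraction of probes fails (p > 0.01) in a configurable fraction of samples.
#'
#' @param config a \code{\link{sim_config}}; uses \code{det_fail_frac} and
#'   \code{det_fail_sample_frac}.
#' @return list with \code{meth}, \code{unmeth}, \code{detp} (samples x
#'   probes), \code{beta} (the generating beta matrix), \code{sheet}, and
#'   \code{failed_probes} (ids of the planted detection failures).
#' @export
simulate_intensities <- function(config = sim_config()) {
  validate_sim_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  n_ind <- config$n_female + config$n_male
  probes <- sprintf("cg%07d", seq_len(config$n_probes))
  samples <- sprintf("S%03d", seq_len(n_ind))

  bm <- config$beta_mix
  low <- runif(config$n_probes) < bm$weight
  mu <- ifelse(low, rbeta(config$n_probes, bm$low[1], bm$low[2]),
               rbeta(config$n_probes, bm$high[1], bm$high[2]))
  lin <- sweep(matrix(rnorm(n_ind * config$n_probes, sd = config$logit_sd),
                      n_ind), 2, qlogis(clamp(mu, 0.02, 0.98)), `+`)
  beta <- plogis(lin)
  total <- matrix(rlnorm(n_ind * config$n_probes, log(5000), 0.3), n_ind)
  meth <- beta * total
  unmeth <- total - meth

  detp <- matrix(runif(n_ind * config$n_probes, 0, 0.009), n_ind)
  n_fail <- round(config$det_fail_frac * config$n_probes)
  failed <- sample(config$n_probes, n_fail)
  for (j in failed) {
    rows <- sample(n_ind, ceiling(config$det_fail_sample_frac * n_ind))
    detp[rows, j] <- runif(length(rows), 0.011, 1)
  }
  dimnames(meth) <- dimnames(unmeth) <- dimnames(detp) <-
    dimnames(beta) <- list(samples, probes)

  sheet <- data.frame(sample_id = samples,
                      individual = samples,
                      sex = rep(c("F", "M"), c(config$n_female, config$n_male)),
                      timepoint = "pre", stringsAsFactors = FALSE)
  list(meth = meth, unmeth = unmeth, detp = detp, beta = beta, sheet = sheet,
       failed_probes = probes[failed])
}

#' Simulate post-puberty expression with planted module structure
#'
#' Expression for the post-timepoint samples of a simulated cohort. Genes in
#' a planted module load on a shared standard-normal latent factor with the
#' configured loading; a \code{frac_cis} subset of genes additionally depends
#' linearly on methylation at the probe assigned to the gene (requires
#' \code{beta_post}).
#'
#' @param sheet sample sheet from \code{\link{simulate_cohort}} (post rows
#'   are used).
#' @param truth truth table from \code{\link{simulate_cohort}} (probe-to-gene
#'   assignment for cis effects).
#' @param config a \code{\link{sim_config}}.
#' @param beta_post post-timepoint beta matrix; required when
#'   \code{frac_cis > 0}.
#' @return samples x genes matrix with attributes \code{module} (planted
#'   module label per gene, 0 = none) and \code{cis_genes} (genes with a
#'   planted methylation dependence).
#' @export
simulate_expression <- function(sheet, truth, config = sim_config(),
                                beta_post = NULL) {
  validate_sim_config(config)
  post <- sheet[sheet$timepoint == "post", , drop = FALSE]
  if (nrow(post) == 0) stop("sheet contains no post-timepoint samples")
  if (!is.null(config$seed)) set.seed(config$seed + 1L)
  n_s <- nrow(post)
  genes <- sprintf("GENE%05d", seq_len(config$n_genes))

  module <- integer(config$n_genes)
  nxt <- 1L
  for (m in seq_along(config$expr_modules)) {
    sz <- config$expr_modules[[m]]$size
    module[nxt:(nxt + sz - 1L)] <- m
    nxt <- nxt + sz
  }

  expr <- matrix(rnorm(n_s * config$n_genes), n_s)
  for (m in seq_along(config$expr_modules)) {
    lam <- config$expr_modules[[m]]$loading
    f <- rnorm(n_s)
    idx <- which(module == m)
    expr[, idx] <- lam * f + sqrt(1 - lam^2) * expr[, idx]
  }

  cis_genes <- character(0)
  if (config$frac_cis > 0) {
    if (is.null(beta_post))
      stop("beta_post is required when frac_cis > 0")
    assigned <- truth[!is.na(truth$gene) & truth$gene %in% genes, ]
    ## one probe per gene (first assignment wins)
    assigned <- assigned[!duplicated(assigned$gene), ]
    n_cis <- min(round(config$frac_cis * config$n_genes), nrow(assigned))
    pick <- assigned[sample(nrow(assigned), n_cis), ]
    for (i in seq_len(nrow(pick))) {
      g <- match(pick$gene[i], genes)
      b <- beta_post[post$sample_id, pick$probe[i]]
      bs <- if (sd(b) > 0) (b - mean(b)) / sd(b) else b * 0
      expr[, g] <- config$cis_strength * bs +
        sqrt(max(0, 1 - config$cis_strength^2)) * expr[, g]
    }
    cis_genes <- pick$gene
  }
  dimnames(expr) <- list(post$sample_id, genes)
  attr(expr, "module") <- setNames(module, genes)
  attr(expr, "cis_genes") <- cis_genes
  expr
}
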