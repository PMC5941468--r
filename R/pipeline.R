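#' Pipeline configuration
#'
#' Collects all stage parameters and the global seed. The simulation
#' sub-config inherits the global seed unless it carries its own.
#'
#' @param seed global RNG seed; recorded in every output manifest.
#' @param sim a \code{\link{sim_config}} for the synthetic cohort.
#' @param fdr_level FDR level for DMP calling (default 0.05).
#' @param fdr_level_network FDR level used to widen the gene list for module
#'   detection (default 0.10).
#' @param n_perm permutations for enrichment stages. The pipeline default is
#'   deliberately scaled down from the 500,000 used for the published bound;
#'   raise it for reproduction runs.
#' @param enrich_mode "literal" or "universe".
#' @param adjust_mode batch adjustment mode (see \code{\link{adjust_batch}}).
#' @param power,min_size module detection parameters.
#' @param linkage,metric classifier parameters.
#' @param stages character vector of stages to run (subset of the default).
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(seed = 1L, sim = NULL, fdr_level = 0.05,
                            fdr_level_network = 0.10, n_perm = 2000L,
                            enrich_mode = "literal",
                            adjust_mode = "meancenter",
                            power = 6, min_size = 30,
                            linkage = "complete", metric = "euclidean",
                            stages = c("simulate", "filter", "adjust",
                                       "screen", "dmp", "enrich",
                                       "coexpress", "classify",
                                       "confounds")) {
  if (is.null(sim)) sim <- sim_config(seed = seed)
  if (is.null(sim$seed)) sim$seed <- seed
  structure(list(seed = as.integer(seed), sim = sim, fdr_level = fdr_level,
                 fdr_level_network = fdr_level_network,
                 n_perm = as.integer(n_perm), enrich_mode = enrich_mode,
                 adjust_mode = adjust_mode, power = power,
                 min_size = min_size, linkage = linkage, metric = metric,
                 stages = stages),
            class = "pipeline_config")
}

run_stage <- function(name, log_con, expr) {
  msg <- sprintf("[%s] stage %s", format(Sys.time(), "%H:%M:%S"), name)
  if (!is.null(log_con)) writeLines(msg, log_con)
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes the stages in dependency order on data from
#' \code{\link{simulate_cohort}}, writes delimited tables, a JSON report and
#' a log to \code{outdir} (when given), and returns the report. The report
#' contains a contingency block shaped like the published 2x2 gene-set
#' table, a classifier block with sensitivity/specificity, the DMP summary
#' block, and DMP recovery statistics against the simulation truth.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param outdir output directory, or \code{NULL} to skip writing files.
#' @return the report, invisibly a list; stage outputs under
#'   \code{$stages}.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  set.seed(config$seed)
  log_con <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    log_con <- file(file.path(outdir, "pipeline.log"), open = "wt")
    on.exit(close(log_con), add = TRUE)
    write_manifest(config, file.path(outdir, "manifest.json"),
                   seed = config$seed)
  }
  st <- list()

  cohort <- run_stage("simulate", log_con, simulate_cohort(config$sim))
  st$cohort <- cohort

  beta_all <- rbind(cohort$beta_pre, cohort$beta_post)
  detp <- matrix(runif(length(beta_all), 0, 0.009), nrow(beta_all),
                 dimnames = dimnames(beta_all))
  report <- run_stage("filter", log_con, {
    filter_probes(beta_all, detp, cohort$annotation)
  })
  st$filter <- report
  beta_all <- apply_filter(beta_all, report)

  if ("adjust" %in% config$stages && config$sim$n_batches >= 2) {
    batch <- cohort$sheet$batch[match(rownames(beta_all),
                                      cohort$sheet$sample_id)]
    beta_all <- run_stage("adjust", log_con,
                          adjust_batch(beta_all, batch,
                                       mode = config$adjust_mode))
    beta_all <- clamp(beta_all, 0, 1)
  }
  if ("screen" %in% config$stages) {
    st$pca <- run_stage("screen", log_con,
                        pca_screen(beta_all, cohort$sheet,
                                   covariates = c("batch", "sex",
                                                  "timepoint")))
  }

  pre <- beta_all[cohort$sheet$sample_id[cohort$sheet$timepoint == "pre"], ,
                  drop = FALSE]
  post <- beta_all[cohort$sheet$sample_id[cohort$sheet$timepoint == "post"], ,
                   drop = FALSE]
  dmp <- run_stage("dmp", log_con, {
    delta <- paired_delta(pre, post, cohort$sheet)
    sex <- attr(delta, "sex")
    delta_f <- delta[sex == "F", , drop = FALSE]
    delta_m <- delta[sex == "M", , drop = FALSE]
    res_f <- moderated_paired_test(delta_f, group = "female")
    res_m <- moderated_paired_test(delta_m, group = "male")
    res_c <- moderated_paired_test(delta, group = "combined")
    res_i <- interaction_test(delta_f, delta_m)
    sets <- classify_dmps(res_f, res_m, res_c, config$fdr_level)
    sets10 <- classify_dmps(res_f, res_m, res_c, 0.10)
    list(delta = delta, delta_f = delta_f, delta_m = delta_m,
         female = res_f, male = res_m, combined = res_c,
         interaction = res_i, sets = sets, sets10 = sets10)
  })
  st$dmp <- dmp

  summaries <- list(
    female_specific = summarize_dmps(dmp$sets$female_specific, dmp$delta_f,
                                     cohort$annotation),
    male_specific = summarize_dmps(dmp$sets$male_specific, dmp$delta_m,
                                   cohort$annotation),
    shared = summarize_dmps(dmp$sets$shared, dmp$delta, cohort$annotation))

  enrich <- NULL
  if ("enrich" %in% config$stages) {
    enrich <- run_stage("enrich", log_con, {
      obs <- genes_near_dmps(dmp$sets$female_specific, cohort$annotation)
      if (length(obs) >= 2 &&
          length(intersect(toupper(obs), cohort$er_set$genes)) >= 1 &&
          (config$enrich_mode != "literal" ||
           length(cohort$er_set$genes) >= length(obs))) {
        permutation_enrichment(obs, cohort$er_set, cohort$genes$gene,
                               n_perm = config$n_perm,
                               mode = config$enrich_mode,
                               seed = config$seed)
      } else NULL
    })
  }
  st$enrich <- enrich

  coexp <- NULL
  if ("coexpress" %in% config$stages) {
    coexp <- run_stage("coexpress", log_con, {
      expr <- simulate_expression(cohort$sheet, cohort$truth, config$sim,
                                  beta_post = cohort$beta_post)
      subset_genes <- intersect(
        genes_near_dmps(dmp$sets10$female_specific, cohort$annotation),
        colnames(expr))
      mods <- if (length(subset_genes) >= 3)
        suppressWarnings(detect_modules(expr, subset_genes,
                                        power = config$power,
                                        min_size = config$min_size))
      else NULL
      list(expr = expr, modules = mods)
    })
  }
  st$coexpress <- coexp

  classifier <- NULL
  if ("classify" %in% config$stages) {
    classifier <- run_stage("classify", log_con, {
      panel <- cohort$truth$probe[cohort$truth$class == "shared"]
      panel <- intersect(panel, colnames(beta_all))
      if (length(panel) >= 2)
        classify_puberty(beta_all, panel, cohort$sheet,
                         linkage = config$linkage, metric = config$metric)
      else NULL
    })
  }
  st$classifier <- classifier

  confounds <- NULL
  if ("confounds" %in% config$stages) {
    confounds <- run_stage("confounds", log_con, {
      cells <- do.call(rbind, lapply(c("lymphocyte", "monocyte",
                                       "eosinophil"),
                                     function(ct)
                                       paired_cell_test(cohort$sheet, ct)))
      noneuro <- unique(cohort$sheet$individual[
        cohort$sheet$ancestry != "European"])
      dmp_probes <- unique(unlist(dmp$sets[c("female_specific",
                                             "male_specific", "shared")]))
      sens <- if (length(dmp_probes) >= 2 && length(noneuro) > 0)
        subset_sensitivity(dmp$delta, noneuro, dmp_probes) else NULL
      cis <- if (!is.null(coexp) && length(dmp$sets$female_specific) > 0)
        cis_correlation(post, coexp$expr, cohort$annotation,
                        dmp$sets$female_specific) else NULL
      list(cell_tests = cells, ancestry_sensitivity = sens, cis = cis)
    })
  }
  st$confounds <- confounds

  ## recovery against simulation truth at the |delta beta| >= 0.05 level:
  ## precision over called probes whose estimated effect reaches 0.05 in
  ## any analysis, recall over truths planted at >= 0.05
  truth <- cohort$truth
  big <- truth$probe[truth$class != "null" & abs(truth$true_delta) >= 0.05]
  called <- unique(unlist(dmp$sets[c("female_specific", "male_specific",
                                     "shared")]))
  est_eff <- pmax(abs(colMeans(dmp$delta_f)), abs(colMeans(dmp$delta_m)),
                  abs(colMeans(dmp$delta)))
  called_large <- called[est_eff[called] >= 0.05]
  true_dmps <- truth$probe[truth$class != "null"]
  recovery <- list(
    n_called = length(called),
    n_called_large = length(called_large),
    precision = if (length(called_large))
      mean(called_large %in% true_dmps) else NA_real_,
    recall_large = if (length(big))
      mean(big %in% called) else NA_real_)

  report <- list(
    seed = config$seed,
    filter_counts = as.list(attr(st$filter, "counts")),
    dmp_counts = as.list(dmp$sets$counts),
    dmp_summary = summaries,
    contingency = if (!is.null(enrich)) list(
      table = as.vector(enrich$table), k_obs = enrich$k_obs,
      x_obs = enrich$x_obs, pct_in_set =
        round(100 * enrich$x_obs / enrich$k_obs, 1),
      K = enrich$K, N = enrich$N, r = enrich$r, p_perm = enrich$p_perm,
      p_bound = enrich$p_bound, p_hyper = enrich$p_hyper,
      mode = enrich$mode) else NULL,
    classifier = if (!is.null(classifier)) list(
      TP = classifier$TP, FP = classifier$FP, TN = classifier$TN,
      FN = classifier$FN, sensitivity = classifier$sensitivity,
      specificity = classifier$specificity,
      n_panel_used = classifier$n_panel_used) else NULL,
    cell_tests = if (!is.null(confounds)) confounds$cell_tests else NULL,
    ancestry_sensitivity = if (!is.null(confounds) &&
                               !is.null(confounds$ancestry_sensitivity))
      confounds$ancestry_sensitivity[c("r", "n_full", "n_subset")]
    else NULL,
    recovery = recovery)

  if (!is.null(outdir)) {
    write_matrix(cohort$beta_pre, file.path(outdir, "beta_pre.tsv"))
    write_matrix(cohort$beta_post, file.path(outdir, "beta_post.tsv"))
    write_sample_sheet(cohort$sheet, file.path(outdir, "sample_sheet.tsv"))
    write.table(cohort$annotation, file.path(outdir, "probe_annotation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(cohort$truth, file.path(outdir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_gene_set(cohort$er_set, file.path(outdir, "er_set.txt"))
    for (g in c("female", "male", "combined", "interaction"))
      write.table(dmp[[g]], file.path(outdir, paste0("dmp_", g, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
  }
  out <- c(report, list(stages = st))
  invisible(out)
}
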