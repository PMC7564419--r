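#' Pipeline configuration
#'
#' One configuration object drives the full synthetic analysis: cohort
#' generation for a discovery cohort (with copy number) and an
#' expression-only replication cohort, a normal-tissue panel, per-gene
#' screens, cross-cohort replication with its overlap FDR, the
#' triple-significance signature, fold change versus normal, and the
#' four-criterion funnel. All randomness flows from the single top-level
#' \code{seed} through fixed per-stage substreams, so identical
#' configurations give identical reports and any stage can be re-run in
#' isolation.
#'
#' @param synthetic A [synthetic_config()] describing the discovery cohort;
#'   the replication cohort reuses its planted genes.
#' @param alpha Significance level for every screen.
#' @param adjust Clinical adjustment covariates for the survival screens.
#' @param prevalence_threshold Funnel prevalence threshold.
#' @param flags Curated actionability flags (see [apply_funnel()]); NULL
#'   marks the planted genes fully actionable and all others not, a
#'   convenient default for simulation studies.
#' @param n_normal Normal-panel size.
#' @param seed Top-level integer seed.
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            alpha = 0.05,
                            adjust = c("race", "metastasis_at_diagnosis"),
                            prevalence_threshold = 0.3,
                            flags = NULL,
                            n_normal = 10,
                            seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, n_normal >= 2)
  structure(list(synthetic = synthetic, alpha = alpha, adjust = adjust,
                 prevalence_threshold = prevalence_threshold,
                 flags = flags, n_normal = n_normal, seed = as.integer(seed)),
            class = "pipeline_config")
}

# fixed substream offsets keep stage seeds < 2^31 and non-colliding
stage_seed <- function(seed, stage) {
  offsets <- c(discovery = 11L, replication = 211L, normal = 3011L)
  (seed * 7919L + offsets[[stage]]) %% 2147483647L
}

#' Run the full synthetic discovery pipeline
#'
#' Executes simulate -> screen (expression and CNV vs survival, expression vs
#' CNV) -> replicate -> integrate -> enrich -> funnel on synthetic cohorts
#' and returns a machine-readable report. The same config yields a
#' byte-identical report.
#'
#' @param config A [pipeline_config()].
#' @return List of class \code{pipeline_report}: per-stage counts, the three
#'   association tables, the replicated overlap and its estimated FDR, the
#'   signature table, the chromosome-free enrichment input (per-gene table),
#'   funnel ranking, fold changes versus the normal panel, and the truth
#'   ledger of the discovery cohort.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  syn <- config$synthetic
  syn$seed <- stage_seed(config$seed, "discovery")
  discovery <- generate_cohort(syn)

  syn_rep <- syn
  syn_rep$seed <- stage_seed(config$seed, "replication")
  replication <- generate_cohort(syn_rep)

  normal <- generate_normal_panel(
    config$n_normal,
    gene_means = discovery$truth$baseline_expression,
    noise_sd = syn$expression_noise_sd,
    seed = stage_seed(config$seed, "normal"))

  ge_surv <- genewise_screen(discovery$expression, discovery$clinical,
                             adjust = config$adjust, alpha = config$alpha,
                             kind = "GE~survival")
  ge_surv_rep <- genewise_screen(replication$expression, replication$clinical,
                                 adjust = config$adjust, alpha = config$alpha,
                                 kind = "GE~survival")
  cnv_surv <- genewise_screen(discovery$cnv_categorical, discovery$clinical,
                              adjust = config$adjust, alpha = config$alpha,
                              kind = "CNV~survival")
  ge_cnv <- correlate_ge_cnv(discovery$expression, discovery$cnv_continuous)

  replicated <- replicated_overlap(ge_surv, ge_surv_rep, config$alpha)
  n_common <- length(intersect(ge_surv$gene, ge_surv_rep$gene))
  replicated_fdr <- if (length(replicated) >= 1) {
    overlap_fdr(n_common, c(config$alpha, config$alpha),
                direction_levels = 2, observed_overlap = length(replicated))
  } else {
    NA_real_
  }

  signature <- triple_signature(ge_surv, cnv_surv, ge_cnv, config$alpha)
  signature_fdr <- if (sum(signature$coherent) >= 1) {
    overlap_fdr(n_common, rep(config$alpha, 3), direction_levels = 4,
                observed_overlap = sum(signature$coherent))
  } else {
    NA_real_
  }

  fc <- fold_change_vs_normal(discovery$expression, normal)

  prevalence <- vapply(signature$gene, function(g) {
    risk_cat <- if (signature$class[match(g, signature$gene)] ==
                    "deletion_down") -1 else 1
    risk_prevalence(discovery$cnv_categorical, g, risk_cat)
  }, numeric(1))

  flags <- config$flags
  if (is.null(flags)) {
    planted <- syn$planted_genes$symbol
    flags <- data.frame(gene = rownames(discovery$expression),
                        stringsAsFactors = FALSE)
    flags$targetable_network <- flags$gene %in% planted
    flags$inhibitor_available <- flags$gene %in% planted
    flags$model_available <- flags$gene %in% planted
  }
  funnel <- apply_funnel(signature, flags, prevalence,
                         config$prevalence_threshold)

  report <- list(
    config = config,
    counts = list(
      n_patients = nrow(discovery$clinical),
      n_genes = nrow(discovery$expression),
      ge_surv_significant = sum(ge_surv$significant),
      ge_surv_rep_significant = sum(ge_surv_rep$significant),
      cnv_surv_significant = sum(cnv_surv$significant),
      cnv_surv_inestimable = sum(!cnv_surv$converged),
      replicated = length(replicated),
      signature = sum(signature$coherent),
      funnel = nrow(funnel)),
    ge_surv = ge_surv, ge_surv_rep = ge_surv_rep,
    cnv_surv = cnv_surv, ge_cnv = ge_cnv,
    replicated_genes = replicated,
    replicated_fdr = replicated_fdr,
    signature = signature,
    signature_fdr = signature_fdr,
    fold_change = fc,
    prevalence = prevalence,
    funnel = funnel,
    truth = discovery$truth)
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Integrative CNV-expression-survival pipeline report\n")
  cat(sprintf("  cohort: %d patients x %d genes\n",
              x$counts$n_patients, x$counts$n_genes))
  cat(sprintf("  GE~survival significant: %d (replication cohort: %d)\n",
              x$counts$ge_surv_significant, x$counts$ge_surv_rep_significant))
  cat(sprintf("  CNV~survival significant: %d\n",
              x$counts$cnv_surv_significant))
  cat(sprintf("  replicated overlap: %d genes (est. FDR %.3f)\n",
              x$counts$replicated,
              ifelse(is.na(x$replicated_fdr), NaN, x$replicated_fdr)))
  cat(sprintf("  triple signature: %d genes (est. FDR %.4f)\n",
              x$counts$signature,
              ifelse(is.na(x$signature_fdr), NaN, x$signature_fdr)))
  cat(sprintf("  funnel candidates: %d\n", x$counts$funnel))
  if (nrow(x$funnel) > 0) {
    print(x$funnel[, c("gene", "class", "prevalence", "cnv_surv_p")])
  }
  invisible(x)
}

#' Write the stage tables of a pipeline report to disk
#'
#' Emits the association tables, signature, fold-change and funnel tables as
#' TSV plus a JSON summary, sufficient to re-run any downstream stage in
#' isolation.
#'
#' @param report A \code{pipeline_report}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_pipeline_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(tab, name) {
    utils::write.table(as.data.frame(tab), file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(report$ge_surv, "ge_survival.tsv")
  wt(report$ge_surv_rep, "ge_survival_replication.tsv")
  wt(report$cnv_surv, "cnv_survival.tsv")
  wt(report$ge_cnv, "ge_cnv.tsv")
  wt(report$signature, "signature.tsv")
  wt(report$fold_change, "fold_change.tsv")
  wt(report$funnel, "funnel.tsv")
  summary <- c(report$counts,
               list(replicated_fdr = report$replicated_fdr,
                    signature_fdr = report$signature_fdr,
                    replicated_genes = report$replicated_genes,
                    schema_version = "1.0"))
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
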