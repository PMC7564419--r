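#' Per-gene regression of expression on copy number
#'
#' For each gene shared by the two matrices, fits a simple linear regression
#' of expression on continuous copy number across the shared samples and
#' reports the slope, its standard error and the two-sided p-value. Genes
#' whose copy number has zero variance are flagged inestimable.
#'
#' @param expression Genes x samples log-scale expression matrix.
#' @param cnv_continuous Genes x samples continuous copy-number matrix.
#' @return An \code{association_table} with kind \code{"GE~CNV"}; \code{beta}
#'   is the regression slope and \code{hazard_ratio} is NA.
#' @export
correlate_ge_cnv <- function(expression, cnv_continuous) {
  genes <- intersect(rownames(expression), rownames(cnv_continuous))
  samples <- intersect(colnames(expression), colnames(cnv_continuous))
  if (length(samples) < 3) stop("need at least 3 shared samples")
  e <- expression[genes, samples, drop = FALSE]
  cn <- cnv_continuous[genes, samples, drop = FALSE]
  n <- length(samples)
  # closed-form per-gene OLS, vectorized over genes
  mx <- rowMeans(cn); my <- rowMeans(e)
  sxx <- rowSums((cn - mx)^2)
  sxy <- rowSums((cn - mx) * (e - my))
  ok <- sxx > 0
  slope <- ifelse(ok, sxy / sxx, NA_real_)
  resid_ss <- rowSums((e - my - slope * (cn - mx))^2)
  se <- ifelse(ok, sqrt(resid_ss / (n - 2) / sxx), NA_real_)
  tstat <- slope / se
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  tab <- data.frame(gene = genes, beta = slope, hazard_ratio = NA_real_,
                    se = se, p_value = p,
                    direction = sign(slope),
                    converged = ok, n_used = n, n_events = NA_integer_,
                    kind = "GE~CNV", significant = NA,
                    stringsAsFactors = FALSE)
  class(tab) <- c("association_table", "data.frame")
  rownames(tab) <- NULL
  tab
}

#' Direction-consistent overlap of two association tables
#'
#' Genes significant (p < alpha, converged) in both tables with the same
#' direction of association.
#'
#' @param table_a,table_b \code{association_table}s keyed by gene symbol.
#' @param alpha Significance level applied to both tables.
#' @return Character vector of replicated gene symbols.
#' @export
replicated_overlap <- function(table_a, table_b, alpha = 0.05) {
  sig <- function(tab) {
    tab[!is.na(tab$p_value) & tab$converged & tab$p_value < alpha, ,
        drop = FALSE]
  }
  a <- sig(table_a); b <- sig(table_b)
  common <- intersect(a$gene, b$gene)
  if (length(common) == 0) return(character(0))
  same_dir <- a$direction[match(common, a$gene)] ==
    b$direction[match(common, b$gene)]
  common[same_dir]
}

#' Empirical false discovery rate of a replicated gene overlap
#'
#' Estimates the FDR of an overlap of independently screened gene lists as
#' the expected chance overlap divided by the observed overlap:
#' \code{expected = n_common * prod(alphas) / direction_levels}, capped at 1.
#' \code{direction_levels} counts how many of the possible sign patterns are
#' accepted as coherent relative to one: 2 for a two-list same-direction
#' overlap (2 coherent of 4 patterns), 4 for the triple signature (2 coherent
#' of 8).
#'
#' @param n_common Size of the common gene universe.
#' @param alphas Significance level(s); recycled or one per list.
#' @param direction_levels Direction-coherence divisor (see above).
#' @param observed_overlap Observed number of replicated genes (>= 1).
#' @return Estimated FDR in [0, 1].
#' @export
overlap_fdr <- function(n_common, alphas, direction_levels = 2,
                        observed_overlap) {
  if (observed_overlap < 1) stop("observed_overlap must be >= 1")
  expected <- n_common * prod(alphas) / direction_levels
  min(1, expected / observed_overlap)
}

#' Triple-significance prognostic signature
#'
#' Intersects three per-gene association tables — expression vs survival,
#' copy-number category vs survival, expression vs copy number — keeping
#' genes significant in all three (p < alpha) whose directions are coherent:
#' expression must track copy number (positive GE~CNV slope) and the two
#' survival associations must agree in sign, giving the two admissible
#' classes \emph{gain/up, HR > 1} (risk through gain) and \emph{deletion/down,
#' HR < 1} (risk through deletion). Genes passing all three significance
#' gates with a mixed direction pattern are reported with
#' \code{coherent = FALSE} but not admitted to the signature.
#'
#' @param ge_surv,cnv_surv,ge_cnv \code{association_table}s.
#' @param alpha Significance level applied to all three tables.
#' @return A data.frame of class \code{signature_table}: one row per gene
#'   passing the three significance gates, with per-table betas/p-values,
#'   \code{class} ("gain_up" / "deletion_down" / "mixed"), and
#'   \code{coherent}. Attribute \code{alpha} records the level.
#' @export
triple_signature <- function(ge_surv, cnv_surv, ge_cnv, alpha = 0.05) {
  sig <- function(tab) {
    tab[!is.na(tab$p_value) & tab$converged & tab$p_value < alpha, ,
        drop = FALSE]
  }
  a <- sig(ge_surv); b <- sig(cnv_surv); c3 <- sig(ge_cnv)
  genes <- Reduce(intersect, list(a$gene, b$gene, c3$gene))
  out <- data.frame(gene = character(), class = character(),
                    coherent = logical(),
                    ge_surv_beta = numeric(), ge_surv_p = numeric(),
                    cnv_surv_beta = numeric(), cnv_surv_p = numeric(),
                    ge_cnv_slope = numeric(), ge_cnv_p = numeric(),
                    stringsAsFactors = FALSE)
  if (length(genes) > 0) {
    ia <- match(genes, a$gene); ib <- match(genes, b$gene)
    ic <- match(genes, c3$gene)
    tracks <- c3$direction[ic] > 0
    agree <- a$direction[ia] == b$direction[ib]
    coherent <- tracks & agree
    cls <- ifelse(!coherent, "mixed",
                  ifelse(a$direction[ia] > 0, "gain_up", "deletion_down"))
    out <- data.frame(gene = genes, class = cls, coherent = coherent,
                      ge_surv_beta = a$beta[ia], ge_surv_p = a$p_value[ia],
                      cnv_surv_beta = b$beta[ib], cnv_surv_p = b$p_value[ib],
                      ge_cnv_slope = c3$beta[ic], ge_cnv_p = c3$p_value[ic],
                      stringsAsFactors = FALSE)
  }
  attr(out, "alpha") <- alpha
  class(out) <- c("signature_table", "data.frame")
  rownames(out) <- NULL
  out
}

#' Fold change and Wilcoxon rank-sum test versus a normal panel
#'
#' Per gene, the fold change is the geometric-mean ratio on the linear scale:
#' \code{log_base^(mean(tumor) - mean(normal))} for log-scale input. Group
#' differences are tested with the Wilcoxon rank-sum test (exact for small
#' samples without ties, normal approximation otherwise, as in
#' \code{stats::wilcox.test}) and Benjamini-Hochberg adjusted across genes.
#'
#' @param tumor,normal Genes x samples log-scale expression matrices sharing
#'   a gene universe.
#' @param log_base Base of the input log scale (default 2).
#' @return data.frame: \code{gene}, \code{fold_change} (linear scale,
#'   tumor over normal), \code{p_value}, \code{p_adjusted}.
#' @export
fold_change_vs_normal <- function(tumor, normal, log_base = 2) {
  genes <- intersect(rownames(tumor), rownames(normal))
  if (ncol(tumor) < 2 || ncol(normal) < 2) {
    stop("each group needs at least 2 samples")
  }
  t_m <- tumor[genes, , drop = FALSE]
  n_m <- normal[genes, , drop = FALSE]
  fc <- log_base^(rowMeans(t_m) - rowMeans(n_m))
  p <- vapply(genes, function(g) {
    suppressWarnings(stats::wilcox.test(t_m[g, ], n_m[g, ])$p.value)
  }, numeric(1))
  data.frame(gene = genes, fold_change = unname(fc), p_value = unname(p),
             p_adjusted = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Prevalence of a risk copy-number category
#'
#' Fraction of patients carrying the risk category for a gene. With
#' \code{include_normal = TRUE} the gain-or-normal reading is used (category
#' >= 0 counts as at risk), mirroring the alternative dichotomization used
#' for deletion-driven risk genes.
#'
#' @param cnv_categorical Genes x samples matrix of -1/0/+1 calls.
#' @param gene Gene symbol.
#' @param risk_category -1 or +1.
#' @param include_normal Count normal (0) together with the risk category.
#' @return Fraction of patients in [0, 1].
#' @export
risk_prevalence <- function(cnv_categorical, gene, risk_category = 1,
                            include_normal = FALSE) {
  if (!gene %in% rownames(cnv_categorical)) stop("gene absent: ", gene)
  calls <- cnv_categorical[gene, ]
  hit <- if (include_normal) {
    if (risk_category > 0) calls >= 0 else calls <= 0
  } else {
    calls == risk_category
  }
  mean(hit)
}

#' Four-criterion candidate prioritization
#'
#' Filters a signature table to candidates whose risk-category prevalence
#' meets the threshold and which carry all three curated actionability flags
#' (member of a targetable network, clinically relevant inhibitor available,
#' molecularly characterized model available), then ranks by the
#' CNV-vs-survival p-value, most significant first. The flags are curated
#' knowledge supplied by the analyst, not computed.
#'
#' @param signature A \code{signature_table} from [triple_signature()].
#' @param flags data.frame with columns \code{gene},
#'   \code{targetable_network}, \code{inhibitor_available},
#'   \code{model_available} (logical).
#' @param prevalence Named numeric vector: risk-category prevalence per gene
#'   (see [risk_prevalence()]).
#' @param prevalence_threshold Minimum prevalence; genes strictly below are
#'   excluded.
#' @return The qualifying rows of \code{signature} with \code{prevalence}
#'   attached, ordered by \code{cnv_surv_p} ascending.
#' @export
apply_funnel <- function(signature, flags, prevalence,
                         prevalence_threshold = 0.9) {
  keep <- signature[signature$coherent, , drop = FALSE]
  keep$prevalence <- prevalence[keep$gene]
  i <- match(keep$gene, flags$gene)
  pass_flags <- !is.na(i) & flags$targetable_network[i] &
    flags$inhibitor_available[i] & flags$model_available[i]
  keep <- keep[pass_flags & !is.na(keep$prevalence) &
                 keep$prevalence >= prevalence_threshold, , drop = FALSE]
  keep <- keep[order(keep$cnv_surv_p), , drop = FALSE]
  rownames(keep) <- NULL
  keep
}
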