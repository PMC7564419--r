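#' Configuration for the synthetic cohort generator
#'
#' Defines the planted structure of a simulated osteosarcoma-like cohort:
#' copy-number gains in a handful of risk genes, expression linearly coupled
#' to copy number for those genes, and exponential survival under
#' proportional hazards with a metastasis covariate. All downstream stages of
#' the package can be validated against the returned truth ledger.
#'
#' The defaults describe the study conditions used throughout the package's
#' tests: a 400-patient cohort over 400 genes with three planted risk genes
#' carrying a copy-number gain in 40% of patients, expression rising 1.5
#' log2-units per extra copy, and a per-unit-expression log hazard of 0.7
#' (HR about 2 per log2-unit). Metastasis at diagnosis (prevalence 0.2)
#' carries log hazard 1.5, matching the roughly five-fold mortality contrast
#' reported for metastatic presentation in pediatric osteosarcoma. Roughly
#' 30% of follow-up is censored. Because every planted gene's expression
#' enters the hazard, the genes a marginal per-gene screen omits act as a
#' shared frailty that attenuates the remaining genes' marginal effects; the
#' default cohort size, number of planted genes, and coupling slope were
#' chosen by power analysis so that each planted gene still clears the
#' copy-number screen with a large margin (per-gene Wald z around 8).
#'
#' @param n_patients Cohort size.
#' @param n_genes Number of genes in the expression/copy-number universe.
#' @param planted_genes data.frame with columns \code{symbol},
#'   \code{cnv_gain_prevalence}, \code{ge_cnv_slope} (log2-units expression
#'   per copy above diploid), \code{log_hazard_per_unit_expression}.
#'   \code{NULL} plants three default risk genes RISK1..RISK3.
#' @param baseline_hazard Exponential baseline hazard per year.
#' @param censoring_rate Target fraction of censored patients in [0, 1).
#' @param metastasis_prevalence,metastasis_log_hazard Metastasis covariate.
#' @param expression_noise_sd,marker_noise_sd Gaussian noise SDs for
#'   expression and measured copy number.
#' @param background_cnv_prevalence Fraction of samples with a sporadic,
#'   survival-neutral gain or deletion in a non-planted gene.
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return A list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_patients = 400,
                             n_genes = 400,
                             planted_genes = NULL,
                             baseline_hazard = 0.15,
                             censoring_rate = 0.3,
                             metastasis_prevalence = 0.2,
                             metastasis_log_hazard = 1.5,
                             expression_noise_sd = 0.5,
                             marker_noise_sd = 0.1,
                             background_cnv_prevalence = 0.1,
                             seed = 1L) {
  if (is.null(planted_genes)) {
    planted_genes <- data.frame(
      symbol = paste0("RISK", 1:3),
      cnv_gain_prevalence = 0.4,
      ge_cnv_slope = 1.5,
      log_hazard_per_unit_expression = 0.7,
      stringsAsFactors = FALSE)
  }
  stopifnot(n_patients >= 2, n_genes >= nrow(planted_genes),
            baseline_hazard > 0,
            censoring_rate >= 0, censoring_rate < 1,
            metastasis_prevalence >= 0, metastasis_prevalence <= 1,
            expression_noise_sd > 0, marker_noise_sd > 0,
            background_cnv_prevalence >= 0, background_cnv_prevalence <= 1,
            all(planted_genes$cnv_gain_prevalence >= 0),
            all(planted_genes$cnv_gain_prevalence <= 1))
  structure(list(n_patients = n_patients, n_genes = n_genes,
                 planted_genes = planted_genes,
                 baseline_hazard = baseline_hazard,
                 censoring_rate = censoring_rate,
                 metastasis_prevalence = metastasis_prevalence,
                 metastasis_log_hazard = metastasis_log_hazard,
                 expression_noise_sd = expression_noise_sd,
                 marker_noise_sd = marker_noise_sd,
                 background_cnv_prevalence = background_cnv_prevalence,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

gene_universe <- function(config) {
  n_bg <- config$n_genes - nrow(config$planted_genes)
  c(config$planted_genes$symbol,
    sprintf("G%04d", seq_len(n_bg)))
}

#' Generate a synthetic survival cohort with planted CNV-expression effects
#'
#' For each planted gene, a fraction of patients (the gain prevalence) carries
#' a discrete gain of 3 or 4 copies; everyone else is diploid. Expression is
#' baseline + slope x (copies - 2) + Gaussian noise. Survival times are
#' exponential with hazard
#' \code{baseline_hazard * exp(met_lh * metastasis + sum_g beta_g * (expr_g -
#' baseline_g))}, and independent exponential censoring is tuned to the target
#' censoring rate. Non-planted genes receive sporadic survival-neutral gains
#' or deletions at the background prevalence so that a genewise screen has a
#' realistic null.
#'
#' @param config A [synthetic_config()].
#' @return A list with \code{clinical} (clinical_table), \code{expression},
#'   \code{cnv_continuous}, \code{cnv_categorical} (gene x sample matrices),
#'   and \code{truth} (the planted-parameter ledger, including per-gene true
#'   log hazards and each gene's baseline expression).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_patients
  genes <- gene_universe(config)
  G <- length(genes)
  planted <- config$planted_genes
  is_planted <- genes %in% planted$symbol

  patient_id <- sprintf("P%04d", seq_len(n))
  metastasis <- stats::rbinom(n, 1, config$metastasis_prevalence)
  race <- sample(c("white", "black", "asian", "other"), n, replace = TRUE,
                 prob = c(0.6, 0.2, 0.1, 0.1))
  gender <- sample(c("male", "female"), n, replace = TRUE)
  age_years <- round(stats::runif(n, 5, 25), 1)

  # true (noise-free) copies, then measured continuous copy number
  copies <- matrix(2, G, n, dimnames = list(genes, patient_id))
  for (i in seq_len(nrow(planted))) {
    g <- planted$symbol[i]
    gained <- stats::runif(n) < planted$cnv_gain_prevalence[i]
    copies[g, gained] <- sample(c(3, 4), sum(gained), replace = TRUE)
  }
  bg <- which(!is_planted)
  if (config$background_cnv_prevalence > 0 && length(bg) > 0) {
    altered <- matrix(stats::runif(length(bg) * n) <
                        config$background_cnv_prevalence,
                      length(bg), n)
    state <- matrix(sample(c(1, 3), length(bg) * n, replace = TRUE),
                    length(bg), n)
    copies[bg, ][altered] <- state[altered]
  }
  cnv_continuous <- copies +
    matrix(stats::rnorm(G * n, 0, config$marker_noise_sd), G, n)
  cnv_continuous[cnv_continuous <= 0.05] <- 0.05
  attr(cnv_continuous, "kind") <- "copy_number_continuous"

  baseline_expr <- stats::setNames(round(stats::runif(G, 4, 10), 2), genes)
  slope <- stats::setNames(numeric(G), genes)
  slope[planted$symbol] <- planted$ge_cnv_slope
  expression <- baseline_expr + slope * (copies - 2) +
    matrix(stats::rnorm(G * n, 0, config$expression_noise_sd), G, n)
  dimnames(expression) <- list(genes, patient_id)
  attr(expression, "kind") <- "expression"

  # proportional-hazards survival on expression deviations from baseline
  log_hr <- stats::setNames(numeric(G), genes)
  log_hr[planted$symbol] <- planted$log_hazard_per_unit_expression
  lp <- config$metastasis_log_hazard * metastasis
  for (g in planted$symbol) {
    lp <- lp + log_hr[g] * (expression[g, ] - baseline_expr[g])
  }
  hazard <- config$baseline_hazard * exp(lp)
  t_event <- stats::rexp(n, hazard)
  if (config$censoring_rate > 0) {
    cens_hazard <- config$baseline_hazard *
      config$censoring_rate / (1 - config$censoring_rate)
    t_cens <- stats::rexp(n, cens_hazard)
  } else {
    t_cens <- rep(Inf, n)
  }
  event <- as.integer(t_event <= t_cens)
  survival_years <- pmin(t_event, t_cens)

  clinical <- data.frame(patient_id = patient_id,
                         survival_years = survival_years,
                         event = event,
                         metastasis_at_diagnosis = metastasis,
                         race = race, gender = gender,
                         age_years = age_years,
                         stringsAsFactors = FALSE)
  attr(clinical, "optional_present") <-
    c("metastasis_at_diagnosis", "race", "gender", "age_years")
  class(clinical) <- c("clinical_table", "data.frame")

  truth <- list(planted = planted,
                log_hazard = log_hr[planted$symbol],
                ge_cnv_slope = slope[planted$symbol],
                baseline_expression = baseline_expr,
                true_copies = copies,
                metastasis_log_hazard = config$metastasis_log_hazard,
                baseline_hazard = config$baseline_hazard,
                seed = config$seed)

  list(clinical = clinical,
       expression = expression,
       cnv_continuous = cnv_continuous,
       cnv_categorical = categorize_copy_number(cnv_continuous),
       truth = truth)
}

#' Generate a marker-level copy-number track with known breakpoints
#'
#' @param segments_spec data.frame with columns \code{chromosome},
#'   \code{n_markers}, \code{copy_number}: consecutive constant-copy blocks.
#' @param marker_noise_sd Gaussian noise SD added to each marker.
#' @param seed Integer seed.
#' @param sample_id Sample label.
#' @param spacing Base pairs between consecutive markers.
#' @return List with \code{track} (a \code{marker_track}) and
#'   \code{breakpoints}: data.frame of true boundaries, one per adjacent block
#'   pair within a chromosome, giving the 1-based index of the last marker of
#'   the left block.
#' @export
generate_marker_track <- function(segments_spec, marker_noise_sd = 0.1,
                                  seed = 1L, sample_id = "S1",
                                  spacing = 1000L) {
  stopifnot(all(segments_spec$n_markers >= 1))
  if (any(segments_spec$copy_number <= 0)) {
    stop("copy_number spec must be positive")
  }
  set.seed(as.integer(seed))
  rows <- list(); bps <- list()
  for (chrom in unique(segments_spec$chromosome)) {
    blocks <- segments_spec[segments_spec$chromosome == chrom, , drop = FALSE]
    cn <- rep(blocks$copy_number, blocks$n_markers)
    m <- length(cn)
    noise <- if (marker_noise_sd > 0) stats::rnorm(m, 0, marker_noise_sd) else 0
    rows[[chrom]] <- data.frame(
      sample = sample_id, chromosome = chrom,
      position = as.integer(seq_len(m)) * spacing,
      copy_number = pmax(cn + noise, 0.05),
      stringsAsFactors = FALSE)
    if (nrow(blocks) > 1) {
      bps[[chrom]] <- data.frame(
        chromosome = chrom,
        last_marker_left = cumsum(blocks$n_markers)[-nrow(blocks)])
    }
  }
  track <- as_marker_track(do.call(rbind, c(rows, list(make.row.names = FALSE))))
  breakpoints <- if (length(bps) > 0) {
    do.call(rbind, c(bps, list(make.row.names = FALSE)))
  } else {
    data.frame(chromosome = character(), last_marker_left = integer())
  }
  list(track = track, breakpoints = breakpoints)
}

#' Generate a normal-tissue expression panel
#'
#' Stands in for a non-neoplastic reference panel (e.g. primary normal
#' osteoblasts): independent Gaussian expression around supplied gene means.
#'
#' @param n_samples Number of normal samples.
#' @param gene_means Named numeric vector of per-gene mean expression
#'   (log scale).
#' @param noise_sd Gaussian noise SD.
#' @param seed Integer seed.
#' @return An expression matrix (genes x samples).
#' @export
generate_normal_panel <- function(n_samples, gene_means, noise_sd = 0.5,
                                  seed = 1L) {
  stopifnot(n_samples >= 1, noise_sd > 0, !is.null(names(gene_means)))
  set.seed(as.integer(seed))
  G <- length(gene_means)
  m <- gene_means + matrix(stats::rnorm(G * n_samples, 0, noise_sd),
                           G, n_samples)
  dimnames(m) <- list(names(gene_means), sprintf("N%03d", seq_len(n_samples)))
  attr(m, "kind") <- "expression"
  m
}

#' Generate a checkerboard dose-response matrix from Hill curves
#'
#' Single-agent margins follow the median-effect (Hill) curve
#' \code{fa(D) = 1 / (1 + (Dm/D)^m)}. Each combination cell is the Bliss
#' expected value of its margins plus a controllable interaction term
#' \code{interaction_delta} (positive = planted synergy), clipped to [0, 1],
#' plus Gaussian noise per replicate.
#'
#' @param hill_a,hill_b Lists with elements \code{Dm} (dose of half-maximal
#'   effect, uM) and \code{m} (sigmoidicity), both positive.
#' @param doses_a,doses_b Strictly increasing positive dose grids.
#' @param interaction_delta Fraction-affected excess added to every
#'   combination cell before clipping.
#' @param replicates Number of replicate plates.
#' @param noise_sd Gaussian noise SD on the fraction-affected scale.
#' @param seed Integer seed.
#' @return List with \code{single_a}, \code{single_b} (margin vectors),
#'   \code{combo} (a \code{dose_response_matrix}; \code{effects} is a 3-d
#'   array when \code{replicates > 1}), and \code{truth} holding the planted
#'   per-cell delta after clipping.
#' @export
generate_dose_matrix <- function(hill_a, hill_b, doses_a, doses_b,
                                 interaction_delta = 0, replicates = 1,
                                 noise_sd = 0, seed = 1L) {
  stopifnot(hill_a$Dm > 0, hill_a$m > 0, hill_b$Dm > 0, hill_b$m > 0)
  set.seed(as.integer(seed))
  fa <- function(D, h) 1 / (1 + (h$Dm / D)^h$m)
  A <- fa(doses_a, hill_a)
  B <- fa(doses_b, hill_b)
  expected <- outer(A, B, function(a, b) a + b - a * b)
  true_combo <- pmin(pmax(expected + interaction_delta, 0), 1)
  eff <- array(rep(true_combo, replicates),
               dim = c(length(doses_a), length(doses_b), replicates))
  if (noise_sd > 0) {
    eff <- eff + array(stats::rnorm(length(eff), 0, noise_sd), dim = dim(eff))
    eff <- pmin(pmax(eff, 0), 1)
  }
  if (replicates == 1) eff <- eff[, , 1, drop = TRUE]
  if (is.null(dim(eff))) eff <- matrix(eff, length(doses_a), length(doses_b))
  combo <- dose_response_matrix(doses_a, doses_b, eff)
  list(single_a = A, single_b = B, combo = combo,
       truth = list(delta = true_combo - expected,
                    expected = expected,
                    interaction_delta = interaction_delta,
                    hill_a = hill_a, hill_b = hill_b))
}
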