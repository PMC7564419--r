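#' Fit a Cox proportional-hazards model
#'
#' Thin, validating wrapper around the partial-likelihood Newton-Raphson
#' fitter of the survival package with Efron tie handling by default (ties
#' are certain at yearly resolution; Breslow is available behind the
#' \code{ties} flag). Rows with missing covariates are dropped listwise and
#' the dropped count is reported. Constant covariates are rejected, and
#' monotone-likelihood fits (perfect separation) are flagged as
#' non-converged rather than silently returned.
#'
#' @param times Positive follow-up times.
#' @param events 0/1 event indicators (1 = death observed).
#' @param covariates Numeric matrix or data.frame (factors are expanded to
#'   treatment contrasts) of predictors.
#' @param ties \code{"efron"} (default) or \code{"breslow"}.
#' @return Object of class \code{cox_fit}: \code{coefficients}, \code{se},
#'   \code{hazard_ratio}, \code{z}, \code{p}, \code{loglik} (maximized
#'   partial log-likelihood), \code{converged}, \code{n_used},
#'   \code{n_events}, \code{n_dropped}.
#' @export
fit_cox <- function(times, events, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (is.data.frame(covariates)) {
    complete <- stats::complete.cases(covariates) & is.finite(times) &
      !is.na(events)
    df <- covariates[complete, , drop = FALSE]
    for (j in seq_along(df)) if (is.character(df[[j]])) df[[j]] <- factor(df[[j]])
    x <- stats::model.matrix(~ ., data = df)[, -1, drop = FALSE]
  } else {
    x <- as.matrix(covariates)
    if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
    complete <- stats::complete.cases(x) & is.finite(times) & !is.na(events)
    x <- x[complete, , drop = FALSE]
  }
  n_dropped <- sum(!complete)
  times <- times[complete]; events <- events[complete]
  if (sum(events) < 1) stop("need at least one observed event")
  const <- apply(x, 2, function(col) stats::var(col) == 0)
  if (any(const)) {
    stop("constant covariate(s): ", paste(colnames(x)[const], collapse = ", "))
  }
  storage.mode(x) <- "double"
  y <- survival::Surv(as.numeric(times), events)
  control <- survival::coxph.control(eps = 1e-9, iter.max = 100)
  fit <- survival::coxph.fit(x, y, strata = NULL, offset = NULL, init = NULL,
                             control = control,
                             weights = NULL, method = ties,
                             rownames = seq_len(nrow(x)))
  beta <- stats::setNames(fit$coefficients, colnames(x))
  se <- stats::setNames(sqrt(diag(as.matrix(fit$var))), colnames(x))
  # monotone partial likelihood drives |beta| and its SE jointly to infinity
  converged <- is.finite(sum(beta)) &&
    fit$iter < control$iter.max &&
    all(abs(beta) < 15) && all(se < 50 * (1 + abs(beta)))
  z <- beta / se
  structure(list(coefficients = beta, se = se,
                 hazard_ratio = exp(beta), z = z,
                 p = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
                 loglik = fit$loglik[2], loglik_null = fit$loglik[1],
                 converged = converged, iter = fit$iter,
                 n_used = nrow(x), n_events = sum(events),
                 n_dropped = n_dropped, ties = ties),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional-hazards fit (", x$ties, " ties), n = ", x$n_used,
      ", events = ", x$n_events, "\n", sep = "")
  if (!x$converged) cat("WARNING: fit did not converge\n")
  print(data.frame(beta = x$coefficients, HR = x$hazard_ratio,
                   se = x$se, z = x$z, p = x$p))
  invisible(x)
}

adjustment_design <- function(clinical, adjust) {
  if (length(adjust) == 0) return(NULL)
  missing_cols <- setdiff(adjust, names(clinical))
  if (length(missing_cols) > 0) {
    stop("adjustment covariate(s) not in clinical table: ",
         paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(clinical)[, adjust, drop = FALSE]
  for (j in seq_along(df)) if (is.character(df[[j]])) df[[j]] <- factor(df[[j]])
  mm <- stats::model.matrix(~ ., data = df)[, -1, drop = FALSE]
  if (nrow(mm) != nrow(clinical)) {
    stop("missing values in adjustment covariates are not supported here; ",
         "drop those patients first")
  }
  mm
}

#' Genewise Cox screen of a feature matrix against overall survival
#'
#' Fits one Cox model per gene with the gene's feature (expression, or the
#' -1/0/+1 copy-number category entered as a single ordinal covariate) as
#' exposure, adjusted by default for race and metastasis at diagnosis.
#' Genes whose fit fails to converge, or whose feature is constant, are
#' flagged and excluded from the significant set.
#'
#' @param features Genes x samples matrix; sample ids must appear in
#'   \code{clinical$patient_id}.
#' @param clinical A \code{clinical_table}.
#' @param adjust Character vector of clinical adjustment columns; use
#'   \code{character(0)} for univariate screening.
#' @param alpha Significance level for the screened subset.
#' @param kind Association label: \code{"GE~survival"} or
#'   \code{"CNV~survival"}.
#' @return A data.frame of class \code{association_table} with one row per
#'   gene: \code{gene}, \code{beta}, \code{hazard_ratio}, \code{se},
#'   \code{p_value}, \code{direction} (sign of beta), \code{converged},
#'   \code{n_used}, \code{n_events}, \code{kind}, \code{significant}
#'   (p < alpha among converged fits). Attribute \code{alpha} records the
#'   level used.
#' @export
genewise_screen <- function(features, clinical,
                            adjust = c("race", "metastasis_at_diagnosis"),
                            alpha = 0.05, kind = "GE~survival") {
  common <- intersect(colnames(features), clinical$patient_id)
  if (length(common) == 0) stop("no samples shared by features and clinical")
  clin <- as.data.frame(clinical)
  clin <- clin[match(common, clin$patient_id), , drop = FALSE]
  features <- features[, common, drop = FALSE]
  adj <- adjustment_design(clin, adjust)
  times <- clin$survival_years
  events <- clin$event
  storage.mode(features) <- "double"
  y <- survival::Surv(as.numeric(times), events)
  control <- survival::coxph.control(eps = 1e-9, iter.max = 100)

  fit_one <- function(feat) {
    x <- cbind(feature = feat, adj)
    if (stats::var(feat) == 0) return(c(NA, NA, NA, FALSE))
    fit <- tryCatch(
      survival::coxph.fit(x, y, strata = NULL, offset = NULL, init = NULL,
                          control = control, weights = NULL,
                          method = "efron", rownames = seq_along(feat)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$coefficients[1])) {
      return(c(NA, NA, NA, FALSE))
    }
    beta <- fit$coefficients[1]
    se <- sqrt(diag(as.matrix(fit$var)))[1]
    conv <- fit$iter < control$iter.max && abs(beta) < 15 &&
      se < 50 * (1 + abs(beta))
    p <- 2 * stats::pnorm(abs(beta / se), lower.tail = FALSE)
    c(beta, se, p, conv)
  }
  res <- t(apply(features, 1, fit_one))
  tab <- data.frame(gene = rownames(features),
                    beta = res[, 1],
                    hazard_ratio = exp(res[, 1]),
                    se = res[, 2],
                    p_value = res[, 3],
                    direction = sign(res[, 1]),
                    converged = as.logical(res[, 4]),
                    n_used = length(common),
                    n_events = sum(events),
                    kind = kind,
                    stringsAsFactors = FALSE)
  tab$significant <- tab$converged & !is.na(tab$p_value) & tab$p_value < alpha
  attr(tab, "alpha") <- alpha
  class(tab) <- c("association_table", "data.frame")
  rownames(tab) <- NULL
  tab
}

#' Two-group log-rank test
#'
#' @param times_a,events_a Follow-up times and 0/1 events for group A.
#' @param times_b,events_b Same for group B.
#' @return List with \code{statistic} (1-df chi-square) and \code{p}.
#' @export
logrank <- function(times_a, events_a, times_b, events_b) {
  if (length(times_a) == 0 || length(times_b) == 0) {
    stop("both groups must be non-empty")
  }
  if (sum(events_a) + sum(events_b) < 1) stop("need at least one event")
  g <- factor(rep(c("A", "B"), c(length(times_a), length(times_b))))
  sd <- survival::survdiff(
    survival::Surv(c(times_a, times_b), c(events_a, events_b)) ~ g)
  stat <- sd$chisq
  list(statistic = unname(stat),
       p = stats::pchisq(unname(stat), df = 1, lower.tail = FALSE))
}

#' Kaplan-Meier product-limit estimate
#'
#' @param times Follow-up times.
#' @param events 0/1 event indicators.
#' @return Object of class \code{survival_curve}: \code{time} (ordered unique
#'   observed times), \code{n_risk}, \code{n_event}, \code{surv} (stepwise
#'   survival probabilities, S(0) = 1 implied), \code{median} (NA and
#'   \code{median_defined = FALSE} when the curve never reaches 0.5 or no
#'   event occurs).
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) == length(events), all(times > 0))
  sf <- survival::survfit(survival::Surv(times, events) ~ 1)
  med <- unname(summary(sf)$table["median"])
  structure(list(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
                 surv = sf$surv,
                 median = med,
                 median_defined = is.finite(med) && sum(events) > 0),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat("Kaplan-Meier curve over", length(x$time), "time points; median =",
      if (x$median_defined) signif(x$median, 4) else "undefined", "\n")
  invisible(x)
}

#' Dichotomize patients by a gene's copy-number category
#'
#' Two grouping rules are supported: \code{"gain_vs_rest"} (gain versus
#' normal-or-deletion) and \code{"gain_or_normal_vs_deletion"}.
#'
#' @param cnv_categorical Genes x samples matrix of -1/0/+1 calls.
#' @param gene Gene symbol.
#' @param rule Grouping rule.
#' @return Factor of group labels, one per sample, levels with the risk
#'   group first.
#' @export
dichotomize_by_cnv <- function(cnv_categorical, gene,
                               rule = c("gain_vs_rest",
                                        "gain_or_normal_vs_deletion")) {
  rule <- match.arg(rule)
  if (!gene %in% rownames(cnv_categorical)) stop("gene absent: ", gene)
  calls <- cnv_categorical[gene, ]
  if (rule == "gain_vs_rest") {
    factor(ifelse(calls == 1, "gain", "no_gain"),
           levels = c("gain", "no_gain"))
  } else {
    factor(ifelse(calls >= 0, "gain_or_normal", "deletion"),
           levels = c("gain_or_normal", "deletion"))
  }
}
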