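#' Convert odds to a predicted probability
#'
#' `probability = odds / (1 + odds)`.
#'
#' @param odds non-negative odds (vectorized).
#' @return probabilities in `[0, 1)`.
#' @export
odds_to_probability <- function(odds) {
  if (!is.numeric(odds) || any(is.na(odds)) || any(odds < 0))
    stop("odds_to_probability: odds must be non-negative numbers")
  odds / (1 + odds)
}

#' Build the merged analysis table
#'
#' Joins per-subject accepted acoustic features to phenotype results and
#' adds the binary outcome columns the association models use.
#'
#' @param features `data.frame` with `subject_id` and `A1`..`A4` (accepted
#'   values; `NA` where a parameter failed QC).
#' @param phenotypes output of [score_phenotypes()].
#' @return `data.frame` with features, statuses, and logical columns
#'   `ebf_frail`, `sbf_frail`, `hbf_e`, `hbf_s` plus `four_category`.
#' @export
analysis_table <- function(features, phenotypes) {
  for (nm in c("subject_id", "A1", "A2", "A3", "A4"))
    if (!nm %in% names(features))
      stop("analysis_table: feature table lacks column ", nm)
  d <- merge(features, phenotypes, by = "subject_id")
  d$ebf_frail <- d$ebf_status == "frail"
  d$sbf_frail <- d$sbf_status == "frail"
  d
}

# shared model-input checks and row filtering; returns list(data, n_excluded)
prepare_model_frame <- function(data, outcome, exposure, covariates) {
  vars <- c(outcome, exposure, covariates)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols))
    stop("association: data lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  d <- data[, vars, drop = FALSE]
  keep <- stats::complete.cases(d)
  n_excluded <- sum(!keep)
  if (n_excluded > 0)
    message("association: excluded ", n_excluded,
            " subject(s) with indeterminate outcome or missing exposure")
  d <- d[keep, , drop = FALSE]
  if (stats::var(as.numeric(d[[exposure]])) == 0)
    stop("association: exposure '", exposure, "' has zero variance")
  list(data = d, n_excluded = n_excluded)
}

# coefs_scaled are slope coefficients multiplied by their covariate's SD, so
# the divergence test is invariant to the exposure's measurement unit
check_separation <- function(fitted_p, coefs_scaled) {
  pinned <- fitted_p > 1 - 1e-8 | fitted_p < 1e-8
  if (any(pinned) || max(abs(coefs_scaled)) > 7)
    stop("association: perfect or quasi-separation detected ",
         "(diverging coefficients or fitted probabilities pinned at 0/1); ",
         "no estimate reported")
}

term_sds <- function(d, terms) {
  vapply(terms, function(t) stats::sd(as.numeric(d[[t]])), numeric(1))
}

#' Binomial logistic association model
#'
#' Fits a maximum-likelihood logistic regression of a binary frailty outcome
#' on a single acoustic exposure (each acoustic variable is evaluated in its
#' own model), optionally adjusted for covariates. Reports the odds ratio
#' `exp(beta)` with a Wald 95% CI `exp(beta +/- z * SE)`. Subjects with an
#' indeterminate outcome or missing exposure are excluded (complete case)
#' with a logged count. Perfect or quasi-separation and non-convergence are
#' errors, not estimates.
#'
#' @param data analysis table (see [analysis_table()]).
#' @param outcome name of a logical/0-1 outcome column (e.g. `"ebf_frail"`,
#'   `"sbf_frail"`, `"hbf_e"`, `"hbf_s"`).
#' @param exposure name of the acoustic exposure column (one of `A1`..`A4`).
#' @param covariates optional character vector of adjustment covariates;
#'   `NULL` (crude model) by default.
#' @param standardize_exposure if `TRUE` the exposure is divided by its
#'   sample SD so the OR is per-SD rather than per natural unit.
#' @param conf_level confidence level for the Wald interval.
#' @return a `data.frame` (one row per non-intercept term; the exposure row
#'   first) with columns `effect_type` ("OR"), `outcome`, `exposure`,
#'   `term`, `estimate`, `ci_low`, `ci_high`, `se_log`, `p_value`,
#'   `n_used`, `baseline_category` (`NA` for binomial models).
#' @export
fit_binomial <- function(data, outcome, exposure, covariates = NULL,
                         standardize_exposure = FALSE, conf_level = 0.95) {
  prep <- prepare_model_frame(data, outcome, exposure, covariates)
  d <- prep$data
  y <- as.integer(as.logical(d[[outcome]]))
  if (length(unique(y)) < 2L)
    stop("association: outcome '", outcome, "' does not have both levels")
  d[[outcome]] <- y
  if (standardize_exposure)
    d[[exposure]] <- d[[exposure]] / stats::sd(d[[exposure]])
  f <- stats::reformulate(c(exposure, covariates), response = outcome)
  fit <- withCallingHandlers(
    stats::glm(f, data = d, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (!fit$converged) stop("association: logistic fit did not converge")
  slope_terms <- c(exposure, covariates)
  check_separation(stats::fitted(fit),
                   stats::coef(fit)[slope_terms] * term_sds(d, slope_terms))
  sm <- summary(fit)$coefficients
  terms <- setdiff(rownames(sm), "(Intercept)")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  b <- sm[terms, "Estimate"]
  se <- sm[terms, "Std. Error"]
  data.frame(effect_type = "OR", outcome = outcome, exposure = exposure,
             term = terms, estimate = exp(b), ci_low = exp(b - z * se),
             ci_high = exp(b + z * se), se_log = se,
             p_value = sm[terms, "Pr(>|z|)"], n_used = nrow(d),
             baseline_category = NA_character_, row.names = NULL)
}

#' Multinomial logistic association model
#'
#' Fits a multinomial logit of the four-category frailty outcome (nonfrail /
#' EBF-only / SBF-only / both) on a single acoustic exposure, with nonfrail
#' as the baseline category. Reports one relative risk ratio (RRR, the
#' exponentiated coefficient: the ratio of the odds of a category versus the
#' baseline per unit exposure) per non-baseline category, with Wald 95% CIs.
#' Categories with no members are dropped with a warning. With only two
#' categories present the RRR reduces to the binomial odds ratio.
#'
#' @inheritParams fit_binomial
#' @param outcome name of the categorical outcome column.
#' @param baseline baseline (reference) category.
#' @return a `data.frame` as in [fit_binomial()], one row per non-baseline
#'   category and term, with `effect_type = "RRR"`, `term` the model term,
#'   a `category` column, and `baseline_category` filled in.
#' @export
fit_multinomial <- function(data, outcome = "four_category", exposure,
                            covariates = NULL, baseline = "nonfrail",
                            standardize_exposure = FALSE, conf_level = 0.95) {
  prep <- prepare_model_frame(data, outcome, exposure, covariates)
  d <- prep$data
  yf <- d[[outcome]]
  if (!is.factor(yf)) yf <- factor(as.character(yf))
  counts <- table(yf)
  if (any(counts == 0))
    warning("association: empty categor(ies) dropped: ",
            paste(names(counts)[counts == 0], collapse = ", "))
  yf <- droplevels(yf)
  if (!baseline %in% levels(yf))
    stop("association: baseline category '", baseline, "' has no members")
  if (nlevels(yf) < 2L)
    stop("association: need at least two outcome categories")
  d[[outcome]] <- stats::relevel(yf, ref = baseline)
  if (standardize_exposure)
    d[[exposure]] <- d[[exposure]] / stats::sd(d[[exposure]])
  f <- stats::reformulate(c(exposure, covariates), response = outcome)
  fit <- nnet::multinom(f, data = d, trace = FALSE, Hess = TRUE,
                        maxit = 500, reltol = 1e-14)
  if (fit$convergence != 0)
    stop("association: multinomial fit did not converge")
  cf <- stats::coef(fit)
  if (is.null(dim(cf))) {  # two categories: coerce to matrix form
    cf <- matrix(cf, nrow = 1,
                 dimnames = list(setdiff(levels(d[[outcome]]), baseline),
                                 names(cf)))
  }
  slope_terms <- c(exposure, covariates)
  scaled <- sweep(cf[, slope_terms, drop = FALSE], 2L, term_sds(d, slope_terms),
                  `*`)
  check_separation(as.vector(stats::fitted(fit)), as.vector(scaled))
  vc <- stats::vcov(fit)
  se_all <- sqrt(diag(vc))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  terms <- setdiff(colnames(cf), "(Intercept)")
  out <- do.call(rbind, lapply(rownames(cf), function(cat) {
    b <- cf[cat, terms]
    se_names <- if (nrow(cf) == 1L) terms else paste(cat, terms, sep = ":")
    se <- se_all[se_names]
    data.frame(effect_type = "RRR", outcome = outcome, exposure = exposure,
               category = cat, term = terms, estimate = exp(b),
               ci_low = exp(b - z * se), ci_high = exp(b + z * se),
               se_log = unname(se),
               p_value = 2 * stats::pnorm(-abs(b / se)), n_used = nrow(d),
               baseline_category = baseline, row.names = NULL)
  }))
  out
}

#' Predicted category probabilities from a fitted multinomial model
#'
#' Convenience wrapper kept for completeness: given exponentiated linear
#' predictors (odds against the baseline), returns normalized category
#' probabilities that sum to one.
#'
#' @param odds_matrix matrix of odds versus baseline, one column per
#'   non-baseline category, one row per subject.
#' @return matrix of probabilities (baseline first column), rows summing to 1.
#' @export
multinomial_probabilities <- function(odds_matrix) {
  om <- cbind(baseline = 1, as.matrix(odds_matrix))
  if (any(om < 0)) stop("multinomial_probabilities: odds must be >= 0")
  om / rowSums(om)
}
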