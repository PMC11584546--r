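#' Default assessment-item distributions for a synthetic cohort
#'
#' Sampling distributions for the clinical items feeding phenotype scoring.
#' Defaults are chosen so that roughly 12-15% of subjects score frail on
#' each index (a realistic community prevalence for older outpatients), not
#' to match any particular study sample.
#'
#' @return a named list of distribution parameters (prevalences, means, SDs).
#' @export
default_assessment_distributions <- function() {
  list(
    p_female = 0.5,
    body_weight = list(mean = 60, sd = 10),          # kg
    weight_loss = list(p_loss = 0.40,                # any loss in past year
                       kg_meanlog = log(4), kg_sdlog = 0.7),
    p_exhaustion = 0.50,
    p_chair_rise_unable = 0.30,
    grip = list(male_mean = 30, male_sd = 7,         # kg
                female_mean = 20, female_sd = 5),
    gait = list(mean = 1.1, sd = 0.3),               # m/s
    p_non_ambulatory = 0.05,
    p_adl_deterioration = 0.30
  )
}

#' Default phenotype-to-feature model (generation mode 1)
#'
#' Mean A1-A4 as a linear function of frailty status plus Gaussian noise.
#' Intercepts are typical sustained-/a/ values; the frailty effects follow
#' the directions reported for older adults (lower zero-crossing rate and
#' higher low-frequency energy ratio with energy-based frailty; larger
#' amplitude and formant variation with sarcopenia-based frailty).
#'
#' @return a named list, one element per feature:
#'   `list(intercept, ebf_frail, sbf_frail, sd)`.
#' @export
default_feature_model <- function() {
  list(
    A1 = list(intercept = 0.050, ebf_frail = -0.012, sbf_frail = 0,     sd = 0.010),
    A2 = list(intercept = 8,     ebf_frail = 0,      sbf_frail = 4,     sd = 2.5),
    A3 = list(intercept = 15,    ebf_frail = 0,      sbf_frail = 8,     sd = 5),
    A4 = list(intercept = 0.70,  ebf_frail = 0.10,   sbf_frail = 0,     sd = 0.08)
  )
}

#' Specification of a synthetic cohort
#'
#' Two generation modes:
#'
#' * **mode 1 (phenotype-linked)**: assessment items are drawn from
#'   `assessment_distributions`, true phenotypes are scored by the package's
#'   scoring rules, and A1-A4 are drawn conditionally on phenotype via
#'   `feature_model`. The outcome table holds the true phenotypes.
#' * **mode 2 (outcome-linked)**: A1-A4 are drawn marginally (from the
#'   `feature_model` intercepts and SDs), and binary outcomes are drawn as
#'   `Bernoulli(plogis(intercept + sum(coef * feature)))` from
#'   `outcome_link`. This is the parameter-recovery harness for the
#'   association models: the generating log-odds coefficients are known.
#'
#' @param n_subjects number of subjects (>= 0; 0 yields empty tables).
#' @param assessment_distributions see
#'   [default_assessment_distributions()].
#' @param feature_model see [default_feature_model()].
#' @param outcome_link for mode 2: a named list, one element per binary
#'   outcome, each `list(intercept = ..., coefs = c(A1 = ..., ...))` on the
#'   log-odds scale per natural feature unit. Required in mode 2.
#' @param mode 1 (phenotype-linked) or 2 (outcome-linked).
#' @param seed integer random seed (the generator is then fully
#'   reproducible), or `NULL` to draw from the current RNG stream (for
#'   replicate loops seeded once at the top).
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects,
                        assessment_distributions = default_assessment_distributions(),
                        feature_model = default_feature_model(),
                        outcome_link = NULL, mode = 1L, seed = 1L) {
  if (!is.numeric(n_subjects) || n_subjects < 0)
    stop("cohort_spec: n_subjects must be >= 0")
  mode <- as.integer(mode)
  if (!mode %in% c(1L, 2L)) stop("cohort_spec: mode must be 1 or 2")
  if (mode == 2L && is.null(outcome_link))
    stop("cohort_spec: outcome_link is required in mode 2")
  sds <- c(assessment_distributions$body_weight$sd,
           assessment_distributions$grip$male_sd,
           assessment_distributions$grip$female_sd,
           assessment_distributions$gait$sd,
           vapply(feature_model, function(m) m$sd, numeric(1)))
  if (any(sds < 0)) stop("cohort_spec: all SDs must be >= 0")
  probs <- unlist(assessment_distributions[c("p_female", "p_exhaustion",
                                             "p_chair_rise_unable",
                                             "p_non_ambulatory",
                                             "p_adl_deterioration")])
  if (any(probs < 0 | probs > 1))
    stop("cohort_spec: prevalences must be in [0, 1]")
  structure(list(n_subjects = as.integer(n_subjects),
                 assessment_distributions = assessment_distributions,
                 feature_model = feature_model, outcome_link = outcome_link,
                 mode = mode,
                 seed = if (!is.null(seed)) as.integer(seed)),
            class = "cohort_spec")
}

empty_assessments <- function() {
  data.frame(subject_id = character(), sex = character(),
             weight_loss_kg = numeric(), weight_loss_pct = numeric(),
             exhaustion = logical(), chair_rise_unable = logical(),
             grip_kg = numeric(), gait_speed_mps = numeric(),
             non_ambulatory = logical(), adl_deterioration = logical())
}

#' Generate a synthetic cohort
#'
#' Draws assessments, acoustic features and outcomes per the
#' [cohort_spec()] mode. Deterministic under the spec's seed.
#'
#' @param spec a [cohort_spec()].
#' @return a list of class `synthetic_cohort` with `data.frame`s
#'   `assessments`, `features` (`subject_id`, `A1`..`A4`), and `outcomes`
#'   (mode 1: the scored phenotype table; mode 2: `subject_id` plus one
#'   logical column per `outcome_link` entry), plus `mode` and `seed`.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop("generate_cohort: need a cohort_spec")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_subjects
  if (n == 0L) {
    warning("generate_cohort: n_subjects = 0; returning empty tables")
    feats <- data.frame(subject_id = character(), A1 = numeric(),
                        A2 = numeric(), A3 = numeric(), A4 = numeric())
    out <- if (spec$mode == 1L) score_phenotypes(empty_assessments()) else
      data.frame(subject_id = character())
    return(structure(list(assessments = empty_assessments(), features = feats,
                          outcomes = out, mode = spec$mode, seed = spec$seed),
                     class = "synthetic_cohort"))
  }
  ad <- spec$assessment_distributions
  subject_id <- sprintf("S%04d", seq_len(n))
  sex <- ifelse(runif(n) < ad$p_female, "female", "male")
  body_weight <- pmax(30, rnorm(n, ad$body_weight$mean, ad$body_weight$sd))
  lost <- runif(n) < ad$weight_loss$p_loss
  weight_loss_kg <- ifelse(lost, rlnorm(n, ad$weight_loss$kg_meanlog,
                                        ad$weight_loss$kg_sdlog), 0)
  weight_loss_kg <- pmin(weight_loss_kg, 0.25 * body_weight)  # physiologic cap
  weight_loss_pct <- 100 * weight_loss_kg / body_weight
  grip_mu <- ifelse(sex == "male", ad$grip$male_mean, ad$grip$female_mean)
  grip_sd <- ifelse(sex == "male", ad$grip$male_sd, ad$grip$female_sd)
  assessments <- data.frame(
    subject_id = subject_id, sex = sex,
    weight_loss_kg = weight_loss_kg, weight_loss_pct = weight_loss_pct,
    exhaustion = runif(n) < ad$p_exhaustion,
    chair_rise_unable = runif(n) < ad$p_chair_rise_unable,
    grip_kg = pmax(0, rnorm(n, grip_mu, grip_sd)),
    gait_speed_mps = pmax(0, rnorm(n, ad$gait$mean, ad$gait$sd)),
    non_ambulatory = runif(n) < ad$p_non_ambulatory,
    adl_deterioration = runif(n) < ad$p_adl_deterioration
  )
  phen <- score_phenotypes(assessments)
  fm <- spec$feature_model
  if (spec$mode == 1L) {
    ebf_f <- as.integer(phen$ebf_status == "frail")
    sbf_f <- as.integer(phen$sbf_status == "frail")
    feats <- data.frame(subject_id = subject_id)
    for (nm in names(fm)) {
      m <- fm[[nm]]
      feats[[nm]] <- m$intercept + m$ebf_frail * ebf_f + m$sbf_frail * sbf_f +
        rnorm(n, 0, m$sd)
    }
    for (nm in intersect(c("A1", "A4"), names(feats)))
      feats[[nm]] <- pmin(1, pmax(0, feats[[nm]]))
    for (nm in intersect(c("A2", "A3"), names(feats)))
      feats[[nm]] <- pmax(0, feats[[nm]])
    outcomes <- phen
  } else {
    feats <- data.frame(subject_id = subject_id)
    for (nm in names(fm))
      feats[[nm]] <- fm[[nm]]$intercept + rnorm(n, 0, fm[[nm]]$sd)
    outcomes <- data.frame(subject_id = subject_id)
    for (onm in names(spec$outcome_link)) {
      link <- spec$outcome_link[[onm]]
      eta <- rep(link$intercept, n)
      for (fn in names(link$coefs)) eta <- eta + link$coefs[[fn]] * feats[[fn]]
      outcomes[[onm]] <- rbinom(n, 1L, plogis(eta)) == 1L
    }
  }
  structure(list(assessments = assessments, features = feats,
                 outcomes = outcomes, mode = spec$mode, seed = spec$seed),
            class = "synthetic_cohort")
}
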