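#' Frailty phenotype scoring
#'
#' Two rule-based frailty indices are scored from a clinical assessment, plus
#' two hybrid phenotypes and a four-category outcome:
#'
#' * **EBF** (energy-based frailty), 2 criteria: unintentional weight loss
#'   (>= 4.5 kg or > 5% of body weight in the previous year) and exhaustion
#'   ("less energy to do the things you want" in the last week). 2 criteria
#'   met = frail, 1 = prefrail, 0 = robust.
#' * **SBF** (sarcopenia-based frailty), 4 criteria: low resistance (unable
#'   to rise from a chair 5 consecutive times without using the arms), low
#'   grip strength (dominant hand < 28 kg for men, < 18 kg for women), low
#'   walking ability (gait speed < 1.0 m/s, or unable to walk, e.g.
#'   wheelchair users), and low physical activity (deterioration in basic
#'   activities of daily living in the last year). >= 3 criteria met =
#'   frail, 1-2 = prefrail, 0 = robust.
#' * **HBF-E**: frail on EBF while at least prefrail on SBF.
#' * **HBF-S**: frail on SBF while at least prefrail on EBF.
#' * **four-category outcome**: nonfrail / EBF-only / SBF-only / both,
#'   by which of the two indices score frail.
#'
#' Boundary conventions (fixed, visible in the cutoff arguments): weight
#' loss in kg is inclusive at 4.5 ("at least"), the percentage is strict at
#' 5 (">"), grip cutoffs are strict ("low" strictly below 28/18 kg), gait is
#' strict below 1.0 m/s. Missing required items yield an indeterminate (NA)
#' status; a missing gait speed with `non_ambulatory = TRUE` is not missing
#' (non-ambulatory subjects count as low mobility).
#'
#' @param weight_loss_kg kg lost in the previous year (>= 0), or `NA`.
#' @param weight_loss_pct percent of body weight lost, or `NA`.
#' @param exhaustion logical: "yes" to the energy question.
#' @param sex `"male"` or `"female"` (grip cutoffs differ).
#' @param chair_rise_unable logical: cannot rise 5 consecutive times.
#' @param grip_kg dominant-hand grip strength in kg, or `NA`.
#' @param gait_speed_mps gait speed in m/s, or `NA`.
#' @param non_ambulatory logical: cannot perform the walking test.
#' @param adl_deterioration logical: deterioration in activities of daily
#'   living in the last year.
#' @param kg_cutoff,pct_cutoff weight-loss criterion cutoffs.
#' @param grip_cutoff_male_kg,grip_cutoff_female_kg grip criteria cutoffs.
#' @param gait_cutoff_mps slow-gait cutoff.
#' @return for `score_ebf()`/`score_sbf()`: a list with vectors
#'   `criteria_met` (integer, `NA` if indeterminate) and `status` (factor
#'   robust/prefrail/frail, `NA` if indeterminate). All arguments are
#'   vectorized over subjects.
#' @name phenotype-scoring
NULL

status_levels <- c("robust", "prefrail", "frail")
four_category_levels <- c("nonfrail", "EBF-only", "SBF-only", "both")

as_status <- function(i, frail_at) {
  factor(ifelse(is.na(i), NA_character_,
                ifelse(i >= frail_at, "frail",
                       ifelse(i >= 1L, "prefrail", "robust"))),
         levels = status_levels)
}

#' @rdname phenotype-scoring
#' @export
score_ebf <- function(weight_loss_kg, weight_loss_pct, exhaustion,
                      kg_cutoff = 4.5, pct_cutoff = 5) {
  n <- max(length(weight_loss_kg), length(weight_loss_pct), length(exhaustion))
  weight_loss_kg <- rep_len(as.numeric(weight_loss_kg), n)
  weight_loss_pct <- rep_len(as.numeric(weight_loss_pct), n)
  exhaustion <- rep_len(as.logical(exhaustion), n)
  if (any(weight_loss_kg < 0, na.rm = TRUE) ||
      any(weight_loss_pct < 0 | weight_loss_pct > 100, na.rm = TRUE))
    stop("score_ebf: weight loss must be >= 0 (kg) and in [0, 100] (%)")
  # NA-propagating OR: TRUE | NA is TRUE, FALSE | NA is NA
  weight_crit <- (weight_loss_kg >= kg_cutoff) | (weight_loss_pct > pct_cutoff)
  met <- as.integer(weight_crit) + as.integer(exhaustion)
  list(criteria_met = met, status = as_status(met, frail_at = 2L))
}

#' @rdname phenotype-scoring
#' @export
score_sbf <- function(sex, chair_rise_unable, grip_kg, gait_speed_mps,
                      non_ambulatory, adl_deterioration,
                      grip_cutoff_male_kg = 28, grip_cutoff_female_kg = 18,
                      gait_cutoff_mps = 1.0) {
  n <- max(length(sex), length(chair_rise_unable), length(grip_kg),
           length(gait_speed_mps), length(non_ambulatory),
           length(adl_deterioration))
  sex <- rep_len(as.character(sex), n)
  chair_rise_unable <- rep_len(as.logical(chair_rise_unable), n)
  grip_kg <- rep_len(as.numeric(grip_kg), n)
  gait_speed_mps <- rep_len(as.numeric(gait_speed_mps), n)
  non_ambulatory <- rep_len(as.logical(non_ambulatory), n)
  adl_deterioration <- rep_len(as.logical(adl_deterioration), n)
  if (!all(sex %in% c("male", "female") | is.na(sex)))
    stop("score_sbf: sex must be 'male' or 'female'")
  if (any(grip_kg < 0, na.rm = TRUE) || any(gait_speed_mps < 0, na.rm = TRUE))
    stop("score_sbf: grip_kg and gait_speed_mps must be >= 0")
  cutoff <- ifelse(sex == "male", grip_cutoff_male_kg, grip_cutoff_female_kg)
  grip_crit <- grip_kg < cutoff
  # non-ambulatory subjects are low-mobility even with no gait measurement
  walk_crit <- non_ambulatory | (gait_speed_mps < gait_cutoff_mps)
  met <- as.integer(chair_rise_unable) + as.integer(grip_crit) +
    as.integer(walk_crit) + as.integer(adl_deterioration)
  list(criteria_met = met, status = as_status(met, frail_at = 3L))
}

#' Derive the hybrid phenotypes and four-category outcome
#'
#' @param ebf_status,sbf_status factors (or strings) in
#'   robust/prefrail/frail, vectorized; `NA` for indeterminate subjects.
#' @return a list with logical vectors `hbf_e`, `hbf_s` and the factor
#'   `four_category` (levels nonfrail, EBF-only, SBF-only, both).
#'   Indeterminate inputs give indeterminate outputs.
#' @export
derive_hybrids <- function(ebf_status, sbf_status) {
  e <- factor(as.character(ebf_status), levels = status_levels)
  s <- factor(as.character(sbf_status), levels = status_levels)
  if (length(e) != length(s))
    stop("derive_hybrids: statuses must have equal length")
  e_frail <- e == "frail"
  s_frail <- s == "frail"
  hbf_e <- e_frail & s %in% c("prefrail", "frail") & !is.na(s)
  hbf_s <- s_frail & e %in% c("prefrail", "frail") & !is.na(e)
  hbf_e[is.na(e_frail) | is.na(s_frail)] <- NA
  hbf_s[is.na(e_frail) | is.na(s_frail)] <- NA
  four <- ifelse(is.na(e_frail) | is.na(s_frail), NA_character_,
                 ifelse(e_frail & s_frail, "both",
                        ifelse(e_frail, "EBF-only",
                               ifelse(s_frail, "SBF-only", "nonfrail"))))
  list(hbf_e = hbf_e, hbf_s = hbf_s,
       four_category = factor(four, levels = four_category_levels))
}

#' Score all phenotypes for an assessment table
#'
#' Applies [score_ebf()], [score_sbf()] and [derive_hybrids()] to a
#' one-row-per-subject assessment table.
#'
#' @param assessments `data.frame` with columns `subject_id`, `sex`,
#'   `weight_loss_kg`, `weight_loss_pct`, `exhaustion`,
#'   `chair_rise_unable`, `grip_kg`, `gait_speed_mps`, `non_ambulatory`,
#'   `adl_deterioration`.
#' @param ... cutoff overrides passed to the scorers.
#' @return `data.frame` with `subject_id`, criteria counts, EBF/SBF
#'   statuses, `hbf_e`, `hbf_s`, and `four_category`.
#' @export
score_phenotypes <- function(assessments, ...) {
  required <- c("subject_id", "sex", "weight_loss_kg", "weight_loss_pct",
                "exhaustion", "chair_rise_unable", "grip_kg",
                "gait_speed_mps", "non_ambulatory", "adl_deterioration")
  missing_cols <- setdiff(required, names(assessments))
  if (length(missing_cols))
    stop("score_phenotypes: assessment table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  dots <- list(...)
  ebf_args <- dots[names(dots) %in% c("kg_cutoff", "pct_cutoff")]
  sbf_args <- dots[names(dots) %in% c("grip_cutoff_male_kg",
                                      "grip_cutoff_female_kg",
                                      "gait_cutoff_mps")]
  ebf <- do.call(score_ebf, c(list(assessments$weight_loss_kg,
                                   assessments$weight_loss_pct,
                                   assessments$exhaustion), ebf_args))
  sbf <- do.call(score_sbf, c(list(assessments$sex,
                                   assessments$chair_rise_unable,
                                   assessments$grip_kg,
                                   assessments$gait_speed_mps,
                                   assessments$non_ambulatory,
                                   assessments$adl_deterioration), sbf_args))
  hy <- derive_hybrids(ebf$status, sbf$status)
  data.frame(subject_id = assessments$subject_id,
             ebf_criteria_met = ebf$criteria_met, ebf_status = ebf$status,
             sbf_criteria_met = sbf$criteria_met, sbf_status = sbf$status,
             hbf_e = hy$hbf_e, hbf_s = hy$hbf_s,
             four_category = hy$four_category)
}
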