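# Evaluation of recommendations against retrospective clinical decisions:
# RMSE similarity score and the outcome-based self-evaluation scheme tagging
# each recommendation Good / Bad / Unsure from the observed (LC, RP2)
# outcome and the dose difference delta = AI dose - clinical dose.

#' Similarity score (RMSE) between AI and clinical doses
#'
#' `sqrt(mean((ai - clinical)^2))` in Gy/frac, computed between the
#' ensemble-averaged recommendations and the retrospective clinical
#' decisions. Zero only for identical vectors; note a score of exactly 0 is
#' not the goal — the premise of response adaptation is that current
#' practice is suboptimal — but a low score indicates recommendations close
#' to clinically validated practice.
#'
#' @param ai_doses,clinical_doses Equal-length nonempty numeric vectors
#'   (Gy/frac).
#' @return Scalar RMSE (Gy/frac).
#' @export
similarity_score <- function(ai_doses, clinical_doses) {
  if (length(ai_doses) == 0L || length(ai_doses) != length(clinical_doses)) {
    stop_domain("dose vectors must be nonempty and of equal length")
  }
  sqrt(mean((ai_doses - clinical_doses)^2))
}

#' Self-evaluation of a recommendation from outcome and dose difference
#'
#' Tags a recommendation Good / Bad / Unsure given the observed binary
#' outcomes and `delta` = AI dose minus clinical dose (Gy/frac), assuming
#' dose escalation raises both tumor control and toxicity risk:
#'
#' * `LC = 0, RP2 = 0`: escalation would have helped — Good iff
#'   `delta > 0`.
#' * `LC = 0, RP2 = 1`: direction unclear, but toxicity caps the dose —
#'   Good iff `delta < -0.1` (a 0.1 Gy/frac cushion below the clinical
#'   dose), else Bad.
#' * `LC = 1, RP2 = 0`: the desirable outcome; Good within the
#'   `|delta| <= 0.5` margin of the clinical dose, Unsure outside it.
#' * `LC = 1, RP2 = 1`: de-escalation would have helped — Good iff
#'   `delta < 0`.
#'
#' The two branches for each outcome pair partition the real line, so every
#' input receives exactly one tag.
#'
#' @param lc,rp2 Binary outcomes (vectorized).
#' @param delta Dose difference, AI minus clinical (Gy/frac).
#' @return Character vector over `"Good"`, `"Bad"`, `"Unsure"`.
#' @examples
#' self_evaluate(0, 0, 0.3)  # Good
#' self_evaluate(1, 0, 0.6)  # Unsure
#' @export
self_evaluate <- function(lc, rp2, delta) {
  k <- max(length(lc), length(rp2), length(delta))
  lc <- rep_len(lc, k)
  rp2 <- rep_len(rp2, k)
  delta <- rep_len(delta, k)
  if (!all(lc %in% c(0, 1)) || !all(rp2 %in% c(0, 1))) {
    stop_domain("lc and rp2 must be binary 0/1")
  }
  if (any(!is.finite(delta))) stop_domain("delta must be finite")
  out <- character(k)
  g00 <- lc == 0 & rp2 == 0
  g01 <- lc == 0 & rp2 == 1
  g10 <- lc == 1 & rp2 == 0
  g11 <- lc == 1 & rp2 == 1
  out[g00] <- ifelse(delta[g00] > 0, "Good", "Bad")
  out[g01] <- ifelse(delta[g01] < -0.1, "Good", "Bad")
  out[g10] <- ifelse(abs(delta[g10]) <= 0.5, "Good", "Unsure")
  out[g11] <- ifelse(delta[g11] < 0, "Good", "Bad")
  out
}

#' Evaluate AI recommendations over a cohort
#'
#' Joins recommendations to patient records by id, applies
#' [self_evaluate()] to each patient, and reports the Good/Bad/Unsure
#' percentages together with the similarity score. A clinical-decision
#' baseline is included, scored from outcomes alone: the clinical dose is
#' Good exactly when the observed outcome was the desirable `(LC = 1,
#' RP2 = 0)`, else Bad (the dose-difference rules cannot apply to the
#' clinical decision against itself).
#'
#' @param cohort Cohort data frame with `patient_id`, `clinical_dose`, `lc`,
#'   `rp2`.
#' @param recommendations Data frame with `patient_id` and `dose_mean`
#'   (ensemble-averaged AI dose, Gy/frac), as from [recommend_dose()].
#' @return A list of class `eval_report`: per-patient table, AI and clinical
#'   percentage breakdowns (full precision and integer-rounded), and
#'   `similarity` (Gy/frac).
#' @export
evaluate_cohort <- function(cohort, recommendations) {
  if (nrow(recommendations) == 0L) stop_domain("recommendation set is empty")
  if (!"patient_id" %in% names(recommendations)) {
    stop_domain("recommendations must carry patient_id")
  }
  dose_col <- if ("dose_mean" %in% names(recommendations)) "dose_mean" else "dose"
  if (!dose_col %in% names(recommendations)) {
    stop_domain("recommendations must carry a dose_mean (or dose) column")
  }
  idx <- match(cohort$patient_id, recommendations$patient_id)
  if (any(is.na(idx)) || nrow(recommendations) != nrow(cohort)) {
    stop_domain("patient ids of cohort and recommendations do not match")
  }
  ai <- recommendations[[dose_col]][idx]
  delta <- ai - cohort$clinical_dose
  tag <- self_evaluate(cohort$lc, cohort$rp2, delta)
  clinical_tag <- ifelse(cohort$lc == 1 & cohort$rp2 == 0, "Good", "Bad")
  pct <- function(tags) {
    p <- 100 * vapply(c("Good", "Bad", "Unsure"),
                      function(lv) mean(tags == lv), numeric(1))
    names(p) <- c("Good", "Bad", "Unsure")
    p
  }
  structure(
    list(
      table = data.frame(
        patient_id = cohort$patient_id, ai_dose = ai,
        clinical_dose = cohort$clinical_dose, delta = delta,
        lc = cohort$lc, rp2 = cohort$rp2, tag = tag,
        clinical_tag = clinical_tag
      ),
      ai_percent = pct(tag),
      ai_percent_rounded = round(pct(tag)),
      clinical_percent = pct(clinical_tag),
      clinical_percent_rounded = round(pct(clinical_tag)),
      similarity = similarity_score(ai, cohort$clinical_dose),
      n = nrow(cohort)
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d patients\n", x$n))
  cat(sprintf("  similarity score (RMSE): %.3f Gy/frac\n", x$similarity))
  m <- rbind(AI = x$ai_percent, Clinical = x$clinical_percent)
  cat("  self-evaluation (% of patients):\n")
  print(round(m, 1))
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report An [evaluate_cohort()] report.
#' @param path Output path.
#' @param meta Optional named list merged into the JSON (e.g. config hash
#'   and seed).
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path, meta = NULL) {
  payload <- c(meta, list(
    n = report$n,
    similarity_gy_frac = report$similarity,
    ai_percent = as.list(report$ai_percent),
    clinical_percent = as.list(report$clinical_percent),
    patients = report$table
  ))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
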