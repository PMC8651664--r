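# Patient data model: the five-feature state (IP10 cytokine, GLSZM-ZSV PET
# radiomics, tumor gEUD, lung gEUD, cxcr1-Rs2234671 allele count), longitudinal
# records, synthetic cohort generation and CSV round-trip.

#' Canonical cohort CSV column order
#' @export
cohort_columns <- c(
  "patient_id",
  "ip10_pre", "zsv_pre", "tumor_geud_pre", "lung_geud_pre", "genotype",
  "ip10_mid", "zsv_mid", "tumor_geud_mid", "lung_geud_mid",
  "clinical_dose", "lc", "rp2"
)

#' Zone-size variance of a gray-level size zone matrix
#'
#' Computes the ZSV radiomics feature from a GLSZM whose rows index gray
#' levels `i` and whose columns index zone sizes `j`. Under the default
#' probability normalization the matrix is converted to a zone probability
#' distribution `p(i, j) = counts / sum(counts)` and the feature is the
#' variance of the zone size `j` under that distribution:
#' `sum(p * (j - mu)^2)` with `mu = sum(j * p)`. The `"printed"` variant keeps
#' a `1 / (N_g * L_z)` prefactor in place of probability normalization,
#' computing `mean((j * p - mean(j * p))^2)` over all cells; it is retained
#' for comparison only and is not a variance of the zone-size distribution.
#'
#' @param counts Nonnegative numeric matrix of zone counts
#'   (gray level x zone size).
#' @param normalization `"probability"` (default) or `"printed"`.
#' @return Nonnegative scalar.
#' @examples
#' compute_zsv(matrix(c(1, 1, 1, 1), 2, 2)) # 0.25
#' @export
compute_zsv <- function(counts, normalization = c("probability", "printed")) {
  normalization <- match.arg(normalization)
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop_domain("counts must be a numeric matrix")
  }
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop_domain("GLSZM entries must be finite and nonnegative")
  }
  total <- sum(counts)
  if (total <= 0) stop_domain("GLSZM must contain at least one positive entry")
  p <- counts / total
  j <- matrix(rep(seq_len(ncol(counts)), each = nrow(counts)), nrow = nrow(counts))
  if (normalization == "probability") {
    mu <- sum(j * p)
    sum(p * (j - mu)^2)
  } else {
    jp <- j * p
    n_cells <- length(p)
    mu_j <- sum(jp) / n_cells
    sum((jp - mu_j)^2) / n_cells
  }
}

#' Read a GLSZM from a dense CSV of nonnegative integers
#'
#' @param path Path to a headerless CSV; rows are gray levels, columns zone
#'   sizes.
#' @return Numeric matrix.
#' @export
read_glszm <- function(path) {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- "numeric"
  if (any(is.na(m))) stop_schema("non-numeric entries in GLSZM file ", path)
  m
}

#' Configuration for the synthetic cohort generator
#'
#' Defines the marginal distributions of the five patient features at the
#' baseline and mid-treatment (post two-thirds) observation points, the
#' clinical dose distribution for the final treatment third, and the
#' dose-response parameters used to label binary local control (LC) and
#' grade 2+ pneumonitis (RP2) outcomes. Labels are drawn from logistic
#' dose-response curves on the end-of-treatment tumor and lung gEUD, so both
#' P(LC = 1) and P(RP2 = 1) increase with the delivered dose per fraction.
#'
#' @param n_patients Number of patients to generate.
#' @param seed Integer RNG seed.
#' @param ip10_meanlog,ip10_sdlog Log-normal parameters for baseline IP10.
#' @param zsv_meanlog,zsv_sdlog Log-normal parameters for baseline GLSZM-ZSV.
#' @param tumor_geud_mean,tumor_geud_sd Truncated-normal parameters (Gy) for
#'   baseline tumor gEUD, truncated to positive values.
#' @param lung_geud_mean,lung_geud_sd Same for baseline lung gEUD.
#' @param genotype_freq Allele frequency of the cxcr1-Rs2234671 variant;
#'   genotype is the allele count `Binomial(2, genotype_freq)`.
#' @param mid_tumor_gain,mid_lung_gain Mean gEUD increment (Gy) accrued over
#'   the first two treatment thirds.
#' @param biomarker_logratio_sd Log-scale noise on the mid/pre ratio of IP10
#'   and ZSV.
#' @param dose_mean,dose_sd Truncated-normal parameters (Gy/frac) for the
#'   clinical dose of the final third.
#' @param dose_min,dose_max Support of the clinical dose (Gy/frac).
#' @param kappa_tumor,kappa_lung gEUD accrual constants for the final third
#'   (Gy per unit of `d * (1 + d / ab)`).
#' @param mu_lc,t_lc Logistic midpoint (Gy) and negative slope (Gy) of the
#'   local-control dose-response on end-of-treatment tumor gEUD.
#' @param mu_rp2,t_rp2 Same for pneumonitis on lung gEUD.
#' @param genotype_mu_shift Shift (Gy) of the pneumonitis midpoint per risk
#'   allele (negative = more radiosensitive).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 200L,
                          seed = 1L,
                          ip10_meanlog = log(150), ip10_sdlog = 0.5,
                          zsv_meanlog = log(50), zsv_sdlog = 0.6,
                          tumor_geud_mean = 25, tumor_geud_sd = 6,
                          lung_geud_mean = 6, lung_geud_sd = 2,
                          genotype_freq = 0.3,
                          mid_tumor_gain = 18, mid_lung_gain = 6,
                          biomarker_logratio_sd = 0.2,
                          dose_mean = 2.4, dose_sd = 0.7,
                          dose_min = 1.0, dose_max = 4.1,
                          kappa_tumor = 10, kappa_lung = 3,
                          mu_lc = 60, t_lc = -5,
                          mu_rp2 = 25, t_rp2 = -4,
                          genotype_mu_shift = -1.5) {
  if (n_patients < 0) stop_config("n_patients must be >= 0")
  if (genotype_freq < 0 || genotype_freq > 1) {
    stop_config("genotype_freq must lie in [0, 1]")
  }
  for (nm in c("ip10_sdlog", "zsv_sdlog", "tumor_geud_sd", "lung_geud_sd",
               "biomarker_logratio_sd", "dose_sd")) {
    if (get(nm) < 0) stop_config(nm, " must be nonnegative")
  }
  if (dose_min >= dose_max) stop_config("dose_min must be below dose_max")
  if (t_lc >= 0 || t_rp2 >= 0) {
    stop_config("t_lc and t_rp2 must be negative so probabilities rise with dose")
  }
  cfg <- as.list(environment())
  cfg$n_patients <- as.integer(n_patients)
  cfg$seed <- as.integer(seed)
  class(cfg) <- "cohort_config"
  cfg
}

rtruncnorm_pos <- function(n, mean, sd, lower = .Machine$double.eps) {
  # rejection sampling; distributions here are far from the boundary
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lower)
  while (length(bad) > 0L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lower]
  }
  x
}

#' Generate a synthetic longitudinal NSCLC cohort
#'
#' Draws baseline and mid-treatment patient states, a clinical dose per
#' fraction for the final treatment third, and binary LC / RP2 outcomes from
#' logistic dose-response curves (see [cohort_config()]). Deterministic given
#' `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A data frame with the columns in [cohort_columns].
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) {
    stop_config("config must be created with cohort_config()")
  }
  n <- config$n_patients
  if (n == 0L) {
    df <- as.data.frame(
      stats::setNames(rep(list(numeric(0)), length(cohort_columns)), cohort_columns)
    )
    df$patient_id <- character(0)
    return(df[cohort_columns])
  }
  set.seed(config$seed)
  ip10_pre <- stats::rlnorm(n, config$ip10_meanlog, config$ip10_sdlog)
  zsv_pre <- stats::rlnorm(n, config$zsv_meanlog, config$zsv_sdlog)
  tumor_pre <- rtruncnorm_pos(n, config$tumor_geud_mean, config$tumor_geud_sd)
  lung_pre <- rtruncnorm_pos(n, config$lung_geud_mean, config$lung_geud_sd)
  genotype <- stats::rbinom(n, 2L, config$genotype_freq)

  # mid-treatment state after the first two-thirds (standard fractionation)
  ip10_mid <- ip10_pre * stats::rlnorm(n, -0.1, config$biomarker_logratio_sd)
  zsv_mid <- zsv_pre * stats::rlnorm(n, -0.15, config$biomarker_logratio_sd)
  tumor_mid <- tumor_pre +
    rtruncnorm_pos(n, config$mid_tumor_gain, config$mid_tumor_gain * 0.15)
  lung_mid <- lung_pre +
    rtruncnorm_pos(n, config$mid_lung_gain, config$mid_lung_gain * 0.2)

  dose <- pmin(pmax(stats::rnorm(n, config$dose_mean, config$dose_sd),
                    config$dose_min), config$dose_max)

  g6_tumor <- tumor_mid + config$kappa_tumor * dose * (1 + dose / 10)
  g6_lung <- lung_mid + config$kappa_lung * dose * (1 + dose / 4)
  p_lc <- stats::plogis((config$mu_lc - g6_tumor) / config$t_lc)
  mu_rp2_i <- config$mu_rp2 + config$genotype_mu_shift * genotype
  p_rp2 <- stats::plogis((mu_rp2_i - g6_lung) / config$t_rp2)
  lc <- stats::rbinom(n, 1L, p_lc)
  rp2 <- stats::rbinom(n, 1L, p_rp2)

  data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    ip10_pre = ip10_pre, zsv_pre = zsv_pre,
    tumor_geud_pre = tumor_pre, lung_geud_pre = lung_pre,
    genotype = as.integer(genotype),
    ip10_mid = ip10_mid, zsv_mid = zsv_mid,
    tumor_geud_mid = tumor_mid, lung_geud_mid = lung_mid,
    clinical_dose = dose,
    lc = as.integer(lc), rp2 = as.integer(rp2),
    stringsAsFactors = FALSE
  )
}

#' Validate a cohort data frame against the canonical schema
#'
#' @param df Data frame to validate.
#' @return The data frame, invisibly, with columns in canonical order (an
#'   optional `is_synthetic` flag column is preserved).
#' @export
validate_cohort <- function(df) {
  missing <- setdiff(cohort_columns, names(df))
  if (length(missing) > 0L) {
    stop_schema("cohort is missing column(s): ", paste(missing, collapse = ", "))
  }
  num_cols <- setdiff(cohort_columns, c("patient_id", "genotype", "lc", "rp2"))
  for (cl in num_cols) {
    bad <- which(!is.finite(as.numeric(df[[cl]])))
    if (length(bad) > 0L) {
      stop_schema("non-finite value in column ", cl, " at row ", bad[1L])
    }
  }
  for (cl in c("lc", "rp2")) {
    bad <- which(!(df[[cl]] %in% c(0L, 1L)))
    if (length(bad) > 0L) {
      stop_schema("column ", cl, " must be 0/1; offending row ", bad[1L])
    }
  }
  bad_geno <- which(!(df$genotype %in% c(0L, 1L, 2L)))
  if (length(bad_geno) > 0L) {
    stop_schema("genotype must be an allele count in {0,1,2}; offending row ",
                bad_geno[1L])
  }
  bad_dose <- which(df$clinical_dose <= 0)
  if (length(bad_dose) > 0L) {
    stop_schema("clinical_dose must be positive; offending row ", bad_dose[1L])
  }
  keep <- c(cohort_columns, intersect("is_synthetic", names(df)))
  invisible(df[keep])
}

#' Read / write a cohort CSV
#'
#' The CSV schema is fixed to [cohort_columns] (an `is_synthetic` flag column
#' emitted by the augmentation stage is also accepted). Reading validates the
#' schema and reports the first offending row on failure; writing followed by
#' reading reproduces every field up to floating-point text round-trip.
#'
#' @param path File path.
#' @param df Cohort data frame.
#' @return `read_cohort` returns the validated data frame; `write_cohort`
#'   returns `path` invisibly.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- validate_cohort(df)
  df$genotype <- as.integer(df$genotype)
  df$lc <- as.integer(df$lc)
  df$rp2 <- as.integer(df$rp2)
  df
}

#' @rdname read_cohort
#' @export
write_cohort <- function(df, path) {
  df <- validate_cohort(df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
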