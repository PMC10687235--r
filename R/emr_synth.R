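# Synthetic longitudinal EMR cohorts with a known planted logistic
# outcome model, emulating the record structure an opportunistic-CT
# cohort is built from: encounters, dated vitals/labs, coded diagnoses,
# procedures and medications, and a planted post-scan IHD outcome code.

emr_obs_names <- c("sbp", "dbp", "bmi", "total_cholesterol", "ldl",
                   "hdl", "triglycerides", "glucose", "hba1c")
emr_feature_names <- c("age", "sex_male", emr_obs_names)

#' Patient record container
#'
#' @param patient_id Character id.
#' @param scan_datetime Scan acquisition date (`Date`).
#' @param birthdate Date of birth.
#' @param sex "male" or "female".
#' @param encounters Vector of encounter `Date`s.
#' @param observations data.frame(date, name, value) of dated vitals
#'   and labs.
#' @param codes data.frame(date, system, code) with system in ICD10,
#'   CPT, DRUG.
#' @return Object of class `patient_record`.
#' @export
patient_record <- function(patient_id, scan_datetime, birthdate, sex,
                           encounters,
                           observations = data.frame(
                             date = as.Date(character()),
                             name = character(), value = numeric()),
                           codes = data.frame(
                             date = as.Date(character()),
                             system = character(), code = character())) {
  stopifnot(inherits(scan_datetime, "Date"), inherits(birthdate, "Date"))
  if (!sex %in% c("male", "female")) stop("sex must be male or female")
  encounters <- sort(as.Date(encounters))
  observations <- observations[order(observations$date,
                                     observations$name), , drop = FALSE]
  codes <- codes[order(codes$date, codes$system, codes$code), ,
                 drop = FALSE]
  if (nrow(codes) > 0 && !all(codes$system %in% c("ICD10", "CPT", "DRUG")))
    stop("code system must be ICD10, CPT or DRUG")
  structure(list(patient_id = patient_id, scan_datetime = scan_datetime,
                 birthdate = birthdate, sex = sex,
                 encounters = encounters, observations = observations,
                 codes = codes),
            class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf(
    "<patient_record> %s, %s, scan %s, %d encounters, %d obs, %d codes\n",
    x$patient_id, x$sex, format(x$scan_datetime), length(x$encounters),
    nrow(x$observations), nrow(x$codes)))
  invisible(x)
}

# Age in years at the scan date.
age_at_scan <- function(record) {
  as.numeric(record$scan_datetime - record$birthdate) / 365.25
}

#' Generate a synthetic EMR cohort with planted outcome signal
#'
#' Draws per-patient latent clinical values (vitals, lipids, glycemia)
#' from population-plausible distributions, emits dated noisy
#' measurements of them inside the pre-scan year (whole series dropped
#' with probability `missingness`), assigns diagnosis / procedure /
#' medication codes from a toy ontology with probabilities tied to the
#' latent values (e.g. hypertension codes track blood pressure), and
#' draws the binary IHD outcome from a logistic model on the
#' standardized latent features with the intercept calibrated to the
#' target prevalence.  Positive patients receive an ischemic heart
#' disease ICD10 code (I20-I25) at a random date within the horizon, so
#' the downstream labeling and inclusion machinery can run end to end.
#' Every record has at least one encounter in the pre-scan year and
#' follow-up encounters past the horizon.  Outcome draws use an RNG
#' stream separate from record generation.
#'
#' @param spec A [cohort_spec]; coefficient names must be among `age`,
#'   `sex_male`, `sbp`, `dbp`, `bmi`, `total_cholesterol`, `ldl`,
#'   `hdl`, `triglycerides`, `glucose`, `hba1c`.
#' @param missingness Probability that a lab/vital series is absent
#'   entirely (0 = every series observed).
#' @param horizon_years Outcome horizon (1 or 5).
#' @return List with `records` (list of [patient_record]), `labels`,
#'   `linear_predictor`, `coefficients`, `intercept`, and `truth` (the
#'   latent feature data.frame).
#' @export
make_emr_cohort <- function(spec, missingness = 0.2, horizon_years = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  beta <- spec$outcome_coefficients
  bad <- setdiff(names(beta), emr_feature_names)
  if (length(bad) > 0)
    stop("unknown EMR feature(s) in outcome_coefficients: ",
         paste(bad, collapse = ", "))
  if (missingness < 0 || missingness > 1)
    stop("missingness must be in [0, 1]")
  n <- spec$n_patients
  old <- .Random.seed_safe_set(spec$seed)
  on.exit(.Random.seed_safe_restore(old), add = TRUE)

  scan <- as.Date("2016-01-01") + sample.int(730, n, replace = TRUE)
  age <- pmin(90, pmax(18, stats::rnorm(n, 52, 17)))
  sex_male <- stats::rbinom(n, 1, 0.45)
  truth <- data.frame(
    age = age, sex_male = sex_male,
    sbp = stats::rnorm(n, 125, 18), dbp = stats::rnorm(n, 75, 12),
    bmi = pmax(15, stats::rnorm(n, 27, 5)),
    ldl = pmax(40, stats::rnorm(n, 110, 30)),
    hdl = pmax(20, stats::rnorm(n, 50, 15)),
    triglycerides = pmax(40, stats::rnorm(n, 130, 60)),
    glucose = pmax(60, stats::rnorm(n, 100, 25)),
    hba1c = pmax(4, stats::rnorm(n, 5.6, 0.8)))
  truth$total_cholesterol <- truth$ldl + truth$hdl +
    truth$triglycerides / 5

  horizon_days <- round(horizon_years * 365.25)
  records <- vector("list", n)
  for (i in seq_len(n)) {
    sd_i <- scan[i]
    # ceiling at the 18-year floor so date rounding cannot drop a
    # patient below the adult-age inclusion filter
    birth <- sd_i - max(round(truth$age[i] * 365.25), 6575)
    # encounters: guaranteed one in the prior year, a few extras, and
    # follow-up past the horizon
    enc_pre <- sd_i - c(sample.int(364, 1),
                        sample.int(364, stats::rpois(1, 3),
                                   replace = TRUE))
    enc_post <- sd_i + c(sample.int(horizon_days, 1 + stats::rpois(1, 2),
                                    replace = TRUE),
                         horizon_days + sample(5:120, 1))
    obs <- list()
    scales <- c(sbp = 6, dbp = 5, bmi = 0.8, total_cholesterol = 12,
                ldl = 8, hdl = 4, triglycerides = 20, glucose = 10,
                hba1c = 0.2)
    for (nm in emr_obs_names) {
      if (missingness > 0 && stats::runif(1) < missingness) next
      k <- 1 + stats::rpois(1, 1.5)
      obs[[nm]] <- data.frame(
        date = sd_i - sample.int(364, k, replace = TRUE),
        name = nm,
        value = round(truth[[nm]][i] + stats::rnorm(k, 0, scales[nm]), 1))
    }
    observations <- if (length(obs) > 0) do.call(rbind, obs) else
      data.frame(date = as.Date(character()), name = character(),
                 value = numeric())

    codes <- list()
    add_code <- function(system, code, day_offset = NULL) {
      d <- if (is.null(day_offset)) sd_i - sample.int(364, 1) else
        sd_i + day_offset
      codes[[length(codes) + 1L]] <<-
        data.frame(date = d, system = system, code = code)
    }
    if (stats::runif(1) < stats::plogis((truth$sbp[i] - 135) / 8)) {
      add_code("ICD10", "I10")
      if (stats::runif(1) < 0.6) add_code("DRUG", "lisinopril")
    }
    diabetic <- stats::runif(1) < stats::plogis((truth$glucose[i] - 126) / 12)
    if (diabetic) {
      add_code("ICD10", "E11.9")
      if (stats::runif(1) < 0.7) add_code("DRUG", "metformin")
    }
    if (stats::runif(1) < 0.05) add_code("ICD10", "N18.3")
    if (stats::runif(1) < 0.10) add_code("ICD10", "J45.909")
    if (stats::runif(1) < 0.15) add_code("ICD10", "R07.9")
    if (truth$ldl[i] > 130 && stats::runif(1) < 0.6)
      add_code("DRUG", "atorvastatin")
    if (stats::runif(1) < 0.08) add_code("DRUG", "furosemide")
    for (e in seq_along(enc_pre))
      if (stats::runif(1) < 0.7) add_code("CPT", "99213")
    if (stats::runif(1) < 0.4) add_code("CPT", "80061")
    if (stats::runif(1) < 0.2) add_code("CPT", "93000")
    codes_df <- if (length(codes) > 0) do.call(rbind, codes) else
      data.frame(date = as.Date(character()), system = character(),
                 code = character())

    records[[i]] <- patient_record(
      patient_id = sprintf("P%05d", i), scan_datetime = sd_i,
      birthdate = birth, sex = if (sex_male[i] == 1) "male" else "female",
      encounters = c(enc_pre, enc_post),
      observations = observations, codes = codes_df)
  }

  # outcome on its own stream
  set.seed(spec$seed + 2000003L)
  eta <- rep(0, n)
  if (length(beta) > 0) {
    xs <- scale(as.matrix(truth[, names(beta), drop = FALSE]))
    eta <- as.numeric(xs %*% beta)
  }
  eta <- eta + stats::rnorm(n, 0, spec$noise_sd)
  b0 <- calibrate_intercept(eta, spec$prevalence_target)
  y <- stats::rbinom(n, 1, stats::plogis(b0 + eta))

  ihd_codes <- c("I20.0", "I21.4", "I24.9", "I25.10")
  for (i in which(y == 1L)) {
    d <- records[[i]]$scan_datetime +
      sample(seq(30, horizon_days - 1), 1)
    extra <- data.frame(date = d, system = "ICD10",
                        code = sample(ihd_codes, 1))
    rec <- records[[i]]
    rec$codes <- rbind(rec$codes, extra)
    rec$codes <- rec$codes[order(rec$codes$date, rec$codes$system,
                                 rec$codes$code), , drop = FALSE]
    # an encounter accompanies the diagnosis
    rec$encounters <- sort(c(rec$encounters, d))
    records[[i]] <- rec
  }

  list(records = records, labels = y, linear_predictor = b0 + eta,
       coefficients = beta, intercept = b0, truth = truth)
}
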