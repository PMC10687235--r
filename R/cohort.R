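# Cohort construction (outcome labeling, inclusion filters, stratified
# splits) and the EMR-to-feature-vector pipeline.
#
# Window conventions: the history window is half-open (scan - 365 d,
# scan]; the outcome window is (scan, scan + round(horizon * 365.25) d].

HISTORY_DAYS <- 365
DEDUP_DAYS <- 182

horizon_days <- function(horizon_years) round(horizon_years * 365.25)

ihd_prefixes <- sprintf("I2%d", 0:5)

has_ihd_code <- function(codes, after, upto) {
  if (nrow(codes) == 0) return(FALSE)
  icd <- codes[codes$system == "ICD10", , drop = FALSE]
  if (nrow(icd) == 0) return(FALSE)
  is_ihd <- substr(icd$code, 1, 3) %in% ihd_prefixes
  any(is_ihd & icd$date > after & icd$date <= upto)
}

#' Label the IHD outcome of a record
#'
#' TRUE iff the record carries an ICD10 code with prefix I20-I25 dated
#' strictly after the scan and within the horizon.  Codes at or before
#' the scan do not label; they trigger exclusion upstream (see
#' [apply_inclusion_filters]).
#'
#' @param record A [patient_record].
#' @param horizon_years Outcome horizon in years (1 or 5).
#' @return Logical.
#' @export
label_outcome <- function(record, horizon_years = 1) {
  stopifnot(inherits(record, "patient_record"))
  has_ihd_code(record$codes, record$scan_datetime,
               record$scan_datetime + horizon_days(horizon_years))
}

#' Apply cohort inclusion filters
#'
#' Keeps records satisfying, in order: age at scan >= 18; no IHD
#' diagnosis at or before the scan; at least one encounter in the
#' pre-scan year; follow-up reaching the horizon (an encounter at or
#' past scan + horizon, or an IHD outcome inside the horizon); and a
#' 6-month deduplication rule -- among multiple scans of the same
#' patient, processed chronologically, a scan within 182 days of an
#' already-included scan is dropped.  Each removal is attributed to the
#' first rule it violates, so input count = included + sum of per-rule
#' drops.
#'
#' @param records List of [patient_record] objects.
#' @param horizon_years Outcome horizon in years.
#' @return List with `included` (records), `audit` (data.frame rule,
#'   n_dropped), `drops` (data.frame patient_id, scan_datetime, rule).
#' @export
apply_inclusion_filters <- function(records, horizon_years = 1) {
  rules <- c("age_under_18", "prior_ihd", "no_encounter_prior_year",
             "insufficient_followup", "duplicate_within_6mo")
  hd <- horizon_days(horizon_years)
  ord <- order(vapply(records, function(r) r$patient_id, character(1)),
               vapply(records, function(r) as.numeric(r$scan_datetime),
                      numeric(1)))
  included <- list()
  drops <- list()
  kept_scans <- list()  # per patient, included scan dates
  for (i in ord) {
    r <- records[[i]]
    scan <- r$scan_datetime
    rule <- NULL
    if (age_at_scan(r) < 18) {
      rule <- "age_under_18"
    } else if (has_ihd_code(r$codes, as.Date("0001-01-01"), scan)) {
      rule <- "prior_ihd"
    } else if (!any(r$encounters > scan - HISTORY_DAYS &
                    r$encounters <= scan)) {
      rule <- "no_encounter_prior_year"
    } else if (!(label_outcome(r, horizon_years) ||
                 (length(r$encounters) > 0 &&
                  max(r$encounters) >= scan + hd))) {
      rule <- "insufficient_followup"
    } else {
      prev <- kept_scans[[r$patient_id]]
      if (!is.null(prev) &&
          any(abs(as.numeric(scan - prev)) <= DEDUP_DAYS)) {
        rule <- "duplicate_within_6mo"
      }
    }
    if (is.null(rule)) {
      included[[length(included) + 1L]] <- r
      kept_scans[[r$patient_id]] <- c(kept_scans[[r$patient_id]], scan)
    } else {
      drops[[length(drops) + 1L]] <-
        data.frame(patient_id = r$patient_id,
                   scan_datetime = scan, rule = rule)
    }
  }
  drops_df <- if (length(drops) > 0) do.call(rbind, drops) else
    data.frame(patient_id = character(),
               scan_datetime = as.Date(character()), rule = character())
  audit <- data.frame(
    rule = rules,
    n_dropped = vapply(rules, function(r) sum(drops_df$rule == r),
                       numeric(1)))
  list(included = included, audit = audit, drops = drops_df)
}

#' Stratified train/test split
#'
#' Samples a fixed fraction of each outcome class into the test set, so
#' prevalence is equal between splits up to integer rounding;
#' deterministic given the seed.
#'
#' @param labels Binary outcome vector.
#' @param test_fraction Fraction assigned to the test set.
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, test_fraction = 0.2, seed = 1) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be in (0, 1)")
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    warning("single-class cohort: split is stratified on one class only")
  old <- .Random.seed_safe_set(seed)
  on.exit(.Random.seed_safe_restore(old), add = TRUE)
  test <- integer(0)
  for (g in sort(unique(labels))) {
    idx <- which(labels == g)
    k <- round(length(idx) * test_fraction)
    if (k > 0) test <- c(test, sort(sample(idx, k)))
  }
  test <- sort(test)
  list(train = setdiff(seq_along(labels), test), test = test)
}

#' Exponentially time-weighted average of repeated measurements
#'
#' Combines repeated pre-scan measurements into one value with weights
#' decaying in the time gap to the scan: `u_i = exp(-lambda * dt_i)`
#' (default half-life 30 days), or the inverse-time alternative
#' `u_i = 1 / (1 + dt_i)` behind `form = "inverse"`.  With `lambda = 0`
#' the result is the arithmetic mean; as `lambda` grows it approaches
#' the most recent value.
#'
#' @param values Numeric measurements.
#' @param times Measurement dates (`Date` or numeric days).
#' @param scan_time Scan date, same type as `times`; all `times` must
#'   be at or before it.
#' @param lambda Decay rate per day (>= 0).
#' @param form "exp" or "inverse".
#' @return Weighted average, or NA for an empty series.
#' @export
exp_weighted_value <- function(values, times, scan_time,
                               lambda = log(2) / 30,
                               form = c("exp", "inverse")) {
  form <- match.arg(form)
  if (length(values) == 0) return(NA_real_)
  if (length(values) != length(times))
    stop("values and times must have equal length")
  if (lambda < 0) stop("lambda must be >= 0")
  dt <- as.numeric(scan_time - times)
  if (any(dt < 0)) stop("all measurement times must be at or before scan")
  # shift by the smallest gap before exponentiating: identical weights
  # up to normalization, but immune to underflow at large lambda
  u <- if (form == "exp") exp(-lambda * (dt - min(dt))) else 1 / (1 + dt)
  sum(u * values) / sum(u)
}

#' Count measurements inside the pre-scan window
#'
#' @param times Measurement dates.
#' @param scan_time Scan date.
#' @param window_days Window length (default one year).
#' @return Integer count of measurements in (scan - window, scan].
#' @export
measurement_count <- function(times, scan_time, window_days = HISTORY_DAYS) {
  sum(times > scan_time - window_days & times <= scan_time)
}

#' Read an ontology mapping table
#'
#' TSV with columns `system` (ICD10/CPT/DRUG), `prefix`, `group` and an
#' optional description; prefixes must be unique within a system so the
#' longest-prefix match is unambiguous.
#'
#' @param path File path; default is the toy ontology shipped with the
#'   package.
#' @return data.frame with the validated map.
#' @export
read_ontology_map <- function(path = system.file("extdata",
                                                 "ontology_toy.tsv",
                                                 package = "ihdrisk")) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("system", "prefix", "group")
  if (!all(need %in% names(m)))
    stop("ontology map needs columns: ", paste(need, collapse = ", "))
  if (any(m$group == "")) stop("every mapping target must be nonempty")
  if (anyDuplicated(m[, c("system", "prefix")]) > 0)
    stop("duplicate (system, prefix) rows make matching ambiguous")
  m
}

#' Roll up codes to ontology groups
#'
#' Maps each code dated inside the pre-scan window to its group by
#' longest-prefix match within its code system (ICD10 blocks, CPT
#' groups, drug-to-ATC therapeutic subgroup) and returns occurrence
#' counts per group.  Unmapped codes are counted in the `unmapped`
#' attribute, never fatal.
#'
#' @param codes data.frame(date, system, code).
#' @param map Ontology map (see [read_ontology_map]).
#' @param scan_time Scan date; codes outside (scan - window, scan] are
#'   ignored.
#' @param window_days Window length.
#' @return Named integer vector with one entry per group in the map;
#'   attribute `unmapped` holds the count of unmatched in-window codes.
#' @export
rollup_codes <- function(codes, map, scan_time,
                         window_days = HISTORY_DAYS) {
  groups <- sort(unique(map$group))
  counts <- stats::setNames(integer(length(groups)), groups)
  unmapped <- 0L
  if (nrow(codes) > 0) {
    inwin <- codes$date > scan_time - window_days &
      codes$date <= scan_time
    codes <- codes[inwin, , drop = FALSE]
    for (i in seq_len(nrow(codes))) {
      cand <- map[map$system == codes$system[i] &
                    startsWith(codes$code[i], map$prefix), , drop = FALSE]
      if (nrow(cand) == 0) {
        unmapped <- unmapped + 1L
      } else {
        g <- cand$group[which.max(nchar(cand$prefix))]
        counts[g] <- counts[g] + 1L
      }
    }
  }
  attr(counts, "unmapped") <- unmapped
  counts
}

#' Read a Charlson comorbidity mapping table
#'
#' TSV with columns `condition`, `prefix`, `weight`: one row per ICD10
#' prefix, several rows per condition.  The shipped default follows the
#' standard ICD-10 coding of the index with the original condition
#' weights; it is editable config, not hard-coded.
#'
#' @param path File path; default is the shipped mapping.
#' @return data.frame(condition, prefix, weight).
#' @export
read_charlson_map <- function(path = system.file("extdata",
                                                 "charlson_icd10.tsv",
                                                 package = "ihdrisk")) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("condition", "prefix", "weight")
  if (!all(need %in% names(m)))
    stop("charlson map needs columns: ", paste(need, collapse = ", "))
  m$weight <- as.numeric(m$weight)
  m
}

#' Charlson comorbidity index
#'
#' Sum of condition weights over the distinct Charlson conditions
#' matched by ICD10 prefix among the record's in-window diagnosis
#' codes; each condition counts once however many codes match it.
#'
#' @param codes data.frame(date, system, code).
#' @param charlson_map Mapping table (see [read_charlson_map]).
#' @param scan_time Scan date (window (scan - window, scan]); NULL uses
#'   all codes.
#' @param window_days Window length.
#' @return Non-negative numeric index.
#' @export
charlson_index <- function(codes, charlson_map, scan_time = NULL,
                           window_days = HISTORY_DAYS) {
  if (nrow(codes) == 0) return(0)
  icd <- codes[codes$system == "ICD10", , drop = FALSE]
  if (!is.null(scan_time))
    icd <- icd[icd$date > scan_time - window_days &
                 icd$date <= scan_time, , drop = FALSE]
  if (nrow(icd) == 0) return(0)
  total <- 0
  for (cond in unique(charlson_map$condition)) {
    sub <- charlson_map[charlson_map$condition == cond, , drop = FALSE]
    hit <- any(vapply(icd$code, function(cd)
      any(startsWith(cd, sub$prefix)), logical(1)))
    if (hit) total <- total + sub$weight[1]
  }
  total
}

#' Iteratively remove highly correlated features
#'
#' Greedy deterministic rule: walk columns in their given order and
#' drop any column whose absolute Pearson correlation (pairwise
#' complete observations) with an already-kept column exceeds `r_max`
#' (strictly).  The surviving table has max pairwise |r| <= r_max;
#' zero-variance columns (correlation undefined) are kept.
#'
#' @param features data.frame or matrix of numeric features (>= 2
#'   rows).
#' @param r_max Correlation threshold (default 0.5).
#' @return List with `features` (reduced table) and `dropped`
#'   (character vector of removed column names).
#' @export
prune_correlated <- function(features, r_max = 0.5) {
  x <- as.data.frame(features)
  if (nrow(x) < 2) stop("need at least 2 rows to estimate correlations")
  num <- vapply(x, is.numeric, logical(1))
  cn <- names(x)[num]
  r <- suppressWarnings(
    stats::cor(x[cn], use = "pairwise.complete.obs"))
  kept <- character(0)
  dropped <- character(0)
  for (j in cn) {
    high <- FALSE
    if (length(kept) > 0) {
      rj <- abs(r[j, kept])
      # strict threshold with a round-off guard so an exactly-boundary
      # correlation is retained
      high <- any(!is.na(rj) & rj > r_max + 1e-12)
    }
    if (high) dropped <- c(dropped, j) else kept <- c(kept, j)
  }
  list(features = x[, setdiff(names(x), dropped), drop = FALSE],
       dropped = dropped)
}

#' Training-set medians for targeted imputation
#'
#' @param features Training data.frame.
#' @param targets Feature names to impute downstream.
#' @return Named numeric vector of medians (ignoring NA).
#' @export
train_medians <- function(features, targets) {
  stats::setNames(vapply(targets, function(t) {
    stats::median(features[[t]], na.rm = TRUE)
  }, numeric(1)), targets)
}

#' Targeted median imputation
#'
#' Imputes only the named features, using medians computed on the
#' training split; every other missing value passes through untouched
#' (the downstream learner handles them).  A target whose training
#' median is undefined (all-missing) is an error demanding an explicit
#' default.
#'
#' @param features data.frame to impute.
#' @param medians Named numeric vector from [train_medians].
#' @return Imputed data.frame.
#' @export
impute_targeted_median <- function(features, medians) {
  for (t in names(medians)) {
    if (!t %in% names(features)) stop("unknown target feature: ", t)
    if (is.na(medians[t]))
      stop("training median for '", t,
           "' is undefined (all missing); supply an explicit default")
    miss <- is.na(features[[t]])
    features[[t]][miss] <- medians[t]
  }
  features
}

#' Feature-pipeline configuration
#'
#' @param ontology_map Ontology mapping table (default shipped toy
#'   map).
#' @param charlson_map Charlson mapping table (default shipped map).
#' @param lambda Time-decay rate per day for [exp_weighted_value].
#' @param weight_form "exp" or "inverse".
#' @param obs_names Vital/lab names to featurize.
#' @return Object of class `feature_config`.
#' @export
feature_config <- function(ontology_map = read_ontology_map(),
                           charlson_map = read_charlson_map(),
                           lambda = log(2) / 30,
                           weight_form = "exp",
                           obs_names = emr_obs_names) {
  structure(list(ontology_map = ontology_map,
                 charlson_map = charlson_map, lambda = lambda,
                 weight_form = weight_form, obs_names = obs_names),
            class = "feature_config")
}

#' Build a fixed-length EMR feature vector for one record
#'
#' Deterministic composition of the feature pipeline: demographics (age
#' at scan in years, male-sex indicator; race/ethnicity is not a
#' feature), exponentially time-weighted vitals/labs plus their
#' measurement counts, ontology code roll-up counts, and the Charlson
#' index.  Missing lab series yield NA for the weighted value and 0 for
#' the count.  The name set is fixed by the config, so vectors from
#' different records always align.
#'
#' @param record A [patient_record].
#' @param config A [feature_config].
#' @return Named numeric vector with attribute `provenance` tagging
#'   each feature (demographic, vital_lab, count, icd_block, cpt_group,
#'   atc_group, charlson).
#' @export
build_feature_vector <- function(record, config = feature_config()) {
  stopifnot(inherits(record, "patient_record"),
            inherits(config, "feature_config"))
  scan <- record$scan_datetime
  obs <- record$observations
  vals <- c(age_years = age_at_scan(record),
            sex_male = as.numeric(record$sex == "male"))
  prov <- c("demographic", "demographic")
  for (nm in config$obs_names) {
    sel <- obs$name == nm & obs$date > scan - HISTORY_DAYS &
      obs$date <= scan
    series <- obs[sel, , drop = FALSE]
    w <- exp_weighted_value(series$value, series$date, scan,
                            config$lambda, config$weight_form)
    vals <- c(vals,
              stats::setNames(w, paste0(nm, "_wmean")),
              stats::setNames(nrow(series), paste0(nm, "_n")))
    prov <- c(prov, "vital_lab", "count")
  }
  map <- config$ontology_map
  sys_tag <- c(ICD10 = "icd_block", CPT = "cpt_group", DRUG = "atc_group")
  sys_prefix <- c(ICD10 = "icd_", CPT = "cpt_", DRUG = "atc_")
  for (sys in c("ICD10", "CPT", "DRUG")) {
    sub <- map[map$system == sys, , drop = FALSE]
    if (nrow(sub) == 0) next
    counts <- rollup_codes(record$codes[record$codes$system == sys, ,
                                        drop = FALSE],
                           sub, scan)
    names(counts) <- paste0(sys_prefix[sys], names(counts))
    vals <- c(vals, counts)
    prov <- c(prov, rep(sys_tag[sys], length(counts)))
  }
  vals <- c(vals, charlson = charlson_index(record$codes,
                                            config$charlson_map, scan))
  prov <- c(prov, "charlson")
  attr(vals, "provenance") <- stats::setNames(prov, names(vals))
  vals
}

#' Build the feature matrix for a cohort
#'
#' @param records List of [patient_record] objects.
#' @param config A [feature_config].
#' @return data.frame with one row per record, a `patient_id` column,
#'   and the fixed feature columns of [build_feature_vector].
#' @export
build_feature_matrix <- function(records, config = feature_config()) {
  rows <- lapply(records, build_feature_vector, config = config)
  out <- as.data.frame(do.call(rbind, rows))
  out <- cbind(patient_id = vapply(records, function(r) r$patient_id,
                                   character(1)),
               out)
  rownames(out) <- NULL
  out
}
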