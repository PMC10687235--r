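# Cohort construction and EMR feature engineering.

mk_record <- function(id = "P1", scan = as.Date("2016-06-01"),
                      age = 50, sex = "female",
                      enc_offsets = c(-100, 400),
                      codes = NULL, obs = NULL) {
  codes <- if (is.null(codes))
    data.frame(date = as.Date(character()), system = character(),
               code = character()) else codes
  obs <- if (is.null(obs))
    data.frame(date = as.Date(character()), name = character(),
               value = numeric()) else obs
  patient_record(patient_id = id, scan_datetime = scan,
                 birthdate = scan - round(age * 365.25), sex = sex,
                 encounters = scan + enc_offsets,
                 observations = obs, codes = codes)
}

icd <- function(code, scan, offset)
  data.frame(date = scan + offset, system = "ICD10", code = code)

test_that("outcome labeling keys on post-scan I20-I25 inside the horizon", {
  scan <- as.Date("2016-06-01")
  pos <- mk_record(codes = icd("I21.4", scan, 100))
  expect_true(label_outcome(pos, 1))
  late <- mk_record(codes = icd("I21.4", scan, 400))
  expect_false(label_outcome(late, 1))
  expect_true(label_outcome(late, 5))
  other <- mk_record(codes = icd("I26.0", scan, 100))
  expect_false(label_outcome(other, 1))
  prior <- mk_record(codes = icd("I25.1", scan, -50))
  expect_false(label_outcome(prior, 1))
})

test_that("inclusion filters drop one record per rule with full audit", {
  scan <- as.Date("2016-06-01")
  ok <- mk_record(id = "A")
  minor <- mk_record(id = "B", age = 15)
  prior <- mk_record(id = "C", codes = icd("I20.0", scan, -10))
  no_enc <- mk_record(id = "D", enc_offsets = c(-500, 400))
  short_fu <- mk_record(id = "E", enc_offsets = c(-100, 330))
  dup <- mk_record(id = "A", scan = scan + 90,
                   enc_offsets = c(-100, 400))
  out <- apply_inclusion_filters(list(ok, minor, prior, no_enc,
                                      short_fu, dup), 1)
  expect_equal(length(out$included), 1)
  expect_equal(out$included[[1]]$patient_id, "A")
  expect_equal(sum(out$audit$n_dropped), 5)
  expect_equal(out$audit$n_dropped[out$audit$rule == "age_under_18"], 1)
  expect_equal(out$audit$n_dropped[out$audit$rule == "prior_ihd"], 1)
  expect_equal(
    out$audit$n_dropped[out$audit$rule == "no_encounter_prior_year"], 1)
  expect_equal(
    out$audit$n_dropped[out$audit$rule == "insufficient_followup"], 1)
  expect_equal(
    out$audit$n_dropped[out$audit$rule == "duplicate_within_6mo"], 1)
  # conservation
  expect_equal(6, length(out$included) + sum(out$audit$n_dropped))
  # an 11-month-followup positive case is retained (outcome observed)
  pos_short <- mk_record(id = "F", enc_offsets = c(-100, 200),
                         codes = icd("I21.0", scan, 150))
  out2 <- apply_inclusion_filters(list(pos_short), 1)
  expect_equal(length(out2$included), 1)
})

test_that("same-patient scans seven months apart are both retained", {
  scan <- as.Date("2016-06-01")
  a <- mk_record(id = "A")
  b <- mk_record(id = "A", scan = scan + 213)
  out <- apply_inclusion_filters(list(a, b), 1)
  expect_equal(length(out$included), 2)
})

test_that("stratified split balances prevalence and is deterministic", {
  y <- rep(c(1, 0), c(25, 75))
  sp <- stratified_split(y, 0.2, seed = 3)
  expect_equal(sum(y[sp$test]), 5)
  expect_equal(length(sp$test), 20)
  expect_equal(sort(c(sp$train, sp$test)), 1:100)
  sp2 <- stratified_split(y, 0.2, seed = 3)
  expect_identical(sp, sp2)
  expect_warning(stratified_split(rep(0, 20), 0.2, seed = 1),
                 "single-class")
  # prevalence equality over many random cohorts
  set.seed(17)
  for (i in 1:100) {
    n <- sample(50:300, 1)
    yy <- rbinom(n, 1, runif(1, 0.1, 0.5))
    s <- stratified_split(yy, 0.2, seed = i)
    n_test_pos <- round(sum(yy) * 0.2)
    expect_equal(sum(yy[s$test]), n_test_pos)
  }
})

test_that("exponential time weighting follows the declared form", {
  scan <- as.Date("2016-06-01")
  expect_equal(exp_weighted_value(42, scan - 10, scan), 42)
  expect_equal(exp_weighted_value(c(10, 20, 60), scan - c(1, 5, 9), scan,
                                  lambda = 0), 30)
  lam <- log(2) / 30
  v <- exp_weighted_value(c(100, 200), scan - c(0, 30), scan, lam)
  expect_equal(v, (100 + 200 * 0.5) / 1.5, tolerance = 1e-12)
  # bounds and the large-decay limit
  set.seed(19)
  for (i in 1:20) {
    vals <- runif(5, 0, 100)
    times <- scan - sample(0:300, 5)
    w <- exp_weighted_value(vals, times, scan, runif(1, 0, 0.2))
    expect_gte(w, min(vals))
    expect_lte(w, max(vals))
    w_inf <- exp_weighted_value(vals, times, scan, lambda = 1e3)
    expect_equal(w_inf, vals[which.max(as.numeric(times))],
                 tolerance = 1e-6)
  }
  expect_true(is.na(exp_weighted_value(numeric(0), as.Date(character()),
                                       scan)))
  # inverse-time alternative
  vi <- exp_weighted_value(c(100, 200), scan - c(0, 1), scan,
                           form = "inverse")
  expect_equal(vi, (100 + 200 / 2) / 1.5)
})

test_that("measurement counts respect the one-year window", {
  scan <- as.Date("2016-06-01")
  expect_equal(measurement_count(as.Date(character()), scan), 0)
  times <- scan - c(5, 100, 300, 400, 0)
  expect_equal(measurement_count(times, scan), 4)
  expect_equal(measurement_count(scan - c(365, 366), scan), 0)
  expect_equal(measurement_count(scan - 364, scan), 1)
})

test_that("code rollups use longest-prefix matching inside the window", {
  map <- data.frame(system = c("ICD10", "ICD10", "ICD10"),
                    prefix = c("I1", "I10", "E11"),
                    group = c("cardio_other", "hypertension", "diabetes"))
  scan <- as.Date("2016-06-01")
  codes <- data.frame(
    date = scan - c(10, 20, 30, 500),
    system = "ICD10",
    code = c("I10", "I15.1", "E11.9", "I10"))
  out <- rollup_codes(codes, map, scan)
  expect_equal(unname(out["hypertension"]), 1L)  # longest prefix beats I1
  expect_equal(unname(out["cardio_other"]), 1L)  # I15.1 via I1
  expect_equal(unname(out["diabetes"]), 1L)
  expect_equal(attr(out, "unmapped"), 0L)
  # repeated code counts twice; out-of-window ignored; unmapped logged
  codes2 <- data.frame(date = scan - c(1, 2, 3),
                       system = "ICD10",
                       code = c("I10", "I10", "Z99.9"))
  out2 <- rollup_codes(codes2, map, scan)
  expect_equal(unname(out2["hypertension"]), 2L)
  expect_equal(attr(out2, "unmapped"), 1L)
  empty <- rollup_codes(codes2[0, ], map, scan)
  expect_true(all(empty == 0L))
})

test_that("the shipped ontology map loads and is unambiguous", {
  map <- read_ontology_map()
  expect_true(all(c("system", "prefix", "group") %in% names(map)))
  expect_equal(anyDuplicated(map[, c("system", "prefix")]), 0)
})

test_that("charlson index sums distinct condition weights once", {
  cm <- read_charlson_map()
  scan <- as.Date("2016-06-01")
  none <- data.frame(date = scan - 10, system = "ICD10", code = "I10")
  expect_equal(charlson_index(none, cm, scan), 0)
  mi_dm <- data.frame(date = scan - c(10, 20), system = "ICD10",
                      code = c("I21.4", "E11.9"))
  expect_equal(charlson_index(mi_dm, cm, scan), 2)
  twice <- data.frame(date = scan - c(10, 20), system = "ICD10",
                      code = c("I21.4", "I22.1"))
  expect_equal(charlson_index(twice, cm, scan), 1)
  severe <- data.frame(date = scan - 5, system = "ICD10", code = "C78.0")
  expect_equal(charlson_index(severe, cm, scan), 6)
  empty <- charlson_index(none[0, ], cm, scan)
  expect_equal(empty, 0)
})

test_that("correlation pruning enforces the threshold deterministically", {
  set.seed(23)
  n <- 200
  a <- rnorm(n)
  x <- data.frame(a = a, b = a, c = rnorm(n),
                  d = a + rnorm(n, 0, 0.2), e = rnorm(n))
  out <- prune_correlated(x, 0.5)
  expect_true("a" %in% names(out$features))
  expect_true(all(c("b", "d") %in% out$dropped))  # later copies dropped
  r <- abs(stats::cor(out$features, use = "pairwise.complete.obs"))
  diag(r) <- 0
  expect_lte(max(r), 0.5)
  # boundary: an exactly r = 0.5 pair is retained (strict >)
  u <- rnorm(100)
  v <- 0.5 * scale(u)[, 1] + sqrt(0.75) * scale(resid(lm(rnorm(100) ~ u)))[, 1]
  exact <- data.frame(u = scale(u)[, 1], v = v)
  expect_equal(abs(cor(exact$u, exact$v)), 0.5, tolerance = 1e-10)
  out2 <- prune_correlated(exact, 0.5)
  expect_equal(ncol(out2$features), 2)
  # three mutually correlated columns leave one survivor
  base <- rnorm(n)
  tri <- data.frame(p = base + rnorm(n, 0, 0.3),
                    q = base + rnorm(n, 0, 0.3),
                    r = base + rnorm(n, 0, 0.3))
  out3 <- prune_correlated(tri, 0.5)
  expect_equal(ncol(out3$features), 1)
})

test_that("targeted median imputation touches only its targets", {
  train <- data.frame(ldl = c(100, 120, NA, 110),
                      hdl = c(NA, 50, 60, 40),
                      glucose = c(NA, 90, 100, 95))
  med <- train_medians(train, c("ldl", "hdl"))
  expect_equal(unname(med["ldl"]), 110)
  test <- data.frame(ldl = c(NA, 130), hdl = c(45, NA),
                     glucose = c(NA, 88))
  out <- impute_targeted_median(test, med)
  expect_equal(out$ldl, c(110, 130))
  expect_equal(out$hdl, c(45, 50))
  expect_true(is.na(out$glucose[1]))  # non-target passes through
  bad <- train_medians(data.frame(ldl = c(NA_real_, NA_real_)), "ldl")
  expect_error(impute_targeted_median(test, bad), "explicit default")
})

test_that("feature vectors are pure, aligned and order-invariant", {
  scan <- as.Date("2016-06-01")
  obs <- data.frame(date = scan - c(30, 0, 90), name = "glucose",
                    value = c(100, 120, 90))
  codes <- rbind(icd("I10", scan, -40),
                 data.frame(date = scan - 15, system = "DRUG",
                            code = "lisinopril"))
  rec <- mk_record(codes = codes, obs = obs)
  cfg <- feature_config()
  v1 <- build_feature_vector(rec, cfg)
  v2 <- build_feature_vector(rec, cfg)
  expect_identical(v1, v2)
  # hand-computed spot checks
  expect_equal(unname(v1["age_years"]),
               as.numeric(scan - rec$birthdate) / 365.25)
  expect_equal(unname(v1["sex_male"]), 0)
  lam <- log(2) / 30
  u <- exp(-lam * c(30, 0, 90))
  expect_equal(unname(v1["glucose_wmean"]),
               sum(u * c(100, 120, 90)) / sum(u))
  expect_equal(unname(v1["glucose_n"]), 3)
  expect_equal(unname(v1["icd_hypertensive_diseases"]), 1)
  expect_equal(unname(v1["atc_C09_ras_agents"]), 1)
  expect_equal(unname(v1["charlson"]), 0)
  expect_true(is.na(v1["ldl_wmean"]))
  expect_equal(unname(v1["ldl_n"]), 0)
  # permuting same-day event order leaves the vector unchanged
  obs_perm <- obs[c(3, 1, 2), ]
  rec_perm <- mk_record(codes = codes[c(2, 1), ], obs = obs_perm)
  expect_identical(build_feature_vector(rec_perm, cfg), v1)
  prov <- attr(v1, "provenance")
  expect_equal(unname(prov["age_years"]), "demographic")
  expect_equal(unname(prov["glucose_wmean"]), "vital_lab")
  expect_equal(unname(prov["charlson"]), "charlson")
})

test_that("EMR cohorts round-trip through the three-CSV layout", {
  co <- make_emr_cohort(cohort_spec(6, 0.3, c(age = 1), seed = 2))
  dir <- tempfile("emr")
  write_emr_csv(co$records, dir)
  back <- read_emr_csv(dir)
  expect_equal(length(back), 6)
  cfg <- feature_config()
  for (i in seq_along(back))
    expect_equal(build_feature_vector(back[[i]], cfg),
                 build_feature_vector(co$records[[i]], cfg))
  unlink(dir, recursive = TRUE)
})
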