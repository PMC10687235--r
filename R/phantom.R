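# Synthetic L3-level CT phantoms with ground-truth tissue masks.
#
# Geometry is a set of concentric ellipses: a subcutaneous fat (SAT)
# ring at the body surface, a muscle wall inside it, and an inner
# cavity split between visceral fat (VAT, smooth random blobs) and
# other tissues.  Chosen for closed-form areas and an unambiguous
# VAT/SAT separation.

#' Phantom specification
#'
#' Describes the geometry, pixel grid and per-tissue Hounsfield-unit
#' distributions of a synthetic L3 body phantom.
#'
#' @param image_size Pixels per side (>= 64).
#' @param pixel_spacing_mm (row, col) spacing in mm, both > 0.
#' @param body_axes_mm Ellipse semi-axes (row, col) of the body
#'   outline, in mm.
#' @param sat_thickness_mm Width of the subcutaneous fat ring, mm.
#' @param muscle_wall_mm Width of the muscle layer inside the SAT ring,
#'   mm.
#' @param vat_fraction Fraction of the inner cavity assigned to
#'   visceral fat, in (0, 1).
#' @param hu_params Named list of c(mean, sd) HU per class:
#'   `background`, `sat`, `vat`, `muscle`, `other`, `bed`.  Defaults
#'   follow standard attenuation conventions (air -1000, fat around
#'   -100 to -90, muscle around 45).
#' @param bed_present Render a thin scanner-bed strip of about 0 HU
#'   below the body.
#' @param seed Integer seed; phantom generation is deterministic given
#'   it.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 256,
                         pixel_spacing_mm = c(2, 2),
                         body_axes_mm = c(110, 160),
                         sat_thickness_mm = 25,
                         muscle_wall_mm = 15,
                         vat_fraction = 0.35,
                         hu_params = NULL,
                         bed_present = TRUE,
                         seed = 1L) {
  defaults <- list(background = c(-1000, 5), sat = c(-100, 15),
                   vat = c(-90, 15), muscle = c(45, 12),
                   other = c(30, 40), bed = c(0, 10))
  if (is.null(hu_params)) hu_params <- defaults
  for (nm in names(defaults))
    if (is.null(hu_params[[nm]])) hu_params[[nm]] <- defaults[[nm]]
  if (image_size < 64) stop("image_size must be at least 64")
  if (any(pixel_spacing_mm <= 0)) stop("pixel spacing must be positive")
  if (sat_thickness_mm <= 0 || muscle_wall_mm <= 0)
    stop("geometric widths must be positive")
  if (sat_thickness_mm + muscle_wall_mm >= min(body_axes_mm))
    stop("SAT + muscle widths must be smaller than the body semi-minor axis")
  if (vat_fraction <= 0 || vat_fraction >= 1)
    stop("vat_fraction must be in (0, 1)")
  sds <- vapply(hu_params, `[`, numeric(1), 2)
  if (any(sds < 0)) stop("HU standard deviations must be >= 0")
  if (hu_params$sat[1] >= hu_params$muscle[1] ||
      hu_params$vat[1] >= hu_params$muscle[1])
    stop("fat HU means must be below the muscle HU mean")
  structure(list(image_size = as.integer(image_size),
                 pixel_spacing_mm = as.numeric(pixel_spacing_mm),
                 body_axes_mm = as.numeric(body_axes_mm),
                 sat_thickness_mm = sat_thickness_mm,
                 muscle_wall_mm = muscle_wall_mm,
                 vat_fraction = vat_fraction,
                 hu_params = hu_params,
                 bed_present = isTRUE(bed_present),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Logical mask of an ellipse with semi-axes (ar, ac) mm centered at
# (cr, cc) pixels on an n x n grid with the given spacing.
ellipse_mask <- function(n, spacing, center_px, axes_mm) {
  y <- (seq_len(n) - center_px[1]) * spacing[1]
  x <- (seq_len(n) - center_px[2]) * spacing[2]
  outer((y / axes_mm[1])^2, (x / axes_mm[2])^2, `+`) <= 1
}

#' Generate a phantom slice and its ground-truth mask
#'
#' Renders the concentric-ellipse anatomy of the spec, draws per-pixel
#' HU from each tissue's normal distribution, rounds to integer HU and
#' clips to the valid CT range.  VAT is placed where a smooth random
#' blob field (a handful of Gaussian bumps) exceeds its
#' `vat_fraction`-quantile over the cavity, so the cavity split hits
#' the requested fraction up to ties.  Deterministic given `spec$seed`.
#'
#' @param spec A [phantom_spec].
#' @return List with `slice` (a [ct_slice]) and `mask` (integer label
#'   matrix, see [tissue_labels]).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  old <- .Random.seed_safe_set(spec$seed)
  on.exit(.Random.seed_safe_restore(old), add = TRUE)
  labs <- tissue_labels()
  n <- spec$image_size
  sp <- spec$pixel_spacing_mm
  # body center: middle of the grid, nudged up to leave room for a bed
  center <- c(n / 2 - 2, n / 2 + 0.5)
  ax <- spec$body_axes_mm
  s <- spec$sat_thickness_mm
  m <- spec$muscle_wall_mm

  body <- ellipse_mask(n, sp, center, ax)
  sat_in <- ellipse_mask(n, sp, center, ax - s)
  mus_in <- ellipse_mask(n, sp, center, ax - s - m)
  sat <- body & !sat_in
  muscle <- sat_in & !mus_in
  cavity <- mus_in

  # smooth blob field over the cavity -> VAT where field is high
  idx <- which(cavity, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty class: other (cavity has no pixels)")
  k <- 6
  ctr <- idx[sample.int(nrow(idx), k, replace = TRUE), , drop = FALSE]
  sigma <- max(ax - s - m) / (2.5 * mean(sp))   # in pixels
  field <- numeric(nrow(idx))
  for (j in seq_len(k)) {
    d2 <- (idx[, 1] - ctr[j, 1])^2 + (idx[, 2] - ctr[j, 2])^2
    field <- field + exp(-d2 / (2 * sigma^2))
  }
  thr <- stats::quantile(field, 1 - spec$vat_fraction, names = FALSE)
  vat_sel <- field > thr

  mask <- matrix(labs["background"], n, n)
  mask[sat] <- labs["sat"]
  mask[muscle] <- labs["muscle"]
  mask[cavity] <- labs["other"]
  mask[idx[vat_sel, , drop = FALSE]] <- labs["vat"]

  for (cls in core_tissue_names())
    if (!any(mask == labs[cls])) stop("empty class: ", cls)

  hu <- matrix(0, n, n)
  draw <- function(sel, par) {
    k <- sum(sel)
    hu[sel] <<- stats::rnorm(k, par[1], par[2])
  }
  draw(mask == labs["background"], spec$hu_params$background)
  draw(mask == labs["sat"], spec$hu_params$sat)
  draw(mask == labs["vat"], spec$hu_params$vat)
  draw(mask == labs["muscle"], spec$hu_params$muscle)
  draw(mask == labs["other"], spec$hu_params$other)

  if (spec$bed_present) {
    bottom <- ceiling(center[1] + ax[1] / sp[1])
    bed_rows <- seq(min(bottom + 4, n - 2), min(bottom + 6, n))
    bed_cols <- seq(round(n * 0.2), round(n * 0.8))
    bed_sel <- matrix(FALSE, n, n)
    bed_sel[bed_rows, bed_cols] <- TRUE
    bed_sel <- bed_sel & mask == labs["background"]
    draw(bed_sel, spec$hu_params$bed)
    # bed stays background in the tissue mask
  }

  hu <- pmin(HU_MAX, pmax(HU_MIN, round(hu)))
  storage.mode(mask) <- "integer"
  list(slice = ct_slice(matrix(as.integer(hu), n), sp), mask = mask)
}

#' Synthetic cohort specification
#'
#' Shared parameters of the imaging and EMR cohort generators: cohort
#' size, target outcome prevalence, the planted logistic outcome model,
#' and the latent noise level.
#'
#' @param n_patients Number of patients (>= 2).
#' @param prevalence_target Target outcome prevalence in (0, 1).
#' @param outcome_coefficients Named numeric vector of logistic
#'   coefficients on standardized generated features.  Allowed names
#'   depend on the generator ([make_imaging_cohort],
#'   [make_emr_cohort]).
#' @param noise_sd Standard deviation of latent Gaussian noise added to
#'   the linear predictor (>= 0).
#' @param seed Integer seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients, prevalence_target = 0.25,
                        outcome_coefficients = c(vat_sat_ratio = 1),
                        noise_sd = 0.5, seed = 1L) {
  if (n_patients < 2) stop("n_patients must be at least 2")
  if (prevalence_target <= 0 || prevalence_target >= 1)
    stop("prevalence_target must be in (0, 1)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(outcome_coefficients) > 0 &&
      is.null(names(outcome_coefficients)))
    stop("outcome_coefficients must be named")
  structure(list(n_patients = as.integer(n_patients),
                 prevalence_target = prevalence_target,
                 outcome_coefficients = outcome_coefficients,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Solve for the intercept that hits the target mean of plogis(b0 + eta).
calibrate_intercept <- function(eta, target) {
  f <- function(b0) mean(stats::plogis(b0 + eta)) - target
  stats::uniroot(f, c(-50, 50), tol = 1e-10)$root
}

imaging_feature_names <- c("mean_muscle_hu", "vat_sat_ratio",
                           "vat_area_cm2", "sat_area_cm2",
                           "muscle_area_cm2")

#' Generate an imaging cohort of phantoms with planted outcome signal
#'
#' Per patient, jitters the phantom geometry and HU means (so
#' body-composition features vary), renders the phantom, computes its
#' true-mask body-composition features, and draws a binary label from a
#' logistic model on the standardized features:
#' `logit P(y=1) = b0 + X beta + eps`, `eps ~ N(0, noise_sd)`, with the
#' intercept calibrated so the expected prevalence equals
#' `prevalence_target`.  Geometry/HU noise and label noise use separate
#' RNG streams derived from the seed, so the same anatomy supports
#' different outcome draws.
#'
#' @param spec A [cohort_spec]; `outcome_coefficients` names must be
#'   among `mean_muscle_hu`, `vat_sat_ratio`, `vat_area_cm2`,
#'   `sat_area_cm2`, `muscle_area_cm2`.
#' @param phantom Base [phantom_spec] jittered per patient.
#' @param keep_images Keep the rendered slices and masks (memory-heavy
#'   for large cohorts).
#' @return List with `features` (data.frame, raw scale), `labels` (0/1),
#'   `linear_predictor` (the true b0 + X beta + eps), `coefficients`
#'   (planted, standardized scale), `intercept`, and optionally
#'   `slices`, `masks`.
#' @export
make_imaging_cohort <- function(spec, phantom = phantom_spec(),
                                keep_images = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(phantom, "phantom_spec"))
  beta <- spec$outcome_coefficients
  bad <- setdiff(names(beta), imaging_feature_names)
  if (length(bad) > 0)
    stop("unknown imaging feature(s) in outcome_coefficients: ",
         paste(bad, collapse = ", "))
  n <- spec$n_patients
  old <- .Random.seed_safe_set(spec$seed)
  on.exit(.Random.seed_safe_restore(old), add = TRUE)
  jit <- data.frame(
    ax_row = phantom$body_axes_mm[1] * exp(stats::rnorm(n, 0, 0.08)),
    ax_col = phantom$body_axes_mm[2] * exp(stats::rnorm(n, 0, 0.08)),
    sat = phantom$sat_thickness_mm * exp(stats::rnorm(n, 0, 0.2)),
    wall = phantom$muscle_wall_mm * exp(stats::rnorm(n, 0, 0.15)),
    vatf = pmin(0.8, pmax(0.05,
      phantom$vat_fraction * exp(stats::rnorm(n, 0, 0.3)))),
    mus_hu = phantom$hu_params$muscle[1] + stats::rnorm(n, 0, 8))

  feats <- matrix(NA_real_, n, length(imaging_feature_names),
                  dimnames = list(NULL, imaging_feature_names))
  slices <- if (keep_images) vector("list", n) else NULL
  masks <- if (keep_images) vector("list", n) else NULL
  labs <- tissue_labels()
  for (i in seq_len(n)) {
    hu <- phantom$hu_params
    hu$muscle <- c(jit$mus_hu[i], phantom$hu_params$muscle[2])
    ps <- phantom_spec(image_size = phantom$image_size,
                       pixel_spacing_mm = phantom$pixel_spacing_mm,
                       body_axes_mm = c(jit$ax_row[i], jit$ax_col[i]),
                       sat_thickness_mm = jit$sat[i],
                       muscle_wall_mm = jit$wall[i],
                       vat_fraction = jit$vatf[i],
                       hu_params = hu,
                       bed_present = phantom$bed_present,
                       seed = spec$seed + 7L * i)
    ph <- make_phantom(ps)
    sp <- ph$slice$spacing
    feats[i, "mean_muscle_hu"] <-
      mean_radiodensity(ph$slice, ph$mask, "muscle")
    feats[i, "vat_area_cm2"] <- tissue_area(ph$mask, "vat", sp)
    feats[i, "sat_area_cm2"] <- tissue_area(ph$mask, "sat", sp)
    feats[i, "muscle_area_cm2"] <- tissue_area(ph$mask, "muscle", sp)
    feats[i, "vat_sat_ratio"] <- vat_sat_ratio(ph$mask)
    if (keep_images) {
      slices[[i]] <- ph$slice
      masks[[i]] <- ph$mask
    }
  }

  # outcome draw on a separate stream so geometry and labels decouple
  set.seed(spec$seed + 1000003L)
  eta <- rep(0, n)
  if (length(beta) > 0) {
    xs <- scale(feats[, names(beta), drop = FALSE])
    eta <- as.numeric(xs %*% beta)
  }
  eta <- eta + stats::rnorm(n, 0, spec$noise_sd)
  b0 <- calibrate_intercept(eta, spec$prevalence_target)
  p <- stats::plogis(b0 + eta)
  y <- stats::rbinom(n, 1, p)

  out <- list(features = data.frame(patient_id = sprintf("P%05d", seq_len(n)),
                                    feats),
              labels = y, linear_predictor = b0 + eta,
              coefficients = beta, intercept = b0)
  if (keep_images) {
    out$slices <- slices
    out$masks <- masks
  }
  out
}

#' Linear differentiable scorer
#'
#' A risk scorer with score `S(I) = sum_ij W_ij I_ij` and constant
#' gradient `W`.  For 3-channel inputs the weight grid applies to each
#' channel.  Serves as a closed-form oracle for the saliency pipeline.
#'
#' @param weights Numeric matrix of pixel weights.
#' @return Object of class `scorer` with `score(x)` and `gradient(x)`.
#' @export
linear_scorer <- function(weights) {
  if (!is.matrix(weights) || any(!is.finite(weights)))
    stop("weights must be a finite matrix")
  grad_one <- weights
  score <- function(x) {
    if (length(dim(x)) == 3) {
      sum(vapply(seq_len(dim(x)[3]),
                 function(k) sum(grad_one * x[, , k]), numeric(1)))
    } else {
      sum(grad_one * x)
    }
  }
  gradient <- function(x) {
    if (length(dim(x)) == 3) {
      array(rep(grad_one, dim(x)[3]), dim = dim(x))
    } else {
      grad_one
    }
  }
  structure(list(score = score, gradient = gradient, name = "linear"),
            class = "scorer")
}
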