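# Body-composition metrics, segmentation evaluation and a reference
# threshold segmenter.

# Resolve a class given as name ("muscle") or integer code.
tissue_code <- function(cls) {
  labs <- tissue_labels()
  if (is.character(cls)) {
    if (!cls %in% names(labs)) stop("unknown tissue class: ", cls)
    return(unname(labs[cls]))
  }
  cls <- as.integer(cls)
  if (!cls %in% labs) stop("unknown tissue class code: ", cls)
  cls
}

#' Dice overlap coefficient for one tissue class
#'
#' `2|A n B| / (|A| + |B|)` for the binary masks of class `cls` in two
#' label masks; 1 indicates perfect agreement.  When the class is
#' absent from both masks the score is defined as 1 (perfect agreement
#' on absence), which keeps per-class sweeps free of NaN.
#'
#' @param a,b Integer tissue label masks of the same shape.
#' @param cls Class name or code (see [tissue_labels]).
#' @return Dice score in \[0, 1\].
#' @export
dice <- function(a, b, cls) {
  if (!all(dim(a) == dim(b))) stop("masks must have the same shape")
  code <- tissue_code(cls)
  A <- a == code
  B <- b == code
  na <- sum(A)
  nb <- sum(B)
  if (na + nb == 0) return(1)
  2 * sum(A & B) / (na + nb)
}

#' Root-mean-squared coefficient of variation
#'
#' Duplicate-measurement convention for paired manual/automated
#' measurements: for each pair the standard deviation is `|m - a| /
#' sqrt(2)`, the CV is that divided by the pair mean, and the summary
#' is `100 * sqrt(mean(CV^2))`, in percent.
#'
#' @param manual,auto Paired numeric vectors of measurements; every
#'   pair mean must be positive.
#' @return RMS-CV in percent.
#' @export
rms_cv <- function(manual, auto) {
  if (length(manual) != length(auto) || length(manual) == 0)
    stop("manual and auto must be non-empty vectors of equal length")
  means <- (manual + auto) / 2
  if (any(means <= 0)) stop("all pair means must be positive")
  cv <- (abs(manual - auto) / sqrt(2)) / means
  100 * sqrt(mean(cv^2))
}

#' Cross-sectional area of a tissue class
#'
#' @param mask Integer tissue label mask.
#' @param cls Class name or code.
#' @param spacing Pixel spacing (row_mm, col_mm).
#' @return Area in cm^2 (pixel count x pixel area / 100).
#' @export
tissue_area <- function(mask, cls, spacing) {
  code <- tissue_code(cls)
  sum(mask == code) * spacing[1] * spacing[2] / 100
}

#' Mean radiodensity of a tissue class
#'
#' Arithmetic mean HU over the pixels of `cls`.  An empty class is an
#' error rather than a silent zero.
#'
#' @param slice A [ct_slice].
#' @param mask Integer tissue label mask aligned to the slice.
#' @param cls Class name or code.
#' @return Mean HU.
#' @export
mean_radiodensity <- function(slice, mask, cls) {
  stopifnot(inherits(slice, "ct_slice"))
  if (!all(dim(mask) == dim(slice$pixels)))
    stop("mask and slice must have the same shape")
  code <- tissue_code(cls)
  sel <- mask == code
  if (!any(sel)) stop("class has no pixels: ", cls)
  mean(slice$pixels[sel])
}

#' Visceral-to-subcutaneous adipose tissue area ratio
#'
#' `area(VAT) / area(SAT)`; pixel spacing cancels, so the ratio is
#' computed from pixel counts.  An empty SAT class is an error.
#'
#' @param mask Integer tissue label mask.
#' @return VAT/SAT ratio (>= 0).
#' @export
vat_sat_ratio <- function(mask) {
  labs <- tissue_labels()
  n_sat <- sum(mask == labs["sat"])
  if (n_sat == 0) stop("SAT class is empty; VAT/SAT ratio undefined")
  sum(mask == labs["vat"]) / n_sat
}

#' Body-composition feature row
#'
#' Convenience extractor for the features used by the bivariate
#' segmentation-based risk model and downstream fusion.
#'
#' @inheritParams mean_radiodensity
#' @return Named list: `mean_muscle_hu`, `muscle_area_cm2`,
#'   `vat_area_cm2`, `sat_area_cm2`, `vat_sat_ratio`.
#' @export
bodycomp_features <- function(slice, mask) {
  sp <- slice$spacing
  list(mean_muscle_hu = mean_radiodensity(slice, mask, "muscle"),
       muscle_area_cm2 = tissue_area(mask, "muscle", sp),
       vat_area_cm2 = tissue_area(mask, "vat", sp),
       sat_area_cm2 = tissue_area(mask, "sat", sp),
       vat_sat_ratio = vat_sat_ratio(mask))
}

#' Reference attenuation-threshold segmenter
#'
#' A simple rule-based segmenter so the full pipeline runs without a
#' trained network; any segmenter mapping a slice to a tissue mask can
#' be plugged in instead.  Inside the body mask: adipose tissue is HU
#' in `adipose_range`; adipose connected components reaching within
#' `sat_touch_mm` of the body surface are SAT, the rest VAT; muscle is
#' HU in `muscle_range` within `muscle_reach_mm` of the SAT ring (the
#' abdominal wall); everything else in the body is other tissue;
#' everything outside is background.
#'
#' @param slice A [ct_slice].
#' @param body Logical body mask (see [extract_body_mask]).
#' @param adipose_range,muscle_range HU intervals, defaults
#'   (-190, -30) and (-29, 150) per common body-composition
#'   conventions.
#' @param sat_touch_mm Maximum distance from the body surface for an
#'   adipose component to count as subcutaneous.
#' @param muscle_reach_mm Dilation radius around SAT within which
#'   muscle-range HU is labeled muscle.
#' @return Integer tissue label mask.
#' @export
threshold_segmenter <- function(slice, body,
                                adipose_range = c(-190, -30),
                                muscle_range = c(-29, 150),
                                sat_touch_mm = 4,
                                muscle_reach_mm = 17) {
  stopifnot(inherits(slice, "ct_slice"))
  if (!any(body)) stop("empty body mask")
  labs <- tissue_labels()
  hu <- slice$pixels
  sp <- slice$spacing
  n <- nrow(hu)

  adipose <- body & hu >= adipose_range[1] & hu <= adipose_range[2]
  mask <- matrix(labs["background"], n, ncol(hu))
  mask[body] <- labs["other"]

  if (any(adipose)) {
    comp <- EBImage::bwlabel(matrix(as.numeric(adipose), n))
    # depth of each pixel inside the body (mm, approx via pixel distmap)
    depth <- EBImage::distmap(matrix(as.numeric(body), n)) * mean(sp)
    ncomp <- max(comp)
    sat_sel <- matrix(FALSE, n, ncol(hu))
    for (k in seq_len(ncomp)) {
      sel <- comp == k
      if (min(depth[sel]) <= sat_touch_mm) sat_sel[sel] <- TRUE
    }
    mask[adipose & sat_sel] <- labs["sat"]
    mask[adipose & !sat_sel] <- labs["vat"]

    if (any(sat_sel)) {
      r_px <- max(1L, round(muscle_reach_mm / mean(sp)))
      brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
      near_sat <- EBImage::dilate(matrix(as.numeric(sat_sel), n), brush) > 0
      mus <- body & !adipose & near_sat &
        hu >= muscle_range[1] & hu <= muscle_range[2]
      mask[mus] <- labs["muscle"]
    }
  }
  storage.mode(mask) <- "integer"
  mask
}
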