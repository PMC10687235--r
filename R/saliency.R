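# Tissue saliency: pixel-gradient attributions of a differentiable
# risk scorer aggregated by tissue class, contrasting the observed
# share of gradient magnitude in each tissue with the share expected
# from the tissue's pixel count alone.

#' Pixel saliency map of a scorer
#'
#' Computes `w_ij = dS/dI | I_ij`, the derivative of the scorer's risk
#' score with respect to each input pixel.  For 3-channel inputs (the
#' channels are replicated copies of one grid) the channel gradients
#' are summed, since the derivative with respect to the underlying
#' pixel is the channel sum.  If the input was resized (it carries a
#' `native_dim` attribute from [prepare_scorer_input]), the gradient is
#' mapped back to native pixel coordinates through the adjoint of the
#' bilinear resize, so the saliency map always aligns to the original
#' slice.
#'
#' @param scorer A `scorer` (fields `score`, `gradient`), e.g.
#'   [linear_scorer].
#' @param input Prepared input grid: a matrix or a (rows x cols x 3)
#'   array, optionally with attribute `native_dim`.
#' @return Signed saliency matrix aligned to the native grid.
#' @export
pixel_saliency <- function(scorer, input) {
  if (!inherits(scorer, "scorer"))
    stop("scorer must be a 'scorer' object with score and gradient")
  g <- scorer$gradient(input)
  if (any(!is.finite(g))) stop("non-finite gradient")
  if (length(dim(g)) == 3) {
    w <- g[, , 1]
    for (k in 2:dim(g)[3]) w <- w + g[, , k]
  } else {
    w <- g
  }
  native <- attr(input, "native_dim")
  if (!is.null(native) && !all(dim(w) == native))
    w <- resize_adjoint(w, native)
  w
}

#' Observed tissue saliency fractions
#'
#' For each tissue class t, the L1 norm of the saliency over the
#' class's pixels divided by the L1 norm of the total saliency:
#' `S_O(t) = sum_{ij in t} |w_ij| / sum_ij |w_ij|`.  The five class
#' fractions sum to 1.  An all-zero saliency map has no defined
#' partition and raises an error rather than returning NaN.
#'
#' @param sal Signed saliency matrix (from [pixel_saliency]).
#' @param mask Integer tissue label mask of the same shape, restricted
#'   to the five core classes (collapse bone first with
#'   [assign_saliency_classes]).
#' @return Named numeric vector of fractions over background, muscle,
#'   vat, sat, other.
#' @export
observed_saliency <- function(sal, mask) {
  if (!all(dim(sal) == dim(mask)))
    stop("saliency map and mask must have the same shape")
  validate_tissue_mask(mask, allow_bone = FALSE)
  a <- abs(sal)
  total <- sum(a)
  if (total == 0) stop("undefined saliency: total |w| is zero")
  labs <- tissue_labels()[core_tissue_names()]
  vapply(labs, function(l) sum(a[mask == l]) / total, numeric(1))
}

#' Expected tissue saliency fractions
#'
#' The share of saliency each tissue would receive if saliency were
#' uniform: the proportion of image pixels belonging to the tissue.
#'
#' @param mask Integer tissue label mask (five core classes).
#' @return Named numeric vector of pixel fractions summing to 1.
#' @export
expected_saliency <- function(mask) {
  validate_tissue_mask(mask, allow_bone = FALSE)
  class_fractions(mask)
}

#' Resolve segmentation labels against a body mask
#'
#' Builds the saliency partition: pixels inside the body not labeled
#' muscle, VAT or SAT (including any extended bone label) become other
#' tissue; every pixel outside the body mask becomes background, even
#' if the segmenter labeled it (the body mask defines background).
#'
#' @param mask Integer tissue label mask (bone allowed).
#' @param body Logical body mask of the same shape.
#' @return Integer mask over the five core classes.
#' @export
assign_saliency_classes <- function(mask, body) {
  if (!all(dim(mask) == dim(body)))
    stop("mask and body mask must have the same shape")
  validate_tissue_mask(mask, allow_bone = TRUE)
  labs <- tissue_labels()
  out <- mask
  keep <- mask == labs["muscle"] | mask == labs["vat"] |
    mask == labs["sat"]
  out[body & !keep] <- labs["other"]
  out[!body] <- labs["background"]
  storage.mode(out) <- "integer"
  out
}

#' Per-image tissue saliency result
#'
#' Convenience wrapper: observed and expected fractions for one image.
#'
#' @inheritParams observed_saliency
#' @return Object of class `tissue_saliency` with `observed` and
#'   `expected` named vectors.
#' @export
tissue_saliency <- function(sal, mask) {
  structure(list(observed = observed_saliency(sal, mask),
                 expected = expected_saliency(mask)),
            class = "tissue_saliency")
}

#' Cohort-level tissue saliency summary
#'
#' Averages per-image observed and expected fractions over the cohort,
#' reports the ratio of means `Obar/Ebar` per class (the headline
#' statistic; the mean of per-image ratios is also exposed), and a
#' two-tailed paired t-test of observed vs expected per class.
#'
#' @param results List of [tissue_saliency] objects (n >= 1; t-tests
#'   need n >= 2 and otherwise return NA with a warning).
#' @return Object of class `cohort_saliency`: a data.frame `table` with
#'   columns class, mean_observed, mean_expected, ratio,
#'   mean_ratio_per_image, t, p, plus `n_images`.
#' @export
cohort_saliency <- function(results) {
  if (length(results) == 0) stop("no results to aggregate")
  if (!all(vapply(results, inherits, logical(1), "tissue_saliency")))
    stop("results must be tissue_saliency objects")
  classes <- core_tissue_names()
  O <- t(vapply(results, `[[`, numeric(5), "observed"))
  E <- t(vapply(results, `[[`, numeric(5), "expected"))
  colnames(O) <- colnames(E) <- classes
  n <- nrow(O)
  if (n < 2) warning("n < 2: paired t-test undefined")
  rows <- lapply(classes, function(cl) {
    o <- O[, cl]
    e <- E[, cl]
    ratio <- mean(o) / mean(e)
    per_image <- mean(ifelse(e > 0, o / e, NA_real_), na.rm = TRUE)
    if (n >= 2 && stats::sd(o - e) > 0) {
      tt <- stats::t.test(o, e, paired = TRUE)
      tv <- unname(tt$statistic)
      pv <- tt$p.value
    } else if (n >= 2) {
      tv <- 0
      pv <- 1
    } else {
      tv <- NA_real_
      pv <- NA_real_
    }
    data.frame(class = cl, mean_observed = mean(o),
               mean_expected = mean(e), ratio = ratio,
               mean_ratio_per_image = per_image, t = tv, p = pv)
  })
  structure(list(table = do.call(rbind, rows), n_images = n),
            class = "cohort_saliency")
}

#' @export
print.cohort_saliency <- function(x, ...) {
  cat(sprintf("<cohort_saliency> %d images\n", x$n_images))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Run the tissue-saliency pipeline over a cohort
#'
#' For each slice: prepare the scorer input, compute the pixel saliency
#' map, build the saliency partition from the segmentation mask and the
#' body mask, and accumulate observed/expected fractions.  Images whose
#' total saliency is zero carry no gradient information; they are
#' excluded from cohort averages and counted in `n_zero_saliency`,
#' never imputed.
#'
#' @param scorer A `scorer`.
#' @param slices List of [ct_slice] objects.
#' @param masks List of tissue label masks aligned to the slices.
#' @param out_size Scorer input side length (default: native size, no
#'   resize).
#' @param body_masks Optional list of logical body masks; computed with
#'   [extract_body_mask] when omitted.
#' @return A [cohort_saliency] with extra fields `per_image` (list of
#'   [tissue_saliency]) and `n_zero_saliency`.
#' @export
run_tissue_saliency <- function(scorer, slices, masks, out_size = NULL,
                                body_masks = NULL) {
  if (length(slices) != length(masks))
    stop("slices and masks must have equal length")
  results <- list()
  n_zero <- 0L
  for (i in seq_along(slices)) {
    sl <- slices[[i]]
    input <- prepare_scorer_input(
      sl, if (is.null(out_size)) nrow(sl$pixels) else out_size)
    w <- pixel_saliency(scorer, input)
    body <- if (is.null(body_masks)) extract_body_mask(sl)
            else body_masks[[i]]
    m <- assign_saliency_classes(masks[[i]], body)
    res <- tryCatch(tissue_saliency(w, m), error = function(e) NULL)
    if (is.null(res)) n_zero <- n_zero + 1L else results[[length(results) + 1L]] <- res
  }
  if (length(results) == 0) stop("all images had zero total saliency")
  out <- cohort_saliency(results)
  out$per_image <- results
  out$n_zero_saliency <- n_zero
  out
}
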