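# Tissue label conventions shared by masks, segmenters and saliency.

#' Tissue label codes
#'
#' Integer codes used in tissue label masks.  The five core classes
#' (background, muscle, VAT, SAT, other body tissues) partition every
#' slice; `bone` is an extended label allowed in manual-annotation
#' masks and collapsed to `other` before saliency aggregation.
#'
#' @return Named integer vector of label codes.
#' @export
tissue_labels <- function() {
  c(background = 0L, muscle = 1L, vat = 2L, sat = 3L, other = 4L,
    bone = 5L)
}

# Core saliency partition (no bone).
core_tissue_names <- function() c("background", "muscle", "vat", "sat", "other")

#' Validate a tissue mask
#'
#' @param mask Integer matrix of label codes.
#' @param allow_bone Whether the extended `bone` label is permitted.
#' @return The mask, invisibly, with integer storage.
#' @export
validate_tissue_mask <- function(mask, allow_bone = TRUE) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  labs <- tissue_labels()
  allowed <- if (allow_bone) labs else labs[core_tissue_names()]
  bad <- setdiff(unique(as.vector(mask)), unname(allowed))
  if (length(bad) > 0)
    stop("mask contains labels outside the declared set: ",
         paste(bad, collapse = ", "))
  storage.mode(mask) <- "integer"
  invisible(mask)
}

# Per-class pixel fractions of a mask over the five core classes.
class_fractions <- function(mask) {
  labs <- tissue_labels()[core_tissue_names()]
  n <- length(mask)
  vapply(labs, function(l) sum(mask == l) / n, numeric(1))
}
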