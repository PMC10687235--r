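# Deterministic CT preprocessing: HU clipping, window/level
# normalization, channel stacking, resizing and body-mask extraction.

HU_MIN <- -1024L
HU_MAX <- 3071L

#' CT slice container
#'
#' A single axial CT slice: a rectangular integer grid of Hounsfield
#' units plus the physical pixel spacing.  Row-major, 1-based indexing,
#' pixel centers; masks produced downstream are always co-registered to
#' this grid.
#'
#' @param pixels Integer matrix of HU values in \[-1024, 3071\].
#' @param spacing Numeric (row_mm, col_mm), both > 0.
#' @return Object of class `ct_slice` with fields `pixels`, `spacing`.
#' @export
ct_slice <- function(pixels, spacing = c(1, 1)) {
  if (!is.matrix(pixels) || length(pixels) == 0)
    stop("pixels must be a non-empty matrix")
  if (any(!is.finite(pixels))) stop("pixels must be finite")
  if (any(pixels < HU_MIN) || any(pixels > HU_MAX))
    stop("HU values must lie in [-1024, 3071]")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 2 || any(spacing <= 0))
    stop("spacing must be two positive values (row_mm, col_mm)")
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, spacing = spacing), class = "ct_slice")
}

#' @export
print.ct_slice <- function(x, ...) {
  cat(sprintf("<ct_slice> %d x %d px, spacing %.2f x %.2f mm, HU [%d, %d]\n",
              nrow(x$pixels), ncol(x$pixels), x$spacing[1], x$spacing[2],
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Window/level specification
#'
#' @param width Window width in HU (> 0).
#' @param level Window center in HU.
#' @return Object of class `window_spec`.
#' @export
window_spec <- function(width, level) {
  if (!is.numeric(width) || width <= 0) stop("window width must be > 0")
  structure(list(width = width, level = level), class = "window_spec")
}

#' Standard window presets
#'
#' The three window/level settings used to build the segmenter's
#' three-channel input: soft tissue 400/50, bone 1800/400, and a custom
#' soft-tissue variant 500/50 (all W/L in HU).
#'
#' @return Named list of [window_spec] objects (`soft`, `bone`,
#'   `custom`).
#' @export
window_presets <- function() {
  list(soft   = window_spec(400, 50),
       bone   = window_spec(1800, 400),
       custom = window_spec(500, 50))
}

#' Clip Hounsfield units to a range
#'
#' @param slice A [ct_slice].
#' @param lo,hi Clipping bounds in HU, `lo < hi`.
#' @return A new `ct_slice` with every pixel clamped into \[lo, hi\];
#'   shape and spacing preserved.
#' @export
clip_hu <- function(slice, lo = -1000, hi = 1000) {
  stopifnot(inherits(slice, "ct_slice"))
  if (lo >= hi) stop("lo must be strictly less than hi")
  p <- pmin(hi, pmax(lo, slice$pixels))
  ct_slice(matrix(as.integer(p), nrow(slice$pixels)), slice$spacing)
}

#' Apply a window/level mapping
#'
#' Linear ramp convention: HU at `level - width/2` maps to 0, at
#' `level + width/2` to 1, clamped outside; monotone nondecreasing in
#' the input.
#'
#' @param slice A [ct_slice].
#' @param w A [window_spec].
#' @return Numeric matrix in \[0, 1\], same shape as the slice.
#' @export
apply_window <- function(slice, w) {
  stopifnot(inherits(slice, "ct_slice"), inherits(w, "window_spec"))
  v <- (slice$pixels - (w$level - w$width / 2)) / w$width
  matrix(pmin(1, pmax(0, v)), nrow(slice$pixels))
}

#' Stack windowed channels
#'
#' Builds the segmenter's multi-channel input by applying each window
#' in order and stacking along a third dimension.
#'
#' @param slice A [ct_slice].
#' @param windows List of three [window_spec]s (default
#'   [window_presets]).
#' @return Numeric array (rows x cols x 3) in \[0, 1\].
#' @export
stack_channels <- function(slice, windows = window_presets()) {
  stopifnot(inherits(slice, "ct_slice"))
  if (length(windows) != 3) stop("exactly three windows are required")
  ch <- lapply(windows, function(w) apply_window(slice, w))
  array(c(ch[[1]], ch[[2]], ch[[3]]),
        dim = c(nrow(slice$pixels), ncol(slice$pixels), 3))
}

# Separable interpolation matrix mapping n_in samples to n_out samples.
# Pixel-center convention: output center i maps to input coordinate
# (i + 0.5) * n_in/n_out - 0.5 (0-based), clamped at the edges, so
# constants are preserved exactly and corner samples are retained.
interp_matrix <- function(n_in, n_out, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  A <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  src <- (seq_len(n_out) - 0.5) * scale - 0.5   # 0-based input coord
  src <- pmin(pmax(src, 0), n_in - 1)
  if (method == "nearest") {
    j <- round(src) + 1
    A[cbind(seq_len(n_out), j)] <- 1
  } else {
    j0 <- pmin(floor(src), n_in - 1)
    frac <- src - j0
    j0 <- j0 + 1
    j1 <- pmin(j0 + 1, n_in)
    for (i in seq_len(n_out)) {
      A[i, j0[i]] <- A[i, j0[i]] + (1 - frac[i])
      A[i, j1[i]] <- A[i, j1[i]] + frac[i]
    }
  }
  A
}

#' Resize a 2-D grid
#'
#' Separable resize with pixel-center sampling; bilinear for images,
#' nearest-neighbour for label masks (keeps labels categorical).  The
#' map is linear, so its adjoint (used to carry gradients back to the
#' native grid, see [resize_adjoint]) is exact.
#'
#' @param x Numeric matrix.
#' @param out_dim Integer (rows, cols) of the output.
#' @param method "bilinear" or "nearest".
#' @return Resized matrix.
#' @export
resize_grid <- function(x, out_dim, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  Rr <- interp_matrix(nrow(x), out_dim[1], method)
  Rc <- interp_matrix(ncol(x), out_dim[2], method)
  Rr %*% x %*% t(Rc)
}

#' Adjoint of the bilinear resize
#'
#' Maps a gradient defined on the resized grid back to the native grid:
#' if resize is `Y = Rr X Rc'`, then `dL/dX = Rr' G Rc` for a gradient
#' `G = dL/dY`.  Used so saliency maps align to the original slice
#' pixels.
#'
#' @param g Numeric matrix on the resized grid.
#' @param in_dim Integer (rows, cols) of the native grid.
#' @return Matrix of shape `in_dim`.
#' @export
resize_adjoint <- function(g, in_dim) {
  Rr <- interp_matrix(in_dim[1], nrow(g), "bilinear")
  Rc <- interp_matrix(in_dim[2], ncol(g), "bilinear")
  t(Rr) %*% g %*% Rc
}

#' Prepare a slice as scorer input
#'
#' Deterministic contract for feeding a differentiable risk scorer:
#' clip HU to \[-1000, 1000\], bilinearly resize to `out_size` x
#' `out_size`, and replicate the grid into three identical channels.
#' The inverse (adjoint) resize in [resize_adjoint] maps gradients back
#' to input-pixel coordinates for saliency.
#'
#' @param slice A [ct_slice].
#' @param out_size Output side length in pixels (>= 8).
#' @return Numeric array (out_size x out_size x 3) with attribute
#'   `native_dim` recording the slice dimensions.
#' @export
prepare_scorer_input <- function(slice, out_size = nrow(slice$pixels)) {
  stopifnot(inherits(slice, "ct_slice"))
  if (out_size < 8) stop("out_size must be at least 8")
  x <- pmin(pmax(slice$pixels, -1000), 1000)  # matrix first keeps dims
  if (out_size != nrow(x) || out_size != ncol(x))
    x <- resize_grid(x, c(out_size, out_size), "bilinear")
  out <- array(rep(as.numeric(x), 3), dim = c(out_size, out_size, 3))
  attr(out, "native_dim") <- dim(slice$pixels)
  out
}

#' Extract a body mask from a CT slice
#'
#' Traditional image-processing recipe: threshold above air (default
#' -200 HU), label connected components, discard bed-like components
#' (bounding box touching the bottom image edge and area under 20% of
#' the largest component), keep the largest remaining component, and
#' fill internal holes.
#'
#' @param slice A [ct_slice].
#' @param air_threshold HU threshold separating tissue from air.
#' @return Logical matrix (TRUE = body) of the slice's shape.
#' @export
extract_body_mask <- function(slice, air_threshold = -200) {
  stopifnot(inherits(slice, "ct_slice"))
  fg <- slice$pixels > air_threshold
  if (!any(fg)) stop("empty body mask: no pixels above the air threshold")
  lab <- EBImage::bwlabel(matrix(as.numeric(fg), nrow(fg)))
  sizes <- tabulate(lab[lab > 0])
  biggest <- max(sizes)
  n_row <- nrow(fg)
  keep <- rep(TRUE, length(sizes))
  for (k in seq_along(sizes)) {
    touches_bottom <- any(lab[n_row, ] == k)
    if (touches_bottom && sizes[k] < 0.2 * biggest) keep[k] <- FALSE
  }
  cand <- which(keep)
  if (length(cand) == 0) stop("empty body mask: all components bed-like")
  main <- cand[which.max(sizes[cand])]
  body <- lab == main
  filled <- EBImage::fillHull(matrix(as.numeric(body), n_row))
  matrix(filled > 0, n_row)
}
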