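# Tissue saliency: gradients, observed/expected partitions, cohort
# aggregation and planted-signal recovery.

test_that("pixel_saliency returns the exact gradient for analytic scorers", {
  W <- matrix(rnorm(25), 5)
  sc <- linear_scorer(W)
  x <- matrix(runif(25), 5)
  expect_identical(pixel_saliency(sc, x), W)

  const <- structure(list(score = function(x) 1,
                          gradient = function(x) x * 0,
                          name = "const"), class = "scorer")
  expect_true(all(pixel_saliency(const, x) == 0))

  sq <- structure(list(score = function(x) sum(x^2),
                       gradient = function(x) 2 * x,
                       name = "sumsq"), class = "scorer")
  expect_equal(pixel_saliency(sq, x), 2 * x)

  bad <- structure(list(score = function(x) NA,
                        gradient = function(x) x * NA_real_),
                   class = "scorer")
  expect_error(pixel_saliency(bad, x), "non-finite")
})

test_that("channel gradients are summed over replicated channels", {
  W <- matrix(1:4, 2)
  sc <- linear_scorer(W)
  x3 <- array(runif(12), dim = c(2, 2, 3))
  expect_equal(pixel_saliency(sc, x3), 3 * W)
})

test_that("resized pipeline carries gradients back to native pixels", {
  sl <- ct_slice(matrix(as.integer(sample(-500:500, 64)), 8), c(2, 2))
  W <- matrix(rnorm(16 * 16), 16)
  sc <- linear_scorer(W)
  input <- prepare_scorer_input(sl, 16)
  w <- pixel_saliency(sc, input)
  expect_equal(dim(w), c(8, 8))
  # adjoint identity: native gradient of the composed linear map
  expect_equal(w, resize_adjoint(3 * W, c(8, 8)), tolerance = 1e-12)
})

test_that("observed saliency is the L1 partition over classes", {
  mask <- matrix(c(1L, 1L, 2L, 0L), 2, byrow = TRUE)
  w <- matrix(c(1, 3, 2, 2), 2, byrow = TRUE)
  so <- observed_saliency(w, mask)
  expect_equal(unname(so["muscle"]), 0.5)
  expect_equal(unname(so["vat"]), 0.25)
  expect_equal(unname(so["background"]), 0.25)
  expect_equal(sum(so), 1)
  # concentration on muscle
  w2 <- matrix(0, 2, 2); w2[1, ] <- c(-2, 5)
  so2 <- observed_saliency(w2, mask)
  expect_equal(unname(so2["muscle"]), 1)
  expect_error(observed_saliency(matrix(0, 2, 2), mask),
               "undefined saliency")
})

test_that("uniform saliency reproduces expected fractions exactly", {
  ph <- make_phantom(small_phantom_spec(seed = 4))
  w <- matrix(1, nrow(ph$mask), ncol(ph$mask))
  expect_equal(observed_saliency(w, ph$mask), expected_saliency(ph$mask),
               tolerance = 0)
})

test_that("observed saliency is invariant to rescaling the map", {
  set.seed(8)
  ph <- make_phantom(small_phantom_spec(seed = 8))
  w <- matrix(rnorm(length(ph$mask)), nrow(ph$mask))
  base <- observed_saliency(w, ph$mask)
  for (c_ in c(2, -3, 1e-6)) {
    expect_equal(observed_saliency(c_ * w, ph$mask), base,
                 tolerance = 1e-12)
  }
})

test_that("expected saliency matches the analytic phantom geometry", {
  spec <- phantom_spec(image_size = 256, seed = 2)
  ph <- make_phantom(spec)
  se <- expected_saliency(ph$mask)
  expect_equal(sum(se), 1, tolerance = 1e-12)
  # analytic ellipse areas in pixels
  px_area <- prod(spec$pixel_spacing_mm)
  total <- 256^2 * px_area
  ax <- spec$body_axes_mm
  body_frac <- pi * ax[1] * ax[2] / total
  sat_frac <- pi * (ax[1] * ax[2] -
                      (ax[1] - 25) * (ax[2] - 25)) / total
  expect_equal(1 - unname(se["background"]), body_frac, tolerance = 0.01)
  expect_equal(unname(se["sat"]), sat_frac, tolerance = 0.01)
  single <- matrix(1L, 4, 4)
  expect_equal(unname(expected_saliency(single)["muscle"]), 1)
  half <- matrix(c(1L, 1L, 2L, 2L), 2)
  expect_equal(unname(expected_saliency(half)["muscle"]), 0.5)
})

test_that("saliency class assignment follows the body-mask-wins rule", {
  labs <- tissue_labels()
  mask <- matrix(c(labs["bone"], labs["muscle"], labs["other"],
                   labs["vat"]), 2)
  body <- matrix(c(TRUE, FALSE, TRUE, TRUE), 2)
  out <- assign_saliency_classes(mask, body)
  expect_equal(out[1, 1], unname(labs["other"]))      # bone collapses
  expect_equal(out[2, 1], unname(labs["background"])) # outside body wins
  expect_equal(out[1, 2], unname(labs["other"]))
  expect_equal(out[2, 2], unname(labs["vat"]))
  all_bg <- assign_saliency_classes(mask, matrix(FALSE, 2, 2))
  expect_true(all(all_bg == labs["background"]))
})

test_that("full linear pipeline matches the closed-form L1 partition", {
  set.seed(12)
  for (i in 1:5) {
    ph <- make_phantom(small_phantom_spec(seed = 100 + i))
    W <- matrix(rnorm(length(ph$mask)), nrow(ph$mask))
    sc <- linear_scorer(W)
    input <- prepare_scorer_input(ph$slice)
    w <- pixel_saliency(sc, input)
    so <- observed_saliency(w, ph$mask)
    labs <- tissue_labels()
    # closed form: |W| summed per class (3 channels cancel in the ratio)
    closed <- vapply(c("background", "muscle", "vat", "sat", "other"),
                     function(cl) sum(abs(W)[ph$mask == labs[cl]]) /
                       sum(abs(W)), numeric(1))
    expect_equal(unname(so), unname(closed), tolerance = 1e-10)
  }
})

test_that("cohort aggregation computes ratio of means and paired tests", {
  mk <- function(o, e) structure(list(
    observed = stats::setNames(o, core_names),
    expected = stats::setNames(e, core_names)), class = "tissue_saliency")
  core_names <- c("background", "muscle", "vat", "sat", "other")
  r1 <- mk(c(0.2, 0.4, 0.2, 0.1, 0.1), c(0.35, 0.25, 0.2, 0.1, 0.1))
  r2 <- mk(c(0.1, 0.6, 0.1, 0.1, 0.1), c(0.45, 0.25, 0.1, 0.1, 0.1))
  cs <- cohort_saliency(list(r1, r2))
  tab <- cs$table
  expect_equal(tab$ratio[tab$class == "muscle"], 0.5 / 0.25)
  expect_equal(cs$n_images, 2)
  # identical observed and expected: ratio 1, t = 0, p = 1
  same <- mk(c(0.2, 0.2, 0.2, 0.2, 0.2), c(0.2, 0.2, 0.2, 0.2, 0.2))
  cs2 <- cohort_saliency(list(same, same))
  expect_true(all(cs2$table$ratio == 1))
  expect_true(all(cs2$table$p == 1))
  expect_warning(cohort_saliency(list(r1)), "n < 2")
})

test_that("a planted VAT scorer is recovered as the top cohort ratio", {
  set.seed(77)
  n_img <- 20
  results <- vector("list", n_img)
  for (i in seq_len(n_img)) {
    ph <- make_phantom(small_phantom_spec(seed = 300 + i))
    labs <- tissue_labels()
    W <- matrix(rnorm(length(ph$mask), 0, 0.05), nrow(ph$mask))
    W[ph$mask == labs["vat"]] <- W[ph$mask == labs["vat"]] + 1
    sc <- linear_scorer(W)
    body <- extract_body_mask(ph$slice)
    w <- pixel_saliency(sc, prepare_scorer_input(ph$slice))
    results[[i]] <- tissue_saliency(w, assign_saliency_classes(ph$mask,
                                                               body))
  }
  cs <- cohort_saliency(results)
  tab <- cs$table
  vat_ratio <- tab$ratio[tab$class == "vat"]
  expect_gt(vat_ratio, 1)
  expect_equal(tab$class[which.max(tab$ratio)], "vat")
  expect_lt(tab$ratio[tab$class == "background"], 1)
  expect_lt(tab$p[tab$class == "vat"], 0.001)
})

test_that("zero-saliency images are excluded and counted, not imputed", {
  ph1 <- make_phantom(small_phantom_spec(seed = 41))
  ph2 <- make_phantom(small_phantom_spec(seed = 42))
  # a scorer flat on one image: gradient vanishes when the input sum
  # sits below a cutoff placed between the two phantoms' input sums
  s1 <- sum(prepare_scorer_input(ph1$slice))
  s2 <- sum(prepare_scorer_input(ph2$slice))
  cutoff <- (s1 + s2) / 2
  lo_first <- s1 < s2
  sc <- structure(list(
    score = function(x) max(sum(x) - cutoff, 0),
    gradient = function(x) array(as.numeric(sum(x) > cutoff),
                                 dim = dim(x))), class = "scorer")
  mixed <- suppressWarnings(  # single surviving image: t-test undefined
    run_tissue_saliency(sc, list(ph1$slice, ph2$slice),
                        list(ph1$mask, ph2$mask)))
  expect_equal(mixed$n_images, 1)
  expect_equal(mixed$n_zero_saliency, 1L)
  # every image flat -> explicit error, never a silent NaN
  flat <- structure(list(score = function(x) 0,
                         gradient = function(x) array(0, dim = dim(x))),
                    class = "scorer")
  expect_error(run_tissue_saliency(flat, list(ph1$slice),
                                   list(ph1$mask)),
               "zero total saliency")
})
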