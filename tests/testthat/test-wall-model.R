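test_that("default presets encode the reported wall architecture", {
  m <- default_wall_model("YTT")
  th <- vapply(m$layers, function(l) l$thickness, numeric(1))
  names(th) <- vapply(m$layers, function(l) l$name, character(1))
  expect_equal(sum(th), 15000)
  expect_gte(th[["POZ"]], 1000)   # printed 1-1.5 um Ca-poor zone
  expect_lte(th[["POZ"]], 1500)
  expect_gt(th[["OCL"]], th[["ICL"]])
  ca <- function(layer) m$layers[[match(layer, c("ICL", "POZ", "OCL", "GC"))]]$concentration_scale[["Ca.Ka"]]
  expect_equal(ca("GC") / ca("POZ"), 1.5)   # crust ~50% more Ca than POZ
  expect_equal(ca("ICL") / ca("POZ"), 1.2)

  mod <- default_wall_model("modern")
  expect_equal(wall_thickness(mod), 5000)
  expect_error(default_wall_model("fossil"), "arg")
})

test_that("constructors reject invalid geometry and scales", {
  expect_error(layer_spec("POZ", -5, c(Ca.Ka = 1)), "positive")
  expect_error(layer_spec("POZ", 100, c(Ca.Ka = -1)), ">= 0")
  expect_error(banding_spec("Mn.Ka", 500, 400, c(ICL = 0.1)), "band_width")
  m <- default_wall_model("YTT")
  expect_error(wall_model(m$layers[c(2, 1, 3, 4)], bulk_scale = c(Ca.Ka = 1)),
               "order")
  expect_error(acquisition_spec(dwell_time = 0), "dwell_time")
})

test_that("concentration field matches the layer scales and banding model", {
  m <- default_wall_model("YTT")
  # centre of the crust: no banding there, bare layer scale
  expect_equal(concentration_profile(m, "Mn.Ka", 12625), 0.05)
  # ICL Ca at a modulation node (banding clock distance 150 nm mod 300 from
  # the POZ-facing edge): bare layer scale
  expect_equal(concentration_profile(m, "Ca.Ka", 3000 - 150), 1.2)
  expect_error(concentration_profile(m, "Ca.Ka", -1), "within")
  expect_error(concentration_profile(m, "Ca.Ka", 15001), "within")
  # deterministic and non-negative over the full wall
  x <- seq(0, 15000, by = 7)
  for (ln in c("Ca.Ka", "Mn.Ka", "Mg.Ka", "P.Ka")) {
    y <- concentration_profile(m, ln, x)
    expect_identical(y, concentration_profile(m, ln, x))
    expect_true(all(y >= 0))
  }
})

test_that("per-unit-length Mn integrals of ICL and OCL are in ratio 2", {
  # the banding modulation is mean-subtracted, so layer densities reduce to
  # the bare scales 0.4 and 0.2
  m <- default_wall_model("YTT")
  dens <- function(a, b) {
    x <- seq(a, b, by = 1)
    y <- concentration_profile(m, "Mn.Ka", x)
    sum((y[-1] + y[-length(y)]) / 2) / (b - a)
  }
  expect_equal(dens(0, 3000) / dens(4250, 10250), 2.0, tolerance = 0.01)
})

test_that("rendered maps are integer, non-negative, and seed-reproducible", {
  m <- tiny_wall_model()
  acq <- acquisition_spec(pixel_size = 60, dwell_time = 3,
                          map_extent = c(42, 5), seed = 99)
  s1 <- render_element_maps(m, acq)
  s2 <- render_element_maps(m, acq)
  for (ln in names(s1$maps)) {
    expect_identical(s1$maps[[ln]]$counts, s2$maps[[ln]]$counts)
    expect_true(is.integer(s1$maps[[ln]]$counts))
    expect_true(all(s1$maps[[ln]]$counts >= 0))
  }
  # a line rendered alone matches its map in the full set
  solo <- render_element_maps(m, acq, "Mn.Ka")
  expect_identical(solo$maps$Mn.Ka$counts, s1$maps$Mn.Ka$counts)
})

test_that("zero bulk scale yields an all-zero map", {
  m <- tiny_wall_model()
  m$bulk_scale[["Mn.Ka"]] <- 0
  acq <- acquisition_spec(map_extent = c(42, 3), seed = 1)
  s <- render_element_maps(m, acq, "Mn.Ka")
  expect_true(all(s$maps$Mn.Ka$counts == 0L))
})

test_that("renderer is Poisson: mean matches expectation and dispersion is unit", {
  m <- tiny_wall_model()
  acq <- acquisition_spec(map_extent = c(42, 4), seed = 0)
  lam <- expected_element_maps(m, acq, "Mn.Ka")$Mn.Ka
  nseed <- 200
  s <- 0; s2 <- 0
  for (k in seq_len(nseed)) {
    a <- acquisition_spec(map_extent = c(42, 4), seed = k)
    x <- render_element_maps(m, a, "Mn.Ka")$maps$Mn.Ka$counts
    s <- s + x; s2 <- s2 + x^2
  }
  mn <- s / nseed
  vr <- (s2 - nseed * mn^2) / (nseed - 1)
  # empirical mean vs analytic expectation, aggregated over pixels
  expect_equal(mean(mn), mean(lam), tolerance = 0.01)
  z <- (mn - lam) / sqrt(lam / nseed)
  expect_lt(abs(mean(z)), 4 / sqrt(length(lam)) * 2 + 0.2)
  # index of dispersion: per-pixel variance/mean averaged over pixels
  disp <- mean(vr[lam > 0] / mn[lam > 0])
  expect_gt(disp, 0.9)
  expect_lt(disp, 1.1)
})

test_that("a mirror-symmetric wall renders a mirror-symmetric expected map", {
  layers <- list(
    layer_spec("ICL", 500, c(Ca.Ka = 1.3)),
    layer_spec("POZ", 600, c(Ca.Ka = 0.8)),
    layer_spec("OCL", 600, c(Ca.Ka = 0.8)),
    layer_spec("GC", 500, c(Ca.Ka = 1.3))
  )
  m <- wall_model(layers, bulk_scale = c(Ca.Ka = 1e4))
  acq <- acquisition_spec(pixel_size = 55, map_extent = c(40, 2), seed = 1)
  lam <- expected_element_maps(m, acq, "Ca.Ka")$Ca.Ka[1, ]
  expect_equal(lam, rev(lam), tolerance = 1e-10)
})

test_that("expected totals are invariant under pixel-size refinement", {
  # same physical extent (2500 nm wall) sampled at 50 and 25 nm pixels;
  # totals per row agree to well under 0.5%
  m <- tiny_wall_model()
  # depth-integral scale: per-row total times pixel size
  tot <- vapply(c(50, 25), function(px) {
    extent <- c(wall_thickness(m) / px, 2)
    acq <- acquisition_spec(pixel_size = px, map_extent = extent, seed = 1)
    px * sum(expected_element_maps(m, acq, "Ca.Ka")$Ca.Ka) / extent[2]
  }, numeric(1))
  expect_equal(tot[1], tot[2], tolerance = 0.005)
  # and the map total matches the depth-integral bulk expectation up to the
  # beam-tail leakage at the two wall edges (sub-percent here)
  acq <- acquisition_spec(pixel_size = 50, map_extent = c(50, 2), seed = 1)
  eb <- expected_bulk_counts(m, acq, "Ca.Ka")
  expect_equal(tot[1], 50 * unname(eb), tolerance = 0.02)
})

test_that("bulk expectations are linear in dwell and zero for absent lines", {
  m <- tiny_wall_model()
  m$bulk_scale[["Mn.Ka"]] <- 0
  a1 <- acquisition_spec(dwell_time = 3, map_extent = c(42, 3), seed = 1)
  a2 <- acquisition_spec(dwell_time = 6, map_extent = c(42, 3), seed = 1)
  e1 <- expected_bulk_counts(m, a1)
  e2 <- expected_bulk_counts(m, a2)
  expect_equal(e2, 2 * e1)
  expect_equal(unname(e1["Mn.Ka"]), 0)
  expect_gt(e1[["Ca.Ka"]], 0)
})

test_that("fossil/modern presets encode a bulk Mn enrichment of 7.5", {
  ytt <- default_wall_model("YTT")
  mod <- default_wall_model("modern")
  ay <- default_acquisition(ytt, seed = 1)
  am <- default_acquisition(mod, seed = 1)
  r <- expected_bulk_counts(ytt, ay, "Mn.Ka") / expected_bulk_counts(mod, am, "Mn.Ka")
  expect_equal(unname(r), 7.5, tolerance = 1e-6)
})
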