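test_that("segmentation recovers the generator layer boundaries within 2 px", {
  fx <- ytt_fixture()
  seg <- segment_wall(fx$profiles$Ca.Ka)
  truth <- c(ICL_POZ = 3000, POZ_OCL = 4250, OCL_GC = 10250)
  expect_true(all(abs(seg$boundaries - truth) <= 2 * 60))
  poz_width <- seg$boundaries["POZ_OCL"] - seg$boundaries["ICL_POZ"]
  expect_gte(unname(poz_width), 1000)   # printed 1-1.5 um
  expect_lte(unname(poz_width), 1500)
})

test_that("degenerate Ca profiles raise segmentation failures", {
  flat <- make_profile(((1:100) - 0.5) * 60, rep(500, 100),
                       sqrt(rep(500 * 21, 100)) / 21, line = "Ca.Ka")
  expect_error(segment_wall(flat), "segmentation failure")
  mono <- make_profile(((1:100) - 0.5) * 60, seq(100, 1000, length.out = 100),
                       rep(3, 100), line = "Ca.Ka")
  expect_error(segment_wall(mono), "segmentation failure")
})

test_that("segmentation is equivariant under profile reversal", {
  fx <- ytt_fixture()
  ca <- fx$profiles$Ca.Ka
  seg <- segment_wall(ca, orientation = "inner_first")
  rev_ca <- make_profile(ca$position, rev(ca$counts), rev(ca$sigma),
                         line = "Ca.Ka", width = 21L)
  seg_r <- segment_wall(rev_ca, orientation = "outer_first")
  total <- length(ca$position) * 60
  expect_equal(unname(sort(total - seg_r$boundaries)),
               unname(sort(seg$boundaries)))
  # labels mirror: the POZ sits at mirrored positions
  expect_equal(sum(seg$labels == "POZ"), sum(seg_r$labels == "POZ"))
})

test_that("per-layer enrichments recover the generator contrasts", {
  fx <- ytt_fixture()
  seg <- segment_wall(fx$profiles$Ca.Ka)
  st <- layer_statistics(fx$profiles[c("Ca.Ka", "Mn.Ka")], seg = seg)
  enr <- function(src, layer) st$enrichment[st$source == src & st$layer == layer]
  expect_equal(enr("Mn.Ka", "ICL"), 0.4, tolerance = 0.1)
  expect_equal(enr("Mn.Ka", "OCL"), 0.2, tolerance = 0.1)
  expect_equal(enr("Ca.Ka", "OCL"), 1.5, tolerance = 0.1)
  expect_equal(enr("Ca.Ka", "GC"), 1.5, tolerance = 0.1)
  expect_equal(enr("Ca.Ka", "POZ"), 1)
})

test_that("an all-equal profile has unit enrichment everywhere", {
  fx <- ytt_fixture()
  seg <- segment_wall(fx$profiles$Ca.Ka)
  const <- make_profile(fx$profiles$Ca.Ka$position,
                        rep(42, length(seg$position)),
                        rep(1, length(seg$position)), line = "S.Ka")
  st <- layer_statistics(list(S.Ka = const), seg = seg)
  expect_equal(st$enrichment, rep(1, 4))
})

test_that("empty layers are reported with undefined statistics", {
  fx <- ytt_fixture()
  seg <- segment_wall(fx$profiles$Ca.Ka)
  seg$labels[seg$labels == "GC"] <- "OCL"   # no crust points left
  expect_warning(
    st <- layer_statistics(fx$profiles["Ca.Ka"], seg = seg),
    "empty"
  )
  expect_true(is.na(st$mean[st$layer == "GC"]))
})

test_that("correlation handles exact lines and degenerate inputs", {
  pos <- ((1:50) - 0.5) * 60
  x <- make_ratio(pos, seq(0.001, 0.05, length.out = 50), rep(1e-4, 50))
  y <- make_ratio(pos, 0.19 * x$ratio, rep(1e-5, 50), num = "Zn.Ka")
  r <- correlate_ratios(x, y)
  expect_equal(r$slope, 0.19, tolerance = 1e-12)
  expect_equal(r$pearson_rho, 1)
  yneg <- make_ratio(pos, -x$ratio, rep(1e-5, 50))
  expect_equal(correlate_ratios(x, yneg)$pearson_rho, -1)
  xconst <- make_ratio(pos, rep(0.02, 50), rep(1e-4, 50))
  expect_warning(rz <- correlate_ratios(xconst, y), "zero variance")
  expect_true(is.na(rz$slope))
})

test_that("the fit is shift-invariant and rho is affine-invariant", {
  set.seed(11)
  pos <- ((1:80) - 0.5) * 60
  xv <- runif(80, 0.001, 0.02)
  yv <- 0.19 * xv + rnorm(80, 0, 5e-4)
  x <- make_ratio(pos, xv, rep(1e-4, 80))
  y <- make_ratio(pos, yv, rep(1e-4, 80), num = "Zn.Ka")
  y_shift <- make_ratio(pos, yv + 0.37, rep(1e-4, 80), num = "Zn.Ka")
  expect_equal(correlate_ratios(x, y_shift)$slope,
               correlate_ratios(x, y)$slope, tolerance = 1e-12)
  x_aff <- make_ratio(pos, 2.5 * xv + 1, rep(1e-4, 80))
  expect_equal(correlate_ratios(x_aff, y)$pearson_rho,
               correlate_ratios(x, y)$pearson_rho, tolerance = 1e-12)
})

test_that("synthetic Zn/Ca vs Mn/Ca recovers the encoded 0.19 slope", {
  fx <- ytt_fixture()
  mnca <- ratio_profile(fx$profiles$Mn.Ka, fx$profiles$Ca.Ka)
  znca <- ratio_profile(fx$profiles$Zn.Ka, fx$profiles$Ca.Ka)
  r <- correlate_ratios(mnca, znca)
  expect_gte(0.19, r$slope_ci[1])
  expect_lte(0.19, r$slope_ci[2])
  expect_gt(r$pearson_rho, 0.97)
})

test_that("trajectories place the layers at the expected scatter extremes", {
  fx <- ytt_fixture()
  seg <- segment_wall(fx$profiles$Ca.Ka)
  tr <- trajectory(fx$profiles$Mn.Ka, fx$profiles$Ca.Ka, seg)
  means <- aggregate(cbind(x, y) ~ layer, tr, mean)
  poz <- means[means$layer == "POZ", ]
  gc <- means[means$layer == "GC", ]
  expect_equal(poz$x, max(means$x))  # POZ: Mn-richest
  expect_equal(poz$y, min(means$y))  # POZ: Ca-poorest
  expect_equal(gc$x, min(means$x))   # crust: Mn-poorest
  # crust among the Ca-richest (shares the OCL's Ca level)
  expect_gt(gc$y, 0.99 * max(means$y))
  expect_gt(gc$y, means$y[means$layer == "ICL"])
})

test_that("constant profiles collapse each layer to one repeated point", {
  fx <- ytt_fixture()
  seg <- segment_wall(fx$profiles$Ca.Ka)
  n <- length(seg$position)
  cx <- make_profile(seg$position, rep(3, n), rep(1, n), line = "Mn.Ka")
  cy <- make_profile(seg$position, rep(8, n), rep(1, n), line = "Ca.Ka")
  tr <- trajectory(cx, cy, seg)
  expect_true(all(tr$x == 3) && all(tr$y == 8))
  expect_setequal(unique(as.character(tr$layer)),
                  c("ICL", "POZ", "OCL", "GC"))
})
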