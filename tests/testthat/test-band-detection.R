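test_that("central differences are exact for polynomials up to degree 2", {
  pos <- (0:20) * 1
  lin <- make_ratio(pos, 3 + 0.5 * pos, rep(0.01, 21))
  expect_equal(second_derivative(lin)$d2, rep(0, 19))
  quad <- make_ratio(pos, pos^2, rep(0.01, 21))
  expect_equal(second_derivative(quad)$d2, rep(2, 19))
})

test_that("second-derivative error on a sinusoid shrinks as dx^2", {
  omega <- 2 * pi / 500
  err <- vapply(c(20, 10), function(dx) {
    pos <- seq(0, 3000, by = dx)
    rp <- make_ratio(pos, sin(omega * pos), rep(0, length(pos)))
    d2 <- second_derivative(rp)
    max(abs(d2$d2 - (-omega^2 * sin(omega * d2$position))))
  }, numeric(1))
  expect_gt(err[1] / err[2], 3)   # halving dx cuts the error ~4x
  expect_lt(err[1] / err[2], 5)
})

test_that("non-uniform spacing and short profiles are rejected", {
  rp <- make_ratio(c(0, 10, 25), c(1, 1, 1), rep(0.1, 3))
  expect_error(second_derivative(rp), "uniform")
  rp2 <- make_ratio(c(0, 10), c(1, 1), rep(0.1, 2))
  expect_error(second_derivative(rp2), "at least 3")
})

test_that("propagated d2 uncertainty carries the stencil factors", {
  pos <- (0:10) * 1
  s <- 0.02
  rp <- make_ratio(pos, rep(1, 11), rep(s, 11))
  exact <- d2_uncertainty(rp, "exact_sqrt6")
  expect_equal(exact$sigma_d2, rep(sqrt(6) * s, 9))
  expect_equal(exact$threshold, sqrt(6) * s)
  oper <- d2_uncertainty(rp, "paper_factor2")
  expect_equal(oper$threshold / exact$threshold, 2 / sqrt(6))
  expect_error(d2_uncertainty(rp, "bogus_method"), "arg")
})

test_that("exact propagation matches the Monte-Carlo spread of d2", {
  # oracle: empirical SD of the three-point stencil over 1e5 Poisson
  # replicates of a flat trace/Ca ratio
  sx <- 2500; sy <- 250000
  n <- 1e5
  set.seed(2718)
  x <- matrix(rpois(3 * n, sx), ncol = 3)
  y <- matrix(rpois(3 * n, sy), ncol = 3)
  r <- x / y
  d2 <- (r[, 3] - 2 * r[, 2] + r[, 1])   # dx = 1
  emp <- sd(d2)
  sigma_r <- (sx / sy) * sqrt(1 / sx + 1 / sy)
  expect_equal(sqrt(6) * sigma_r, emp, tolerance = 0.03)
})

test_that("noise-free sinusoids give the analytic band count and widths", {
  P <- 600; L <- 6000; dx <- 20
  pos <- seq(0, L, by = dx)
  rp <- make_ratio(pos, 1 + 0.2 * sin(2 * pi * pos / P),
                   rep(1e-9, length(pos)))
  d2p <- attach_uncertainty(second_derivative(rp),
                            d2_uncertainty(rp, "exact_sqrt6"))
  bs <- detect_bands(d2p)
  expect_true(all(bs$bands$significant))
  n_expect <- floor(2 * L / P)
  expect_gte(nrow(bs$bands), n_expect - 1)
  expect_lte(nrow(bs$bands), n_expect + 1)
  interior <- bs$bands[-c(1, nrow(bs$bands)), ]
  expect_true(all(abs(interior$width - P / 2) <= dx))
  # alternating signs by construction
  expect_true(all(interior$sign[-1] != interior$sign[-nrow(interior)]))
})

test_that("band recovery is complete for strong noise-free bands", {
  # bands with |d2| extrema > 10x threshold: recall 100%, widths within 2 px
  P <- 600; L <- 6000; dx <- 60
  pos <- seq(dx / 2, L, by = dx)
  amp <- 0.2
  rp <- make_ratio(pos, 1 + amp * sin(2 * pi * pos / P),
                   rep(amp * (2 * pi / P)^2 * dx^2 / (sqrt(6) * 20),
                       length(pos)))
  d2p <- attach_uncertainty(second_derivative(rp),
                            d2_uncertainty(rp, "exact_sqrt6"))
  expect_gt(max(abs(d2p$d2)) / d2p$threshold, 10)
  bs <- detect_bands(d2p)
  sig <- bs$bands[bs$bands$significant, ]
  # true enriched band centres (ratio maxima) interior to the trace
  centres <- seq(P / 4, L, by = P)
  centres <- centres[centres > pos[2] & centres < pos[length(pos) - 1]]
  hits <- vapply(centres, function(cc) {
    any(sig$start <= cc & sig$end >= cc & sig$sign == "enriched")
  }, logical(1))
  expect_true(all(hits))                      # 100% recall
  interior <- sig[sig$start > pos[2] & sig$end < pos[length(pos) - 1], ]
  expect_true(all(abs(interior$width - P / 2) <= 2 * dx))
})

test_that("pure-noise profiles rarely produce significant bands at 3 sigma", {
  sx <- 2500; sy <- 250000
  npt <- 10
  pos <- ((1:npt) - 0.5) * 60
  zero_sig <- vapply(1:100, function(seed) {
    set.seed(seed)
    px <- make_profile(pos, rpois(npt, sx), sqrt(rep(sx, npt)), line = "Mn.Ka")
    py <- make_profile(pos, rpois(npt, sy), sqrt(rep(sy, npt)), line = "Ca.Ka")
    rp <- ratio_profile(px, py)
    d2p <- attach_uncertainty(second_derivative(rp),
                              d2_uncertainty(rp, "exact_sqrt6",
                                             multiplier = 3))
    detect_bands(d2p)$n_significant == 0L
  }, logical(1))
  expect_gte(sum(zero_sig), 95)
})

test_that("detection is invariant to offsets and equivariant to scaling", {
  P <- 600; dx <- 20
  pos <- seq(0, 3000, by = dx)
  base <- 1 + 0.1 * sin(2 * pi * pos / P)
  sig <- rep(1e-4, length(pos))
  mk <- function(r, s) {
    rp <- make_ratio(pos, r, s)
    attach_uncertainty(second_derivative(rp), d2_uncertainty(rp, "exact_sqrt6"))
  }
  b0 <- detect_bands(mk(base, sig))
  b_shift <- detect_bands(mk(base + 5, sig))
  expect_equal(b_shift$bands, b0$bands)
  cfac <- 3.7
  d2s <- mk(base * cfac, sig * cfac)
  b_scale <- detect_bands(d2s)
  expect_equal(b_scale$bands$extremum, cfac * b0$bands$extremum)
  expect_equal(b_scale$bands$significant, b0$bands$significant)
  expect_equal(b_scale$bands$start, b0$bands$start)
})

test_that("an all-zero second derivative yields an empty band set", {
  pos <- (0:10) * 10
  rp <- make_ratio(pos, rep(2, 11), rep(0.01, 11))
  d2p <- attach_uncertainty(second_derivative(rp),
                            d2_uncertainty(rp, "exact_sqrt6"))
  bs <- detect_bands(d2p)
  expect_equal(nrow(bs$bands), 0L)
  expect_equal(bs$n_significant, 0L)
})

test_that("fossil-wall Mn/Ca bands are a few hundred nm and anti-phase with Ca", {
  fx <- ytt_fixture()
  rp <- ratio_profile(fx$profiles$Mn.Ka, fx$profiles$Ca.Ka)
  d2p <- attach_uncertainty(second_derivative(rp),
                            d2_uncertainty(rp, "exact_sqrt6"))
  bs <- detect_bands(d2p)
  expect_gt(bs$n_significant, 10)
  # significant bands inside the banded calcitic layers have widths on the
  # generator's 300 nm scale
  sig <- bs$bands[bs$bands$significant & bs$bands$start > 4250 &
                    bs$bands$end < 10250, ]
  expect_gt(nrow(sig), 5)
  expect_true(median(sig$width) > 150 && median(sig$width) < 450)
  # anti-phase: within the OCL the Mn/Ca modulation opposes the Ca one
  keep <- rp$position > 4400 & rp$position < 10100
  detrend <- function(v) v - stats::filter(v, rep(1 / 11, 11))
  expect_lt(cor(detrend(rp$ratio)[keep],
                detrend(fx$profiles$Ca.Ka$counts)[keep],
                use = "complete.obs"),
            -0.3)
})
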