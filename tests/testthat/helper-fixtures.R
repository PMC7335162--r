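# fixtures are built in code: small wall models and hand-made profiles

# a reduced wall for cheap property checks (same architecture, ~2.5 um)
tiny_wall_model <- function() {
  scales <- function(ICL, POZ, OCL, GC) c(ICL = ICL, POZ = POZ, OCL = OCL, GC = GC)
  layers <- list(
    layer_spec("ICL", 600, c(Ca.Ka = 1.2, Mn.Ka = 0.4)),
    layer_spec("POZ", 400, c(Ca.Ka = 1.0, Mn.Ka = 1.0)),
    layer_spec("OCL", 900, c(Ca.Ka = 1.5, Mn.Ka = 0.2)),
    layer_spec("GC", 600, c(Ca.Ka = 1.5, Mn.Ka = 0.05))
  )
  bandings <- list(
    banding_spec("Mn.Ka", 150, 300, c(ICL = 0.5, OCL = 0.2),
                 phase = "anti_phase_with_Ca")
  )
  wall_model(layers, bandings, pos_position = 200,
             bulk_scale = c(Ca.Ka = 2e4, Mn.Ka = 800))
}

constant_map <- function(value, nr = 25, nc = 40, line = "Ca.Ka",
                         pixel_size = 60, dwell_time = 3) {
  element_map(line, matrix(as.integer(value), nr, nc),
              pixel_size = pixel_size, dwell_time = dwell_time)
}

# profile object built directly from arrays (for analytic band tests)
make_profile <- function(position, counts, sigma, line = "X.Ka", width = 1L) {
  foramXRF:::new_xrf_profile(line = line, position = position,
                             counts = counts, sigma = sigma,
                             averaging_width = width)
}

make_ratio <- function(position, ratio, sigma, num = "Mn.Ka", den = "Ca.Ka") {
  structure(list(numerator = num, denominator = den, position = position,
                 ratio = ratio, sigma = sigma, n_masked = 0L),
            class = "ratio_profile")
}

# default-YTT render shared across tests (cached per session)
ytt_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- default_wall_model("YTT")
      acq <- default_acquisition(m, seed = 20240917)
      stack <- render_element_maps(m, acq, c("Ca.Ka", "Mn.Ka", "Zn.Ka"))
      mid <- (acq$map_extent[2] + 1) %/% 2
      w <- acq$map_extent[1]
      profs <- lapply(stack$maps, function(mp)
        extract_profile(mp, c(mid, 1), c(mid, w), width = 21))
      cache <<- list(model = m, acq = acq, stack = stack, profiles = profs)
    }
    cache
  }
})
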