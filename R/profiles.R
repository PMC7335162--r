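# Averaged 1D profiles across the wall and elemental-ratio traces with
# Poisson-propagated uncertainties.
#
# Counting statistics follow the Poisson rule: the uncertainty of a raw count
# N is sqrt(N). Averaging across a w-pixel-wide rectangle keeps profiles in
# per-pixel count units, so a profile point is S = (sum of raw counts)/w with
# sigma_S = sqrt(sum)/w.

new_xrf_profile <- function(line, position, counts, sigma, averaging_width,
                            raw_sums = NULL) {
  structure(list(line = line, position = position, counts = counts,
                 sigma = sigma, averaging_width = averaging_width,
                 raw_sums = raw_sums),
            class = "xrf_profile")
}

#' @export
print.xrf_profile <- function(x, ...) {
  cat(sprintf("<xrf_profile> %s  %d points, width %s px, [%g, %g] nm\n",
              x$line, length(x$position), x$averaging_width,
              min(x$position), max(x$position)))
  invisible(x)
}

#' Extract an averaged profile from an element map
#'
#' Averages raw counts across an axis-aligned rectangle of odd width centred
#' on the extraction axis (the conventional 21 pixel-wide box for nanoprobe
#' maps). For each position along the axis, `counts` is the sum across the
#' width divided by the width and `sigma` is `sqrt(sum)/width`; positions are
#' pixel centres converted to nm. Points whose summed raw counts are zero get
#' the Poisson unit floor `sigma = 1/width` so error bars never collapse.
#'
#' @param map An [element_map()].
#' @param axis_start,axis_end `c(row, col)` pixel indices (1-based) of the
#'   axis ends; the axis must be aligned with a grid direction (same row or
#'   same column).
#' @param width Averaging width in pixels (odd, >= 1).
#' @return An object of class `xrf_profile`.
#' @export
#' @examples
#' m <- element_map("Ca.Ka", matrix(100L, 25, 40), pixel_size = 60,
#'                  dwell_time = 3)
#' p <- extract_profile(m, c(13, 1), c(13, 40), width = 21)
extract_profile <- function(map, axis_start, axis_end, width = 21) {
  stopifnot(inherits(map, "element_map"))
  if (width < 1 || width %% 2 == 0) stop("width must be odd and >= 1")
  hw <- (width - 1) / 2
  counts <- map$counts
  if (axis_start[1] == axis_end[1]) {          # horizontal axis, along columns
    r <- axis_start[1]
    cols <- axis_start[2]:axis_end[2]
    rows <- (r - hw):(r + hw)
    if (min(rows) < 1 || max(rows) > nrow(counts) ||
        min(cols) < 1 || max(cols) > ncol(counts)) {
      stop("extraction rectangle out of bounds")
    }
    sums <- colSums(counts[rows, cols, drop = FALSE])
    idx <- cols
  } else if (axis_start[2] == axis_end[2]) {   # vertical axis, along rows
    cc <- axis_start[2]
    rows <- axis_start[1]:axis_end[1]
    cols <- (cc - hw):(cc + hw)
    if (min(rows) < 1 || max(rows) > nrow(counts) ||
        min(cols) < 1 || max(cols) > ncol(counts)) {
      stop("extraction rectangle out of bounds")
    }
    sums <- rowSums(counts[rows, cols, drop = FALSE])
    idx <- rows
  } else {
    stop("extraction axis must be grid-aligned (same row or same column)")
  }
  sigma <- sqrt(pmax(sums, 1)) / width  # unit floor for zero-count sums
  new_xrf_profile(line = map$line,
                  position = (idx - 0.5) * map$pixel_size,
                  counts = sums / width, sigma = sigma,
                  averaging_width = width, raw_sums = sums)
}

#' Elemental-ratio profile with propagated uncertainty
#'
#' Forms the count-rate ratio `S_X/S_Y` of two profiles on one position grid
#' and propagates the Poisson uncertainties:
#' `sigma = (S_X/S_Y) * sqrt((sigma_X/S_X)^2 + (sigma_Y/S_Y)^2)`.
#' Because the dominating Ca line has very small relative uncertainty, the
#' relative uncertainty of a trace-element/Ca ratio is close to that of the
#' trace element alone. Points with zero denominator counts are masked (NA)
#' and reported via a warning and the `n_masked` field.
#'
#' @param num,den [extract_profile()] results on identical positions.
#' @return An object of class `ratio_profile` with fields `numerator`,
#'   `denominator`, `position`, `ratio`, `sigma`, `n_masked`.
#' @export
ratio_profile <- function(num, den) {
  stopifnot(inherits(num, "xrf_profile"), inherits(den, "xrf_profile"))
  if (length(num$position) != length(den$position) ||
      !isTRUE(all.equal(num$position, den$position))) {
    stop("profiles must share positions exactly")
  }
  bad <- den$counts <= 0
  if (any(bad)) {
    warning(sum(bad), " position(s) with zero denominator counts masked")
  }
  ratio <- ifelse(bad, NA_real_, num$counts / den$counts)
  # absolute form of the relative-quadrature rule; stays positive when the
  # numerator counts are zero (the numerator sigma carries the unit floor)
  sigma <- ifelse(bad, NA_real_,
                  sqrt((num$sigma / den$counts)^2 +
                       (num$counts * den$sigma / den$counts^2)^2))
  structure(list(numerator = num$line, denominator = den$line,
                 position = num$position, ratio = ratio,
                 sigma = sigma,
                 n_masked = sum(bad)),
            class = "ratio_profile")
}

#' @export
print.ratio_profile <- function(x, ...) {
  cat(sprintf("<ratio_profile> %s/%s  %d points (%d masked)\n",
              x$numerator, x$denominator, length(x$position), x$n_masked))
  invisible(x)
}
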