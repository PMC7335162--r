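# Wall-layer segmentation from a Ca profile and per-layer statistics.
#
# The ICL-POZ-OCL-GC architecture is recovered from the Ca trace alone:
# the Ca-poor POZ is the contiguous region around the global minimum whose
# counts stay below the midpoint between that minimum and the flanking layer
# medians; the outer OCL/GC boundary is placed where the Ca nano-banding
# variability (a rolling SD) collapses, since the homogeneous crust lacks the
# thin Ca-poor bands. The rule is parameter-light and is validated against
# the synthetic generator's ground truth rather than against any visual
# segmentation.

rolling_sd <- function(y, window) {
  n <- length(y)
  if (window > n) stop("rolling window longer than profile")
  cs <- cumsum(c(0, y))
  cs2 <- cumsum(c(0, y^2))
  i0 <- seq_len(n - window + 1L)
  s <- cs[i0 + window] - cs[i0]
  s2 <- cs2[i0 + window] - cs2[i0]
  v <- pmax((s2 - s^2 / window) / (window - 1), 0)
  sqrt(v)
}

#' Segment the wall layers from a Ca profile
#'
#' @param ca An [extract_profile()] result for the Ca line spanning the full
#'   wall.
#' @param orientation `"inner_first"` if the profile starts at the inner wall
#'   surface, `"outer_first"` if it starts at the outer surface. The caller
#'   must declare the orientation; it is never auto-detected.
#' @param window Rolling-SD window (pixels) for the crust boundary.
#' @param homogeneity_factor The crust is declared where the rolling SD stays
#'   below this fraction of the banded-region rolling-SD median.
#' @param min_contrast Minimum relative Ca depletion of the POZ below its
#'   flanks for the segmentation to be meaningful; flatter profiles raise a
#'   segmentation-failure error.
#' @return An object of class `wall_segmentation`: `boundaries` (named nm
#'   positions `ICL_POZ`, `POZ_OCL`, `OCL_GC`), `labels` (per-position layer
#'   factor), `position`.
#' @export
segment_wall <- function(ca, orientation = c("inner_first", "outer_first"),
                         window = 10, homogeneity_factor = 0.5,
                         min_contrast = 0.05) {
  stopifnot(inherits(ca, "xrf_profile"))
  orientation <- match.arg(orientation)
  flipped <- orientation == "outer_first"
  pos <- ca$position
  y <- ca$counts
  sig <- ca$sigma
  if (flipped) {
    y <- rev(y)
    sig <- rev(sig)
  }
  n <- length(y)
  dx <- .check_uniform(pos)
  imin <- which.min(y)
  if (imin <= 2 || imin >= n - 1) {
    stop("segmentation failure: no interior Ca minimum")
  }
  med_l <- stats::median(y[1:(imin - 1)])
  med_r <- stats::median(y[(imin + 1):n])
  m <- y[imin]
  if (min(med_l, med_r) - m < max(min_contrast * m, 5 * sig[imin])) {
    stop("segmentation failure: profile has no Ca-poor interior minimum")
  }
  thr_l <- (m + med_l) / 2
  thr_r <- (m + med_r) / 2
  i1 <- imin
  while (i1 > 1 && y[i1 - 1] < thr_l) i1 <- i1 - 1
  i2 <- imin
  while (i2 < n && y[i2 + 1] < thr_r) i2 <- i2 + 1
  if (i1 == 1 || i2 == n) {
    stop("segmentation failure: POZ reaches the profile edge")
  }
  x <- (seq_len(n) - 0.5) * dx  # internal inner-first coordinate
  b1 <- (x[i1 - 1] + x[i1]) / 2
  b2 <- (x[i2] + x[i2 + 1]) / 2
  # crust boundary: outermost point where the banding variability dies.
  # Right-aligned rolling SD over the region outward of the POZ.
  right <- (i2 + 1):n
  if (length(right) <= window + 2) {
    stop("segmentation failure: no room outward of the POZ")
  }
  rs <- rolling_sd(y[right], window)
  ends <- right[window:length(right)]      # window end indices
  ref <- stats::median(rs)
  thr_sd <- homogeneity_factor * ref
  # windows containing the outermost pixel see the beam's partial overlap
  # with the wall edge and are excluded from the homogeneity scan
  above <- which(rs[-length(rs)] >= thr_sd)
  if (!length(above) || max(above) == length(rs) - 1L) {
    stop("segmentation failure: no homogeneous crust found outward of the banding")
  }
  last_hi <- max(above)
  # a right-aligned window ending at index e still sees banded samples while
  # e - window + q <= B for the q ~ window * factor^2 samples that push the
  # partial SD over the threshold; invert that first-order relation
  q <- window * homogeneity_factor^2
  b3 <- x[ends[last_hi]] - (window - q - 1) * dx
  if (b3 <= b2 || b3 >= x[n]) {
    stop("segmentation failure: crust boundary collapsed onto the POZ")
  }
  bounds <- c(ICL_POZ = b1, POZ_OCL = b2, OCL_GC = b3)
  if (flipped) {
    total <- n * dx
    bounds <- sort(total - bounds)
    names(bounds) <- c("ICL_POZ", "POZ_OCL", "OCL_GC")  # outer-first axis
    labs <- cut(pos, c(-Inf, bounds, Inf),
                labels = c("GC", "OCL", "POZ", "ICL"))
  } else {
    labs <- cut(pos, c(-Inf, bounds, Inf),
                labels = c("ICL", "POZ", "OCL", "GC"))
  }
  structure(list(boundaries = bounds, labels = labs, position = pos,
                 orientation = orientation, window = window,
                 sd_threshold = thr_sd),
            class = "wall_segmentation")
}

#' @export
print.wall_segmentation <- function(x, ...) {
  b <- x$boundaries
  cat(sprintf("<wall_segmentation> ICL|POZ %g nm, POZ|OCL %g nm, OCL|GC %g nm (%s)\n",
              b[1], b[2], b[3], x$orientation))
  invisible(x)
}

#' Per-layer statistics and enrichment
#'
#' Means and SDs of each profile (and each ratio profile) within each
#' segmented layer, plus the relative enrichment of every layer over the POZ
#' (layer mean / POZ mean).
#'
#' @param profiles Named list of [extract_profile()] results.
#' @param ratio_profiles Named list of [ratio_profile()] results (optional).
#' @param seg A [segment_wall()] result on the same position grid.
#' @return An object of class `layer_stats`: a data frame with columns
#'   `source`, `layer`, `n`, `mean`, `sd`, `enrichment`.
#' @export
layer_statistics <- function(profiles, ratio_profiles = list(), seg) {
  stopifnot(inherits(seg, "wall_segmentation"))
  one <- function(name, position, values) {
    if (!isTRUE(all.equal(position, seg$position))) {
      stop("profile '", name, "' is not on the segmentation grid")
    }
    res <- lapply(.LAYER_NAMES, function(ln) {
      v <- values[seg$labels == ln]
      v <- v[!is.na(v)]
      if (!length(v)) {
        warning("layer ", ln, " is empty for ", name,
                "; statistics undefined")
        return(data.frame(source = name, layer = ln, n = 0L,
                          mean = NA_real_, sd = NA_real_))
      }
      data.frame(source = name, layer = ln, n = length(v),
                 mean = mean(v), sd = stats::sd(v))
    })
    df <- do.call(rbind, res)
    poz <- df$mean[df$layer == "POZ"]
    df$enrichment <- df$mean / poz
    df
  }
  out <- list()
  for (nm in names(profiles)) {
    p <- profiles[[nm]]
    out[[length(out) + 1L]] <- one(nm, p$position, p$counts)
  }
  for (nm in names(ratio_profiles)) {
    rp <- ratio_profiles[[nm]]
    out[[length(out) + 1L]] <- one(nm, rp$position, rp$ratio)
  }
  structure(do.call(rbind, out), class = c("layer_stats", "data.frame"))
}

#' Correlation and linear fit between two ratio profiles
#'
#' Ordinary least squares of `y` on `x` with free intercept, plus the Pearson
#' correlation, over all shared positions or restricted to one layer. The
#' slope confidence interval uses heteroscedasticity-robust (HC3) standard
#' errors, since Poisson ratio noise differs strongly between layers.
#'
#' @param x,y [ratio_profile()]s on identical positions.
#' @param seg Optional [segment_wall()] result for layer restriction.
#' @param layer Optional layer name to restrict to.
#' @param conf_level Confidence level for the slope interval.
#' @return An object of class `correlation_result`: `slope`, `intercept`,
#'   `pearson_rho`, `n`, `slope_ci` (two-sided), `conf_level`.
#' @export
correlate_ratios <- function(x, y, seg = NULL, layer = NULL,
                             conf_level = 0.95) {
  stopifnot(inherits(x, "ratio_profile"), inherits(y, "ratio_profile"))
  if (!isTRUE(all.equal(x$position, y$position))) {
    stop("ratio profiles must share positions")
  }
  keep <- !is.na(x$ratio) & !is.na(y$ratio)
  if (!is.null(layer)) {
    if (is.null(seg)) stop("layer restriction needs a segmentation")
    keep <- keep & seg$labels == layer
  }
  xv <- x$ratio[keep]
  yv <- y$ratio[keep]
  if (length(xv) < 3) stop("need at least 3 points")
  if (stats::sd(xv) == 0) {
    warning("zero variance in x; slope undefined")
    return(structure(list(slope = NA_real_, intercept = NA_real_,
                          pearson_rho = NA_real_, n = length(xv),
                          slope_ci = c(NA_real_, NA_real_),
                          conf_level = conf_level),
                     class = "correlation_result"))
  }
  fit <- stats::lm(yv ~ xv)
  # robust (HC3) slope interval: the Poisson noise is strongly
  # heteroscedastic across layers and the classical OLS interval undercovers
  X <- cbind(1, xv)
  e <- stats::resid(fit)
  h <- stats::hatvalues(fit)
  XtXi <- solve(crossprod(X))
  Xu <- X * (e / (1 - h))
  V <- XtXi %*% crossprod(Xu, Xu) %*% XtXi
  se <- sqrt(V[2, 2])
  tq <- stats::qt(1 - (1 - conf_level) / 2, length(xv) - 2)
  b <- unname(stats::coef(fit)[2])
  ci <- c(b - tq * se, b + tq * se)
  structure(list(slope = b,
                 intercept = unname(stats::coef(fit)[1]),
                 pearson_rho = stats::cor(xv, yv),
                 n = length(xv),
                 slope_ci = ci,
                 conf_level = conf_level),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> slope %.4g [%.4g, %.4g], rho %.4f, n %d\n",
              x$slope, x$slope_ci[1], x$slope_ci[2], x$pearson_rho, x$n))
  invisible(x)
}

#' Per-layer growth trajectories
#'
#' Pairs two profiles point-by-point and groups the pairs by segmented layer
#' in growth order, for scatter exports of one element against another (e.g.
#' Ca versus Mn depletion trajectories).
#'
#' @param x,y [extract_profile()]s on identical positions.
#' @param seg A [segment_wall()] result.
#' @return A data frame with columns `position`, `layer`, `x`, `y`, ordered by
#'   position within layer.
#' @export
trajectory <- function(x, y, seg) {
  stopifnot(inherits(seg, "wall_segmentation"))
  if (!isTRUE(all.equal(x$position, y$position))) {
    stop("profiles must share positions")
  }
  df <- data.frame(position = x$position, layer = seg$labels,
                   x = x$counts, y = y$counts)
  df[order(df$layer, df$position), ]
}
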