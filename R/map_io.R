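# Containers and lossless I/O for element count maps and profile tables.
# Maps travel as one multi-page 32-bit TIFF per stack plus a JSON metadata
# sidecar; profiles as delimited text.

#' Element count map
#'
#' One emission line's 2D integer count image with acquisition metadata.
#'
#' @param line Emission-line id (element + Ka/Kb tag), e.g. `"Mn.Ka"`.
#' @param counts Integer matrix of raw counts (>= 0). Rows run parallel to the
#'   wall surface; columns run across the wall.
#' @param pixel_size Pixel size in nm (> 0).
#' @param dwell_time Per-pixel dwell time in s (> 0).
#' @param excitation_energy Incident energy in keV.
#' @param provenance Free-text provenance note.
#' @return An object of class `element_map`.
#' @export
element_map <- function(line, counts, pixel_size, dwell_time,
                        excitation_energy = NA_real_, provenance = "") {
  counts <- as.matrix(counts)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("counts must be a non-negative integer matrix")
  }
  if (!(pixel_size > 0)) stop("pixel_size must be > 0")
  if (!(dwell_time > 0)) stop("dwell_time must be > 0")
  storage.mode(counts) <- "integer"
  structure(list(line = line, counts = counts, pixel_size = pixel_size,
                 dwell_time = dwell_time,
                 excitation_energy = excitation_energy,
                 provenance = provenance),
            class = "element_map")
}

#' @export
print.element_map <- function(x, ...) {
  cat(sprintf("<element_map> %s  %d x %d px  (%g nm px, %g s dwell)\n",
              x$line, nrow(x$counts), ncol(x$counts), x$pixel_size,
              x$dwell_time))
  invisible(x)
}

#' Map stack
#'
#' A set of [element_map()]s sharing one pixel grid plus acquisition/sample
#' metadata.
#'
#' @param maps Named list of [element_map()]s with identical shape, pixel size
#'   and dwell time.
#' @param metadata List of additional descriptors.
#' @return An object of class `map_stack`.
#' @export
map_stack <- function(maps, metadata = list()) {
  if (!length(maps)) stop("map_stack needs at least one element map")
  if (is.null(names(maps))) {
    names(maps) <- vapply(maps, function(m) m$line, character(1))
  }
  dims <- vapply(maps, function(m) dim(m$counts), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("shape mismatch: all maps in a stack must share one grid")
  }
  px <- vapply(maps, function(m) m$pixel_size, numeric(1))
  dw <- vapply(maps, function(m) m$dwell_time, numeric(1))
  if (any(px != px[1]) || any(dw != dw[1])) {
    stop("all maps in a stack must share pixel size and dwell time")
  }
  structure(list(maps = maps, metadata = metadata), class = "map_stack")
}

#' @export
print.map_stack <- function(x, ...) {
  d <- dim(x$maps[[1]]$counts)
  cat(sprintf("<map_stack> %d line(s), %d x %d px: %s\n", length(x$maps),
              d[1], d[2], paste(names(x$maps), collapse = ", ")))
  invisible(x)
}

.SIDECAR_KEYS <- c("lines", "shape", "pixel_size", "dwell_time",
                   "excitation_energy", "provenance", "metadata")

#' Write / read a map stack
#'
#' The counts travel as one multi-page TIFF (one 32-bit page per line, written
#' losslessly) and the metadata as a JSON sidecar with a fixed key order, so a
#' round trip is bit-exact and identical inputs give identical bytes.
#'
#' @param stack A [map_stack()].
#' @param path Output path without extension; `<path>.tif` and `<path>.json`
#'   are written.
#' @return `write_map_stack()` returns `path` invisibly; `read_map_stack()`
#'   returns a [map_stack()].
#' @export
write_map_stack <- function(stack, path) {
  stopifnot(inherits(stack, "map_stack"))
  scale <- 2^32 - 1
  pages <- lapply(stack$maps, function(m) m$counts / scale)
  tiff::writeTIFF(pages, paste0(path, ".tif"), bits.per.sample = 32L,
                  compression = "none")
  first <- stack$maps[[1]]
  meta <- list(
    lines = names(stack$maps),
    shape = dim(first$counts),
    pixel_size = first$pixel_size,
    dwell_time = first$dwell_time,
    excitation_energy = vapply(stack$maps, function(m)
      m$excitation_energy, numeric(1)),
    provenance = vapply(stack$maps, function(m) m$provenance, character(1)),
    metadata = stack$metadata
  )
  writeLines(jsonlite::toJSON(meta, auto_unbox = FALSE, digits = NA,
                              null = "null"),
             paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_map_stack
#' @export
read_map_stack <- function(path) {
  tif <- paste0(path, ".tif")
  js <- paste0(path, ".json")
  if (!file.exists(tif) || !file.exists(js)) {
    stop("malformed container: expected both ", tif, " and ", js)
  }
  meta <- jsonlite::fromJSON(readLines(js, warn = FALSE),
                             simplifyVector = TRUE)
  missing_keys <- setdiff(.SIDECAR_KEYS, names(meta))
  if (length(missing_keys)) {
    stop("missing metadata keys: ", paste(missing_keys, collapse = ", "))
  }
  pages <- tiff::readTIFF(tif, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != length(meta$lines)) {
    stop("malformed container: ", length(pages), " TIFF pages for ",
         length(meta$lines), " lines")
  }
  scale <- 2^32 - 1
  maps <- lapply(seq_along(pages), function(i) {
    counts <- round(pages[[i]] * scale)
    if (!identical(dim(counts), as.integer(meta$shape))) {
      stop("shape mismatch between TIFF page and metadata")
    }
    element_map(meta$lines[i], counts, pixel_size = meta$pixel_size,
                dwell_time = meta$dwell_time,
                excitation_energy = meta$excitation_energy[i],
                provenance = meta$provenance[i])
  })
  names(maps) <- meta$lines
  md <- meta$metadata
  map_stack(maps, metadata = if (is.null(md)) list() else md)
}

#' Write / read a profile table
#'
#' Delimited text with the position in nm and per-line mean counts and
#' uncertainties (`counts_<line>`, `sigma_<line>` columns); values round-trip
#' at full precision.
#'
#' @param profiles List of [extract_profile()] results sharing one position
#'   grid (possibly empty).
#' @param path Output CSV path.
#' @return `write_profile_table()` returns `path` invisibly;
#'   `read_profile_table()` returns a named list of profiles.
#' @export
write_profile_table <- function(profiles, path) {
  if (!length(profiles)) {
    writeLines("position_nm", path)
    return(invisible(path))
  }
  pos <- profiles[[1]]$position
  for (p in profiles) {
    if (!isTRUE(all.equal(p$position, pos))) {
      stop("profiles in one table must share positions")
    }
  }
  df <- data.frame(position_nm = pos, check.names = FALSE)
  for (p in profiles) {
    df[[paste0("counts_", p$line)]] <- p$counts
    df[[paste0("sigma_", p$line)]] <- p$sigma
  }
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profile_table
#' @param averaging_width Averaging width (pixels) recorded on the profiles
#'   read back (the CSV schema does not carry it).
#' @export
read_profile_table <- function(path, averaging_width = NA_integer_) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!("position_nm" %in% names(df))) {
    stop("missing columns: profile table needs a position_nm column")
  }
  cn <- setdiff(names(df), "position_nm")
  lines <- unique(sub("^(counts|sigma)_", "", cn))
  out <- list()
  for (ln in lines) {
    ccol <- paste0("counts_", ln)
    scol <- paste0("sigma_", ln)
    if (!(ccol %in% names(df)) || !(scol %in% names(df))) {
      stop("missing columns for line ", ln)
    }
    if (any(df[[ccol]] < 0)) stop("negative counts in profile table for ", ln)
    if (any(df[[scol]] < 0)) stop("negative sigma in profile table for ", ln)
    out[[ln]] <- new_xrf_profile(line = ln, position = df$position_nm,
                                 counts = df[[ccol]], sigma = df[[scol]],
                                 averaging_width = averaging_width)
  }
  out
}
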