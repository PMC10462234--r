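#' Intensity field for RNAscope dot quantification
#'
#' Wraps a 2-D non-negative intensity array together with a background
#' estimate and a detection threshold. When the threshold is not supplied
#' it defaults to background_mean + 3 * background SD; when the background
#' is not supplied it is estimated as the mean of below-threshold pixels.
#' If neither is supplied, an initial split at the image mean seeds the
#' background estimate, from which the threshold is derived.
#'
#' @param intensity 2-D numeric matrix, finite and non-negative.
#' @param background_mean optional known background level.
#' @param detect_threshold optional detection threshold; must be >= the
#'   background mean.
#' @return a \code{dot_field} object.
#' @export
dot_field <- function(intensity, background_mean = NULL,
                      detect_threshold = NULL) {
  intensity <- as.matrix(intensity)
  if (!all(is.finite(intensity)) || any(intensity < 0))
    stop("intensity must be finite and non-negative")
  if (is.null(background_mean) && is.null(detect_threshold)) {
    split <- mean(intensity)
    bg_px <- intensity[intensity <= split]
    background_mean <- mean(bg_px)
    bg_sd <- stats::sd(bg_px)
    if (is.na(bg_sd)) bg_sd <- 0
    detect_threshold <- background_mean + 3 * bg_sd
  } else if (is.null(detect_threshold)) {
    bg_px <- intensity[intensity <= background_mean * 1.000001]
    bg_sd <- if (length(bg_px) > 1) stats::sd(bg_px) else 0
    if (is.na(bg_sd)) bg_sd <- 0
    detect_threshold <- background_mean + 3 * bg_sd
  } else if (is.null(background_mean)) {
    below <- intensity[intensity < detect_threshold]
    background_mean <- if (length(below)) mean(below) else 0
  }
  if (detect_threshold < background_mean)
    stop("detect_threshold must be >= background_mean")
  structure(list(intensity = intensity,
                 background_mean = background_mean,
                 detect_threshold = detect_threshold),
            class = "dot_field")
}

#' Read a single-channel image as a dot field
#'
#' Reads PNG (via the png package) or TIFF (via the tiff package when
#' available); multi-channel images are averaged to one channel.
#'
#' @param path image file.
#' @param ... passed to \code{\link{dot_field}}.
#' @return a \code{dot_field}.
#' @export
load_dot_image <- function(path, ...) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stop("unsupported image format: .", ext))
  if (length(dim(img)) == 3) img <- apply(img, c(1, 2), mean)
  dot_field(img, ...)
}

#' Detect discrete signal dots
#'
#' Pixels at or above the detection threshold are grouped into 8-connected
#' components (diagonal neighbours join); each component is one dot, with
#' its pixel area and the sum of its raw intensities (background included).
#'
#' @param f a \code{dot_field}.
#' @return data.frame: dot, area_px, integrated_intensity.
#' @export
detect_dots <- function(f) {
  stopifnot(inherits(f, "dot_field"))
  img <- f$intensity
  on_idx <- which(img >= f$detect_threshold)
  empty <- data.frame(dot = integer(), area_px = integer(),
                      integrated_intensity = numeric())
  if (!length(on_idx)) return(empty)
  nr <- nrow(img)
  nc <- ncol(img)
  on <- matrix(FALSE, nr, nc)
  on[on_idx] <- TRUE
  row_i <- ((on_idx - 1L) %% nr) + 1L
  col_i <- ((on_idx - 1L) %/% nr) + 1L
  # edges to the 4 forward neighbours (E, S, SE, SW) give full
  # 8-connectivity without duplicates
  offs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(-1L, 1L))
  from <- integer(0); to <- integer(0)
  for (o in offs) {
    r2 <- row_i + o[1]; c2 <- col_i + o[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- on[nb]
    from <- c(from, on_idx[ok][hit])
    to <- c(to, nb[hit])
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(from), to = as.character(to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(on_idx)))
  comp <- igraph::components(g)$membership
  px <- as.integer(names(comp))
  agg <- split(px, comp)
  data.frame(
    dot = seq_along(agg),
    area_px = vapply(agg, length, integer(1)),
    integrated_intensity = vapply(agg, function(ix) sum(img[ix]),
                                  numeric(1)),
    row.names = NULL)
}

#' Average background-corrected intensity per single dot
#'
#' Computed over a representative region (around 20 discrete dots in
#' practice): (sum of integrated dot intensities - background_mean * sum
#' of dot areas) / number of dots.
#'
#' @param dots output of \code{\link{detect_dots}} (needs >= 1 dot).
#' @param background_mean average background intensity per pixel.
#' @return the average net intensity of one dot.
#' @export
avg_intensity_per_dot <- function(dots, background_mean) {
  if (!nrow(dots)) stop("no dots detected; cannot calibrate")
  (sum(dots$integrated_intensity) -
     background_mean * sum(dots$area_px)) / nrow(dots)
}

#' Estimate the total dot number in a region
#'
#' (total region intensity - background_mean * region area) /
#' average intensity per dot. Linear in above-background signal and zero
#' for a pure-background region when the background estimate is exact.
#'
#' @param region_total_intensity summed raw intensity of the region.
#' @param background_mean average background intensity per pixel.
#' @param region_area region area in pixels.
#' @param avg_per_dot calibrated average net intensity per dot (> 0).
#' @return estimated dot count (real-valued).
#' @export
total_dot_number <- function(region_total_intensity, background_mean,
                             region_area, avg_per_dot) {
  if (avg_per_dot <= 0) stop("avg_per_dot must be positive")
  (region_total_intensity - background_mean * region_area) / avg_per_dot
}

#' End-to-end dot quantification of one field
#'
#' Detects dots, calibrates the average per-dot intensity on them, and
#' estimates the total dot number over the whole field.
#'
#' @param f a \code{dot_field}.
#' @return list: dots (data.frame), n_dots_detected, avg_per_dot,
#'   total_dot_estimate.
#' @export
quantify_dot_field <- function(f) {
  dots <- detect_dots(f)
  if (!nrow(dots))
    return(list(dots = dots, n_dots_detected = 0L, avg_per_dot = NA_real_,
                total_dot_estimate = 0))
  avg <- avg_intensity_per_dot(dots, f$background_mean)
  total <- total_dot_number(sum(f$intensity), f$background_mean,
                            length(f$intensity), avg)
  list(dots = dots, n_dots_detected = nrow(dots), avg_per_dot = avg,
       total_dot_estimate = total)
}
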