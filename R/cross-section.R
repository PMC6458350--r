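# Cross-sectional geometry of an incisor from a binary raster.
#
# The section is a boolean occupancy grid with an isotropic pixel size in
# mm. Conventions (bit-exact, documented once here): raster rows are the
# image y axis and columns the image x axis; the centre of pixel
# [row i, col j] (1-based) sits at x = (j - 0.5) * pixel_size,
# y = (i - 0.5) * pixel_size. Each occupied pixel is a filled square, so
# moments include the pixel's own-square term s^4/12 as well as the
# parallel-axis term -- a single pixel has nonzero second moment.
#
# Moment naming: Ixx = integral of y^2 dA (second moment about the x
# axis, i.e. resistance to bending by loads in y), Iyy = integral of
# x^2 dA, Ixy = integral of x*y dA about the centroid.

#' Construct a section mask
#'
#' @param grid A logical or 0/1 numeric matrix; `TRUE`/nonzero = tooth
#'   material. Greyscale input is binarized at > 0.
#' @param pixel_size Edge length of one (square) pixel, in mm.
#' @param axes Length-2 character vector naming the anatomical direction
#'   of the raster x (column) and y (row) axes, in that order. Default
#'   puts the mesio-distal axis along x and the labio-lingual axis along
#'   y.
#' @return An object of class `section_mask`.
#' @export
section_mask <- function(grid, pixel_size,
                         axes = c(x = "mesio-distal", y = "labio-lingual")) {
  if (!is.matrix(grid)) stop("`grid` must be a matrix", call. = FALSE)
  if (length(pixel_size) != 1 || !is.finite(pixel_size) || pixel_size <= 0) {
    stop("`pixel_size` must be a single positive number (mm); ",
         "anisotropic pixels are not supported", call. = FALSE)
  }
  grid <- grid > 0
  if (!any(grid)) stop("mask has no occupied pixels", call. = FALSE)
  axes <- as.character(axes)
  if (!setequal(axes, c("mesio-distal", "labio-lingual"))) {
    stop("`axes` must name 'mesio-distal' and 'labio-lingual'",
         call. = FALSE)
  }
  structure(list(grid = grid, pixel_size = pixel_size,
                 axes = c(x = axes[1], y = axes[2])),
            class = "section_mask")
}

#' @export
print.section_mask <- function(x, ...) {
  cat("<section_mask> ", nrow(x$grid), "x", ncol(x$grid), " px, ",
      x$pixel_size, " mm/px, ", sum(x$grid), " occupied (",
      format(mask_area(x), digits = 4), " mm^2)\n", sep = "")
  invisible(x)
}

# mm coordinates of occupied pixel centres, columns x and y
occupied_centres <- function(mask) {
  idx <- which(mask$grid, arr.ind = TRUE)
  s <- mask$pixel_size
  cbind(x = (idx[, "col"] - 0.5) * s, y = (idx[, "row"] - 0.5) * s)
}

#' Cross-sectional area of a mask
#'
#' Occupied-pixel count times squared pixel size.
#'
#' @param mask A [section_mask()].
#' @return CSA in mm^2.
#' @export
mask_area <- function(mask) {
  stopifnot(inherits(mask, "section_mask"))
  sum(mask$grid) * mask$pixel_size^2
}

#' Centroid of a mask
#'
#' Area-weighted mean of occupied pixel centres.
#'
#' @inheritParams mask_area
#' @return Named numeric vector `c(x = , y = )` in mm.
#' @export
mask_centroid <- function(mask) {
  stopifnot(inherits(mask, "section_mask"))
  colMeans(occupied_centres(mask))
}

#' Centroidal second moments of area
#'
#' Sums per-pixel contributions treating each occupied pixel as a filled
#' square of side `pixel_size`: own-square term `pixel_size^4 / 12` plus
#' the parallel-axis term (distance from the section centroid)^2 *
#' pixel area. Principal moments come from the eigen-decomposition of the
#' 2x2 inertia tensor; `principal_angle` is the orientation (radians from
#' the raster x axis, in [-pi/2, pi/2)) of the centroidal axis about
#' which the second moment is minimal -- for an elongate section this is
#' its long axis.
#'
#' @inheritParams mask_area
#' @return A list with `Ixx`, `Iyy`, `Ixy`, `Imin`, `Imax` (mm^4) and
#'   `principal_angle` (radians).
#' @export
second_moments <- function(mask) {
  stopifnot(inherits(mask, "section_mask"))
  pc <- occupied_centres(mask)
  s <- mask$pixel_size
  n <- nrow(pc)
  ctr <- colMeans(pc)
  dx <- pc[, "x"] - ctr["x"]
  dy <- pc[, "y"] - ctr["y"]
  own <- s^4 / 12
  Ixx <- sum(dy^2) * s^2 + n * own
  Iyy <- sum(dx^2) * s^2 + n * own
  Ixy <- sum(dx * dy) * s^2
  # axis at angle t has normal n = (-sin t, cos t); moment = n' S n with
  # S = [[Iyy, Ixy], [Ixy, Ixx]] (the "x^2 / xy / y^2" tensor)
  S <- matrix(c(Iyy, Ixy, Ixy, Ixx), 2, 2)
  eig <- eigen(S, symmetric = TRUE)
  Imin <- eig$values[2]
  Imax <- eig$values[1]
  # minimal moment axis is parallel to the eigenvector of the larger
  # eigenvalue (its normal is the small-eigenvalue direction)
  v <- eig$vectors[, 1]
  ang <- atan2(v[2], v[1])
  if (ang >= pi / 2) ang <- ang - pi
  if (ang < -pi / 2) ang <- ang + pi
  list(Ixx = Ixx, Iyy = Iyy, Ixy = Ixy, Imin = Imin, Imax = Imax,
       principal_angle = ang)
}

#' Second moment of area about an arbitrary centroidal axis
#'
#' Moment about the centroidal axis pointing along `direction`, with
#' distances measured perpendicular to the axis. Equivalent to rotating
#' the section: an axis along the principal directions returns
#' `Imin`/`Imax`.
#'
#' @inheritParams mask_area
#' @param direction Length-2 numeric vector (raster x, y components); need
#'   not be unit length, but must be nonzero.
#' @return Second moment in mm^4.
#' @export
sma_about_axis <- function(mask, direction) {
  stopifnot(inherits(mask, "section_mask"))
  if (length(direction) != 2 || all(direction == 0) ||
      any(!is.finite(direction))) {
    stop("`direction` must be a nonzero length-2 vector", call. = FALSE)
  }
  u <- direction / sqrt(sum(direction^2))
  m <- second_moments(mask)
  # I(theta) = n' S n, n = (-sin, cos) = (-u[2], u[1])
  nx <- -u[2]; ny <- u[1]
  nx^2 * m$Iyy + 2 * nx * ny * m$Ixy + ny^2 * m$Ixx
}

#' Full cross-section geometry
#'
#' Composes area, centroid and moments, and selects the second moment
#' about the chosen loading axis. The default, `"mesio-distal"`, is the
#' moment about the mesio-distal centroidal axis, i.e. the resistance to
#' bending by labio-lingually directed loads -- the direction an incisor
#' is loaded during gnawing. A section expanded labio-lingually (like the
#' aye-aye's) therefore scores a large `SMA_loading`.
#'
#' @inheritParams mask_area
#' @param loading_axis One of `"mesio-distal"`, `"labio-lingual"`,
#'   `"principal-max"`, `"principal-min"`.
#' @return A one-row tibble with `CSA_mm2`, `centroid_x`, `centroid_y`,
#'   `Ixx`, `Iyy`, `Ixy`, `Imin`, `Imax`, `principal_angle`,
#'   `SMA_loading`, `sqrt_CSA`, `fourth_root_SMA`.
#' @export
section_geometry <- function(mask, loading_axis = "mesio-distal") {
  stopifnot(inherits(mask, "section_mask"))
  choices <- c("mesio-distal", "labio-lingual", "principal-max",
               "principal-min")
  if (!is.character(loading_axis) || length(loading_axis) != 1 ||
      !loading_axis %in% choices) {
    stop("`loading_axis` must be one of: ", paste(choices, collapse = ", "),
         call. = FALSE)
  }
  m <- second_moments(mask)
  ctr <- mask_centroid(mask)
  sma <- switch(loading_axis,
    "mesio-distal" = {
      dir <- if (mask$axes[["x"]] == "mesio-distal") c(1, 0) else c(0, 1)
      sma_about_axis(mask, dir)
    },
    "labio-lingual" = {
      dir <- if (mask$axes[["x"]] == "labio-lingual") c(1, 0) else c(0, 1)
      sma_about_axis(mask, dir)
    },
    "principal-max" = m$Imax,
    "principal-min" = m$Imin
  )
  csa <- mask_area(mask)
  tibble::tibble(
    CSA_mm2 = csa,
    centroid_x = ctr[["x"]], centroid_y = ctr[["y"]],
    Ixx = m$Ixx, Iyy = m$Iyy, Ixy = m$Ixy,
    Imin = m$Imin, Imax = m$Imax,
    principal_angle = m$principal_angle,
    SMA_loading = sma,
    sqrt_CSA = sqrt(csa),
    fourth_root_SMA = sma^0.25
  )
}

#' Read a section mask from file
#'
#' Accepts a PNG or TIFF image (any nonzero channel value = occupied; the
#' first channel is used) or a whitespace-delimited plain-text 0/1 grid.
#'
#' @param path Path to the image or text grid.
#' @param pixel_size Pixel edge length in mm.
#' @inheritParams section_mask
#' @return A [section_mask()].
#' @export
read_mask <- function(path, pixel_size,
                      axes = c(x = "mesio-distal", y = "labio-lingual")) {
  ext <- tolower(tools::file_ext(path))
  grid <- if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) img <- img[, , 1]
    img
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path)
    if (length(dim(img)) == 3) img <- img[, , 1]
    img
  } else {
    as.matrix(utils::read.table(path, header = FALSE))
  }
  section_mask(unname(as.matrix(grid)), pixel_size, axes = axes)
}

#' Plot a section mask
#'
#' @param object A [section_mask()].
#' @param ... Unused.
#' @return A ggplot object showing occupied pixels in mm coordinates with
#'   the centroid marked.
#' @method autoplot section_mask
#' @export
autoplot.section_mask <- function(object, ...) {
  pc <- tibble::as_tibble(occupied_centres(object))
  ctr <- mask_centroid(object)
  ggplot2::ggplot(pc, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(fill = "grey30") +
    ggplot2::annotate("point", x = ctr[["x"]], y = ctr[["y"]],
                      colour = "red", shape = 3, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)")
}
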