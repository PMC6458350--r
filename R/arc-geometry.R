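# Circular-arc geometry of an incisor from three labial-surface landmarks.
#
# The tooth curve is treated as a circular arc through three labelled
# landmarks: the tip, the midpoint on the labial surface at the alveolar
# margin, and the distalmost extremity (base). All quantities are derived
# from the three chord lengths alone, so 2D and 3D landmarks are handled
# identically (three points always define a plane; no projection needed).

#' Chord lengths of the landmark triangle
#'
#' Treats the three incisor landmarks as vertices of a triangle and returns
#' the Euclidean lengths of its sides: `a` (tip to alveolar margin), `b`
#' (margin to base) and `c` (tip to base).
#'
#' @param landmarks A data frame with one row per landmark and columns
#'   `specimen_id`, `landmark` (one of `"tip"`, `"margin"`, `"base"`),
#'   `x`, `y` and optionally `z` (assumed 0 when absent). Coordinates in mm.
#' @return A tibble with columns `specimen_id`, `a`, `b`, `c` (mm).
#' @examples
#' lm <- tibble::tibble(
#'   specimen_id = "s1",
#'   landmark = c("tip", "margin", "base"),
#'   x = c(0, 3, 3), y = c(0, 0, 4)
#' )
#' chord_lengths(lm) # a = 3, b = 4, c = 5
#' @export
chord_lengths <- function(landmarks) {
  landmarks <- validate_landmarks(landmarks)
  dplyr::group_by(landmarks, .data$specimen_id) |>
    dplyr::group_modify(function(df, key) {
      pts <- landmark_points(df, key$specimen_id)
      tibble::tibble(
        a = point_dist(pts$tip, pts$margin),
        b = point_dist(pts$margin, pts$base),
        c = point_dist(pts$tip, pts$base)
      )
    }) |>
    dplyr::ungroup()
}

# Check/normalise a landmark table: required columns, z default, labels,
# coincident-point rejection.
validate_landmarks <- function(landmarks) {
  landmarks <- tibble::as_tibble(landmarks)
  required <- c("specimen_id", "landmark", "x", "y")
  missing <- setdiff(required, names(landmarks))
  if (length(missing) > 0) {
    stop("landmark table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"z" %in% names(landmarks)) landmarks$z <- 0
  landmarks$z[is.na(landmarks$z)] <- 0
  bad <- setdiff(unique(landmarks$landmark), c("tip", "margin", "base"))
  if (length(bad) > 0) {
    stop("unknown landmark label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  landmarks
}

# Extract the three labelled points of one specimen as a named list of
# length-3 numeric vectors; errors on missing/duplicated labels or
# coincident points.
landmark_points <- function(df, id) {
  labs <- c("tip", "margin", "base")
  counts <- table(factor(df$landmark, levels = labs))
  if (any(counts != 1)) {
    stop("specimen '", id, "': need exactly one of each landmark ",
         "(tip, margin, base); got counts ",
         paste(labs, "=", as.integer(counts), collapse = ", "),
         call. = FALSE)
  }
  pts <- lapply(labs, function(l) {
    row <- df[df$landmark == l, , drop = FALSE]
    as.numeric(c(row$x, row$y, row$z))
  })
  names(pts) <- labs
  pairs <- list(c("tip", "margin"), c("margin", "base"), c("tip", "base"))
  for (p in pairs) {
    if (point_dist(pts[[p[1]]], pts[[p[2]]]) <= 0) {
      stop("specimen '", id, "': landmarks '", p[1], "' and '", p[2],
           "' coincide", call. = FALSE)
    }
  }
  pts
}

point_dist <- function(p, q) sqrt(sum((p - q)^2))

#' Radius of curvature from triangle side lengths
#'
#' Circumradius of a triangle with side lengths `a`, `b`, `c`, via the
#' side-length form r = abc / sqrt(2a^2 b^2 + 2b^2 c^2 + 2a^2 c^2 - a^4 -
#' b^4 - c^4) (a rearrangement of Heron's formula). This is the radius of
#' the circle through the three landmarks, i.e. the incisor's radius of
#' curvature when its curve is modelled as a circular arc.
#'
#' @param a,b,c Side lengths (mm); vectorized.
#' @return Circumradius (mm), same length as the inputs.
#' @examples
#' circumradius(3, 4, 5) # 2.5 (right triangle: hypotenuse / 2)
#' @export
circumradius <- function(a, b, c) {
  stopifnot(length(a) == length(b), length(b) == length(c))
  if (any(a <= 0 | b <= 0 | c <= 0)) {
    stop("side lengths must be strictly positive", call. = FALSE)
  }
  radicand <- 2 * a^2 * b^2 + 2 * b^2 * c^2 + 2 * a^2 * c^2 -
    a^4 - b^4 - c^4
  # numerical collinearity floor for double precision
  floor_tol <- 1e-12 * (a * b * c)^(4 / 3)
  if (any(radicand < floor_tol)) {
    stop("landmarks are (near-)collinear: circumradius is infinite",
         call. = FALSE)
  }
  a * b * c / sqrt(radicand)
}

#' Angle subtended by a chord on a circle
#'
#' The central angle (minor arc) subtended by a chord of length `chord` on
#' a circle of radius `r`: theta = 2 asin(chord / 2r). Arguments within
#' 1e-9 of the asin boundary are clamped; a chord longer than the diameter
#' beyond that tolerance is an error.
#'
#' @param chord Chord length (mm); vectorized.
#' @param r Circle radius (mm).
#' @return Angle in radians, in (0, pi].
#' @export
subtended_angle <- function(chord, r) {
  if (any(r <= 0)) stop("radius must be positive", call. = FALSE)
  ratio <- chord / (2 * r)
  over <- ratio > 1
  if (any(ratio[over] - 1 > 1e-9)) {
    stop("chord exceeds the circle's diameter", call. = FALSE)
  }
  ratio[over] <- 1
  2 * asin(ratio)
}

#' Total subtended angle with reflex correction
#'
#' The minor-arc formula 2 asin(c/2r) is only valid for arcs up to pi
#' radians. The cosine-rule discriminant X = a^2 + b^2 - c^2 detects a
#' tooth whose arc exceeds a semicircle (X > 0, i.e. the angle at the
#' margin vertex is acute): the angle is then corrected by subtraction
#' from 2 pi. X = 0 is exactly the semicircle boundary (returns pi).
#'
#' @param a,b,c Chord lengths (mm); `c` spans tip to base. Vectorized.
#' @param r Circumradius of the same triangle (mm).
#' @return Total subtended angle in radians, in (0, 2 pi).
#' @export
total_angle <- function(a, b, c, r) {
  theta_minor <- subtended_angle(c, r)
  X <- a^2 + b^2 - c^2
  ifelse(X > 0, 2 * pi - theta_minor,
         ifelse(X == 0, pi, theta_minor))
}

#' Sub-arc angles at the alveolar margin
#'
#' Splits the total arc at the margin landmark into the external (tip to
#' margin) and internal (margin to base) sub-arcs. Computed via the
#' inscribed-angle identities -- theta_ext = 2 * (angle at the base
#' vertex), theta_int = 2 * (angle at the tip vertex) -- which satisfy
#' theta_ext + theta_int = theta_total for all arcs, including reflex ones
#' where the plain chord-substitution form (2 asin(a/2r), 2 asin(b/2r))
#' would pick the wrong branch. For arcs up to a semicircle the two forms
#' agree.
#'
#' @inheritParams total_angle
#' @return A list with numeric components `theta_ext` and `theta_int`
#'   (radians).
#' @export
sub_arc_angles <- function(a, b, c, r) {
  # law of cosines; clamp tiny floating excess
  cos_tip <- pmin(1, pmax(-1, (a^2 + c^2 - b^2) / (2 * a * c)))
  cos_base <- pmin(1, pmax(-1, (b^2 + c^2 - a^2) / (2 * b * c)))
  theta_ext <- 2 * acos(cos_base)
  theta_int <- 2 * acos(cos_tip)
  total <- total_angle(a, b, c, r)
  resid <- abs(theta_ext + theta_int - total)
  if (any(resid > 1e-6 * pmax(total, 1))) {
    stop("sub-arc angles do not sum to the total angle; landmarks are not ",
         "consistent with a single circle", call. = FALSE)
  }
  list(theta_ext = theta_ext, theta_int = theta_int)
}

#' Arc metrics for each specimen
#'
#' Full arc-geometry pipeline: chord lengths, radius of curvature,
#' subtended angles, arc lengths and fraction of circle, one row per
#' specimen. TTL (total tooth length) = r * theta_total; ETL and ITL are
#' the external (tip to alveolar margin) and internal (margin to base)
#' arc lengths, with ETL + ITL = TTL by construction.
#'
#' @inheritParams chord_lengths
#' @return A tibble with columns `specimen_id`, `a`, `b`, `c`, `r`,
#'   `theta_total_rad`, `theta_ext_rad`, `theta_int_rad`, `pct_circle`
#'   (percentage of a full circle encompassed), `TTL`, `ETL`, `ITL` (mm).
#' @examples
#' arc <- make_arc_landmarks(r = 10, theta_total = 0.4 * pi)
#' arc_metrics(arc$landmarks)
#' @export
arc_metrics <- function(landmarks) {
  chords <- chord_lengths(landmarks)
  chords |>
    dplyr::mutate(
      r = circumradius(.data$a, .data$b, .data$c),
      theta_total_rad = total_angle(.data$a, .data$b, .data$c, .data$r)
    ) |>
    dplyr::mutate(
      theta_ext_rad = sub_arc_angles(.data$a, .data$b, .data$c,
                                     .data$r)$theta_ext,
      theta_int_rad = sub_arc_angles(.data$a, .data$b, .data$c,
                                     .data$r)$theta_int,
      pct_circle = 100 * .data$theta_total_rad / (2 * pi),
      TTL = .data$r * .data$theta_total_rad,
      ETL = .data$r * .data$theta_ext_rad,
      ITL = .data$r * .data$theta_int_rad
    )
}

#' Read a landmark file
#'
#' Reads a comma- or tab-delimited landmark table with a header row and
#' columns `specimen_id`, `landmark` (tip|margin|base), `x`, `y` and
#' optionally `z`.
#'
#' @param path Path to the delimited text file.
#' @return A validated landmark tibble.
#' @export
read_landmarks <- function(path) {
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  validate_landmarks(df)
}
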