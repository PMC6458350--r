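# Synthetic inputs with known ground truth: circular-arc specimens,
# elliptical section masks, pure-birth trees and Brownian trait tables.
# Every generator is deterministic under a fixed seed and returns its
# ground truth alongside the object, so each downstream module has an
# end-to-end recovery test with known answers.

#' Generate landmarks on a circular arc
#'
#' Places the tip at the arc start, the base at the arc end, and the
#' alveolar-margin landmark at a chosen split point, all exactly on a
#' circle of radius `r`, then optionally applies a rigid 3D rotation and
#' translation and adds isotropic Gaussian coordinate noise. The split is
#' tip-sided: `margin_split` is the external fraction of the arc, so
#' ETL = margin_split * TTL.
#'
#' @param r True radius of curvature (mm).
#' @param theta_total True subtended angle (radians, in (0, 2 pi);
#'   values above pi give reflex arcs like the aye-aye's).
#' @param margin_split Fraction of the arc external to the bone
#'   (tip side), in (0, 1).
#' @param rotation Optional 3x3 rotation matrix (default identity).
#' @param translation Optional length-3 offset (mm).
#' @param noise_sd Isotropic Gaussian landmark noise, mm (default 0).
#' @param seed Optional integer seed for the noise.
#' @param specimen_id Identifier used in the landmark table.
#' @return A list with `landmarks` (tibble in [read_landmarks()] layout)
#'   and `truth` (one-row tibble of the generating `r`,
#'   `theta_total_rad`, `pct_circle`, `TTL`, `ETL`, `ITL`).
#' @examples
#' arc <- make_arc_landmarks(r = 10, theta_total = 0.4 * pi)
#' arc_metrics(arc$landmarks)$pct_circle # 20
#' @export
make_arc_landmarks <- function(r, theta_total, margin_split = 0.5,
                               rotation = NULL, translation = c(0, 0, 0),
                               noise_sd = 0, seed = NULL,
                               specimen_id = "synthetic") {
  if (!is.finite(r) || r <= 0) stop("`r` must be positive", call. = FALSE)
  if (!is.finite(theta_total) || theta_total <= 0 || theta_total >= 2 * pi) {
    stop("`theta_total` must lie in (0, 2*pi)", call. = FALSE)
  }
  if (margin_split <= 0 || margin_split >= 1) {
    stop("`margin_split` must lie in (0, 1)", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  angles <- c(tip = 0, margin = margin_split * theta_total,
              base = theta_total)
  pts <- cbind(r * cos(angles), r * sin(angles), 0)
  if (!is.null(rotation)) {
    stopifnot(is.matrix(rotation), dim(rotation) == c(3, 3))
    pts <- pts %*% t(rotation)
  }
  pts <- sweep(pts, 2, translation, "+")
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- .Random.seed_save()
      on.exit(.Random.seed_restore(old), add = TRUE)
      set.seed(seed)
    }
    pts <- pts + matrix(stats::rnorm(9, sd = noise_sd), 3, 3)
  }
  landmarks <- tibble::tibble(
    specimen_id = specimen_id,
    landmark = c("tip", "margin", "base"),
    x = pts[, 1], y = pts[, 2], z = pts[, 3]
  )
  truth <- tibble::tibble(
    specimen_id = specimen_id,
    r = r,
    theta_total_rad = theta_total,
    pct_circle = 100 * theta_total / (2 * pi),
    TTL = r * theta_total,
    ETL = r * margin_split * theta_total,
    ITL = r * (1 - margin_split) * theta_total
  )
  list(landmarks = landmarks, truth = truth)
}

# save/restore the RNG state so seeded generators do not disturb the
# caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Rasterize a filled ellipse as a section mask
#'
#' A pixel is occupied iff its centre lies inside the ellipse
#' (centre-inclusion, no anti-aliasing, so the raster is bit-exact
#' reproducible). The closed-form section properties of the continuous
#' ellipse are attached as ground truth: CSA = pi a b, moment about the
#' major axis pi a b^3 / 4, about the minor axis pi a^3 b / 4.
#'
#' @param semi_major,semi_minor Ellipse semi-axes a >= b > 0 (mm).
#' @param orientation Major-axis angle from the raster x axis (radians).
#' @param pixel_size Pixel edge (mm).
#' @param margin Blank border around the ellipse, in pixels.
#' @return A [section_mask()] with a `truth` attribute (list: `CSA`,
#'   `I_major`, `I_minor`, `orientation`).
#' @export
make_ellipse_mask <- function(semi_major, semi_minor, orientation = 0,
                              pixel_size, margin = 2) {
  if (!(semi_major >= semi_minor && semi_minor > 0)) {
    stop("need semi_major >= semi_minor > 0", call. = FALSE)
  }
  if (pixel_size <= 0) stop("`pixel_size` must be positive", call. = FALSE)
  if (2 * semi_minor < pixel_size) {
    stop("ellipse is smaller than one pixel at this resolution",
         call. = FALSE)
  }
  half <- semi_major + margin * pixel_size
  n <- ceiling(2 * half / pixel_size)
  cx <- cy <- n * pixel_size / 2
  xs <- (seq_len(n) - 0.5) * pixel_size - cx
  ys <- (seq_len(n) - 0.5) * pixel_size - cy
  co <- cos(orientation); si <- sin(orientation)
  # rotate pixel centres into the ellipse frame
  X <- outer(ys * 0, xs, "+")   # columns vary with x
  Y <- outer(ys, xs * 0, "+")
  u <- co * X + si * Y
  v <- -si * X + co * Y
  grid <- (u / semi_major)^2 + (v / semi_minor)^2 < 1
  mask <- section_mask(grid, pixel_size)
  attr(mask, "truth") <- list(
    CSA = pi * semi_major * semi_minor,
    I_major = pi * semi_major * semi_minor^3 / 4,
    I_minor = pi * semi_major^3 * semi_minor / 4,
    orientation = orientation
  )
  mask
}

#' Simulate a pure-birth (Yule) tree
#'
#' Ultrametric tree with exponential waiting times between speciation
#' events, via [ape::rphylo()] with zero extinction; reproducible by
#' seed.
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Integer seed.
#' @param birth Speciation rate (default 1; sets the time scale only).
#' @return A `phylo` tree with tips `t1..tn`.
#' @export
simulate_pure_birth_tree <- function(n_tips, seed, birth = 1) {
  if (n_tips < 2) stop("`n_tips` must be >= 2", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  ape::rphylo(n_tips, birth = birth, death = 0)
}

#' Simulate a Brownian bivariate trait table on a tree
#'
#' The predictor x evolves as unit-rate Brownian motion on the tree
#' (multivariate normal with the tree's Brownian covariance C); the
#' response is y = intercept + slope * x + e with e ~ N(0, sigma2 * C).
#' This is exactly the generative model that [pgls_fit()] assumes, so
#' the fit should recover `slope` up to sampling error.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param intercept,slope Regression coefficients.
#' @param sigma2 Residual Brownian rate (> 0, or 0 for the noiseless
#'   limit).
#' @param seed Integer seed.
#' @return A tibble with columns `species`, `x`, `y`.
#' @export
simulate_bm_regression <- function(tree, intercept, slope, sigma2, seed) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a phylo object",
                                     call. = FALSE)
  if (sigma2 < 0) stop("`sigma2` must be >= 0", call. = FALSE)
  C <- bm_covariance(tree)
  n <- nrow(C)
  L <- t(chol(C))   # lower factor: L %*% z has covariance C
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  x <- as.numeric(L %*% stats::rnorm(n))
  eps <- if (sigma2 > 0) {
    as.numeric(L %*% stats::rnorm(n)) * sqrt(sigma2)
  } else rep(0, n)
  tibble::tibble(
    species = rownames(C),
    x = x,
    y = intercept + slope * x + eps
  )
}

#' The bundled percent-of-circle species table
#'
#' Percentage of a full circle encompassed by the lower incisor of each
#' of the 33 diprotodont species in the study sample (27 rodents and 6
#' non-rodent diprotodonts: two lagomorphs, two hyraxes, the aye-aye and
#' the wombat).
#'
#' @return A tibble with columns `species`, `pct_circle`, `is_rodent`.
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "percent_of_circle.csv",
                      package = "incisorarc", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE) |>
    dplyr::mutate(is_rodent = as.logical(.data$is_rodent))
}

#' Generate a complete synthetic study
#'
#' Bundles everything the pipeline ingests, with known ground truth:
#' `n` arc specimens spanning the observed range of incisor curvature
#' (12-51% of a circle), size-correlated elliptical cross-sections, a
#' pure-birth phylogeny over the same species, and the per-specimen truth
#' table. Specimen radii grow with the fraction of circle so that arc
#' lengths, CSA and SMA co-vary with size, as in real incisors.
#'
#' @param n Number of specimens/species (default 30).
#' @param seed Integer seed.
#' @param pct_range Range of percent-of-circle values spanned (default
#'   `c(12, 51)`).
#' @param pixel_size Raster resolution for the section masks (mm).
#' @return A list: `landmarks` (all specimens), `masks` (named list of
#'   [section_mask()]), `tree`, `truth` (per-specimen ground truth
#'   including section closed forms).
#' @export
synthetic_study <- function(n = 30, seed = 1, pct_range = c(12, 51),
                            pixel_size = 0.05) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  ids <- sprintf("sp%02d", seq_len(n))
  pct <- seq(pct_range[1], pct_range[2], length.out = n)
  # radius grows with fraction of circle (larger teeth curl further);
  # lognormal scatter around the trend
  r <- 2 + 12 * (pct / 100)^1.2 * exp(stats::rnorm(n, sd = 0.15))
  split <- stats::runif(n, 0.35, 0.65)
  rot_seeds <- sample.int(1e6, n)
  specs <- purrr::pmap(
    list(ids, r, pct, split, rot_seeds),
    function(id, ri, pi_, si, rs) {
      set.seed(rs)
      rot <- random_rotation()
      make_arc_landmarks(r = ri, theta_total = pi_ / 100 * 2 * pi,
                         margin_split = si, rotation = rot,
                         translation = stats::rnorm(3, sd = 5),
                         specimen_id = id)
    }
  )
  landmarks <- purrr::map(specs, "landmarks") |> purrr::list_rbind()
  truth <- purrr::map(specs, "truth") |> purrr::list_rbind()
  # elliptical sections: area scales with external length
  etl <- truth$ETL
  semi_minor <- 0.18 * etl * exp(stats::rnorm(n, sd = 0.1))
  aspect <- stats::runif(n, 1.1, 1.8)
  semi_major <- semi_minor * aspect
  masks <- purrr::pmap(list(semi_major, semi_minor), function(a, b) {
    make_ellipse_mask(a, b, orientation = 0, pixel_size = pixel_size)
  })
  names(masks) <- ids
  truth$CSA_true <- pi * semi_major * semi_minor
  truth$I_major_true <- pi * semi_major * semi_minor^3 / 4
  truth$I_minor_true <- pi * semi_major^3 * semi_minor / 4
  tree <- simulate_pure_birth_tree(n, seed = seed + 1)
  tree$tip.label <- ids
  list(landmarks = landmarks, masks = masks, tree = tree, truth = truth)
}

# uniform random 3D rotation via QR of a Gaussian matrix
random_rotation <- function() {
  qr_d <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
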