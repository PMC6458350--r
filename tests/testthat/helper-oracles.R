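# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the circumcentre is solved algebraically from
# coordinates, section moments are brute-force per-pixel sums, and the
# pooled t is the textbook formula.

# Circumcircle radius of three 2D points by solving the perpendicular
# bisector system (not via side lengths).
oracle_circumradius_2d <- function(p1, p2, p3) {
  A <- rbind(2 * (p2 - p1), 2 * (p3 - p1))
  b <- c(sum(p2^2) - sum(p1^2), sum(p3^2) - sum(p1^2))
  centre <- solve(A, b)
  sqrt(sum((p1 - centre)^2))
}

# Second moment of a mask about an axis through `point` (mm) along
# `direction`, by direct per-pixel summation: perpendicular-distance^2
# times pixel area, plus the square pixel's own isotropic term s^4/12.
oracle_sma <- function(mask, direction, point = NULL) {
  idx <- which(mask$grid, arr.ind = TRUE)
  s <- mask$pixel_size
  x <- (idx[, "col"] - 0.5) * s
  y <- (idx[, "row"] - 0.5) * s
  if (is.null(point)) point <- c(mean(x), mean(y))
  u <- direction / sqrt(sum(direction^2))
  d <- -(x - point[1]) * u[2] + (y - point[2]) * u[1]
  sum(d^2) * s^2 + length(x) * s^4 / 12
}

# Textbook pooled-variance Student t.
oracle_pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# Landmarks exactly on a circle of radius r in 3D: arc positions (rad)
# for tip, margin, base, then an arbitrary rigid transform.
on_circle_landmarks <- function(r, angles, rotation = diag(3),
                                translation = c(0, 0, 0),
                                specimen_id = "oracle") {
  pts <- cbind(r * cos(angles), r * sin(angles), 0) %*% t(rotation)
  pts <- sweep(pts, 2, translation, "+")
  tibble::tibble(
    specimen_id = specimen_id,
    landmark = c("tip", "margin", "base"),
    x = pts[, 1], y = pts[, 2], z = pts[, 3]
  )
}

random_rotation_3d <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# A random blob-ish mask: union of a few filled discs on a small grid.
random_mask <- function(n_px = 40, pixel_size = 0.1) {
  grid <- matrix(FALSE, n_px, n_px)
  centres <- cbind(runif(3, 0.3, 0.7) * n_px, runif(3, 0.3, 0.7) * n_px)
  radii <- runif(3, 0.1, 0.25) * n_px
  for (i in seq_len(nrow(grid))) {
    for (j in seq_len(ncol(grid))) {
      d2 <- (i - centres[, 1])^2 + (j - centres[, 2])^2
      if (any(d2 < radii^2)) grid[i, j] <- TRUE
    }
  }
  section_mask(grid, pixel_size)
}
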