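# Arc geometry: chords, circumradius, subtended angles, arc lengths.

lm_tbl <- function(tip, margin, base, id = "s1") {
  pts <- rbind(tip, margin, base)
  if (ncol(pts) == 2) pts <- cbind(pts, 0)
  tibble::tibble(specimen_id = id,
                 landmark = c("tip", "margin", "base"),
                 x = pts[, 1], y = pts[, 2], z = pts[, 3])
}

test_that("chord lengths are plain Euclidean distances with the a/b/c pairing", {
  iso <- chord_lengths(lm_tbl(c(0, 0), c(1, 1), c(2, 0)))
  expect_equal(iso$a, sqrt(2))
  expect_equal(iso$b, sqrt(2))
  expect_equal(iso$c, 2)

  tri345 <- chord_lengths(lm_tbl(c(0, 0, 0), c(3, 0, 0), c(3, 4, 0)))
  expect_equal(c(tri345$a, tri345$b, tri345$c), c(3, 4, 5))

  # chords of arcs on a known circle: chord = 2 r sin(arc/2)
  lm <- on_circle_landmarks(10, c(0, 60, 150) * pi / 180)
  ch <- chord_lengths(lm)
  expect_equal(ch$a, 2 * 10 * sin(30 * pi / 180))
  expect_equal(ch$b, 2 * 10 * sin(45 * pi / 180))
  expect_equal(ch$c, 2 * 10 * sin(75 * pi / 180))
})

test_that("degenerate landmark sets are rejected, naming the offending pair", {
  expect_error(chord_lengths(lm_tbl(c(0, 0), c(0, 0), c(1, 0))),
               "'tip' and 'margin' coincide")
  expect_error(
    chord_lengths(tibble::tibble(specimen_id = "s1",
                                 landmark = c("tip", "tip", "base"),
                                 x = 0:2, y = 0)),
    "exactly one of each landmark")
})

test_that("circumradius matches closed forms and rejects collinear input", {
  expect_equal(circumradius(2, 2, 2), 2 / sqrt(3))
  expect_equal(circumradius(3, 4, 5), 2.5)
  # equilateral s/sqrt(3) for a sweep of sizes
  for (s in c(0.01, 1, 5, 1000)) {
    expect_equal(circumradius(s, s, s), s / sqrt(3))
  }
  expect_error(circumradius(1, 1, 2), "collinear")
  expect_error(circumradius(1, -1, 1), "strictly positive")
})

test_that("side-length circumradius agrees with the coordinate circumcentre solve", {
  set.seed(11)
  for (i in 1:300) {
    pts <- matrix(runif(6, -10, 10), 3, 2)
    sides <- c(dist(pts))
    area2 <- abs((pts[2, 1] - pts[1, 1]) * (pts[3, 2] - pts[1, 2]) -
                 (pts[3, 1] - pts[1, 1]) * (pts[2, 2] - pts[1, 2]))
    if (area2 < 1e-3) next
    r_sides <- circumradius(sides[1], sides[2], sides[3])
    r_coord <- oracle_circumradius_2d(pts[1, ], pts[2, ], pts[3, ])
    expect_equal(r_sides, r_coord, tolerance = 1e-9)
  }
})

test_that("subtended angle handles the diameter limit and clamps asin", {
  expect_equal(subtended_angle(2, 1), pi)
  expect_equal(subtended_angle(1, 1), pi / 3)
  expect_equal(subtended_angle(sqrt(2), 1), pi / 2)
  expect_equal(subtended_angle(2 + 1e-12, 1), pi) # within clamp
  expect_error(subtended_angle(2.1, 1), "exceeds")
  expect_error(subtended_angle(1, 0), "positive")
})

test_that("total angle applies the reflex correction exactly when X > 0", {
  # right angle at margin: a^2 + b^2 = c^2 is the semicircle boundary
  a <- b <- 1; c <- sqrt(2)
  r <- circumradius(a, b, c)
  expect_equal(total_angle(a, b, c, r), pi)

  # 220 degree arc on the unit circle, margin at the midpoint
  a2 <- 2 * sin(55 * pi / 180); c2 <- 2 * sin(110 * pi / 180)
  r2 <- circumradius(a2, a2, c2)
  expect_equal(r2, 1, tolerance = 1e-12)
  expect_equal(total_angle(a2, a2, c2, r2), 220 * pi / 180,
               tolerance = 1e-9)

  # 90 degree arc: no correction
  lm <- on_circle_landmarks(1, c(0, 40, 90) * pi / 180)
  ch <- chord_lengths(lm)
  r3 <- circumradius(ch$a, ch$b, ch$c)
  expect_equal(total_angle(ch$a, ch$b, ch$c, r3), pi / 2,
               tolerance = 1e-9)

  # asin branch and inscribed-angle form 2*(pi - margin angle) agree
  set.seed(7)
  for (i in 1:100) {
    th <- runif(1, 0.2, 1.9) * pi
    split <- runif(1, 0.1, 0.9)
    lm <- on_circle_landmarks(runif(1, 1, 20), c(0, split * th, th))
    ch <- chord_lengths(lm)
    r <- circumradius(ch$a, ch$b, ch$c)
    margin_angle <- acos((ch$a^2 + ch$b^2 - ch$c^2) / (2 * ch$a * ch$b))
    expect_equal(total_angle(ch$a, ch$b, ch$c, r),
                 2 * (pi - margin_angle), tolerance = 1e-8)
  }
})

test_that("sub-arc angles split the arc at the margin and stay additive", {
  # 120 degree arc split at the midpoint
  lm <- on_circle_landmarks(1, c(0, 60, 120) * pi / 180)
  ch <- chord_lengths(lm)
  r <- circumradius(ch$a, ch$b, ch$c)
  sub <- sub_arc_angles(ch$a, ch$b, ch$c, r)
  expect_equal(sub$theta_ext, 60 * pi / 180, tolerance = 1e-12)
  expect_equal(sub$theta_int, 60 * pi / 180, tolerance = 1e-12)

  # reflex 220 degree arc, margin at midpoint: each sub-arc 110
  lm <- on_circle_landmarks(1, c(0, 110, 220) * pi / 180)
  ch <- chord_lengths(lm)
  r <- circumradius(ch$a, ch$b, ch$c)
  sub <- sub_arc_angles(ch$a, ch$b, ch$c, r)
  expect_equal(sub$theta_ext, 110 * pi / 180, tolerance = 1e-9)
  expect_equal(sub$theta_int, 110 * pi / 180, tolerance = 1e-9)
  expect_equal(sub$theta_ext + sub$theta_int,
               total_angle(ch$a, ch$b, ch$c, r), tolerance = 1e-9)

  # 90 degree arc with the margin 30 degrees from the tip
  lm <- on_circle_landmarks(1, c(0, 30, 90) * pi / 180)
  ch <- chord_lengths(lm)
  r <- circumradius(ch$a, ch$b, ch$c)
  sub <- sub_arc_angles(ch$a, ch$b, ch$c, r)
  expect_equal(sub$theta_ext, 30 * pi / 180, tolerance = 1e-9)
  expect_equal(sub$theta_int, 60 * pi / 180, tolerance = 1e-9)
})

test_that("sub-arc angles match the chord-substitution form for minor arcs", {
  set.seed(21)
  for (i in 1:50) {
    th <- runif(1, 0.2, 0.95) * pi # below a semicircle
    split <- runif(1, 0.1, 0.9)
    lm <- on_circle_landmarks(runif(1, 1, 20), c(0, split * th, th))
    ch <- chord_lengths(lm)
    r <- circumradius(ch$a, ch$b, ch$c)
    sub <- sub_arc_angles(ch$a, ch$b, ch$c, r)
    expect_equal(sub$theta_ext, 2 * asin(ch$a / (2 * r)),
                 tolerance = 1e-8)
    expect_equal(sub$theta_int, 2 * asin(ch$b / (2 * r)),
                 tolerance = 1e-8)
  }
})

test_that("arc_metrics composes the pieces: constructed arcs round-trip", {
  # 72 degree arc of a circle r = 10, margin at midpoint
  arc <- make_arc_landmarks(r = 10, theta_total = 0.2 * 2 * pi,
                            margin_split = 0.5)
  m <- arc_metrics(arc$landmarks)
  expect_equal(m$pct_circle, 20, tolerance = 1e-9)
  expect_equal(m$TTL, 0.4 * pi * 10, tolerance = 1e-9)
  expect_equal(m$ETL, m$ITL, tolerance = 1e-9)
  expect_equal(m$ETL, 2 * pi * 10 * 0.1, tolerance = 1e-9)

  # semicircle, r = 5
  semi <- make_arc_landmarks(r = 5, theta_total = pi - 1e-12)
  ms <- arc_metrics(semi$landmarks)
  expect_equal(ms$pct_circle, 50, tolerance = 1e-6)
  expect_equal(ms$TTL, 5 * pi, tolerance = 1e-6)
})

test_that("exact on-circle landmarks are recovered under any rigid 3D transform", {
  set.seed(42)
  for (i in 1:200) {
    r <- runif(1, 0.5, 50)
    th <- runif(1, 0.05, 1.94) * pi # includes strongly reflex arcs
    split <- runif(1, 0.05, 0.95)
    lm <- on_circle_landmarks(r, c(0, split * th, th),
                              rotation = random_rotation_3d(),
                              translation = runif(3, -100, 100))
    m <- arc_metrics(lm)
    expect_equal(m$r, r, tolerance = 1e-9)
    expect_equal(m$theta_total_rad, th, tolerance = 1e-9)
    expect_lt(abs(m$ETL + m$ITL - m$TTL), 1e-9 * m$TTL)
  }
})

test_that("fraction of circle is scale-invariant and increasing in the angle", {
  lm <- on_circle_landmarks(3, c(0, 0.8, 2.1))
  m1 <- arc_metrics(lm)
  lm_scaled <- dplyr::mutate(lm, x = x * 7.3, y = y * 7.3, z = z * 7.3)
  m2 <- arc_metrics(lm_scaled)
  expect_equal(m1$pct_circle, m2$pct_circle, tolerance = 1e-9)
  expect_equal(m2$r, 3 * 7.3, tolerance = 1e-9)

  ths <- seq(0.3, 5.9, length.out = 20)
  pct <- vapply(ths, function(th) {
    arc_metrics(on_circle_landmarks(2, c(0, th / 2, th)))$pct_circle
  }, numeric(1))
  expect_true(all(diff(pct) > 0))
})

test_that("noisy landmarks recover the generating circle approximately", {
  arc <- make_arc_landmarks(r = 10, theta_total = 2 * pi / 3,
                            margin_split = 0.5, noise_sd = 0.01, seed = 99)
  m <- arc_metrics(arc$landmarks)
  expect_lt(abs(m$r - 10), 0.1)
  expect_lt(abs(m$pct_circle - 100 / 3), 0.5)
})

test_that("landmark files round-trip through read_landmarks in csv and tsv", {
  lm <- on_circle_landmarks(4, c(0, 1, 2), specimen_id = "spec A")
  csv <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(lm, csv)
  expect_equal(as.data.frame(read_landmarks(csv)), as.data.frame(lm))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(dplyr::select(lm, -z), tsv)
  got <- read_landmarks(tsv)
  expect_equal(got$z, rep(0, 3)) # z optional, defaults to 0
  expect_error(suppressWarnings(
    read_landmarks(withr::local_tempfile(fileext = ".csv"))))
})
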