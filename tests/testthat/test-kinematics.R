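ray_samples <- function(r, angle_deg, rate = 60) {
  th <- angle_deg * pi / 180
  data.frame(t_s = (seq_along(r) - 1) / rate,
             x_deg = r * cos(th), y_deg = r * sin(th))
}

test_that("outward segment ends at the first radial maximum", {
  mono <- ray_samples(seq(0, 9, length.out = 20), 30)
  expect_identical(outward_segment(mono), mono)

  r <- c(seq(0, 9, length.out = 17), seq(8.5, 2, length.out = 13))
  outback <- ray_samples(r, 50)
  expect_equal(nrow(outward_segment(outback)), 17)

  tie <- ray_samples(c(0, 4, 9, 5, 9, 3), 10)
  expect_equal(nrow(outward_segment(tie)), 3)  # earliest maximum wins

  degenerate <- ray_samples(c(0, 0, 0), 10)
  expect_error(outward_segment(degenerate), "degenerate")
})

test_that("pointing direction equals the orthogonal line fit through the start", {
  expect_equal(fit_pointing_direction(ray_samples(1:10, 45)), 45)
  expect_equal(fit_pointing_direction(ray_samples(1:10, 0)), 0)
  expect_equal(fit_pointing_direction(ray_samples(1:10, 170)), 170)
  expect_equal(fit_pointing_direction(ray_samples(1:10, -90)), -90)

  # noisy samples about a 30-degree line: independent oracle minimises the
  # summed squared orthogonal distance to a line through the origin
  set.seed(42)
  base <- ray_samples(seq(0.3, 9, length.out = 20), 30)
  base$x_deg <- base$x_deg + rnorm(20, 0, 0.3)
  base$y_deg <- base$y_deg + rnorm(20, 0, 0.3)
  loss <- function(th) {
    u <- c(cos(th), sin(th))
    sum((base$x_deg * u[2] - base$y_deg * u[1])^2)
  }
  opt <- optimize(loss, c(0, pi / 2), tol = 1e-12)$minimum * 180 / pi
  expect_equal(fit_pointing_direction(base), opt, tolerance = 1e-6)

  expect_error(fit_pointing_direction(ray_samples(c(0, 0, 0), 0)),
               "zero spatial variance")
})

test_that("pointing-direction fit is rotation-equivariant", {
  set.seed(8)
  base <- ray_samples(seq(0.3, 9, length.out = 15), 40)
  base$x_deg <- base$x_deg + rnorm(15, 0, 0.2)
  base$y_deg <- base$y_deg + rnorm(15, 0, 0.2)
  ref <- fit_pointing_direction(base)
  for (th in c(-120, -35, 10, 90)) {
    rad <- th * pi / 180
    rot <- base
    rot$x_deg <- base$x_deg * cos(rad) - base$y_deg * sin(rad)
    rot$y_deg <- base$x_deg * sin(rad) + base$y_deg * cos(rad)
    d <- (fit_pointing_direction(rot) - ref - th) %% 360
    expect_lt(min(d, 360 - d), 1e-9)
  }
})

test_that("chord deviation matches geometry and is rigid-motion invariant", {
  straight <- ray_samples(seq(0, 9, length.out = 12), 25)
  expect_equal(max_chord_deviation(straight), 0)

  # circular arc: maximum deviation from the chord is the sagitta
  R <- 12; phi <- seq(-0.4, 0.4, length.out = 4001)
  arc <- data.frame(t_s = seq_along(phi) / 60,
                    x_deg = R * cos(phi), y_deg = R * sin(phi))
  chord <- sqrt(sum((arc[4001, c("x_deg", "y_deg")] -
                       arc[1, c("x_deg", "y_deg")])^2))
  sagitta <- R - sqrt(R^2 - (chord / 2)^2)
  expect_equal(max_chord_deviation(arc), sagitta, tolerance = 1e-6)

  # invariance under rotation + translation
  rad <- 77 * pi / 180
  moved <- arc
  moved$x_deg <- arc$x_deg * cos(rad) - arc$y_deg * sin(rad) + 5.3
  moved$y_deg <- arc$x_deg * sin(rad) + arc$y_deg * cos(rad) - 2.1
  expect_equal(max_chord_deviation(moved), max_chord_deviation(arc),
               tolerance = 1e-9)

  coincident <- ray_samples(c(0, 1, 0), 10)
  expect_error(max_chord_deviation(coincident), "coincident")
})

test_that("peak speed is the maximum finite-difference speed", {
  still <- data.frame(t_s = 0:4 / 10, x_deg = rep(1, 5), y_deg = rep(2, 5))
  expect_equal(peak_speed(still), 0)

  uniform <- ray_samples(seq(0, 1, length.out = 11), 60, rate = 60)
  # 1 degree in 10 steps of 1/60 s -> 6 deg/s
  expect_equal(peak_speed(uniform), 6, tolerance = 1e-9)

  set.seed(12)
  jit <- data.frame(t_s = cumsum(runif(30, 0.01, 0.03)),
                    x_deg = cumsum(rnorm(30)), y_deg = cumsum(rnorm(30)))
  oracle <- max(sapply(2:30, function(i)
    sqrt((jit$x_deg[i] - jit$x_deg[i - 1])^2 +
           (jit$y_deg[i] - jit$y_deg[i - 1])^2) /
      (jit$t_s[i] - jit$t_s[i - 1])))
  expect_equal(peak_speed(jit), oracle, tolerance = 1e-12)

  bad <- data.frame(t_s = c(0, 0.1, 0.1), x_deg = 1:3, y_deg = 1:3)
  expect_error(peak_speed(bad), "strictly increasing")
})

test_that("trial classification applies the validity and exclusion rules", {
  trials <- rbind(
    make_trial("A", 1, "feedback", manipulation = 10, amplitude = 4),
    make_trial("A", 2, "probe", preceding = 10),               # follows invalid
    make_trial("A", 3, "feedback", manipulation = -20),
    make_trial("A", 4, "probe", preceding = -20, max_dev = 3), # curved
    make_trial("A", 5, "feedback", manipulation = 0, peak_speed = 150),
    make_trial("A", 6, "probe", preceding = 0),                # follows excluded
    make_trial("A", 7, "feedback", manipulation = 5, epd = NA),
    make_trial("A", 8, "probe", preceding = 5),
    make_trial("A", 9, "feedback", manipulation = 40),
    make_trial("A", 10, "probe", preceding = 40)
  )
  out <- classify_and_filter(trials)
  expect_identical(out$status,
                   c("invalid_amplitude", "discarded_follow",
                     "valid", "excluded_curvature",
                     "excluded_velocity", "discarded_follow",
                     "invalid_no_estimate", "discarded_follow",
                     "valid", "valid"))
  # evaluable: 2 feedback trials, 1 probe trial
  expect_equal(sum(out$status == "valid" & out$condition == "feedback"), 2)
  expect_equal(sum(out$status == "valid" & out$condition == "probe"), 1)

  # row order of the input does not affect the assigned statuses
  perm <- sample(nrow(trials))
  out2 <- classify_and_filter(trials[perm, ])
  expect_identical(out2$status[order(out2$trial_index)],
                   out$status[order(out$trial_index)])
})

test_that("exclusion thresholds are strict inequalities", {
  boundary <- rbind(
    make_trial("B", 1, "feedback", manipulation = 0,
               max_dev = 2.25, peak_speed = 120),
    make_trial("B", 2, "probe", preceding = 0,
               max_dev = 2.25, peak_speed = 120),
    make_trial("B", 3, "feedback", manipulation = 0, amplitude = 4.5)
  )
  out <- classify_and_filter(boundary)
  expect_identical(out$status, c("valid", "valid", "valid"))

  over <- classify_and_filter(rbind(
    make_trial("B", 1, "feedback", manipulation = 0, max_dev = 2.2500001),
    make_trial("B", 3, "feedback", manipulation = 0, peak_speed = 120.0001)))
  expect_identical(over$status, c("excluded_curvature", "excluded_velocity"))
})
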