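test_that("velocity estimate is exact on constant and linear traces", {
  tr <- data.frame(t = 0:100, x = 1.5, y = -2, valid = TRUE)
  v <- compute_velocity(tr)
  expect_true(all(v$speed[!is.na(v$speed)] == 0))
  # linear drift at 100 deg/s
  tr <- data.frame(t = 0:100, x = 0.1 * (0:100), y = 0, valid = TRUE)
  v <- compute_velocity(tr)
  interior <- v$speed[10:90]
  expect_true(all(abs(interior - 100) < 1))
  expect_error(compute_velocity(tr[1:3, ]), "shorter")
})

test_that("over-speed segments and tracking loss are masked locally", {
  # a 4000 deg/s segment (100:110 ms) inside a 20 deg/s drift
  x <- 0.02 * (0:200)
  x[101:201] <- x[101:201] + pmin((1:101) * 4, 10 * 4)
  tr <- data.frame(t = 0:200, x = x, y = 0, valid = TRUE)
  v <- compute_velocity(tr)
  expect_true(all(is.na(v$speed[102:108])))
  expect_true(all(abs(v$speed[10:90] - 20) < 1))
  expect_true(all(abs(v$speed[130:190] - 20) < 1))
  # invalid samples propagate to windows touching them
  tr$valid[50] <- FALSE
  v2 <- compute_velocity(tr)
  expect_true(is.na(v2$speed[50]))
  expect_true(is.na(v2$speed[48]))
  expect_false(is.na(v2$speed[40]))
})

test_that("saccade detection finds synthetic minimum-jerk events", {
  # fixation only
  set.seed(1)
  tr <- data.frame(t = 0:400, x = rnorm(401, 0, 0.005),
                   y = rnorm(401, 0, 0.005), valid = TRUE)
  expect_equal(nrow(detect_saccades(tr)), 0)
  # one 10 degree saccade at 250 ms
  tr <- make_minjerk_trace(rt_ms = 250, amplitude = 10, peak_velocity = 450)
  ev <- detect_saccades(tr)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$onset_ms - 250), 2.5)
  expect_lt(abs(ev$amplitude_deg - 10), 0.05)
  # two saccades separated by 200 ms of fixation, in temporal order
  t2 <- make_minjerk_trace(rt_ms = 150, amplitude = 8, peak_velocity = 400,
                           t_end = 1000)
  D1 <- 1.875 * 8 / 400 * 1000
  start2 <- 150 + D1 + 200
  idx <- t2$t >= start2
  tau <- pmin(pmax((t2$t[idx] - start2) / 40, 0), 1)
  t2$x[idx] <- t2$x[idx] + 5 * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
  ev2 <- detect_saccades(t2)
  expect_equal(nrow(ev2), 2)
  expect_true(ev2$onset_ms[1] < ev2$onset_ms[2])
  expect_lt(abs(ev2$onset_ms[2] - start2), 3)
})

test_that("primary-saccade selection applies the amplitude/RT/velocity rules", {
  ev <- data.frame(onset_ms = c(80, 150, 300), offset_ms = c(110, 160, 340),
                   amplitude_deg = c(2, 0.5, 8),
                   peak_velocity_deg_s = c(200, 40, 420),
                   start_x = 0, start_y = 0, end_x = 1, end_y = 0)
  # 80 ms is too early, 150 ms too small: the 300 ms event wins
  sel <- select_primary_saccade(ev)
  expect_true(sel$included)
  expect_equal(sel$event$onset_ms, 300)
  # no events
  none <- select_primary_saccade(ev[0, ])
  expect_false(none$included)
  expect_equal(none$reason, "no_primary_saccade")
  # peak velocity out of bounds
  ev$peak_velocity_deg_s[3] <- 1700
  fast <- select_primary_saccade(ev)
  expect_false(fast$included)
  expect_equal(fast$reason, "velocity_bounds")
})

test_that("residual velocity has the OLS identities within each group", {
  # exact main-sequence data -> all residuals zero
  set.seed(8)
  d <- data.frame(participant = rep(c("P1", "P2"), each = 40),
                  drug = rep(c("placebo", "THP"), 40),
                  amplitude = runif(80, 8, 14))
  d$peak_velocity <- 30 * d$amplitude + 100
  r <- residual_velocity(d)
  expect_true(all(abs(r$residual_velocity) < 1e-8))

  # balanced injected offsets are recovered (closed-form OLS oracle)
  d2 <- data.frame(participant = "P1", drug = "placebo",
                   amplitude = rep(c(9, 10, 11, 12), each = 3))
  off <- rep(c(20, -20, 0), 4)
  d2$peak_velocity <- 25 * d2$amplitude + 150 + off
  r2 <- residual_velocity(d2)
  oracle <- stats::residuals(stats::lm(peak_velocity ~ amplitude, d2))
  expect_equal(r2$residual_velocity, unname(oracle), tolerance = 1e-10)
  expect_equal(r2$residual_velocity, off, tolerance = 1e-8)

  # per-group zero mean and orthogonality to amplitude
  cfg <- small_generator_config(seed = 8)
  tab <- residual_velocity(generate_trial_table(cfg))
  grp <- interaction(tab$participant, tab$drug)
  for (g in levels(grp)) {
    sel <- grp == g & !is.na(tab$residual_velocity)
    expect_lt(abs(mean(tab$residual_velocity[sel])), 1e-8)
    expect_lt(abs(sum(tab$residual_velocity[sel] * tab$amplitude[sel])) /
                sum(sel), 1e-6)
  }
})

test_that("session-wise fitting removes session offsets that pooling keeps", {
  set.seed(9)
  d <- data.frame(participant = "P1",
                  drug = rep(c("placebo", "THP"), each = 50),
                  amplitude = runif(100, 8, 14))
  d$peak_velocity <- 30 * d$amplitude + 100 +
    ifelse(d$drug == "THP", 50, 0) + rnorm(100, 0, 5)
  r <- residual_velocity(d)
  for (ss in c("placebo", "THP")) {
    expect_lt(abs(mean(r$residual_velocity[d$drug == ss])), 1e-8)
  }
  pooled <- stats::residuals(stats::lm(peak_velocity ~ amplitude, d))
  expect_gt(abs(mean(pooled[d$drug == "THP"])), 5)
})

test_that("small groups are flagged and left without residuals", {
  d <- data.frame(participant = c("P1", "P1", "P2"),
                  drug = "placebo", amplitude = c(10, 11, 12),
                  peak_velocity = c(400, 430, 460))
  expect_message(r <- residual_velocity(d), "flagged")
  expect_true(all(is.na(r$residual_velocity)))
})

test_that("pull angle follows the planar geometry and sign convention", {
  fix <- c(0, 0); targ <- c(11, 0)
  dist_up <- c(11 * cos(pi / 3), 11 * sin(pi / 3))   # +60 deg side
  straight <- data.frame(t = 0:50, x = seq(0, 5, length.out = 51), y = 0,
                         valid = TRUE)
  expect_equal(as.numeric(
    distractor_pull(straight, fix, targ, dist_up)), 0, tolerance = 1e-9)
  rot <- function(deg) {
    th <- deg * pi / 180
    data.frame(t = 0:50, x = seq(0, 5, length.out = 51) * cos(th),
               y = seq(0, 5, length.out = 51) * sin(th), valid = TRUE)
  }
  expect_equal(as.numeric(distractor_pull(rot(30), fix, targ, dist_up)),
               30, tolerance = 1e-9)
  expect_equal(as.numeric(distractor_pull(rot(-30), fix, targ, dist_up)),
               -30, tolerance = 1e-9)
  # mirror-reflecting the distractor flips every pull
  dist_dn <- c(dist_up[1], -dist_up[2])
  for (a in c(-70, -30, 0, 15, 45)) {
    expect_equal(
      as.numeric(distractor_pull(rot(a), fix, targ, dist_up)),
      -as.numeric(distractor_pull(rot(a), fix, targ, dist_dn)),
      tolerance = 1e-9)
  }
  # gaze that never leaves the fixation circle is excluded
  stay <- data.frame(t = 0:50, x = 0.1, y = 0.1, valid = TRUE)
  res <- distractor_pull(stay, fix, targ, dist_up)
  expect_true(is.na(res))
  expect_equal(attr(res, "reason"), "no_exit")
})

test_that("parsing is invariant to rigid rotation and translation", {
  tr <- make_minjerk_trace(rt_ms = 220, amplitude = 11,
                           peak_velocity = 480, angle_deg = 0)
  geom <- list(fixation = c(0, 0), target = c(11, 0),
               distractor = 11 * c(cos(pi / 3), sin(pi / 3)))
  attr(tr, "geometry") <- geom
  k0 <- trial_kinematics(tr)
  th <- 77 * pi / 180; sh <- c(3.2, -1.7)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  tr2 <- tr
  xy <- as.matrix(tr[, c("x", "y")]) %*% t(R)
  tr2$x <- xy[, 1] + sh[1]; tr2$y <- xy[, 2] + sh[2]
  attr(tr2, "geometry") <- lapply(geom, function(p) drop(R %*% p) + sh)
  k1 <- trial_kinematics(tr2)
  expect_equal(k0$rt_ms, k1$rt_ms)
  expect_equal(k0$amplitude_deg, k1$amplitude_deg, tolerance = 1e-9)
  expect_equal(k0$peak_velocity_deg_s, k1$peak_velocity_deg_s,
               tolerance = 1e-9)
  expect_equal(k0$pull_deg, k1$pull_deg, tolerance = 1e-7)
  # log RT is a strictly monotone transform of RT
  rts <- c(120, 180, 250, 400, 890)
  expect_equal(order(log(rts)), order(rts))
})

test_that("kernel densities integrate to one and find planted modes", {
  vals <- rep(30, 40)
  dens <- kinematics_summary_density(vals + rnorm(40, 0, 0.1),
                                     participant = rep(c("P1", "P2"), 20),
                                     condition = rep("a", 40), bw = 2)
  step <- mean(diff(dens$grid))
  expect_equal(sum(dens$mean[1, ] * step), 1, tolerance = 1e-6)
  expect_lt(abs(dens$grid[which.max(dens$mean[1, ])] - 30), 2)

  # bimodal mixture: modes within 2 degrees of -10 and +30
  set.seed(12)
  v <- ifelse(runif(4000) < 0.8, rnorm(4000, -10, 8), rnorm(4000, 30, 8))
  d2 <- kinematics_summary_density(v, participant = rep("P1", 4000),
                                   condition = rep("a", 4000), bw = 4)
  y <- d2$mean[1, ]
  peaks <- which(diff(sign(diff(y))) == -2) + 1
  modes <- d2$grid[peaks[order(y[peaks], decreasing = TRUE)][1:2]]
  expect_lt(min(abs(modes - (-10))), 2)
  expect_lt(min(abs(modes - 30)), 2)

  expect_error(kinematics_summary_density(
    1, participant = "P1", condition = "a"), "fewer than 2")
})
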