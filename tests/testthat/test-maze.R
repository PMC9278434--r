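g20 <- barnes_geometry(exit_index = 1)

# straight-line trajectory through the given hole centres
path_through_holes <- function(g, holes, rate = 10, speed = 30) {
  wp <- rbind(c(0, 0), cbind(g$hole_x[holes], g$hole_y[holes]))
  xs <- ys <- ts <- numeric(0)
  t <- 0
  for (i in 2:nrow(wp)) {
    d <- sqrt(sum((wp[i, ] - wp[i - 1, ])^2))
    n <- max(2, ceiling(d / speed * rate))
    fr <- seq(0, 1, length.out = n)[-1]
    xs <- c(xs, wp[i - 1, 1] + fr * diff(wp[, 1])[i - 1])
    ys <- c(ys, wp[i - 1, 2] + fr * diff(wp[, 2])[i - 1])
    ts <- c(ts, t + fr * d / speed)
    t <- t + d / speed
  }
  maze_trajectory(c(0, ts), c(0, xs), c(0, ys), g)
}

test_that("hole visits record entries in order, once per entry", {
  traj <- path_through_holes(g20, c(3, 4, 5))
  expect_equal(detect_hole_visits(traj)$hole, c(3, 4, 5))

  still <- maze_trajectory(0:10, rep(0, 11), rep(0, 11), g20)
  expect_equal(nrow(detect_hole_visits(still)), 0)
})

test_that("exit errors count abortive exit visits, not the terminal exit", {
  v1 <- tibble::tibble(time_s = 10, hole = 1)
  expect_equal(count_exit_errors(v1, 1, 10.5), 0L)

  v2 <- tibble::tibble(time_s = c(5, 8, 12), hole = c(1, 7, 1))
  expect_equal(count_exit_errors(v2, 1, 12.5), 1L)

  # trial that never ends at the exit: every exit visit is an error
  v3 <- tibble::tibble(time_s = c(5, 8), hole = c(1, 7))
  expect_equal(count_exit_errors(v3, 1, 60), 1L)
})

test_that("scripted abortive exit visits are counted exactly", {
  for (k in c(0L, 3L)) {
    traj <- simulate_maze_path("serial", g20, seed = 5,
                               abortive_exit_visits = k)
    visits <- detect_hole_visits(traj)
    errs <- count_exit_errors(visits, g20$exit_index,
                              max(traj$time_s))
    expect_equal(errs, k)
  }
})

test_that("constructed prototype paths get their defining labels", {
  spatial <- path_through_holes(g20, c(2, 1))  # adjacent hole then exit
  expect_equal(as.character(classify_search_strategy(spatial)), "spatial")

  serial <- path_through_holes(g20, c(5, 6, 7, 8, 1))
  lab <- classify_search_strategy(serial)
  expect_equal(as.character(lab), "serial")
  expect_false(attr(lab, "fallback"))
})

test_that("strategy recovery holds across simulated trajectories", {
  for (strat in c("spatial", "serial", "random")) {
    hits <- vapply(1:12, function(s) {
      traj <- simulate_maze_path(strat, g20, seed = s)
      as.character(classify_search_strategy(traj)) == strat
    }, TRUE)
    expect_gte(mean(hits), 0.95)
  }
})

test_that("maze paths are reproducible under a fixed seed", {
  t1 <- simulate_maze_path("random", g20, seed = 9)
  t2 <- simulate_maze_path("random", g20, seed = 9)
  expect_identical(t1$x_cm, t2$x_cm)
  expect_error(simulate_maze_path("zigzag", g20), "unknown strategy")
})

test_that("arm entries honour the penetration-depth hysteresis", {
  gy <- ymaze_geometry()
  traj <- simulate_ymaze_path(gy, c("novel", "open"), seed = 1)
  expect_equal(detect_arm_entries(traj)$arm, c("novel", "open"))

  # oscillation at the arm mouth, never penetrating d_entry
  a <- gy$arm_angle[1]
  depth <- 5 + 3 * sin(seq(0, 20, by = 0.1))
  osc <- maze_trajectory(seq_along(depth) / 10,
                         depth * cos(a), depth * sin(a), gy)
  expect_equal(nrow(detect_arm_entries(osc)), 0)
})

test_that("scripted alternation sequences are recovered exactly", {
  gy <- ymaze_geometry()
  seqs <- c("entry", "novel", "open", "novel", "entry", "open")
  traj <- simulate_ymaze_path(gy, seqs, seed = 3)
  expect_equal(detect_arm_entries(traj)$arm, seqs)
})

test_that("novelty metrics compute preference and discrimination ratios", {
  gy <- ymaze_geometry()
  # equal dwations in novel and open arms -> 50% time preference
  traj <- simulate_ymaze_path(gy, c("novel", "open"), seed = 2,
                              dwell_s = 5)
  m <- novelty_metrics(traj)
  expect_equal(unname(m$preference_pct[["time"]]), 50, tolerance = 5)

  entries <- tibble::tibble(time_s = 1:4,
                            arm = c("novel", "novel", "open", "entry"))
  m2 <- novelty_metrics(traj, entries = entries)
  expect_equal(unname(m2$discrimination_ratio[["entries"]]), 0.5)

  # a trajectory that never leaves the centre has undefined preferences
  still <- maze_trajectory(0:10, rep(0, 11), rep(0, 11), gy)
  m3 <- novelty_metrics(still, entries = tibble::tibble(time_s = numeric(0),
                                                        arm = character(0)))
  expect_true(is.na(m3$preference_pct[["time"]]))
})

test_that("scripted strong novel-arm preference is recovered", {
  gy <- ymaze_geometry()
  traj <- simulate_ymaze_path(gy, c("novel", "open", "novel", "novel"),
                              seed = 4, dwell_s = 3)
  m <- novelty_metrics(traj)
  expect_gt(m$preference_pct[["entries"]], 50)
})

test_that("occupancy heat maps conserve trial duration on any grid", {
  traj <- simulate_maze_path("random", g20, seed = 2)
  dur <- max(traj$time_s) - min(traj$time_s)
  for (grid in c(2, 5, 11)) {
    hm <- occupancy_heatmap(traj, grid_cm = grid)
    expect_equal(sum(hm$dwell_s), dur, tolerance = 1e-9)
  }

  still <- maze_trajectory(seq(0, 30, by = 0.1), rep(3, 301), rep(3, 301),
                           g20)
  hm <- occupancy_heatmap(still, grid_cm = 5)
  expect_equal(nrow(hm[hm$dwell_s > 0, ]), 1)
  expect_equal(sum(hm$dwell_s), 30)
})

test_that("path distance is invariant under time reversal", {
  traj <- simulate_maze_path("serial", g20, seed = 6)
  dist <- function(x, y) sum(sqrt(diff(x)^2 + diff(y)^2))
  expect_equal(dist(traj$x_cm, traj$y_cm),
               dist(rev(traj$x_cm), rev(traj$y_cm)), tolerance = 1e-9)
})

test_that("geometries validate their invariants", {
  expect_error(barnes_geometry(n_holes = 2), ">= 3")
  expect_error(barnes_geometry(exit_index = 25), "out of range")
  expect_error(ymaze_geometry(labels = c("a", "b")), "exactly 3")
  g <- barnes_geometry()
  expect_equal(length(g$hole_x), 20)
  ang <- sort(g$hole_angle)
  expect_equal(diff(ang), rep(2 * pi / 20, 19), tolerance = 1e-9)
})
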