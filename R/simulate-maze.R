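# Prototype maze trajectories with known strategy labels, used to validate
# the scoring rules. Paths are piecewise-linear waypoint tours traversed at
# constant speed with small positional jitter.

interp_waypoints <- function(wp, speed_cm_s, rate_hz, dwell_s, jitter_cm) {
  xs <- ys <- ts <- numeric(0)
  t <- 0
  for (i in seq_len(nrow(wp))) {
    if (i > 1) {
      d <- sqrt((wp$x[i] - wp$x[i - 1])^2 + (wp$y[i] - wp$y[i - 1])^2)
      n <- max(2L, ceiling(d / speed_cm_s * rate_hz))
      frac <- seq(0, 1, length.out = n)[-1]
      xs <- c(xs, wp$x[i - 1] + frac * (wp$x[i] - wp$x[i - 1]))
      ys <- c(ys, wp$y[i - 1] + frac * (wp$y[i] - wp$y[i - 1]))
      ts <- c(ts, t + frac * d / speed_cm_s)
      t <- t + d / speed_cm_s
    } else {
      xs <- wp$x[1]; ys <- wp$y[1]; ts <- 0
    }
    dw <- dwell_s[i]
    if (dw > 0) {
      n <- max(1L, round(dw * rate_hz))
      xs <- c(xs, rep(wp$x[i], n)); ys <- c(ys, rep(wp$y[i], n))
      ts <- c(ts, t + seq_len(n) / rate_hz)
      t <- t + n / rate_hz
    }
  }
  xs <- xs + stats::rnorm(length(xs), 0, jitter_cm)
  ys <- ys + stats::rnorm(length(ys), 0, jitter_cm)
  list(t = ts, x = xs, y = ys)
}

#' Simulate a Barnes-maze trajectory following a named search strategy
#'
#' Builds a path satisfying the defining rule of the requested strategy:
#' `spatial` heads straight to a hole within 2 holes of the exit and stays
#' in the exit quadrant; `serial` progresses hole-by-hole through at least
#' six consecutive holes into the exit; `random` crosses the open field
#' repeatedly before exiting. Optionally scripts abortive exit visits (the
#' animal reaches the exit hole but stays on the maze) before the terminal
#' exit.
#'
#' @param strategy `"spatial"`, `"serial"` or `"random"`.
#' @param geometry a [barnes_geometry()].
#' @param seed integer seed; identical seeds give identical paths.
#' @param abortive_exit_visits number of scripted exit visits before the
#'   terminal one.
#' @param rate_hz,speed_cm_s,jitter_cm tracking rate, locomotion speed and
#'   positional jitter.
#' @return A [maze_trajectory()].
#' @export
simulate_maze_path <- function(strategy, geometry, seed = 1L,
                               abortive_exit_visits = 0L,
                               rate_hz = 10, speed_cm_s = 25,
                               jitter_cm = 0.3) {
  abort_if(!strategy %in% c("spatial", "serial", "random"),
           paste0("unknown strategy label: ", strategy))
  g <- geometry
  abort_if(g$kind != "barnes", "simulate_maze_path needs a Barnes geometry")
  abort_if(g$n_holes < 3, "geometry needs >= 3 holes")
  hole <- function(i) {
    i <- ((i - 1) %% g$n_holes) + 1
    c(g$hole_x[i], g$hole_y[i])
  }
  ex <- g$exit_index
  with_local_seed(seed, {
    wps <- list(c(0, 0)); dwell <- 0.2
    add <- function(p, dw = 0.3) {
      wps[[length(wps) + 1]] <<- p
      dwell <<- c(dwell, dw)
    }
    sgn <- if (stats::runif(1) < 0.5) 1 else -1
    if (strategy == "spatial") {
      add(hole(ex + sgn))        # first hole: adjacent to the exit
      bounce <- hole(ex - 2 * sgn)
    } else if (strategy == "serial") {
      start_off <- sample(5:7, 1)
      for (k in rev(seq_len(start_off))) add(hole(ex - sgn * k), 0.2)
      bounce <- hole(ex + 3)
    } else {
      offs <- c(7, -5, 4)
      for (o in offs) add(hole(ex + o), 0.2)
      bounce <- hole(ex + 3)
    }
    if (abortive_exit_visits > 0) {
      for (k in seq_len(abortive_exit_visits)) {
        add(hole(ex), 0.3)
        add(bounce, 0.2)
      }
    }
    add(hole(ex), 1)
    wp <- as.data.frame(do.call(rbind, wps))
    names(wp) <- c("x", "y")
    path <- interp_waypoints(wp, speed_cm_s, rate_hz, dwell, jitter_cm)
    maze_trajectory(path$t, path$x, path$y, g)
  })
}

#' Simulate a Y-maze trajectory visiting a scripted arm sequence
#'
#' @param geometry a [ymaze_geometry()].
#' @param arms character vector of arm labels to visit, in order.
#' @param seed integer seed.
#' @param depth_cm how far into each arm the path penetrates.
#' @param dwell_s dwell at each arm tip, seconds.
#' @inheritParams simulate_maze_path
#' @return A [maze_trajectory()].
#' @export
simulate_ymaze_path <- function(geometry, arms, seed = 1L, depth_cm = 30,
                                dwell_s = 1, rate_hz = 10, speed_cm_s = 25,
                                jitter_cm = 0.3) {
  g <- geometry
  abort_if(g$kind != "ymaze", "needs a Y-maze geometry")
  abort_if(!all(arms %in% g$labels), "unknown arm label in `arms`")
  with_local_seed(seed, {
    wps <- list(c(0, 0)); dwell <- 0.3
    for (a in arms) {
      k <- match(a, g$labels)
      wps[[length(wps) + 1]] <- depth_cm * c(cos(g$arm_angle[k]),
                                             sin(g$arm_angle[k]))
      dwell <- c(dwell, dwell_s)
      wps[[length(wps) + 1]] <- c(0, 0)
      dwell <- c(dwell, 0.2)
    }
    wp <- as.data.frame(do.call(rbind, wps))
    names(wp) <- c("x", "y")
    path <- interp_waypoints(wp, speed_cm_s, rate_hz, dwell, jitter_cm)
    maze_trajectory(path$t, path$x, path$y, g)
  })
}
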