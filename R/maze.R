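#' Maze geometries
#'
#' `barnes_geometry()` describes the circular Barnes maze (default 122 cm
#' diameter, 20 equally spaced perimeter holes of 9 cm diameter, one exit
#' hole). `ymaze_geometry()` describes a three-arm Y maze (default arms
#' 50 x 10 cm at 120 degrees, labelled entry/open/novel).
#'
#' @param diameter_cm maze diameter.
#' @param n_holes number of perimeter holes (>= 3).
#' @param hole_radius_cm hole radius.
#' @param exit_index 1-based index of the escape hole.
#' @param hole_ring_fraction radial position of hole centres as a fraction
#'   of the maze radius.
#' @return A list of class `maze_geometry` (`kind` `"barnes"` or `"ymaze"`).
#' @export
barnes_geometry <- function(diameter_cm = 122, n_holes = 20,
                            hole_radius_cm = 4.5, exit_index = 1,
                            hole_ring_fraction = 0.9) {
  abort_if(n_holes < 3, "Barnes geometry needs >= 3 holes")
  abort_if(exit_index < 1 || exit_index > n_holes, "exit_index out of range")
  r <- diameter_cm / 2
  ang <- 2 * pi * (seq_len(n_holes) - 1) / n_holes
  structure(list(
    kind = "barnes", radius_cm = r, n_holes = n_holes,
    hole_radius_cm = hole_radius_cm, exit_index = exit_index,
    hole_x = r * hole_ring_fraction * cos(ang),
    hole_y = r * hole_ring_fraction * sin(ang),
    hole_angle = ang
  ), class = "maze_geometry")
}

#' @rdname barnes_geometry
#' @param arm_length_cm,arm_width_cm arm dimensions.
#' @param labels arm labels, length 3 (conventionally entry, open, novel).
#' @export
ymaze_geometry <- function(arm_length_cm = 50, arm_width_cm = 10,
                           labels = c("entry", "open", "novel")) {
  abort_if(length(labels) != 3, "a Y maze has exactly 3 arms")
  ang <- c(pi / 2, pi / 2 + 2 * pi / 3, pi / 2 + 4 * pi / 3)
  structure(list(
    kind = "ymaze", arm_length_cm = arm_length_cm,
    arm_width_cm = arm_width_cm, labels = labels, arm_angle = ang
  ), class = "maze_geometry")
}

#' Build a maze trajectory tibble
#'
#' @param times_s strictly increasing sample times.
#' @param x_cm,y_cm tracked position.
#' @param geometry a [barnes_geometry()] or [ymaze_geometry()].
#' @return A tibble of class `maze_trajectory`.
#' @export
maze_trajectory <- function(times_s, x_cm, y_cm, geometry) {
  abort_if(any(diff(times_s) <= 0), "times must be strictly increasing")
  out <- tibble::tibble(time_s = times_s, x_cm = x_cm, y_cm = y_cm)
  attr(out, "geometry") <- geometry
  class(out) <- c("maze_trajectory", class(out))
  out
}

traj_geometry <- function(traj, geometry = NULL) {
  g <- geometry %||% attr(traj, "geometry")
  abort_if(is.null(g), "trajectory carries no geometry")
  g
}

#' Detect hole visits on a Barnes-maze trajectory
#'
#' A visit is the entry of the tracked point into a hole's radius after
#' being outside it (consecutive samples in the same hole count once).
#'
#' @param traj a [maze_trajectory()].
#' @param geometry optional override geometry.
#' @return A tibble `time_s`, `hole` (1-based index).
#' @export
detect_hole_visits <- function(traj, geometry = NULL) {
  g <- traj_geometry(traj, geometry)
  abort_if(g$kind != "barnes", "hole visits require a Barnes geometry")
  d2 <- outer(traj$x_cm, g$hole_x, "-")^2 + outer(traj$y_cm, g$hole_y, "-")^2
  nearest <- max.col(-d2)
  inside <- d2[cbind(seq_len(nrow(traj)), nearest)] <= g$hole_radius_cm^2
  cur <- ifelse(inside, nearest, NA_integer_)
  new_visit <- inside & (seq_along(cur) == 1 |
    is.na(dplyr::lag(cur)) | dplyr::lag(cur) != cur)
  new_visit[is.na(new_visit)] <- FALSE
  tibble::tibble(time_s = traj$time_s[new_visit], hole = cur[new_visit])
}

#' Count exit errors
#'
#' Exit errors are visits to the exit hole after which the animal remained
#' on the maze: every exit-hole visit strictly before the terminal exit. The
#' final visit counts as the terminal exit when it is to the exit hole and
#' falls within 2 s of the trial end; otherwise the trial did not end at the
#' exit and every exit visit is an error.
#'
#' @param visits a [detect_hole_visits()] tibble.
#' @param exit_index exit hole index.
#' @param trial_end_time trial end, seconds.
#' @return Integer error count.
#' @export
count_exit_errors <- function(visits, exit_index, trial_end_time) {
  n_exit <- sum(visits$hole == exit_index)
  if (n_exit == 0) return(0L)
  terminal <- nrow(visits) > 0 &&
    visits$hole[nrow(visits)] == exit_index &&
    visits$time_s[nrow(visits)] >= trial_end_time - 2
  as.integer(n_exit - as.integer(terminal))
}

# maximal runs of the trajectory inside the central disc, with entry/exit
# angular separation; runs touching the trajectory start are ignored (the
# animal starts at the centre).
open_field_crossings <- function(traj, g, core_fraction = 0.5) {
  r <- sqrt(traj$x_cm^2 + traj$y_cm^2)
  inside <- r < core_fraction * g$radius_cm
  rr <- rle(inside)
  ends <- cumsum(rr$lengths); starts <- ends - rr$lengths + 1L
  n_cross <- 0L
  for (j in which(rr$values)) {
    if (starts[j] == 1L) next
    a_in <- atan2(traj$y_cm[starts[j] - 1L], traj$x_cm[starts[j] - 1L])
    k <- min(ends[j] + 1L, nrow(traj))
    a_out <- atan2(traj$y_cm[k], traj$x_cm[k])
    dphi <- abs(atan2(sin(a_out - a_in), cos(a_out - a_in)))
    if (dphi > pi / 2) n_cross <- n_cross + 1L
  }
  n_cross
}

#' Classify the Barnes-maze search strategy
#'
#' Rules, in order of precedence:
#' * `spatial` — the first hole visited lies within 2 holes of the exit
#'   (inclusive, modulo the ring) and the whole path stays inside the exit
#'   quadrant (90 degree sector centred on the exit hole; points within a
#'   quarter radius of the centre are exempt, since trials start there);
#' * `serial` — some run of >= 3 consecutive hole visits progresses
#'   hole-by-hole (steps of +1, or of -1, around the ring);
#' * `random` — the path crosses the open field (inner half-radius disc,
#'   leaving at > 90 degrees from where it entered) at least twice.
#'
#' Trajectories matching none of the rules fall back to `random`; the
#' returned label then carries attribute `fallback = TRUE`.
#'
#' @param traj a [maze_trajectory()].
#' @param visits optional precomputed [detect_hole_visits()].
#' @param geometry optional override geometry.
#' @return `"spatial"`, `"serial"` or `"random"` (attribute `fallback`).
#' @export
classify_search_strategy <- function(traj, visits = NULL, geometry = NULL) {
  g <- traj_geometry(traj, geometry)
  if (is.null(visits)) visits <- detect_hole_visits(traj, g)
  n <- g$n_holes
  ring_dist <- function(a, b) pmin((a - b) %% n, (b - a) %% n)

  if (nrow(visits) > 0 &&
      ring_dist(visits$hole[1], g$exit_index) <= 2) {
    exit_ang <- g$hole_angle[g$exit_index]
    r <- sqrt(traj$x_cm^2 + traj$y_cm^2)
    ang <- atan2(traj$y_cm, traj$x_cm)
    dphi <- abs(atan2(sin(ang - exit_ang), cos(ang - exit_ang)))
    in_quadrant <- dphi <= pi / 4 | r < 0.25 * g$radius_cm
    if (all(in_quadrant)) {
      return(structure("spatial", fallback = FALSE))
    }
  }
  if (nrow(visits) >= 3) {
    d <- diff(visits$hole) %% n
    step_run <- function(v) {
      rr <- rle(v)
      any(rr$values & rr$lengths >= 2)
    }
    if (step_run(d == 1) || step_run(d == n - 1)) {
      return(structure("serial", fallback = FALSE))
    }
  }
  if (open_field_crossings(traj, g) >= 2) {
    return(structure("random", fallback = FALSE))
  }
  structure("random", fallback = TRUE)
}

#' Detect arm entries on a Y-maze trajectory
#'
#' The two-paw entry rule is approximated by penetration depth with
#' hysteresis: an entry is recorded when the tracked point penetrates at
#' least `d_entry_cm` along an arm's axis, and no re-entry counts until the
#' point has retreated below `d_exit_cm`.
#'
#' @param traj a [maze_trajectory()] over a [ymaze_geometry()].
#' @param geometry optional override geometry.
#' @param d_entry_cm,d_exit_cm entry/exit penetration thresholds.
#' @return A tibble `time_s`, `arm` (label).
#' @export
detect_arm_entries <- function(traj, geometry = NULL, d_entry_cm = 10,
                               d_exit_cm = 5) {
  g <- traj_geometry(traj, geometry)
  abort_if(g$kind != "ymaze", "arm entries require a Y-maze geometry")
  pen <- ymaze_penetration(traj, g)
  in_arm <- pen$arm
  depth <- pen$depth
  times <- character(0); arms <- character(0); ts <- numeric(0)
  state <- NA_character_
  for (i in seq_len(nrow(traj))) {
    if (is.na(state)) {
      if (!is.na(in_arm[i]) && depth[i] >= d_entry_cm) {
        state <- in_arm[i]
        ts <- c(ts, traj$time_s[i]); arms <- c(arms, state)
      }
    } else if (is.na(in_arm[i]) || in_arm[i] != state ||
               depth[i] < d_exit_cm) {
      state <- NA_character_
      # allow an immediate entry into a different arm on the same sample
      if (!is.na(in_arm[i]) && depth[i] >= d_entry_cm) {
        state <- in_arm[i]
        ts <- c(ts, traj$time_s[i]); arms <- c(arms, state)
      }
    }
  }
  tibble::tibble(time_s = ts, arm = arms)
}

# per-sample arm membership and penetration depth along the arm axis
ymaze_penetration <- function(traj, g) {
  n <- nrow(traj)
  arm <- rep(NA_character_, n)
  depth <- rep(NA_real_, n)
  for (k in 1:3) {
    ux <- cos(g$arm_angle[k]); uy <- sin(g$arm_angle[k])
    proj <- traj$x_cm * ux + traj$y_cm * uy
    perp <- abs(-traj$x_cm * uy + traj$y_cm * ux)
    ok <- proj > 0 & proj <= g$arm_length_cm & perp <= g$arm_width_cm / 2
    better <- ok & (is.na(depth) | proj > depth)
    arm[better] <- g$labels[k]
    depth[better] <- proj[better]
  }
  list(arm = arm, depth = depth)
}

#' Y-maze novelty metrics
#'
#' Per-arm entries, dwell time and path distance, with the novel-arm
#' preference (novel vs previously open arm, percent) and the discrimination
#' ratio (novel over all three arms) for each metric. Metrics with a zero
#' total are reported as `NA` (undefined), not 0.
#'
#' @param traj a trial-2 [maze_trajectory()] (all arms open).
#' @param entries optional precomputed [detect_arm_entries()].
#' @param geometry optional override geometry.
#' @return A list: `per_arm` (tibble arm/entries/time_s/distance_cm),
#'   `preference_pct` and `discrimination_ratio` (named vectors over
#'   entries/time/distance).
#' @export
novelty_metrics <- function(traj, entries = NULL, geometry = NULL) {
  g <- traj_geometry(traj, geometry)
  if (is.null(entries)) entries <- detect_arm_entries(traj, g)
  pen <- ymaze_penetration(traj, g)
  n <- nrow(traj)
  dt <- c(diff(traj$time_s), 0)
  seg <- c(sqrt(diff(traj$x_cm)^2 + diff(traj$y_cm)^2), 0)
  per_arm <- purrr::map_dfr(g$labels, function(a) {
    idx <- !is.na(pen$arm) & pen$arm == a
    tibble::tibble(
      arm = a,
      entries = sum(entries$arm == a),
      time_s = sum(dt[idx]),
      distance_cm = sum(seg[idx])
    )
  })
  met <- function(v) {
    novel <- v[per_arm$arm == "novel"]
    open <- v[per_arm$arm == "open"]
    entry <- v[per_arm$arm == "entry"]
    c(preference = if (novel + open > 0) 100 * novel / (novel + open)
        else NA_real_,
      discrimination = if (novel + open + entry > 0)
        novel / (novel + open + entry) else NA_real_)
  }
  m_e <- met(per_arm$entries); m_t <- met(per_arm$time_s)
  m_d <- met(per_arm$distance_cm)
  list(
    per_arm = per_arm,
    preference_pct = c(entries = m_e[["preference"]],
                       time = m_t[["preference"]],
                       distance = m_d[["preference"]]),
    discrimination_ratio = c(entries = m_e[["discrimination"]],
                             time = m_t[["discrimination"]],
                             distance = m_d[["discrimination"]])
  )
}

#' Occupancy heat map
#'
#' Dwell time on a square grid; each sample contributes the interval to the
#' next sample, so cell values sum exactly to the trial duration whatever
#' the grid size.
#'
#' @param traj a [maze_trajectory()].
#' @param grid_cm cell edge length, cm.
#' @return A tibble `x_cm`, `y_cm` (cell centres), `dwell_s`.
#' @export
occupancy_heatmap <- function(traj, grid_cm = 5) {
  dt <- c(diff(traj$time_s), 0)
  gx <- floor(traj$x_cm / grid_cm)
  gy <- floor(traj$y_cm / grid_cm)
  out <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(gx = gx, gy = gy, dt = dt),
                    .data$gx, .data$gy),
    dwell_s = sum(.data$dt), .groups = "drop")
  tibble::tibble(
    x_cm = (out$gx + 0.5) * grid_cm,
    y_cm = (out$gy + 0.5) * grid_cm,
    dwell_s = out$dwell_s
  )
}
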