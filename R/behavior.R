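# Position-derived kinematics, maze linearization and accuracy summaries.

#' Default T-maze path polyline
#'
#' One circuit of the maze used for linearization: delay box at the stem
#' base, a 74 cm stem, a 63.5 cm choice arm, and the return arm back to
#' the delay box. Left/right circuits are folded onto one canonical loop
#' by taking |x| before projection, so alternating arms share bins.
#'
#' @return matrix with columns `x_cm`, `y_cm`.
#' @export
default_maze_path <- function() {
  cbind(x_cm = c(0, 0, 63.5, 63.5, 0),
        y_cm = c(0, 74, 74, 0, 0))
}

#' Running speed from a position trace
#'
#' Distance travelled between consecutive samples divided by the elapsed
#' time, assigned to the interval midpoint.
#'
#' @param positions data.frame with `t_s`, `x_cm`, `y_cm`.
#' @param smooth_n optional odd window length for a running-mean smooth
#'   (0 = none).
#' @return data.frame with `t_s` (midpoints) and `speed_cm_s`.
#' @export
running_speed <- function(positions, smooth_n = 0) {
  p <- positions
  if (nrow(p) < 2) stop("validation error: need at least 2 position samples", call. = FALSE)
  dt <- diff(p$t_s)
  if (any(dt <= 0)) stop("validation error: duplicate or decreasing timestamps", call. = FALSE)
  d <- sqrt(diff(p$x_cm)^2 + diff(p$y_cm)^2)
  sp <- d / dt
  if (smooth_n > 1) {
    k <- rep(1 / smooth_n, smooth_n)
    sp <- as.numeric(stats::filter(sp, k, sides = 2))
    sp[is.na(sp)] <- 0
  }
  data.frame(t_s = p$t_s[-nrow(p)] + dt / 2, speed_cm_s = sp)
}

# Project points onto a polyline; returns arc-length position and
# distance to the nearest path point.
project_to_path <- function(x, y, path) {
  seg_dx <- diff(path[, 1]); seg_dy <- diff(path[, 2])
  seg_len <- sqrt(seg_dx^2 + seg_dy^2)
  seg_start_arc <- c(0, cumsum(seg_len))[seq_along(seg_len)]
  n <- length(x)
  best_arc <- best_d <- rep(Inf, n)
  for (s in seq_along(seg_len)) {
    px <- path[s, 1]; py <- path[s, 2]
    t <- ((x - px) * seg_dx[s] + (y - py) * seg_dy[s]) / seg_len[s]^2
    t <- pmin(1, pmax(0, t))
    qx <- px + t * seg_dx[s]; qy <- py + t * seg_dy[s]
    d <- sqrt((x - qx)^2 + (y - qy)^2)
    upd <- d < best_d
    best_d[upd] <- d[upd]
    best_arc[upd] <- seg_start_arc[s] + t[upd] * seg_len[s]
  }
  list(arc = best_arc, dist = best_d, total = sum(seg_len))
}

#' Linearize positions onto the maze path and bin into 35 bins
#'
#' Each sample is projected to the nearest point of the path polyline
#' (left/right arms folded via |x|); the path's arc length is split into
#' 35 equal bins. Because the circuit is closed, the bin grid is
#' circular and centered on the path start, so the delay box occupies
#' bin 1 rather than splitting between the first and last bin. Samples
#' farther from the path than `tolerance_cm` are excluded and counted.
#'
#' @param positions data.frame with `t_s`, `x_cm`, `y_cm`.
#' @param path path polyline (default [default_maze_path()]).
#' @param n_bins number of equal arc-length bins (35).
#' @param tolerance_cm max allowed distance from the path.
#' @return list with `samples` (data.frame: t_s, bin, arc_cm, dist_cm,
#'   kept), `bin_speed` (data.frame: bin, mean_speed_cm_s, n), and
#'   `n_excluded`.
#' @export
linearize_and_bin <- function(positions, path = default_maze_path(),
                              n_bins = 35, tolerance_cm = 15) {
  pr <- project_to_path(abs(positions$x_cm), positions$y_cm, path)
  kept <- pr$dist <= tolerance_cm
  w <- pr$total / n_bins
  bin <- (floor(((pr$arc + w / 2) %% pr$total) / w) %% n_bins) + 1L
  sp <- running_speed(positions)
  # pair each speed interval with the bin of its left sample
  sp_bin <- bin[-length(bin)]
  sp_keep <- kept[-length(kept)]
  agg <- tapply(sp$speed_cm_s[sp_keep], factor(sp_bin[sp_keep], levels = seq_len(n_bins)), mean)
  cnt <- tapply(rep(1, sum(sp_keep)), factor(sp_bin[sp_keep], levels = seq_len(n_bins)), sum)
  list(
    samples = data.frame(t_s = positions$t_s, bin = bin, arc_cm = pr$arc,
                         dist_cm = pr$dist, kept = kept),
    bin_speed = data.frame(bin = seq_len(n_bins),
                           mean_speed_cm_s = as.numeric(agg),
                           n = ifelse(is.na(cnt), 0, as.numeric(cnt))),
    n_excluded = sum(!kept)
  )
}

#' Proportion correct by delay category (and group, if present)
#'
#' @param trials a trial table from [build_trial_table()], optionally
#'   with a `group` column when pooling sessions across groups.
#' @return data.frame with one row per (group x) delay_category:
#'   `p_correct` and `n_trials`. Empty input returns an empty frame with
#'   a warning.
#' @export
accuracy_by_delay <- function(trials) {
  if (nrow(trials) == 0) {
    warning("empty trial table")
    return(data.frame(group = character(), delay_category = character(),
                      p_correct = numeric(), n_trials = integer()))
  }
  grp <- if ("group" %in% names(trials)) trials$group else "all"
  key <- interaction(grp, trials$delay_category, drop = TRUE, lex.order = TRUE)
  rows <- lapply(levels(key), function(k) {
    sel <- key == k
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    data.frame(group = parts[1], delay_category = parts[2],
               p_correct = mean(trials$outcome[sel] == "correct"),
               n_trials = sum(sel), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
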