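#' Time-averaged mean squared displacement
#'
#' MSD at frame lag L is the mean of squared displacements over every ordered
#' pair of observations separated by exactly L frames. Gap frames simply
#' contribute no pair at the lags they interrupt.
#'
#' @param trk a [track()].
#' @param max_lag largest lag in frames (must be below the track's frame span).
#' @return Data frame with columns `lag` (frames), `lag_s` (seconds),
#'   `msd` (um^2) and `n_pairs`.
#' @export
msd <- function(trk, max_lag = 10) {
  span <- trk$frame[nrow(trk)] - trk$frame[1]
  check_scalar(max_lag, "max_lag", min = 1, max = span, integer = TRUE)
  xy <- track_positions(trk)
  dt <- attr(trk, "frame_interval")
  out <- lapply(seq_len(max_lag), function(L) {
    j <- match(trk$frame + L, trk$frame)
    i <- which(!is.na(j))
    if (!length(i))
      return(data.frame(lag = L, lag_s = L * dt, msd = NA_real_, n_pairs = 0L))
    d <- xy[j[i], , drop = FALSE] - xy[i, , drop = FALSE]
    data.frame(lag = L, lag_s = L * dt, msd = mean(rowSums(d^2)),
               n_pairs = length(i))
  })
  do.call(rbind, out)
}

#' Classify a track as confined, linear, or unclassified
#'
#' The MSD exponent alpha is the slope of log MSD versus log lag over lags
#' 1..min(10, floor(N/3)). Confined motion plateaus (alpha < `alpha_confined`),
#' directed motion is super-diffusive (alpha > `alpha_linear`); pure diffusion
#' (alpha near 1) stays unclassified. Tracks shorter than `min_points` are
#' unclassified; a zero-variance (stationary) track is confined by convention
#' with exponent 0.
#'
#' @param trk a [track()].
#' @param alpha_confined,alpha_linear exponent thresholds,
#'   0 < alpha_confined < alpha_linear.
#' @param min_points minimum track length for classification.
#' @return List with `class` (`"confined"`, `"linear"` or `"unclassified"`)
#'   and `msd_exponent`.
#' @export
classify_track <- function(trk, alpha_confined = 0.7, alpha_linear = 1.3,
                           min_points = 20) {
  if (!(alpha_confined > 0 && alpha_confined < alpha_linear))
    stop("need 0 < alpha_confined < alpha_linear", call. = FALSE)
  n <- nrow(trk)
  if (n < min_points)
    return(list(class = "unclassified", msd_exponent = NA_real_))
  xy <- track_positions(trk)
  if (all(apply(xy, 2, stats::var) == 0))
    return(list(class = "confined", msd_exponent = 0))
  max_lag <- min(10, floor(n / 3))
  m <- msd(trk, max_lag)
  m <- m[is.finite(m$msd) & m$msd > 0, ]
  if (nrow(m) < 2)
    return(list(class = "confined", msd_exponent = 0))
  alpha <- unname(stats::coef(stats::lm(log(msd) ~ log(lag_s), data = m))[2])
  cls <- if (alpha < alpha_confined) "confined"
         else if (alpha > alpha_linear) "linear"
         else "unclassified"
  list(class = cls, msd_exponent = alpha)
}

#' Confinement area of a track
#'
#' Area (um^2) of the minimal enclosing circle of the track's positions —
#' the circle drawn around a confined vesicle's excursion. A 2-sigma
#' principal-axis ellipse is available as an alternative summary.
#'
#' @param trk a [track()].
#' @param method `"mec"` (default) or `"sd_ellipse"` (area
#'   `pi * (2 sd1) * (2 sd2)` from the principal-component standard
#'   deviations).
#' @return Area in um^2 (0 for a stationary track).
#' @export
confinement_area <- function(trk, method = c("mec", "sd_ellipse")) {
  method <- match.arg(method)
  xy <- track_positions(trk)
  if (method == "mec")
    return(min_enclosing_circle(xy)$area)
  s <- sqrt(pmax(eigen(stats::cov(xy), symmetric = TRUE)$values, 0))
  pi * (2 * s[1]) * (2 * s[2])
}

#' Mean speed of a track
#'
#' Mean over consecutive observed pairs of Euclidean displacement divided by
#' elapsed time; a gap contributes one sample over its actual elapsed time.
#'
#' @param trk a [track()].
#' @return Speed in um/s.
#' @export
mean_speed <- function(trk) {
  mean(step_lengths(track_positions(trk)) / track_dts(trk))
}

## Per-step instantaneous speeds (um/s) and the pause indicator.
step_speeds <- function(trk) {
  step_lengths(track_positions(trk)) / track_dts(trk)
}

#' Detect pauses in a track
#'
#' A pause is a maximal run of one or more consecutive steps whose
#' instantaneous speed (step displacement / elapsed time) is strictly below
#' the threshold. The pause rate divides the number of pause onsets by the
#' full track duration.
#'
#' @param trk a [track()].
#' @param pause_speed_threshold um/s; a step at exactly the threshold is
#'   not paused.
#' @return List with `segments` (data frame of `start_step`, `end_step`,
#'   1-based step indices), `n_pauses`, `pause_rate` (onsets per second) and
#'   the logical per-step vector `paused`.
#' @export
detect_pauses <- function(trk, pause_speed_threshold = 0.1) {
  check_scalar(pause_speed_threshold, "pause_speed_threshold",
               min = 0, strict_min = TRUE)
  paused <- step_speeds(trk) < pause_speed_threshold
  r <- rle(paused)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- data.frame(start_step = starts[r$values], end_step = ends[r$values])
  list(segments = seg, n_pauses = nrow(seg),
       pause_rate = nrow(seg) / track_duration(trk), paused = paused)
}

#' Direction changes along the principal axis
#'
#' Finds the first principal axis of the position cloud (all positions,
#' including paused ones), projects each consecutive displacement onto it,
#' drops displacements belonging to paused steps and exactly-zero
#' projections, and counts sign changes between successive retained
#' projections. The count is symmetric under the principal axis' sign
#' ambiguity.
#'
#' @param trk a [track()] with at least 3 points.
#' @param pause_speed_threshold um/s, as in [detect_pauses()].
#' @return List with `n_changes` and `rate` (changes per second of track
#'   duration); both `NA` when every step is paused or projections vanish.
#' @export
direction_changes <- function(trk, pause_speed_threshold = 0.1) {
  if (nrow(trk) < 3)
    stop("direction changes need at least 3 points", call. = FALSE)
  xy <- track_positions(trk)
  axis <- stats::prcomp(xy, center = TRUE)$rotation[, 1]
  proj <- diff(xy) %*% axis
  keep <- !detect_pauses(trk, pause_speed_threshold)$paused & proj[, 1] != 0
  s <- sign(proj[keep, 1])
  if (length(s) < 2)
    return(list(n_changes = NA_integer_, rate = NA_real_))
  n_changes <- sum(diff(s) != 0)
  list(n_changes = n_changes, rate = n_changes / track_duration(trk))
}

#' Per-track motion report
#'
#' Runs the full motion workup on each track: classification, confinement
#' area (confined tracks), mean speed, pause rate, and direction-change rate
#' (linear tracks).
#'
#' @param tracks list of [track()] objects.
#' @param alpha_confined,alpha_linear,min_points see [classify_track()].
#' @param pause_speed_threshold see [detect_pauses()].
#' @return Data frame with one row per track: `track_id`, `class`,
#'   `msd_exponent`, `confinement_area`, `mean_speed`, `pause_rate`,
#'   `direction_changes_per_s`, `duration`, `total_path_length`. Fields not
#'   applicable to a track's class are `NA`.
#' @export
motion_report <- function(tracks, alpha_confined = 0.7, alpha_linear = 1.3,
                          min_points = 20, pause_speed_threshold = 0.1) {
  rows <- lapply(tracks, function(trk) {
    cls <- classify_track(trk, alpha_confined, alpha_linear, min_points)
    area <- if (cls$class == "confined") confinement_area(trk) else NA_real_
    dc <- if (cls$class == "linear" && nrow(trk) >= 3)
      direction_changes(trk, pause_speed_threshold)$rate else NA_real_
    data.frame(track_id = attr(trk, "track_id"),
               class = cls$class,
               msd_exponent = cls$msd_exponent,
               confinement_area = area,
               mean_speed = mean_speed(trk),
               pause_rate = detect_pauses(trk, pause_speed_threshold)$pause_rate,
               direction_changes_per_s = dc,
               duration = track_duration(trk),
               total_path_length = sum(step_lengths(track_positions(trk))))
  })
  do.call(rbind, rows)
}

#' Compare a motion metric between two groups
#'
#' Two-sided Wilcoxon rank-sum test on a per-track metric, chosen because
#' track parameters are typically far from normal. Also reports group means,
#' standard errors, and the fold change (b over a).
#'
#' @param reports_a,reports_b [motion_report()] data frames (or any data
#'   frames holding the metric column).
#' @param metric column name to compare.
#' @return List with `statistic`, `p_value`, `mean_a`, `mean_b`, `se_a`,
#'   `se_b`, `fold_change`, `n_a`, `n_b`.
#' @export
compare_groups <- function(reports_a, reports_b, metric) {
  for (nm in c("a", "b")) {
    rep <- if (nm == "a") reports_a else reports_b
    if (!metric %in% names(rep))
      stop(sprintf("metric '%s' absent in group %s", metric, nm),
           call. = FALSE)
  }
  a <- reports_a[[metric]][is.finite(reports_a[[metric]])]
  b <- reports_b[[metric]][is.finite(reports_b[[metric]])]
  if (!length(a) || !length(b))
    stop(sprintf("metric '%s' has no finite values in one group", metric),
         call. = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       mean_a = mean(a), mean_b = mean(b),
       se_a = stats::sd(a) / sqrt(length(a)),
       se_b = stats::sd(b) / sqrt(length(b)),
       fold_change = mean(b) / mean(a),
       n_a = length(a), n_b = length(b))
}
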