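# Time-lapse trace analysis: segment single-cell PIP-FUCCI intensity traces
# into G1 / S / G2 within one cytokinesis-to-mitosis span, then summarize
# phase durations, intermitotic intervals and per-phase migration.
#
# The mVenus-Cdt1(1-17) signal is the clock: it degrades sharply at the G1/S
# transition and re-expresses at S/G2. Detection runs on the per-span
# min-max-normalized, 3-frame-median-smoothed venus trace with two
# thresholds (hysteresis): the trace must first exceed theta_on, the first
# later drop below theta_off marks G1/S, and the first subsequent re-crossing
# of theta_on marks S/G2. G2 ends at the closing mitosis. mCherry-Gem(1-110)
# should be high during the detected S interval; if it never crosses its
# threshold there, the segmentation is flagged low-confidence (the mCherry
# signal can lag S entry as it accumulates).

#' Construct a single-cell track
#'
#' @param track_id integer identifier.
#' @param t_hr frame timestamps in hours, strictly increasing with a constant
#'   step (10-minute frames by default).
#' @param venus,cherry reporter intensity series.
#' @param x,y position series (pixels); optional.
#' @param mitosis_frames 1-based frame indices of observed mitoses.
#' @return list of class `cell_track`.
#' @export
cell_track <- function(track_id, t_hr, venus, cherry, x = NULL, y = NULL,
                       mitosis_frames = integer()) {
  n <- length(t_hr)
  stopifnot(length(venus) == n, length(cherry) == n,
            is.null(x) || length(x) == n, is.null(y) || length(y) == n)
  if (n >= 2) {
    dt <- diff(t_hr)
    if (any(dt <= 0) || diff(range(dt)) > 1e-8) {
      stop("timestamps must be strictly increasing with a constant step",
           call. = FALSE)
    }
  }
  structure(list(track_id = as.integer(track_id), t_hr = as.numeric(t_hr),
                 venus = as.numeric(venus), cherry = as.numeric(cherry),
                 x = x, y = y,
                 mitosis_frames = sort(as.integer(mitosis_frames))),
            class = "cell_track")
}

#' Read tracks from CSV
#'
#' Expected columns: `track_id, frame, t_hr, x, y, venus, cherry, is_mitosis`.
#'
#' @param path CSV path.
#' @return list of [cell_track()] objects.
#' @export
read_tracks <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  abort_missing_cols(df, c("track_id", "frame", "t_hr", "venus", "cherry",
                           "is_mitosis"), basename(path))
  lapply(split(df, df$track_id), function(sub) {
    sub <- sub[order(sub$frame), ]
    cell_track(sub$track_id[1], sub$t_hr, sub$venus, sub$cherry,
               x = sub$x, y = sub$y,
               mitosis_frames = which(as.logical(sub$is_mitosis)))
  })
}

#' Write tracks to CSV
#'
#' @param tracks list of [cell_track()] objects.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  df <- do.call(rbind, lapply(tracks, function(tr) {
    n <- length(tr$t_hr)
    data.frame(track_id = tr$track_id, frame = seq_len(n), t_hr = tr$t_hr,
               x = tr$x %||% rep(NA_real_, n), y = tr$y %||% rep(NA_real_, n),
               venus = tr$venus, cherry = tr$cherry,
               is_mitosis = seq_len(n) %in% tr$mitosis_frames)
  }))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Segment one mitosis-to-mitosis span into G1, S and G2
#'
#' @param track a [cell_track()].
#' @param span length-2 integer vector of frame indices of two consecutive
#'   mitoses (defaults to the track's first two recorded mitoses).
#' @param theta_off normalized-venus level below which degradation is called
#'   (G1/S), after the trace has exceeded `theta_on`.
#' @param theta_on normalized-venus level for "expressed"; its re-crossing
#'   after G1/S marks S/G2.
#' @param cherry_on absolute mCherry threshold for the confidence check; by
#'   default half of the span's cherry range above its minimum.
#' @return data.frame of class `phase_segments` with columns `phase`
#'   (`G1`, `S`, `G2`), `start_hr`, `end_hr`, `duration_hr`; attribute
#'   `low_confidence` (logical) marks spans where cherry never rose during
#'   the detected S interval.
#' @export
segment_track_phases <- function(track, span = NULL, theta_off = 0.2,
                                 theta_on = 0.5, cherry_on = NULL) {
  stopifnot(inherits(track, "cell_track"), theta_off < theta_on)
  if (is.null(span)) {
    if (length(track$mitosis_frames) < 2) {
      stop("track has fewer than 2 recorded mitoses and no explicit span",
           call. = FALSE)
    }
    span <- track$mitosis_frames[1:2]
  }
  i1 <- span[1]; i2 <- span[2]
  stopifnot(i1 < i2, i2 <= length(track$t_hr))
  idx <- i1:i2
  v <- track$venus[idx]
  rng <- range(v)
  if (diff(rng) <= 0) stop("flat venus trace: span is unsegmentable", call. = FALSE)
  vn <- (v - rng[1]) / diff(rng)
  if (length(vn) >= 3) vn <- stats::runmed(vn, 3, endrule = "median")

  rise <- which(vn >= theta_on)
  if (!length(rise)) stop("venus never expressed: span is unsegmentable", call. = FALSE)
  drop <- which(vn < theta_off & seq_along(vn) > rise[1])
  if (!length(drop)) {
    stop("no venus degradation found: span is unsegmentable", call. = FALSE)
  }
  g1s <- drop[1]
  rerise <- which(vn >= theta_on & seq_along(vn) > g1s)
  if (!length(rerise)) {
    stop("no venus re-expression found: span is unsegmentable", call. = FALSE)
  }
  sg2 <- rerise[1]

  t_span <- track$t_hr[idx]
  seg <- data.frame(
    phase = c("G1", "S", "G2"),
    start_hr = c(t_span[1], t_span[g1s], t_span[sg2]),
    end_hr = c(t_span[g1s], t_span[sg2], t_span[length(t_span)]),
    stringsAsFactors = FALSE
  )
  seg$duration_hr <- seg$end_hr - seg$start_hr
  if (any(seg$duration_hr <= 0)) {
    stop("degenerate segmentation (non-positive phase duration)", call. = FALSE)
  }

  ch <- track$cherry[idx]
  if (is.null(cherry_on)) cherry_on <- min(ch) + 0.5 * diff(range(ch))
  s_frames <- g1s:sg2
  low_conf <- !any(ch[s_frames] >= cherry_on)

  structure(seg, class = c("phase_segments", "data.frame"),
            span_frames = c(i1, i2),
            boundary_frames = c(g1s = i1 + g1s - 1L, sg2 = i1 + sg2 - 1L),
            low_confidence = low_conf)
}

#' Mean phase durations across cells
#'
#' @param segments list of `phase_segments` (one per cell-cycle span).
#' @return list with `per_phase` (named mean hours for G1, S, G2), `total_hr`
#'   (sum of the three means), `g2_s_ratio` (ratio of the G2 and S mean
#'   durations, reported to 1 decimal) and `n` (spans per phase).
#' @export
summarize_durations <- function(segments) {
  if (!length(segments)) stop("no segmentations supplied", call. = FALSE)
  all_seg <- do.call(rbind, lapply(segments, as.data.frame))
  per_phase <- tapply(all_seg$duration_hr,
                      factor(all_seg$phase, levels = c("G1", "S", "G2")), mean)
  total <- sum(per_phase)
  list(per_phase = per_phase, total_hr = total,
       g2_s_ratio = round_half_away(per_phase[["G2"]] / per_phase[["S"]], 1),
       n = tapply(all_seg$duration_hr,
                  factor(all_seg$phase, levels = c("G1", "S", "G2")), length))
}

#' Intermitotic intervals of one track
#'
#' Total cell-cycle length measured directly as the time between consecutive
#' recorded mitoses.
#'
#' @param track a [cell_track()], or a numeric vector of mitosis times in
#'   hours.
#' @return numeric vector of intervals (hours), one per consecutive mitosis
#'   pair.
#' @export
intermitotic_interval <- function(track) {
  times <- if (inherits(track, "cell_track")) {
    track$t_hr[track$mitosis_frames]
  } else {
    as.numeric(track)
  }
  if (length(times) < 2) stop("need >= 2 mitosis events", call. = FALSE)
  diff(sort(times))
}

#' Per-phase migration metrics
#'
#' Velocity is the mean frame-to-frame displacement divided by the frame
#' interval within each phase. The normalized distance is the path length a
#' cell accumulates per time window equal to the cohort's mean G2 duration,
#' i.e. `path_length / phase_duration * g2_window_hr`, which puts the three
#' phases (of very different lengths) on a common time base.
#'
#' @param track a [cell_track()] with positions.
#' @param segments `phase_segments` for the span to analyze.
#' @param g2_window_hr cohort mean G2 duration (hours) used as the
#'   normalization window; defaults to this track's G2 duration.
#' @return data.frame per phase: `velocity_px_hr`, `path_px`,
#'   `dist_per_g2win_px`, `n_frames`, `flag` (set when a phase spans < 2
#'   frames).
#' @export
migration_metrics <- function(track, segments, g2_window_hr = NULL) {
  if (is.null(track$x) || is.null(track$y)) {
    stop("track has no positions", call. = FALSE)
  }
  if (is.null(g2_window_hr)) {
    g2_window_hr <- segments$duration_hr[segments$phase == "G2"]
  }
  dt <- diff(track$t_hr[1:2])
  out <- do.call(rbind, lapply(seq_len(nrow(segments)), function(i) {
    inside <- track$t_hr >= segments$start_hr[i] &
      track$t_hr <= segments$end_hr[i]
    xs <- track$x[inside]; ys <- track$y[inside]
    if (sum(inside) < 2) {
      return(data.frame(phase = segments$phase[i], velocity_px_hr = NA_real_,
                        path_px = NA_real_, dist_per_g2win_px = NA_real_,
                        n_frames = sum(inside), flag = "too_few_frames",
                        stringsAsFactors = FALSE))
    }
    steps <- sqrt(diff(xs)^2 + diff(ys)^2)
    path <- sum(steps)
    dur <- segments$duration_hr[i]
    data.frame(phase = segments$phase[i],
               velocity_px_hr = mean(steps) / dt,
               path_px = path,
               dist_per_g2win_px = path / dur * g2_window_hr,
               n_frames = sum(inside), flag = "",
               stringsAsFactors = FALSE)
  }))
  out
}
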