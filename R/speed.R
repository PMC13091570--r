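#' Validate a sprint position trace
#'
#' A trace is a tibble/data.frame with columns `t_s` (strictly increasing,
#' uniformly sampled time stamps, s) and `x_m`, `y_m` (planar pelvis
#' position, m), with at least 3 samples.
#'
#' @param trace A data frame to check.
#' @param tol Allowed deviation from uniform sampling, s.
#' @return The trace, invisibly; errors describe the first violation.
#' @export
validate_trace <- function(trace, tol = 1e-6) {
  missing <- setdiff(c("t_s", "x_m", "y_m"), names(trace))
  if (length(missing) > 0) {
    abort(paste0("trace is missing columns: ", paste(missing, collapse = ", ")))
  }
  if (nrow(trace) < 3) {
    abort("trace must have at least 3 samples")
  }
  dt <- diff(trace$t_s)
  if (any(dt <= 0)) {
    abort(sprintf("trace time stamps must be strictly increasing (first violation at sample %d)",
                  which(dt <= 0)[1] + 1L))
  }
  off <- which(abs(dt - dt[1]) > tol)
  if (length(off) > 0) {
    abort(sprintf("trace must be uniformly sampled within %g s (first violation at sample %d)",
                  tol, off[1] + 1L))
  }
  if (anyNA(trace[c("t_s", "x_m", "y_m")])) {
    abort("trace contains missing values")
  }
  invisible(trace)
}

trace_sample_rate <- function(trace) {
  1 / (trace$t_s[2] - trace$t_s[1])
}

#' Distance travelled from the sprint start
#'
#' Planar Euclidean displacement of the pelvis from its position at the first
#' sample. For a straight sprint this coincides with path length; unlike path
#' length it is not inflated without bound by positional noise.
#'
#' @param trace A validated sprint trace (see [validate_trace()]).
#' @return Numeric vector of distances, m; first element 0.
#' @examples
#' tr <- tibble::tibble(t_s = seq(0, 2, 0.01), x_m = 5 * t_s, y_m = 0)
#' tail(distance_from_start(tr), 1) # 10 m after 2 s at 5 m/s
#' @export
distance_from_start <- function(trace) {
  validate_trace(trace)
  sqrt((trace$x_m - trace$x_m[1])^2 + (trace$y_m - trace$y_m[1])^2)
}

# Butterworth prototype poles (unit cutoff, left half-plane) for order n,
# returned as second-order (and possibly one first-order) sections after a
# bilinear transform with cutoff prewarping. Each section is
# list(b = c(b0, b1, b2), a = c(1, a1, a2)).
butter_sections <- function(order, cutoff_hz, sample_rate) {
  if (!is_count(order)) abort("filter `order` must be a positive integer")
  if (cutoff_hz <= 0 || cutoff_hz >= sample_rate / 2) {
    abort("`cutoff_hz` must lie in (0, sample_rate / 2)")
  }
  w <- tan(pi * cutoff_hz / sample_rate) # prewarped normalized cutoff
  sections <- list()
  n_pairs <- order %/% 2
  for (k in seq_len(n_pairs)) {
    re_p <- Re(exp(1i * pi * (2 * k + order - 1) / (2 * order)))
    d0 <- 1 - 2 * re_p * w + w^2
    sections[[k]] <- list(
      b = c(w^2, 2 * w^2, w^2) / d0,
      a = c(1, (2 * w^2 - 2) / d0, (1 + 2 * re_p * w + w^2) / d0)
    )
  }
  if (order %% 2 == 1) { # real pole at s = -1
    sections[[n_pairs + 1]] <- list(
      b = c(w, w, 0) / (1 + w),
      a = c(1, (w - 1) / (1 + w), 0)
    )
  }
  sections
}

# single-pass IIR biquad cascade, states initialized at DC steady state for
# the first sample (direct form II transposed); exact for constant input
apply_sections <- function(x, sections) {
  for (sec in sections) {
    b <- sec$b; a <- sec$a
    y <- numeric(length(x))
    x0 <- x[1]
    s1 <- (b[2] + b[3]) * x0 - (a[2] + a[3]) * x0
    s2 <- b[3] * x0 - a[3] * x0
    for (n in seq_along(x)) {
      y[n] <- b[1] * x[n] + s1
      s1 <- b[2] * x[n] + s2 - a[2] * y[n]
      s2 <- b[3] * x[n] - a[3] * y[n]
    }
    x <- y
  }
  x
}

#' Zero-phase Butterworth low-pass filter
#'
#' Filters a series forward and backward (zero phase, so the timing of the
#' speed peak is not lagged) with a Butterworth low-pass of order `order / 2`
#' per pass, giving the stated effective order. Defaults give a 1 Hz cutoff
#' and effective 4th order. The combined amplitude response is the squared
#' single-pass magnitude, `1 / (1 + (f / cutoff)^order)` up to bilinear
#' warping. Edges are handled by odd-reflection padding of three filter
#' characteristic lengths (`3 * sample_rate / cutoff_hz` samples) so the
#' series must be longer than the pad.
#'
#' @param series Numeric vector to filter.
#' @param sample_rate Sampling rate, Hz (must exceed `2 * cutoff_hz`).
#' @param cutoff_hz Low-pass cutoff, Hz (default 1).
#' @param order Effective filter order after the two passes; must be even
#'   (default 4, i.e. order 2 per pass).
#' @return Filtered series, same length as the input.
#' @examples
#' lowpass_1hz(rep(10, 400), sample_rate = 100)[1:3] # DC gain is 1
#' @export
lowpass_1hz <- function(series, sample_rate, cutoff_hz = 1, order = 4) {
  assert_number(sample_rate, "sample_rate", 2 * cutoff_hz,
                strict_lower = TRUE)
  if (order %% 2 != 0) {
    abort("`order` is the effective order of the two passes and must be even")
  }
  sections <- butter_sections(order / 2, cutoff_hz, sample_rate)
  pad <- ceiling(3 * sample_rate / cutoff_hz)
  n <- length(series)
  if (n <= pad) {
    abort(sprintf(
      "series of length %d is too short for edge padding: at least %d samples (> 3 characteristic lengths of the %g Hz filter at %g Hz) are required",
      n, pad + 1L, cutoff_hz, sample_rate))
  }
  padded <- c(2 * series[1] - series[(pad + 1):2],
              series,
              2 * series[n] - series[(n - 1):(n - pad)])
  y <- apply_sections(padded, sections)
  y <- rev(apply_sections(rev(y), sections))
  y[(pad + 1):(pad + n)]
}

#' Differentiate a uniformly sampled series
#'
#' Central differences at interior samples (second-order accurate, exact for
#' quadratics) and one-sided first differences at the two endpoints (exact
#' for affine series).
#'
#' @param series Numeric vector, uniformly sampled.
#' @param sample_rate Sampling rate, Hz.
#' @return Derivative series, same length as the input.
#' @examples
#' differentiate(3 * seq(0, 1, 0.01), sample_rate = 100)[1:3] # constant 3
#' @export
differentiate <- function(series, sample_rate) {
  n <- length(series)
  if (n < 3) abort("differentiation requires at least 3 samples")
  assert_number(sample_rate, "sample_rate", 0, strict_lower = TRUE)
  d <- numeric(n)
  d[1] <- (series[2] - series[1]) * sample_rate
  d[n] <- (series[n] - series[n - 1]) * sample_rate
  d[2:(n - 1)] <- (series[3:n] - series[1:(n - 2)]) * sample_rate / 2
  d
}

#' Peak sprint speed for one athlete
#'
#' For each trial: distance from the start ([distance_from_start()]), 1 Hz
#' zero-phase Butterworth low-pass ([lowpass_1hz()]), numerical
#' differentiation ([differentiate()]); the trial's peak speed is the maximum
#' of the resulting speed series and its peak distance is the filtered
#' distance at that sample. The athlete's value is the arithmetic mean of
#' the trial peaks (the reference protocol used two trials; other counts are
#' averaged with a warning).
#'
#' @param trials A single trace or a list of traces (see [validate_trace()]).
#' @param cutoff_hz,order Filter settings passed to [lowpass_1hz()].
#' @return A tibble of class `sv_speed_result` with one row per trial
#'   (`trial`, `peak_speed_mps`, `peak_distance_m`) and attribute
#'   `athlete_peak_speed` (also via [glance()]).
#' @examples
#' trials <- generate_sprint_trace(trace_spec(7.4, noise_sd = 0), seed = 1)
#' glance(peak_speed(trials))
#' @export
peak_speed <- function(trials, cutoff_hz = 1, order = 4) {
  if (is.data.frame(trials)) trials <- list(trials)
  if (!is.list(trials) || length(trials) < 1) {
    abort("`trials` must be one trace or a non-empty list of traces")
  }
  if (length(trials) != 2) {
    warn(sprintf("averaging peak speed over %d trial(s); the reference protocol used 2",
                 length(trials)))
  }
  rows <- purrr::imap(trials, function(trace, i) {
    res <- tryCatch({
      validate_trace(trace)
      fs <- trace_sample_rate(trace)
      d <- distance_from_start(trace)
      f <- lowpass_1hz(d, fs, cutoff_hz = cutoff_hz, order = order)
      v <- differentiate(f, fs)
      k <- which.max(v)
      tibble::tibble(trial = as.integer(i), peak_speed_mps = v[k],
                     peak_distance_m = f[k])
    }, error = function(e) {
      abort(sprintf("trial %s failed speed extraction: %s", i,
                    conditionMessage(e)))
    })
    res
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "athlete_peak_speed") <- mean(out$peak_speed_mps)
  class(out) <- c("sv_speed_result", class(out))
  out
}

#' @export
glance.sv_speed_result <- function(x, ...) {
  tibble::tibble(
    n_trials = nrow(x),
    athlete_peak_speed = attr(x, "athlete_peak_speed"),
    max_trial_peak = max(x$peak_speed_mps),
    min_trial_peak = min(x$peak_speed_mps)
  )
}

#' @export
tidy.sv_speed_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "sv_speed_result")
  attr(out, "athlete_peak_speed") <- NULL
  out
}

#' Per-athlete speed table from trace files
#'
#' Maps [peak_speed()] over a named list of athletes' trials and returns one
#' row per athlete.
#'
#' @param trials_by_athlete Named list: for each athlete id, a list of trace
#'   tibbles.
#' @param cutoff_hz,order Filter settings passed to [lowpass_1hz()].
#' @return A tibble with columns `athlete_id`, `speed_mps` (mean of trial
#'   peaks), `n_trials`, and per-trial peaks/distances in list columns
#'   `trial_peaks`, `trial_distances`.
#' @export
speed_table <- function(trials_by_athlete, cutoff_hz = 1, order = 4) {
  if (is.null(names(trials_by_athlete))) {
    abort("`trials_by_athlete` must be a named list (names = athlete ids)")
  }
  purrr::imap(trials_by_athlete, function(trials, id) {
    res <- withCallingHandlers(
      peak_speed(trials, cutoff_hz = cutoff_hz, order = order),
      warning = function(w) invokeRestart("muffleWarning"))
    tibble::tibble(
      athlete_id = id,
      speed_mps = attr(res, "athlete_peak_speed"),
      n_trials = nrow(res),
      trial_peaks = list(res$peak_speed_mps),
      trial_distances = list(res$peak_distance_m)
    )
  }) |>
    dplyr::bind_rows()
}
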