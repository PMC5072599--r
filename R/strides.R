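#' Stride events detected from vertical ground reaction force
#'
#' Footstrikes are upward crossings of a force threshold, toe-offs downward
#' crossings. Crossings are debounced: after a footstrike, a toe-off is
#' accepted only after `min_stance` seconds, and vice versa, so force-plate
#' chatter near the threshold does not create spurious strides.
#'
#' @param grf_vertical a [sampled_signal()] (N) or numeric vector with
#'   `sample_rate`; must be non-negative.
#' @param threshold force threshold in N (default 20).
#' @param min_stance debounce interval in seconds (default 0.1).
#' @param sample_rate required for numeric input.
#' @return object of class `stride_events`: list with `footstrike_times` and
#'   `toeoff_times` (seconds, strictly increasing, alternating).
#' @export
detect_strides <- function(grf_vertical, threshold = 20, min_stance = 0.1,
                           sample_rate = NULL) {
  if (inherits(grf_vertical, "sampled_signal")) {
    v <- grf_vertical$values; fs <- grf_vertical$sample_rate
    t0 <- grf_vertical$t0
  } else {
    if (is.null(sample_rate)) stop("`sample_rate` is required", call. = FALSE)
    v <- as.numeric(grf_vertical); fs <- sample_rate; t0 <- 0
  }
  if (any(v < 0)) stop("vertical GRF must be non-negative", call. = FALSE)
  above <- v >= threshold
  d <- diff(above)
  up <- which(d == 1) + 1L   # first sample at/above threshold
  down <- which(d == -1) + 1L  # first sample below threshold
  if (!length(up) && !length(down))
    stop("no-stride error: GRF never crosses the ", threshold, " N threshold",
         call. = FALSE)
  ev <- rbind(
    if (length(up)) data.frame(i = up, type = "fs") else NULL,
    if (length(down)) data.frame(i = down, type = "to") else NULL
  )
  ev <- ev[order(ev$i), ]
  # debounced state machine; first accepted event sets the state
  fs_i <- integer(0); to_i <- integer(0)
  last_i <- -Inf; last_type <- NA_character_
  min_gap <- min_stance * fs
  for (r in seq_len(nrow(ev))) {
    type <- ev$type[r]; i <- ev$i[r]
    if (identical(type, last_type)) next
    if (i - last_i < min_gap && !is.na(last_type)) next
    if (type == "fs") fs_i <- c(fs_i, i) else to_i <- c(to_i, i)
    last_i <- i; last_type <- type
  }
  if (!length(fs_i))
    stop("no-stride error: no footstrike detected", call. = FALSE)
  structure(list(footstrike_times = t0 + (fs_i - 1) / fs,
                 toeoff_times = t0 + (to_i - 1) / fs),
            class = "stride_events")
}

#' @export
print.stride_events <- function(x, ...) {
  cat(sprintf("<stride_events> %d footstrikes, %d toe-offs (%d complete strides)\n",
              length(x$footstrike_times), length(x$toeoff_times),
              n_complete_strides(x)))
  invisible(x)
}

#' Number of complete footstrike-to-footstrike strides
#' @param events a `stride_events` object.
#' @return integer count.
#' @export
n_complete_strides <- function(events) {
  max(length(events$footstrike_times) - 1L, 0L)
}

#' Mean stride duration
#' @param events a `stride_events` object.
#' @return seconds.
#' @export
stride_duration <- function(events) {
  if (n_complete_strides(events) < 1L)
    stop("no complete stride in events", call. = FALSE)
  mean(diff(events$footstrike_times))
}

#' Mean toe-off timing as a fraction of the stride
#'
#' For each complete stride, the toe-off falling inside it is located and
#' expressed as a fraction of that stride's duration; fractions are averaged.
#'
#' @param events a `stride_events` object.
#' @return fraction in (0, 1).
#' @export
toeoff_fraction <- function(events) {
  fs <- events$footstrike_times
  n <- n_complete_strides(events)
  if (n < 1L) stop("no complete stride in events", call. = FALSE)
  fr <- vapply(seq_len(n), function(k) {
    to <- events$toeoff_times
    to <- to[to > fs[k] & to < fs[k + 1]]
    if (!length(to)) return(NA_real_)
    (to[1] - fs[k]) / (fs[k + 1] - fs[k])
  }, numeric(1))
  fr <- fr[!is.na(fr)]
  if (!length(fr)) stop("no toe-off found within any stride", call. = FALSE)
  mean(fr)
}

#' Divide a signal into strides and average on a common grid
#'
#' Each complete stride (footstrike to ipsilateral footstrike) is resampled by
#' linear interpolation onto `grid_points` samples spanning 0--100% of the
#' stride, then the strides are averaged pointwise. The pointwise standard
#' deviation across strides is retained.
#'
#' @param x a [sampled_signal()] or numeric vector (`sample_rate` required).
#' @param events a `stride_events` object from [detect_strides()].
#' @param grid_points stride grid resolution (default 1000).
#' @param sample_rate required for numeric input.
#' @return a [stride_waveform()].
#' @export
stride_average <- function(x, events, grid_points = 1000L, sample_rate = NULL) {
  if (inherits(x, "sampled_signal")) {
    v <- x$values; fs <- x$sample_rate; t0 <- x$t0; units <- x$units
  } else {
    if (is.null(sample_rate)) stop("`sample_rate` is required", call. = FALSE)
    v <- as.numeric(x); fs <- sample_rate; t0 <- 0; units <- ""
  }
  nst <- n_complete_strides(events)
  if (nst < 1L) stop("need at least one complete stride", call. = FALSE)
  tt <- t0 + (seq_along(v) - 1) / fs
  sg <- (seq_len(grid_points) - 1) / grid_points
  fsx <- events$footstrike_times
  mat <- matrix(NA_real_, nst, grid_points)
  for (k in seq_len(nst)) {
    a <- fsx[k]; b <- fsx[k + 1]
    if ((b - a) * fs < 2)
      stop("resampling error: stride ", k, " spans fewer than 2 samples",
           call. = FALSE)
    mat[k, ] <- stats::approx(tt, v, xout = a + sg * (b - a), rule = 2)$y
  }
  m <- colMeans(mat)
  s <- if (nst > 1L) apply(mat, 2, stats::sd) else numeric(grid_points)
  stride_waveform(m, units = units, sd = s, n_strides = nst)
}
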