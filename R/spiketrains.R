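#' Construct a spike train
#'
#' A spike train is the independent variable of every model in this package:
#' an ordered set of presynaptic stimulation times, mathematically a sum of
#' Dirac delta functions \eqn{S(t) = \sum_j \delta(t - t_j)}.
#'
#' @param times Numeric vector of spike times in seconds, strictly
#'   increasing, all non-negative.
#' @param duration Total duration in seconds; must be at least the last
#'   spike time. Defaults to the last spike time (or 0 for an empty train).
#' @param label Free-text label.
#' @return An object of class `spike_train` with elements `times`,
#'   `duration` and `label`.
#' @examples
#' spike_train(c(0, 0.01, 0.02))
#' @export
spike_train <- function(times, duration = NULL, label = "") {
  times <- as.numeric(times)
  if (anyNA(times)) stop("spike times must not contain NA")
  if (length(times) > 0) {
    if (any(times < 0)) stop("spike times must be non-negative")
    if (any(diff(times) <= 0)) stop("spike times must be strictly increasing")
  }
  if (is.null(duration)) duration <- if (length(times)) max(times) else 0
  if (duration < (if (length(times)) max(times) else 0))
    stop("duration must be >= the last spike time")
  structure(list(times = times, duration = as.numeric(duration),
                 label = as.character(label)),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes over %.4g s%s\n", length(x$times),
              x$duration,
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

#' @export
length.spike_train <- function(x) length(x$times)

#' Regular stimulation train
#'
#' `n_pulses` spikes at a fixed frequency, the standard protocol for probing
#' short-term facilitation and depression (e.g. 5 spikes at 50 Hz).
#'
#' @param frequency Stimulation frequency in Hz (> 0).
#' @param n_pulses Number of pulses (>= 1).
#' @param t0 Time of the first pulse in seconds.
#' @param label Free-text label.
#' @return A [spike_train()].
#' @export
regular_train <- function(frequency, n_pulses, t0 = 0, label = "") {
  if (!is.finite(frequency) || frequency <= 0) stop("frequency must be > 0")
  if (n_pulses < 1 || n_pulses != round(n_pulses)) stop("n_pulses must be a positive integer")
  spike_train(t0 + (seq_len(n_pulses) - 1) / frequency, label = label)
}

#' Protocol specification
#'
#' An ordered list of (pulse count, frequency) segments describing a compound
#' stimulation protocol such as "5x100 Hz + 1x20 Hz" (a high-frequency burst
#' followed by a recovery pulse).
#'
#' @param segments A list of length-2 numeric vectors `c(pulse_count, frequency_hz)`.
#' @param label Free-text label.
#' @return An object of class `protocol_spec`.
#' @examples
#' protocol_spec(list(c(5, 100), c(1, 20)), label = "5x100Hz+1x20Hz")
#' @export
protocol_spec <- function(segments, label = "") {
  if (!is.list(segments) || length(segments) == 0)
    stop("segments must be a non-empty list of c(pulse_count, frequency) pairs")
  segments <- lapply(segments, function(s) {
    s <- as.numeric(s)
    if (length(s) != 2) stop("each segment must be c(pulse_count, frequency)")
    if (s[1] < 1 || s[1] != round(s[1])) stop("pulse_count must be a positive integer")
    if (!is.finite(s[2]) || s[2] <= 0) stop("frequency must be > 0")
    s
  })
  structure(list(segments = segments, label = as.character(label)),
            class = "protocol_spec")
}

#' Compound stimulation train from a protocol spec
#'
#' Concatenates the segments of a [protocol_spec()]: the first spike of
#' segment k+1 follows the last spike of segment k by the inter-spike
#' interval of segment k+1 (the recovery-pulse convention).
#'
#' @param spec A [protocol_spec()].
#' @param t0 Time of the first pulse in seconds.
#' @return A [spike_train()].
#' @examples
#' compound_train(protocol_spec(list(c(5, 100), c(1, 20))))$times
#' @export
compound_train <- function(spec, t0 = 0) {
  if (!inherits(spec, "protocol_spec")) spec <- protocol_spec(spec)
  times <- numeric(0)
  t <- t0
  first <- TRUE
  for (s in spec$segments) {
    n <- s[1]; isi <- 1 / s[2]
    start <- if (first) t else t + isi
    seg <- start + (seq_len(n) - 1) * isi
    times <- c(times, seg)
    t <- seg[n]
    first <- FALSE
  }
  spike_train(times, label = spec$label)
}

#' Poisson stimulation train
#'
#' A homogeneous Poisson spike train: cumulative sums of exponentially
#' distributed inter-spike intervals with mean `1/rate`. Used as a
#' naturalistic stimulation pattern for parameter inference.
#'
#' @param rate Mean firing rate in Hz (> 0).
#' @param n_spikes Number of spikes (>= 1).
#' @param seed Optional integer seed; fixing it makes the train reproducible.
#' @param t0 Time of the first possible interval start (seconds).
#' @param label Free-text label.
#' @return A [spike_train()].
#' @export
poisson_train <- function(rate, n_spikes, seed = NULL, t0 = 0, label = "poisson") {
  if (!is.finite(rate) || rate <= 0) stop("rate must be > 0")
  if (n_spikes < 1 || n_spikes != round(n_spikes)) stop("n_spikes must be a positive integer")
  isi <- with_seed_if(seed, stats::rexp(n_spikes, rate = rate))
  spike_train(t0 + cumsum(isi), label = label)
}

#' Burst followed by a delayed test spike
#'
#' The protocol used to probe post-burst (delayed) facilitation: a burst of
#' `burst_n` spikes at `burst_freq`, followed by a single test spike placed
#' `delay` seconds after the last burst spike.
#'
#' @param burst_n Number of spikes in the burst (>= 1).
#' @param burst_freq Burst frequency in Hz (> 0).
#' @param delay Delay from last burst spike to the test spike in seconds (> 0).
#' @return A [spike_train()] with `burst_n + 1` spikes.
#' @export
burst_plus_test <- function(burst_n, burst_freq, delay) {
  if (!is.finite(delay) || delay <= 0) stop("delay must be > 0")
  burst <- regular_train(burst_freq, burst_n)
  spike_train(c(burst$times, max(burst$times) + delay),
              label = sprintf("%dx%gHz+test", burst_n, burst_freq))
}

#' Read and write spike-time files
#'
#' Plain-text format: one spike time (seconds) per line; lines beginning
#' with `#` are treated as comments.
#'
#' @param path File path.
#' @param train A [spike_train()] (for writing).
#' @return `read_spike_times` returns a [spike_train()];
#'   `write_spike_times` returns `path` invisibly.
#' @export
read_spike_times <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  spike_train(as.numeric(lines), label = basename(path))
}

#' @rdname read_spike_times
#' @export
write_spike_times <- function(train, path) {
  writeLines(format(train$times, digits = 17, scientific = FALSE, trim = TRUE), path)
  invisible(path)
}

#' Standard validation protocol set
#'
#' The regular and compound stimulation protocols used for model validation:
#' 10x100 Hz, 10x20 Hz, 5x100 Hz + 1x20 Hz, 5x20 Hz + 1x100 Hz and
#' 5x100 Hz + 1x10 Hz. Optionally appends a seeded Poisson train as a
#' synthetic stand-in for a naturalistic (in-vivo-like) stimulation pattern.
#'
#' @param include_poisson Append the synthetic Poisson stand-in?
#' @param poisson_rate,poisson_n,poisson_seed Parameters of the stand-in.
#' @return Named list of [spike_train()] objects.
#' @export
validation_protocols <- function(include_poisson = TRUE, poisson_rate = 10,
                                 poisson_n = 12, poisson_seed = 1L) {
  p <- list(
    "10x100Hz"        = regular_train(100, 10, label = "10x100Hz"),
    "10x20Hz"         = regular_train(20, 10, label = "10x20Hz"),
    "5x100Hz+1x20Hz"  = compound_train(protocol_spec(list(c(5, 100), c(1, 20)),
                                                     label = "5x100Hz+1x20Hz")),
    "5x20Hz+1x100Hz"  = compound_train(protocol_spec(list(c(5, 20), c(1, 100)),
                                                     label = "5x20Hz+1x100Hz")),
    "5x100Hz+1x10Hz"  = compound_train(protocol_spec(list(c(5, 100), c(1, 10)),
                                                     label = "5x100Hz+1x10Hz"))
  )
  if (include_poisson) {
    p[["poisson-synthetic"]] <- poisson_train(poisson_rate, poisson_n,
                                              seed = poisson_seed,
                                              label = "poisson-synthetic")
  }
  p
}

# Run expr under a temporary RNG state seeded with `seed` (if non-NULL),
# restoring the caller's RNG afterwards.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
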