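#' Read and write amplitude tables
#'
#' Columnar delimited text with a header row naming pulse positions
#' (`pulse1`, `pulse2`, ...): rows are trials, columns stimulus positions.
#' Missing values are written as `NA`.
#'
#' @param amplitudes A trials x pulses numeric matrix.
#' @param path File path (`.csv`, comma-separated).
#' @return `read_amplitude_table` returns a numeric matrix;
#'   `write_amplitude_table` returns `path` invisibly.
#' @export
write_amplitude_table <- function(amplitudes, path) {
  amplitudes <- as.matrix(amplitudes)
  colnames(amplitudes) <- paste0("pulse", seq_len(ncol(amplitudes)))
  utils::write.csv(amplitudes, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_amplitude_table
#' @export
read_amplitude_table <- function(path) {
  as.matrix(utils::read.csv(path, check.names = FALSE))
}

#' Write and read a full amplitude dataset as a directory of files
#'
#' One `<label>_amplitudes.csv` and one `<label>_spikes.txt` per protocol.
#'
#' @param data An [amplitude_data()].
#' @param dir Directory (created if needed).
#' @return `read_amplitude_dir` returns an [amplitude_data()];
#'   `write_amplitude_dir` returns `dir` invisibly.
#' @export
write_amplitude_dir <- function(data, dir) {
  stopifnot(inherits(data, "amplitude_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(data$protocols)) {
    safe <- gsub("[^A-Za-z0-9_.+-]", "_", nm)
    write_amplitude_table(data$protocols[[nm]]$amplitudes,
                          file.path(dir, paste0(safe, "_amplitudes.csv")))
    write_spike_times(data$protocols[[nm]]$train,
                      file.path(dir, paste0(safe, "_spikes.txt")))
  }
  invisible(dir)
}

#' @rdname write_amplitude_dir
#' @export
read_amplitude_dir <- function(dir) {
  amp_files <- list.files(dir, pattern = "_amplitudes\\.csv$", full.names = TRUE)
  if (length(amp_files) == 0) stop("no *_amplitudes.csv files in ", dir)
  protocols <- list()
  for (f in amp_files) {
    label <- sub("_amplitudes\\.csv$", "", basename(f))
    sf <- file.path(dir, paste0(label, "_spikes.txt"))
    if (!file.exists(sf)) stop("missing spike file for protocol ", label)
    protocols[[label]] <- list(train = read_spike_times(sf),
                               amplitudes = read_amplitude_table(f))
  }
  amplitude_data(protocols)
}

# Parse a time value from config: plain numbers are seconds; strings may
# carry an explicit unit suffix ("ms" or "s"), e.g. "15 ms".
parse_time <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(as.character(x))
  if (grepl("ms$", x)) return(as.numeric(sub("ms$", "", x)) / 1000)
  if (grepl("s$", x)) return(as.numeric(sub("s$", "", x)))
  as.numeric(x)
}

#' Kernel serialization for run configs
#'
#' Converts between [kernel()] objects and the plain-list representation
#' used in YAML/JSON configs:
#' `list(bases = list(list(type = "exp", tau = 0.015), ...),
#' amplitudes = ..., baseline = ...)`. Time fields accept an explicit
#' `"ms"` suffix.
#'
#' @param x A plain list (from a parsed config).
#' @param k A [kernel()].
#' @return `kernel_from_config` returns a [kernel()];
#'   `kernel_to_config` returns a plain list.
#' @export
kernel_from_config <- function(x) {
  bases <- lapply(x$bases, function(b) {
    switch(b$type,
           exp = exp_basis(parse_time(b$tau)),
           gaussian = gaussian_basis(parse_time(b$mu), parse_time(b$sd)),
           stop("unknown basis type: ", b$type))
  })
  kernel(bases, as.numeric(unlist(x$amplitudes)),
         baseline = if (is.null(x$baseline)) 0 else as.numeric(x$baseline))
}

#' @rdname kernel_from_config
#' @export
kernel_to_config <- function(k) {
  list(bases = lapply(k$bases, function(b) {
    if (inherits(b, "exp_basis")) list(type = "exp", tau = b$tau)
    else list(type = "gaussian", mu = b$mu, sd = b$sd)
  }), amplitudes = k$amplitudes, baseline = k$baseline)
}

#' SRP parameter serialization for run configs
#'
#' @param x A plain list with `mu_kernel`, `sigma_kernel`, `sigma_scale`,
#'   `variance_mode`.
#' @param p An [srp_parameters()].
#' @return `srp_from_config` returns [srp_parameters()];
#'   `srp_to_config` a plain list. Round-trips exactly.
#' @export
srp_from_config <- function(x) {
  srp_parameters(
    mu_kernel = kernel_from_config(x$mu_kernel),
    sigma_kernel = if (!is.null(x$sigma_kernel)) kernel_from_config(x$sigma_kernel),
    sigma_scale = if (is.null(x$sigma_scale)) 1 else as.numeric(x$sigma_scale),
    variance_mode = if (is.null(x$variance_mode)) "kernel" else x$variance_mode)
}

#' @rdname srp_from_config
#' @export
srp_to_config <- function(p) {
  out <- list(mu_kernel = kernel_to_config(p$mu_kernel),
              sigma_scale = p$sigma_scale, variance_mode = p$variance_mode)
  if (!is.null(p$sigma_kernel)) out$sigma_kernel <- kernel_to_config(p$sigma_kernel)
  out
}

#' Read and write run configurations
#'
#' Configs are YAML (`.yml`/`.yaml`) or JSON (`.json`); parsing then
#' serializing then parsing yields an identical config.
#'
#' @param path File path.
#' @param config A plain list.
#' @return `read_run_config` returns the config list.
#' @export
read_run_config <- function(path) {
  if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  if (grepl("\\.json$", path))
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  else yaml::write_yaml(config, path)
  invisible(path)
}

# Build the named list of spike trains described by a config's data section.
# Each protocol entry has a `label` and either `segments` (compound train)
# or `poisson` (rate, n_spikes); Poisson sub-seeds derive from `seed`.
trains_from_config <- function(data_cfg, seed = 1L) {
  protos <- data_cfg$protocols
  if (is.null(protos) || length(protos) == 0)
    stop("config error: data.protocols is missing or empty")
  trains <- list()
  for (i in seq_along(protos)) {
    p <- protos[[i]]
    label <- if (!is.null(p$label)) p$label else paste0("protocol", i)
    if (!is.null(p$segments)) {
      segs <- lapply(p$segments, function(s) as.numeric(unlist(s)))
      trains[[label]] <- compound_train(protocol_spec(segs, label = label))
    } else if (!is.null(p$poisson)) {
      trains[[label]] <- poisson_train(as.numeric(p$poisson$rate),
                                       as.integer(p$poisson$n_spikes),
                                       seed = as.integer(seed) + 13L * i,
                                       label = label)
    } else if (!is.null(p$spike_file)) {
      trains[[label]] <- read_spike_times(p$spike_file)
    } else {
      stop(sprintf("config error: protocol '%s' needs 'segments', 'poisson' or 'spike_file'", label))
    }
  }
  trains
}
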