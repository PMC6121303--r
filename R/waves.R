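#' Pump-pool configurations
#'
#' Describes one pool of Na/K-ATPase as a plane wave: the caveolar
#' "signaling" pool (slow conformational cycling, complexed with
#' caveolin-1/Src) and the "pumping" pool (fast cycling, ion transport)
#' occupy disjoint spatial domains and oscillate at distinct frequencies.
#' Defaults: signaling 250 arb units of space at 150 Hz; pumping 500 arb
#' units at 500 Hz.
#'
#' @param name Pool name, `"signaling"` or `"pumping"` (free-form names are
#'   allowed for custom pools).
#' @param spatial_extent Width of the pool's spatial domain (arb units,
#'   > 0).
#' @param frequency Oscillation frequency in Hz (> 0).
#' @param amplitude Wave amplitude (arb units, >= 0).
#' @param phase Phase offset in radians.
#' @return One-row tibble; bind rows to form a multi-pool configuration.
#' @export
#' @examples
#' default_pools()
pool_config <- function(name, spatial_extent, frequency, amplitude = 1, phase = 0) {
  if (frequency <= 0 || spatial_extent <= 0 || amplitude < 0) {
    abort("need frequency > 0, spatial_extent > 0, amplitude >= 0",
          class = "pumploop_argument_error")
  }
  tibble(name = name, spatial_extent = spatial_extent, frequency = frequency,
         amplitude = amplitude, phase = phase)
}

#' @rdname pool_config
#' @export
default_pools <- function() {
  bind_rows(
    pool_config("signaling", spatial_extent = 250, frequency = 150),
    pool_config("pumping",   spatial_extent = 500, frequency = 500)
  )
}

#' Shift the E2:E1 balance with ouabain
#'
#' Ouabain (a cardiotonic steroid) stabilises the E2 conformation, removing
#' part of the E1-state Src-inhibiting contribution of the signaling pool.
#' In the wave picture this is an amplitude rescaling of the signaling pool
#' by `1 - shift_fraction`; the pumping pool is unchanged.
#'
#' @param pools Pool tibble as from [default_pools()].
#' @param shift_fraction Fraction of the E2:E1 balance shifted, in `[0, 1]`.
#' @return Modified pool tibble.
#' @export
#' @examples
#' apply_ouabain_shift(default_pools(), 0.05)
apply_ouabain_shift <- function(pools, shift_fraction) {
  if (!is.numeric(shift_fraction) || length(shift_fraction) != 1 ||
      is.na(shift_fraction) || shift_fraction < 0 || shift_fraction > 1) {
    abort("shift_fraction must be a single number in [0, 1]",
          class = "pumploop_argument_error")
  }
  pools %>%
    mutate(amplitude = ifelse(.data$name == "signaling",
                              .data$amplitude * (1 - shift_fraction),
                              .data$amplitude))
}

#' Build the superposed wave field
#'
#' Lays the pools' spatial domains end-to-end (in row order) and evaluates
#' each pool's complex plane wave `A exp(i(2 pi f t + phase))` on its own
#' domain; the field is zero elsewhere. The real part represents the
#' E1 <-> E2 transition coordinate and the imaginary part the
#' phosphorylation coordinate.
#'
#' @param pools Pool tibble.
#' @param duration Total sampled time in seconds (default 1).
#' @param sample_rate Temporal sampling rate in Hz (default 4096); must
#'   exceed twice the highest configured frequency (Nyquist).
#' @param dx Spatial grid resolution in arb units (default 1).
#' @return A `wave_field` list: `space`, `time`, complex matrix `values`
#'   (space x time), `pools`, `sample_rate`, and per-position pool
#'   membership `domain`.
#' @export
build_field <- function(pools, duration = 1, sample_rate = 4096, dx = 1) {
  fmax <- max(pools$frequency)
  if (sample_rate <= 2 * fmax) {
    abort(sprintf("sampling rate %g Hz violates Nyquist; need > %g Hz",
                  sample_rate, 2 * fmax),
          class = "pumploop_argument_error")
  }
  n_t <- round(duration * sample_rate)
  time <- seq(0, by = 1 / sample_rate, length.out = n_t)
  edges <- c(0, cumsum(pools$spatial_extent))
  space <- seq(dx / 2, max(edges) - dx / 2, by = dx)
  domain <- as.character(cut(space, breaks = edges, labels = pools$name))
  values <- matrix(0 + 0i, nrow = length(space), ncol = n_t)
  for (i in seq_len(nrow(pools))) {
    rows <- which(domain == pools$name[i])
    if (!length(rows)) next
    wave <- pools$amplitude[i] *
      exp(1i * (2 * pi * pools$frequency[i] * time + pools$phase[i]))
    values[rows, ] <- matrix(wave, nrow = length(rows), ncol = n_t, byrow = TRUE)
  }
  structure(
    list(space = space, time = time, values = values, pools = pools,
         sample_rate = sample_rate, domain = domain),
    class = "wave_field"
  )
}

#' @export
print.wave_field <- function(x, ...) {
  cat("<wave_field> ", length(x$space), " positions x ", length(x$time),
      " time samples @ ", x$sample_rate, " Hz\n", sep = "")
  print(x$pools)
  invisible(x)
}

#' Fourier power spectrum of a wave field
#'
#' Discrete Fourier transform of the field along time at every spatial
#' position, with the per-position periodograms `|F_k|^2 / N^2` averaged
#' over space. This aggregation preserves Parseval's identity: the summed
#' spectral power equals the spatially averaged time-domain mean-square
#' amplitude. No window is applied (rectangular). Frequencies span
#' `[0, sample_rate)` at resolution `sample_rate / N`; for the complex
#' (analytic) fields built here all signal power lies below Nyquist.
#'
#' @param field A [build_field()] result with a uniform time grid.
#' @return A `power_spectrum` tibble with columns `frequency` (Hz) and
#'   `power` (>= 0), and attributes `bin_width` and `n_time`.
#' @export
power_spectrum <- function(field) {
  dt <- diff(field$time)
  if (length(dt) < 1 || max(abs(dt - dt[1])) > 1e-12 * dt[1]) {
    abort("power spectrum requires a uniform time grid",
          class = "pumploop_argument_error")
  }
  n <- length(field$time)
  # columns = time series per position
  F <- mvfft(t(field$values))
  pow <- rowMeans(Mod(F)^2) / n^2
  df <- field$sample_rate / n
  new_tibble(
    list(frequency = (seq_len(n) - 1) * df, power = pow),
    nrow = n, class = "power_spectrum",
    bin_width = df, n_time = n
  )
}

#' Locate the dominant spectral peaks
#'
#' Finds local maxima of the power spectrum (bins strictly greater than
#' both neighbours and strictly positive) and returns the `n_peaks` tallest,
#' sorted by height descending, with frequency reported at bin centre.
#'
#' @param spectrum A [power_spectrum()] result.
#' @param n_peaks Number of peaks requested (default 2).
#' @return Tibble with columns `frequency`, `height`. If fewer local maxima
#'   exist than requested, the shorter list is returned with a warning.
#' @export
peak_locations <- function(spectrum, n_peaks = 2) {
  p <- spectrum$power
  n <- length(p)
  left <- c(-Inf, p[-n])
  right <- c(p[-1], -Inf)
  is_peak <- p > left & p > right & p > 0
  peaks <- tibble(frequency = spectrum$frequency[is_peak], height = p[is_peak]) %>%
    arrange(desc(.data$height)) %>%
    slice_head(n = n_peaks)
  if (nrow(peaks) < n_peaks) {
    warn(sprintf("only %d local maxima found (requested %d)", nrow(peaks), n_peaks))
  }
  peaks
}

#' @method tidy power_spectrum
#' @export
tidy.power_spectrum <- function(x, ...) as_tibble(x)

#' @method glance power_spectrum
#' @export
glance.power_spectrum <- function(x, ...) {
  pk <- suppressWarnings(peak_locations(x, n_peaks = 2))
  tibble(
    total_power = sum(x$power),
    bin_width = attr(x, "bin_width"),
    n_peaks_top2 = nrow(pk),
    peak1_frequency = if (nrow(pk) >= 1) pk$frequency[1] else NA_real_,
    peak2_frequency = if (nrow(pk) >= 2) pk$frequency[2] else NA_real_
  )
}

#' @method autoplot power_spectrum
#' @export
autoplot.power_spectrum <- function(object, fmax = NULL, ...) {
  d <- as_tibble(object)
  if (!is.null(fmax)) d <- filter(d, .data$frequency <= fmax)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$frequency, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)", y = "power (arb units)") +
    ggplot2::theme_minimal()
}

#' @method autoplot wave_field
#' @export
autoplot.wave_field <- function(object, ...) {
  d <- tibble(
    space = rep(object$space, times = length(object$time)),
    time = rep(object$time, each = length(object$space)),
    re = as.vector(Re(object$values))
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$space,
                                  fill = .data$re)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "time (s)", y = "position (arb units)",
                  fill = "Re(field)") +
    ggplot2::theme_minimal()
}

#' Write a power spectrum as two-column CSV
#'
#' Columns `frequency_Hz`, `power`, full double precision.
#'
#' @param spectrum A [power_spectrum()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  df <- data.frame(frequency_Hz = sprintf("%.17g", spectrum$frequency),
                   power = sprintf("%.17g", spectrum$power))
  write.csv(df, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}
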