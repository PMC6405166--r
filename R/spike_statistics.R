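## Smoothed spike-time densities and population statistics, all normalised
## to the Src (input) population so that different input spreads sigma_inp
## are comparable. Note the smoothed histograms are deliberately NOT
## normalised by sample count: d(t) is a smoothed count density, not a
## probability density, and only ratios against the Src density are
## interpreted.

#' Raised-cosine (Hanning) smoothing window
#'
#' Symmetric positive window of length `n` without zero endpoints,
#' `w_k = 0.5 (1 - cos(2 pi k / (n + 1)))`, `k = 1..n`.
#'
#' @param n Window length in bins (default 20, the analysis standard here).
#' @return Numeric vector of weights (not normalised to unit sum).
#' @export
hanning_window <- function(n = 20) {
  k <- seq_len(n)
  0.5 * (1 - cos(2 * pi * k / (n + 1)))
}

density_breaks <- function(all_times, bin_width, align, pad_bins = 200) {
  lo <- floor((min(all_times) - align) / bin_width) - pad_bins
  hi <- ceiling((max(all_times) - align) / bin_width) + pad_bins
  align + (lo:hi) * bin_width
}

#' Smoothed spike-time density
#'
#' Histograms spike times with a bin width of `sigma_inp / 10` (avoiding
#' under-sampling at small input spreads and over-sampling at large ones) and
#' convolves the counts with a Hanning window of size 20 (`"same"`-length
#' output). Bin edges are aligned to `align` (typically the mean Src spike
#' time) and the range is padded so the smoothing never truncates mass.
#'
#' @param spike_times Spike times (ms), pooled over neurons and trials.
#' @param sigma_inp Input-timing SD (ms); sets the bin width.
#' @param breaks Optional explicit bin edges (ms); computed when `NULL`.
#' @param align Edge alignment (ms) used when computing breaks.
#' @param window_size Hanning window length in bins.
#' @return List of class `spike_density`: `centers` (ms), `d` (smoothed
#'   counts), `counts`, `bin_width`, `breaks`.
#' @export
estimate_density <- function(spike_times, sigma_inp, breaks = NULL,
                             align = 0, window_size = 20) {
  stopifnot(sigma_inp > 0)
  bin_width <- sigma_inp / 10
  if (length(spike_times) == 0) {
    warning("empty spike set; returning zero density")
    if (is.null(breaks)) breaks <- align + (0:1) * bin_width
  } else if (is.null(breaks)) {
    breaks <- density_breaks(spike_times, bin_width, align)
  }
  counts <- if (length(spike_times) == 0) {
    rep(0, length(breaks) - 1)
  } else {
    graphics::hist(spike_times, breaks = breaks, plot = FALSE)$counts
  }
  w <- hanning_window(window_size)
  d <- convolve_same(counts, w)
  structure(list(centers = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 d = d, counts = counts, bin_width = bin_width,
                 breaks = breaks),
            class = "spike_density")
}

# linear convolution, central ("same") part, via FFT-free direct filter
convolve_same <- function(x, w) {
  nw <- length(w)
  full <- stats::convolve(x, rev(w), type = "open")
  start <- floor((nw - 1) / 2) + 1
  out <- full[start:(start + length(x) - 1)]
  # clip tiny negative ripple from floating point
  pmax(out, 0)
}

# first time the density reaches frac of its own maximum
density_onset <- function(dens, frac = 0.1) {
  m <- max(dens$d)
  if (m <= 0) return(NA_real_)
  dens$centers[which(dens$d >= frac * m)[1]]
}

#' Normalised spike-time distribution statistics of a population
#'
#' All statistics compare a population's pooled spike times against the Src
#' population's, per parameter set:
#' * `norm_mean`: mean spike time minus the Src mean (ms);
#' * `norm_sd`: SD of spike times over the Src SD;
#' * `norm_max_density`: max of the smoothed density over the Src max;
#' * `norm_total`: area under the smoothed density over the Src area
#'   (total response);
#' * `rel_latency`: first time the density reaches 10% of its own maximum,
#'   minus the same measure for Src (ms).
#' Both densities are built on a common set of bin edges aligned to the mean
#' Src spike time.
#'
#' @param times_c Spike times of the population of interest (ms).
#' @param times_src Spike times of the Src population (ms).
#' @param sigma_inp Input-timing SD (ms); sets the density bin width.
#' @param latency_frac Density threshold fraction for the latency measure
#'   (default 0.1 of the distribution's own maximum).
#' @param latency_ref Whether the 10% threshold refers to each
#'   distribution's `"own"` maximum (default) or to the `"src"` maximum,
#'   for sensitivity analysis.
#' @return One-row data.frame with the five statistics.
#' @export
distribution_stats <- function(times_c, times_src, sigma_inp,
                               latency_frac = 0.1,
                               latency_ref = c("own", "src")) {
  latency_ref <- match.arg(latency_ref)
  if (length(times_src) == 0) stop("Src produced no spikes")
  if (length(times_c) == 0) {
    return(data.frame(norm_mean = NA_real_, norm_sd = NA_real_,
                      norm_max_density = NA_real_, norm_total = NA_real_,
                      rel_latency = NA_real_))
  }
  align <- mean(times_src)
  breaks <- density_breaks(c(times_c, times_src), sigma_inp / 10, align)
  d_src <- estimate_density(times_src, sigma_inp, breaks = breaks)
  d_c <- estimate_density(times_c, sigma_inp, breaks = breaks)
  onset_c <- if (latency_ref == "src") {
    thr <- latency_frac * max(d_src$d)
    if (max(d_c$d) < thr) NA_real_ else d_c$centers[which(d_c$d >= thr)[1]]
  } else {
    density_onset(d_c, latency_frac)
  }
  data.frame(
    norm_mean = mean(times_c) - mean(times_src),
    norm_sd = stats::sd(times_c) / stats::sd(times_src),
    norm_max_density = max(d_c$d) / max(d_src$d),
    norm_total = sum(d_c$d) / sum(d_src$d),
    rel_latency = onset_c - density_onset(d_src, latency_frac))
}

#' Gain of a statistic relative to the electrically uncoupled case
#'
#' `Gain[Q(theta)] = Q(theta) - Q(theta with zero electrical coupling)`;
#' identically zero for the uncoupled parameter set itself.
#'
#' @param q Statistic at the parameter set of interest.
#' @param q_uncoupled Same statistic with electrical coupling set to zero
#'   (all other parameters equal).
#' @return The difference, vectorised.
#' @export
gain <- function(q, q_uncoupled) q - q_uncoupled

#' Population response rate
#'
#' Fraction of neurons in a population that fired at least one spike,
#' averaged over trials, as a percentage (100% = every neuron spiked in
#' every trial).
#'
#' @param raster Raster from [run_trials()].
#' @param population Population name (default `"Tgt"`).
#' @param n_units,n_trials Dimensions; taken from raster attributes when
#'   omitted.
#' @return Percentage in `[0, 100]`.
#' @export
response_rate <- function(raster, population = "Tgt",
                          n_units = attr(raster, "n_units"),
                          n_trials = attr(raster, "n_trials")) {
  fs <- first_spike_times(raster, population, n_units, n_trials)
  100 * mean(!is.na(fs))
}
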