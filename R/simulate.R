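#' Noise specification
#'
#' White sensor noise is generated as discrete-time Gaussian samples with
#' per-channel standard deviation `white_density * sqrt(bandwidth)` (the rms
#' a physicist quotes for a flat noise floor over the stated bandwidth;
#' 10 fT/sqrt(Hz) over 80 Hz gives 89 fT rms). Optionally, spatially coloured
#' noise from random cortical dipoles is added on top, see
#' [simulate_coloured_noise()].
#'
#' @param white_density noise amplitude density (fT/sqrt(Hz)).
#' @param bandwidth noise bandwidth (Hz).
#' @param coloured_n_sources number of random cortical noise dipoles (0 = none).
#' @param coloured_strength per-dipole strength (nAm).
#' @param coloured_scale multiplier applied to the coloured-noise field.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(white_density = 10, bandwidth = 80,
                       coloured_n_sources = 0, coloured_strength = 1,
                       coloured_scale = 1) {
  stopifnot(white_density >= 0, bandwidth > 0, coloured_n_sources >= 0,
            coloured_strength >= 0)
  structure(list(white_density = white_density, bandwidth = bandwidth,
                 coloured_n_sources = coloured_n_sources,
                 coloured_strength = coloured_strength,
                 coloured_scale = coloured_scale), class = "noise_spec")
}

#' White-noise variance implied by a noise spec (fT^2)
#'
#' @param noise a [noise_spec()].
#' @return Per-channel, per-sample variance of the white noise.
#' @export
white_noise_variance <- function(noise) noise$white_density^2 * noise$bandwidth

new_epoch_data <- function(samples, fs, label = NA_real_) {
  structure(list(samples = samples, sampling_rate = fs, window_label = label),
            class = "epoch_data")
}

#' @export
print.epoch_data <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf("epoch_data: %d epochs x %d samples x %d channels @ %g Hz (Q = %g)\n",
              d[1], d[2], d[3], x$sampling_rate, x$window_label))
  invisible(x)
}

#' Simulate one analysis window
#'
#' Every element of the extended source shares a coherent 40 Hz sinusoidal
#' activation; the sensor signal is `Q` (total moment, nAm) times the
#' unit-moment patch lead field times the sinusoid, plus white Gaussian noise
#' with per-sample sd `white_density * sqrt(bandwidth)`. Epochs are
#' independent noise realisations of the same signal.
#'
#' @param lead_field a `lead_field` (fT/nAm) or plain numeric vector.
#' @param Q total source strength (nAm); 0 gives a pure noise window.
#' @param noise a [noise_spec()].
#' @param n_epochs,n_samples,fs epochs, samples per epoch, sampling rate (Hz).
#' @param seed integer seed; the window is bit-reproducible given it.
#' @param f_signal activation frequency (Hz).
#' @return An `epoch_data` object (epochs x samples x channels array, fT).
#' @export
simulate_window <- function(lead_field, Q, noise, n_epochs = 100,
                            n_samples = 120, fs = 600, seed = 1L,
                            f_signal = 40) {
  if (fs <= 2 * f_signal) stop("sampling rate must exceed twice the signal frequency")
  lf <- if (inherits(lead_field, "lead_field")) lead_field$values else as.numeric(lead_field)
  nchan <- length(lf)
  tt <- (seq_len(n_samples) - 1) / fs
  signal <- (Q * sin(2 * pi * f_signal * tt)) %o% lf  # samples x channels
  sd_noise <- noise$white_density * sqrt(noise$bandwidth)
  set.seed(as.integer(seed))
  x <- array(stats::rnorm(n_epochs * n_samples * nchan, sd = sd_noise),
             dim = c(n_epochs, n_samples, nchan))
  for (e in seq_len(n_epochs)) x[e, , ] <- x[e, , ] + signal
  new_epoch_data(x, fs, Q)
}

#' Spatially coloured noise from random cortical dipoles
#'
#' Draws `n_sources` mesh vertices without replacement, places a dipole along
#' each local normal with the given strength and an independent Gaussian time
#' course per epoch, and returns the summed sensor field (times `scale`) as an
#' `epoch_data` increment to add to a simulated window. Its channel
#' covariance has rank at most `n_sources`.
#'
#' @param mesh a [trimesh()].
#' @param head a [head_model()].
#' @param sensors sensor array.
#' @param n_epochs,n_samples,fs window dimensions.
#' @param n_sources number of noise dipoles.
#' @param strength dipole strength (nAm) scaling the unit-variance time course.
#' @param scale overall multiplier.
#' @param seed integer seed.
#' @return An `epoch_data` increment (fT).
#' @export
simulate_coloured_noise <- function(mesh, head, sensors, n_epochs = 100,
                                    n_samples = 120, fs = 600,
                                    n_sources = 100, strength = 1, scale = 1,
                                    seed = 1L) {
  nv <- nrow(mesh$vertices)
  if (n_sources > nv) stop("n_sources exceeds the number of mesh vertices")
  nchan <- nrow(sensors$positions)
  out <- array(0, dim = c(n_epochs, n_samples, nchan))
  if (n_sources == 0L) return(new_epoch_data(out, fs, NA_real_))
  set.seed(as.integer(seed))
  vs <- sample.int(nv, n_sources)
  L <- dipole_leadfield_matrix(head, mesh$vertices[vs, , drop = FALSE],
                               mesh$normals[vs, , drop = FALSE], sensors)
  for (e in seq_len(n_epochs)) {
    ts <- matrix(stats::rnorm(n_samples * n_sources, sd = strength),
                 n_samples, n_sources)
    out[e, , ] <- scale * ts %*% t(L)
  }
  new_epoch_data(out, fs, NA_real_)
}

#' Add two epoch-data objects
#'
#' @param a,b `epoch_data` with identical dimensions and sampling rate.
#' @return `epoch_data` with summed samples and `a`'s label.
#' @export
add_epoch_data <- function(a, b) {
  stopifnot(identical(dim(a$samples), dim(b$samples)),
            a$sampling_rate == b$sampling_rate)
  new_epoch_data(a$samples + b$samples, a$sampling_rate, a$window_label)
}

band_power <- function(window, band = c(35, 45)) {
  d <- dim(window$samples)
  n <- d[2]
  freqs <- (seq_len(n) - 1) * window$sampling_rate / n
  keep <- which(freqs >= band[1] & freqs <= band[2] & freqs <= window$sampling_rate / 2)
  if (length(keep) == 0L) stop("no periodogram bins fall inside the band")
  tot <- 0
  for (e in seq_len(d[1])) {
    sp <- Mod(stats::mvfft(window$samples[e, , ]))^2 / n
    tot <- tot + mean(sp[keep, ])
  }
  tot / d[1]
}

#' Band-power SNR of a window
#'
#' The average 35-45 Hz periodogram power over all channels and epochs of the
#' signal window, divided by the same quantity for the pure-noise (Q = 0)
#' reference window, minus 1. By construction a window simulated with Q = 0
#' has SNR approximately 0 and SNR grows as Q^2.
#'
#' @param signal_window,noise_window `epoch_data` with the same geometry and
#'   sampling rate.
#' @param band frequency band (Hz), inclusive of bin centres.
#' @return Dimensionless SNR estimate.
#' @export
estimate_snr <- function(signal_window, noise_window, band = c(35, 45)) {
  stopifnot(signal_window$sampling_rate == noise_window$sampling_rate,
            dim(signal_window$samples)[3] == dim(noise_window$samples)[3])
  pn <- band_power(noise_window, band)
  if (pn <= 0) stop("noise window has zero band power (degenerate reference)")
  band_power(signal_window, band) / pn - 1
}

#' Simulate the full multi-strength dataset for one source
#'
#' One window per source strength (default ladder Q = 0, 2, 4, 6, 8, 10, 20,
#' 50, 100 nAm), sharing geometry but with independent noise seeds per
#' window. The Q = 0 window is the noise reference for [estimate_snr()].
#'
#' @param truth a [patch_source()] (the generating source, any total moment;
#'   its unit-moment lead field is scaled by each Q).
#' @param head a [head_model()].
#' @param sensors sensor array.
#' @param noise a [noise_spec()].
#' @param Q_list source strengths (nAm); must contain 0.
#' @param n_epochs,n_samples,fs window dimensions.
#' @param seed master seed; per-window seeds are derived from it.
#' @param mesh optional [trimesh()], required when the noise spec includes
#'   coloured noise.
#' @return An object of class `experiment_dataset`: list of `epoch_data`
#'   windows (named by Q), the truth patch, and metadata.
#' @export
build_dataset <- function(truth, head, sensors, noise,
                          Q_list = c(0, 2, 4, 6, 8, 10, 20, 50, 100),
                          n_epochs = 100, n_samples = 120, fs = 600,
                          seed = 1L, mesh = NULL) {
  if (!any(Q_list == 0)) stop("Q_list must contain 0 (the noise reference)")
  lf <- patch_lead_field(head, truth, sensors)
  seed <- as.integer(seed)
  windows <- vector("list", length(Q_list))
  names(windows) <- as.character(Q_list)
  for (i in seq_along(Q_list)) {
    w <- simulate_window(lf, Q_list[i], noise, n_epochs, n_samples, fs,
                         seed = (seed * 131L + i) %% .Machine$integer.max)
    if (noise$coloured_n_sources > 0) {
      if (is.null(mesh)) stop("coloured noise needs a mesh")
      cn <- simulate_coloured_noise(mesh, head, sensors, n_epochs, n_samples,
                                    fs, noise$coloured_n_sources,
                                    noise$coloured_strength,
                                    noise$coloured_scale,
                                    seed = (seed * 131L + i + 7919L) %%
                                      .Machine$integer.max)
      w <- add_epoch_data(w, cn)
      w$window_label <- Q_list[i]
    }
    windows[[i]] <- w
  }
  structure(list(windows = windows, truth = truth,
                 metadata = list(seed = seed, Q_list = Q_list, noise = noise)),
            class = "experiment_dataset")
}
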