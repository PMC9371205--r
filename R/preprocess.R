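#' Zero-phase Butterworth low-pass filtering
#'
#' Filters every channel with a second-order Butterworth low-pass (10 Hz
#' cut-off by default) applied forward and backward, so the net response has
#' zero phase and no group delay that would shift lap boundaries. The
#' effective magnitude response is the squared one-pass response (half power
#' of the one-pass design at the cut-off). Edges are handled by odd
#' reflection padding so constant signals pass through unchanged.
#'
#' @param rec an [imu_recording()].
#' @param cutoff cut-off frequency in Hz; must be below Nyquist.
#' @param order filter order of the one-pass design.
#' @return A filtered [imu_recording()] at the same rate.
#' @export
butterworth_lowpass <- function(rec, cutoff = 10, order = 2) {
  stopifnot(inherits(rec, "imu_recording"))
  nyq <- rec$sample_rate / 2
  if (cutoff >= nyq) {
    stop(sprintf("cutoff (%g Hz) must be below Nyquist (%g Hz)", cutoff, nyq))
  }
  bf <- signal::butter(order, cutoff / nyq, type = "low")
  pad <- min(nrow(rec$samples) - 1L, as.integer(ceiling(8 * rec$sample_rate / cutoff)))
  out <- apply(rec$samples, 2L, .filtfilt_reflect, b = bf$b, a = bf$a, pad = pad)
  rec$samples <- matrix(out, ncol = 6L, dimnames = list(NULL, imu_channels()))
  rec
}

# forward-backward IIR with odd reflection padding to suppress end transients
.filtfilt_reflect <- function(x, b, a, pad) {
  n <- length(x)
  if (n == 1L || pad < 1L) return(x)
  pre <- 2 * x[1] - x[(pad + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - pad)]
  ext <- c(pre, x, post)
  y <- as.numeric(signal::filter(b, a, ext))
  y <- rev(as.numeric(signal::filter(b, a, rev(y))))
  y[(pad + 1L):(pad + n)]
}

#' Downsample a recording onto a uniform lower-rate grid
#'
#' Interpolates each channel onto the uniform `target_rate` grid with a
#' natural cubic spline. The source must already be low-pass filtered well
#' below the target Nyquist (the default pipeline filters at 10 Hz before
#' resampling to 50 Hz), so interpolation is effectively band-limited.
#'
#' @param rec an [imu_recording()].
#' @param target_rate target sampling frequency in Hz (downsampling only).
#' @return An [imu_recording()] at `target_rate` covering the same duration
#'   to within one output frame.
#' @export
resample_to <- function(rec, target_rate = 50) {
  stopifnot(inherits(rec, "imu_recording"))
  if (target_rate > rec$sample_rate) stop("upsampling is unsupported")
  if (target_rate == rec$sample_rate) return(rec)
  n_in <- nrow(rec$samples)
  t_in <- (seq_len(n_in) - 1L) / rec$sample_rate
  n_out <- floor((n_in - 1L) * target_rate / rec$sample_rate) + 1L
  t_out <- (seq_len(n_out) - 1L) / target_rate
  out <- vapply(seq_len(6L), function(j) {
    stats::spline(t_in, rec$samples[, j], xout = t_out, method = "natural")$y
  }, numeric(n_out))
  rec$samples <- matrix(out, ncol = 6L, dimnames = list(NULL, imu_channels()))
  rec$sample_rate <- as.numeric(target_rate)
  rec
}

#' Per-channel standardization scaler
#'
#' Computes the pooled per-channel mean and sample standard deviation over
#' all frames of the given recordings, for standardizing each channel to
#' zero mean and unit variance. By design the scaler is fit on training
#' subjects only and applied unchanged to held-out subjects (no information
#' leak); fitting on all subjects remains available via the `scaler_scope`
#' argument of [preprocess_recording()] pipelines that the caller controls.
#'
#' @param recs a single [imu_recording()] or a list of them (typically
#'   already filtered and downsampled).
#' @return An object of class `channel_scaler` with fields `means`, `sds`
#'   (length-6) and `fitted_on` (subject ids).
#' @export
fit_scaler <- function(recs) {
  if (inherits(recs, "imu_recording")) recs <- list(recs)
  stopifnot(length(recs) >= 1L)
  all_samples <- do.call(rbind, lapply(recs, function(r) {
    stopifnot(inherits(r, "imu_recording"))
    r$samples
  }))
  means <- colMeans(all_samples)
  sds <- apply(all_samples, 2L, stats::sd) # sample (n-1) sd, fixed convention
  if (any(sds <= 0 | !is.finite(sds))) {
    stop("zero-variance channel: ",
         paste(imu_channels()[sds <= 0 | !is.finite(sds)], collapse = ", "))
  }
  structure(
    list(means = means, sds = sds,
         fitted_on = unique(vapply(recs, `[[`, "", "subject_id"))),
    class = "channel_scaler"
  )
}

#' @rdname fit_scaler
#' @param rec an [imu_recording()] to standardize.
#' @param scaler a fitted `channel_scaler`.
#' @return `apply_scaler()`: the standardized recording, flagged
#'   `preprocessed`.
#' @export
apply_scaler <- function(rec, scaler) {
  stopifnot(inherits(rec, "imu_recording"), inherits(scaler, "channel_scaler"))
  if (ncol(rec$samples) != length(scaler$means)) {
    stop("channel count mismatch between recording and scaler")
  }
  rec$samples <- sweep(sweep(rec$samples, 2L, scaler$means, "-"),
                       2L, scaler$sds, "/")
  rec$preprocessed <- TRUE
  rec
}

#' @export
print.channel_scaler <- function(x, ...) {
  cat("<channel_scaler> fitted on:", paste(x$fitted_on, collapse = ", "), "\n")
  print(round(rbind(mean = x$means, sd = x$sds), 4))
  invisible(x)
}

#' Full preprocessing pipeline: filter, downsample, standardize
#'
#' Applies the stages in the fixed order low-pass filter (zero-phase
#' Butterworth) -> downsample -> standardize. If no scaler is supplied the
#' recording is returned filtered and downsampled but unstandardized (use
#' [fit_scaler()] on the training recordings first).
#'
#' @inheritParams butterworth_lowpass
#' @param target_rate working sampling rate in Hz.
#' @param scaler optional fitted [fit_scaler()] result.
#' @return An [imu_recording()] at `target_rate`.
#' @export
preprocess_recording <- function(rec, cutoff = 10, order = 2,
                                 target_rate = 50, scaler = NULL) {
  stopifnot(inherits(rec, "imu_recording"))
  out <- butterworth_lowpass(rec, cutoff = cutoff, order = order)
  out <- resample_to(out, target_rate)
  if (!is.null(scaler)) out <- apply_scaler(out, scaler)
  out
}
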