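#' IMU recording container
#'
#' A uniformly sampled 6-channel inertial time series: three accelerometer
#' axes in g and three gyroscope axes in deg/s, in fixed column order
#' `ax, ay, az, gx, gy, gz`. Raw recordings come off the sensor at 280 Hz;
#' preprocessed recordings (filtered, downsampled, standardized) are at
#' 50 Hz and carry `preprocessed = TRUE`.
#'
#' @param samples numeric matrix, frames x 6, columns `ax,ay,az,gx,gy,gz`
#'   (named columns in any order are reordered; unnamed are taken as-is).
#' @param sample_rate sampling frequency in Hz.
#' @param subject_id,session_id identifiers.
#' @param preprocessed logical; has the preprocessing pipeline been applied.
#' @return An object of class `imu_recording`.
#' @export
imu_recording <- function(samples, sample_rate, subject_id = "S1",
                          session_id = "A", preprocessed = FALSE) {
  samples <- as.matrix(samples)
  chans <- imu_channels()
  if (!is.null(colnames(samples))) {
    missing <- setdiff(chans, colnames(samples))
    if (length(missing)) {
      stop("missing channel column: ", paste(missing, collapse = ", "))
    }
    samples <- samples[, chans, drop = FALSE]
  } else {
    if (ncol(samples) != 6L) stop("samples must have exactly 6 channels")
    colnames(samples) <- chans
  }
  if (nrow(samples) < 1L) stop("recording must contain at least 1 frame")
  if (!all(is.finite(samples))) stop("samples contain non-finite values")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0) {
    stop("sample_rate must be a positive number")
  }
  structure(
    list(samples = samples, sample_rate = as.numeric(sample_rate),
         subject_id = as.character(subject_id),
         session_id = as.character(session_id),
         preprocessed = isTRUE(preprocessed)),
    class = "imu_recording"
  )
}

#' @rdname imu_recording
#' @export
imu_channels <- function() c("ax", "ay", "az", "gx", "gy", "gz")

#' @rdname imu_recording
#' @param x an `imu_recording`.
#' @export
n_frames <- function(x) UseMethod("n_frames")

#' @export
n_frames.imu_recording <- function(x) nrow(x$samples)

#' @export
n_frames.label_sequence <- function(x) length(x$labels)

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf(
    "<imu_recording> subject %s session %s: %d frames @ %g Hz (%.2f s)%s\n",
    x$subject_id, x$session_id, nrow(x$samples), x$sample_rate,
    nrow(x$samples) / x$sample_rate,
    if (x$preprocessed) ", preprocessed" else ", raw"
  ))
  invisible(x)
}
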