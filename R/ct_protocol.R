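#' CT acquisition protocol
#'
#' @param mAs tube current-time product.
#' @param kVp tube voltage.
#' @param pitch helical pitch.
#' @param algorithm CT reconstruction algorithm: \code{"FBP"} (filtered back
#'   projection) or \code{"IR"} (iterative reconstruction).
#' @param ir_level ordinal noise-suppression level of the IR algorithm
#'   (default 3).
#' @param reference logical; is this the reference protocol?
#' @export
ct_protocol <- function(mAs, kVp, pitch = 0.828, algorithm = c("IR", "FBP"),
                        ir_level = 3L, reference = FALSE) {
  algorithm <- match.arg(algorithm)
  if (!is.finite(mAs) || mAs < 0) stop("mAs must be nonnegative")
  if (!is.finite(kVp) || kVp <= 0) stop("kVp must be positive")
  structure(list(mAs = mAs, kVp = kVp, pitch = pitch, algorithm = algorithm,
                 ir_level = as.integer(ir_level), reference = reference),
            class = "ct_protocol")
}

#' @export
format.ct_protocol <- function(x, ...) {
  sprintf("%g mAs / %g kVp / pitch %g / %s%s", x$mAs, x$kVp, x$pitch,
          x$algorithm, if (x$reference) " (reference)" else "")
}

#' @export
print.ct_protocol <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Default CT acquisition grid
#'
#' Enumerates the study's 24 acquisition combinations (mAs 15/25/40/50,
#' kVp 80/100/120, pitch 0.671/0.828), each reconstructed with both FBP and
#' IR: 48 protocols in total. The reference protocol is 50 mAs, 120 kVp,
#' pitch 0.828, IR.
#'
#' @param mAs,kVp,pitch vectors of acquisition parameter levels.
#' @return list of \code{ct_protocol}, exactly one flagged as reference.
#' @export
default_protocol_grid <- function(mAs = c(15, 25, 40, 50),
                                  kVp = c(80, 100, 120),
                                  pitch = c(0.671, 0.828)) {
  acq <- expand.grid(mAs = mAs, kVp = kVp, pitch = pitch,
                     KEEP.OUT.ATTRS = FALSE)
  grid <- list()
  for (alg in c("FBP", "IR")) {
    for (i in seq_len(nrow(acq))) {
      ref <- alg == "IR" && acq$mAs[i] == 50 && acq$kVp[i] == 120 &&
        acq$pitch[i] == 0.828
      grid[[length(grid) + 1L]] <-
        ct_protocol(acq$mAs[i], acq$kVp[i], acq$pitch[i], alg, reference = ref)
    }
  }
  grid
}

#' Scanner CTDI calibration table
#'
#' Scanner-reported CTDIvol (mGy) per (mAs, kVp) combination; the reporting
#' is pitch-independent at this precision. Returned as a data frame.
#' @export
ctdi_calibration <- function() {
  data.frame(
    mAs = rep(c(15, 25, 40, 50), times = 3),
    kVp = rep(c(80, 100, 120), each = 4),
    # the 25 mAs / 100 kVp protocol is reported both as 0.9 and (in the
    # voxel-analysis table and the dose-reduction computation) 1.0 mGy by the
    # scanner workstation; the calibration adopts 1.0
    ctdi = c(0.3, 0.8, 1.0, 2.0,
             0.5, 1.0, 1.6, 2.6,
             0.6, 1.0, 1.6, 3.3)
  )
}

#' CTDI dose model
#'
#' Predicts the scanner-reported CTDIvol (mGy) for a protocol from a
#' calibration table. Within each calibrated voltage a monotone
#' (Hyman-filtered) spline through the calibration points, anchored at
#' (0 mAs, 0 mGy), interpolates over tube current; voltages between
#' calibrated levels are interpolated linearly. Pitch does not enter the
#' model (the calibration is pitch-independent at the scanner's reporting
#' precision). The model is monotone nondecreasing in mAs at fixed kVp.
#'
#' @param protocol a \code{ct_protocol} (or a list with \code{mAs},
#'   \code{kVp}).
#' @param calibration calibration data frame (columns mAs, kVp, ctdi).
#' @param extrapolate allow voltages outside the calibrated range.
#' @return dose in mGy.
#' @export
ctdi_model <- function(protocol, calibration = ctdi_calibration(),
                       extrapolate = FALSE) {
  kv <- sort(unique(calibration$kVp))
  if ((protocol$kVp < min(kv) || protocol$kVp > max(kv)) && !extrapolate)
    stop(sprintf("voltage %g kVp outside calibrated range [%g, %g]",
                 protocol$kVp, min(kv), max(kv)))
  dose_at_kv <- function(k) {
    sub <- calibration[calibration$kVp == k, ]
    sub <- sub[order(sub$mAs), ]
    f <- stats::splinefun(c(0, sub$mAs), c(0, sub$ctdi), method = "hyman")
    max(0, f(protocol$mAs))
  }
  if (protocol$kVp %in% kv) return(dose_at_kv(protocol$kVp))
  # linear interpolation (or edge extrapolation) across voltage
  k_lo <- if (protocol$kVp < min(kv)) kv[1] else max(kv[kv <= protocol$kVp])
  k_hi <- if (protocol$kVp > max(kv)) kv[length(kv)] else min(kv[kv >= protocol$kVp])
  if (k_lo == k_hi) return(dose_at_kv(k_lo))
  w <- (protocol$kVp - k_lo) / (k_hi - k_lo)
  (1 - w) * dose_at_kv(k_lo) + w * dose_at_kv(k_hi)
}
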