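#' Simplified acoustic feature extraction
#'
#' A compact, self-contained extractor for the 13 voice parameters used in
#' the analyses: F0 mean, normalized F0 SD, F0 range (20th-80th
#' percentile), mean rising/falling F0 slopes, loudness mean and
#' rising/falling slopes, mean jitter, mean shimmer, mean harmonics-to-noise
#' ratio, voiced segments per second and mean unvoiced segment length.
#' F0 statistics use the semitone scale anchored at 27.5 Hz. Pitch and
#' voicing come from a framewise normalized-autocorrelation tracker with
#' parabolic peak interpolation; jitter and shimmer are measured on
#' period-level pulse peaks within voiced segments. Loudness is an
#' RMS-based intensity proxy, not an auditory-model loudness; within-person
#' standardization downstream makes analyses invariant to that choice.
#'
#' @name acoustic_features
NULL

ACOUSTIC_FEATURES <- c("f0_mean", "f0_sd_norm", "f0_range", "f0_rise_slope",
                       "f0_fall_slope", "loudness_mean", "loudness_rise_slope",
                       "loudness_fall_slope", "jitter_mean", "shimmer_mean",
                       "hnr_mean", "voiced_segments_per_second",
                       "mean_unvoiced_segment_length")

#' Construct an audio clip
#'
#' @param samples numeric vector of amplitudes in [-1, 1].
#' @param sample_rate sampling rate in Hz.
#' @return An `emolang_clip` list with `samples`, `sample_rate`, `duration`.
#' @export
audio_clip <- function(samples, sample_rate) {
  stopifnot(is.numeric(samples), sample_rate > 0, all(is.finite(samples)))
  structure(list(samples = as.numeric(samples),
                 sample_rate = sample_rate,
                 duration = length(samples) / sample_rate),
            class = "emolang_clip")
}

#' Read a RIFF WAV file (PCM)
#'
#' Supports 8- and 16-bit PCM, mono or stereo (channels averaged). Clips
#' are resampled to 16 kHz by linear interpolation when recorded at another
#' rate, so all downstream framing operates on one rate.
#'
#' @param path WAV file path.
#' @param target_rate rate to resample to (default 16000 Hz).
#' @return An `emolang_clip`.
#' @export
read_wav <- function(path, target_rate = 16000) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stopf("%s: not a RIFF file", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stopf("%s: not a WAVE file", path)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        channels     = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        sample_rate  = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate    = readBin(con, "integer", 1, 4, endian = "little"),
        block_align  = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        bits         = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE))
      if (size > 16) invisible(readBin(con, "raw", size - 16))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stopf("%s: missing fmt/data chunk", path)
  if (fmt$audio_format != 1) stopf("%s: only PCM WAV supported", path)
  if (fmt$bits == 16) {
    n <- length(data_raw) %/% 2
    x <- readBin(data_raw, "integer", n, 2, endian = "little") / 32768
  } else if (fmt$bits == 8) {
    x <- (as.integer(data_raw) - 128) / 128
  } else stopf("%s: unsupported bit depth %d", path, fmt$bits)
  if (fmt$channels > 1) {
    x <- colMeans(matrix(x, nrow = fmt$channels))
  }
  if (fmt$sample_rate != target_rate) {
    t_old <- seq_along(x) / fmt$sample_rate
    t_new <- seq(t_old[1], t_old[length(t_old)], by = 1 / target_rate)
    x <- stats::approx(t_old, x, xout = t_new)$y
    audio_clip(x, target_rate)
  } else {
    audio_clip(x, fmt$sample_rate)
  }
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param clip an `emolang_clip` (samples clipped to [-1, 1]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path) {
  x <- clamp(clip$samples, -1, 1)
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")            # PCM
  writeBin(1L, con, 2, endian = "little")            # mono
  writeBin(as.integer(clip$sample_rate), con, 4, endian = "little")
  writeBin(as.integer(clip$sample_rate * 2), con, 4, endian = "little")
  writeBin(2L, con, 2, endian = "little")
  writeBin(16L, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}

#' Hz to semitones above 27.5 Hz
#'
#' `12 * log2(f / 27.5)`: 27.5 Hz maps to 0, each octave adds 12.
#'
#' @param f_hz frequency in Hz, strictly positive.
#' @return semitone value(s).
#' @export
hz_to_semitone <- function(f_hz) {
  if (any(!is.finite(f_hz)) || any(f_hz <= 0))
    stopf("hz_to_semitone: frequencies must be positive and finite")
  12 * log2(f_hz / 27.5)
}

#' Framewise voicing and F0 tracking
#'
#' Splits the clip into overlapping frames and estimates a fundamental
#' period per frame from the normalized autocorrelation over the 55-500 Hz
#' search band, with parabolic interpolation of the peak lag. A frame is
#' voiced iff the normalized peak reaches `voicing_threshold` and the frame
#' RMS is above `energy_floor_db` below the clip's peak amplitude
#' (tie-break: unvoiced). An all-silent clip yields all-unvoiced frames.
#'
#' @param clip an `emolang_clip`.
#' @param frame_len frame length in seconds (default 0.04: two 55 Hz periods).
#' @param hop hop in seconds (default 0.01).
#' @param f0_min,f0_max F0 search band in Hz.
#' @param voicing_threshold normalized autocorrelation threshold.
#' @param energy_floor_db silence floor relative to clip peak, in dB.
#' @return data.frame per frame: `time` (frame center, s), `voiced`,
#'   `f0_hz` (NA on unvoiced frames), `energy` (RMS), `r_max`.
#' @export
detect_voicing_and_f0 <- function(clip, frame_len = 0.04, hop = 0.01,
                                  f0_min = 55, f0_max = 500,
                                  voicing_threshold = 0.45,
                                  energy_floor_db = 60) {
  sr <- clip$sample_rate
  if (clip$duration < frame_len) stopf("clip shorter than one frame")
  flen <- round(frame_len * sr)
  fhop <- round(hop * sr)
  starts <- seq(1, length(clip$samples) - flen + 1, by = fhop)
  nfr <- length(starts)
  lag_min <- max(2L, floor(sr / f0_max))
  lag_max <- min(flen - 1L, ceiling(sr / f0_min))
  nfft <- 2^ceiling(log2(2 * flen))
  peak_amp <- max(abs(clip$samples))
  floor_rms <- peak_amp * 10^(-energy_floor_db / 20)

  idx <- outer(seq_len(flen), starts - 1L, "+")
  frames <- matrix(clip$samples[idx], nrow = flen)
  frames <- sweep(frames, 2, colMeans(frames))
  energy <- sqrt(colMeans(frames^2))

  # FFT-based autocorrelation of all frames at once
  padded <- rbind(frames, matrix(0, nfft - flen, nfr))
  sp <- stats::mvfft(padded)
  ac <- Re(stats::mvfft(sp * Conj(sp), inverse = TRUE)) / nfft

  # unbiased autocorrelation: undo the rectangular-window taper so that a
  # perfectly periodic frame peaks at r = 1 regardless of lag
  taper <- flen / (flen - 0:(nfft - 1))
  taper[!is.finite(taper) | taper < 0] <- 0

  f0 <- rep(NA_real_, nfr); rmax <- rep(NA_real_, nfr)
  for (j in seq_len(nfr)) {
    a0 <- ac[1, j]
    if (a0 <= 0) { rmax[j] <- 0; next }
    band <- ac[(lag_min + 1):(lag_max + 1), j] *
      taper[(lag_min + 1):(lag_max + 1)] / a0
    k <- which.max(band)
    # octave-error guard: prefer the shortest-lag local maximum that is
    # within 90% of the global peak (harmonics of a periodic frame all
    # reach comparable autocorrelation after taper correction)
    nb <- length(band)
    if (nb >= 3) {
      locmax <- which(band[2:(nb - 1)] > band[1:(nb - 2)] &
                      band[2:(nb - 1)] >= band[3:nb]) + 1
      cand <- locmax[band[locmax] >= 0.9 * band[k]]
      if (length(cand)) k <- min(cand)
    }
    r <- band[k]
    lag <- lag_min + k - 1
    # parabolic interpolation around the peak
    if (k > 1 && k < length(band)) {
      y1 <- band[k - 1]; y2 <- band[k]; y3 <- band[k + 1]
      denom <- y1 - 2 * y2 + y3
      if (is.finite(denom) && abs(denom) > 1e-12) {
        delta <- 0.5 * (y1 - y3) / denom
        if (abs(delta) <= 1) {
          lag <- lag + delta
          r <- y2 - 0.25 * (y1 - y3) * delta
        }
      }
    }
    rmax[j] <- r
    f0[j] <- sr / lag
  }
  voiced <- !is.na(rmax) & rmax >= voicing_threshold & energy >= floor_rms &
    !is.na(f0) & f0 >= f0_min & f0 <= f0_max
  data.frame(time = (starts - 1 + flen / 2) / sr,
             voiced = voiced,
             f0_hz = ifelse(voiced, f0, NA_real_),
             energy = energy,
             r_max = rmax)
}

# Maximal runs of a logical vector: data.frame(start, end, value)
runs_of <- function(x) {
  r <- rle(x)
  end <- cumsum(r$lengths)
  data.frame(start = end - r$lengths + 1, end = end, value = r$values)
}

# Mean least-squares slopes over maximal monotone runs of a contour.
# Returns c(rise, fall) with fall as a positive magnitude; NA when a
# direction has no run of >= 2 points.
monotone_slopes <- function(value, time) {
  n <- length(value)
  if (n < 2) return(c(rise = NA_real_, fall = NA_real_))
  v <- if (n >= 3) stats::runmed(value, 3) else value
  d <- sign(diff(v))
  # zero differences extend the current run
  for (i in seq_along(d)) if (d[i] == 0 && i > 1) d[i] <- d[i - 1]
  d[d == 0] <- 1
  rr <- runs_of(d)
  rise <- c(); fall <- c()
  for (i in seq_len(nrow(rr))) {
    i0 <- rr$start[i]; i1 <- rr$end[i] + 1  # run of diffs spans one more point
    if (i1 - i0 < 1) next
    tt <- time[i0:i1]; vv <- v[i0:i1]
    if (max(tt) == min(tt)) next
    sl <- stats::cov(tt, vv) / stats::var(tt)
    if (rr$value[i] > 0) rise <- c(rise, sl) else fall <- c(fall, abs(sl))
  }
  c(rise = if (length(rise)) mean(rise) else NA_real_,
    fall = if (length(fall)) mean(fall) else NA_real_)
}

# Period-level pulse picking within one voiced stretch of samples.
# Peak positions and amplitudes are refined by parabolic interpolation so
# periods are measured on a sub-sample grid. Returns list(periods, amps)
# in samples / linear amplitude.
pick_periods <- function(samples, t0_samples) {
  n <- length(samples)
  if (n < 2 * t0_samples) return(list(periods = numeric(0), amps = numeric(0)))
  refine <- function(p) {
    if (p <= 1 || p >= n) return(c(p, samples[p]))
    y1 <- samples[p - 1]; y2 <- samples[p]; y3 <- samples[p + 1]
    denom <- y1 - 2 * y2 + y3
    if (!is.finite(denom) || abs(denom) < 1e-12) return(c(p, y2))
    delta <- 0.5 * (y1 - y3) / denom
    if (abs(delta) > 1) return(c(p, y2))
    c(p + delta, y2 - 0.25 * (y1 - y3) * delta)
  }
  w0 <- min(n, ceiling(1.5 * t0_samples))
  p <- which.max(samples[1:w0])
  pr <- refine(p)
  pos <- pr[1]; amps <- pr[2]
  repeat {
    lo <- round(p + 0.7 * t0_samples); hi <- round(p + 1.3 * t0_samples)
    if (hi >= n) break  # never search a truncated window
    q <- lo + which.max(samples[lo:hi]) - 1
    qr <- refine(q)
    pos <- c(pos, qr[1]); amps <- c(amps, qr[2])
    p <- q
  }
  if (length(pos) < 3) return(list(periods = numeric(0), amps = numeric(0)))
  periods <- diff(pos)
  keep <- periods > 0.7 * t0_samples & periods < 1.3 * t0_samples
  list(periods = periods[keep], amps = amps)
}

#' Extract the 13 acoustic parameters from a clip
#'
#' F0 statistics are computed over voiced frames on the semitone scale:
#' mean; normalized SD (SD divided by mean); range as the 80th minus 20th
#' percentile; mean rising and falling slopes (semitones/second, falling
#' reported as a magnitude) over maximal monotone runs of the
#' median-smoothed voiced contour. Loudness is the framewise RMS intensity
#' proxy with mean and monotone-run slopes computed analogously. Jitter is
#' the mean absolute consecutive-period difference over the mean period;
#' shimmer the mean absolute dB ratio of consecutive period peak
#' amplitudes; HNR is `10*log10(r/(1-r))` of the normalized autocorrelation
#' peak averaged over voiced frames. Clips with no voiced frame return NA
#' for the F0/jitter/shimmer/HNR fields while segment statistics are still
#' computed.
#'
#' @param clip an `emolang_clip`.
#' @param frame_len,hop,voicing_threshold,energy_floor_db passed to
#'   [detect_voicing_and_f0()].
#' @return one-row data.frame with the 13 parameters.
#' @export
extract_acoustic_features <- function(clip, frame_len = 0.04, hop = 0.01,
                                      voicing_threshold = 0.45,
                                      energy_floor_db = 60) {
  trk <- detect_voicing_and_f0(clip, frame_len, hop,
                               voicing_threshold = voicing_threshold,
                               energy_floor_db = energy_floor_db)
  sr <- clip$sample_rate
  out <- stats::setNames(as.list(rep(NA_real_, length(ACOUSTIC_FEATURES))),
                         ACOUSTIC_FEATURES)

  vr <- runs_of(trk$voiced)
  vruns <- vr[vr$value, , drop = FALSE]
  out$voiced_segments_per_second <- nrow(vruns) / clip$duration
  if (nrow(vruns) >= 2) {
    iruns <- vr[!vr$value & vr$start > min(vruns$start) & vr$end < max(vruns$end), ,
                drop = FALSE]
    if (nrow(iruns) > 0)
      out$mean_unvoiced_segment_length <- mean((iruns$end - iruns$start + 1) * hop)
  }

  # loudness family over all frames
  out$loudness_mean <- mean(trk$energy)
  ls <- monotone_slopes(trk$energy, trk$time)
  out$loudness_rise_slope <- ls[["rise"]]
  out$loudness_fall_slope <- ls[["fall"]]

  if (any(trk$voiced)) {
    st <- hz_to_semitone(trk$f0_hz[trk$voiced])
    out$f0_mean <- mean(st)
    out$f0_sd_norm <- stats::sd(st) / out$f0_mean
    if (length(st) == 1) out$f0_sd_norm <- 0
    qs <- stats::quantile(st, c(0.2, 0.8), names = FALSE)
    out$f0_range <- qs[2] - qs[1]

    # slopes over the voiced contour, per voiced run
    rises <- c(); falls <- c()
    for (i in seq_len(nrow(vruns))) {
      sel <- vruns$start[i]:vruns$end[i]
      sl <- monotone_slopes(hz_to_semitone(trk$f0_hz[sel]), trk$time[sel])
      if (is.finite(sl[["rise"]])) rises <- c(rises, sl[["rise"]])
      if (is.finite(sl[["fall"]])) falls <- c(falls, sl[["fall"]])
    }
    out$f0_rise_slope <- if (length(rises)) mean(rises) else NA_real_
    out$f0_fall_slope <- if (length(falls)) mean(falls) else NA_real_

    r <- clamp(trk$r_max[trk$voiced], 1e-6, 1 - 1e-6)
    out$hnr_mean <- mean(10 * log10(r / (1 - r)))

    # period-level jitter / shimmer per voiced run
    flen <- round(frame_len * sr); fhop <- round(hop * sr)
    jit_num <- 0; jit_den <- 0; shim <- c(); nper <- 0; ndiff <- 0
    for (i in seq_len(nrow(vruns))) {
      sel <- vruns$start[i]:vruns$end[i]
      s0 <- (vruns$start[i] - 1) * fhop + 1
      s1 <- min(length(clip$samples), (vruns$end[i] - 1) * fhop + flen)
      t0 <- sr / mean(trk$f0_hz[sel])
      pp <- pick_periods(clip$samples[s0:s1], t0)
      if (length(pp$periods) >= 2) {
        jit_num <- jit_num + sum(abs(diff(pp$periods)))
        jit_den <- jit_den + sum(pp$periods)
        nper <- nper + length(pp$periods)
        ndiff <- ndiff + length(pp$periods) - 1
      }
      a <- pp$amps[pp$amps > 0]
      if (length(a) >= 2) shim <- c(shim, abs(20 * log10(a[-1] / a[-length(a)])))
    }
    if (jit_den > 0 && ndiff >= 1) {
      # mean |dT| / mean T, with means over all retained periods
      out$jitter_mean <- (jit_num / ndiff) / (jit_den / nper)
    }
    if (length(shim)) out$shimmer_mean <- mean(shim)
  }
  as.data.frame(out)
}
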