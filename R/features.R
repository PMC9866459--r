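#' Feature extraction parameters
#'
#' All fixed parameterizations of the 60-group feature extractor live in this
#' one table. The extractor names its feature groups 1-60; groups 1-16 are
#' statistical, 17-34 temporal, 35-60 spectral. Multi-valued groups (ECDF
#' levels, histogram bins, cepstral coefficients, spectrogram bins, wavelet
#' levels) expand to several columns; the group-to-column map is carried by
#' the feature matrix so subset selection can act on whole groups.
#'
#' @return Named list of constants:
#' \describe{
#'   \item{hist_bins}{histogram and value-entropy bins (10), spanning
#'     `[min, max]` of the window}
#'   \item{ecdf_levels}{ECDF summary levels (deciles 0.1..1.0)}
#'   \item{ecdf_percentiles}{the two ECDF percentiles reported (0.2, 0.8)}
#'   \item{acf_lag}{autocorrelation lag (1, normalized)}
#'   \item{peak_neighbourhood}{half-width for neighbourhood peak counting (5)}
#'   \item{lpcc_n}{number of linear-prediction cepstral coefficients (12)}
#'   \item{mfcc_n, mel_filters}{mel-frequency cepstral coefficients (12) over
#'     a 20-filter triangular mel bank spanning 0..fs/2}
#'   \item{rolloff, rollon}{cumulative-power fractions for spectral roll-off
#'     (0.85) and roll-on (0.05)}
#'   \item{maxfreq_q}{cumulative-power fraction defining "maximum frequency"
#'     (0.95)}
#'   \item{human_band}{walking cadence band in Hz (0.6-2.5)}
#'   \item{wavelet_levels}{depth of the Haar detail pyramid (3)}
#'   \item{spectrogram_win}{STFT window length in samples (32, halved when the
#'     segment is shorter), Hann-tapered, 50\% hop}
#' }
#' @export
feature_params <- function() {
  list(
    hist_bins = 10L,
    ecdf_levels = seq(0.1, 1.0, by = 0.1),
    ecdf_percentiles = c(0.2, 0.8),
    acf_lag = 1L,
    peak_neighbourhood = 5L,
    lpcc_n = 12L,
    mfcc_n = 12L,
    mel_filters = 20L,
    rolloff = 0.85,
    rollon = 0.05,
    maxfreq_q = 0.95,
    human_band = c(0.6, 2.5),
    wavelet_levels = 3L,
    spectrogram_win = 32L
  )
}

#' Names and domains of the 60 feature groups
#'
#' @return Data frame with columns `number`, `name`, `domain`.
#' @export
feature_table <- function() {
  data.frame(
    number = 1:60,
    name = c(
      "ECDF", "ECDF percentile", "ECDF percentile count", "Histogram",
      "Interquartile range", "Minimum", "Maximum", "Mean", "Median",
      "Mean absolute deviation", "Median absolute deviation",
      "Root mean square", "Variance", "Standard deviation", "Kurtosis",
      "Skewness",
      "Absolute energy", "Total energy", "Centroid", "Area under the curve",
      "Autocorrelation", "Shannon entropy", "Mean absolute differences",
      "Median absolute differences", "Mean of differences",
      "Median of differences", "Sum of absolute differences",
      "Positive turning points", "Negative turning points",
      "Zero-crossing rate", "Peak to peak distance", "Traveled distance",
      "Slope of signal", "Neighbourhood peaks",
      "Spectrogram frequency means", "Fundamental frequency",
      "Human range energy ratio", "LPC cepstral coefficients",
      "Mel-frequency cepstral coefficients", "Spectral positive turning points",
      "Spectral roll-off", "Spectral entropy", "Spectral roll-on",
      "Maximum power spectral density", "Maximum frequency",
      "Median frequency", "PSD bandwidth", "Spectral centroid",
      "Spectral decrease", "Spectral distance", "Spectral kurtosis",
      "Spectral skewness", "Spectral slope", "Spectral spread",
      "Spectral variation", "Wavelet absolute mean", "Wavelet energy",
      "Wavelet standard deviation", "Wavelet entropy", "Wavelet variance"
    ),
    domain = c(rep("statistical", 16), rep("temporal", 18), rep("spectral", 26))
  )
}

# impute a scalar that may be NaN/Inf (0/0, log 0, zero-variance moments)
.fin <- function(v) {
  v[!is.finite(v)] <- 0
  v
}

.named <- function(num, values) {
  stats::setNames(values, sprintf("f%02d_%d", num, seq_along(values) - 1L))
}

#' Statistical features (groups 1-16)
#'
#' ECDF deciles, ECDF percentiles (0.2/0.8) and their sample counts, a 10-bin
#' histogram over `[min, max]`, interquartile range, min, max, mean, median,
#' mean/median absolute deviation, root mean square, population variance and
#' standard deviation, excess kurtosis and skewness (population moments;
#' imputed to 0 for constant windows).
#'
#' @param signal Numeric vector, length >= 2.
#' @return Named numeric vector; names are `f<group>_<sub>`.
#' @export
extract_statistical <- function(signal) {
  stopifnot(length(signal) >= 2)
  p <- feature_params()
  n <- length(signal)
  mu <- mean(signal)
  m2 <- mean((signal - mu)^2)
  m3 <- mean((signal - mu)^3)
  m4 <- mean((signal - mu)^4)
  ecdf_q <- unname(stats::quantile(signal, p$ecdf_levels, type = 1))
  pct <- unname(stats::quantile(signal, p$ecdf_percentiles, type = 1))
  pct_count <- vapply(pct, function(q) sum(signal <= q), 0)
  counts <- .hist_counts(signal, p$hist_bins)
  c(
    .named(1, ecdf_q),
    .named(2, pct),
    .named(3, pct_count),
    .named(4, counts),
    .named(5, unname(stats::quantile(signal, 0.75) - stats::quantile(signal, 0.25))),
    .named(6, min(signal)),
    .named(7, max(signal)),
    .named(8, mu),
    .named(9, stats::median(signal)),
    .named(10, mean(abs(signal - mu))),
    .named(11, stats::median(abs(signal - stats::median(signal)))),
    .named(12, sqrt(mean(signal^2))),
    .named(13, m2),
    .named(14, sqrt(m2)),
    .named(15, .fin(m4 / m2^2 - 3)),
    .named(16, .fin(m3 / m2^1.5))
  )
}

# fixed-bin histogram counts over [min, max]; bin edges by direct rescaling
# (not seq()) so edge values land deterministically; all mass in bin 1 when
# the window is constant
.hist_counts <- function(signal, bins) {
  lo <- min(signal); hi <- max(signal)
  if (hi == lo) return(c(length(signal), rep(0, bins - 1L)))
  idx <- pmin(bins, 1L + floor((signal - lo) / (hi - lo) * bins))
  tabulate(idx, nbins = bins)
}

#' Temporal features (groups 17-34)
#'
#' Absolute and per-second energy, temporal centroid, trapezoidal area under
#' the rectified curve, lag-1 autocorrelation, Shannon entropy of the value
#' histogram, mean/median absolute differences, mean/median of differences,
#' sum of absolute differences, positive/negative turning points (strict
#' local maxima/minima), zero crossings, peak-to-peak amplitude, traveled
#' distance, least-squares slope against time, and neighbourhood peak count.
#'
#' @param signal Numeric vector, length >= 2.
#' @param fs Sampling frequency in Hz.
#' @return Named numeric vector.
#' @export
extract_temporal <- function(signal, fs) {
  stopifnot(length(signal) >= 2, fs > 0)
  p <- feature_params()
  n <- length(signal)
  t <- (seq_len(n) - 1) / fs
  d <- diff(signal)
  energy <- sum(signal^2)
  counts <- .hist_counts(signal, p$hist_bins)
  prob <- counts / n
  prob <- prob[prob > 0]
  tmu <- mean(t)
  c(
    .named(17, energy),
    .named(18, energy * fs / (n - 1)),
    .named(19, .fin(sum(t * signal^2) / energy)),
    .named(20, sum(diff(t) * (abs(signal[-n]) + abs(signal[-1])) / 2)),
    .named(21, .acf1(signal)),
    .named(22, -sum(prob * log2(prob))),
    .named(23, mean(abs(d))),
    .named(24, stats::median(abs(d))),
    .named(25, mean(d)),
    .named(26, stats::median(d)),
    .named(27, sum(abs(d))),
    .named(28, sum(d[-(n - 1)] > 0 & d[-1] < 0)),
    .named(29, sum(d[-(n - 1)] < 0 & d[-1] > 0)),
    .named(30, sum(signal[-n] * signal[-1] < 0)),
    .named(31, max(signal) - min(signal)),
    .named(32, sum(abs(d))),
    .named(33, .fin(sum((t - tmu) * (signal - mean(signal))) / sum((t - tmu)^2))),
    .named(34, .neighbourhood_peaks(signal, p$peak_neighbourhood))
  )
}

.acf1 <- function(signal) {
  n <- length(signal)
  mu <- mean(signal)
  den <- sum((signal - mu)^2)
  if (den == 0) return(0)
  sum((signal[-n] - mu) * (signal[-1] - mu)) / den
}

.neighbourhood_peaks <- function(signal, nb) {
  n <- length(signal)
  if (n < 2 * nb + 1) return(0)
  cnt <- 0L
  for (i in (nb + 1L):(n - nb)) {
    win <- signal[(i - nb):(i + nb)]
    if (signal[i] > max(win[-(nb + 1L)])) cnt <- cnt + 1L
  }
  cnt
}

# one-sided magnitude spectrum: frequencies 0..fs/2 and |FFT|
.spectrum <- function(signal, fs) {
  n <- length(signal)
  nh <- n %/% 2L + 1L
  mag <- Mod(stats::fft(signal))[seq_len(nh)]
  list(f = (seq_len(nh) - 1) * fs / n, mag = mag, psd = mag^2, n = n)
}

#' Spectral features (groups 35-60)
#'
#' FFT, spectrogram, cepstral and wavelet descriptors of a window. An
#' all-zero window returns all zeros (the pipeline's imputation rule for
#' degenerate spectra); other degenerate ratios (zero spread, empty bands)
#' impute the affected feature to 0.
#'
#' @param signal Numeric vector, length >= 8.
#' @param fs Sampling frequency in Hz.
#' @return Named numeric vector. The spectrogram group (35) yields one column
#'   per STFT frequency bin, groups 38/39 yield 12 cepstral coefficients
#'   each, wavelet groups 56-58 and 60 one value per decomposition level.
#' @export
extract_spectral <- function(signal, fs) {
  stopifnot(length(signal) >= 8, fs > 0)
  p <- feature_params()
  n <- length(signal)
  win <- min(p$spectrogram_win, 2^floor(log2(n)))
  nbins_sg <- win %/% 2L + 1L

  if (all(signal == 0)) {
    return(c(
      .named(35, rep(0, nbins_sg)), .named(36, 0), .named(37, 0),
      .named(38, rep(0, p$lpcc_n)), .named(39, rep(0, p$mfcc_n)),
      .named(40, 0), .named(41, 0), .named(42, 0), .named(43, 0),
      .named(44, 0), .named(45, 0), .named(46, 0), .named(47, 0),
      .named(48, 0), .named(49, 0), .named(50, 0), .named(51, 0),
      .named(52, 0), .named(53, 0), .named(54, 0), .named(55, 0),
      .named(56, rep(0, p$wavelet_levels)), .named(57, rep(0, p$wavelet_levels)),
      .named(58, rep(0, p$wavelet_levels)), .named(59, 0),
      .named(60, rep(0, p$wavelet_levels))
    ))
  }

  sp <- .spectrum(signal, fs)
  f <- sp$f; mag <- sp$mag; psd <- sp$psd
  tot_psd <- sum(psd)
  cum <- cumsum(psd) / tot_psd

  # moments of the normalized PSD treated as a distribution over frequency
  w <- psd / tot_psd
  centroid <- sum(f * w)
  spread2 <- sum((f - centroid)^2 * w)
  spread <- sqrt(spread2)

  # ratio of walking-band power to non-DC power
  band <- f >= p$human_band[1] & f <= p$human_band[2]
  nondc <- sum(psd[-1])
  human <- if (nondc > 0) sum(psd[band]) / nondc else 0

  dmag <- diff(mag)
  nm <- length(mag)
  sg <- .spectrogram_means(signal, fs, win)
  cum_mag <- cumsum(mag)
  line <- seq(cum_mag[1], cum_mag[nm], length.out = nm)
  fmu <- mean(f)
  half <- which(psd >= max(psd) / 2)
  dwt <- .haar_details(signal, p$wavelet_levels)
  wav_energy <- vapply(dwt, function(d) sum(d^2), 0)
  wtot <- sum(wav_energy)
  wp <- if (wtot > 0) wav_energy / wtot else rep(0, length(wav_energy))
  wp <- wp[wp > 0]

  c(
    .named(35, sg),
    .named(36, f[which.max(psd[-1]) + 1L]),
    .named(37, human),
    .named(38, .lpcc(signal, p$lpcc_n)),
    .named(39, .mfcc(psd, f, fs, p$mel_filters, p$mfcc_n)),
    .named(40, sum(dmag[-(nm - 1)] > 0 & dmag[-1] < 0)),
    .named(41, f[which(cum >= p$rolloff)[1]]),
    .named(42, .spectral_entropy(psd)),
    .named(43, f[which(cum >= p$rollon)[1]]),
    .named(44, max(2 * psd / (fs * sp$n))),
    .named(45, f[which(cum >= p$maxfreq_q)[1]]),
    .named(46, f[which(cum >= 0.5)[1]]),
    .named(47, if (length(half) > 1) f[max(half)] - f[min(half)] else 0),
    .named(48, centroid),
    .named(49, .fin(sum((mag[-1] - mag[1]) / seq_len(nm - 1)) / sum(mag[-1]))),
    .named(50, sum(line - cum_mag)),
    .named(51, .fin(sum((f - centroid)^4 * w) / spread2^2)),
    .named(52, .fin(sum((f - centroid)^3 * w) / spread^3)),
    .named(53, .fin(sum((f - fmu) * (mag - mean(mag))) / sum((f - fmu)^2))),
    .named(54, spread),
    .named(55, .spectral_variation(signal, fs)),
    .named(56, vapply(dwt, function(d) mean(abs(d)), 0)),
    .named(57, wav_energy),
    .named(58, vapply(dwt, function(d) sqrt(mean((d - mean(d))^2)), 0)),
    .named(59, if (length(wp)) -sum(wp * log(wp)) else 0),
    .named(60, vapply(dwt, function(d) mean((d - mean(d))^2), 0))
  )
}

# normalized Shannon entropy of the non-DC PSD; 1 = flat spectrum
.spectral_entropy <- function(psd) {
  pr <- psd[-1]
  s <- sum(pr)
  if (s == 0 || length(pr) < 2) return(0)
  pr <- pr[pr > 0] / s
  -sum(pr * log(pr)) / log(length(psd) - 1)
}

# mean over time of Hann-windowed STFT magnitude, one value per frequency bin
.spectrogram_means <- function(signal, fs, win) {
  n <- length(signal)
  hop <- win %/% 2L
  hann <- 0.5 - 0.5 * cos(2 * pi * (0:(win - 1)) / (win - 1))
  starts <- seq.int(1L, n - win + 1L, by = hop)
  nh <- win %/% 2L + 1L
  acc <- rep(0, nh)
  for (s0 in starts) {
    seg <- signal[s0:(s0 + win - 1L)] * hann
    acc <- acc + Mod(stats::fft(seg))[seq_len(nh)]
  }
  acc / length(starts)
}

# 1 minus the cosine similarity between the magnitude spectra of the two
# half-windows; 0 for a stationary spectrum
.spectral_variation <- function(signal, fs) {
  n <- length(signal)
  h <- n %/% 2L
  m1 <- .spectrum(signal[1:h], fs)$mag
  m2 <- .spectrum(signal[(n - h + 1L):n], fs)$mag
  den <- sqrt(sum(m1^2) * sum(m2^2))
  if (den == 0) return(0)
  1 - sum(m1 * m2) / den
}

# Haar detail coefficients, `levels` deep; odd tails dropped per level
.haar_details <- function(signal, levels) {
  a <- signal
  out <- vector("list", levels)
  for (l in seq_len(levels)) {
    m <- length(a) %/% 2L
    even <- a[2 * seq_len(m)]
    odd <- a[2 * seq_len(m) - 1L]
    out[[l]] <- (odd - even) / sqrt(2)
    a <- (odd + even) / sqrt(2)
  }
  out
}

# linear-prediction cepstral coefficients: Levinson-Durbin on the biased
# autocovariance of the demeaned window, then the standard LPC-to-cepstrum
# recursion; order equals the number of coefficients returned
.lpcc <- function(signal, ncoef) {
  x <- signal - mean(signal)
  n <- length(x)
  ord <- min(ncoef, n - 1L)
  r <- vapply(0:ord, function(k) sum(x[1:(n - k)] * x[(1 + k):n]) / n, 0)
  if (r[1] <= 0) return(rep(0, ncoef))
  a <- rep(0, ord)          # A(z) = 1 + a1 z^-1 + ... (sign convention)
  err <- r[1]
  for (i in seq_len(ord)) {
    k <- -(r[i + 1] + if (i > 1) sum(a[1:(i - 1)] * r[i:2]) else 0) / err
    a_new <- a
    a_new[i] <- k
    if (i > 1) a_new[1:(i - 1)] <- a[1:(i - 1)] + k * rev(a[1:(i - 1)])
    a <- a_new
    err <- err * (1 - k^2)
    if (err <= 0) break
  }
  cep <- rep(0, ncoef)
  for (m in seq_len(ncoef)) {
    am <- if (m <= ord) a[m] else 0
    acc <- -am
    if (m > 1) {
      for (k in 1:(m - 1)) {
        amk <- if ((m - k) <= ord) a[m - k] else 0
        acc <- acc - (k / m) * cep[k] * amk
      }
    }
    cep[m] <- acc
  }
  .fin(cep)
}

# mel-frequency cepstral coefficients from a one-sided power spectrum
.mfcc <- function(psd, f, fs, nfilt, ncoef) {
  mel <- function(hz) 2595 * log10(1 + hz / 700)
  imel <- function(m) 700 * (10^(m / 2595) - 1)
  edges <- imel(seq(0, mel(fs / 2), length.out = nfilt + 2L))
  e <- vapply(seq_len(nfilt), function(j) {
    lo <- edges[j]; mid <- edges[j + 1]; hi <- edges[j + 2]
    up <- (f - lo) / max(mid - lo, 1e-12)
    down <- (hi - f) / max(hi - mid, 1e-12)
    wgt <- pmax(0, pmin(up, down))
    sum(psd * wgt)
  }, 0)
  loge <- log(e + 1e-12)
  j <- seq_len(nfilt)
  vapply(seq_len(ncoef), function(m) {
    sqrt(2 / nfilt) * sum(loge * cos(pi * m * (j - 0.5) / nfilt))
  }, 0)
}

#' Assemble the segments-by-features matrix
#'
#' Runs the statistical, temporal and spectral extractors on each axis of
#' each segment and stacks the results. Columns are named
#' `f<group>_<axis>_<sub>`; a selected feature group activates all of its
#' columns across the three axes, which is how the PSO mask of length 60 maps
#' onto the matrix. Non-finite values are imputed to 0 and recorded in the
#' `imputations` attribute.
#'
#' @param segments Non-empty list of segments sharing `window_s` and `fs`
#'   (see [segment_recording()]).
#' @return An object of class `feature_matrix`: list with `values`
#'   (numeric matrix), `subject_id`, `label` (per row), `group_map`
#'   (named list, feature number to column indices), `window_s`, `fs`.
#' @export
build_feature_matrix <- function(segments) {
  if (length(segments) == 0L) stop("no segments supplied", call. = FALSE)
  ws <- unique(vapply(segments, `[[`, 0, "window_s"))
  fss <- unique(vapply(segments, `[[`, 0, "fs"))
  if (length(ws) != 1L || length(fss) != 1L) {
    stop("all segments must share window_s and fs", call. = FALSE)
  }
  fs <- fss
  rows <- lapply(segments, function(seg) {
    unlist(lapply(c("x", "y", "z"), function(ax) {
      s <- seg$data[, ax]
      v <- c(extract_statistical(s), extract_temporal(s, fs),
             extract_spectral(s, fs))
      names(v) <- sub("^(f[0-9]+)_", sprintf("\\1_%s_", ax), names(v))
      v
    }))
  })
  values <- do.call(rbind, rows)
  bad <- which(!is.finite(values), arr.ind = TRUE)
  imputations <- data.frame(row = integer(), column = character())
  if (nrow(bad)) {
    imputations <- data.frame(row = bad[, 1],
                              column = colnames(values)[bad[, 2]])
    values[bad] <- 0
  }
  grp <- as.integer(sub("^f([0-9]+)_.*$", "\\1", colnames(values)))
  group_map <- split(seq_along(grp), grp)
  structure(
    list(values = values,
         subject_id = vapply(segments, `[[`, "", "subject_id"),
         label = vapply(segments, `[[`, "", "label"),
         group_map = group_map,
         window_s = ws, fs = fs),
    imputations = imputations,
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "<feature_matrix> %d segments x %d columns (%d feature groups), %d walking / %d other\n",
    nrow(x$values), ncol(x$values), length(x$group_map),
    sum(x$label == "walking"), sum(x$label == "other")))
  invisible(x)
}

#' Column indices activated by a feature-group mask
#'
#' @param fm A [build_feature_matrix()] result.
#' @param mask Logical vector over feature groups (in `group_map` order).
#' @return Integer vector of column positions.
#' @export
mask_columns <- function(fm, mask) {
  stopifnot(length(mask) == length(fm$group_map))
  sort(unlist(fm$group_map[mask], use.names = FALSE))
}

#' Fit / apply column standardization
#'
#' Z-scores columns using means and standard deviations estimated on training
#' rows only (constant columns get unit scale). Distance-based steps (the kNN
#' wrapper, ADASYN neighbour search) require commensurate feature scales.
#'
#' @param X Numeric matrix of training rows.
#' @return `standardize_fit`: a list with `center` and `scale`.
#' @export
standardize_fit <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

#' @rdname standardize_fit
#' @param scaler A fit from [standardize_fit()].
#' @return `standardize_apply`: the standardized matrix.
#' @export
standardize_apply <- function(X, scaler) {
  sweep(sweep(X, 2, scaler$center, "-"), 2, scaler$scale, "/")
}

#' Export a feature matrix to CSV
#'
#' Header is `subject_id,label,f<num>_<axis>_<sub>,...`.
#'
#' @param fm A feature matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(subject_id = fm$subject_id, label = fm$label,
                   fm$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
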