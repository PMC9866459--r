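# Independent naive oracles for every single-valued feature group.
# Deliberately written loop-by-loop (and via lm / naive DFT) so they share no
# code path with the package's vectorized extractors.

naive_quantile7 <- function(s, p) {
  s <- sort(s)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
}

naive_hist_probs <- function(s, bins = 10) {
  lo <- min(s); hi <- max(s)
  if (hi == lo) {
    counts <- c(length(s), rep(0, bins - 1))
  } else {
    counts <- rep(0, bins)
    for (v in s) {
      b <- 1 + floor((v - lo) / (hi - lo) * bins)
      if (b > bins) b <- bins
      counts[b] <- counts[b] + 1
    }
  }
  counts / length(s)
}

# naive O(n^2) DFT, one-sided magnitudes
naive_dft_mag <- function(s) {
  n <- length(s)
  nh <- n %/% 2 + 1
  mag <- numeric(nh)
  for (k in 0:(nh - 1)) {
    re <- 0; im <- 0
    for (j in 0:(n - 1)) {
      re <- re + s[j + 1] * cos(2 * pi * k * j / n)
      im <- im - s[j + 1] * sin(2 * pi * k * j / n)
    }
    mag[k + 1] <- sqrt(re^2 + im^2)
  }
  mag
}

naive_haar_details <- function(s, levels = 3) {
  out <- list()
  a <- s
  for (l in 1:levels) {
    m <- length(a) %/% 2
    d <- numeric(m); ap <- numeric(m)
    for (i in 1:m) {
      d[i] <- (a[2 * i - 1] - a[2 * i]) / sqrt(2)
      ap[i] <- (a[2 * i - 1] + a[2 * i]) / sqrt(2)
    }
    out[[l]] <- d
    a <- ap
  }
  out
}

# returns values named by the extractor's column names (f<num>_0)
naive_single_features <- function(s, fs) {
  n <- length(s)
  t <- (0:(n - 1)) / fs
  mu <- sum(s) / n
  cmom <- function(k) sum((s - mu)^k) / n
  d <- s[-1] - s[-n]

  out <- c(
    f05 = naive_quantile7(s, 0.75) - naive_quantile7(s, 0.25),
    f06 = min(s), f07 = max(s), f08 = mu,
    f09 = naive_quantile7(s, 0.5),
    f10 = sum(abs(s - mu)) / n,
    f11 = naive_quantile7(abs(s - naive_quantile7(s, 0.5)), 0.5),
    f12 = sqrt(sum(s^2) / n),
    f13 = cmom(2), f14 = sqrt(cmom(2)),
    f15 = if (cmom(2) == 0) 0 else cmom(4) / cmom(2)^2 - 3,
    f16 = if (cmom(2) == 0) 0 else cmom(3) / cmom(2)^1.5
  )

  # temporal
  prob <- naive_hist_probs(s)
  prob <- prob[prob > 0]
  pos_turn <- 0; neg_turn <- 0; zc <- 0
  for (i in 2:(n - 1)) {
    if (s[i] > s[i - 1] && s[i] > s[i + 1]) pos_turn <- pos_turn + 1
    if (s[i] < s[i - 1] && s[i] < s[i + 1]) neg_turn <- neg_turn + 1
  }
  for (i in 1:(n - 1)) if (s[i] * s[i + 1] < 0) zc <- zc + 1
  trapz <- 0
  for (i in 1:(n - 1)) trapz <- trapz + (t[i + 1] - t[i]) * (abs(s[i]) + abs(s[i + 1])) / 2
  acf1 <- if (cmom(2) == 0) 0 else
    sum((s[1:(n - 1)] - mu) * (s[2:n] - mu)) / sum((s - mu)^2)
  nb <- 5; peaks <- 0
  if (n >= 2 * nb + 1) {
    for (i in (nb + 1):(n - nb)) {
      if (all(s[i] > s[(i - nb):(i - 1)]) && all(s[i] > s[(i + 1):(i + nb)])) {
        peaks <- peaks + 1
      }
    }
  }
  out <- c(out,
    f17 = sum(s^2),
    f18 = sum(s^2) * fs / (n - 1),
    f19 = if (sum(s^2) == 0) 0 else sum(t * s^2) / sum(s^2),
    f20 = trapz,
    f21 = acf1,
    f22 = -sum(prob * log2(prob)),
    f23 = sum(abs(d)) / (n - 1),
    f24 = naive_quantile7(abs(d), 0.5),
    f25 = sum(d) / (n - 1),
    f26 = naive_quantile7(d, 0.5),
    f27 = sum(abs(d)),
    f28 = pos_turn, f29 = neg_turn, f30 = zc,
    f31 = max(s) - min(s),
    f32 = sum(abs(d)),
    f33 = unname(stats::coef(stats::lm(s ~ t))[2]),
    f34 = peaks
  )

  # spectral
  if (all(s == 0)) {
    sing <- c(36, 37, 40:55, 59)
    sp <- stats::setNames(rep(0, length(sing)), sprintf("f%02d", sing))
    out <- c(out, sp)
  } else {
    mag <- naive_dft_mag(s)
    nh <- length(mag)
    f <- (0:(nh - 1)) * fs / n
    psd <- mag^2
    w <- psd / sum(psd)
    cum <- cumsum(psd) / sum(psd)
    cen <- sum(f * w)
    spr2 <- sum((f - cen)^2 * w)
    sturn <- 0
    dm <- mag[-1] - mag[-nh]
    for (i in 2:(nh - 1) - 1) if (dm[i] > 0 && dm[i + 1] < 0) sturn <- sturn + 1
    first_at <- function(q) { for (i in 1:nh) if (cum[i] >= q) return(f[i]) }
    pr <- psd[-1]; prn <- pr[pr > 0] / sum(pr)
    sent <- if (sum(pr) == 0 || nh < 3) 0 else -sum(prn * log(prn)) / log(nh - 1)
    half <- which(psd >= max(psd) / 2)
    bw <- if (length(half) > 1) f[max(half)] - f[min(half)] else 0
    dec <- if (sum(mag[-1]) == 0) 0 else
      sum((mag[-1] - mag[1]) / (1:(nh - 1))) / sum(mag[-1])
    cm <- cumsum(mag)
    line <- seq(cm[1], cm[nh], length.out = nh)
    h <- n %/% 2
    m1 <- naive_dft_mag(s[1:h]); m2 <- naive_dft_mag(s[(n - h + 1):n])
    varn <- if (sum(m1^2) == 0 || sum(m2^2) == 0) 0 else
      1 - sum(m1 * m2) / sqrt(sum(m1^2) * sum(m2^2))
    nondc <- sum(psd[-1])
    band <- 0
    for (i in 1:nh) if (f[i] >= 0.6 && f[i] <= 2.5) band <- band + psd[i]
    dets <- naive_haar_details(s)
    we <- vapply(dets, function(x) sum(x^2), 0)
    wp <- if (sum(we) > 0) we / sum(we) else rep(0, 3)
    wp <- wp[wp > 0]
    out <- c(out,
      f36 = f[which.max(psd[-1]) + 1],
      f37 = if (nondc == 0) 0 else band / nondc,
      f40 = sturn,
      f41 = first_at(0.85),
      f42 = sent,
      f43 = first_at(0.05),
      f44 = max(2 * psd / (fs * n)),
      f45 = first_at(0.95),
      f46 = first_at(0.5),
      f47 = bw,
      f48 = cen,
      f49 = dec,
      f50 = sum(line - cm),
      f51 = if (spr2 == 0) 0 else sum((f - cen)^4 * w) / spr2^2,
      f52 = if (spr2 == 0) 0 else sum((f - cen)^3 * w) / spr2^1.5,
      f53 = unname(stats::coef(stats::lm(mag ~ f))[2]),
      f54 = sqrt(spr2),
      f55 = varn,
      f59 = if (length(wp)) -sum(wp * log(wp)) else 0
    )
  }
  stats::setNames(out, paste0(names(out), "_0"))
}

# extractor output for one signal, named f<num>_<sub>
extract_all <- function(s, fs) {
  c(extract_statistical(s), extract_temporal(s, fs), extract_spectral(s, fs))
}
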