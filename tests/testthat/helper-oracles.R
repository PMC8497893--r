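# Independent brute-force oracles, deliberately written from the bare
# definitions (explicit double loops, no shared code with the package).

sampen_brute <- function(x, m = 2, r_frac = 0.2) {
  n <- length(x)
  r <- r_frac * stats::sd(x)
  count_pairs <- function(len) {
    tot <- 0L
    for (i in 1:(n - m - 1)) {
      for (j in (i + 1):(n - m)) {
        if (max(abs(x[i:(i + len - 1)] - x[j:(j + len - 1)])) <= r) {
          tot <- tot + 1L
        }
      }
    }
    tot
  }
  bm <- count_pairs(m)
  bm1 <- count_pairs(m + 1)
  if (bm == 0 || bm1 == 0) return(NA_real_)
  -log(bm1 / bm)
}

rmssd_brute <- function(x) {
  s <- 0
  for (i in 2:length(x)) s <- s + (x[i] - x[i - 1])^2
  sqrt(s / (length(x) - 1))
}

# dominant frequency of an event-rate series by an ordinary periodogram
# (interpolation to a uniform grid + spec.pgram), independent of the
# package's Morlet machinery
rate_peak_freq <- function(event_times) {
  iv <- diff(event_times)
  rate <- 60 / iv
  at <- event_times[-1]
  grid <- seq(at[1], at[length(at)], by = 0.25)
  vals <- stats::approx(at, rate, xout = grid)$y
  sp <- stats::spec.pgram(stats::ts(vals - mean(vals), frequency = 4),
                          plot = FALSE, taper = 0, detrend = FALSE)
  sp$freq[which.max(sp$spec)]
}

# magnitude-squared coherence at a target frequency via smoothed
# cross-periodogram
coherence_at <- function(x, y, fs, f0) {
  sp <- stats::spec.pgram(stats::ts(cbind(x, y), frequency = fs),
                          spans = c(11, 11), plot = FALSE, taper = 0,
                          detrend = TRUE)
  i <- which.min(abs(sp$freq - f0))
  sp$coh[i]
}

paired_t_brute <- function(a, b) {
  d <- a - b
  n <- length(d)
  tt <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = tt, p = 2 * stats::pt(-abs(tt), df = n - 1))
}
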