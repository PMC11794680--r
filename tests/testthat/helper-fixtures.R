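# Shared fixture builders: everything is generated in code, no stored data.

# uniform beat train: n intervals of ibi_ms, first opening beat at start_ms
uniform_series <- function(n, ibi_ms = 800, start_ms = 0, ...) {
  peaks <- start_ms + ibi_ms * (0:n)
  peaks_to_ibis(peaks, ...)
}

# beat train whose IBI follows a sinusoid: ibi(t) = mean + amp*sin(2*pi*f*t)
tone_series <- function(duration_s = 300, mean_ms = 900, amp_ms = 50,
                        freq_hz = 0.25, start_ms = 0, ...) {
  t <- start_ms
  onsets <- numeric(0)
  ibis <- numeric(0)
  while (t <= start_ms + duration_s * 1000) {
    ibi <- round(mean_ms + amp_ms * sin(2 * pi * freq_hz * t / 1000))
    t <- t + ibi
    if (t > start_ms + duration_s * 1000) break
    onsets <- c(onsets, t)
    ibis <- c(ibis, ibi)
  }
  ibi_series(onsets, ibis, ...)
}

# random plausible series (seeded by caller)
random_series <- function(n, mean_ms = 850, sd_ms = 40, start_ms = 0, ...) {
  ibis <- round(pmax(350, rnorm(n, mean_ms, sd_ms)))
  peaks_to_ibis(start_ms + cumsum(c(0, ibis)), ...)
}
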