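# shared in-code fixtures

grid30 <- function(n, start = 0) epoch_grid(start, n, 30L)

sw <- function(labels, source = "test", start = 0) {
  sleepwake(grid30(length(labels), start), labels, source)
}

# random sleep/wake label vector guaranteed to contain both classes
rand_labels <- function(n, p_sleep = 0.7) {
  l <- ifelse(stats::runif(n) < p_sleep, "sleep", "wake")
  if (!any(l == "sleep")) l[sample.int(n, 1L)] <- "sleep"
  if (!any(l == "wake")) l[sample.int(n, 1L)] <- "wake"
  l
}

# single-axis sinusoid recording at `fs` Hz with gravity on z
sine_recording <- function(freq_hz, amp_g, minutes = 1, fs = 40) {
  n <- round(fs * 60 * minutes)
  tt <- (seq_len(n) - 1L) / fs
  raw_recording("sine", 0, fs, amp_g * sin(2 * pi * freq_hz * tt),
                rep(0, n), rep(1, n))
}

const_recording <- function(x = 0, y = 0, z = 1, n = 2400, fs = 40) {
  raw_recording("const", 0, fs, rep(x, n), rep(y, n), rep(z, n))
}
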