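# Shared fixture builders: everything is generated in code at test time.

# Single-channel recording holding a pure sine, for filter-response oracles.
sine_rec <- function(freq, fs = 125, dur = 10, amp = 1, channels = "Pz",
                     units = "uV") {
  tt <- (seq_len(round(dur * fs)) - 1) / fs
  mat <- matrix(rep(amp * sin(2 * pi * freq * tt), length(channels)),
                ncol = length(channels))
  recording(mat, channels, fs = fs, units = units)
}

rms <- function(x) sqrt(mean(x^2))

# Small two-segment schedule for short synthetic sessions (10 min).
short_schedule <- function() {
  lap_schedule(
    data.frame(segment = 1:2, t_start_s = c(60, 400), t_end_s = c(120, 460)),
    task_start = 0, task_end = 600
  )
}

# Greedy nearest matching of detected events to ground-truth times.
match_events <- function(detected, truth, tol = 0.15) {
  vapply(truth, function(t) {
    if (!length(detected)) return(NA_real_)
    i <- which.min(abs(detected - t))
    if (abs(detected[i] - t) <= tol) detected[i] else NA_real_
  }, numeric(1))
}
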