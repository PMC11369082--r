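# Shared fixtures, built in code at test time.

# One z-scored synthetic trial for a named study condition; onsets are the
# per-condition group-mean latencies after the stimulus at 10 s.
study_conditions <- list(
  respiration = list(onset = 1.8, amp = 5),
  ph          = list(onset = 2.0, amp = -5),
  velocity    = list(onset = 2.9, amp = -5),
  dilation    = list(onset = 5.8, amp = 5)
)

make_z_trial <- function(cond, seed, noise_sd = 1, fs = 10) {
  cc <- study_conditions[[cond]]
  g <- gen_response_trace(
    response_model = list(amplitude = cc$amp, tau_rise = 0.5, tau_decay = 10),
    onset_true = 10 + cc$onset, noise_sd = noise_sd,
    duration = 40, fs = fs, seed = seed)
  zscore(g$trace)
}

# A small movie with a centred bright disk of given radius (px) per frame.
make_disk_movie <- function(radius, n_frames = 3, size = 48) {
  fr <- outer(seq_len(size) - (size + 1) / 2, seq_len(size) - (size + 1) / 2,
              function(r, c) as.numeric(r^2 + c^2 <= radius^2))
  movie <- array(0, c(n_frames, size, size))
  for (i in seq_len(n_frames)) movie[i, , ] <- fr
  movie
}
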