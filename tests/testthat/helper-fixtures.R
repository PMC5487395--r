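# Shared builders for small synthetic fixtures; everything is generated in
# code at test time.

toy_montage <- function(n = 9) default_montage()[seq_len(n), ]

# Epoch set holding explicit data, with minimal metadata.
toy_epochs <- function(data, srate = 256, tmin = -500, rt = NULL,
                       cond = "compatible") {
  n_tr <- dim(data)[1]
  n_s <- dim(data)[3]
  time_ms <- tmin + (seq_len(n_s) - 1) * 1000 / srate
  mo <- default_montage()[seq_len(dim(data)[2]), ]
  meta <- data.frame(subject = 1, group = "ADD",
                     compatibility = rep_len(cond, n_tr),
                     rt_ms = if (is.null(rt)) rep(400, n_tr) else rt,
                     correct = TRUE, retained = TRUE)
  epoch_set(data, srate, time_ms, mo, meta)
}

# One simulated subject pushed through the preprocessing front end.
sim_subject_epochs <- function(preset, subject, seed, n_blocks = 2,
                               trials_per_block = 30, noise = NULL,
                               templates = default_templates(),
                               srate = 256, tmin = -2000, tmax = 2000) {
  sch <- generate_trial_schedule(n_blocks, trials_per_block, seed = seed)
  beh <- simulate_behavior(sch, preset, seed = seed + 1, subject = subject)
  simulate_epochs(sch, beh, preset, templates = templates,
                  seed = seed + 2, subject = subject, srate_hz = srate,
                  tmin_ms = tmin, tmax_ms = tmax,
                  noise_level = if (is.null(noise)) preset$noise_level
                                else noise)
}

# A deterministic noise-free zero-jitter subject (used by the degenerate
# equivalence checks).
zero_jitter_setup <- function(c_amp = 35, c_latency = 530, n_trials = 30,
                              seed = 5) {
  p <- group_preset("ADD")
  p$rt_within_sd[] <- 0
  p$rt_cond_sd <- 0
  subj <- draw_subjects(p, n = 1, seed = seed)
  subj$c_jitter_sd <- 0
  subj$c_latency <- c_latency
  subj$c_amp_compatible <- c_amp
  subj$c_amp_incompatible <- c_amp
  subj$accuracy_compatible <- 1
  subj$accuracy_incompatible <- 1
  tpl <- default_templates(jitter_scale = 0)
  sch <- generate_trial_schedule(1, n_trials, seed = seed)
  beh <- simulate_behavior(sch, p, seed = seed + 1, subject = subj)
  ep <- simulate_epochs(sch, beh, p, templates = tpl, seed = seed + 2,
                        subject = subj, noise_level = 0)
  list(preset = p, subject = subj, schedule = sch, behavior = beh,
       epochs = ep)
}
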