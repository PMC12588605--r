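# Shared fixtures and independent oracles, all generated in code.

# A small hand-written trial table covering both ears and conditions.
make_small_table <- function() {
  df <- data.frame(
    participant_id = "p01", experiment = "exp1", block = 1L,
    trial_index = 1:8, ear = rep(c("L", "R"), 4),
    condition = rep(c("f1", "f2"), each = 4),
    delay_s = c(0.3, 0.6, 0.9, 1.2, 0.45, 0.75, 1.05, 1.5),
    response = c("opt1", "opt1", "opt2", "opt1", "opt1", "opt2", "opt2",
                 "opt2"),
    correct = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE),
    rt_s = c(0.49, 0.64, 0.81, 1, 0.36, 0.25, 1.21, 0.16),
    stim_param = 1, dual_task = FALSE, dot_change = FALSE,
    dot_response = "none", stringsAsFactors = FALSE
  )
  trial_table(df)
}

# Simulate a small cohort of observers on a common design.
sim_cohort <- function(n_participants, params, seed = 1L,
                       n_blocks = 8L, trials_per_block = 190L) {
  tabs <- lapply(seq_len(n_participants), function(i) {
    cfg <- design_config("exp1", n_blocks = n_blocks,
                         trials_per_block = trials_per_block,
                         seed = seed + 13L * i)
    d <- generate_design(cfg, participant_id = sprintf("p%02d", i))
    simulate_observer(d, params, seed = seed + 7919L * i)
  })
  tab <- do.call(rbind, tabs)
  reference_delays(transform_rt(filter_outliers(trial_table(tab))))
}

# Brute-force O(N^2) DFT amplitude oracle.
dft_amplitude <- function(x, k) {
  n <- length(x)
  vapply(k, function(kk) {
    re <- sum(x * cos(-2 * pi * kk * (0:(n - 1)) / n))
    im <- sum(x * sin(-2 * pi * kk * (0:(n - 1)) / n))
    sqrt(re^2 + im^2)
  }, numeric(1))
}

# Step-up Benjamini-Hochberg oracle, written independently of p.adjust.
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}
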