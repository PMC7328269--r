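# Small shared fixtures, built in code at test time.

tiny_profile <- function(n = 500L, seed = 101L) {
  emulate_parameter_profile(n, seed = seed)
}

# mid-range profile that never clamps, for exact-arithmetic checks
flat_profile <- function(n = 200L, mean_beta = 0.5, sd_beta = 0.02) {
  tibble::tibble(
    probe_id = sprintf("cg%08d", seq_len(n)),
    mean_beta = mean_beta,
    sd_beta = sd_beta,
    design_type = "II",
    platform = "EPIC"
  )
}

layout48 <- function(design = "random", seed = 1L) {
  assign_groups(build_layout(48L), design, seed)
}

# brute-force Benjamini-Hochberg step-up, the independent oracle
bh_brute_force <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, m * p[o[i]] / i)
    q[o[i]] <- prev
  }
  q
}
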