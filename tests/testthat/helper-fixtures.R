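# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# default-calibrated dataset (10 subjects x 2 tasks x 450 trials), normalized
fixture_trials <- function() {
  if (is.null(.fixture_env$trials)) {
    .fixture_env$trials <-
      normalize_localizations(simulate_dataset(sim_params(seed = 424242L)))
  }
  .fixture_env$trials
}

# deterministic subject profile with explicit fields (no sampling)
make_profile <- function(bias = 0, task_bias = c(0, 0),
                         sigma_a_uni = 7.5, sigma_v_uni = 2.8,
                         sigma_a_bi = 5.8, sigma_v_bi = 3.1,
                         w = 0.95,
                         mu_logT = c(a_uni = log(0.95), a_bi = log(0.80),
                                     v_uni = log(0.75), v_bi = log(0.62)),
                         delta_ecc = 0.1, delta_ecc_primary = 0,
                         sigma_logT = 0.41, subject_T_offset = 0) {
  structure(list(bias = bias, task_bias = task_bias,
                 sigma_a_uni = sigma_a_uni, sigma_v_uni = sigma_v_uni,
                 sigma_a_bi = sigma_a_bi, sigma_v_bi = sigma_v_bi,
                 w = w, mu_logT = mu_logT, delta_ecc = delta_ecc,
                 delta_ecc_primary = delta_ecc_primary,
                 sigma_logT = sigma_logT,
                 subject_T_offset = subject_T_offset),
            class = "avl_profile")
}

# parameters with all between-subject variability and noise collapsed
noiseless_params <- function(seed = 1L, n_subjects = 3L, n_reps = 3L,
                             w_mean = 0.9) {
  sim_params(n_subjects = n_subjects, n_reps = n_reps, seed = seed,
             bias_sd = 0, task_bias_sd = 0,
             sigma_a_uni = 1e-9, sigma_v_uni = 1e-9,
             sigma_a_bi = 1e-9, sigma_v_bi = 1e-9,
             sigma_sd_frac = 0, w_mean = w_mean, w_sd = 0,
             sigma_logT = 1e-9, t_offset_sd = 0)
}

# entropy of a probability vector/array, computed independently of the
# package (test-side oracle)
oracle_entropy <- function(p) {
  p <- as.numeric(p); p <- p[p > 0]
  -sum(p * log2(p))
}

# brute-force normalized MI from an explicit joint pmf (double sum)
oracle_nmi <- function(joint) {
  px <- rowSums(joint); py <- colSums(joint)
  mi <- 0
  for (i in seq_len(nrow(joint))) for (j in seq_len(ncol(joint))) {
    if (joint[i, j] > 0)
      mi <- mi + joint[i, j] * log2(joint[i, j] / (px[i] * py[j]))
  }
  h <- oracle_entropy(joint)
  if (h == 0) 0 else mi / h
}

# expand an explicit pmf into a sample with exactly proportional counts
sample_from_pmf <- function(joint, n_per_unit) {
  idx <- which(joint > 0, arr.ind = TRUE)
  counts <- round(joint[joint > 0] * n_per_unit)
  do.call(rbind, lapply(seq_len(nrow(idx)), function(k) {
    matrix(rep(idx[k, ], counts[k]), ncol = ncol(idx), byrow = TRUE)
  }))
}
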