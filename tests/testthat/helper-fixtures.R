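# Shared builders and independent oracles for the test suite.

# the study's post-dose sampling schedule (h)
paper_schedule <- function() {
  c(c(5, 10, 20, 30, 45, 60) / 60, c(1.5, 2, 4, 6, 8, 10))
}

# profile generated from known parameters, optional proportional noise
make_profile <- function(params, dose, noise_sd = 0, lloq = 0.25,
                         analyte = "iohexol", animal_id = "A1",
                         group = "control", occasion = "M1",
                         times = paper_schedule()) {
  f <- predict_concentration(params, dose, times)
  obs <- f * (1 + stats::rnorm(length(f), 0, noise_sd))
  blq <- obs < lloq
  plasma_profile(animal_id, group, occasion, analyte, dose, 14.1,
                 times, ifelse(blq, NA_real_, obs), blq, lloq)
}

# brute-force sign-pattern enumeration oracle for the signed-rank test
signed_rank_enum_p <- function(d, alternative) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% r
  pg <- mean(w_all >= w_obs)
  pl <- mean(w_all <= w_obs)
  switch(alternative,
         greater = pg, less = pl,
         two.sided = min(1, 2 * min(pg, pl)))
}

# brute-force arrangement enumeration oracle for the Mann-Whitney U test
mann_whitney_enum_p <- function(x, y, alternative) {
  n <- length(x); m <- length(y)
  pooled <- rank(c(x, y))
  u_obs <- sum(pooled[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  ranks <- rank(c(x, y))  # no ties assumed: ranks are 1..n+m
  u_all <- apply(combos, 2, function(idx) sum(seq_len(n + m)[idx])) -
    n * (n + 1) / 2
  pg <- mean(u_all >= u_obs)
  pl <- mean(u_all <= u_obs)
  switch(alternative,
         greater = pg, less = pl,
         two.sided = min(1, 2 * min(pg, pl)))
}

# small cohort config used by I/O and pipeline tests
small_config <- function(...) {
  simulation_config(n_control = 3L, n_treatment = 3L, ...)
}
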