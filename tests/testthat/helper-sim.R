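# Shared fixtures, built in code at test time.

darkness <- function() light_schedule()

# active fraction identically zero on a frame grid
zero_activity <- function(duration_s, fps = 67) {
  t <- seq(0, duration_s, by = 1 / fps)
  time_series(t, rep(0, length(t)))
}

# standard 1 s pulse protocol used across tests
std_pulse <- function(onset = 10, wavelength = 520, irradiance = 0.5) {
  light_schedule(onset, onset + 1, wavelength, irradiance)
}

# a default MosOpn3-like arrest trial (noiseless unless stated)
arrest_trial <- function(seed = 7, noise_sd = 0, phase0 = 0.3,
                         duration_s = 40, onset = 10) {
  reg <- opsin_regime("mosopn3_like")
  a <- simulate_photostate(
    reg$photostate, std_pulse(onset, reg$stim_wavelength_nm),
    duration_s, 1 / 67
  )
  simulate_heart_trial(
    heart_sim_params(noise_sd = noise_sd), a, duration_s,
    seed = seed, stim_onset_s = onset, phase0 = phase0
  )
}

# independent brute-force two-sided rank-sum p by full enumeration of all
# group labelings (no ties assumed)
enumerate_ranksum_p <- function(a, b) {
  x <- c(a, b)
  n <- length(x)
  na <- length(a)
  r <- rank(x)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  labelings <- utils::combn(n, na)
  u_all <- apply(labelings, 2, function(idx) {
    sum(r[idx]) - na * (na + 1) / 2
  })
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# independent brute-force trial classification used as locomotion oracle
oracle_classify <- function(bouts, onset, window = 8) {
  pre <- FALSE
  best <- NULL
  for (i in seq_len(nrow(bouts))) {
    if (bouts$start_s[i] < onset) pre <- TRUE
    if (bouts$start_s[i] >= onset &&
      (is.null(best) || bouts$start_s[i] < best$start_s)) {
      best <- bouts[i, ]
    }
  }
  if (is.null(best)) {
    return(list(
      pre = pre, induced = FALSE, latency = NA_real_,
      duration = NA_real_, strength = NA_real_
    ))
  }
  lat <- best$start_s - onset
  list(
    pre = pre, induced = lat <= window, latency = lat,
    duration = best$end_s - best$start_s, strength = best$peak_displacement
  )
}

# random non-overlapping bout table
random_bouts <- function(n, t_max = 25) {
  if (n == 0) {
    return(data.frame(
      start_s = numeric(0), end_s = numeric(0),
      peak_displacement = numeric(0)
    ))
  }
  starts <- sort(stats::runif(n, 0, t_max))
  durs <- stats::runif(n, 0.2, 2)
  for (i in seq_len(n - 1)) {
    durs[i] <- min(durs[i], (starts[i + 1] - starts[i]) * 0.9)
  }
  data.frame(
    start_s = starts, end_s = starts + durs,
    peak_displacement = stats::runif(n, 0.05, 0.5)
  )
}
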