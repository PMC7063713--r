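# Shared fixtures, all generated in code.

# exhaustive minimum-cost path enumeration; the independent oracle for
# trace_boundary on small instances
brute_force_path <- function(cost, max_step) {
  n <- nrow(cost); m <- ncol(cost)
  best <- NULL; best_cost <- Inf
  rec <- function(path, acc) {
    j <- length(path)
    if (j == m) {
      if (acc < best_cost) {
        best_cost <<- acc; best <<- path
      }
      return()
    }
    r <- path[j]
    for (nr in max(1, r - max_step):min(n, r + max_step)) {
      rec(c(path, nr), acc + cost[nr, j + 1])
    }
  }
  for (r0 in seq_len(n)) rec(r0, cost[r0, 1])
  best
}

# minimal clustered three-group cohort for null / power simulations:
# a fraction of patients contributes two correlated eyes
clustered_groups <- function(n_eyes = c(38, 36, 38),
                             means = c(90, 90, 90),
                             sds = c(10, 10, 10),
                             rho_eye = 0.6, bilateral = 0.65) {
  groups <- c("control", "nonDON", "DON")
  do.call(rbind, lapply(1:3, function(gi) {
    np <- max(1, round(n_eyes[gi] / (1 + bilateral)))
    nbi <- n_eyes[gi] - np
    pidx <- rep(seq_len(np), ifelse(seq_len(np) <= nbi, 2, 1))
    zp <- rnorm(np); ze <- rnorm(length(pidx))
    data.frame(
      patient_id = paste0(groups[gi], "_", pidx),
      group = groups[gi],
      y = means[gi] + sds[gi] * (sqrt(rho_eye) * zp[pidx] +
                                   sqrt(1 - rho_eye) * ze))
  }))
}

# one 18-meridian phantom eye (B-scans plus truth boundary sets)
make_eye_phantom <- function(seed = 1, speckle = 0.1) {
  angles <- seq(0, 170, by = 10)
  lapply(angles, function(a) {
    ph <- make_bscan_phantom(shape = "pit", amplitude = 12,
                             speckle = speckle, blur_sigma = 1,
                             meridian_angle = a, seed = seed * 1000 + a)
    ph
  })
}
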