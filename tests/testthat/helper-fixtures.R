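# Shared fixtures and independent oracles used across test files.

# A small trap grid with full operation.
tiny_traps <- function(J_side = 2, spacing = 1000, K = 5) {
  make_trap_grid(J_side, J_side, spacing, K = K)
}

# Write a trap deployment CSV with setup/retrieval dates and return its path.
write_trap_csv <- function(n, window, setup = NULL, retrieval = NULL,
                           spacing = 1000) {
  path <- tempfile(fileext = ".csv")
  df <- data.frame(
    station = sprintf("S%02d", seq_len(n)),
    x = ((seq_len(n) - 1) %% 8) * spacing,
    y = ((seq_len(n) - 1) %/% 8) * spacing,
    setup_date = if (is.null(setup)) rep(window[1], n) else setup,
    retrieval_date = if (is.null(retrieval)) rep(window[2], n) else retrieval)
  write.csv(df, path, row.names = FALSE)
  path
}

# The tiny discretized instance used for the exhaustive-enumeration oracle:
# 2 traps, M = 3, 25 candidate activity-center sites, K = 1, all parameters
# fixed.  Returns the dataset, the site list, and the fixed parameter values.
tiny_discrete_instance <- function() {
  traps <- trap_array(c("A", "B"), rbind(c(0, 0), c(1000, 0)),
                      matrix(1, 2, 1))
  sites <- as.matrix(expand.grid(x = seq(-500, 1500, by = 500),
                                 y = seq(-1000, 1000, by = 500)))
  ss <- build_state_space(traps, 2000)
  y_id <- array(0L, c(1, 2, 1)); y_id[1, 1, 1] <- 1L
  n_noid <- matrix(c(1L, 1L), 2, 1)
  cap <- capture_data(y_id, n_noid, "IND1", traps = traps)
  list(dataset = scr_dataset(traps, cap, ss), sites = sites, traps = traps,
       lambda0 = 0.5, sigma = 800, theta = 0.7, psi = 0.5)
}

# Brute-force posterior P(N = 1..3) for tiny_discrete_instance(), summing
# the complete-data probability over every membership vector, every
# assignment of the two unidentified counts to eligible individuals, and
# (factorized) every candidate site per individual.  Independent of the
# sampler code path.
enumerate_tiny_posterior <- function(inst) {
  sites <- inst$sites
  d <- sqrt(outer(sites[, 1], inst$traps$xy[, 1], "-")^2 +
              outer(sites[, 2], inst$traps$xy[, 2], "-")^2)
  lam_site <- inst$lambda0 * exp(-d^2 / (2 * inst$sigma^2))  # 25 x 2
  yid_i <- rbind(c(1, 0), c(0, 0), c(0, 0))
  pN <- numeric(3)
  for (z2 in 0:1) for (z3 in 0:1) {
    z <- c(1, z2, z3)  # individual 1 has an identified detection
    elig <- which(z == 1)
    for (a1 in elig) for (a2 in elig) {
      u <- matrix(0, 3, 2)
      u[a1, 1] <- u[a1, 1] + 1
      u[a2, 2] <- u[a2, 2] + 1
      yfull <- yid_i + u
      w <- prod(vapply(1:3, function(i) {
        if (z[i] == 0) {
          if (any(yfull[i, ] > 0)) return(0)
          return(1)  # site sum = 1 with no likelihood term
        }
        sum(vapply(1:25, function(k)
          1 / 25 * prod(dpois(yfull[i, ], lam_site[k, ])) *
            prod(dbinom(yid_i[i, ], yfull[i, ], inst$theta)),
          numeric(1)))
      }, numeric(1)))
      w <- w * inst$psi^sum(z) * (1 - inst$psi)^(3 - sum(z))
      pN[sum(z)] <- pN[sum(z)] + w
    }
  }
  pN / sum(pN)
}

# Naive, loop-based complete-data log density; deliberately independent of
# log_complete_likelihood()'s vectorized implementation.
naive_log_density <- function(state, captures, traps, state_space, priors) {
  eff <- rowSums(traps$operation)
  M <- length(state$z)
  J <- nrow(traps$xy)
  y_id_all <- rbind(apply(captures$y_id, c(1, 2), sum),
                    matrix(0, M - dim(captures$y_id)[1], J))
  n_noid <- rowSums(captures$n_noid)
  ll <- 0
  for (j in seq_len(J)) {
    if (sum(state$y_full[, j] - y_id_all[, j]) != n_noid[j]) return(-Inf)
  }
  for (i in seq_len(M)) {
    if (!in_state_space(state_space, state$s[i, 1], state$s[i, 2]))
      return(-Inf)
    ll <- ll + dbinom(state$z[i], 1, state$psi, log = TRUE)
    ll <- ll - log(state_space$area_km2 * 1e6)
    for (j in seq_len(J)) {
      yf <- state$y_full[i, j]
      if (state$z[i] == 0) {
        if (yf > 0) return(-Inf)
        next
      }
      d <- sqrt(sum((state$s[i, ] - traps$xy[j, ])^2))
      lam <- eff[j] * state$lambda0 * exp(-d^2 / (2 * state$sigma^2))
      ll <- ll + dpois(yf, lam, log = TRUE)
      ll <- ll + dbinom(y_id_all[i, j], yf, state$theta, log = TRUE)
    }
  }
  ll + dunif(state$lambda0, priors$lambda0[1], priors$lambda0[2], log = TRUE) +
    dunif(state$sigma, priors$sigma[1], priors$sigma[2], log = TRUE) +
    dbeta(state$theta, priors$theta[1], priors$theta[2], log = TRUE) +
    dbeta(state$psi, priors$psi[1], priors$psi[2], log = TRUE)
}

# Fast small study-emulating simulation + fit used by several tests.
quick_fit <- function(seed, n_iter = 6000, n_burnin = 2000, M = 60,
                      n_chains = 2, model = "rtscr", theta = 0.87) {
  des <- jaguar_design()
  tr <- des$truth
  tr$theta <- theta
  tr$seed <- seed
  sim <- simulate_dataset(tr, des$traps, des$state_space)
  fitter <- if (model == "rtscr") fit_rtscr else fit_scr
  fit <- suppressWarnings(fitter(
    sim$dataset,
    config = mcmc_config(n_chains = n_chains, n_iter = n_iter,
                         n_burnin = n_burnin, thin = 5, M = M, seed = seed)))
  list(sim = sim, fit = fit)
}
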