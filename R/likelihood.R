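#' Half-normal encounter rate
#'
#' `lambda0 * exp(-d^2 / (2 sigma^2))`: the expected number of encounters per
#' occasion for an individual whose activity center lies `d` meters from the
#' detector.
#'
#' @param d distance(s) in meters (>= 0); vectors and matrices are accepted.
#' @param lambda0 baseline rate at distance zero (> 0).
#' @param sigma half-normal scale in meters (> 0).
#' @return rates with the shape of `d`.
#' @export
encounter_rate <- function(d, lambda0, sigma) {
  if (any(d < 0)) stop("'d' must be nonnegative")
  if (lambda0 <= 0) stop("'lambda0' must be positive")
  if (sigma <= 0) stop("'sigma' must be positive")
  lambda0 * exp(-d^2 / (2 * sigma^2))
}

#' Distance matrix from activity centers to traps
#' @param s n x 2 matrix of activity centers (meters).
#' @param traps a [trap_array()].
#' @return n x J distance matrix, meters.
#' @export
ac_trap_distance <- function(s, traps) {
  s <- matrix(s, ncol = 2)
  sqrt(outer(s[, 1], traps$xy[, 1], "-")^2 +
         outer(s[, 2], traps$xy[, 2], "-")^2)
}

# Collapse capture data to the trap-total sufficient statistics used by the
# sampler: y_id (n_id x J), n_noid (J), effort (J).
collapse_captures <- function(captures, traps) {
  J <- n_traps(traps)
  n_id <- dim(captures$y_id)[1]
  y_id <- if (n_id > 0) apply(captures$y_id, c(1, 2), sum) else numeric(0)
  y_id <- matrix(as.integer(y_id), nrow = n_id, ncol = J)
  list(y_id = y_id,
       n_noid = as.integer(rowSums(captures$n_noid)),
       effort = rowSums(traps$operation))
}

#' Complete-data log likelihood of an rt-SCR latent state
#'
#' Sums the Poisson log-mass of the full (identified + latent unidentified)
#' trap totals, the binomial log-mass of the identified counts given the full
#' counts, the Bernoulli membership terms, the uniform activity-center prior,
#' and the parameter log-priors.  Any state violating the model constraints
#' (counts below the identified counts, detections for non-members, activity
#' centers outside the state space, trap sums not matching the observed
#' unidentified counts, parameters outside their prior support) returns
#' `-Inf` rather than throwing, so the value can be used directly in
#' Metropolis-Hastings ratios.
#'
#' @param state list with elements `lambda0`, `sigma`, `theta`, `psi`,
#'   `z` (length M), `s` (M x 2), `y_full` (M x J trap totals).
#' @param captures a [capture_data()]; its first `n_id` individuals
#'   correspond to the first rows of the state.
#' @param traps a [trap_array()].
#' @param state_space a [build_state_space()] result.
#' @param priors a [rtscr_priors()] list.
#' @return scalar log probability (possibly `-Inf`).
#' @export
log_complete_likelihood <- function(state, captures, traps, state_space,
                                    priors = rtscr_priors()) {
  cc <- collapse_captures(captures, traps)
  M <- length(state$z)
  J <- n_traps(traps)
  y_id <- rbind(cc$y_id, matrix(0L, M - nrow(cc$y_id), J))
  y_full <- matrix(state$y_full, M, J)
  z <- state$z
  s <- matrix(state$s, M, 2)

  if (state$lambda0 < priors$lambda0[1] || state$lambda0 > priors$lambda0[2] ||
      state$sigma < priors$sigma[1] || state$sigma > priors$sigma[2] ||
      state$theta < 0 || state$theta > 1 ||
      state$psi < 0 || state$psi > 1)
    return(-Inf)
  if (any(y_full < y_id)) return(-Inf)
  if (any(y_full[z == 0, ] > 0)) return(-Inf)
  u_sums <- colSums(y_full - y_id)
  if (!all(u_sums == cc$n_noid)) return(-Inf)
  if (!all(in_state_space(state_space, s[, 1], s[, 2]))) return(-Inf)

  lam <- state$lambda0 *
    exp(-ac_trap_distance(s, traps)^2 / (2 * state$sigma^2)) *
    matrix(cc$effort, M, J, byrow = TRUE)
  live <- which(z == 1)
  ll <- sum(dpois(y_full[live, , drop = FALSE],
                  lam[live, , drop = FALSE], log = TRUE))
  ll <- ll + sum(dbinom(y_id[live, , drop = FALSE],
                        y_full[live, , drop = FALSE], state$theta,
                        log = TRUE))
  ll <- ll + sum(dbinom(z, 1, state$psi, log = TRUE))
  ll <- ll - M * log(state_space$area_km2 * 1e6)  # uniform s prior
  ll <- ll + dunif(state$lambda0, priors$lambda0[1], priors$lambda0[2],
                   log = TRUE)
  ll <- ll + dunif(state$sigma, priors$sigma[1], priors$sigma[2], log = TRUE)
  ll <- ll + dbeta(state$theta, priors$theta[1], priors$theta[2], log = TRUE)
  ll <- ll + dbeta(state$psi, priors$psi[1], priors$psi[2], log = TRUE)
  ll
}

#' Multinomial allocation of counts with given weights
#'
#' Draws one multinomial vector of size `n` with probabilities proportional
#' to `weights`.  Used for the exact full-conditional reallocation of
#' unidentified counts: Poisson thinning makes the per-individual
#' unidentified counts at a trap conditionally multinomial given their sum,
#' with weights `z_i * lambda_ij`.
#'
#' @param n total count to allocate (>= 0).
#' @param weights nonnegative weights; at least one must be positive.
#' @return integer vector summing to `n`.
#' @export
allocate_counts <- function(n, weights) {
  allocate_counts_cpp(as.integer(n), as.numeric(weights))
}

#' Resample the latent allocation of unidentified counts
#'
#' One Gibbs update of the latent full counts: for every trap with
#' unidentified detections, the counts are reallocated among current
#' population members proportionally to their encounter rates, and
#' `y_full = y_id + allocation` is rebuilt.  The constraint
#' `colSums(y_full - y_id) == n_noid` holds on exit by construction.
#'
#' @param state latent state as in [log_complete_likelihood()].
#' @param captures a [capture_data()].
#' @param traps a [trap_array()].
#' @return the state with a new `y_full`.
#' @export
update_allocation <- function(state, captures, traps) {
  cc <- collapse_captures(captures, traps)
  M <- length(state$z)
  J <- n_traps(traps)
  y_id <- rbind(cc$y_id, matrix(0L, M - nrow(cc$y_id), J))
  lam <- state$lambda0 *
    exp(-ac_trap_distance(matrix(state$s, M, 2), traps)^2 /
          (2 * state$sigma^2)) *
    matrix(cc$effort, M, J, byrow = TRUE)
  y_full <- y_id
  for (j in seq_len(J)) {
    if (cc$n_noid[j] == 0) next
    w <- state$z * lam[, j]
    if (sum(w) <= 0) {
      # no eligible contributor: activate the best-placed individual
      k <- which.max(lam[, j])
      state$z[k] <- 1L
      w <- state$z * lam[, j]
    }
    y_full[, j] <- y_full[, j] + allocate_counts(cc$n_noid[j], w)
  }
  state$y_full <- y_full
  state
}
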