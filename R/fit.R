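#' Prior specification for the rt-SCR model
#'
#' Vague defaults in line with common SCR practice: uniform priors on the
#' detection parameters and Beta(1, 1) on the probabilities.  The upper
#' bound of the sigma prior defaults (at fit time) to the state-space buffer
#' width, or to half the largest state-space extent when the buffer is zero.
#'
#' @param lambda0 length-2 range of the uniform prior on the baseline rate.
#' @param sigma length-2 range of the uniform prior on sigma (meters);
#'   `NA` upper bound = resolve from the state space at fit time.
#' @param theta Beta(a, b) shape parameters for the identification
#'   probability.
#' @param psi Beta(a, b) shape parameters for the data-augmentation
#'   membership probability.
#' @return list of class `rtscr_priors`.
#' @export
rtscr_priors <- function(lambda0 = c(0, 5), sigma = c(0, NA),
                         theta = c(1, 1), psi = c(1, 1)) {
  structure(list(lambda0 = lambda0, sigma = sigma, theta = theta, psi = psi),
            class = "rtscr_priors")
}

#' MCMC configuration
#'
#' @param n_chains number of independent chains.
#' @param n_iter iterations per chain (including burn-in).
#' @param n_burnin burn-in iterations discarded from each chain.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param M data-augmentation size; `NULL` = four times the number of
#'   identified individuals, with a floor of 50.
#' @param seed integer seed; chain c runs under a seed derived from it.
#' @param adapt adapt proposal scales to 25-45% acceptance during burn-in
#'   (frozen afterwards).
#' @param retain_latent keep thinned traces of the activity centers and
#'   membership indicators (needed for GoF and density surfaces).
#' @param allocation `"gibbs"` for the exact multinomial full conditional of
#'   the unidentified counts (default), `"mh"` for a single-unit
#'   Metropolis-Hastings variant kept for cross-checking.
#' @return list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3, n_iter = 20000, n_burnin = 5000,
                        thin = 10, M = NULL, seed = 1, adapt = TRUE,
                        retain_latent = TRUE,
                        allocation = c("gibbs", "mh")) {
  stopifnot(n_burnin < n_iter, thin >= 1, n_chains >= 1)
  structure(list(n_chains = n_chains, n_iter = n_iter, n_burnin = n_burnin,
                 thin = thin, M = M, seed = as.integer(seed), adapt = adapt,
                 retain_latent = retain_latent,
                 allocation = match.arg(allocation)),
            class = "mcmc_config")
}

# Coarse-grid initializer: with detected individuals pinned at the
# count-weighted centroids of their detection traps, maximize the
# complete-data Poisson likelihood over a lambda0 x sigma grid.
init_detection_params <- function(y_id, n_noid, effort, traps, priors_res) {
  n_id <- nrow(y_id)
  tot <- sum(y_id) + sum(n_noid)
  ext <- max(apply(traps$xy, 2, function(v) diff(range(v))), 1)
  sig0 <- ext / 8
  if (n_id > 0) {
    mm <- max_move_init(y_id, traps)
    if (is.finite(mm) && mm > 0) sig0 <- mm / 2
  }
  lam0 <- max(tot, 1) / max(max(n_id, 1) * mean(effort[effort > 0]), 1)
  if (n_id == 0)
    return(list(lambda0 = clamp(lam0, priors_res$lambda0),
                sigma = clamp(sig0, priors_res$sigma)))
  cent <- t(vapply(seq_len(n_id), function(i) {
    w <- y_id[i, ]
    c(sum(w * traps$xy[, 1]), sum(w * traps$xy[, 2])) / sum(w)
  }, numeric(2)))
  d2 <- (outer(cent[, 1], traps$xy[, 1], "-")^2 +
           outer(cent[, 2], traps$xy[, 2], "-")^2)
  lgrid <- lam0 * 2^seq(-3, 3, length.out = 13)
  sgrid <- sig0 * 2^seq(-2, 2, length.out = 13)
  best <- c(lam0, sig0); best_ll <- -Inf
  E <- matrix(effort, n_id, length(effort), byrow = TRUE)
  for (sg in sgrid) {
    base <- exp(-d2 / (2 * sg^2)) * E
    for (lm in lgrid) {
      lam <- lm * base
      ll <- sum(y_id * log(pmax(lam, 1e-300))) - sum(lam)
      if (ll > best_ll) { best_ll <- ll; best <- c(lm, sg) }
    }
  }
  list(lambda0 = clamp(best[1], priors_res$lambda0),
       sigma = clamp(best[2], priors_res$sigma))
}

clamp <- function(x, range) min(max(x, range[1] + 1e-9 * diff(range)),
                                range[2] - 1e-9 * diff(range))

max_move_init <- function(y_id, traps) {
  dists <- apply(y_id, 1, function(y) {
    j <- which(y > 0)
    if (length(j) < 2) return(NA_real_)
    max(dist(traps$xy[j, , drop = FALSE]))
  })
  if (all(is.na(dists))) return(NA_real_)
  mean(dists, na.rm = TRUE)
}

resolve_priors <- function(priors, state_space) {
  if (is.na(priors$sigma[2])) {
    b <- state_space$buffer_width
    ext <- max(state_space$bounds[2] - state_space$bounds[1],
               state_space$bounds[4] - state_space$bounds[3])
    priors$sigma[2] <- if (!is.null(b) && b > 0) b else ext / 2
  }
  priors
}

#' Fit the random-thinning SCR model
#'
#' Metropolis-within-Gibbs sampling with data augmentation: random-walk
#' Metropolis for `lambda0`, `sigma` and the activity centers, conjugate
#' Beta draws for `theta` and `psi`, Gibbs membership updates, and exact
#' multinomial reallocation of the latent unidentified counts (Poisson
#' thinning makes them conditionally multinomial given the observed trap
#' sums).  Occasions are collapsed to trap totals with per-trap effort
#' offsets, a sufficient statistic under the time-constant rate.
#'
#' @param dataset an [scr_dataset()].
#' @param priors an [rtscr_priors()].
#' @param config an [mcmc_config()].
#' @param fixed optional named list fixing parameters (`lambda0`, `sigma`,
#'   `theta`, `psi`) at given values, e.g. for oracle checks.
#' @param sites optional matrix of candidate activity-center sites; when
#'   given, the state space is treated as discrete and center updates jump
#'   between sites.
#' @return An object of class `rtscr_fit`: per-chain draw tables (with the
#'   derived `N` and `D` per 100 km2), optional latent traces, acceptance
#'   rates, and the run configuration.
#' @export
fit_rtscr <- function(dataset, priors = rtscr_priors(),
                      config = mcmc_config(), fixed = list(), sites = NULL) {
  fit_scr_engine(dataset, priors, config, fixed, sites, rtscr = TRUE)
}

#' Fit the standard SCR model (identified detections only)
#'
#' Identical sampler with the identification probability fixed at 1 and the
#' unidentified counts ignored.
#'
#' @inheritParams fit_rtscr
#' @return An `rtscr_fit` with `model = "scr"`.
#' @export
fit_scr <- function(dataset, priors = rtscr_priors(),
                    config = mcmc_config(), fixed = list(), sites = NULL) {
  fit_scr_engine(dataset, priors, config, fixed, sites, rtscr = FALSE)
}

fit_scr_engine <- function(dataset, priors, config, fixed, sites, rtscr) {
  traps <- dataset$traps
  ss <- dataset$state_space
  priors <- resolve_priors(priors, ss)
  cc <- collapse_captures(dataset$captures, traps)
  n_id <- nrow(cc$y_id)
  if (n_id == 0)
    warning("no identified individuals; fitting on unidentified counts alone")
  M <- if (is.null(config$M)) max(4L * n_id, 50L) else config$M
  if (M < max(n_id, 1)) stop("M must be at least the number of identified individuals")
  J <- n_traps(traps)
  y_id_m <- rbind(cc$y_id, matrix(0L, M - n_id, J))
  storage.mode(y_id_m) <- "integer"
  n_noid <- if (rtscr) cc$n_noid else integer(J)

  ss_type <- if (!is.null(sites)) 2L else if (ss$type == "rect") 0L else 1L
  poly <- if (ss$type == "polygon") ss$vertices else matrix(0, 0, 2)
  sites_m <- if (!is.null(sites)) as.matrix(sites) else matrix(0, 0, 2)

  pri <- list(lambda0_min = priors$lambda0[1], lambda0_max = priors$lambda0[2],
              sigma_min = max(priors$sigma[1], 1e-6),
              sigma_max = priors$sigma[2],
              theta_a = priors$theta[1], theta_b = priors$theta[2],
              psi_a = priors$psi[1], psi_b = priors$psi[2])
  fx <- list(lambda0 = "lambda0" %in% names(fixed),
             sigma = "sigma" %in% names(fixed),
             theta = "theta" %in% names(fixed),
             psi = "psi" %in% names(fixed))
  init_ls <- init_detection_params(cc$y_id, n_noid, cc$effort, traps, priors)

  theta0 <- if (rtscr)
    (sum(cc$y_id) + 1) / (sum(cc$y_id) + sum(n_noid) + 2) else 1
  psi0 <- clamp((2 * n_id + 1) / M, c(0.02, 0.95))

  cent <- matrix(NA_real_, n_id, 2)
  if (n_id > 0)
    cent <- t(vapply(seq_len(n_id), function(i) {
      w <- cc$y_id[i, ]
      c(sum(w * traps$xy[, 1]), sum(w * traps$xy[, 2])) / sum(w)
    }, numeric(2)))

  chains <- vector("list", config$n_chains)
  latent <- vector("list", config$n_chains)
  accept <- vector("list", config$n_chains)
  constraint_ok <- logical(0)
  for (ch in seq_len(config$n_chains)) {
    chain_seed <- (config$seed %% 1000000L) * 1000L + ch
    set.seed(chain_seed)
    # overdispersed starts: jitter the grid-initialized detection parameters
    l0 <- clamp(init_ls$lambda0 * exp(runif(1, -0.4, 0.4)), priors$lambda0)
    sg <- clamp(init_ls$sigma * exp(runif(1, -0.3, 0.3)), priors$sigma)
    s0 <- runif_state_space(M, ss)
    if (n_id > 0) {
      keep_in <- which(in_state_space(ss, cent[, 1], cent[, 2]))
      s0[keep_in, ] <- cent[keep_in, , drop = FALSE]
    }
    if (!is.null(sites)) {
      # snap every start to the nearest candidate site
      idx <- apply(s0, 1, function(p)
        which.min((sites_m[, 1] - p[1])^2 + (sites_m[, 2] - p[2])^2))
      s0 <- sites_m[idx, , drop = FALSE]
    }
    z0 <- c(rep(1L, n_id), rbinom(M - n_id, 1, psi0))
    init <- list(
      lambda0 = if (fx$lambda0) fixed$lambda0 else l0,
      sigma = if (fx$sigma) fixed$sigma else sg,
      theta = if (fx$theta) fixed$theta else theta0,
      psi = if (fx$psi) fixed$psi else psi0,
      s = s0, z = z0)
    res <- rtscr_mcmc_cpp(y_id_m, n_noid, cc$effort, traps$xy,
                          ss_type, ss$bounds, poly, sites_m,
                          pri, fx, init,
                          config$n_iter, config$n_burnin, config$thin,
                          config$adapt, config$retain_latent, rtscr,
                          config$allocation == "mh")
    dr <- as.data.frame(res$draws)
    dr$D <- 100 * dr$N / ss$area_km2
    dr$iteration <- config$n_burnin + config$thin * (seq_len(nrow(dr)) - 1) + 1
    dr$chain <- ch
    chains[[ch]] <- dr
    latent[[ch]] <- if (config$retain_latent)
      list(s = res$s, z = res$z) else NULL
    accept[[ch]] <- res$accept
    constraint_ok <- c(constraint_ok, res$constraint_ok)
  }
  fit <- structure(list(
    model = if (rtscr) "rtscr" else "scr",
    chains = chains, latent = latent, accept = accept,
    constraint_ok = constraint_ok,
    priors = priors, config = config, fixed = fixed,
    M = M, n_id = n_id, area_km2 = ss$area_km2,
    traps = traps, captures = dataset$captures, state_space = ss),
    class = "rtscr_fit")
  psi_hi <- quantile(posterior_draws(fit)$psi, 0.975)
  if (psi_hi > 0.9)
    warning("posterior psi upper CRI exceeds 0.9; increase the ",
            "data-augmentation size M")
  fit
}

#' Pooled posterior draws
#'
#' @param fit an `rtscr_fit`.
#' @return data.frame of post-burn-in draws from all chains, with columns
#'   `lambda0`, `sigma`, `theta`, `psi`, `N`, `D`, `iteration`, `chain`.
#' @export
posterior_draws <- function(fit) do.call(rbind, fit$chains)

#' @export
print.rtscr_fit <- function(x, ...) {
  dr <- posterior_draws(x)
  cat(sprintf(
    "%s fit: %d chains x %d retained draws (M = %d, %d identified)\n",
    toupper(x$model), length(x$chains), nrow(x$chains[[1]]), x$M, x$n_id))
  cat(sprintf("  median N = %d,  median D = %.2f / 100 km2\n",
              as.integer(median(dr$N)), median(dr$D)))
  invisible(x)
}

#' Two-stage fit with a 3-sigma buffer
#'
#' Stage one fits the model on a wide provisional buffer; the buffer is then
#' set to three times the stage-one posterior mean of sigma and the model is
#' refitted on the rebuilt state space.
#'
#' @param traps a [trap_array()].
#' @param captures a [capture_data()].
#' @param provisional_buffer stage-one buffer in meters (default 15000).
#' @param priors,config,fixed passed to [fit_rtscr()].
#' @param model `"rtscr"` or `"scr"`.
#' @return list with the final `fit`, the chosen `buffer` (meters), and the
#'   stage-one `fit_initial`.
#' @export
fit_with_3sigma_buffer <- function(traps, captures,
                                   provisional_buffer = 15000,
                                   priors = rtscr_priors(),
                                   config = mcmc_config(),
                                   fixed = list(), model = "rtscr") {
  fitter <- if (model == "rtscr") fit_rtscr else fit_scr
  ss1 <- build_state_space(traps, provisional_buffer)
  fit1 <- fitter(scr_dataset(traps, captures, ss1), priors, config, fixed)
  buffer <- 3 * mean(posterior_draws(fit1)$sigma)
  ss2 <- build_state_space(traps, buffer)
  fit2 <- fitter(scr_dataset(traps, captures, ss2), priors, config, fixed)
  list(fit = fit2, buffer = buffer, fit_initial = fit1)
}

#' Write posterior draws and run metadata to files
#'
#' One CSV per chain (`chain1.csv`, ...) with columns `iteration`,
#' `lambda0`, `sigma_m`, `theta`, `psi`, `N`, `D_per100km2`, plus
#' `run_metadata.json` recording priors, seed, configuration and package
#' version.
#'
#' @param fit an `rtscr_fit`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_fit <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ch in seq_along(fit$chains)) {
    dr <- fit$chains[[ch]]
    out <- data.frame(iteration = dr$iteration, lambda0 = dr$lambda0,
                      sigma_m = dr$sigma, theta = dr$theta, psi = dr$psi,
                      N = dr$N, D_per100km2 = dr$D)
    write.csv(out, file.path(dir, sprintf("chain%d.csv", ch)),
              row.names = FALSE)
  }
  jsonlite::write_json(list(
    model = fit$model,
    priors = unclass(fit$priors), config = unclass(fit$config),
    fixed = fit$fixed, M = fit$M, n_identified = fit$n_id,
    area_km2 = fit$area_km2,
    package_version = as.character(utils::packageVersion("rtscr"))),
    file.path(dir, "run_metadata.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
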