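#' Posterior summary of a fitted model
#'
#' Central 95% equal-tailed credible intervals and Gelman-Rubin diagnostics
#' for every monitored parameter.  Point estimates are posterior means,
#' except abundance `N` and density `D`, which are reported as posterior
#' medians because their posteriors are right-skewed.  The density draws are
#' `D = 100 N / area`, individuals per 100 km2, and the home-range summary
#' applies [home_range_from_sigma()] to the sigma draws.
#'
#' @param fit an `rtscr_fit`.
#' @param area_km2 state-space area; defaults to the fitted one.
#' @return An object of class `fit_summary` with a per-parameter `table`
#'   (mean, median, sd, lower, upper, cv, rhat, estimate) plus `home_range`
#'   (hectares) and run metadata.
#' @export
summarize_fit <- function(fit, area_km2 = fit$area_km2) {
  if (area_km2 <= 0) stop("'area_km2' must be positive")
  draws <- posterior_draws(fit)
  draws$D <- 100 * draws$N / area_km2
  pars <- c("lambda0", "sigma", "theta", "psi", "N", "D")
  rhat <- if (length(fit$chains) >= 2) gelman_rubin(fit)[pars] else {
    warning("single chain: Gelman-Rubin diagnostic omitted")
    setNames(rep(NA_real_, length(pars)), pars)
  }
  tab <- do.call(rbind, lapply(pars, function(p) {
    x <- draws[[p]]
    q <- quantile(x, c(0.025, 0.5, 0.975), names = FALSE)
    m <- mean(x)
    data.frame(parameter = p, mean = m, median = q[2], sd = sd(x),
               lower = q[1], upper = q[3],
               cv = if (m > 0) sd(x) / m else NA_real_,
               rhat = rhat[[p]],
               estimate = if (p %in% c("N", "D")) q[2] else m)
  }))
  rownames(tab) <- tab$parameter
  hr <- home_range_from_sigma(draws$sigma)
  structure(list(table = tab, home_range = hr, area_km2 = area_km2,
                 n_draws = nrow(draws), n_chains = length(fit$chains),
                 model = fit$model),
            class = "fit_summary")
}

#' @export
print.fit_summary <- function(x, digits = 3, ...) {
  cat(sprintf("%s posterior summary (%d draws, %d chains, area %.0f km2)\n",
              toupper(x$model), x$n_draws, x$n_chains, x$area_km2))
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], signif, digits = digits)
  print(tab[, c("estimate", "lower", "upper", "sd", "cv", "rhat")], ...)
  cat(sprintf("home range: %.0f (%.0f-%.0f) ha\n",
              x$home_range$mean, x$home_range$lower, x$home_range$upper))
  invisible(x)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Brooks-Gelman corrected form: with m chains of n draws, within-chain
#' variance W and between-chain variance B/n of the chain means,
#' `Rhat = sqrt((m+1)/m * sigma2_plus / W - (n-1)/(m n))` where
#' `sigma2_plus = (n-1)/n W + B/n`.  Values below 1.1 are conventionally
#' taken as convergence evidence.
#'
#' @param x an `rtscr_fit`, or a list of equal-length numeric vectors (one
#'   per chain), or a matrix with one column per chain.
#' @return named vector of Rhat values (single value for vector input).
#' @export
gelman_rubin <- function(x) {
  if (inherits(x, "rtscr_fit")) {
    pars <- c("lambda0", "sigma", "theta", "psi", "N", "D")
    return(vapply(pars, function(p)
      gelman_rubin(lapply(x$chains, `[[`, p)), numeric(1)))
  }
  if (is.matrix(x)) x <- lapply(seq_len(ncol(x)), function(j) x[, j])
  m <- length(x)
  if (m < 2) stop("need at least two chains")
  n <- unique(lengths(x))
  if (length(n) != 1) stop("chains must have equal length")
  if (n < 10) stop("need at least 10 draws per chain")
  means <- vapply(x, mean, numeric(1))
  W <- mean(vapply(x, var, numeric(1)))
  B_over_n <- var(means)
  if (W == 0) {
    warning("zero within-chain variance: Rhat undefined")
    return(NA_real_)
  }
  s2 <- (n - 1) / n * W + B_over_n
  sqrt((m + 1) / m * s2 / W - (n - 1) / (m * n))
}

#' Home-range area implied by the movement scale sigma
#'
#' Under a bivariate-normal space-use model the 95% home range is the circle
#' containing 95% of the utilisation density:
#' `area = pi * (q sigma)^2` with `q = sqrt(qchisq(0.95, 2)) = 2.447746`.
#' Applied per posterior draw; the point estimate is the posterior mean of
#' the per-draw transform (not the transform of the mean).
#'
#' @param sigma_draws sigma draws in meters (> 0).
#' @return list with `mean`, `lower`, `upper` (95% CRI) and `draws`, all in
#'   hectares.
#' @export
home_range_from_sigma <- function(sigma_draws) {
  if (any(sigma_draws <= 0)) stop("sigma draws must be positive")
  q <- 2.447746  # sqrt(qchisq(0.95, df = 2))
  ha <- pi * (q * sigma_draws)^2 / 1e4  # m2 -> ha
  if (length(ha) == 1)
    return(list(mean = ha, lower = ha, upper = ha, draws = ha))
  ci <- quantile(ha, c(0.025, 0.975), names = FALSE)
  list(mean = mean(ha), lower = ci[1], upper = ci[2], draws = ha)
}

#' Realized activity-center density surface
#'
#' Grids the state space and, for each cell, averages over retained draws
#' the number of population members (z = 1) whose activity center falls in
#' the cell.  Cell values sum to the posterior mean of N (up to edge
#' clipping, which cannot occur for rectangular spaces).
#'
#' @param fit an `rtscr_fit` with latent traces.
#' @param cell_size cell side in meters.
#' @return object of class `ac_surface`: `x`, `y` cell-center coordinates,
#'   `value` matrix (len(x) x len(y)), `cell_size`.
#' @export
activity_center_surface <- function(fit, cell_size) {
  if (is.null(fit$latent[[1]]))
    stop("fit has no latent traces; refit with retain_latent = TRUE")
  b <- fit$state_space$bounds
  if (cell_size > (b[2] - b[1]) || cell_size > (b[4] - b[3]))
    stop("'cell_size' larger than the state space")
  grid_breaks <- function(lo, hi) {
    br <- seq(lo, hi, by = cell_size)
    if (br[length(br)] < hi) br <- c(br, hi)  # partial edge cell
    br
  }
  xb <- grid_breaks(b[1], b[2])
  yb <- grid_breaks(b[3], b[4])
  nx <- length(xb) - 1; ny <- length(yb) - 1
  acc <- matrix(0, nx, ny)
  n_draws <- 0
  for (ch in seq_along(fit$latent)) {
    s <- fit$latent[[ch]]$s
    z <- fit$latent[[ch]]$z
    for (k in seq_len(nrow(z))) {
      live <- which(z[k, ] == 1)
      if (length(live)) {
        ix <- findInterval(s[k, live, 1], xb, rightmost.closed = TRUE)
        iy <- findInterval(s[k, live, 2], yb, rightmost.closed = TRUE)
        ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
        if (any(ok))
          for (p in which(ok))
            acc[ix[p], iy[p]] <- acc[ix[p], iy[p]] + 1
      }
      n_draws <- n_draws + 1
    }
  }
  structure(list(x = (xb[-length(xb)] + xb[-1]) / 2,
                 y = (yb[-length(yb)] + yb[-1]) / 2,
                 value = acc / n_draws, cell_size = cell_size,
                 n_draws = n_draws),
            class = "ac_surface")
}

#' @export
as.data.frame.ac_surface <- function(x, ...) {
  data.frame(x = rep(x$x, times = length(x$y)),
             y = rep(x$y, each = length(x$x)),
             value = as.vector(x$value))
}

#' Write an activity-center surface as a CSV grid
#' @param surface an `ac_surface`.
#' @param path CSV path (columns x, y, value).
#' @export
write_ac_surface <- function(surface, path) {
  write.csv(as.data.frame(surface), path, row.names = FALSE)
  invisible(path)
}

#' Mean maximum distance moved (MMDM)
#'
#' For every identified individual detected at two or more distinct traps,
#' the maximum pairwise distance among those traps; the summary is the mean
#' over such individuals.
#'
#' @param captures a [capture_data()].
#' @param traps a [trap_array()].
#' @return list with `mmdm` (meters; `NA` if no individual was detected at
#'   multiple traps), `range`, and a per-individual `table`.
#' @export
mean_max_distance <- function(captures, traps) {
  n_id <- dim(captures$y_id)[1]
  rows <- lapply(seq_len(n_id), function(i) {
    y <- apply(captures$y_id[i, , , drop = FALSE], 2, sum)
    j <- which(y > 0)
    data.frame(individual = captures$individual_ids[i],
               n_traps = length(j),
               max_dist = if (length(j) >= 2)
                 max(dist(traps$xy[j, , drop = FALSE])) else NA_real_)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(individual = character(), n_traps = integer(),
               max_dist = numeric())
  d <- tab$max_dist[!is.na(tab$max_dist)]
  list(mmdm = if (length(d)) mean(d) else NA_real_,
       range = if (length(d)) range(d) else c(NA_real_, NA_real_),
       table = tab)
}

#' Closure test on capture-history timing
#'
#' The Otis et al. (1978) test for population closure: capture histories are
#' collapsed to binary per-occasion detections; for each individual caught
#' on `n >= 2` occasions, the span between first and last capture is
#' compared with its null distribution given `n` (under closure the `n`
#' capture occasions are exchangeable), `P(span = q) =
#' (t - q) choose(q - 1, n - 2) / choose(t, n)`.  The standardized sum of
#' span deviations is asymptotically standard normal; a negative Z with
#' small one-sided p indicates shorter spans than expected, i.e. a closure
#' violation.
#'
#' @param captures a [capture_data()].
#' @param traps a [trap_array()] (for the number of occasions).
#' @return list with `statistic` (Z), `p_value` (one-sided,
#'   `P(Z <= z)`), `n_individuals` used; `NA`s with a warning when no
#'   individual was captured on two or more occasions.
#' @export
closure_test <- function(captures, traps) {
  K <- n_occasions(traps)
  if (K < 2) stop("need at least two occasions")
  n_id <- dim(captures$y_id)[1]
  if (n_id == 0) {
    warning("no identified individuals: closure test undefined")
    return(list(statistic = NA_real_, p_value = NA_real_, n_individuals = 0))
  }
  det <- t(vapply(seq_len(n_id), function(i)
    as.numeric(apply(captures$y_id[i, , , drop = FALSE], 3, sum) > 0),
    numeric(K)))
  n_i <- rowSums(det)
  use <- which(n_i >= 2)
  if (length(use) == 0) {
    warning("all individuals captured on a single occasion: ",
            "closure test undefined")
    return(list(statistic = NA_real_, p_value = NA_real_, n_individuals = 0))
  }
  span_moments <- function(n, t) {
    q <- (n - 1):(t - 1)
    p <- (t - q) * choose(q - 1, n - 2) / choose(t, n)
    mu <- sum(q * p)
    list(mu = mu, v = sum((q - mu)^2 * p))
  }
  num <- 0; den <- 0
  for (i in use) {
    occ <- which(det[i, ] > 0)
    d <- max(occ) - min(occ)
    m <- span_moments(n_i[i], K)
    num <- num + (d - m$mu)
    den <- den + m$v
  }
  if (den == 0) {
    warning("zero null variance: closure test undefined")
    return(list(statistic = NA_real_, p_value = NA_real_,
                n_individuals = length(use)))
  }
  z <- num / sqrt(den)
  list(statistic = z, p_value = pnorm(z), n_individuals = length(use))
}

#' Compare SCR and rt-SCR posterior summaries
#'
#' @param scr,rtscr `fit_summary` objects fitted on the same data and area.
#' @return data.frame with one row per parameter (`N`, `sigma`, `D`):
#'   estimates and CVs from both models and the percent change in CV
#'   (rt-SCR relative to SCR; negative = more precise).
#' @export
compare_fits <- function(scr, rtscr) {
  if (abs(scr$area_km2 - rtscr$area_km2) > 1e-8 * scr$area_km2)
    stop("summaries use different state-space areas")
  pars <- c("N", "sigma", "D")
  do.call(rbind, lapply(pars, function(p) {
    a <- scr$table[p, ]; b <- rtscr$table[p, ]
    data.frame(parameter = p,
               scr_estimate = a$estimate, rtscr_estimate = b$estimate,
               scr_cv = a$cv, rtscr_cv = b$cv,
               cv_change_pct = 100 * (b$cv - a$cv) / a$cv)
  }))
}

#' Write a fit summary as JSON
#' @param summary a `fit_summary`.
#' @param path output JSON path.
#' @export
write_summary <- function(summary, path) {
  jsonlite::write_json(list(
    model = summary$model, area_km2 = summary$area_km2,
    n_draws = summary$n_draws, n_chains = summary$n_chains,
    parameters = summary$table[, setdiff(names(summary$table), "parameter")],
    home_range_ha = summary$home_range[c("mean", "lower", "upper")]),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
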