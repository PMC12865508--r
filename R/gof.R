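#' Goodness-of-fit discrepancy statistics
#'
#' The three detection summaries used for posterior-predictive checking:
#' `T1` the total number of detections (identified plus unidentified), `T2`
#' the number of individuals with at least one identified detection, and
#' `T3` the number of camera traps visited (any detection).
#'
#' @param captures a [capture_data()].
#' @return named numeric vector `c(total_detections, detected_individuals,
#'   visited_traps)`.
#' @export
gof_statistics <- function(captures) {
  t1 <- sum(captures$y_id) + sum(captures$n_noid)
  n_id <- dim(captures$y_id)[1]
  t2 <- if (n_id > 0) sum(apply(captures$y_id, 1, sum) > 0) else 0L
  by_trap <- rowSums(captures$n_noid)
  if (n_id > 0) by_trap <- by_trap + rowSums(apply(captures$y_id, c(2, 3), sum))
  t3 <- sum(by_trap > 0)
  c(total_detections = t1, detected_individuals = t2, visited_traps = t3)
}

#' Posterior-predictive goodness-of-fit check
#'
#' For each of `n_rep` retained posterior draws, detection data for all M
#' augmented individuals are replicated from that draw's parameters and
#' latent state (Poisson encounters under the observed effort, identities
#' thinned with that draw's theta), the three discrepancy statistics are
#' recomputed, and Bayesian p-values `Pr(T_rep >= T_obs)` are reported.
#' Ties count in favour of the replicate (`>=`), so a replicate
#' distribution degenerate at the observed value gives p = 1.
#'
#' @param fit an `rtscr_fit` with retained latent traces.
#' @param n_rep number of replicated datasets (default 500; capped at the
#'   number of retained draws, with a warning).
#' @param seed RNG seed for the replication.
#' @return An object of class `gof_result`: `observed`, `replicated`
#'   (one row per replicate), `bayes_p`, `n_rep`, `seed`.
#' @export
posterior_predictive_gof <- function(fit, n_rep = 500, seed = 1) {
  if (is.null(fit$latent[[1]]))
    stop("fit has no latent traces; refit with retain_latent = TRUE")
  obs <- gof_statistics(fit$captures)
  draws <- posterior_draws(fit)
  n_avail <- nrow(draws)
  if (n_rep > n_avail) {
    warning("n_rep exceeds the ", n_avail, " retained draws; using all")
    n_rep <- n_avail
  }
  set.seed(seed)
  pick <- sort(sample.int(n_avail, n_rep))
  eff <- rowSums(fit$traps$operation)
  J <- n_traps(fit$traps)
  per_chain <- nrow(fit$chains[[1]])
  rep_stats <- matrix(NA_real_, n_rep, 3)
  for (r in seq_len(n_rep)) {
    g <- pick[r]
    ch <- (g - 1) %/% per_chain + 1
    k <- (g - 1) %% per_chain + 1
    lam0 <- draws$lambda0[g]; sig <- draws$sigma[g]; th <- draws$theta[g]
    z <- fit$latent[[ch]]$z[k, ]
    live <- which(z == 1)
    if (length(live) == 0) { rep_stats[r, ] <- c(0, 0, 0); next }
    s <- cbind(fit$latent[[ch]]$s[k, live, 1],
               fit$latent[[ch]]$s[k, live, 2])
    lam <- lam0 * exp(-ac_trap_distance(s, fit$traps)^2 / (2 * sig^2)) *
      matrix(eff, length(live), J, byrow = TRUE)
    y <- matrix(rpois(length(lam), lam), nrow(lam), J)
    y_ided <- matrix(rbinom(length(y), y, th), nrow(y), J)
    rep_stats[r, ] <- c(sum(y), sum(rowSums(y_ided) > 0),
                        sum(colSums(y) > 0))
  }
  colnames(rep_stats) <- names(obs)
  bayes_p <- vapply(1:3, function(t) mean(rep_stats[, t] >= obs[t]),
                    numeric(1))
  names(bayes_p) <- names(obs)
  structure(list(observed = obs,
                 replicated = as.data.frame(rep_stats),
                 bayes_p = bayes_p, n_rep = n_rep, seed = seed),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat("Posterior-predictive GoF (", x$n_rep, " replicates)\n", sep = "")
  for (t in seq_along(x$observed))
    cat(sprintf("  %-22s observed %5d   Bayesian p = %.3f\n",
                names(x$observed)[t], as.integer(x$observed[t]),
                x$bayes_p[t]))
  invisible(x)
}

#' Histogram panels of replicated vs observed GoF statistics
#'
#' @param x a `gof_result`.
#' @param ... passed to `hist()`.
#' @export
plot.gof_result <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(op))
  for (t in seq_along(x$observed)) {
    graphics::hist(x$replicated[[t]], main = names(x$observed)[t],
                   xlab = "replicated", col = "grey85", border = "white",
                   ...)
    graphics::abline(v = x$observed[t], col = "red", lwd = 2)
    graphics::mtext(sprintf("p = %.2f", x$bayes_p[t]), side = 3, adj = 0.98,
                    line = -1.5, cex = 0.8)
  }
  invisible(x)
}

#' Write a GoF report as JSON
#'
#' @param gof a `gof_result`.
#' @param path output JSON path.
#' @param per_draw optional CSV path for the per-replicate statistics.
#' @export
write_gof <- function(gof, path, per_draw = NULL) {
  jsonlite::write_json(list(observed = as.list(gof$observed),
                            bayes_p = as.list(gof$bayes_p),
                            n_rep = gof$n_rep, seed = gof$seed),
                       path, auto_unbox = TRUE, digits = NA)
  if (!is.null(per_draw))
    write.csv(gof$replicated, per_draw, row.names = FALSE)
  invisible(path)
}
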