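#' Generative parameter set for simulation
#'
#' @param N true number of individuals in the state space.
#' @param lambda0 baseline encounter rate per occasion at distance zero.
#' @param sigma spatial scale of the half-normal detection function, meters.
#' @param theta probability that a detection retains its individual identity.
#' @param seed RNG seed (integer) or NULL.
#' @return A list of class `truth_params`.
#' @export
truth_params <- function(N, lambda0, sigma, theta, seed = NULL) {
  stopifnot(N >= 0, lambda0 > 0, sigma > 0, theta >= 0, theta <= 1)
  structure(list(N = as.integer(N), lambda0 = lambda0, sigma = sigma,
                 theta = theta, seed = seed), class = "truth_params")
}

#' Regular grid of camera stations
#'
#' @param n_x,n_y grid dimensions (>= 1).
#' @param spacing distance between neighbouring stations, meters (> 0).
#' @param origin coordinates of the first station (length-2, meters).
#' @param K number of occasions; the operation matrix is all-ones.
#' @param prefix station label prefix.
#' @return A [trap_array()] with full operation.
#' @export
make_trap_grid <- function(n_x, n_y, spacing, origin = c(0, 0), K = 1,
                           prefix = "T") {
  stopifnot(n_x >= 1, n_y >= 1, K >= 1)
  if (spacing <= 0) stop("'spacing' must be positive")
  g <- expand.grid(x = origin[1] + (seq_len(n_x) - 1) * spacing,
                   y = origin[2] + (seq_len(n_y) - 1) * spacing)
  trap_array(sprintf("%s%02d", prefix, seq_len(nrow(g))),
             as.matrix(g), matrix(1, nrow(g), K))
}

#' Draw activity centers uniformly over a state space
#' @param n number of points.
#' @param state_space a [build_state_space()] result.
#' @return n x 2 matrix of coordinates (meters).
#' @export
runif_state_space <- function(n, state_space) {
  b <- state_space$bounds
  if (n == 0) return(matrix(numeric(0), 0, 2))
  if (state_space$type == "rect")
    return(cbind(runif(n, b[1], b[2]), runif(n, b[3], b[4])))
  out <- matrix(NA_real_, n, 2)
  filled <- 0
  while (filled < n) {
    m <- 2 * (n - filled) + 10
    x <- runif(m, b[1], b[2]); y <- runif(m, b[3], b[4])
    ok <- which(points_in_polygon_cpp(x, y, state_space$vertices))
    take <- head(ok, n - filled)
    if (length(take)) {
      out[filled + seq_along(take), ] <- cbind(x[take], y[take])
      filled <- filled + length(take)
    }
  }
  out
}

#' Simulate a camera-trap dataset under the rt-SCR generative process
#'
#' Activity centers are uniform over the state space; encounters at each
#' active station-occasion are Poisson with half-normal rate
#' `lambda0 * exp(-d^2 / (2 sigma^2))`; each encounter independently retains
#' its individual identity with probability `theta`.  Individuals with no
#' identified detection are absent from the observed identified array; their
#' detections appear only in the unidentified trap-by-occasion counts.
#'
#' @param truth a [truth_params()].
#' @param traps a [trap_array()].
#' @param state_space a [build_state_space()] result containing all traps.
#' @return An object of class `synthetic_scr`: `dataset` (an
#'   [scr_dataset()]), `truth`, `activity_centers` (N x 2), and
#'   `y_full_true` (N x J x K).
#' @export
simulate_dataset <- function(truth, traps, state_space) {
  if (!all(in_state_space(state_space, traps$xy[, 1], traps$xy[, 2])))
    stop("traps must lie inside the state space")
  if (!is.null(truth$seed)) set.seed(truth$seed)
  N <- truth$N
  J <- n_traps(traps); K <- n_occasions(traps)
  s <- runif_state_space(N, state_space)
  d2 <- outer(seq_len(N), seq_len(J), function(i, j)
    (s[i, 1] - traps$xy[j, 1])^2 + (s[i, 2] - traps$xy[j, 2])^2)
  lam <- truth$lambda0 * exp(-d2 / (2 * truth$sigma^2))  # N x J, per occasion

  y_full <- array(0L, c(N, J, K))
  y_id_full <- array(0L, c(N, J, K))
  if (N > 0) {
    op <- traps$operation  # J x K
    lam_cells <- array(lam, c(N, J, K)) *
      array(rep(op, each = N), c(N, J, K))
    y_full[] <- rpois(length(lam_cells), lam_cells)
    y_id_full[] <- rbinom(length(y_full), y_full, truth$theta)
  }
  n_noid <- apply(y_full - y_id_full, c(2, 3), sum)
  storage.mode(n_noid) <- "integer"

  detected <- which(apply(y_id_full, 1, sum) > 0)
  ids <- sprintf("IND%03d", detected)
  captures <- capture_data(y_id_full[detected, , , drop = FALSE], n_noid, ids,
                           traps = traps)
  structure(list(
    dataset = scr_dataset(traps, captures, state_space),
    truth = truth, activity_centers = s, y_full_true = y_full,
    y_id_true = y_id_full, detected = detected),
    class = "synthetic_scr")
}

#' @export
print.synthetic_scr <- function(x, ...) {
  cat("Synthetic rt-SCR dataset: N_true =", x$truth$N, "\n")
  print(x$dataset)
  invisible(x)
}

#' Study-emulating jaguar survey design
#'
#' A 52-station, 91-day paired-camera survey layout: two grid clusters (6x6
#' and 4x4) at 1308-m spacing, mirroring a two-area mountain-corridor
#' deployment with a mean nearest-neighbour spacing of 1308 m.  Staggered
#' per-station downtime yields exactly 3779 active trap-days out of a
#' possible 4732.  With the default 9150-m buffer the rectangular state
#' space covers about 1941 km2.  The default generative values are a
#' low-density jaguar population: N = 25, lambda0 = 0.047 per day,
#' sigma = 3050 m, theta = 0.87.
#'
#' @param buffer_width state-space buffer in meters (default 9150, i.e. three
#'   times sigma).
#' @param full_operation if TRUE, skip the downtime pattern (4732 trap-days).
#' @return list with `traps`, `state_space`, `truth`.
#' @export
jaguar_design <- function(buffer_width = 9150, full_operation = FALSE) {
  spacing <- 1308
  K <- 91
  north <- expand.grid(x = (0:5) * spacing, y = (0:5) * spacing)
  south <- expand.grid(x = 16000 + (0:3) * spacing,
                       y = -26000 + (0:3) * spacing)
  xy <- as.matrix(rbind(north, south))
  J <- nrow(xy)
  op <- matrix(1, J, K)
  if (!full_operation) {
    # 953 downtime trap-days in staggered blocks: 18 days per station,
    # one extra for the first 17 stations (52*18 + 17 = 953)
    for (i in seq_len(J)) {
      d <- 18L + as.integer(i <= 17)
      start <- (i * 7L) %% (K - d) + 1L
      op[i, start:(start + d - 1L)] <- 0
    }
  }
  traps <- trap_array(sprintf("ST%02d", seq_len(J)), xy, op)
  list(traps = traps,
       state_space = build_state_space(traps, buffer_width),
       truth = truth_params(N = 25, lambda0 = 0.047, sigma = 3050,
                            theta = 0.87))
}

#' Expected total detections under a given design and truth
#'
#' Analytic mean of the total encounter count: the sum over activity-center
#' draws is approximated by Monte Carlo integration over the state space
#' unless explicit centers are supplied.
#'
#' @param truth a [truth_params()].
#' @param traps a [trap_array()].
#' @param state_space state space.
#' @param centers optional matrix of activity centers; if given the expected
#'   count conditional on those centers is returned.
#' @param n_mc Monte Carlo points for the uniform-center integral.
#' @return expected number of detections (identified + unidentified).
#' @export
expected_detections <- function(truth, traps, state_space, centers = NULL,
                                n_mc = 20000) {
  eff <- rowSums(traps$operation)
  if (is.null(centers)) {
    s <- runif_state_space(n_mc, state_space)
    d2 <- outer(s[, 1], traps$xy[, 1], "-")^2 + outer(s[, 2], traps$xy[, 2], "-")^2
    m <- mean((exp(-d2 / (2 * truth$sigma^2)) %*% eff)) * truth$lambda0
    truth$N * m
  } else {
    d2 <- outer(centers[, 1], traps$xy[, 1], "-")^2 +
      outer(centers[, 2], traps$xy[, 2], "-")^2
    sum((truth$lambda0 * exp(-d2 / (2 * truth$sigma^2))) %*% eff)
  }
}

#' Write a synthetic dataset to plain-text files
#'
#' Writes the trap table, the capture matrices, and a truth JSON (parameters
#' plus activity-center coordinates) for recovery tests.
#'
#' @param sim a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_traps(sim$dataset$traps, file.path(dir, "traps.csv"))
  write_capture_data(sim$dataset$captures, file.path(dir, "captures.csv"))
  truth <- sim$truth
  jsonlite::write_json(
    list(N = truth$N, lambda0 = truth$lambda0, sigma = truth$sigma,
         theta = truth$theta, seed = truth$seed,
         activity_centers = unname(as.matrix(sim$activity_centers)),
         area_km2 = sim$dataset$state_space$area_km2),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
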