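# Grand-canonical distributions, chemical-potential calibration, and
# per-frame reweighting.

# Fixed particle-number <-> molarity conversion: 1 particle/nm^3 = 1.660539
# mol/L (reciprocal of Avogadro's number times 1e-24 L/nm^3).
PARTICLE_PER_NM3_TO_MOLAR <- 1.660539

#' Buffer-region specification
#'
#' Pairs a buffer volume with a target reagent concentration; the product
#' (after unit conversion) is the grand-canonical mean occupancy of region B
#' that the chemical potential must reproduce.
#'
#' @param V_B Buffer-region volume in nm^3 (> 0).
#' @param concentration Target molarity in mol/L (> 0).
#' @param temperature Temperature in kelvin (default 300).
#' @return Object of class `buffer_spec` with a `target_occupancy` field.
#' @export
buffer_spec <- function(V_B, concentration, temperature = 300) {
  stopifnot(V_B > 0, concentration > 0, temperature > 0)
  structure(list(V_B = V_B, concentration = concentration,
                 temperature = temperature,
                 target_occupancy = concentration * V_B / PARTICLE_PER_NM3_TO_MOLAR),
            class = "buffer_spec")
}

#' Buffer volume from box volume and binding-region radius
#'
#' `V_B = V_box - (4/3) pi r_A^3`, the volume left to the buffer when a
#' spherical binding region of radius `r_A` is carved out of the box.
#'
#' @param V_box Box volume in nm^3.
#' @param r_A Binding-region radius in nm (default 3).
#' @return Buffer volume in nm^3.
#' @export
buffer_volume <- function(V_box, r_A = 3) {
  V_B <- V_box - 4 / 3 * pi * r_A^3
  if (V_B <= 0) stop("binding region exceeds the box volume")
  V_B
}

# log(sum(exp(x))) without overflow
.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log-domain occupancy distribution over k = 0..N_max for one region
.gc_logp <- function(omega, beta_mu) {
  k <- seq_along(omega) - 1
  lw <- ifelse(omega > 0, log(omega) + beta_mu * k, -Inf)
  lw - .logsumexp(lw)
}

#' Grand-canonical occupancy distribution
#'
#' `P(k) = Omega(k) exp(beta_mu * k) / Xi` per region, evaluated in the log
#' domain so that large `|beta_mu|` cannot overflow.  The support is
#' truncated at `N_max`: concentrations whose occupancies exceed the
#' sampled particle-number range are unreliable and the calibration
#' functions refuse them.
#'
#' @param pf A `partition_functions` object.
#' @param beta_mu Dimensionless chemical potential mu / (k_B T).
#' @param temperature Temperature in kelvin (metadata; default 300).
#' @return Object of class `gc_ensemble` with probability vectors `P_A`,
#'   `P_B` (index `k + 1`), log grand sums `log_Xi_A`, `log_Xi_B`, and the
#'   inputs.
#' @export
gc_distribution <- function(pf, beta_mu, temperature = 300) {
  if (all(pf$omega_A <= 0) || all(pf$omega_B <= 0))
    stop("partition functions must have at least one nonzero entry per region")
  k <- 0:pf$N_max
  lpA <- .gc_logp(pf$omega_A, beta_mu)
  lpB <- .gc_logp(pf$omega_B, beta_mu)
  lw <- function(omega) ifelse(omega > 0, log(omega) + beta_mu * k, -Inf)
  P_A <- exp(lpA); P_B <- exp(lpB)
  names(P_A) <- names(P_B) <- k
  structure(list(beta_mu = beta_mu, temperature = temperature,
                 P_A = P_A, P_B = P_B,
                 log_Xi_A = .logsumexp(lw(pf$omega_A)),
                 log_Xi_B = .logsumexp(lw(pf$omega_B)),
                 N_max = pf$N_max),
            class = "gc_ensemble")
}

#' Mean particle numbers in the grand-canonical ensemble
#'
#' @param gce A `gc_ensemble`.
#' @return Named vector `c(mean_A, mean_B)` of grand-canonical average
#'   occupancies.
#' @export
mean_occupancy <- function(gce) {
  k <- 0:gce$N_max
  c(mean_A = sum(k * gce$P_A), mean_B = sum(k * gce$P_B))
}

#' Calibrate the chemical potential from a buffer concentration
#'
#' Finds the dimensionless chemical potential `beta_mu` whose
#' grand-canonical mean occupancy of region B equals the particle number
#' implied by the buffer volume and target molarity.  The root is bracketed
#' by geometric expansion and then refined by bisection.
#'
#' @param pf A `partition_functions` object.
#' @param buffer A `buffer_spec`.
#' @param tol Relative tolerance on the matched occupancy (default 1e-12).
#' @return `beta_mu` (scalar).
#' @export
mu_from_concentration <- function(pf, buffer, tol = 1e-12) {
  stopifnot(inherits(buffer, "buffer_spec"))
  target <- buffer$target_occupancy
  k_sup <- max(which(pf$omega_B > 0)) - 1L     # max attainable occupancy
  if (k_sup < 1L)
    stop("region-B partition function has no support beyond k = 0; cannot calibrate")
  if (target >= k_sup) {
    ceiling_conc <- k_sup * PARTICLE_PER_NM3_TO_MOLAR / buffer$V_B
    stop(sprintf(
      "target concentration %.6g M exceeds the attainable ceiling %.6g M (occupancy support truncated at k = %d)",
      buffer$concentration, ceiling_conc, k_sup))
  }
  mean_B_at <- function(bm) {
    sum((0:pf$N_max) * exp(.gc_logp(pf$omega_B, bm)))
  }
  # geometric bracket expansion around 0
  lo <- -1; hi <- 1
  while (mean_B_at(lo) > target && lo > -1e6) lo <- lo * 2
  while (mean_B_at(hi) < target && hi < 1e6) hi <- hi * 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    m <- mean_B_at(mid)
    if (abs(m - target) <= tol * target) return(mid)
    if (m < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Attainable concentration ceiling
#'
#' Largest buffer concentration representable given the truncation of the
#' region-B occupancy support.
#'
#' @param pf A `partition_functions` object.
#' @param V_B Buffer volume in nm^3.
#' @return Ceiling concentration in mol/L.
#' @export
concentration_ceiling <- function(pf, V_B) {
  k_sup <- max(which(pf$omega_B > 0)) - 1L
  k_sup * PARTICLE_PER_NM3_TO_MOLAR / V_B
}

#' Per-frame grand-canonical weights
#'
#' Weights every pooled frame so that weighted averages over the
#' concatenated constant-N trajectories equal grand-canonical averages at
#' the given chemical potential.  The weight of a frame depends on the
#' frame only through its region-A occupancy `k`: it is proportional to
#' `P_A^GC(k) / A_k`, the target grand-canonical mass at `k` divided by the
#' pooled number of frames observed at `k`.  By construction the weighted
#' occupancy histogram reproduces `P_A^GC` exactly.
#'
#' @param pf A `partition_functions` solved from `counts`.
#' @param beta_mu Dimensionless chemical potential.
#' @param counts The `count_matrix` the partition functions were solved
#'   from.
#' @param occupancy_sequences Named list of per-frame occupancies (same
#'   pooled frames that produced `counts`).
#' @param traj_weights Optional named trajectory weights (Bayesian
#'   bootstrap): each frame's weight is additionally multiplied by its
#'   trajectory's weight, and `counts` is expected to be the matching
#'   reweighted (fractional) count matrix.
#' @return A data frame of class `frame_weight_table` with columns
#'   `trajectory_N`, `frame`, `k_A`, `weight`; weights sum to 1.
#' @export
frame_weights <- function(pf, beta_mu, counts, occupancy_sequences,
                          traj_weights = NULL) {
  P_A <- gc_distribution(pf, beta_mu)$P_A
  lens <- lengths(occupancy_sequences)
  if (sum(lens) == 0L) stop("no frames supplied")
  df <- data.frame(
    trajectory_N = rep(as.integer(names(occupancy_sequences)), lens),
    frame = sequence(lens) - 1L,
    k_A = as.integer(unlist(occupancy_sequences, use.names = FALSE)))
  kk <- df$k_A + 1L
  if (any(df$k_A > counts$N_max))
    stop("frame occupancy exceeds N_max")
  unseen <- counts$A[kk] <= 0
  if (any(unseen))
    stop("frames with region-A occupancy never present in the counts: k = ",
         paste(unique(df$k_A[unseen]), collapse = ", "))
  w <- P_A[kk] / counts$A[kk]
  if (!is.null(traj_weights))
    w <- w * traj_weights[as.character(df$trajectory_N)]
  w <- w / sum(w)
  df$weight <- as.numeric(w)
  class(df) <- c("frame_weight_table", "data.frame")
  df
}

#' Weighted ensemble average of a per-frame observable
#'
#' @param weights A `frame_weight_table`.
#' @param observable Numeric vector, one value per weighted frame (same
#'   order).
#' @return Scalar grand-canonical average `sum_i w_i O_i`.
#' @export
gc_average <- function(weights, observable) {
  if (length(observable) != nrow(weights))
    stop(sprintf("observable length %d does not match %d weighted frames",
                 length(observable), nrow(weights)))
  sum(weights$weight * observable)
}

#' Write a frame-weight table to TSV
#' @param weights A `frame_weight_table`.
#' @param path Output path.
#' @export
write_weights_tsv <- function(weights, path) {
  utils::write.table(as.data.frame(weights), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Serialize partition functions (and optionally an ensemble) to JSON
#'
#' @param pf A `partition_functions`.
#' @param path Output path.
#' @param gce Optional `gc_ensemble` to embed.
#' @export
write_partition_json <- function(pf, path, gce = NULL) {
  obj <- list(omega_A = unname(pf$omega_A), omega_B = unname(pf$omega_B),
              gauge = pf$gauge, iterations = pf$iterations,
              residual = pf$residual, converged = pf$converged)
  if (!is.null(gce)) {
    obj$beta_mu <- gce$beta_mu
    obj$temperature_K <- gce$temperature
    obj$P_A <- unname(gce$P_A)
    obj$P_B <- unname(gce$P_B)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read partition functions from JSON
#' @param path Path written by [write_partition_json()].
#' @return A `partition_functions` object.
#' @export
read_partition_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  omega_A <- as.numeric(obj$omega_A)
  omega_B <- as.numeric(obj$omega_B)
  N_max <- length(omega_A) - 1L
  names(omega_A) <- names(omega_B) <- 0:N_max
  Z <- vapply(seq_len(N_max), function(N) {
    k <- 0:N
    sum(omega_A[k + 1L] * omega_B[N - k + 1L])
  }, numeric(1))
  structure(list(omega_A = omega_A, omega_B = omega_B, Z_N = Z,
                 gauge = obj$gauge %||% "omega0",
                 iterations = obj$iterations %||% NA_integer_,
                 residual = obj$residual %||% NA_real_,
                 converged = obj$converged %||% TRUE,
                 log_lik_trace = numeric(0), N_max = N_max),
            class = "partition_functions")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
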