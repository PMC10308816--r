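# Exactly enumerable two-region lattice model: S_A sites in the binding
# region, S_B in the buffer, particles interacting only through mutual
# exclusion (at most one per site), optionally with one stabilizing site in
# region A contributing eps k_B T (< 0 stabilizes).  Every quantity has a
# closed form, which is what makes the model useful as a ground-truth
# oracle for the maximum-likelihood reweighting machinery.

#' Define a lattice model
#'
#' @param S_A Number of sites in region A (>= 1).
#' @param S_B Number of sites in region B (>= 1).
#' @param eps Free energy of the single stabilizing site in region A, in
#'   k_B T units; 0 gives the purely entropic lattice, negative values
#'   stabilize occupation of that site.
#' @param N_max Maximum particle number (defaults to `S_A + S_B`).
#' @return Object of class `lattice_model`.
#' @export
lattice_model <- function(S_A, S_B, eps = 0, N_max = S_A + S_B) {
  stopifnot(S_A >= 1, S_B >= 1, N_max >= 1, N_max <= S_A + S_B)
  structure(list(S_A = as.integer(S_A), S_B = as.integer(S_B),
                 eps = eps, N_max = as.integer(N_max)),
            class = "lattice_model")
}

#' Exact regional partition function of the lattice
#'
#' Region B (and region A with `eps = 0`) is pure site counting:
#' `Omega(k) = choose(S, k)`.  With one stabilizing site in region A,
#' `Omega_A(k) = choose(S_A - 1, k) + choose(S_A - 1, k - 1) * exp(-eps)`
#' (stabilizing site empty vs occupied).
#'
#' @param model A `lattice_model`.
#' @param region `"A"` or `"B"`.
#' @return Numeric vector over `k = 0..N_max` (index `k + 1`); zero where
#'   `k` exceeds the region's site count.
#' @export
exact_omega <- function(model, region = c("A", "B")) {
  region <- match.arg(region)
  k <- 0:model$N_max
  omega <- if (region == "B") {
    choose(model$S_B, k)
  } else if (model$eps == 0) {
    choose(model$S_A, k)
  } else {
    choose(model$S_A - 1L, k) + choose(model$S_A - 1L, k - 1L) * exp(-model$eps)
  }
  names(omega) <- k
  omega
}

#' Exact canonical occupancy distribution at fixed N
#'
#' `P^N(k) = Omega_A(k) Omega_B(N - k) / Z_N`.  For the purely entropic
#' lattice this is the hypergeometric law
#' `choose(S_A, k) choose(S_B, N - k) / choose(S_A + S_B, N)`.
#'
#' @param model A `lattice_model`.
#' @param N Particle number (`0 <= N <= N_max`).
#' @return Probability vector over `k = 0..N_max`.
#' @export
exact_canonical_distribution <- function(model, N) {
  stopifnot(N >= 0, N <= model$N_max)
  oA <- exact_omega(model, "A")
  oB <- exact_omega(model, "B")
  k <- 0:model$N_max
  w <- numeric(model$N_max + 1L)
  idx <- k <= N
  w[idx] <- oA[k[idx] + 1L] * oB[N - k[idx] + 1L]
  p <- w / sum(w)
  names(p) <- k
  p
}

#' Exact grand-canonical occupancy distributions of the lattice
#'
#' `P(k)` proportional to `Omega(k) z^k` with fugacity `z = exp(beta_mu)`;
#' for the entropic lattice each region is binomial with per-site success
#' probability `z / (1 + z)`.
#'
#' @param model A `lattice_model`.
#' @param beta_mu Dimensionless chemical potential.
#' @return List with probability vectors `P_A` and `P_B` over
#'   `k = 0..N_max`.
#' @export
exact_gc_distribution <- function(model, beta_mu) {
  pA <- exp(.gc_logp(exact_omega(model, "A"), beta_mu))
  pB <- exp(.gc_logp(exact_omega(model, "B"), beta_mu))
  names(pA) <- names(pB) <- 0:model$N_max
  list(P_A = pA, P_B = pB)
}

#' Sample canonical lattice occupancies
#'
#' Direct i.i.d. sampling of the region-A occupancy `k` from the exact
#' canonical distribution at fixed `N`.  Configurations factorize given
#' `k`, so no Markov chain is needed and individual site assignments are
#' never materialized.
#'
#' @param model A `lattice_model`.
#' @param N Particle number.
#' @param n_frames Number of frames to draw.
#' @param seed Optional integer seed for reproducibility.
#' @return Integer vector of length `n_frames` of region-A occupancies.
#' @export
sample_canonical <- function(model, N, n_frames, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_frames == 0L) return(integer(0))
  p <- exact_canonical_distribution(model, N)
  sample(0:model$N_max, size = n_frames, replace = TRUE, prob = p)
}

#' Sample a full set of constant-N lattice trajectories
#'
#' Convenience wrapper: one canonical trajectory per `N` in `1..N_max`,
#' in the occupancy-sequence format consumed by [build_count_matrix()].
#'
#' @param model A `lattice_model`.
#' @param n_frames Frames per trajectory (recycled over N).
#' @param seed Integer seed.
#' @return Named list of occupancy vectors.
#' @export
sample_lattice_trajectories <- function(model, n_frames, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_frames <- rep_len(n_frames, model$N_max)
  out <- lapply(seq_len(model$N_max), function(N)
    sample_canonical(model, N, n_frames[N]))
  names(out) <- seq_len(model$N_max)
  out
}

#' Read a lattice model from a key-value config file
#'
#' Plain `key = value` lines (or `key: value`); keys `S_A`, `S_B`, `eps`
#' (optional, default 0), `N_max` (optional).
#'
#' @param path Config file path.
#' @return A `lattice_model`.
#' @export
read_lattice_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "[=:]")
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- as.numeric(trimws(vapply(kv, `[`, "", 2)))
  get <- function(key, default = NULL) {
    i <- match(key, keys)
    if (is.na(i)) {
      if (is.null(default)) stop("lattice config missing key: ", key)
      default
    } else vals[i]
  }
  S_A <- get("S_A"); S_B <- get("S_B")
  lattice_model(S_A, S_B, eps = get("eps", 0),
                N_max = get("N_max", S_A + S_B))
}
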