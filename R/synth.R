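# Synthetic-data generators with exactly known ground truth.
#
# The statistical generator places N exchangeable particles over M
# nucleotide binding sites (site energies e_i, pairwise couplings J_ij, in
# k_B T), F unbound "free" slots inside region A, and S_B buffer slots,
# with mutual exclusion.  All per-N ensembles are enumerated exactly, so
# every downstream estimate (partition functions, reactivities, coupling
# free energies) has a closed-form reference.

#' Define a synthetic binding model
#'
#' @param M Number of nucleotide sites (<= 12; enumeration is over 2^M
#'   subsets).
#' @param e Site binding energies in k_B T (length M, default 0).
#' @param J Symmetric M x M matrix of pairwise couplings in k_B T
#'   (negative = cooperative; default 0).
#' @param free_slots Unbound-particle slots inside region A (default 0).
#' @param S_B Buffer slots.
#' @param N_max Maximum particle number (default `M + free_slots`, so the
#'   region-A occupancy support is never truncated).
#' @return Object of class `synth_binding_model`.
#' @export
synth_binding_model <- function(M, e = rep(0, M), J = matrix(0, M, M),
                                free_slots = 0L, S_B, N_max = M + free_slots) {
  stopifnot(M >= 1, M <= 12, length(e) == M, all(dim(J) == c(M, M)),
            max(abs(J - t(J))) < 1e-12, S_B >= 1, N_max >= 1)
  if (N_max > M + free_slots + S_B) stop("N_max exceeds total capacity")
  masks <- 0:(2^M - 1)
  member <- t(vapply(masks, function(m) bitwAnd(m, 2^(0:(M - 1))) > 0,
                     logical(M)))
  size <- rowSums(member)
  energy <- vapply(seq_along(masks), function(ix) {
    occ <- which(member[ix, ])
    en <- sum(e[occ])
    if (length(occ) > 1) {
      pr <- utils::combn(occ, 2)
      en <- en + sum(J[cbind(pr[1, ], pr[2, ])])
    }
    en
  }, numeric(1))
  structure(list(M = M, e = e, J = J, free_slots = as.integer(free_slots),
                 S_B = as.integer(S_B), N_max = as.integer(N_max),
                 member = member, size = size, energy = energy),
            class = "synth_binding_model")
}

# Enumerate region-A configurations (site subset x free-slot count) with
# their Boltzmann weights.  Returns a data frame-like list of parallel
# vectors: mask index, f, k = size + f, weight = C(F, f) exp(-E).
.synth_configs <- function(model) {
  Fn <- model$free_slots
  reps <- Fn + 1L
  n_sub <- length(model$size)
  ix <- rep(seq_len(n_sub), each = reps)
  f <- rep(0:Fn, times = n_sub)
  list(ix = ix, f = f, k = model$size[ix] + f,
       w = choose(Fn, f) * exp(-model$energy[ix]))
}

#' Exact regional partition functions of a synthetic model
#'
#' @param model A `synth_binding_model`.
#' @return List with `omega_A`, `omega_B` over `k = 0..N_max`.
#' @export
synth_exact_omega <- function(model) {
  cfg <- .synth_configs(model)
  k <- 0:model$N_max
  omega_A <- vapply(k, function(kk) sum(cfg$w[cfg$k == kk]), numeric(1))
  omega_B <- choose(model$S_B, k)
  names(omega_A) <- names(omega_B) <- k
  list(omega_A = omega_A, omega_B = omega_B)
}

#' Exact grand-canonical references of a synthetic model
#'
#' Per-site bound probabilities and the pairwise coupling matrix in the
#' grand-canonical ensemble at fugacity `exp(beta_mu)`, from full
#' enumeration of region-A configurations.
#'
#' @param model A `synth_binding_model`.
#' @param beta_mu Dimensionless chemical potential.
#' @return List with `R` (length M bound probabilities) and `ddg`
#'   (M x M coupling matrix in k_B T, `NA` diagonal).
#' @export
synth_exact_reference <- function(model, beta_mu) {
  cfg <- .synth_configs(model)
  gw <- cfg$w * exp(beta_mu * cfg$k)
  gw <- gw / sum(gw)
  memb <- model$member[cfg$ix, , drop = FALSE]
  R <- as.numeric(crossprod(memb, gw))
  M <- model$M
  ddg <- matrix(NA_real_, M, M)
  for (a in seq_len(M)) for (b in seq_len(M)) {
    if (b <= a) next
    sa <- memb[, a]; sb <- memb[, b]
    p11 <- sum(gw[sa & sb]); p00 <- sum(gw[!sa & !sb])
    p10 <- sum(gw[sa & !sb]); p01 <- sum(gw[!sa & sb])
    if (min(p11, p00, p10, p01) > 0)
      ddg[a, b] <- ddg[b, a] <- -log((p11 * p00) / (p10 * p01))
  }
  list(R = R, ddg = ddg)
}

#' Sample synthetic constant-N binding trajectories
#'
#' Draws i.i.d. frames per trajectory `N` in `1..N_max` from the exact
#' canonical distribution over region-A configurations (buffer takes the
#' remaining particles), returning the occupancy streams, the binding
#' table, and the exact reference quantities.
#'
#' @param model A `synth_binding_model`.
#' @param n_frames Frames per trajectory (recycled over N).
#' @param seed Optional integer seed.
#' @return List with `occupancies` (named list), `binding`
#'   (`binding_table`), and `exact` (`synth_exact_omega(model)` plus the
#'   model).
#' @export
synth_binding_trajectories <- function(model, n_frames, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_frames <- rep_len(n_frames, model$N_max)
  cfg <- .synth_configs(model)
  occupancies <- list()
  bind_rows <- list()
  for (N in seq_len(model$N_max)) {
    nb <- N - cfg$k                         # particles left for the buffer
    wN <- cfg$w * ifelse(nb >= 0 & nb <= model$S_B, choose(model$S_B, nb), 0)
    if (sum(wN) <= 0) stop("no admissible configuration at N = ", N)
    draw <- sample.int(length(wN), size = n_frames[N], replace = TRUE,
                       prob = wN)
    k <- cfg$k[draw]
    occupancies[[as.character(N)]] <- k
    bound <- model$member[cfg$ix[draw], , drop = FALSE]
    bind_rows[[N]] <- data.frame(trajectory_N = N,
                                 frame = seq_len(n_frames[N]) - 1L,
                                 k_A = k, bound + 0L)
  }
  binding <- do.call(rbind, bind_rows)
  names(binding) <- c("trajectory_N", "frame", "k_A",
                      paste0("nuc", seq_len(model$M)))
  class(binding) <- c("binding_table", "data.frame")
  list(occupancies = occupancies, binding = binding,
       exact = c(synth_exact_omega(model), list(model = model)))
}

#' Construct coordinate frames realizing an intended binding pattern
#'
#' Builds `probe_frame` objects whose geometric analysis reproduces a
#' requested pattern exactly: a bound probe's C7 sits 3.0 Angstrom from
#' its target O2' (all other O2' at >= 6 Angstrom), an unbound probe sits
#' far from every O2', and probe centers are placed inside or outside the
#' region-A sphere as requested.  Nucleotide O2' atoms lie on a 1 nm
#' circle around the RNA center of mass.
#'
#' @param patterns List of per-frame specs: each a list with `targets`
#'   (integer per probe: bound nucleotide index, or `NA` for unbound) and
#'   `in_region` (logical per probe; bound probes must be in-region).
#' @param M Number of nucleotides (<= 8 so the circle spacing stays clean).
#' @param r_A Region radius in nm (default 3).
#' @return List of `probe_frame` objects.
#' @export
synth_probe_frames <- function(patterns, M, r_A = 3) {
  stopifnot(M >= 1, M <= 8)
  ang <- 2 * pi * (seq_len(M) - 1) / M
  o2 <- cbind(cos(ang), sin(ang), 0)        # 1 nm circle
  lapply(patterns, function(pat) {
    targets <- pat$targets
    in_region <- pat$in_region %||% rep(TRUE, length(targets))
    stopifnot(length(in_region) == length(targets))
    if (any(!is.na(targets) & !in_region))
      stop("a bound probe must be inside the binding region")
    if (any(stats::na.omit(targets) > M) || anyDuplicated(stats::na.omit(targets)))
      stop("unrealizable pattern: bad or duplicated target nucleotides")
    n <- length(targets)
    c7 <- matrix(0, n, 3)
    free_in <- 0L; free_out <- 0L
    for (p in seq_len(n)) {
      if (!is.na(targets[p])) {
        c7[p, ] <- o2[targets[p], ] + c(0, 0, 0.30)   # 3.0 Angstrom above O2'
      } else if (in_region[p]) {
        th <- free_in * pi / 4; free_in <- free_in + 1L
        c7[p, ] <- c(2 * cos(th), 2 * sin(th), 1.5)   # in region, > 6 A from O2'
      } else {
        th <- free_out * pi / 4; free_out <- free_out + 1L
        c7[p, ] <- c((r_A + 3) * cos(th), (r_A + 3) * sin(th), 0)
      }
    }
    probe_frame(o2prime = o2, probe_c7 = c7, probe_com = c7,
                rna_com = c(0, 0, 0))
  })
}
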