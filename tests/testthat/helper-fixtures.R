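# Shared fixture builders.

# Exact fractional count matrix of an entropic lattice: t[N, k] equal to
# L * P^N(k) for every trajectory, so the ML solution is noise-free.
exact_lattice_counts <- function(model, L = 1e4) {
  t_mat <- matrix(0, model$N_max, model$N_max + 1L)
  for (N in seq_len(model$N_max))
    t_mat[N, ] <- L * exact_canonical_distribution(model, N)
  gcreweight:::new_count_matrix(t_mat)
}

# Sampled lattice pipeline: trajectories -> counts -> solved pf.
lattice_pipeline <- function(model, n_frames, seed) {
  occ <- sample_lattice_trajectories(model, n_frames, seed = seed)
  counts <- build_count_matrix(occ)
  list(model = model, occ = occ, counts = counts,
       pf = solve_partition_functions(counts))
}

# Synthetic binding setup shared by cooperativity tests: two coupled sites
# (J12 < 0) plus one independent site, with enough free region-A slots to
# support the study design of 19 constant-N trajectories, so occupancy
# truncation never binds at the tested concentrations.
coupled_model <- function(J12 = -1) {
  J <- matrix(0, 3, 3); J[1, 2] <- J[2, 1] <- J12
  synth_binding_model(M = 3, J = J, free_slots = 16, S_B = 25, N_max = 19)
}
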