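test_that("region occupancy counts probes inside the closed r_A ball", {
  fr <- probe_frame(o2prime = matrix(c(1, 0, 0), 1),
                    probe_c7 = rbind(c(1, 0, 0), c(4, 0, 0)),
                    probe_com = rbind(c(1, 0, 0), c(4, 0, 0)),
                    rna_com = c(0, 0, 0))
  expect_equal(assign_region_occupancy(fr, r_A = 3), 1L)
  # boundary probe at exactly r_A is inside
  fr2 <- probe_frame(o2prime = matrix(0, 1, 3),
                     probe_c7 = rbind(c(3, 0, 0)), rna_com = c(0, 0, 0))
  expect_equal(assign_region_occupancy(fr2, r_A = 3), 1L)
})

test_that("minimum-image convention makes occupancy and binding translation invariant", {
  box <- diag(c(8, 8, 8))
  o2 <- rbind(c(1, 0, 0), c(0, 1.2, 0))
  c7 <- rbind(c(1, 0, 0.30), c(5.5, 0, 0))
  fr <- probe_frame(o2prime = o2, probe_c7 = c7, rna_com = c(0, 0, 0),
                    box = box)
  k0 <- assign_region_occupancy(fr)
  b0 <- detect_binding(fr)
  # displace one probe by a full box vector: nothing changes
  c7_shift <- c7; c7_shift[1, ] <- c7_shift[1, ] + box[1, ]
  fr_s <- probe_frame(o2prime = o2, probe_c7 = c7_shift, rna_com = c(0, 0, 0),
                      box = box)
  expect_equal(assign_region_occupancy(fr_s), k0)
  expect_equal(detect_binding(fr_s)$bound, b0$bound)
  # rigid translation of everything (mod box)
  shift <- c(3, -2, 5)
  fr_t <- probe_frame(o2prime = sweep(o2, 2, shift, `+`),
                      probe_c7 = sweep(c7, 2, shift, `+`),
                      rna_com = shift, box = box)
  expect_equal(assign_region_occupancy(fr_t), k0)
  expect_equal(detect_binding(fr_t)$bound, b0$bound)
})

test_that("binding requires nearest nucleotide strictly below the threshold", {
  o2 <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  # C7 at 3.0 A from nucleotide 2, >= 5 A from others
  fr <- probe_frame(o2prime = o2, probe_c7 = rbind(c(1, 0, 0.30)),
                    rna_com = c(1, 0, 0))
  det <- detect_binding(fr, r_th = 3.5)
  expect_equal(det$bound, c(FALSE, TRUE, FALSE))
  expect_equal(det$probe_target, 2L)
  # nearest at 3.6 A: no binding (strict inequality)
  fr2 <- probe_frame(o2prime = o2, probe_c7 = rbind(c(1, 0, 0.36)),
                     rna_com = c(1, 0, 0))
  expect_equal(detect_binding(fr2, r_th = 3.5)$bound, rep(FALSE, 3))
  fr3 <- probe_frame(o2prime = o2, probe_c7 = rbind(c(1, 0, 0.35)),
                     rna_com = c(1, 0, 0))
  expect_equal(detect_binding(fr3, r_th = 3.5)$bound, rep(FALSE, 3))
})

test_that("each probe binds at most one nucleotide; ties go to the lowest index", {
  o2 <- rbind(c(0, 0, 0), c(0.5, 0, 0))
  fr <- probe_frame(o2prime = o2, probe_c7 = rbind(c(0.25, 0, 0)),
                    rna_com = c(0, 0, 0))
  det <- detect_binding(fr)
  expect_equal(det$probe_target, 1L)
  expect_lte(sum(det$bound), 1)
})

test_that("two probes can bind two nucleotides in one frame", {
  frames <- synth_probe_frames(list(list(targets = c(2L, 5L))), M = 6)
  det <- detect_binding(frames[[1]])
  expect_equal(which(det$bound), c(2L, 5L))
  expect_equal(assign_region_occupancy(frames[[1]]), 2L)
})

test_that("pair states enumerate a hand-built fixture correctly", {
  bt <- data.frame(trajectory_N = 2L, frame = 0:5, k_A = c(0, 0, 1, 1, 1, 2),
                   n1 = c(0, 0, 0, 1, 1, 1), n2 = c(0, 0, 1, 0, 0, 1))
  class(bt) <- c("binding_table", "data.frame")
  states <- tabulate_pair_states(bt, "n1", "n2")
  expect_equal(states, c("00", "00", "01", "10", "10", "11"))
  expect_equal(as.integer(table(factor(states, c("00", "01", "10", "11")))),
               c(2L, 1L, 2L, 1L))
  expect_error(tabulate_pair_states(bt, "n1", "zz"), "unknown nucleotide")
  expect_error(tabulate_pair_states(bt, "n1", "n1"), "distinct")
})

test_that("nearest-rule exclusivity bounds bound nucleotides by probe count", {
  set.seed(8)
  for (rep in 1:20) {
    n_probe <- sample(0:4, 1)
    o2 <- matrix(runif(12, -2, 2), 4, 3)
    c7 <- if (n_probe) matrix(runif(3 * n_probe, -2, 2), n_probe, 3) else matrix(0, 0, 3)
    fr <- probe_frame(o2prime = o2, probe_c7 = c7, rna_com = c(0, 0, 0))
    expect_lte(sum(detect_binding(fr)$bound), n_probe)
  }
})

test_that("binding_table aligns occupancy stream with trajectory order", {
  pats <- list(list(targets = c(1L), in_region = TRUE),
               list(targets = NA_integer_, in_region = FALSE),
               list(targets = NA_integer_, in_region = TRUE))
  frames <- synth_probe_frames(pats, M = 3)
  bt <- binding_table(list(`1` = frames), nucleotide_ids = c("a", "b", "c"))
  expect_equal(bt$k_A, c(1L, 0L, 1L))
  expect_equal(bt$a, c(1L, 0L, 0L))
  occ <- occupancies_from_binding(bt)
  expect_equal(occ[["1"]], c(1L, 0L, 1L))

  f <- withr::local_tempfile(fileext = ".tsv")
  write_binding_tsv(bt, f)
  back <- read_binding_tsv(f)
  expect_equal(as.data.frame(back), as.data.frame(bt))
})

test_that("synthetic frames realize requested patterns exactly", {
  pats <- list(list(targets = c(2L, NA), in_region = c(TRUE, TRUE)),
               list(targets = integer(0), in_region = logical(0)))
  frames <- synth_probe_frames(pats, M = 4)
  d1 <- detect_binding(frames[[1]])
  expect_equal(which(d1$bound), 2L)
  expect_equal(assign_region_occupancy(frames[[1]]), 2L)
  expect_equal(assign_region_occupancy(frames[[2]]), 0L)
  expect_error(synth_probe_frames(list(list(targets = c(9L))), M = 4),
               "unrealizable")
  expect_error(synth_probe_frames(list(list(targets = c(1L),
                                            in_region = FALSE)), M = 4),
               "inside the binding region")
})

test_that("PDB round trip through the trajectory reader", {
  pats <- list(list(targets = c(1L, NA), in_region = c(TRUE, TRUE)),
               list(targets = c(NA, 3L), in_region = c(FALSE, TRUE)),
               list(targets = c(NA, NA), in_region = c(FALSE, FALSE)))
  frames <- synth_probe_frames(pats, M = 3)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_frames_pdb(frames, f)
  got <- read_trajectory(f)
  expect_length(got, 3)
  expect_equal(attr(got, "nucleotide_ids"), c("RA1", "RA2", "RA3"))
  for (i in 1:3) {
    expect_equal(got[[i]]$o2prime, frames[[i]]$o2prime, tolerance = 1e-3)
    expect_equal(got[[i]]$probe_c7, frames[[i]]$probe_c7, tolerance = 1e-3)
    expect_equal(detect_binding(got[[i]])$bound,
                 detect_binding(frames[[i]])$bound)
  }
  expect_error(read_trajectory(f, probe_resname = "XXX"), "no probe residues")
  expect_error(read_trajectory(f, trajectory = "x.xtc"), "XTC")
})
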