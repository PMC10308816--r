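# Trajectory input: turn topology + coordinate frames into probe_frame
# objects via bio3d.  Multi-model PDB and DCD are supported; the atom
# bookkeeping (which atoms are nucleotide O2', which residues are probes)
# comes from the topology.

#' Read coordinate frames for binding analysis
#'
#' Resolves per-nucleotide O2' atoms and per-probe reactive-carbonyl (C7)
#' atoms from a PDB topology, then yields one [probe_frame()] per
#' coordinate frame.  Frames come from the trajectory file when given
#' (DCD), otherwise from the models of a multi-model PDB.  Coordinates are
#' converted from Angstrom to nm.  Probe centers of mass use element
#' masses when resolvable, falling back to unweighted means.
#'
#' @param topology Path to a PDB file (atom names, residues; also frames if
#'   `trajectory` is `NULL`).
#' @param trajectory Optional path to a DCD trajectory.
#' @param probe_resname Residue name identifying probe molecules (default
#'   `"1M7"`).
#' @param probe_atom Reactive-carbonyl atom name within the probe residue
#'   (default `"C7"`).
#' @param o2_names Accepted O2' atom names (default `c("O2'", "O2*")`).
#' @param exclude_residues Residue numbers dropped from the nucleotide set
#'   (e.g. restrained terminal bases).
#' @param box Optional 3x3 triclinic box matrix in nm applied to every
#'   frame; `NULL` means open boundaries.
#' @return List of `probe_frame` objects (attribute `nucleotide_ids`
#'   carries residue labels).
#' @export
read_trajectory <- function(topology, trajectory = NULL,
                            probe_resname = "1M7", probe_atom = "C7",
                            o2_names = c("O2'", "O2*"),
                            exclude_residues = NULL, box = NULL) {
  ext <- tolower(tools::file_ext(trajectory %||% topology))
  if (ext %in% c("xtc", "trr"))
    stop("XTC/TRR trajectories are not supported by the available readers; ",
         "convert to DCD or multi-model PDB")
  pdb <- bio3d::read.pdb(topology, multi = is.null(trajectory), verbose = FALSE)
  atoms <- pdb$atom

  is_probe <- atoms$resid == probe_resname
  probe_res <- unique(atoms$resno[is_probe])
  if (length(probe_res) == 0L)
    stop("no probe residues matched resname '", probe_resname, "'")
  nuc_rows <- which(!is_probe & atoms$elety %in% o2_names &
                      !(atoms$resno %in% exclude_residues))
  if (length(nuc_rows) == 0L)
    stop("no nucleotide O2' atoms matched (names tried: ",
         paste(o2_names, collapse = ", "), ")")
  nuc_ids <- paste0(atoms$resid[nuc_rows], atoms$resno[nuc_rows])

  c7_rows <- integer(length(probe_res))
  probe_rows <- vector("list", length(probe_res))
  for (i in seq_along(probe_res)) {
    sel <- which(is_probe & atoms$resno == probe_res[i])
    probe_rows[[i]] <- sel
    hit <- sel[atoms$elety[sel] == probe_atom]
    if (length(hit) != 1L)
      stop("probe residue ", probe_res[i], " is missing atom ", probe_atom)
    c7_rows[i] <- hit
  }

  # per-probe masses for the center of mass; fall back to equal weights
  probe_mass <- lapply(probe_rows, function(sel) {
    m <- tryCatch(bio3d::atom2mass(atoms$elety[sel]),
                  error = function(e) NULL, warning = function(w) NULL)
    if (is.null(m) || any(!is.finite(m))) rep(1, length(sel)) else m
  })

  xyz <- if (is.null(trajectory)) pdb$xyz else bio3d::read.dcd(trajectory, verbose = FALSE)
  xyz <- rbind(xyz)
  n_atoms <- nrow(atoms)
  if (ncol(xyz) != 3L * n_atoms)
    stop("coordinate/topology atom count mismatch")

  frames <- lapply(seq_len(nrow(xyz)), function(f) {
    crd <- matrix(xyz[f, ], ncol = 3, byrow = TRUE) / 10   # Angstrom -> nm
    o2 <- crd[nuc_rows, , drop = FALSE]
    c7 <- crd[c7_rows, , drop = FALSE]
    com <- t(vapply(seq_along(probe_rows), function(i) {
      sel <- probe_rows[[i]]; m <- probe_mass[[i]]
      colSums(crd[sel, , drop = FALSE] * m) / sum(m)
    }, numeric(3)))
    if (length(probe_rows) == 0L) com <- matrix(0, 0, 3)
    rna_rows <- which(!is_probe)
    probe_frame(o2prime = o2, probe_c7 = c7, probe_com = com,
                rna_com = colMeans(crd[rna_rows, , drop = FALSE]),
                box = box)
  })
  attr(frames, "nucleotide_ids") <- nuc_ids
  frames
}

#' Write frames as a multi-model PDB
#'
#' Emits synthetic [probe_frame()] sequences in a format that
#' [read_trajectory()] can round-trip: nucleotides become one O2' atom per
#' residue (resid `RA`), probes one C7 atom per residue (resid given by
#' `probe_resname`).  Coordinates are converted from nm to Angstrom.
#'
#' @param frames List of `probe_frame` objects (equal atom counts).
#' @param path Output PDB path.
#' @param probe_resname Residue name for probes (default `"1M7"`).
#' @export
write_frames_pdb <- function(frames, path, probe_resname = "1M7") {
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00"
  for (f in seq_along(frames)) {
    fr <- frames[[f]]
    writeLines(sprintf("MODEL     %4d", f), con)
    serial <- 0L; resno <- 0L
    for (i in seq_len(nrow(fr$o2prime))) {
      serial <- serial + 1L; resno <- resno + 1L
      p <- fr$o2prime[i, ] * 10
      writeLines(sprintf(fmt, serial, "O2'", "RA", resno, p[1], p[2], p[3]), con)
    }
    for (i in seq_len(nrow(fr$probe_c7))) {
      serial <- serial + 1L; resno <- resno + 1L
      p <- fr$probe_c7[i, ] * 10
      writeLines(sprintf(fmt, serial, "C7", probe_resname, resno, p[1], p[2], p[3]), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
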