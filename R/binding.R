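# Geometric extraction of region occupancies and nucleotide binding states
# from coordinate frames.
#
# Region A is a sphere of radius r_A (default 3 nm) around the RNA center
# of mass; a probe belongs to it when its center of mass lies within the
# minimum-image distance r_A (closed ball).  A probe binds a nucleotide
# when that nucleotide's O2' is the nearest one to the probe's reactive
# carbonyl carbon (C7) and the O2'-C7 distance is strictly below r_th
# (default 3.5 Angstrom).  The subsequent acylation chemistry is not
# modeled.

#' Construct a coordinate frame for binding analysis
#'
#' All coordinates in nm.  `box` is an optional 3x3 matrix of triclinic box
#' vectors (rows); when `NULL`, distances are plain Euclidean (open
#' boundaries).
#'
#' @param o2prime Matrix `n_nuc x 3` of per-nucleotide O2' positions.
#' @param probe_c7 Matrix `n_probe x 3` of per-probe reactive-carbonyl C7
#'   positions.
#' @param probe_com Matrix `n_probe x 3` of probe centers of mass
#'   (defaults to `probe_c7`).
#' @param rna_com Length-3 RNA center of mass.
#' @param box Optional 3x3 triclinic box matrix (nm).
#' @return Object of class `probe_frame`.
#' @export
probe_frame <- function(o2prime, probe_c7, probe_com = probe_c7,
                        rna_com, box = NULL) {
  o2prime <- rbind(o2prime); rna_com <- as.numeric(rna_com)
  probe_c7 <- if (length(probe_c7)) rbind(probe_c7) else matrix(0, 0, 3)
  probe_com <- if (length(probe_com)) rbind(probe_com) else matrix(0, 0, 3)
  stopifnot(ncol(o2prime) == 3, length(rna_com) == 3,
            nrow(probe_c7) == nrow(probe_com))
  if (!all(is.finite(o2prime)) || !all(is.finite(probe_c7)) ||
      !all(is.finite(rna_com)))
    stop("non-finite coordinates")
  if (!is.null(box)) {
    box <- as.matrix(box)
    stopifnot(all(dim(box) == c(3, 3)), is.finite(det(box)), det(box) > 0)
  }
  structure(list(o2prime = o2prime, probe_c7 = probe_c7,
                 probe_com = probe_com, rna_com = rna_com, box = box),
            class = "probe_frame")
}

# Minimum-image distances between one point x and rows of matrix y under a
# triclinic cell (search over the 27 neighbor shifts; valid when distances
# are below half the cell extent, as in the use cases here).
.min_image_dist <- function(x, y, box = NULL) {
  d <- sweep(y, 2, x)
  if (is.null(box)) return(sqrt(rowSums(d^2)))
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1)) %*% box
  best <- rep(Inf, nrow(y))
  for (s in seq_len(nrow(shifts))) {
    ds <- sweep(d, 2, shifts[s, ], `+`)
    best <- pmin(best, rowSums(ds^2))
  }
  sqrt(best)
}

#' Count probes inside the binding region
#'
#' @param frame A `probe_frame`.
#' @param r_A Binding-region radius in nm (default 3).  The boundary is
#'   included (closed ball).
#' @return Integer occupancy `k`.
#' @export
assign_region_occupancy <- function(frame, r_A = 3) {
  stopifnot(inherits(frame, "probe_frame"), r_A > 0)
  if (nrow(frame$probe_com) == 0L) return(0L)
  d <- .min_image_dist(frame$rna_com, frame$probe_com, frame$box)
  sum(d <= r_A)
}

#' Detect nucleotide-probe binding in a frame
#'
#' For each probe, the nearest nucleotide (O2' to probe C7, minimum image)
#' is found; the probe binds it when the distance is strictly below `r_th`.
#' Ties in the nearest-nucleotide search are broken toward the lowest
#' nucleotide index.  A nucleotide is bound when at least one probe binds
#' it; each probe binds at most one nucleotide.
#'
#' @param frame A `probe_frame`.
#' @param r_th Binding distance threshold in Angstrom (default 3.5).
#' @return List with `bound` (logical per nucleotide), `bound_probe`
#'   (index of one binding probe per nucleotide, `NA` if unbound) and
#'   `probe_target` (per probe: bound nucleotide index or `NA`).
#' @export
detect_binding <- function(frame, r_th = 3.5) {
  stopifnot(inherits(frame, "probe_frame"), r_th > 0)
  n_nuc <- nrow(frame$o2prime)
  n_probe <- nrow(frame$probe_c7)
  r_th_nm <- r_th / 10                      # coordinates are in nm
  bound <- rep(FALSE, n_nuc)
  bound_probe <- rep(NA_integer_, n_nuc)
  probe_target <- rep(NA_integer_, n_probe)
  for (p in seq_len(n_probe)) {
    d <- .min_image_dist(frame$probe_c7[p, ], frame$o2prime, frame$box)
    nearest <- which.min(d)                 # which.min takes the lowest index on ties
    if (d[nearest] < r_th_nm) {
      probe_target[p] <- nearest
      bound[nearest] <- TRUE
      if (is.na(bound_probe[nearest])) bound_probe[nearest] <- p
    }
  }
  list(bound = bound, bound_probe = bound_probe, probe_target = probe_target)
}

#' Build a binding table from a sequence of frames
#'
#' Applies [assign_region_occupancy()] and [detect_binding()] to every
#' frame of every constant-N trajectory, preserving frame order so the
#' occupancy stream stays aligned with downstream reweighting.
#'
#' @param frames_by_N Named list (names = trajectory N) of lists of
#'   `probe_frame` objects.
#' @param r_A Region radius in nm.
#' @param r_th Binding threshold in Angstrom.
#' @param nucleotide_ids Character vector of nucleotide labels (defaults
#'   to `nuc1..nucM`).
#' @return Object of class `binding_table`: data frame with columns
#'   `trajectory_N`, `frame`, `k_A` and one 0/1 column per nucleotide.
#' @export
binding_table <- function(frames_by_N, r_A = 3, r_th = 3.5,
                          nucleotide_ids = NULL) {
  rows <- list()
  for (nm in names(frames_by_N)) {
    frames <- frames_by_N[[nm]]
    N <- as.integer(nm)
    for (i in seq_along(frames)) {
      fr <- frames[[i]]
      k <- assign_region_occupancy(fr, r_A)
      if (k > N) stop("occupancy exceeds trajectory particle number N = ", N)
      det <- detect_binding(fr, r_th)
      rows[[length(rows) + 1L]] <-
        c(trajectory_N = N, frame = i - 1L, k_A = k, as.integer(det$bound))
    }
  }
  df <- as.data.frame(do.call(rbind, rows))
  n_nuc <- ncol(df) - 3L
  if (is.null(nucleotide_ids)) nucleotide_ids <- paste0("nuc", seq_len(n_nuc))
  names(df) <- c("trajectory_N", "frame", "k_A", nucleotide_ids)
  class(df) <- c("binding_table", "data.frame")
  df
}

# nucleotide columns of a binding table
.bt_nucleotides <- function(table) {
  setdiff(names(table), c("trajectory_N", "frame", "k_A"))
}

#' Per-frame pairwise binding states
#'
#' States over a nucleotide pair: `"00"` both unbound, `"10"` only `i`
#' bound, `"01"` only `j` bound, `"11"` both bound (necessarily to two
#' distinct probes, since a probe binds at most one nucleotide).
#'
#' @param table A `binding_table`.
#' @param i,j Nucleotide ids (column names), `i != j`.
#' @return Character vector of states, one per frame, in table order.
#' @export
tabulate_pair_states <- function(table, i, j) {
  nucs <- .bt_nucleotides(table)
  if (!(i %in% nucs) || !(j %in% nucs))
    stop("unknown nucleotide id(s): ",
         paste(setdiff(c(i, j), nucs), collapse = ", "))
  if (identical(i, j)) stop("pair states need two distinct nucleotides")
  paste0(table[[i]], table[[j]])
}

#' Write a binding table to TSV
#' @param table A `binding_table`.
#' @param path Output path.
#' @export
write_binding_tsv <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a binding table from TSV
#' @param path Path written by [write_binding_tsv()].
#' @return A `binding_table`.
#' @export
read_binding_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  need <- c("trajectory_N", "frame", "k_A")
  if (!all(need %in% names(df)))
    stop("binding TSV must have columns: ", paste(need, collapse = ", "))
  class(df) <- c("binding_table", "data.frame")
  df
}

#' Occupancy sequences carried by a binding table
#'
#' Extracts the per-trajectory region-A occupancy streams, in frame order,
#' in the format consumed by [build_count_matrix()].
#'
#' @param table A `binding_table`.
#' @return Named list of integer vectors.
#' @export
occupancies_from_binding <- function(table) {
  df <- table[order(table$trajectory_N, table$frame), ]
  split(df$k_A, df$trajectory_N)
}
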