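# Count matrices pooled over constant-N trajectories.
#
# The (N, k) cell counts frames of the N-particle trajectory observed with
# exactly k particles in region A (and hence N - k in region B).  Rows for
# missing simulations are allowed and simply carry zero counts.

#' Build a count matrix from per-frame region-A occupancies
#'
#' Pools a set of constant-N trajectories into the triangular count matrix
#' used by the maximum-likelihood estimator of the regional partition
#' functions.  Each trajectory is a sequence of per-frame occupancies of
#' region A; the trajectory run with N particle copies can only show
#' occupancies in `0..N`.
#'
#' @param occupancy_sequences Named list mapping the trajectory particle
#'   number `N` (names coercible to integer) to an integer vector of
#'   per-frame region-A occupancies.  Empty vectors mark missing
#'   simulations.
#' @param N_max Maximum particle number.  Defaults to the largest `N`
#'   present in `occupancy_sequences`; rows for absent `N` are zero.
#'
#' @return An object of class `count_matrix` with components:
#'   \describe{
#'     \item{t}{numeric matrix `(N_max) x (N_max + 1)`, row `N`, column
#'       `k + 1` holds the frame count `t[N, k]`.}
#'     \item{A}{vector of length `N_max + 1`, `A[k + 1] = sum_N t[N, k]`.}
#'     \item{B}{vector of length `N_max + 1`, `B[k + 1] = sum_N t[N, N - k]`.}
#'     \item{L}{vector of length `N_max`, frames per trajectory.}
#'     \item{N_max}{maximum particle number.}
#'   }
#' @export
#' @examples
#' cm <- build_count_matrix(list(`1` = c(0, 1, 1, 0)))
#' cm$t
build_count_matrix <- function(occupancy_sequences, N_max = NULL) {
  if (length(occupancy_sequences) == 0L)
    stop("no occupancy sequences supplied")
  Ns <- suppressWarnings(as.integer(names(occupancy_sequences)))
  if (anyNA(Ns) || any(Ns < 1L))
    stop("occupancy_sequences must be named by positive trajectory particle numbers")
  if (anyDuplicated(Ns))
    stop("duplicate trajectory particle numbers: ",
         paste(Ns[duplicated(Ns)], collapse = ", "))
  if (is.null(N_max)) N_max <- max(Ns)
  N_max <- as.integer(N_max)
  if (any(Ns > N_max))
    stop("trajectory N exceeds N_max")

  t_mat <- matrix(0, nrow = N_max, ncol = N_max + 1L,
                  dimnames = list(N = seq_len(N_max), k = 0:N_max))
  for (i in seq_along(Ns)) {
    N <- Ns[i]
    occ <- occupancy_sequences[[i]]
    if (length(occ) == 0L) next
    occ <- as.numeric(occ)
    bad <- which(!is.finite(occ) | occ < 0 | occ > N | occ != round(occ))
    if (length(bad))
      stop(sprintf(
        "invalid occupancy %s at frame %d of trajectory N=%d (must be integer in 0..%d)",
        format(occ[bad[1]]), bad[1], N, N))
    t_mat[N, ] <- tabulate(occ + 1L, nbins = N_max + 1L)
  }
  new_count_matrix(t_mat)
}

# Construct the container (with marginals) from a bare t matrix.  Used both
# by build_count_matrix and by the Dirichlet bootstrap, which feeds
# fractional (real-valued) counts through the same ML machinery.
new_count_matrix <- function(t_mat) {
  N_max <- nrow(t_mat)
  stopifnot(ncol(t_mat) == N_max + 1L)
  # triangularity: k > N impossible by construction
  for (N in seq_len(N_max)) {
    if (N < N_max && any(t_mat[N, (N + 2L):(N_max + 1L)] != 0))
      stop("count matrix not triangular: t[N, k] > 0 with k > N at N = ", N)
  }
  A <- colSums(t_mat)
  B <- numeric(N_max + 1L)
  for (N in seq_len(N_max)) {
    for (k in 0:N) B[k + 1L] <- B[k + 1L] + t_mat[N, N - k + 1L]
  }
  L <- rowSums(t_mat)
  names(A) <- names(B) <- 0:N_max
  names(L) <- seq_len(N_max)
  structure(list(t = t_mat, A = A, B = B, L = L, N_max = N_max),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: N_max = %d, %s frames over %d non-empty trajectories\n",
              x$N_max, format(sum(x$L)), sum(x$L > 0)))
  invisible(x)
}

#' Read per-frame occupancies from a TSV file
#'
#' Expects columns `trajectory_N`, `frame`, `k_A`.  Frames are ordered by
#' `frame` within each trajectory.
#'
#' @param path Path to a tab-separated file.
#' @return Named list of occupancy vectors, suitable for
#'   [build_count_matrix()].
#' @export
read_occupancy_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("trajectory_N", "frame", "k_A")
  if (!all(need %in% names(df)))
    stop("occupancy TSV must have columns: ", paste(need, collapse = ", "))
  df <- df[order(df$trajectory_N, df$frame), ]
  split(df$k_A, df$trajectory_N)
}

#' Write per-frame occupancies to a TSV file
#'
#' @param occupancy_sequences Named list as accepted by
#'   [build_count_matrix()].
#' @param path Output path.
#' @export
write_occupancy_tsv <- function(occupancy_sequences, path) {
  rows <- lapply(names(occupancy_sequences), function(nm) {
    occ <- occupancy_sequences[[nm]]
    if (length(occ) == 0L) return(NULL)
    data.frame(trajectory_N = as.integer(nm),
               frame = seq_along(occ) - 1L,
               k_A = as.integer(occ))
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a count matrix as TSV
#'
#' Header row of k values, one row per N.
#' @param counts A `count_matrix`.
#' @param path Output path.
#' @export
write_count_matrix_tsv <- function(counts, path) {
  df <- data.frame(N = seq_len(counts$N_max), counts$t, check.names = FALSE)
  names(df) <- c("N", paste0("k", 0:counts$N_max))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Import a count matrix from TSV
#'
#' @param path Path written by [write_count_matrix_tsv()].
#' @return A `count_matrix`.
#' @export
read_count_matrix_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  t_mat <- as.matrix(df[, -1, drop = FALSE])
  dimnames(t_mat) <- list(N = df$N, k = 0:(ncol(t_mat) - 1L))
  new_count_matrix(t_mat)
}
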