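# Experimental SHAPE concentration series: per-channel read normalization,
# per-nucleotide power-law fits, and group comparison of exponents between
# GNRA-loop and other nucleotides.

#' Normalize raw reads across concentration channels
#'
#' Per channel: negative reads are clipped to zero, the channel is divided
#' by its (post-clipping) sum, and the result is multiplied by the
#' channel's nominal concentration.  This enforces a linear dependence of
#' the average read on concentration while preserving position- and
#' concentration-dependence; the output is invariant to any per-channel
#' multiplicative gain.
#'
#' @param reads Numeric matrix or data frame, rows = positions, one column
#'   per concentration channel.
#' @param concentrations Nominal channel molarities (one per column).
#' @return Matrix of normalized reactivities (same shape).
#' @export
normalize_reads <- function(reads, concentrations) {
  reads <- as.matrix(reads)
  if (length(concentrations) != ncol(reads))
    stop("one nominal concentration per channel required")
  out <- reads
  for (j in seq_len(ncol(reads))) {
    ch <- pmax(reads[, j], 0)
    s <- sum(ch)
    if (s <= 0) stop("channel ", j, " sums to zero after clipping")
    out[, j] <- ch / s * concentrations[j]
  }
  out
}

#' Per-nucleotide power-law fits over a concentration series
#'
#' Log-log least squares of normalized reactivity on channel
#' concentration, per position: `R = alpha * C^beta`.  Also reports the
#' shifted amplitude `alpha * C_ref^beta`, the fitted reactivity moved to
#' a reference concentration inside the measured range, which is far less
#' sensitive to errors on `beta` than the 1 M extrapolation `alpha`.
#'
#' @param normalized Matrix from [normalize_reads()].
#' @param concentrations Channel molarities.
#' @param C_ref Reference concentration for the shifted amplitude
#'   (default 0.0125 M).
#' @return Data frame with `position`, `alpha`, `beta`, `shifted_amplitude`,
#'   `se_beta`, and `ok` (FALSE where the fit was refused because of
#'   nonpositive values — flagged, never silently dropped).
#' @export
fit_concentration_series <- function(normalized, concentrations,
                                     C_ref = 0.0125) {
  normalized <- as.matrix(normalized)
  if (ncol(normalized) < 2L)
    stop("at least two concentration channels required")
  res <- lapply(seq_len(nrow(normalized)), function(i) {
    y <- normalized[i, ]
    if (any(y <= 0))
      return(data.frame(position = i, alpha = NA_real_, beta = NA_real_,
                        shifted_amplitude = NA_real_, se_beta = NA_real_,
                        ok = FALSE))
    fit <- stats::lm(log(y) ~ log(concentrations))
    co <- stats::coef(fit)
    se_beta <- if (length(y) > 2L)
      suppressWarnings(sqrt(stats::vcov(fit)[2, 2])) else NA_real_
    alpha <- exp(unname(co[1])); beta <- unname(co[2])
    data.frame(position = i, alpha = alpha, beta = beta,
               shifted_amplitude = alpha * C_ref^beta, se_beta = se_beta,
               ok = TRUE)
  })
  do.call(rbind, res)
}

#' Compare power-law parameters between structural groups
#'
#' Two-sample t-tests (Welch by default) for the means of the exponent
#' `beta` and of the shifted amplitude between nucleotides inside GNRA
#' tetraloops and all others.  Also reports the mean over G nucleotides at
#' the first tetraloop position when flagged.
#'
#' @param fits Data frame from [fit_concentration_series()] (rows with
#'   `ok == FALSE` are dropped).
#' @param gnra Logical vector: GNRA-loop membership per row of `fits`.
#' @param g1 Optional logical vector: first-position G of a tetraloop.
#' @param pooled Use the pooled-variance t-test instead of Welch.
#' @return List with per-group means, `beta_G1` (or `NA`), and `t_beta`,
#'   `t_amplitude` test results (`NULL` when a group has < 2 members).
#' @export
compare_groups <- function(fits, gnra, g1 = NULL, pooled = FALSE) {
  stopifnot(length(gnra) == nrow(fits))
  keep <- fits$ok
  fits <- fits[keep, ]; gnra <- gnra[keep]
  if (!is.null(g1)) g1 <- g1[keep]
  if (!any(gnra) || !any(!gnra)) stop("both groups must be non-empty")
  grp <- function(x, g) x[g]
  means <- list(
    beta_GNRA = mean(grp(fits$beta, gnra)),
    beta_other = mean(grp(fits$beta, !gnra)),
    amplitude_GNRA = mean(grp(fits$shifted_amplitude, gnra)),
    amplitude_other = mean(grp(fits$shifted_amplitude, !gnra)),
    beta_G1 = if (!is.null(g1) && any(g1)) mean(fits$beta[g1]) else NA_real_,
    amplitude_G1 = if (!is.null(g1) && any(g1))
      mean(fits$shifted_amplitude[g1]) else NA_real_)
  run_test <- function(x) {
    if (sum(gnra) < 2L || sum(!gnra) < 2L) return(NULL)
    # degenerate case: both groups constant and equal -> no evidence
    if (stats::sd(x[gnra]) == 0 && stats::sd(x[!gnra]) == 0 &&
        mean(x[gnra]) == mean(x[!gnra]))
      return(list(statistic = c(t = 0), p.value = 1,
                  estimate = c(mean(x[gnra]), mean(x[!gnra])),
                  method = "degenerate (constant equal groups)"))
    stats::t.test(x[gnra], x[!gnra], var.equal = pooled)
  }
  c(means, list(t_beta = run_test(fits$beta),
                t_amplitude = run_test(fits$shifted_amplitude)))
}

#' Read an experimental concentration-series table
#'
#' CSV with columns `molecule`, `position`, `residue`, `gnra_flag`, then
#' one read column per channel whose header encodes the molarity (e.g.
#' `C_0.0032`).
#'
#' @param path CSV path.
#' @return List with `meta` (data frame), `reads` (matrix), and
#'   `concentrations` (mol/L, parsed from the headers).
#' @export
read_reads_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta_cols <- c("molecule", "position", "residue", "gnra_flag")
  if (!all(meta_cols %in% names(df)))
    stop("reads CSV must have columns: ", paste(meta_cols, collapse = ", "))
  chan <- setdiff(names(df), meta_cols)
  if (length(chan) < 2L) stop("at least two concentration channels required")
  conc <- as.numeric(sub("^[^0-9]*", "", chan))
  if (anyNA(conc)) stop("channel headers must encode molarity, e.g. C_0.0032")
  list(meta = df[meta_cols], reads = as.matrix(df[chan]),
       concentrations = conc)
}
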