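#' Construct a scattering curve
#'
#' @param q scattering vector grid (Angstrom^-1, ascending, >= 0)
#' @param intensity I(q), arbitrary units, positive
#' @param err optional per-point uncertainty
#' @return object of class `scattering_curve` with `q`, `intensity`, `err`,
#'   `i0` (intensity at/toward q = 0)
#' @export
scattering_curve <- function(q, intensity, err = NULL) {
  stopifnot(length(q) == length(intensity))
  if (is.unsorted(q)) stop("`q` must be ascending", call. = FALSE)
  if (any(intensity <= 0)) stop("I(q) must be positive", call. = FALSE)
  structure(list(q = as.numeric(q), intensity = as.numeric(intensity),
                 err = err, i0 = intensity[which.min(q)]),
            class = "scattering_curve")
}

#' Read / write 3-column SAXS .dat files (q, I, err)
#' @param path file path
#' @return a [scattering_curve]
#' @export
read_saxs_dat <- function(path) {
  df <- utils::read.table(path, comment.char = "#",
                          col.names = c("q", "I", "err"), fill = TRUE)
  scattering_curve(df$q, df$I, if (all(is.na(df$err))) NULL else df$err)
}

#' @rdname read_saxs_dat
#' @param curve a [scattering_curve] to write
#' @export
write_saxs_dat <- function(curve, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# q(A^-1) I(arb) err", con)
  err <- curve$err %||% rep(NA_real_, length(curve$q))
  utils::write.table(data.frame(curve$q, curve$intensity, err), con,
                     col.names = FALSE, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Debye scattering profile of an ensemble
#'
#' Reduced-representation Debye formula with uniform point form factors:
#' per frame `I(q) = sum_ij sin(q r_ij) / (q r_ij)` (terms with
#' `q r_ij = 0` contribute 1), averaged over frames. `I(0) = N^2` for N
#' sites.
#'
#' @param ens an [ensemble] (Angstrom)
#' @param q_grid ascending q grid (Angstrom^-1), may include 0
#' @return a [scattering_curve]
#' @export
debye_scattering <- function(ens, q_grid) {
  stopifnot(inherits(ens, "ensemble"))
  if (any(q_grid < 0)) stop("q must be >= 0", call. = FALSE)
  n <- n_sites(ens)
  w <- ens$weights %||% rep(1 / n_frames(ens), n_frames(ens))
  iq <- numeric(length(q_grid))
  for (f in seq_len(n_frames(ens))) {
    d <- stats::dist(frame_xyz(ens$coords, f))  # n(n-1)/2 distances
    qr <- outer(as.numeric(d), q_grid)                # pairs x q
    s <- ifelse(qr == 0, 1, sin(qr) / qr)
    iq <- iq + w[f] * (n + 2 * colSums(s))
  }
  scattering_curve(q_grid, iq)
}

#' Guinier fit of the low-q scattering region
#'
#' Linear fit of `ln I` against `q^2`; `Rg = sqrt(-3 * slope)`. The fitted
#' q-range is shrunk iteratively from the top until `q_max * Rg <= qRg_max`
#' (the standard validity bound; 1.3 for globular, up to ~1.0-2 acceptable for
#' disordered chains).
#'
#' @param curve a [scattering_curve]
#' @param qRg_max upper bound on `q_max * Rg` (default 1.3)
#' @param min_points minimum number of points retained (default 5)
#' @return list with `rg` (Angstrom), `i0`, `q_range`, `n_points`
#' @export
guinier_fit <- function(curve, qRg_max = 1.3, min_points = 5L) {
  stopifnot(inherits(curve, "scattering_curve"))
  keep <- curve$q > 0
  q <- curve$q[keep]; I <- curve$intensity[keep]
  if (length(q) < min_points) stop("too few positive-q points", call. = FALSE)
  hi <- length(q)
  repeat {
    fit <- stats::lm(log(I[1:hi]) ~ I(q[1:hi]^2))
    slope <- stats::coef(fit)[[2]]
    if (slope >= 0)
      stop("non-Guinier curve: positive low-q slope", call. = FALSE)
    rg <- sqrt(-3 * slope)
    if (q[hi] * rg <= qRg_max || hi <= min_points) break
    hi <- hi - 1L
  }
  if (q[hi] * rg > qRg_max)
    warning(sprintf("could not satisfy qRg <= %.2f with >= %d points (qRg = %.2f)",
                    qRg_max, min_points, q[hi] * rg))
  list(rg = rg, i0 = exp(stats::coef(fit)[[1]]),
       q_range = c(q[1L], q[hi]), n_points = hi)
}

#' Dimensionless Kratky transform
#'
#' Returns `x = q * Rg` and `y = x^2 * I(q) / I0`, the compactness diagnostic
#' whose maximum sits at `(sqrt(3), 3/e)` for an ideal Guinier (globular)
#' curve and plateaus for expanded chains.
#'
#' @param curve a [scattering_curve]
#' @param rg radius of gyration (Angstrom), e.g. from [guinier_fit()]
#' @param i0 forward intensity; defaults to the curve's `i0`
#' @return data.frame with `x` (qRg) and `y`
#' @export
kratky_dimensionless <- function(curve, rg, i0 = NULL) {
  stopifnot(inherits(curve, "scattering_curve"))
  i0 <- i0 %||% curve$i0
  if (i0 <= 0) stop("I0 must be positive", call. = FALSE)
  x <- curve$q * rg
  data.frame(x = x, y = x^2 * curve$intensity / i0)
}
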