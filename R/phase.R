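#' Construct a turbidity titration curve
#'
#' Absorbance at 340 nm versus titrant concentration (or molar ratio) at a
#' fixed concentration of the second component; the standard order parameter
#' for coacervation experiments.
#'
#' @param x ascending titrant concentration (uM) or molar ratio
#' @param a340 absorbance at 340 nm per point (>= 0)
#' @param fixed_component optional list `list(name=, conc_uM=)`
#' @param nacl_mM NaCl concentration (mM)
#' @param sd optional per-point replicate SD
#' @return object of class `turbidity_curve`
#' @export
turbidity_curve <- function(x, a340, fixed_component = NULL, nacl_mM = NA,
                            sd = NULL) {
  if (is.unsorted(x, strictly = TRUE))
    stop("`x` must be strictly ascending", call. = FALSE)
  if (any(a340 < 0)) stop("a340 must be >= 0", call. = FALSE)
  if (length(x) != length(a340)) stop("length mismatch", call. = FALSE)
  structure(list(x = as.numeric(x), a340 = as.numeric(a340),
                 fixed_component = fixed_component, nacl_mM = nacl_mM,
                 sd = sd),
            class = "turbidity_curve")
}

moving_average <- function(v, window = 3L) {
  h <- (window - 1L) %/% 2L
  n <- length(v)
  vapply(seq_len(n), function(i)
    mean(v[max(1L, i - h):min(n, i + h)]), numeric(1))
}

#' Extract features from a turbidity titration
#'
#' Smooths the curve with a centered moving average (window 3), locates the
#' turbidity maximum, flags a plateau when the last three smoothed points lie
#' within noise of the maximum, and reports the onset as the first x where
#' a340 exceeds baseline + 3 SD. A monotone-flat curve yields a no-transition
#' flag rather than an error.
#'
#' @param curve a [turbidity_curve] with >= 6 points
#' @param baseline_n number of leading points used to estimate the baseline
#' @return list with `transition` (logical), `peak_x`, `max_a340`, `onset_x`,
#'   `plateau` (logical)
#' @export
titration_features <- function(curve, baseline_n = 3L) {
  stopifnot(inherits(curve, "turbidity_curve"))
  if (length(curve$x) < 6L) stop("need >= 6 points", call. = FALSE)
  sm <- moving_average(curve$a340, 3L)
  base <- mean(curve$a340[seq_len(baseline_n)])
  base_sd <- stats::sd(curve$a340[seq_len(baseline_n)])
  noise <- if (!is.null(curve$sd)) stats::median(curve$sd)
           else max(base_sd, 1e-12)
  mx <- max(sm)
  if (mx - base < 3 * noise || mx - base <= 0)
    return(list(transition = FALSE, peak_x = NA_real_, max_a340 = mx,
                onset_x = NA_real_, plateau = FALSE))
  peak_i <- which.max(sm)
  n <- length(sm)
  plateau <- all(mx - sm[(n - 2L):n] <= 2 * noise)
  above <- which(curve$a340 > base + 3 * noise)
  list(transition = TRUE, peak_x = curve$x[peak_i], max_a340 = mx,
       onset_x = if (length(above)) curve$x[min(above)] else NA_real_,
       plateau = plateau)
}

#' Salt dependence of turbidity
#'
#' Checks that maximal turbidity decreases with NaCl (the hallmark of
#' electrostatically driven coacervation) and interpolates the NaCl
#' concentration at which turbidity falls to half its lowest-salt value.
#'
#' @param curves list of [turbidity_curve]s, each with its `nacl_mM` set (or a
#'   data.frame with columns `nacl_mM`, `a340`)
#' @return list with `monotone_decreasing` (logical), `midpoint_mM`,
#'   and the sorted `series` data.frame
#' @export
salt_dependence <- function(curves) {
  if (is.data.frame(curves)) {
    df <- curves[, c("nacl_mM", "a340")]
  } else {
    df <- data.frame(
      nacl_mM = vapply(curves, function(cu) cu$nacl_mM, numeric(1)),
      a340 = vapply(curves, function(cu) max(cu$a340), numeric(1)))
  }
  if (any(is.na(df$nacl_mM))) stop("every curve needs `nacl_mM`", call. = FALSE)
  if (length(unique(df$nacl_mM)) < 4L)
    stop("need >= 4 distinct salt concentrations", call. = FALSE)
  df <- df[order(df$nacl_mM), ]
  mono <- all(diff(df$a340) <= 0) && df$a340[1L] > df$a340[nrow(df)]
  half <- df$a340[1L] / 2
  midpoint <- NA_real_
  below <- which(df$a340 <= half)
  if (length(below) && min(below) > 1L) {
    i <- min(below)
    midpoint <- stats::approx(df$a340[c(i - 1L, i)], df$nacl_mM[c(i - 1L, i)],
                              xout = half)$y
  }
  list(monotone_decreasing = mono, midpoint_mM = midpoint, series = df)
}

#' Assemble a two-component phase diagram from turbidity measurements
#'
#' Bins measurements onto the (protein, RNA) concentration grid, averages
#' duplicates (with a warning), calls the two-phase region by threshold, and
#' reports threshold crossings along each row and column as boundary points.
#'
#' @param measurements data.frame with columns `c_serf_uM`, `c_tar_uM`, `a340`
#' @param threshold two-phase call threshold on a340; default baseline + 5 SD
#'   where baseline is the smallest measurement
#' @return list of class `phase_diagram`: `grid` (matrix protein x RNA),
#'   `two_phase` (logical matrix), `threshold`, `boundary` (data.frame)
#' @export
assemble_phase_diagram <- function(measurements, threshold = NULL) {
  req <- c("c_serf_uM", "c_tar_uM", "a340")
  if (!all(req %in% names(measurements)))
    stop("measurements need columns c_serf_uM, c_tar_uM, a340", call. = FALSE)
  m <- measurements
  if (nrow(unique(m[, c("c_serf_uM", "c_tar_uM")])) < 4L)
    stop("need >= 4 distinct grid points", call. = FALSE)
  key <- paste(m$c_serf_uM, m$c_tar_uM)
  if (anyDuplicated(key)) {
    warning("duplicate grid cells averaged")
    m <- stats::aggregate(a340 ~ c_serf_uM + c_tar_uM, data = m, FUN = mean)
  }
  ps <- sort(unique(m$c_serf_uM)); rs <- sort(unique(m$c_tar_uM))
  grid <- matrix(NA_real_, length(ps), length(rs),
                 dimnames = list(ps, rs))
  grid[cbind(match(m$c_serf_uM, ps), match(m$c_tar_uM, rs))] <- m$a340
  if (is.null(threshold)) {
    base <- min(m$a340)
    base_sd <- stats::sd(m$a340[m$a340 <= stats::quantile(m$a340, 0.25)])
    threshold <- base + 5 * max(base_sd, 1e-12, na.rm = TRUE)
  }
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  two_phase <- !is.na(grid) & grid > threshold
  boundary <- list()
  cross <- function(xs, vals, fixed, along) {
    ok <- !is.na(vals)
    xs <- xs[ok]; vals <- vals[ok]
    out <- NULL
    if (length(vals) >= 2L) {
      flip <- which(diff(vals > threshold) != 0)
      for (i in flip) {
        xc <- stats::approx(vals[c(i, i + 1L)], xs[c(i, i + 1L)],
                            xout = threshold)$y
        out <- rbind(out, if (along == "serf")
          data.frame(c_serf_uM = xc, c_tar_uM = fixed)
          else data.frame(c_serf_uM = fixed, c_tar_uM = xc))
      }
    }
    out
  }
  for (j in seq_along(rs))
    boundary[[length(boundary) + 1L]] <- cross(ps, grid[, j], rs[j], "serf")
  for (i in seq_along(ps))
    boundary[[length(boundary) + 1L]] <- cross(rs, grid[i, ], ps[i], "tar")
  boundary <- do.call(rbind, boundary)
  structure(list(grid = grid, two_phase = two_phase, threshold = threshold,
                 boundary = boundary %||%
                   data.frame(c_serf_uM = numeric(0), c_tar_uM = numeric(0))),
            class = "phase_diagram")
}

#' Write a phase diagram as TSV grid plus JSON boundary
#' @param pd a `phase_diagram`
#' @param grid_path TSV output for the turbidity grid
#' @param boundary_path JSON output for the boundary point set
#' @return invisibly, the two paths
#' @export
write_phase_diagram <- function(pd, grid_path, boundary_path) {
  utils::write.table(pd$grid, grid_path, sep = "\t", quote = FALSE,
                     col.names = NA)
  jsonlite::write_json(list(threshold = pd$threshold, boundary = pd$boundary),
                       boundary_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(grid_path, boundary_path))
}
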