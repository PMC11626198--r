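#' Construct a conformational ensemble
#'
#' Per-frame coordinates of one interaction site per residue (C-alpha or
#' coarse-grained bead), in Angstrom. Optionally carries a per-frame backbone
#' dihedral table and frame weights.
#'
#' @param coords numeric array `n_frames x n_sites x 3` (Angstrom), or a list
#'   of `n_sites x 3` matrices
#' @param labels optional residue labels (default 1..n_sites as character)
#' @param dihedrals optional array `n_frames x n_sites x 2` of (phi, psi) in
#'   degrees (NA allowed at chain termini)
#' @param weights optional non-negative frame weights (normalized to sum 1)
#' @return object of class `ensemble`
#' @export
ensemble <- function(coords, labels = NULL, dihedrals = NULL, weights = NULL) {
  if (is.list(coords)) {
    ns <- unique(vapply(coords, nrow, integer(1)))
    if (length(ns) != 1L)
      stop("inconsistent site count across frames", call. = FALSE)
    arr <- array(NA_real_, c(length(coords), ns, 3))
    for (i in seq_along(coords)) arr[i, , ] <- as.matrix(coords[[i]])
    coords <- arr
  }
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  if (!all(is.finite(coords))) stop("non-finite coordinates", call. = FALSE)
  if (!is.null(weights)) {
    if (any(weights < 0) || length(weights) != dim(coords)[1])
      stop("weights must be non-negative, one per frame", call. = FALSE)
    weights <- weights / sum(weights)
  }
  if (!is.null(dihedrals))
    stopifnot(dim(dihedrals)[1] == dim(coords)[1],
              dim(dihedrals)[2] == dim(coords)[2])
  structure(list(coords = coords,
                 labels = labels %||% as.character(seq_len(dim(coords)[2])),
                 dihedrals = dihedrals, weights = weights),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<ensemble> %d frames x %d sites (Angstrom)%s%s\n", d[1], d[2],
              if (!is.null(x$dihedrals)) ", with dihedrals" else "",
              if (!is.null(x$weights)) ", weighted" else ""))
  invisible(x)
}

n_frames <- function(ens) dim(ens$coords)[1]
n_sites  <- function(ens) dim(ens$coords)[2]

# one frame as an n_sites x 3 matrix (robust to R's dimension dropping
# when a frame holds a single site)
frame_xyz <- function(arr, f, idx = NULL) {
  if (is.null(idx)) matrix(arr[f, , ], ncol = 3)
  else matrix(arr[f, idx, ], ncol = 3)
}

frame_rg <- function(xyz) {
  ctr <- colMeans(xyz)
  sqrt(mean(rowSums(sweep(xyz, 2, ctr)^2)))
}

#' Radius-of-gyration distribution of an ensemble
#'
#' Per-frame Rg about the unweighted site centroid, plus a kernel density
#' estimate (Scott's bandwidth rule) normalized to integrate to 1.
#'
#' @param ens an [ensemble]
#' @return list with `rg` (per-frame, Angstrom), `mean`, and `density`
#'   (a `stats::density` object; `NULL` when all Rg are identical)
#' @export
rg_distribution <- function(ens) {
  stopifnot(inherits(ens, "ensemble"))
  if (n_sites(ens) == 1L)
    warning("single-site frames: Rg is identically 0")
  rg <- vapply(seq_len(n_frames(ens)),
               function(i) frame_rg(frame_xyz(ens$coords, i)),
               numeric(1))
  if (n_sites(ens) == 1L) rg[] <- 0
  w <- ens$weights %||% rep(1 / length(rg), length(rg))
  dens <- if (length(unique(rg)) > 1L)
    stats::density(rg, bw = "nrd", weights = w) else NULL
  list(rg = rg, mean = sum(w * rg), density = dens)
}

#' Ensemble-mean inter-site distance map
#'
#' Pairwise site-site distances computed per frame and averaged (with frame
#' weights when present). Symmetric with a zero diagonal.
#'
#' @param ens an [ensemble]
#' @return `n_sites x n_sites` matrix of mean distances (Angstrom)
#' @export
mean_distance_map <- function(ens) {
  stopifnot(inherits(ens, "ensemble"))
  n <- n_sites(ens)
  w <- ens$weights %||% rep(1 / n_frames(ens), n_frames(ens))
  acc <- matrix(0, n, n)
  for (i in seq_len(n_frames(ens))) {
    d <- as.matrix(stats::dist(frame_xyz(ens$coords, i)))
    acc <- acc + w[i] * d
  }
  dimnames(acc) <- list(ens$labels, ens$labels)
  acc
}
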