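truth_record <- function(generator, params, seed) {
  structure(list(generator = generator, params = params, seed = seed),
            class = "truth_record")
}

#' Write a truth record as JSON next to a synthetic dataset
#' @param truth a `truth_record`
#' @param path output JSON path
#' @return `path`, invisibly
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Generate a synthetic anisotropy titration
#'
#' Log-spaced titrant grid, anisotropy from the exact 1:1 depletion model
#' (via [anisotropy_model()]) plus i.i.d. Gaussian noise; `replicates` noisy
#' copies are averaged and their SD emitted per point.
#'
#' @param kd true dissociation constant (molar)
#' @param r_free,r_bound anisotropy endpoints
#' @param probe labeled-probe concentration (molar)
#' @param n_points titration points (>= 5)
#' @param x_max top titrant concentration (molar)
#' @param x_min bottom titrant concentration (default `x_max / 4000`)
#' @param noise_sd Gaussian anisotropy noise SD (>= 0)
#' @param replicates technical replicates averaged per point
#' @param seed RNG seed
#' @return list with `series` (a [titration_series]) and `truth`
#' @export
gen_titration <- function(kd, r_free = 0.05, r_bound = 0.20, probe = 1e-8,
                          n_points = 16L, x_max = 2e-5, x_min = x_max / 4000,
                          noise_sd = 0.002, replicates = 3L, seed = 1L) {
  stopifnot_scalar_pos(kd, "kd")
  if (n_points < 5L) stop("need n_points >= 5", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  x <- exp(seq(log(x_min), log(x_max), length.out = n_points))
  mu <- anisotropy_model(probe, x, list(kd = kd, r_free = r_free,
                                        r_bound = r_bound), "one_to_one")
  sim <- with_seed(seed, {
    reps <- matrix(stats::rnorm(n_points * replicates, mean = mu,
                                sd = noise_sd),
                   n_points, replicates)
    list(mean = rowMeans(reps),
         sd = if (replicates > 1L) apply(reps, 1, stats::sd) else NULL)
  })
  series <- titration_series(probe, x, sim$mean, sim$sd)
  list(series = series,
       truth = truth_record("gen_titration",
                            list(kd = kd, r_free = r_free, r_bound = r_bound,
                                 probe = probe, n_points = n_points,
                                 x_max = x_max, x_min = x_min,
                                 noise_sd = noise_sd,
                                 replicates = replicates), seed))
}

# Ideal C-alpha helix template: radius 2.3 A, rise 1.5 A, 100 deg/residue.
helix_template <- function(n) {
  k <- seq_len(n) - 1L
  th <- k * 100 * pi / 180
  cbind(2.3 * cos(th), 2.3 * sin(th), 1.5 * k)
}

random_rotation <- function() {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

#' Generate a synthetic disordered-chain ensemble
#'
#' Freely jointed chain (fixed step `bond_b`) or Gaussian-step chain (RMS
#' step `bond_b`; matching the analytical random-coil reference statistics at
#' every separation). A designated region is replaced by ideal alpha-helical
#' geometry in a stated fraction of frames, coordinates are multiplied by
#' `compaction`, and a (phi, psi) dihedral table consistent with the
#' geometry is emitted (helical residues in the alpha basin, coil residues
#' extended).
#'
#' @param n_res chain length (>= 2)
#' @param bond_b step length in Angstrom
#' @param helix_region `c(start, end, fraction)` or NULL
#' @param compaction global coordinate scale factor
#' @param n_frames number of frames
#' @param seed RNG seed
#' @param step one of `"fjc"` (fixed-length steps) or `"gaussian"`
#' @return list with `ens` (an [ensemble] with dihedrals) and `truth`
#' @export
gen_chain_ensemble <- function(n_res, bond_b = 3.8, helix_region = NULL,
                               compaction = 1, n_frames = 100L, seed = 1L,
                               step = c("fjc", "gaussian")) {
  step <- match.arg(step)
  if (n_res < 2L) stop("need n_res >= 2", call. = FALSE)
  h_start <- h_end <- 0L; h_frac <- 0
  if (!is.null(helix_region)) {
    h_start <- as.integer(helix_region[1L]); h_end <- as.integer(helix_region[2L])
    h_frac <- helix_region[3L]
    if (h_start < 1L || h_end > n_res || h_start >= h_end ||
        h_frac < 0 || h_frac > 1)
      stop("helix region out of range", call. = FALSE)
  }
  tmpl <- helix_template(n_res)
  tmpl_steps <- diff(tmpl)
  out <- with_seed(seed, {
    coords <- array(NA_real_, c(n_frames, n_res, 3))
    dih <- array(NA_real_, c(n_frames, n_res, 2))
    for (f in seq_len(n_frames)) {
      helical_frame <- h_frac > 0 && stats::runif(1) < h_frac
      R <- if (helical_frame) random_rotation() else diag(3)
      xyz <- matrix(0, n_res, 3)
      for (k in seq_len(n_res - 1L)) {
        in_helix <- helical_frame && k >= h_start && k < h_end
        stp <- if (in_helix) {
          as.numeric(tmpl_steps[k, ] %*% R)
        } else if (step == "fjc") {
          v <- stats::rnorm(3); bond_b * v / sqrt(sum(v^2))
        } else {
          stats::rnorm(3, sd = bond_b / sqrt(3))
        }
        xyz[k + 1L, ] <- xyz[k, ] + stp
      }
      coords[f, , ] <- xyz * compaction
      helical_res <- helical_frame & seq_len(n_res) >= h_start &
        seq_len(n_res) <= h_end
      dih[f, , 1] <- ifelse(helical_res, -63, -150)
      dih[f, , 2] <- ifelse(helical_res, -42, 150)
      dih[f, c(1L, n_res), ] <- NA   # chain termini have no full (phi, psi)
    }
    list(coords = coords, dih = dih)
  })
  ens <- ensemble(out$coords, dihedrals = out$dih)
  list(ens = ens,
       truth = truth_record("gen_chain_ensemble",
                            list(n_res = n_res, bond_b = bond_b,
                                 helix_region = helix_region,
                                 compaction = compaction,
                                 n_frames = n_frames, step = step), seed))
}

#' Generate toy hairpin-RNA conformer coordinate sets
#'
#' One site per nucleotide on an idealized helix-junction-helix: the strand
#' runs up stem 1 and stem 2 (A-form geometry: 2.8 Angstrom rise, 9 Angstrom
#' radius, 32.7 degrees twist per step), around a loop arc, and back down.
#' Stem 2 is tilted by the interhelical `bend_deg` about the junction;
#' conformers differ by seeded Gaussian jitter of that bend angle.
#'
#' @param seq RNA [bio_seq]; `2 * sum(stem_lengths) + loop_length` must equal
#'   its length
#' @param stem_lengths per-strand lengths of the two stems, e.g. `c(4, 6)`
#' @param loop_length loop nucleotides
#' @param bend_deg mean interhelical bend angle (degrees)
#' @param n_conformers number of conformers
#' @param jitter_deg SD of the per-conformer bend jitter (degrees)
#' @param seed RNG seed
#' @return list with `conformers` (class `conformer_set`: `seq`, `coords`
#'   array `n_conf x n_sites x 3` in Angstrom, per-conformer `bend_deg`) and
#'   `truth`
#' @export
gen_rna_conformers <- function(seq, stem_lengths = c(4L, 6L),
                               loop_length = 9L, bend_deg = 50,
                               n_conformers = 10L, jitter_deg = 10,
                               seed = 1L) {
  stopifnot(inherits(seq, "bio_seq"), seq$kind == "rna")
  n <- length(seq)
  if (2L * sum(stem_lengths) + loop_length != n)
    stop(sprintf("stems (2x%d) + loop (%d) != sequence length (%d)",
                 sum(stem_lengths), loop_length, n), call. = FALSE)
  n1 <- stem_lengths[1L]; n2 <- stem_lengths[2L]
  rise <- 2.8; radius <- 9; twist <- 32.7 * pi / 180
  strand_pos <- function(k, phase) {
    cbind(radius * cos(k * twist + phase), radius * sin(k * twist + phase),
          rise * k)
  }
  out <- with_seed(seed, {
    bends <- bend_deg + stats::rnorm(n_conformers, sd = jitter_deg)
    coords <- array(NA_real_, c(n_conformers, n, 3))
    for (cfi in seq_len(n_conformers)) {
      th <- bends[cfi] * pi / 180
      # stem 2 axis tilted about the x axis at the junction z = n1 * rise
      Rb <- matrix(c(1, 0, 0,
                     0, cos(th), -sin(th),
                     0, sin(th), cos(th)), 3, 3, byrow = TRUE)
      z0 <- c(0, 0, n1 * rise)
      up1 <- strand_pos(0:(n1 - 1L), 0)
      up2 <- sweep(strand_pos(0:(n2 - 1L), 0) %*% t(Rb), 2, z0, "+")
      # loop: semicircular arc over the top of stem 2 (in its tilted frame)
      ang <- seq(0, pi, length.out = loop_length + 2L)[2:(loop_length + 1L)]
      arc <- cbind(radius * cos(ang), radius * sin(ang) * 0.6,
                   (n2 - 1L) * rise + 4 * sin(ang))
      arc <- sweep(arc %*% t(Rb), 2, z0, "+")
      dn2 <- sweep(strand_pos((n2 - 1L):0, pi * 5 / 6) %*% t(Rb), 2, z0, "+")
      dn1 <- strand_pos((n1 - 1L):0, pi * 5 / 6)
      coords[cfi, , ] <- rbind(up1, up2, arc, dn2, dn1)
    }
    list(coords = coords, bends = bends)
  })
  conf <- structure(list(seq = seq, coords = out$coords,
                         bend_deg = out$bends),
                    class = "conformer_set")
  list(conformers = conf,
       truth = truth_record("gen_rna_conformers",
                            list(stem_lengths = stem_lengths,
                                 loop_length = loop_length,
                                 bend_deg = bend_deg,
                                 n_conformers = n_conformers,
                                 jitter_deg = jitter_deg), seed))
}

#' @export
print.conformer_set <- function(x, ...) {
  cat(sprintf("<conformer_set> %d conformer(s) x %d sites (Angstrom)\n",
              dim(x$coords)[1], dim(x$coords)[2]))
  invisible(x)
}

#' Realized interhelical angle of a hairpin conformer
#'
#' Angle between the two stem axes, each estimated as the principal axis of
#' the base-pair midpoints (midpoints of paired 5' and 3' strand sites lie
#' essentially on the helix axis, unlike the strand sites themselves).
#'
#' @param coords `n_sites x 3` matrix (one conformer)
#' @param stem1,stem2 each a list `list(up = , down = )` of equal-length site
#'   index vectors pairing the 5' strand with its 3' partner (same base-pair
#'   order in both)
#' @return angle in degrees, in [0, 180)
#' @export
interhelical_angle <- function(coords, stem1, stem2) {
  cylinder_axis <- function(pts, mid) {
    # exact helix sites are equidistant from the axis: minimize the variance
    # of point-to-line distances over line direction + perpendicular offset
    u0 <- stats::prcomp(mid)$rotation[, 1L]
    if (sum(u0 * (mid[nrow(mid), ] - mid[1L, ])) < 0) u0 <- -u0
    th0 <- acos(pmin(pmax(u0[3], -1), 1)); ph0 <- atan2(u0[2], u0[1])
    ctr <- colMeans(pts)
    obj <- function(p) {
      u <- c(sin(p[1]) * cos(p[2]), sin(p[1]) * sin(p[2]), cos(p[1]))
      e1 <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      e1 <- e1 - sum(e1 * u) * u; e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
              u[1] * e1[2] - u[2] * e1[1])
      a <- ctr + p[3] * e1 + p[4] * e2
      rel <- sweep(pts, 2, a)
      proj <- rel - outer(as.numeric(rel %*% u), u)
      stats::var(sqrt(rowSums(proj^2)))
    }
    fit <- stats::optim(c(th0, ph0, 0, 0), obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    u <- c(sin(fit$par[1]) * cos(fit$par[2]),
           sin(fit$par[1]) * sin(fit$par[2]), cos(fit$par[1]))
    if (sum(u * (mid[nrow(mid), ] - mid[1L, ])) < 0) u <- -u
    u
  }
  axis_of <- function(stem) {
    mid <- (coords[stem$up, , drop = FALSE] +
              coords[stem$down, , drop = FALSE]) / 2
    cylinder_axis(coords[c(stem$up, stem$down), , drop = FALSE], mid)
  }
  a <- axis_of(stem1); b <- axis_of(stem2)
  acos(pmin(pmax(sum(a * b), -1), 1)) * 180 / pi
}

#' Stem pairing index helper for generated hairpin conformers
#'
#' Site index bookkeeping for [gen_rna_conformers()] geometries: which sites
#' form the 5'/3' strands of each stem and the loop.
#'
#' @param stem_lengths,loop_length as passed to the generator
#' @return list with `stem1`, `stem2` (each `list(up, down)`), `loop`
#' @export
hairpin_indices <- function(stem_lengths, loop_length) {
  n1 <- stem_lengths[1L]; n2 <- stem_lengths[2L]
  up1 <- seq_len(n1)
  up2 <- n1 + seq_len(n2)
  loop <- n1 + n2 + seq_len(loop_length)
  dn2 <- n1 + n2 + loop_length + seq_len(n2)      # stored top-down (k desc)
  dn1 <- n1 + n2 + loop_length + n2 + seq_len(n1)
  list(stem1 = list(up = up1, down = rev(dn1)),
       stem2 = list(up = up2, down = rev(dn2)),
       loop = loop)
}

#' Generate a synthetic turbidity titration
#'
#' Saturating-peak profile: a log-normal bump centered at `peak_ratio`
#' (width on the log axis), or a saturating plateau reaching `amplitude`
#' around `peak_ratio` when `plateau = TRUE`; Gaussian noise added on top of
#' `baseline`.
#'
#' @param peak_ratio molar ratio of maximal turbidity (> 0)
#' @param width log-scale width of the bump (> 0)
#' @param amplitude bump height (a340 units)
#' @param baseline baseline a340
#' @param noise_sd Gaussian noise SD
#' @param n_points number of titration points
#' @param x_max top of the ratio grid (default `4 * peak_ratio`)
#' @param plateau saturating plateau instead of a peak
#' @param seed RNG seed
#' @return list with `curve` (a [turbidity_curve]) and `truth`
#' @export
gen_turbidity <- function(peak_ratio, width = 0.35, amplitude = 1,
                          baseline = 0.02, noise_sd = 0.02, n_points = 25L,
                          x_max = 4 * peak_ratio, plateau = FALSE, seed = 1L) {
  stopifnot_scalar_pos(peak_ratio, "peak_ratio")
  if (width <= 0) stop("width must be > 0", call. = FALSE)
  x <- seq(x_max / n_points, x_max, length.out = n_points)
  shape <- if (plateau) {
    amplitude / (1 + exp(-(log(x) - log(peak_ratio * 0.5)) / (width / 2)))
  } else {
    amplitude * exp(-(log(x / peak_ratio))^2 / (2 * width^2))
  }
  a <- with_seed(seed,
                 pmax(baseline + shape + stats::rnorm(n_points, sd = noise_sd),
                      0))
  curve <- turbidity_curve(x, a, sd = rep(noise_sd, n_points))
  list(curve = curve,
       truth = truth_record("gen_turbidity",
                            list(peak_ratio = peak_ratio, width = width,
                                 amplitude = amplitude, baseline = baseline,
                                 noise_sd = noise_sd, n_points = n_points,
                                 x_max = x_max, plateau = plateau), seed))
}

#' Independent PRE oracle
#'
#' Straight-line re-implementation of the PRE intensity-ratio formulas with
#' no code shared with [pre_profile()]; used as a dual-implementation test
#' oracle.
#'
#' @inheritParams pre_profile
#' @return list with `profile` (data.frame residue/ratio) and `truth`
#' @export
gen_pre_truth <- function(ens, label_site, params = pre_params()) {
  stopifnot(inherits(ens, "ensemble"))
  nres <- dim(ens$coords)[2]; nfr <- dim(ens$coords)[1]
  if (label_site < 1L || label_site > nres)
    stop("label_site outside the chain", call. = FALSE)
  ratio <- numeric(nres)
  for (i in seq_len(nres)) {
    if (i == label_site) { ratio[i] <- 0; next }
    acc <- 0
    for (f in seq_len(nfr)) {
      dx <- ens$coords[f, i, 1] - ens$coords[f, label_site, 1]
      dy <- ens$coords[f, i, 2] - ens$coords[f, label_site, 2]
      dz <- ens$coords[f, i, 3] - ens$coords[f, label_site, 3]
      r <- sqrt(dx^2 + dy^2 + dz^2)
      acc <- acc + 1 / r^6
    }
    g2 <- params$K * params$tau_c * acc / nfr
    ratio[i] <- params$r2_dia * exp(-g2 * params$t_d) / (params$r2_dia + g2)
  }
  list(profile = data.frame(residue = seq_len(nres), ratio = ratio),
       truth = truth_record("gen_pre_truth",
                            list(label_site = label_site, params = params),
                            NA))
}
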