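#' Simulation configuration
#'
#' Defaults are standard for residue-resolution implicit-solvent models of
#' disordered biomolecules: 25 nm box, 300 K, dielectric 80, 150 mM ionic
#' strength, 10 fs timestep, weak friction (0.01 / ps) for efficient
#' configurational sampling; the first 10% of steps are discarded as
#' equilibration.
#'
#' @param box_edge cubic box edge (nm); must exceed twice the electrostatic
#'   cutoff
#' @param temperature_K temperature (K)
#' @param ionic_strength_mM ionic strength (mM), sets the Debye length
#' @param dielectric relative permittivity
#' @param timestep_ps integration step (ps)
#' @param friction_per_ps Langevin friction (1/ps)
#' @param n_steps,save_every total steps and saving stride
#' @param seed RNG seed, recorded in all outputs
#' @param nonbonded_cutoff electrostatic cutoff (nm)
#' @param bound_cutoff_scale bound-contact distance as a multiple of the
#'   touching pair's mean sigma
#' @param bound_min_contacts interchain contacts needed to call a frame bound
#' @param equil_fraction fraction of steps discarded before output
#' @return list of class `sim_config`
#' @export
sim_config <- function(box_edge = 25, temperature_K = 300,
                       ionic_strength_mM = 150, dielectric = 80,
                       timestep_ps = 0.01, friction_per_ps = 0.01,
                       n_steps = 100000L, save_every = 100L, seed = 1L,
                       nonbonded_cutoff = 3.0, bound_cutoff_scale = 1.2,
                       bound_min_contacts = 1L, equil_fraction = 0.1) {
  if (box_edge <= 2 * nonbonded_cutoff)
    stop("box_edge must exceed twice the nonbonded cutoff", call. = FALSE)
  if (n_steps < save_every || save_every < 1L)
    stop("need n_steps >= save_every >= 1", call. = FALSE)
  structure(list(box_edge = box_edge, temperature_K = temperature_K,
                 ionic_strength_mM = ionic_strength_mM,
                 dielectric = dielectric, timestep_ps = timestep_ps,
                 friction_per_ps = friction_per_ps,
                 n_steps = as.integer(n_steps),
                 save_every = as.integer(save_every), seed = as.integer(seed),
                 nonbonded_cutoff = nonbonded_cutoff,
                 bound_cutoff_scale = bound_cutoff_scale,
                 bound_min_contacts = as.integer(bound_min_contacts),
                 equil_fraction = equil_fraction),
            class = "sim_config")
}

# Seeded initial placement. Flexible chains start on a compact,
# overlap-free spiral (bond length preserved, adjacent turns separated by
# more than a bead diameter); rigid bodies at a random orientation. The two
# molecules start at a random, non-overlapping mutual separation so both
# bound and unbound states are reachable.
init_coords <- function(top, config, conformer = 1L) {
  beads <- top$beads
  n <- nrow(beads)
  xyz <- matrix(0, n, 3)
  chains <- unique(beads$chain)
  spiral <- function(nb, r0) {
    R <- 0.8; pitch <- 0.9
    dth <- 2 * asin(min(r0 / (2 * R), 0.99))
    th <- (seq_len(nb) - 1L) * dth
    cbind(R * cos(th), R * sin(th), pitch * th / (2 * pi))
  }
  blocks <- list()
  for (ci in seq_along(chains)) {
    sel <- which(beads$chain == chains[ci])
    if (!is.null(top$rigid) && chains[ci] == top$rigid$chain) {
      body <- matrix(top$rigid$coords[conformer, , ], ncol = 3)
    } else {
      r0 <- if (length(sel) > 1L) {
        bnd <- top$bonds[top$bonds$i %in% sel, , drop = FALSE]
        if (nrow(bnd)) bnd$r0[1L] else 0.38
      } else 0.38
      body <- spiral(length(sel), r0)
    }
    body <- sweep(body, 2, colMeans(body))
    R <- random_rotation()
    blocks[[ci]] <- list(sel = sel, body = body %*% t(R),
                         radius = sqrt(max(rowSums(body^2))))
  }
  half <- config$box_edge / 2
  centers <- list(c(half, half, half))
  if (length(blocks) > 1L) {
    min_sep <- blocks[[1L]]$radius + blocks[[2L]]$radius + 0.5
    max_sep <- max(min(0.48 * config$box_edge, min_sep + 8), min_sep + 0.5)
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    centers[[2L]] <- centers[[1L]] + u * stats::runif(1, min_sep, max_sep)
  }
  for (ci in seq_along(blocks))
    xyz[blocks[[ci]]$sel, ] <- sweep(blocks[[ci]]$body, 2, centers[[ci]], "+")
  xyz
}

#' Run a coarse-grained Langevin simulation
#'
#' Propagates the topology in a periodic cubic box with the BAOAB Langevin
#' integrator (flexible beads) and a rigid-body integrator (rigid RNA
#' conformers: center-of-mass Langevin translation plus isotropic-inertia
#' rotation). For a multi-conformer rigid chain each conformer is simulated
#' in a separate run and the frames are pooled (`pooling = "separate_runs"`
#' recorded in the result). Equilibration frames are discarded before output.
#'
#' @param top a [build_topology()] result
#' @param config a [sim_config()]
#' @param conformers which rigid conformers to run (default all); ignored for
#'   fully flexible systems
#' @return object of class `cg_trajectory`: `frames` (array
#'   `n_frames x n_beads x 3`, nm), `chain` (per-bead chain label), `beads`
#'   (parameter table), `box_edge`, `kinetic_temperature`,
#'   `potential_energy`, `time_ps`, `conformer` (per-frame conformer index),
#'   `config` (echo), `pooling`
#' @export
run_simulation <- function(top, config = sim_config(), conformers = NULL) {
  stopifnot(inherits(top, "cg_topology"), inherits(config, "sim_config"))
  beads <- top$beads
  rigid_idx <- integer(0)
  n_conf <- 1L
  if (!is.null(top$rigid)) {
    rigid_idx <- which(beads$chain == top$rigid$chain) - 1L
    n_conf <- dim(top$rigid$coords)[1]
  }
  conformers <- conformers %||% seq_len(n_conf)
  lam <- debye_length(config$ionic_strength_mM, config$temperature_K,
                      config$dielectric)
  kT <- .kB * config$temperature_K
  equil <- as.integer(floor(config$n_steps * config$equil_fraction))

  runs <- vector("list", length(conformers))
  for (k in seq_along(conformers)) {
    cf <- conformers[k]
    res <- with_seed(child_seed(config$seed, cf), {
      x0 <- init_coords(top, config, conformer = cf)
      .langevin_run(x0, beads$mass_gmol, beads$charge_e, beads$sigma_nm,
                    beads$epsilon_kJmol, beads$mu, beads$nu,
                    as.integer(top$bonds$i - 1L), as.integer(top$bonds$j - 1L),
                    top$bonds$k, top$bonds$r0,
                    as.integer(rigid_idx),
                    matrix(0, 0, 3),
                    config$box_edge, config$timestep_ps,
                    config$friction_per_ps, kT, lam, config$dielectric,
                    config$nonbonded_cutoff, config$n_steps,
                    config$save_every, equil)
    })
    res$conformer <- rep(cf, dim(res$frames)[1])
    runs[[k]] <- res
  }
  nf_each <- vapply(runs, function(r) dim(r$frames)[1], integer(1))
  nb <- nrow(beads)
  frames <- array(NA_real_, c(sum(nf_each), nb, 3))
  at <- 0L
  for (r in runs) {
    frames[at + seq_len(dim(r$frames)[1]), , ] <- r$frames
    at <- at + dim(r$frames)[1]
  }
  structure(list(frames = frames, chain = beads$chain, beads = beads,
                 box_edge = config$box_edge,
                 kinetic_temperature = unlist(lapply(runs, `[[`,
                                                     "kinetic_temperature")),
                 potential_energy = unlist(lapply(runs, `[[`,
                                                  "potential_energy")),
                 time_ps = unlist(lapply(runs, `[[`, "time_ps")),
                 conformer = unlist(lapply(runs, `[[`, "conformer")),
                 config = config, pooling = "separate_runs"),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf(
    "<cg_trajectory> %d frames x %d beads (nm), box %.3g nm, seed %d\n",
    dim(x$frames)[1], dim(x$frames)[2], x$box_edge, x$config$seed))
  invisible(x)
}

#' Write / read a trajectory container
#'
#' Frames are stored as an RDS array next to a JSON sidecar that records
#' units (nm), stride, seed and the full configuration echo.
#'
#' @param traj a `cg_trajectory`
#' @param path basename; writes `<path>.rds` and `<path>.json`
#' @return `path`, invisibly (`read_trajectory` returns the trajectory)
#' @export
write_trajectory <- function(traj, path) {
  saveRDS(traj, paste0(path, ".rds"))
  sidecar <- list(units = "nm", n_frames = dim(traj$frames)[1],
                  n_beads = dim(traj$frames)[2],
                  stride = traj$config$save_every, seed = traj$config$seed,
                  pooling = traj$pooling,
                  config = unclass(traj$config))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) readRDS(paste0(path, ".rds"))
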