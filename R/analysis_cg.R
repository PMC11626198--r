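chain_indices <- function(traj, chain) {
  idx <- which(traj$chain == chain)
  if (length(idx) == 0L)
    stop(sprintf("chain '%s' not present in trajectory", chain),
         call. = FALSE)
  idx
}

two_chains <- function(traj) {
  ch <- unique(traj$chain)
  if (length(ch) < 2L)
    stop("trajectory contains a single chain; interchain analysis needs two",
         call. = FALSE)
  ch[1:2]
}

# Per-pair contact cutoff matrix: scale * mean sigma of the touching pair.
pair_cutoffs <- function(traj, ia, ib, scale) {
  sa <- traj$beads$sigma_nm[ia]; sb <- traj$beads$sigma_nm[ib]
  scale * outer(sa, sb, function(x, y) (x + y) / 2)
}

#' Classify frames as bound or unbound
#'
#' A frame is bound when at least `min_contacts` interchain bead pairs lie
#' within the contact cutoff. By default the cutoff is per-pair,
#' `bound_cutoff_scale` times the mean sigma of the touching beads; passing
#' `cutoff` overrides it with one global distance (nm).
#'
#' @param traj a `cg_trajectory` with two chains
#' @param cutoff optional global contact distance (nm)
#' @param min_contacts contacts required (default from the config)
#' @return object of class `binding_states`: `bound` (logical per frame),
#'   `min_distance` (nm per frame), `n_contacts`, `bound_fraction`
#' @export
classify_bound <- function(traj, cutoff = NULL, min_contacts = NULL) {
  stopifnot(inherits(traj, "cg_trajectory"))
  ch <- two_chains(traj)
  ia <- chain_indices(traj, ch[1L]); ib <- chain_indices(traj, ch[2L])
  min_contacts <- min_contacts %||% traj$config$bound_min_contacts
  cuts <- if (is.null(cutoff))
    pair_cutoffs(traj, ia, ib, traj$config$bound_cutoff_scale)
  else matrix(cutoff, length(ia), length(ib))
  res <- .min_image_counts(traj$frames, as.integer(ia - 1L),
                           as.integer(ib - 1L), traj$box_edge, cuts)
  bound <- res$contacts_per_frame >= min_contacts
  structure(list(bound = bound, min_distance = res$min_distance,
                 n_contacts = res$contacts_per_frame,
                 bound_fraction = mean(bound)),
            class = "binding_states")
}

#' @export
print.binding_states <- function(x, ...) {
  cat(sprintf("<binding_states> %d frames, bound fraction %.3f\n",
              length(x$bound), x$bound_fraction))
  invisible(x)
}

#' Apparent dissociation constant from a two-molecule simulation
#'
#' With exactly one molecule of each partner in a box of volume V, mass
#' action gives `K_D,app = (1 - f_b)^2 / (f_b * V * NA)` where `f_b` is the
#' bound fraction of frames. Saturated runs (`f_b` of 0 or 1) yield `Inf` /
#' `0` with a warning rather than an estimate.
#'
#' @param states a [classify_bound()] result (or a bare bound fraction)
#' @param config the [sim_config()] of the run (for the box volume)
#' @return K_D,app in molar
#' @export
apparent_kd <- function(states, config) {
  fb <- if (inherits(states, "binding_states")) states$bound_fraction
        else states
  stopifnot(inherits(config, "sim_config"))
  V_L <- config$box_edge^3 * 1e-24          # nm^3 -> L
  if (fb <= 0) {
    warning("no bound frames: K_D unbounded (saturation of the unbound state)")
    return(Inf)
  }
  if (fb >= 1) {
    warning("all frames bound: K_D -> 0 (saturation of the bound state)")
    return(0)
  }
  (1 - fb)^2 / (fb * V_L * .NAvogadro)
}

#' Relative affinity of two RNAs from matched simulations
#'
#' `K_D(rna2) / K_D(rna1)`: a value > 1 means the first RNA binds more
#' tightly. Volume-independent when both runs used the same box.
#'
#' @param states1,states2 [classify_bound()] results for the two RNAs
#' @param config1,config2 their configs (must share the box edge)
#' @return dissociation-constant ratio K_D(2) / K_D(1)
#' @export
relative_affinity <- function(states1, states2, config1, config2 = config1) {
  if (abs(config1$box_edge - config2$box_edge) > 1e-9)
    stop("relative affinity requires equal box sizes", call. = FALSE)
  apparent_kd(states2, config2) / apparent_kd(states1, config1)
}

#' Interchain contact-frequency map
#'
#' `freq[i, j]` is the fraction of frames in which protein bead i and RNA
#' bead j are within the contact cutoff. With a pooled multi-conformer
#' trajectory, per-conformer maps are averaged and their SD reported, as is
#' the per-residue marginal (mean over partner beads).
#'
#' @param traj a `cg_trajectory` with two chains
#' @param cutoff optional global contact distance (nm); default per-pair
#'   `bound_cutoff_scale * mean sigma`
#' @param frames optional logical/integer frame subset (e.g. bound frames)
#' @return object of class `contact_map`: `frequency`, `sd` (across
#'   conformers; NULL for a single conformer), `marginal_a`, `marginal_b`
#'   (mean-over-partner marginals), `n_frames`, `marginal_type`
#' @export
contact_frequency <- function(traj, cutoff = NULL, frames = NULL) {
  stopifnot(inherits(traj, "cg_trajectory"))
  if (dim(traj$frames)[1] == 0L) stop("empty trajectory", call. = FALSE)
  ch <- two_chains(traj)
  ia <- chain_indices(traj, ch[1L]); ib <- chain_indices(traj, ch[2L])
  cuts <- if (is.null(cutoff))
    pair_cutoffs(traj, ia, ib, traj$config$bound_cutoff_scale)
  else matrix(cutoff, length(ia), length(ib))
  sel <- seq_len(dim(traj$frames)[1])
  if (!is.null(frames)) sel <- sel[frames]
  if (length(sel) == 0L) stop("no frames selected", call. = FALSE)
  confs <- unique(traj$conformer[sel])
  maps <- lapply(confs, function(cf) {
    sub <- sel[traj$conformer[sel] == cf]
    fr <- traj$frames[sub, , , drop = FALSE]
    .min_image_counts(fr, as.integer(ia - 1L), as.integer(ib - 1L),
                      traj$box_edge, cuts)$contact_frequency
  })
  freq <- Reduce(`+`, maps) / length(maps)
  sdm <- if (length(maps) > 1L)
    sqrt(Reduce(`+`, lapply(maps, function(m) (m - freq)^2)) /
           (length(maps) - 1L)) else NULL
  dimnames(freq) <- list(ia, ib)
  structure(list(frequency = freq, sd = sdm,
                 marginal_a = rowMeans(freq), marginal_b = colMeans(freq),
                 n_frames = length(sel), n_conformers = length(confs),
                 marginal_type = "mean"),
            class = "contact_map")
}

#' Radius-of-gyration statistics partitioned by binding state
#'
#' Per-frame Rg of one chain (protein, typically), split into bound and
#' unbound subsets. Frame counts are conserved: `n_bound + n_unbound` equals
#' the number of frames.
#'
#' @param traj a `cg_trajectory`
#' @param states a [classify_bound()] result aligned to its frames
#' @param chain chain label to analyze (default `"protein"`)
#' @return list with per-frame `rg` (nm), `bound` flags, and `bound` /
#'   `unbound` summaries (`n`, `mean`, `sd`)
#' @export
rg_by_state <- function(traj, states, chain = "protein") {
  stopifnot(inherits(traj, "cg_trajectory"),
            inherits(states, "binding_states"))
  if (length(states$bound) != dim(traj$frames)[1])
    stop("binding states not aligned to trajectory frames", call. = FALSE)
  idx <- chain_indices(traj, chain)
  rg <- vapply(seq_len(dim(traj$frames)[1]), function(f)
    frame_rg(frame_xyz(traj$frames, f, idx)), numeric(1))
  summ <- function(v) list(n = length(v),
                           mean = if (length(v)) mean(v) else NA_real_,
                           sd = if (length(v) > 1L) stats::sd(v) else NA_real_)
  list(rg = rg, bound = states$bound,
       bound_stats = summ(rg[states$bound]),
       unbound_stats = summ(rg[!states$bound]))
}

#' Extract one chain of a trajectory as an ensemble
#'
#' Converts trajectory coordinates (nm) of one chain into an [ensemble]
#' (Angstrom) for the observable back-calculation functions.
#'
#' @param traj a `cg_trajectory`
#' @param chain chain label
#' @param frames optional frame subset
#' @return an [ensemble]
#' @export
trajectory_ensemble <- function(traj, chain = "protein", frames = NULL) {
  idx <- chain_indices(traj, chain)
  sel <- seq_len(dim(traj$frames)[1])
  if (!is.null(frames)) sel <- sel[frames]
  ensemble(traj$frames[sel, idx, , drop = FALSE] * 10)
}
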