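#' Construct a chemical-shift table
#'
#' Long-format per-residue shifts: one row per (residue, nucleus), with the
#' measured shift and the random-coil reference shift in ppm. Nucleus names
#' follow the usual convention (`"CA"`, `"CB"`, `"C"`, `"N"`, `"H"`, ...).
#'
#' @param residue 1-based residue indices
#' @param nucleus nucleus names
#' @param shift_ppm measured chemical shifts (ppm)
#' @param rc_shift_ppm random-coil reference shifts (ppm); required wherever a
#'   measurement is present
#' @return data.frame of class `shift_table`
#' @export
shift_table <- function(residue, nucleus, shift_ppm, rc_shift_ppm = NA) {
  df <- data.frame(residue = as.integer(residue),
                   nucleus = as.character(nucleus),
                   shift_ppm = as.numeric(shift_ppm),
                   rc_shift_ppm = as.numeric(rc_shift_ppm))
  if (any(df$shift_ppm <= 0, na.rm = TRUE))
    stop("shifts must be positive ppm", call. = FALSE)
  class(df) <- c("shift_table", class(df))
  df
}

#' Read a shift table CSV (residue, nucleus, shift_ppm, rc_shift_ppm)
#' @param path CSV file
#' @return a [shift_table]
#' @export
read_shift_csv <- function(path) {
  df <- utils::read.csv(path)
  shift_table(df$residue, df$nucleus, df$shift_ppm,
              df$rc_shift_ppm %||% NA)
}

#' Secondary-structure propensity from CA/CB secondary shifts
#'
#' Per-residue secondary shifts (measured minus random coil) for CA and CB are
#' combined as `dCA - dCB`, averaged over an odd window (truncated at the
#' termini), and scaled by the full-helix reference difference of 2.8 ppm, so
#' that +1 is fully helical and negative values indicate extended/strand
#' character. Residues without a CB (glycine) contribute `dCB = 0`.
#'
#' @param shifts a [shift_table] with CA (and CB where present) rows carrying
#'   random-coil references
#' @param window odd averaging window (default 5)
#' @return data.frame with `residue`, `ssp`
#' @export
ssp_from_shifts <- function(shifts, window = 5L) {
  stopifnot(inherits(shifts, "shift_table"))
  if (window %% 2L != 1L || window < 1L)
    stop("`window` must be odd and positive", call. = FALSE)
  ca <- shifts[shifts$nucleus == "CA", ]
  if (nrow(ca) == 0L) stop("no CA shifts in table", call. = FALSE)
  if (any(is.na(ca$rc_shift_ppm)))
    stop("random-coil reference shifts required for every measured CA",
         call. = FALSE)
  cb <- shifts[shifts$nucleus == "CB", ]
  res <- sort(unique(ca$residue))
  d_ca <- ca$shift_ppm[match(res, ca$residue)] -
    ca$rc_shift_ppm[match(res, ca$residue)]
  d_cb <- rep(0, length(res))
  hit <- match(res, cb$residue)
  ok <- !is.na(hit)
  d_cb[ok] <- cb$shift_ppm[hit[ok]] - cb$rc_shift_ppm[hit[ok]]
  sec <- d_ca - d_cb
  h <- (window - 1L) %/% 2L
  ssp <- vapply(seq_along(res), function(i) {
    lo <- max(1L, i - h); hi <- min(length(res), i + h)
    mean(sec[lo:hi])
  }, numeric(1)) / 2.8
  data.frame(residue = res, ssp = ssp)
}

#' Default chemical-shift-perturbation nucleus weights
#' @return named numeric vector of scale factors
#' @export
csp_weights <- function() c(H = 1.0, N = 0.154, C = 0.25, CA = 0.25,
                            CB = 0.25, C1p = 0.25, C2p = 0.25, C6 = 0.25,
                            C8 = 0.25)

#' Chemical shift perturbation between two states
#'
#' Combined CSP per residue is the root of the mean squared weighted shift
#' difference over the nuclei observed in both states; the max-carbon variant
#' is the largest single-nucleus |delta| among carbon positions (nucleus names
#' beginning with "C").
#'
#' @param state_a,state_b [shift_table]s for the two states (e.g. free and
#'   bound); residues present in only one state are reported as `NA`
#'   (unassigned)
#' @param weights named per-nucleus scale factors, see [csp_weights()]
#' @return data.frame with `residue`, `csp` (combined, ppm),
#'   `max_c_csp` (ppm), `n_nuclei`
#' @export
csp <- function(state_a, state_b, weights = csp_weights()) {
  stopifnot(inherits(state_a, "shift_table"), inherits(state_b, "shift_table"))
  key_a <- paste(state_a$residue, state_a$nucleus)
  key_b <- paste(state_b$residue, state_b$nucleus)
  common <- intersect(key_a, key_b)
  if (length(common) == 0L)
    stop("no residue/nucleus pairs common to both states", call. = FALSE)
  ia <- match(common, key_a); ib <- match(common, key_b)
  dd <- state_b$shift_ppm[ib] - state_a$shift_ppm[ia]
  resi <- state_a$residue[ia]
  nuc <- state_a$nucleus[ia]
  w <- weights[nuc]
  w[is.na(w)] <- 1
  residues <- sort(unique(c(state_a$residue, state_b$residue)))
  out <- data.frame(residue = residues, csp = NA_real_,
                    max_c_csp = NA_real_, n_nuclei = 0L)
  for (i in seq_along(residues)) {
    sel <- resi == residues[i]
    if (!any(sel)) next
    out$csp[i] <- sqrt(mean((w[sel] * dd[sel])^2))
    is_c <- startsWith(nuc[sel], "C")
    if (any(is_c)) out$max_c_csp[i] <- max(abs(dd[sel][is_c]))
    out$n_nuclei[i] <- sum(sel)
  }
  out
}

#' Helix fraction from backbone dihedrals
#'
#' A residue is helical in a frame when its (phi, psi) fall in the alpha basin
#' (phi in [-100, -30], psi in [-80, -5] degrees) and it belongs to a run of
#' at least `min_run` consecutive in-basin residues; the profile is the
#' per-residue fraction of frames satisfying this.
#'
#' @param ens an [ensemble] carrying a dihedral table
#' @param min_run minimum consecutive helical run length (default 3)
#' @return data.frame with `residue`, `helix_fraction`
#' @export
helicity_profile <- function(ens, min_run = 3L) {
  stopifnot(inherits(ens, "ensemble"))
  if (is.null(ens$dihedrals))
    stop("ensemble carries no dihedral table; helicity requires (phi, psi)",
         call. = FALSE)
  nf <- n_frames(ens); n <- n_sites(ens)
  w <- ens$weights %||% rep(1 / nf, nf)
  frac <- numeric(n)
  for (f in seq_len(nf)) {
    phi <- ens$dihedrals[f, , 1]; psi <- ens$dihedrals[f, , 2]
    inb <- !is.na(phi) & !is.na(psi) &
      phi >= -100 & phi <= -30 & psi >= -80 & psi <= -5
    r <- rle(inb)
    keep <- r
    keep$values <- r$values & r$lengths >= min_run
    frac <- frac + w[f] * inverse.rle(keep)
  }
  data.frame(residue = seq_len(n), helix_fraction = frac)
}
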