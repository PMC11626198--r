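# Shared fixtures, all built in code at test time.

serf_seq <- function() example_sequence("serf_synthetic")
tar_seq <- function() example_sequence("tar")

# Hand-built trajectory object for analysis-function oracles.
toy_trajectory <- function(frames, chain, box_edge = 10,
                           sigma = rep(0.5, length(chain))) {
  beads <- data.frame(code = rep("A", length(chain)), kind = "protein",
                      mass_gmol = 100, charge_e = 0, sigma_nm = sigma,
                      epsilon_kJmol = 0.3, mu = 2, nu = 1, chain = chain)
  structure(list(frames = frames, chain = chain, beads = beads,
                 box_edge = box_edge,
                 kinetic_temperature = rep(300, dim(frames)[1]),
                 potential_energy = rep(0, dim(frames)[1]),
                 time_ps = seq_len(dim(frames)[1]),
                 conformer = rep(1L, dim(frames)[1]),
                 config = sim_config(box_edge = box_edge, n_steps = 100L,
                                     save_every = 10L),
                 pooling = "separate_runs"),
            class = "cg_trajectory")
}

# Brute-force min-image interchain recount (independent of the C++ path).
brute_contacts <- function(traj, cutoff) {
  ia <- which(traj$chain == unique(traj$chain)[1])
  ib <- which(traj$chain == unique(traj$chain)[2])
  nf <- dim(traj$frames)[1]
  box <- traj$box_edge
  mi <- function(d) d - box * round(d / box)
  counts <- integer(nf)
  freq <- matrix(0, length(ia), length(ib))
  for (f in seq_len(nf)) {
    for (u in seq_along(ia)) for (v in seq_along(ib)) {
      d <- traj$frames[f, ia[u], ] - traj$frames[f, ib[v], ]
      r <- sqrt(sum(mi(d)^2))
      if (r < cutoff) {
        counts[f] <- counts[f] + 1L
        freq[u, v] <- freq[u, v] + 1
      }
    }
  }
  list(counts = counts, freq = freq / nf)
}

# Minimal multi-MODEL PDB writer for reader tests.
write_toy_pdb <- function(path, coords_list, resnames, atom_names) {
  fmt <- function(serial, name, resname, resno, x, y, z)
    sprintf("ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
            serial, name, resname, resno, x, y, z, 1, 0)
  lines <- character(0)
  for (m in seq_along(coords_list)) {
    lines <- c(lines, sprintf("MODEL     %4d", m))
    s <- 0L
    cc <- coords_list[[m]]
    for (r in seq_along(resnames)) {
      for (a in seq_along(atom_names[[r]])) {
        s <- s + 1L
        lines <- c(lines, fmt(s, atom_names[[r]][a], resnames[r], r,
                              cc[[r]][a, 1], cc[[r]][a, 2], cc[[r]][a, 3]))
      }
    }
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}
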