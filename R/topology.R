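#' Build a two-molecule coarse-grained topology
#'
#' One bead per residue or nucleotide. Flexible chains receive consecutive
#' harmonic bonds; an RNA supplied as a conformer coordinate set becomes one
#' rigid group whose internal geometry is fixed (one rigid body per
#' conformer, pooled across runs).
#'
#' @param protein a [bio_seq] (protein), or `NULL` for RNA-only systems
#' @param rna a [bio_seq] (flexible RNA), or a `conformer_set` from
#'   [gen_rna_conformers()] / [read_conformers_pdb()] (rigid RNA), or `NULL`
#' @param ff force-field table from [load_forcefield()]
#' @param bond_k harmonic bond constant (kJ/mol/nm^2)
#' @param bond_r0_protein,bond_r0_rna equilibrium bond lengths (nm)
#' @return object of class `cg_topology`: per-bead parameter table `beads`
#'   with `chain` ids, `bonds` (i, j, k, r0), and `rigid` (list with chain id
#'   and conformer coordinate array, nm) or `NULL`
#' @export
build_topology <- function(protein = NULL, rna = NULL, ff = load_forcefield(),
                           bond_k = 8033, bond_r0_protein = 0.381,
                           bond_r0_rna = 0.5) {
  chains <- list(); rigid <- NULL
  add_flexible <- function(seq, r0) {
    codes <- bead_codes(seq)
    if (length(codes) == 0L) stop("empty sequence", call. = FALSE)
    list(params = ff_lookup(ff, codes), r0 = r0, rigid = FALSE)
  }
  if (!is.null(protein)) {
    stopifnot(inherits(protein, "bio_seq"), protein$kind == "protein")
    chains$protein <- add_flexible(protein, bond_r0_protein)
  }
  if (!is.null(rna)) {
    if (inherits(rna, "bio_seq")) {
      stopifnot(rna$kind == "rna")
      chains$rna <- add_flexible(rna, bond_r0_rna)
    } else if (inherits(rna, "conformer_set")) {
      codes <- tolower(rna$seq$residues)
      nbead <- dim(rna$coords)[2]
      if (nbead != length(codes))
        stop(sprintf(
          "conformer bead count (%d) does not match RNA length (%d)",
          nbead, length(codes)), call. = FALSE)
      chains$rna <- list(params = ff_lookup(ff, codes), r0 = NA,
                         rigid = TRUE)
      rigid <- list(chain = "rna", coords = rna$coords * 0.1)  # A -> nm
    } else stop("`rna` must be a bio_seq or conformer_set", call. = FALSE)
  }
  if (length(chains) == 0L) stop("no molecules given", call. = FALSE)

  beads <- NULL; bonds <- NULL; offset <- 0L
  for (nm in names(chains)) {
    ch <- chains[[nm]]
    p <- ch$params
    p$chain <- nm
    beads <- rbind(beads, p)
    n <- nrow(p)
    if (!ch$rigid && n > 1L)
      bonds <- rbind(bonds, data.frame(i = offset + seq_len(n - 1L),
                                       j = offset + seq_len(n - 1L) + 1L,
                                       k = bond_k, r0 = ch$r0))
    offset <- offset + n
  }
  rownames(beads) <- NULL
  structure(list(beads = beads,
                 bonds = bonds %||%
                   data.frame(i = integer(0), j = integer(0),
                              k = numeric(0), r0 = numeric(0)),
                 rigid = rigid),
            class = "cg_topology")
}

#' @export
print.cg_topology <- function(x, ...) {
  cat(sprintf("<cg_topology> %d beads in %d chain(s): %s; %d bonds%s\n",
              nrow(x$beads), length(unique(x$beads$chain)),
              paste(sprintf("%s (%d)", unique(x$beads$chain),
                            table(x$beads$chain)[unique(x$beads$chain)]),
                    collapse = ", "),
              nrow(x$bonds),
              if (!is.null(x$rigid))
                sprintf("; rigid chain '%s' with %d conformer(s)",
                        x$rigid$chain, dim(x$rigid$coords)[1]) else ""))
  invisible(x)
}
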