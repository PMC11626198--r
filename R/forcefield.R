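#' Load a coarse-grained force-field table
#'
#' Reads the versioned bead-parameter table (one bead per amino acid or
#' ribonucleotide): mass, charge, Wang-Frenkel `sigma`, `epsilon`, and shape
#' parameters `mu`, `nu`. RNA bead codes are stored lower-case internally so
#' that protein A and adenosine A coexist in one table. The bundled default
#' is an approximate transcription in the style of residue-resolution IDP/RNA
#' force fields (see the package vignette for provenance and caveats).
#'
#' @param path TSV file; default the bundled table
#' @return data.frame of class `ff_table`
#' @export
load_forcefield <- function(path = NULL) {
  path <- path %||% system.file("extdata", "cg_forcefield.tsv",
                                package = "idrbind")
  ff <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("code", "kind", "mass_gmol", "charge_e", "sigma_nm",
            "epsilon_kJmol", "mu", "nu")
  if (!all(need %in% names(ff)))
    stop("force-field table missing columns: ",
         paste(setdiff(need, names(ff)), collapse = ", "), call. = FALSE)
  if (any(ff$sigma_nm <= 0) || any(ff$epsilon_kJmol < 0))
    stop("invalid force-field parameters (sigma <= 0 or epsilon < 0)",
         call. = FALSE)
  if (anyDuplicated(ff$code))
    stop("duplicate bead codes in force-field table", call. = FALSE)
  rownames(ff) <- ff$code
  class(ff) <- c("ff_table", class(ff))
  attr(ff, "source") <- path
  ff
}

# Internal bead code: protein letters upper-case, RNA lower-case.
bead_codes <- function(seq) {
  if (seq$kind == "protein") seq$residues else tolower(seq$residues)
}

ff_lookup <- function(ff, codes) {
  idx <- match(codes, ff$code)
  if (anyNA(idx))
    stop("letter(s) missing from force-field table: ",
         paste(unique(codes[is.na(idx)]), collapse = ", "), call. = FALSE)
  ff[idx, ]
}
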