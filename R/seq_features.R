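#' Per-residue formal charges at a given pH
#'
#' The default integer convention at neutral-to-slightly-basic pH: Arg/Lys +1,
#' Asp/Glu -1, His 0, all else 0; RNA nucleotides -1 each (phosphate
#' bookkeeping, one charge per nucleotide). A pH hook is provided: below
#' pH 6.0 histidine is assigned +1; termini are never charged (the integer
#' convention that reproduces the published whole-protein values).
#'
#' @param kind `"protein"` or `"rna"`
#' @param ph solution pH (only the His rule depends on it)
#' @return named numeric vector of charges over the alphabet
#' @export
charge_table <- function(kind = c("protein", "rna"), ph = 7.5) {
  kind <- match.arg(kind)
  if (kind == "rna") return(setNames(rep(-1, 4), RNA_ALPHABET))
  ch <- setNames(rep(0, length(AA_ALPHABET)), AA_ALPHABET)
  ch[c("R", "K")] <- 1
  ch[c("D", "E")] <- -1
  ch["H"] <- if (ph < 6.0) 1 else 0
  ch
}

residue_charges <- function(seq, ph = 7.5) {
  unname(charge_table(seq$kind, ph = ph)[seq$residues])
}

#' Net formal charge of a sequence
#'
#' Protein: +1 per Arg/Lys, -1 per Asp/Glu, His neutral at the default pH.
#' RNA: -1 per nucleotide.
#'
#' @param seq a [bio_seq]
#' @param ph pH passed to [charge_table()]
#' @return signed integer-valued net charge (elementary charges)
#' @examples
#' net_charge(bio_seq("KKDE", "protein"))  # 0
#' @export
net_charge <- function(seq, ph = 7.5) {
  stopifnot(inherits(seq, "bio_seq"))
  sum(residue_charges(seq, ph = ph))
}

#' Windowed net charge per residue (NCPR) profile
#'
#' Mean per-residue charge in an odd window centered at each position; windows
#' are truncated (shrunk) at the termini so the profile length equals the
#' sequence length.
#'
#' @param seq a [bio_seq]
#' @param window odd positive integer, default 5
#' @param ph pH for the charge table
#' @return data.frame of class `charge_profile` with columns `position`,
#'   `ncpr`; the window size is attached as attribute `window`
#' @export
ncpr_profile <- function(seq, window = 5L, ph = 7.5) {
  stopifnot(inherits(seq, "bio_seq"))
  n <- length(seq)
  if (window %% 2L != 1L || window < 1L || window > n)
    stop("`window` must be an odd positive integer no longer than the sequence",
         call. = FALSE)
  q <- residue_charges(seq, ph = ph)
  h <- (window - 1L) %/% 2L
  ncpr <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    mean(q[lo:hi])
  }, numeric(1))
  out <- data.frame(position = seq_len(n), ncpr = ncpr)
  attr(out, "window") <- as.integer(window)
  class(out) <- c("charge_profile", class(out))
  out
}

#' Write an NCPR profile as two-column TSV
#' @param profile result of [ncpr_profile()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_charge_profile <- function(profile, path) {
  utils::write.table(profile[, c("position", "ncpr")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Charge-matched protein:RNA molar ratio
#'
#' The protein:RNA molar ratio at which positive protein charge exactly
#' balances negative RNA charge, `|z_RNA| / z_protein`. For a +12 protein and
#' a -29 RNA this is 29/12 ~ 2.42, the stoichiometry at which coacervation is
#' expected to be maximal.
#'
#' @param protein,rna [bio_seq] objects with opposite net charge signs
#' @param ph pH for the charge tables
#' @return positive scalar molar ratio (protein per RNA)
#' @export
charge_matched_ratio <- function(protein, rna, ph = 7.5) {
  zp <- net_charge(protein, ph = ph)
  zr <- net_charge(rna, ph = ph)
  if (zp <= 0 || zr >= 0)
    stop("charge-matched stoichiometry undefined: need net positive protein ",
         sprintf("and net negative RNA (got %+d and %+d)", zp, zr),
         call. = FALSE)
  abs(zr) / zp
}

#' Sequence composition counts
#'
#' @param seq a [bio_seq]
#' @return list with `length`, named per-letter `counts`, and
#'   `non_proline_count` (equals `length` for RNA)
#' @export
composition_counts <- function(seq) {
  stopifnot(inherits(seq, "bio_seq"))
  alpha <- if (seq$kind == "protein") AA_ALPHABET else RNA_ALPHABET
  counts <- table(factor(seq$residues, levels = alpha))
  list(length = length(seq),
       counts = setNames(as.integer(counts), names(counts)),
       non_proline_count = sum(seq$residues != "P"))
}
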