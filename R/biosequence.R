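AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")
RNA_ALPHABET <- c("A","C","G","U")

#' Construct a biological sequence
#'
#' The root input object of the package: a protein or RNA sequence with a
#' strict residue alphabet (20 amino-acid letters, or A/C/G/U).
#'
#' @param residues character vector of one-letter codes, or a single string
#' @param kind `"protein"` or `"rna"`
#' @param id text identifier
#' @return object of class `bio_seq` with fields `id`, `kind`, `residues`
#' @examples
#' bio_seq("GGCAGAUCUGAGCCUGGGAGCUCUCUGCC", "rna", id = "tar")
#' @export
bio_seq <- function(residues, kind = c("protein", "rna"), id = "seq") {
  kind <- match.arg(kind)
  if (length(residues) == 1L && nchar(residues[1L]) > 1L)
    residues <- strsplit(residues, "")[[1L]]
  residues <- toupper(as.character(residues))
  if (kind == "rna") residues[residues == "T"] <- "U"
  if (length(residues) == 0L)
    stop("sequence must be non-empty", call. = FALSE)
  alpha <- if (kind == "protein") AA_ALPHABET else RNA_ALPHABET
  bad <- setdiff(unique(residues), alpha)
  if (length(bad) > 0L)
    stop(sprintf("invalid %s residue letter(s): %s", kind,
                 paste(bad, collapse = ", ")), call. = FALSE)
  structure(list(id = id, kind = kind, residues = residues),
            class = "bio_seq")
}

#' @export
length.bio_seq <- function(x) length(x$residues)

#' @export
print.bio_seq <- function(x, ...) {
  cat(sprintf("<bio_seq> %s (%s), %d residues\n", x$id, x$kind,
              length(x$residues)))
  cat(paste(x$residues, collapse = ""), "\n")
  invisible(x)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file
#' @param kind `"protein"` or `"rna"`; T is normalized to U for RNA
#' @return list of [bio_seq] objects (empty list for an empty file)
#' @export
read_fasta <- function(path, kind = c("protein", "rna")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(list())
  hdr <- grepl("^>", lines)
  if (!hdr[1L])
    stop(sprintf("malformed FASTA at line 1 of %s: expected '>'", path),
         call. = FALSE)
  idx <- cumsum(hdr)
  out <- vector("list", max(idx))
  for (k in seq_len(max(idx))) {
    block <- lines[idx == k]
    id <- sub("^>\\s*", "", block[1L])
    id <- strsplit(id, "\\s+")[[1L]][1L]
    if (length(block) < 2L)
      stop(sprintf("malformed FASTA record '%s': no sequence lines", id),
           call. = FALSE)
    seqstr <- gsub("\\s", "", paste(block[-1L], collapse = ""))
    out[[k]] <- bio_seq(seqstr, kind = kind, id = id)
  }
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs a [bio_seq] or list of them
#' @param path output file
#' @param width line-wrap width
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (inherits(seqs, "bio_seq")) seqs <- list(seqs)
  con <- file(path, "w"); on.exit(close(con))
  for (s in seqs) {
    writeLines(paste0(">", s$id), con)
    str <- paste(s$residues, collapse = "")
    starts <- seq(1L, nchar(str), by = width)
    writeLines(substring(str, starts, pmin(starts + width - 1L, nchar(str))),
               con)
  }
  invisible(path)
}

#' Bundled example sequences
#'
#' Returns the packaged sequences: the printed 29-nt HIV-1 TAR stem-loop
#' fragment, a synthetic SERF-like 68-residue protein (composition-matched
#' stand-in, see the package vignette), and poly-rU of a given length.
#'
#' @param which one of `"serf_synthetic"`, `"tar"`, `"rU"`
#' @param n length for `"rU"` (default 30)
#' @return a [bio_seq]
#' @export
example_sequence <- function(which = c("serf_synthetic", "tar", "rU"),
                             n = 30L) {
  which <- match.arg(which)
  if (which == "rU")
    return(bio_seq(strrep("U", n), "rna", id = sprintf("rU%d", n)))
  f <- system.file("extdata", paste0(which, ".fasta"), package = "idrbind")
  kind <- if (which == "tar") "rna" else "protein"
  read_fasta(f, kind = kind)[[1L]]
}
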