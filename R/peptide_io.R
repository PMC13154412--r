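#' Fixed-length peptide alignment
#'
#' Container for a gap-free alignment of `M` peptides of common length `L`
#' over a fixed alphabet, optionally labelled with the HLA allotype the
#' peptides bind.  This is the matrix `a = {a_mu_i}` of M sequences aligned
#' at L positions on which all evolutionary statistics are computed.
#'
#' @param sequences character vector of peptide strings, all of length `L`.
#' @param allotype free-text allotype label, e.g. `"HLA-DRB5*01:01"`.
#' @param alphabet residue alphabet; defaults to the 20 canonical amino
#'   acids in alphabetical order ([AA_ALPHABET]).
#' @param validate check sequences against the alphabet and common length.
#' @return An object of class `peptide_alignment` with fields `sequences`,
#'   `M`, `L`, `allotype`, `alphabet`.
#' @export
peptide_alignment <- function(sequences, allotype = NA_character_,
                              alphabet = AA_ALPHABET, validate = TRUE) {
  sequences <- as.character(sequences)
  if (length(sequences) < 1L) stop("alignment must contain at least one sequence")
  L <- nchar(sequences[[1L]])
  aln <- structure(
    list(sequences = sequences, M = length(sequences), L = L,
         allotype = allotype, alphabet = alphabet),
    class = "peptide_alignment"
  )
  if (validate) validate_alignment(aln)
  aln
}

#' @export
print.peptide_alignment <- function(x, ...) {
  cat(sprintf("peptide_alignment: M=%d sequences, L=%d positions, allotype=%s\n",
              x$M, x$L, ifelse(is.na(x$allotype), "<none>", x$allotype)))
  show <- utils::head(x$sequences, 5L)
  cat(paste0("  ", show, collapse = "\n"), "\n")
  if (x$M > 5L) cat(sprintf("  ... (%d more)\n", x$M - 5L))
  invisible(x)
}

validate_alignment <- function(aln) {
  stopifnot(inherits(aln, "peptide_alignment"))
  if (aln$M != length(aln$sequences)) stop("M does not match number of sequences")
  len <- nchar(aln$sequences)
  if (any(len != aln$L)) {
    bad <- which(len != aln$L)[1L]
    stop(sprintf("sequence %d has length %d, expected L=%d", bad, len[bad], aln$L))
  }
  ok <- grepl(sprintf("^[%s]+$", paste(aln$alphabet, collapse = "")), aln$sequences)
  if (!all(ok)) {
    bad <- which(!ok)[1L]
    stop(sprintf("sequence %d ('%s') contains characters outside the %d-letter alphabet",
                 bad, aln$sequences[bad], length(aln$alphabet)))
  }
  invisible(aln)
}

#' Ordered collection of per-allotype alignments
#'
#' @param alignments named list of [peptide_alignment] objects; names are the
#'   allotype labels (unique) and all alignments must share the same `L`.
#' @return Object of class `allotype_dataset`.
#' @export
allotype_dataset <- function(alignments) {
  if (is.null(names(alignments)) || anyDuplicated(names(alignments)))
    stop("alignments must be a named list with unique allotype labels")
  Ls <- vapply(alignments, function(a) a$L, integer(1))
  if (length(unique(Ls)) > 1L) stop("all alignments must share the same length L")
  structure(alignments, class = "allotype_dataset")
}

#' @export
print.allotype_dataset <- function(x, ...) {
  cat(sprintf("allotype_dataset: %d allotype(s), L=%d\n",
              length(x), if (length(x)) x[[1L]]$L else NA_integer_))
  for (nm in names(x)) cat(sprintf("  %-28s M=%d\n", nm, x[[nm]]$M))
  invisible(x)
}

#' Read a fixed-length peptide alignment or multi-allotype dataset
#'
#' Supported dialects: `"fasta"` (standard FASTA, parsed with Biostrings),
#' `"lines"` (one peptide per line, blank lines ignored), and `"table"`
#' (two-column comma- or tab-separated file with a header row naming the
#' columns `allotype` and `peptide`).  The table dialect returns an
#' [allotype_dataset]; the other two return a single [peptide_alignment].
#'
#' In `strict` mode any sequence failing validation (wrong length,
#' non-canonical residue) is an error; in `lenient` mode offending sequences
#' are dropped with a message reporting the count.
#'
#' @param path input file path.
#' @param format one of `"fasta"`, `"lines"`, `"table"`.
#' @param length expected alignment length L (default 9, the MHCII
#'   binding-core length); `NA` accepts the length of the first sequence.
#' @param allotype allotype label attached to single-alignment dialects.
#' @param mode `"strict"` or `"lenient"`.
#' @param alphabet residue alphabet.
#' @return A [peptide_alignment] or, for `format = "table"`, an
#'   [allotype_dataset].
#' @export
read_alignment <- function(path, format = c("fasta", "lines", "table"),
                           length = 9L, allotype = NA_character_,
                           mode = c("strict", "lenient"),
                           alphabet = AA_ALPHABET) {
  format <- match.arg(format)
  mode <- match.arg(mode)
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))

  if (format == "table") {
    tab <- read_peptide_table(path)
    groups <- split(tab$peptide, factor(tab$allotype, levels = unique(tab$allotype)))
    alns <- lapply(names(groups), function(lab) {
      seqs <- screen_sequences(groups[[lab]], length, alphabet, mode,
                               what = sprintf("allotype %s", lab))
      peptide_alignment(seqs, allotype = lab, alphabet = alphabet)
    })
    names(alns) <- names(groups)
    return(allotype_dataset(alns))
  }

  seqs <- switch(format,
    fasta = as.character(Biostrings::readBStringSet(path)),
    lines = {
      x <- readLines(path, warn = FALSE)
      x <- trimws(x)
      x[nzchar(x)]
    })
  seqs <- screen_sequences(unname(seqs), length, alphabet, mode, what = path)
  peptide_alignment(seqs, allotype = allotype, alphabet = alphabet)
}

read_peptide_table <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("allotype", "peptide")
  if (!all(need %in% names(tab)))
    stop("table dialect requires header columns 'allotype' and 'peptide'")
  tab[, need]
}

screen_sequences <- function(seqs, length, alphabet, mode, what = "input") {
  seqs <- toupper(seqs)
  if (is.na(length)) length <- nchar(seqs[[1L]])
  okpat <- sprintf("^[%s]{%d}$", paste(alphabet, collapse = ""), length)
  ok <- grepl(okpat, seqs)
  if (!all(ok)) {
    if (mode == "strict") {
      bad <- which(!ok)[1L]
      stop(sprintf("%s: sequence %d ('%s') fails validation (expected %d canonical residues)",
                   what, bad, seqs[bad], length))
    }
    message(sprintf("%s: dropped %d of %d sequences failing validation",
                    what, sum(!ok), base::length(seqs)))
    seqs <- seqs[ok]
  }
  if (base::length(seqs) == 0L) stop(sprintf("%s: no valid sequences", what))
  seqs
}

#' Keep only allotypes with enough sequences
#'
#' Per-allotype screening of a multi-allotype dataset: an allotype is kept
#' when it has no fewer than `min_sequences` binding cores (boundary
#' inclusive).  Entry order is preserved; dropped allotypes are reported
#' with a message.
#'
#' @param ds an [allotype_dataset].
#' @param min_sequences minimum M per allotype (default 200).
#' @return Filtered [allotype_dataset]; may be empty.
#' @export
filter_allotypes <- function(ds, min_sequences = 200L) {
  stopifnot(inherits(ds, "allotype_dataset"))
  keep <- vapply(ds, function(a) a$M >= min_sequences, logical(1))
  if (any(!keep))
    message(sprintf("filter_allotypes: dropped %d allotype(s) with M < %d: %s",
                    sum(!keep), min_sequences,
                    paste(names(ds)[!keep], collapse = ", ")))
  allotype_dataset(unclass(ds)[keep])
}

#' Encode an alignment as an integer matrix
#'
#' Maps each residue to its 0-based index in the alignment's alphabet
#' (alphabetical one-letter order by default, so A=0, C=1, ..., Y=19).
#'
#' @param aln a [peptide_alignment].
#' @return Integer matrix of dimension M x L with values in `0:(A-1)`.
#' @seealso [decode_alignment()]
#' @export
encode_alignment <- function(aln) {
  validate_alignment(aln)
  chars <- matrix(unlist(strsplit(aln$sequences, "", fixed = TRUE), use.names = FALSE),
                  nrow = aln$M, ncol = aln$L, byrow = TRUE)
  idx <- match(chars, aln$alphabet)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop(sprintf("unknown character '%s' in alignment", chars[bad]))
  }
  matrix(idx - 1L, nrow = aln$M, ncol = aln$L)
}

#' Decode an integer matrix back to a peptide alignment
#'
#' Inverse of [encode_alignment()] under the same alphabet ordering.
#'
#' @param mat integer matrix M x L with values in `0:(A-1)`.
#' @param allotype allotype label for the decoded alignment.
#' @param alphabet residue alphabet.
#' @return A [peptide_alignment].
#' @export
decode_alignment <- function(mat, allotype = NA_character_, alphabet = AA_ALPHABET) {
  if (any(mat < 0L) || any(mat >= length(alphabet)))
    stop("encoded values out of alphabet range")
  ch <- matrix(alphabet[mat + 1L], nrow = nrow(mat))
  seqs <- apply(ch, 1L, paste, collapse = "")
  peptide_alignment(seqs, allotype = allotype, alphabet = alphabet)
}

#' Write a (designed) alignment or dataset to disk
#'
#' FASTA headers carry `allotype|strategy|index` so that exported designs can
#' be fed to downstream affinity or structure predictors and round-trip
#' losslessly through [read_alignment()].  The `lines` dialect writes bare
#' sequences; the `table` dialect writes a header row plus one
#' `allotype,peptide` row per sequence and accepts either a single alignment
#' or an [allotype_dataset].
#'
#' @param aln a [peptide_alignment] or [allotype_dataset].
#' @param path output file path.
#' @param format one of `"fasta"`, `"lines"`, `"table"`.
#' @param strategy design-strategy tag recorded in FASTA headers
#'   (e.g. `"FS"`, `"L2"`, `"MC2"`, `"native"`).
#' @return `path`, invisibly.
#' @export
write_designed <- function(aln, path, format = c("fasta", "lines", "table"),
                           strategy = "design") {
  format <- match.arg(format)
  if (inherits(aln, "allotype_dataset")) {
    if (format != "table")
      stop("multi-allotype export requires format = 'table'")
    rows <- do.call(rbind, lapply(names(aln), function(lab)
      data.frame(allotype = lab, peptide = aln[[lab]]$sequences)))
    utils::write.table(rows, path, sep = ",", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  validate_alignment(aln)
  lab <- ifelse(is.na(aln$allotype), "unknown", aln$allotype)
  switch(format,
    fasta = {
      x <- Biostrings::BStringSet(aln$sequences)
      names(x) <- sprintf("%s|%s|%d", lab, strategy, seq_len(aln$M))
      Biostrings::writeXStringSet(x, path)
    },
    lines = writeLines(aln$sequences, path),
    table = {
      rows <- data.frame(allotype = lab, peptide = aln$sequences)
      utils::write.table(rows, path, sep = ",", quote = FALSE, row.names = FALSE)
    })
  invisible(path)
}
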