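# Sequence-level comparison: Kyte-Doolittle hydropathy (GRAVY), net charge
# of residue subsets, and percent identity from alignments. These are the
# quantities used to rationalize why isoforms with similar binding free
# energies can differ in surface chemistry.

#' Kyte-Doolittle hydropathy scale
#'
#' The original 20-residue scale (one decimal per residue), as used by
#' ProtParam.
#'
#' @return Named numeric vector over the canonical one-letter codes.
#' @export
kyte_doolittle <- function() {
  c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
    L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
}

check_canonical <- function(residues) {
  bad <- which(!residues %in% names(kyte_doolittle()))
  if (length(bad)) {
    stop(sprintf("non-canonical residue '%s' at position %d",
                 residues[bad[1]], bad[1]))
  }
  invisible(residues)
}

split_residues <- function(seq) {
  seq <- toupper(gsub("\\s", "", seq))
  if (nchar(seq) == 0L) stop("empty sequence")
  strsplit(seq, "")[[1]]
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over all residues. Returned at full
#' precision; report to 3 decimals for comparison with published values.
#'
#' @param seq Amino-acid sequence (one-letter string, canonical residues
#'   only; non-canonical letters are rejected with their position).
#' @return Dimensionless mean hydropathy; positive = hydrophobic.
#' @export
gravy <- function(seq) {
  r <- check_canonical(split_residues(seq))
  mean(kyte_doolittle()[r])
}

#' GRAVY of a residue subset
#'
#' GRAVY restricted to a domain (contiguous `start:end`, 1-based
#' inclusive) or to an explicit position vector, e.g. the non-identical
#' columns of an isoform alignment mapped onto one sequence.
#'
#' @param seq Amino-acid sequence.
#' @param start,end 1-based inclusive bounds (used when `positions` is
#'   NULL).
#' @param positions Optional integer vector of positions overriding
#'   `start`/`end`.
#' @return GRAVY over the selected residues.
#' @export
domain_gravy <- function(seq, start = 1L, end = NULL, positions = NULL) {
  r <- check_canonical(split_residues(seq))
  if (is.null(positions)) {
    if (is.null(end)) end <- length(r)
    if (start < 1L || end > length(r) || start > end) {
      stop("domain bounds outside the sequence")
    }
    positions <- start:end
  }
  positions <- as.integer(positions)
  if (length(positions) == 0L) stop("empty residue subset")
  if (any(positions < 1L | positions > length(r))) {
    stop("positions outside the sequence")
  }
  mean(kyte_doolittle()[r[positions]])
}

#' Net charge of a sequence or subset
#'
#' Neutral-pH approximation: lysine and arginine count +1, aspartate and
#' glutamate -1, histidine neutral.
#'
#' @param seq Amino-acid sequence.
#' @param positions Optional 1-based positions restricting the count.
#' @return Integer net charge.
#' @export
net_charge <- function(seq, positions = NULL) {
  r <- check_canonical(split_residues(seq))
  if (!is.null(positions)) {
    positions <- as.integer(positions)
    if (any(positions < 1L | positions > length(r))) {
      stop("positions outside the sequence")
    }
    r <- r[positions]
  }
  sum(r %in% c("K", "R")) - sum(r %in% c("D", "E"))
}

#' Percent identity of an aligned pair
#'
#' Default identity convention: identical non-gap columns divided by the
#' number of alignment columns carrying at least one residue (columns with
#' a gap in one sequence count as mismatches; columns gapped in both are
#' invalid input). `denominator = "aligned_pairs"` instead divides by the
#' columns where both sequences carry a residue, the convention of several
#' aligners' identity matrices. Published percent identities routinely
#' differ by 1-2 points between the two conventions, so both are
#' available. Returned at full precision; round to the nearest integer
#' for reporting.
#'
#' @param a,b Equal-length gapped sequences (letters plus `-`).
#' @param denominator `"any_residue"` (default) or `"aligned_pairs"`.
#' @return Percent identity in [0, 100].
#' @export
pairwise_identity <- function(a, b,
                              denominator = c("any_residue", "aligned_pairs")) {
  denominator <- match.arg(denominator)
  ra <- strsplit(toupper(gsub("\\s", "", a)), "")[[1]]
  rb <- strsplit(toupper(gsub("\\s", "", b)), "")[[1]]
  if (length(ra) == 0L || length(ra) != length(rb)) {
    stop("aligned sequences must be non-empty and of equal length")
  }
  ok <- c(names(kyte_doolittle()), "-")
  if (!all(ra %in% ok) || !all(rb %in% ok)) {
    stop("alignment may contain only canonical residues and '-' gaps")
  }
  if (all(ra == "-" & rb == "-")) stop("all-gap alignment")
  if (any(ra == "-" & rb == "-")) {
    stop("columns gapped in both sequences are not allowed")
  }
  ident <- ra == rb & ra != "-"
  den <- if (denominator == "aligned_pairs") {
    sum(ra != "-" & rb != "-")
  } else {
    length(ra)
  }
  if (den == 0L) stop("no aligned residue pairs")
  100 * sum(ident) / den
}

#' Read sequences from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  out <- as.character(x)
  names(out) <- vapply(strsplit(names(x), "\\s+"), `[[`, character(1), 1)
  out
}

#' Read a multiple alignment (aligned FASTA or Clustal)
#'
#' @param path Alignment file.
#' @param format "fasta" or "clustal".
#' @return Named character vector of equal-length gapped sequences.
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  aln <- Biostrings::readAAMultipleAlignment(path, format = format)
  out <- as.character(Biostrings::unmasked(aln))
  names(out) <- vapply(strsplit(names(out), "\\s+"), `[[`, character(1), 1)
  if (length(unique(nchar(out))) != 1L) stop("ragged alignment")
  out
}

#' Identity matrix of an alignment
#'
#' Pairwise [pairwise_identity()] over all sequence pairs of a multiple
#' alignment; pairwise columns gapped in both sequences are dropped before
#' comparison.
#'
#' @param aln Named character vector of gapped sequences (equal length).
#' @param denominator Identity convention, see [pairwise_identity()].
#' @return Symmetric numeric matrix of percent identities (diagonal 100).
#' @export
identity_matrix <- function(aln,
                            denominator = c("any_residue", "aligned_pairs")) {
  denominator <- match.arg(denominator)
  n <- length(aln)
  m <- matrix(100, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- strsplit(aln[[i]], "")[[1]]
      b <- strsplit(aln[[j]], "")[[1]]
      keep <- !(a == "-" & b == "-")
      pid <- pairwise_identity(paste(a[keep], collapse = ""),
                               paste(b[keep], collapse = ""),
                               denominator = denominator)
      m[i, j] <- m[j, i] <- pid
    }
  }
  m
}

#' Read domain annotations
#'
#' CSV with header `name,start,end` (1-based inclusive positions).
#'
#' @param path CSV file.
#' @return data.frame with columns name, start, end.
#' @export
read_domains <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "start", "end") %in% names(d))) {
    stop("domain CSV must have columns name,start,end")
  }
  if (any(d$start < 1 | d$end < d$start)) stop("invalid domain bounds")
  d
}
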