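#' Simulate a random reference genome
#'
#' Draws i.i.d. bases with a target GC content, standing in for a bacterial
#' reference (a single multi-megabase bacterial chromosome in practice).
#' Deterministic given `seed`.
#'
#' @param n_contigs Number of contigs.
#' @param lengths Integer vector of contig lengths (recycled to `n_contigs`).
#' @param gc_fraction Target GC content in `[0, 1]`.
#' @param seed Integer RNG seed.
#' @return A `pv_reference`: list with `seq`, a named character vector of
#'   uppercase ACGT contig sequences.
#' @export
generate_reference <- function(n_contigs = 1L, lengths = 1e5L,
                               gc_fraction = 0.35, seed = 1L) {
  lengths <- rep_len(as.integer(lengths), n_contigs)
  if (any(!is.finite(lengths)) || any(lengths <= 0L))
    stop("contig lengths must be positive")
  if (gc_fraction < 0 || gc_fraction > 1) stop("gc_fraction must be in [0, 1]")
  set.seed(as.integer(seed))
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  seqs <- vapply(lengths, function(L) {
    paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
  }, character(1))
  names(seqs) <- sprintf("contig%02d", seq_len(n_contigs))
  new_reference(seqs)
}

#' Construct a reference genome from sequences
#'
#' @param seqs Named character vector of uppercase ACGT sequences.
#' @return A `pv_reference` object.
#' @export
new_reference <- function(seqs) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("contig ids must be present and unique")
  if (any(nchar(seqs) == 0L)) stop("contig sequences must be non-empty")
  if (any(grepl("[^ACGT]", seqs))) stop("alphabet restricted to ACGT")
  structure(list(seq = seqs), class = "pv_reference")
}

#' @export
print.pv_reference <- function(x, ...) {
  cat("<pv_reference> ", length(x$seq), " contig(s), ",
      format(sum(nchar(x$seq)), big.mark = ","), " bp total\n", sep = "")
  invisible(x)
}

contig_lengths <- function(ref) setNames(nchar(ref$seq), names(ref$seq))

ref_base <- function(ref, contig, pos, len = 1L) {
  substr(ref$seq[[contig]], pos, pos + len - 1L)
}

#' Read a reference genome from FASTA
#' @param path Path to a FASTA file.
#' @return A `pv_reference` object.
#' @export
read_reference <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  new_reference(toupper(seqs))
}

#' Write a reference genome to FASTA
#' @param ref A `pv_reference`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ref$seq), path)
  invisible(path)
}
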