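#' Read alignments from SAM/BAM into the internal alignment table
#'
#' SAM input is converted with [Rsamtools::asBam()] and read back with
#' [Rsamtools::scanBam()]. SEQ is kept in SAM (reference-forward)
#' orientation.
#'
#' @param path Path to a `.sam` or `.bam` file.
#' @return Alignment data frame (qname, read1, contig, pos, strand, mapq,
#'   cigar, seq, qual, unmapped).
#' @export
read_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  flag <- b$flag
  data.frame(qname = b$qname,
             read1 = bitwAnd(flag, 64L) > 0L,
             contig = as.character(b$rname),
             pos = b$pos,
             strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
             mapq = ifelse(is.na(b$mapq), 0L, b$mapq),
             cigar = ifelse(is.na(b$cigar), "*", b$cigar),
             seq = as.character(b$seq),
             qual = as.character(Biostrings::BStringSet(b$qual)),
             unmapped = bitwAnd(flag, 4L) > 0L,
             stringsAsFactors = FALSE)
}

as_alignment_table <- function(alignments) {
  if (inherits(alignments, "pv_readset")) return(alignments$alignments)
  if (is.character(alignments) && length(alignments) == 1L)
    return(read_alignments(alignments))
  stopifnot(is.data.frame(alignments))
  alignments
}

#' Build a per-site evidence pileup
#'
#' One evidence column per covered site: base counts split by strand,
#' summed base qualities, indel and soft-clip support, and (for
#' non-reference observations) the distance of each supporting base from
#' the nearer read end. Bases below `min_base_quality` and reads below
#' `min_mapping_quality` are excluded from counts; overlapping mate pairs
#' contribute once per site, the higher-quality base winning.
#'
#' @param alignments A `pv_readset`, an alignment data frame
#'   (see [read_alignments()]), or a SAM/BAM path.
#' @param reference A `pv_reference` matching the alignments.
#' @param min_mapping_quality,min_base_quality Inclusion thresholds
#'   (defaults 20/20).
#' @return A `pv_pileup` object.
#' @export
build_pileup <- function(alignments, reference,
                         min_mapping_quality = 20L, min_base_quality = 20L) {
  if (inherits(alignments, "pv_readset") && is.null(reference))
    reference <- alignments$reference
  aln <- as_alignment_table(alignments)
  stopifnot(inherits(reference, "pv_reference"))
  bad <- !aln$unmapped & !aln$contig %in% names(reference$seq)
  if (any(bad))
    stop("alignment contig(s) not in reference: ",
         paste(unique(aln$contig[bad]), collapse = ", "))
  contigs <- list()
  max_rl <- 0L
  for (ctg in names(reference$seq)) {
    sub <- aln[!aln$unmapped & aln$contig == ctg, , drop = FALSE]
    refseq <- reference$seq[[ctg]]
    if (nrow(sub) == 0L) {
      contigs[[ctg]] <- empty_pileup_contig(nchar(refseq))
      next
    }
    mate <- mate_index(sub$qname, sub$read1)
    res <- pileup_core(sub$seq, sub$qual, sub$cigar, sub$pos,
                       as.integer(sub$strand == "-"), sub$mapq,
                       mate - 1L, sub$unmapped, refseq,
                       as.integer(min_mapping_quality),
                       as.integer(min_base_quality))
    max_rl <- max(max_rl, res$read_length)
    contigs[[ctg]] <- list(
      counts = res$counts, qsum = res$qsum,
      ins_support = res$ins_support, del_support = res$del_support,
      clip_lead = res$clip_lead, clip_trail = res$clip_trail,
      mismatches = data.frame(pos = res$mism_pos,
                              base = BASES[res$mism_base],
                              strand = ifelse(res$mism_strand == 1L, "-", "+"),
                              offset = res$mism_offset, qual = res$mism_qual,
                              stringsAsFactors = FALSE),
      events = data.frame(type = ifelse(res$ev_type == 1L, "insertion", "deletion"),
                          pos = res$ev_pos, len = res$ev_len,
                          seq = as.character(res$ev_seq),
                          support = res$ev_support, stringsAsFactors = FALSE))
  }
  structure(list(contigs = contigs, reference = reference,
                 read_length = max_rl,
                 params = list(min_mapping_quality = min_mapping_quality,
                               min_base_quality = min_base_quality)),
            class = "pv_pileup")
}

empty_pileup_contig <- function(L) {
  list(counts = matrix(0L, L, 8), qsum = matrix(0, L, 4),
       ins_support = integer(L), del_support = integer(L),
       clip_lead = integer(L), clip_trail = integer(L),
       mismatches = data.frame(pos = integer(), base = character(),
                               strand = character(), offset = integer(),
                               qual = integer()),
       events = data.frame(type = character(), pos = integer(),
                           len = integer(), seq = character(),
                           support = integer()))
}

#' @export
print.pv_pileup <- function(x, ...) {
  dp <- vapply(x$contigs, function(c) sum(as.numeric(c$counts)), numeric(1))
  cat("<pv_pileup> ", length(x$contigs), " contig(s), ",
      format(sum(dp), big.mark = ","), " retained base observations\n", sep = "")
  invisible(x)
}

pileup_depth <- function(pc) rowSums(pc$counts)

# counts for one base as c(fwd, rev)
base_strand_counts <- function(pc, pos, base) {
  b <- match(base, BASES)
  c(fwd = pc$counts[pos, (b - 1L) * 2L + 1L],
    rev = pc$counts[pos, (b - 1L) * 2L + 2L])
}

base_totals <- function(pc, pos) {
  cc <- pc$counts[pos, ]
  setNames(cc[c(1, 3, 5, 7)] + cc[c(2, 4, 6, 8)], BASES)
}

#' Extract one evidence column from a pileup
#'
#' @param pileup A `pv_pileup`.
#' @param contig Contig id.
#' @param pos 1-based position.
#' @return A `pv_column` list: contig, pos, ref, depth, `base_counts`
#'   (4 x 2 matrix, bases x strands), `quality_sums`, `read_offsets`
#'   (offsets of non-reference observations, by base; distances to the
#'   nearer read end), `insertion_support`, `deletion_support`,
#'   `clip_support`.
#' @export
pileup_column <- function(pileup, contig, pos) {
  pc <- pileup$contigs[[contig]]
  if (is.null(pc)) stop("unknown contig: ", contig)
  cc <- pc$counts[pos, ]
  bc <- matrix(cc, nrow = 4, ncol = 2, byrow = TRUE,
               dimnames = list(BASES, c("fwd", "rev")))
  mm <- pc$mismatches[pc$mismatches$pos == pos, , drop = FALSE]
  offs <- split(mm$offset, factor(mm$base, levels = BASES))
  structure(list(contig = contig, pos = pos,
                 ref = ref_base(pileup$reference, contig, pos),
                 depth = sum(bc),
                 base_counts = bc,
                 quality_sums = setNames(pc$qsum[pos, ], BASES),
                 read_offsets = offs,
                 insertion_support = pc$ins_support[pos],
                 deletion_support = pc$del_support[pos],
                 clip_support = pc$clip_lead[pos] + pc$clip_trail[pos]),
            class = "pv_column")
}

#' Construct a pileup column directly from counts (fixture helper)
#'
#' @param ref Reference base.
#' @param counts Named list/vector base -> count, or 4x2 matrix.
#' @param quality Flat per-base quality used for `quality_sums`.
#' @return A `pv_column`, as from [pileup_column()].
#' @export
make_column <- function(ref, counts, quality = 30) {
  bc <- matrix(0, 4, 2, dimnames = list(BASES, c("fwd", "rev")))
  if (is.matrix(counts)) bc[rownames(counts), colnames(counts)] <- counts
  else for (b in names(counts)) { bc[b, "fwd"] <- ceiling(counts[[b]] / 2)
                                  bc[b, "rev"] <- floor(counts[[b]] / 2) }
  structure(list(contig = "contig01", pos = 1L, ref = ref, depth = sum(bc),
                 base_counts = bc,
                 quality_sums = setNames(rowSums(bc) * quality, BASES),
                 read_offsets = setNames(vector("list", 4), BASES),
                 insertion_support = 0L, deletion_support = 0L,
                 clip_support = 0L),
            class = "pv_column")
}

#' Export covered pileup columns as a TSV-ready data frame
#'
#' @param pileup A `pv_pileup`.
#' @param contig Contig id (default: first).
#' @param min_depth Only emit sites with at least this depth.
#' @return Data frame of per-site counts and support.
#' @export
pileup_table <- function(pileup, contig = names(pileup$contigs)[1],
                         min_depth = 1L) {
  pc <- pileup$contigs[[contig]]
  dp <- pileup_depth(pc)
  keep <- which(dp >= min_depth)
  cn <- as.vector(t(outer(BASES, c("fwd", "rev"), paste, sep = "_")))
  out <- data.frame(contig = contig, pos = keep, depth = dp[keep])
  cnt <- pc$counts[keep, , drop = FALSE]
  colnames(cnt) <- cn
  cbind(out, cnt,
        ins_support = pc$ins_support[keep],
        del_support = pc$del_support[keep],
        clip_support = pc$clip_lead[keep] + pc$clip_trail[keep])
}

#' Insert-size statistics and discordant read pairs
#'
#' Proper pairs (both mates mapped to the same contig in forward/reverse
#' orientation) define the insert-size distribution; a pair is discordant
#' when its orientation is anomalous or its implied insert falls outside
#' median +/- 4 * MAD.
#'
#' @param alignments A `pv_readset`, alignment data frame, or SAM/BAM path.
#' @param envelope_mads Half-width of the concordance envelope in MADs.
#' @return A `pv_pairstats` list: `median_insert`, `insert_mad`,
#'   `discordant` (contig, left_pos, right_pos, orientation, implied_size).
#' @export
collect_pair_stats <- function(alignments, envelope_mads = 4) {
  aln <- as_alignment_table(alignments)
  aln <- aln[!aln$unmapped, , drop = FALSE]
  mate <- mate_index(aln$qname, aln$read1)
  i <- which(aln$read1 & mate > 0L)
  j <- mate[i]
  same <- aln$contig[i] == aln$contig[j]
  i <- i[same]; j <- j[same]
  if (length(i) == 0L) stop("no mapped read pairs on a shared contig")
  end_i <- aln$pos[i] + cigar_ref_len(aln$cigar[i]) - 1L
  end_j <- aln$pos[j] + cigar_ref_len(aln$cigar[j]) - 1L
  left_first <- aln$pos[i] <= aln$pos[j]
  lp <- ifelse(left_first, aln$pos[i], aln$pos[j])
  le <- ifelse(left_first, end_i, end_j)
  rp <- ifelse(left_first, aln$pos[j], aln$pos[i])
  re <- ifelse(left_first, end_j, end_i)
  ls <- ifelse(left_first, aln$strand[i], aln$strand[j])
  rs <- ifelse(left_first, aln$strand[j], aln$strand[i])
  insert <- re - lp + 1L
  fr <- ls == "+" & rs == "-"
  orientation <- ifelse(fr, "FR", ifelse(ls == rs, "same_strand", "RF"))
  if (!any(fr)) stop("no proper (FR) pairs found")
  med <- median(insert[fr])
  md <- mad(insert[fr])
  size_out <- abs(insert - med) > envelope_mads * md
  disc <- which(!fr | size_out)
  structure(list(
    median_insert = med, insert_mad = md,
    n_pairs = length(i), envelope_mads = envelope_mads,
    discordant = data.frame(contig = aln$contig[i][disc],
                            left_pos = le[disc], right_pos = rp[disc],
                            orientation = orientation[disc],
                            implied_size = insert[disc] - med,
                            stringsAsFactors = FALSE)),
    class = "pv_pairstats")
}

#' @export
print.pv_pairstats <- function(x, ...) {
  cat("<pv_pairstats> median insert ", x$median_insert, " (MAD ",
      round(x$insert_mad, 1), "), ", nrow(x$discordant),
      " discordant pair(s) of ", x$n_pairs, "\n", sep = "")
  invisible(x)
}
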