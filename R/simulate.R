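#' Simulation configuration
#'
#' Defaults mirror the emulated pooled-resequencing design:
#' ~230 bp fragments (sd 20), 100 bp paired-end reads, 285-fold mean
#' coverage, and a per-base substitution error of 0.001 (Q30).
#'
#' @param depth Mean per-site fold coverage.
#' @param read_length Read length in bp.
#' @param mean_fragment,fragment_sd Fragment length distribution (Normal,
#'   truncated below at `read_length`).
#' @param per_base_error Per-base substitution error probability.
#' @param seed Integer RNG seed.
#' @param artifact_spec List of artifact descriptors (see
#'   [inject_artifacts()]).
#' @return A `pv_simconfig` list.
#' @export
simulation_config <- function(depth = 285, read_length = 100L,
                              mean_fragment = 230, fragment_sd = 20,
                              per_base_error = 0.001, seed = 1L,
                              artifact_spec = list()) {
  if (depth <= 0) stop("depth must be positive")
  if (read_length > mean_fragment) stop("read_length must be <= mean_fragment")
  if (per_base_error < 0 || per_base_error >= 0.5)
    stop("per_base_error must be in [0, 0.5)")
  structure(list(depth = depth, read_length = as.integer(read_length),
                 mean_fragment = mean_fragment, fragment_sd = fragment_sd,
                 per_base_error = per_base_error, seed = as.integer(seed),
                 artifact_spec = artifact_spec),
            class = "pv_simconfig")
}

BASES <- c("A", "C", "G", "T")

flat_qual_char <- function(e) {
  q <- if (e > 0) as.integer(round(-10 * log10(e))) else 40L
  rawToChar(as.raw(min(q, 41L) + 33L))
}

reverse_chars <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

# Vectorized haplotype->reference mapping for read intervals.
map_reads_to_ref <- function(elements, s, e) {
  n <- length(s)
  pos <- rep(NA_integer_, n)
  cigar <- rep("*", n)
  mapped <- rep(FALSE, n)
  if (n == 0L) return(data.frame(pos = pos, cigar = cigar, mapped = mapped))
  idx <- findInterval(s, elements$hap_start)
  fast <- idx >= 1L & elements$type[idx] == "M" & e <= elements$hap_end[idx] &
    s >= elements$hap_start[idx]
  if (any(fast)) {
    i <- which(fast)
    pos[i] <- elements$ref_start[idx[i]] + (s[i] - elements$hap_start[idx[i]])
    cigar[i] <- paste0(e[i] - s[i] + 1L, "M")
    mapped[i] <- TRUE
  }
  for (i in which(!fast)) {
    r <- hap_interval_to_ref(elements, s[i], e[i])
    pos[i] <- r$pos; cigar[i] <- r$cigar; mapped[i] <- r$mapped
  }
  data.frame(pos = pos, cigar = cigar, mapped = mapped)
}

inject_errors <- function(seqs, rl, e) {
  if (e <= 0 || length(seqs) == 0L) return(seqs)
  nerr <- rbinom(length(seqs), rl, e)
  one <- which(nerr == 1L)
  if (length(one)) {
    p <- sample.int(rl, length(one), replace = TRUE)
    ob <- substring(seqs[one], p, p)
    oi <- match(ob, BASES)
    ni <- ((oi - 1L + sample.int(3L, length(one), replace = TRUE)) %% 4L) + 1L
    substring(seqs[one], p, p) <- BASES[ni]
  }
  for (i in which(nerr >= 2L)) {
    ps <- sample.int(rl, nerr[i])
    for (p in ps) {
      oi <- match(substr(seqs[i], p, p), BASES)
      ni <- ((oi - 1L + sample.int(3L, 1L)) %% 4L) + 1L
      substr(seqs[i], p, p) <- BASES[ni]
    }
  }
  seqs
}

#' Simulate pooled paired-end reads from a haplotype pool
#'
#' Fragments are drawn uniformly across haplotypes (equal lineage
#' abundance) and along each haplotype, so a variant carried by k of n
#' haplotypes is observed in reads at expectation k/n. Read SEQ fields are
#' stored in SAM (reference-forward) orientation; the truth alignment
#' records the error-free origin of every read through variant liftover.
#' Reads crossing a junction of an indel >= 50 bp are soft-clipped there,
#' as a gapped short-read aligner would render them.
#'
#' @param pool A `pv_pool` (see [build_pool()]).
#' @param config A `pv_simconfig` (see [simulation_config()]).
#' @return A `pv_readset`: list with `alignments` (truth alignment table),
#'   `truth` (planted variant table), `reference`, `config`, `n_fragments`.
#' @export
simulate_reads <- function(pool, config = simulation_config()) {
  stopifnot(inherits(pool, "pv_pool"), inherits(config, "pv_simconfig"))
  set.seed(config$seed)
  rl <- config$read_length
  haps <- haplotype_sequences(pool)
  recs <- list()
  n_frag_total <- 0L
  for (ctg in names(pool$reference$seq)) {
    L <- nchar(pool$reference$seq[[ctg]])
    hh <- haps[[ctg]]
    hl <- vapply(hh, function(x) nchar(x$seq), integer(1))
    n_frag <- as.integer(round(config$depth * L / (2 * rl)))
    if (n_frag == 0L) next
    hap <- sample.int(pool$n_haplotypes, n_frag, replace = TRUE)
    fl <- as.integer(round(rnorm(n_frag, config$mean_fragment, config$fragment_sd)))
    fl <- pmin(pmax(fl, rl), hl[hap])
    start <- 1L + as.integer(floor(runif(n_frag) * (hl[hap] - fl + 1L)))
    end <- start + fl - 1L
    r1seq <- r2seq <- character(n_frag)
    m1 <- data.frame(pos = rep(NA_integer_, n_frag), cigar = "*", mapped = FALSE)
    m2 <- m1
    for (h in unique(hap)) {
      i <- which(hap == h)
      r1seq[i] <- substring(hh[[h]]$seq, start[i], start[i] + rl - 1L)
      r2seq[i] <- substring(hh[[h]]$seq, end[i] - rl + 1L, end[i])
      m1[i, ] <- map_reads_to_ref(hh[[h]]$elements, start[i], start[i] + rl - 1L)
      m2[i, ] <- map_reads_to_ref(hh[[h]]$elements, end[i] - rl + 1L, end[i])
    }
    qname <- sprintf("%s_f%07d", ctg, n_frag_total + seq_len(n_frag))
    n_frag_total <- n_frag_total + n_frag
    r1 <- data.frame(qname = qname, read1 = TRUE, contig = ctg,
                     pos = m1$pos, strand = "+", mapq = 60L, cigar = m1$cigar,
                     seq = r1seq, qual = NA_character_,
                     unmapped = !m1$mapped, stringsAsFactors = FALSE)
    r2 <- data.frame(qname = qname, read1 = FALSE, contig = ctg,
                     pos = m2$pos, strand = "-", mapq = 60L, cigar = m2$cigar,
                     seq = r2seq, qual = NA_character_,
                     unmapped = !m2$mapped, stringsAsFactors = FALSE)
    recs[[ctg]] <- rbind(r1, r2)
  }
  aln <- do.call(rbind, recs)
  rownames(aln) <- NULL
  aln$seq <- inject_errors(aln$seq, rl, config$per_base_error)
  aln$qual <- strrep(flat_qual_char(config$per_base_error), rl)
  rs <- structure(list(alignments = aln, reference = pool$reference,
                       truth = pool_truth(pool), config = config,
                       n_fragments = n_frag_total, artifacts = NULL),
                  class = "pv_readset")
  if (length(config$artifact_spec))
    rs <- inject_artifacts(rs, config$artifact_spec, seed = config$seed + 1L)
  rs
}

#' @export
print.pv_readset <- function(x, ...) {
  cat("<pv_readset> ", x$n_fragments, " fragments (",
      nrow(x$alignments), " reads), ", nrow(x$truth),
      " planted variant(s)\n", sep = "")
  invisible(x)
}

# mate index (row of the other read of the pair), -1 when absent
mate_index <- function(qname, read1) {
  key_self <- paste0(qname, ifelse(read1, "1", "2"))
  key_mate <- paste0(qname, ifelse(read1, "2", "1"))
  m <- match(key_mate, key_self)
  ifelse(is.na(m), -1L, m)
}

#' Inject sequencing-artifact classes into a simulated read set
#'
#' Two artifact classes that the false-positive filters are built to catch:
#' `strand_biased_cluster` plants G/C mismatches on forward-strand reads
#' only, at >= 3 sites within `width` bp of `position` (a sequence-specific
#' error look-alike); `read_end_only` plants a mismatch at `position` only
#' in reads where that site falls within `width` bp of a read end (an
#' alignment-problem look-alike).
#'
#' @param readset A `pv_readset`.
#' @param artifact_spec List of descriptors, each a list with `kind`
#'   (`"strand_biased_cluster"` or `"read_end_only"`), `contig`,
#'   `position`, `width` (default 10), `intensity` (default 1.0, the
#'   per-eligible-read planting probability).
#' @param seed Integer RNG seed.
#' @return The modified readset; `$artifacts` holds the site-level truth
#'   table (kind, contig, site, n_planted, realized). Artifact positions
#'   covered by no eligible read are recorded as unrealized, with a warning.
#' @export
inject_artifacts <- function(readset, artifact_spec, seed = 1L) {
  stopifnot(inherits(readset, "pv_readset"))
  if (length(artifact_spec) == 0L) return(readset)
  set.seed(as.integer(seed))
  aln <- readset$alignments
  rl <- readset$config$read_length
  simple <- !aln$unmapped & grepl("^[0-9]+M$", aln$cigar)
  art <- list()
  for (ai in seq_along(artifact_spec)) {
    a <- artifact_spec[[ai]]
    kind <- match.arg(a$kind, c("strand_biased_cluster", "read_end_only"))
    width <- if (is.null(a$width)) 10L else as.integer(a$width)
    intensity <- if (is.null(a$intensity)) 1.0 else a$intensity
    if (kind == "strand_biased_cluster") {
      sites <- unique(as.integer(round(seq(a$position, a$position + width - 1L,
                                           length.out = max(3L, min(width, 4L))))))
      for (s in sites) {
        rb <- ref_base(readset$reference, a$contig, s)
        alt <- if (rb == "G") "C" else "G"
        elig <- which(simple & aln$contig == a$contig & aln$strand == "+" &
                        aln$pos <= s & aln$pos + rl - 1L >= s)
        hit <- elig[runif(length(elig)) < intensity]
        if (length(hit)) {
          off <- s - aln$pos[hit] + 1L
          substring(aln$seq[hit], off, off) <- alt
        } else if (length(elig) == 0L) {
          warning("artifact site ", a$contig, ":", s, " covered by no read")
        }
        art[[length(art) + 1L]] <- data.frame(
          kind = kind, contig = a$contig, site = s,
          n_planted = length(hit), realized = length(hit) > 0L)
      }
    } else {
      s <- as.integer(a$position)
      rb <- ref_base(readset$reference, a$contig, s)
      alt <- chartr("ACGT", "GTAC", rb)
      qpos <- s - aln$pos + 1L
      offs <- pmin(qpos - 1L, rl - qpos)
      elig <- which(simple & aln$contig == a$contig &
                      qpos >= 1L & qpos <= rl & offs < width)
      hit <- elig[runif(length(elig)) < intensity]
      if (length(hit)) {
        substring(aln$seq[hit], qpos[hit], qpos[hit]) <- alt
      } else if (length(elig) == 0L) {
        warning("artifact site ", a$contig, ":", s, " covered by no eligible read")
      }
      art[[length(art) + 1L]] <- data.frame(
        kind = kind, contig = a$contig, site = s,
        n_planted = length(hit), realized = length(hit) > 0L)
    }
  }
  readset$alignments <- aln
  readset$artifacts <- rbind(readset$artifacts, do.call(rbind, art))
  readset
}

#' Write simulated reads as paired FASTQ
#'
#' Reads are emitted as sequenced: minus-strand SEQ fields are
#' reverse-complemented back and qualities reversed.
#'
#' @param readset A `pv_readset`.
#' @param r1_path,r2_path Output paths for the two mates.
#' @return Invisible character vector of the two paths.
#' @export
write_fastq <- function(readset, r1_path, r2_path) {
  aln <- readset$alignments
  emit <- function(df, path, tag) {
    seq <- df$seq; qual <- df$qual
    neg <- which(df$strand == "-")
    if (length(neg)) {
      seq[neg] <- revcomp_cpp(seq[neg])
      qual[neg] <- reverse_chars(qual[neg])
    }
    writeLines(paste0("@", df$qname, "/", tag, "\n", seq, "\n+\n", qual), path)
  }
  emit(aln[aln$read1, , drop = FALSE], r1_path, "1")
  emit(aln[!aln$read1, , drop = FALSE], r2_path, "2")
  invisible(c(r1_path, r2_path))
}

#' Write the truth alignment as a coordinate-sorted SAM file
#'
#' @param readset A `pv_readset`.
#' @param path Output path (`.sam`).
#' @return `path`, invisibly.
#' @export
write_sam <- function(readset, path) {
  aln <- readset$alignments
  mate <- mate_index(aln$qname, aln$read1)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(readset$reference$seq),
                   nchar(readset$reference$seq)))
  flag <- 1L + 4L * aln$unmapped + 16L * (aln$strand == "-") +
    64L * aln$read1 + 128L * !aln$read1
  ok <- mate > 0L
  flag[ok] <- flag[ok] + 32L * (aln$strand[mate[ok]] == "-") +
    8L * aln$unmapped[mate[ok]]
  rname <- ifelse(aln$unmapped, "*", aln$contig)
  pos <- ifelse(aln$unmapped, 0L, aln$pos)
  cig <- ifelse(aln$unmapped, "*", aln$cigar)
  rnext <- ifelse(ok & !aln$unmapped[pmax(mate, 1L)], "=", "*")
  pnext <- ifelse(ok, ifelse(aln$unmapped[pmax(mate, 1L)], 0L,
                             aln$pos[pmax(mate, 1L)]), 0L)
  pnext[is.na(pnext)] <- 0L
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t0\t%s\t%s",
                   aln$qname, flag, rname, pos, aln$mapq, cig,
                   rnext, pnext, aln$seq, aln$qual)
  ord <- order(aln$unmapped, aln$contig, pos)
  writeLines(c(hdr, lines[ord]), path)
  invisible(path)
}

#' Write the planted-variant truth table as TSV
#' @param readset A `pv_readset` (or a `pv_pool`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(readset, path) {
  tr <- if (inherits(readset, "pv_pool")) pool_truth(readset) else readset$truth
  write.table(tr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
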