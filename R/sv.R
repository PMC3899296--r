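#' Cluster discordant read pairs into structural-variant candidates
#'
#' Discordant pairs are grouped when their left and right anchors each
#' fall within `median_insert` bp of the cluster and they share an
#' orientation class. Clusters with fewer than `min_pairs` supporting
#' pairs are dropped (discordant-pair callers are false-positive prone in
#' this depth/read-length regime). Kind is assigned from orientation and
#' the sign of the implied size: FR pairs with oversized inserts imply a
#' deletion, undersized an insertion; same-strand pairs are
#' inversion-like.
#'
#' @param pair_stats A `pv_pairstats` (see [collect_pair_stats()]).
#' @param min_pairs Minimum supporting pairs per candidate.
#' @return A `pv_svcalls` data frame: contig, left_breakpoint,
#'   right_breakpoint, kind, pair_support, clip_support, implied_size,
#'   refined.
#' @export
cluster_discordant <- function(pair_stats, min_pairs = 4L) {
  empty <- data.frame(contig = character(), left_breakpoint = integer(),
                      right_breakpoint = integer(), kind = character(),
                      pair_support = integer(), clip_support = integer(),
                      implied_size = numeric(), refined = logical(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("pv_svcalls", "data.frame")
  d <- pair_stats$discordant
  if (nrow(d) == 0L) return(empty)
  gap <- pair_stats$median_insert
  # pairs cluster within a discordance class: orientation plus the sign of
  # the implied size (oversized vs undersized inserts are different events)
  d$class <- paste(d$orientation, sign(d$implied_size))
  d <- d[order(d$contig, d$class, d$left_pos), , drop = FALSE]
  cl <- integer(nrow(d))
  cur <- 1L
  cl[1] <- 1L
  last_left <- d$left_pos[1]
  rmin <- rmax <- d$right_pos[1]
  for (i in seq_len(nrow(d))[-1]) {
    same <- d$contig[i] == d$contig[i - 1] &&
      d$class[i] == d$class[i - 1] &&
      d$left_pos[i] - last_left <= gap &&
      d$right_pos[i] >= rmin - gap && d$right_pos[i] <= rmax + gap
    if (!same) {
      cur <- cur + 1L
      rmin <- rmax <- d$right_pos[i]
    } else {
      rmin <- min(rmin, d$right_pos[i])
      rmax <- max(rmax, d$right_pos[i])
    }
    last_left <- d$left_pos[i]
    cl[i] <- cur
  }
  out <- do.call(rbind, lapply(split(d, cl), function(g) {
    if (nrow(g) < min_pairs) return(NULL)
    lb <- max(g$left_pos) + 1L
    rb <- min(g$right_pos) - 1L
    if (rb < lb) { mid <- as.integer(round((lb + rb) / 2)); lb <- rb <- mid }
    sz <- median(g$implied_size)
    kind <- if (g$orientation[1] == "same_strand") "inversion_like"
      else if (g$orientation[1] != "FR") "unclassified"
      else if (sz > 0) "deletion" else if (sz < 0) "insertion"
      else "unclassified"
    data.frame(contig = g$contig[1], left_breakpoint = lb,
               right_breakpoint = rb, kind = kind,
               pair_support = nrow(g), clip_support = 0L,
               implied_size = abs(sz), refined = FALSE,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  class(out) <- c("pv_svcalls", "data.frame")
  out
}

# modal value, ties to the smallest
modal_min <- function(x) {
  t <- table(x)
  as.integer(names(t)[which(t == max(t))[1]])
}

#' Refine candidate breakpoints from soft-clip consensus
#'
#' A stand-in for manual breakpoint inspection: if at least `min_clips`
#' soft-clipped reads share a clip coordinate within `window` bp of a
#' candidate breakpoint, the breakpoint snaps to the modal clip position
#' (ties to the leftmost) and the candidate is marked refined. The left
#' breakpoint is refined from trailing clips, the right from leading
#' clips.
#'
#' @param candidates A `pv_svcalls` data frame.
#' @param pileup A `pv_pileup` carrying per-site clip counts.
#' @param window Search half-width in bp (use the median insert size).
#' @param min_clips Minimum reads sharing a clip coordinate.
#' @return `candidates` with refined breakpoints, `clip_support` and
#'   `refined` updated.
#' @export
refine_breakpoints <- function(candidates, pileup, window = 230L,
                               min_clips = 2L) {
  for (i in seq_len(nrow(candidates))) {
    pc <- pileup$contigs[[candidates$contig[i]]]
    if (is.null(pc)) next
    L <- nrow(pc$counts)
    clip_n <- 0L
    snapped <- FALSE
    lo <- max(1L, candidates$left_breakpoint[i] - window)
    hi <- min(L, candidates$left_breakpoint[i] + window)
    ct <- pc$clip_trail[lo:hi]
    cand <- lo:hi
    best <- cand[ct == max(ct)][1]
    if (max(ct) >= min_clips) {
      candidates$left_breakpoint[i] <- best
      clip_n <- clip_n + max(ct)
      snapped <- TRUE
    }
    lo <- max(1L, candidates$right_breakpoint[i] - window)
    hi <- min(L, candidates$right_breakpoint[i] + window)
    cls <- pc$clip_lead[lo:hi]
    cand <- lo:hi
    best <- cand[cls == max(cls)][1]
    if (max(cls) >= min_clips) {
      candidates$right_breakpoint[i] <- best - 1L
      clip_n <- clip_n + max(cls)
      snapped <- TRUE
    }
    if (snapped) {
      candidates$clip_support[i] <- clip_n
      candidates$refined[i] <- TRUE
      if (candidates$kind[i] == "deletion")
        candidates$implied_size[i] <-
          candidates$right_breakpoint[i] - candidates$left_breakpoint[i] + 1L
    }
  }
  candidates
}

#' Discordant-pair structural-variant evidence, end to end
#'
#' @param alignments A `pv_readset`, alignment table, or SAM/BAM path.
#' @param pileup Matching `pv_pileup` (for clip refinement); may be `NULL`
#'   to skip refinement.
#' @param min_pairs Minimum supporting pairs per candidate.
#' @return A `pv_svcalls` data frame.
#' @export
find_svs <- function(alignments, pileup = NULL, min_pairs = 4L) {
  ps <- collect_pair_stats(alignments)
  cand <- cluster_discordant(ps, min_pairs = min_pairs)
  if (!is.null(pileup) && nrow(cand))
    cand <- refine_breakpoints(cand, pileup,
                               window = as.integer(ps$median_insert))
  cand
}

#' Write SV candidates as BEDPE
#'
#' @param candidates A `pv_svcalls` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(candidates, path) {
  if (nrow(candidates) == 0L) { writeLines(character(0), path); return(invisible(path)) }
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s\t%d\t.\t.\t%s",
                   candidates$contig, candidates$left_breakpoint - 1L,
                   candidates$left_breakpoint, candidates$contig,
                   candidates$right_breakpoint - 1L, candidates$right_breakpoint,
                   candidates$kind, candidates$pair_support,
                   ifelse(candidates$refined, "refined", "unrefined"))
  writeLines(lines, path)
  invisible(path)
}
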