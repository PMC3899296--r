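#' Planted variant table constructors
#'
#' Variants use VCF-style anchored alleles: a SNP is `ref`/`alt` single
#' bases at `pos`; an insertion has `ref` = anchor base at `pos` and
#' `alt` = anchor + inserted sequence; a deletion has `ref` = anchor +
#' deleted bases and `alt` = anchor base. Coordinates are 1-based.
#'
#' @param contig Contig id.
#' @param pos 1-based position (anchor base for indels).
#' @param ref,alt Reference and alternate alleles.
#' @param kind One of `"snp"`, `"insertion"`, `"deletion"`, `"large_insertion"`.
#' @param freq Requested population frequency in (0, 1].
#' @return A one-row data frame; rows from several calls can be `rbind`-ed.
#' @export
planted_variant <- function(contig, pos, kind, ref, alt, freq) {
  kind <- match.arg(kind, c("snp", "insertion", "deletion", "large_insertion"))
  if (any(freq <= 0) || any(freq > 1)) stop("true_frequency must be in (0, 1]")
  data.frame(contig = contig, pos = as.integer(pos), kind = kind,
             ref = toupper(ref), alt = toupper(alt), true_freq = freq,
             stringsAsFactors = FALSE)
}

#' @rdname planted_variant
#' @export
plant_snp <- function(contig, pos, alt, freq, ref = NA_character_) {
  planted_variant(contig, pos, "snp", ref, alt, freq)
}

#' @rdname planted_variant
#' @param seq Inserted sequence (insertions) .
#' @export
plant_insertion <- function(contig, pos, seq, freq) {
  kind <- if (nchar(seq) >= 50) "large_insertion" else "insertion"
  planted_variant(contig, pos, kind, NA_character_,
                  paste0(NA_character_, seq), freq)
}

#' @rdname planted_variant
#' @param del_len Number of deleted bases (deletions).
#' @export
plant_deletion <- function(contig, pos, del_len, freq) {
  planted_variant(contig, pos, "deletion",
                  strrep("N", del_len + 1L), NA_character_, freq)
}

# Reference footprint of each variant (closed interval on the reference).
variant_footprint <- function(variants) {
  len <- ifelse(variants$kind == "deletion", nchar(variants$ref), 1L)
  data.frame(start = variants$pos, end = variants$pos + len - 1L)
}

# Fill NA ref/alt fields from the reference (plant_* convenience forms).
resolve_alleles <- function(variants, reference) {
  for (i in seq_len(nrow(variants))) {
    ctg <- variants$contig[i]; p <- variants$pos[i]
    anchor <- ref_base(reference, ctg, p)
    if (variants$kind[i] == "snp") {
      if (is.na(variants$ref[i])) variants$ref[i] <- anchor
    } else if (variants$kind[i] %in% c("insertion", "large_insertion")) {
      if (grepl("^NA", variants$alt[i]))
        variants$alt[i] <- paste0(anchor, sub("^NA", "", variants$alt[i]))
      if (is.na(variants$ref[i])) variants$ref[i] <- anchor
    } else if (variants$kind[i] == "deletion") {
      if (grepl("^N+$", variants$ref[i]))
        variants$ref[i] <- ref_base(reference, ctg, p, nchar(variants$ref[i]))
      if (is.na(variants$alt[i])) variants$alt[i] <- anchor
    }
  }
  variants
}

resample <- function(x, k) x[sample.int(length(x), k)]

#' Build a discrete haplotype pool carrying planted variants
#'
#' Each variant is assigned to `round(true_freq * n_haplotypes)` carrier
#' haplotypes (nearest representable fraction, ties rounded down), chosen
#' pseudo-randomly while avoiding two overlapping variants on the same
#' haplotype. The realized frequency `carriers / n_haplotypes` is the truth
#' the estimator is scored against; a requested frequency that rounds to
#' zero carriers is recorded as unrealized.
#'
#' @param reference A `pv_reference`.
#' @param n_haplotypes Number of distinct lineages in the pool.
#' @param variants Planted variant table (see [planted_variant()]).
#' @param seed Integer RNG seed.
#' @return A `pv_pool`: reference, `n_haplotypes`, and the variant table
#'   with `carriers` (list column) and `realized_freq` added.
#' @export
build_pool <- function(reference, n_haplotypes, variants = NULL, seed = 1L) {
  n_haplotypes <- as.integer(n_haplotypes)
  if (n_haplotypes <= 0L) stop("n_haplotypes must be positive")
  if (is.null(variants))
    variants <- data.frame(contig = character(), pos = integer(),
                           kind = character(), ref = character(),
                           alt = character(), true_freq = numeric(),
                           stringsAsFactors = FALSE)
  if (any(variants$true_freq > 1)) stop("true_frequency must be <= 1")
  variants <- resolve_alleles(variants, reference)
  lens <- contig_lengths(reference)
  fp <- variant_footprint(variants)
  for (i in seq_len(nrow(variants))) {
    ctg <- variants$contig[i]
    if (!ctg %in% names(lens)) stop("unknown contig: ", ctg)
    if (variants$pos[i] < 1L || fp$end[i] > lens[[ctg]])
      stop("variant span outside contig at row ", i)
    obs <- ref_base(reference, ctg, variants$pos[i], nchar(variants$ref[i]))
    if (obs != variants$ref[i])
      stop("ref allele mismatch at ", ctg, ":", variants$pos[i],
           " (reference has ", obs, ", variant says ", variants$ref[i], ")")
    if (variants$kind[i] == "snp" && variants$alt[i] == variants$ref[i])
      stop("snp alt equals reference base at ", ctg, ":", variants$pos[i])
  }
  set.seed(as.integer(seed))
  n_var <- nrow(variants)
  carriers <- vector("list", n_var)
  # haplotype -> footprints already assigned (per contig), for conflict checks
  taken <- lapply(seq_len(n_haplotypes), function(i) NULL)
  ord <- order(variants$contig, variants$pos)
  for (i in ord) {
    k <- as.integer(ceiling(variants$true_freq[i] * n_haplotypes - 0.5))
    if (k == 0L) { carriers[[i]] <- integer(0); next }
    eligible <- which(vapply(taken, function(tk) {
      if (is.null(tk)) return(TRUE)
      !any(tk$contig == variants$contig[i] &
             tk$start <= fp$end[i] & tk$end >= fp$start[i])
    }, logical(1)))
    if (length(eligible) < k)
      stop("overlapping variants conflict: cannot place variant at ",
           variants$contig[i], ":", variants$pos[i], " on ", k, " haplotypes")
    hs <- sort(resample(eligible, k))
    carriers[[i]] <- hs
    for (h in hs)
      taken[[h]] <- rbind(taken[[h]],
                          data.frame(contig = variants$contig[i],
                                     start = fp$start[i], end = fp$end[i]))
  }
  variants$carriers <- carriers
  variants$realized_freq <- vapply(carriers, length, integer(1)) / n_haplotypes
  structure(list(reference = reference, n_haplotypes = n_haplotypes,
                 variants = variants, seed = as.integer(seed)),
            class = "pv_pool")
}

#' @export
print.pv_pool <- function(x, ...) {
  cat("<pv_pool> ", x$n_haplotypes, " haplotypes, ",
      nrow(x$variants), " planted variant(s)\n", sep = "")
  invisible(x)
}

#' Truth table of a haplotype pool
#'
#' @param pool A `pv_pool`.
#' @return Data frame with contig, pos, kind, ref, alt, true_freq,
#'   realized_freq (the simulation truth downstream stages are scored on).
#' @export
pool_truth <- function(pool) {
  v <- pool$variants
  data.frame(contig = v$contig, pos = v$pos, kind = v$kind, ref = v$ref,
             alt = v$alt, true_freq = v$true_freq,
             realized_freq = v$realized_freq, stringsAsFactors = FALSE)
}

# --- haplotype sequence construction and coordinate liftover -------------

# For one haplotype on one contig, splice indels and substitute SNPs,
# returning the haplotype sequence plus an element table mapping haplotype
# coordinates back to the reference:
#   type "M": matched block (hap_start..hap_end <-> ref_start..)
#   type "I": inserted segment (no reference span)
# Deletions appear as gaps between consecutive M elements.
build_haplotype <- function(refseq, vars) {
  if (nrow(vars) == 0L) {
    L <- nchar(refseq)
    return(list(seq = refseq,
                elements = data.frame(type = "M", hap_start = 1L, hap_end = L,
                                      ref_start = 1L, stringsAsFactors = FALSE)))
  }
  vars <- vars[order(vars$pos), , drop = FALSE]
  indels <- vars[vars$kind != "snp", , drop = FALSE]
  L <- nchar(refseq)
  pieces <- character(0)
  el <- list()
  ref_i <- 1L; hap_i <- 1L
  add_m <- function(from, to) {
    if (to < from) return(invisible())
    pieces[[length(pieces) + 1L]] <<- substr(refseq, from, to)
    el[[length(el) + 1L]] <<- data.frame(type = "M", hap_start = hap_i,
                                         hap_end = hap_i + (to - from),
                                         ref_start = from)
    hap_i <<- hap_i + (to - from + 1L)
  }
  for (i in seq_len(nrow(indels))) {
    v <- indels[i, ]
    if (v$kind %in% c("insertion", "large_insertion")) {
      add_m(ref_i, v$pos)                      # through the anchor base
      ins <- substr(v$alt, 2L, nchar(v$alt))
      pieces[[length(pieces) + 1L]] <- ins
      el[[length(el) + 1L]] <- data.frame(type = "I", hap_start = hap_i,
                                          hap_end = hap_i + nchar(ins) - 1L,
                                          ref_start = NA_integer_)
      hap_i <- hap_i + nchar(ins)
      ref_i <- v$pos + 1L
    } else {                                   # deletion: span pos+1 .. pos+len
      d1 <- v$pos + 1L; d2 <- v$pos + nchar(v$ref) - 1L
      add_m(ref_i, d1 - 1L)
      ref_i <- d2 + 1L
    }
  }
  add_m(ref_i, L)
  seq <- paste(pieces, collapse = "")
  elements <- do.call(rbind, el)
  # SNP substitution through the map (offsets unchanged by SNPs)
  snps <- vars[vars$kind == "snp", , drop = FALSE]
  for (i in seq_len(nrow(snps))) {
    hp <- ref_to_hap(elements, snps$pos[i])
    if (!is.na(hp)) substr(seq, hp, hp) <- snps$alt[i]
  }
  list(seq = seq, elements = elements)
}

ref_to_hap <- function(elements, ref_pos) {
  m <- elements[elements$type == "M", , drop = FALSE]
  ref_end <- m$ref_start + (m$hap_end - m$hap_start)
  i <- which(m$ref_start <= ref_pos & ref_end >= ref_pos)
  if (length(i) == 0L) return(NA_integer_)
  m$hap_start[i[1]] + (ref_pos - m$ref_start[i[1]])
}

#' Materialize haplotype sequences and liftover maps
#'
#' @param pool A `pv_pool`.
#' @return Per-contig list of per-haplotype `list(seq, elements)`.
#' @keywords internal
#' @export
haplotype_sequences <- function(pool) {
  out <- list()
  for (ctg in names(pool$reference$seq)) {
    refseq <- pool$reference$seq[[ctg]]
    v <- pool$variants[pool$variants$contig == ctg, , drop = FALSE]
    out[[ctg]] <- lapply(seq_len(pool$n_haplotypes), function(h) {
      mine <- v[vapply(v$carriers, function(cs) h %in% cs, logical(1)), ,
                drop = FALSE]
      build_haplotype(refseq, mine)
    })
  }
  out
}

# Map a haplotype interval [h1, h2] to (ref_pos, cigar, mapped) given the
# element table. Indels >= `large_min` are represented the way a gapped
# short-read aligner renders them: the read is truncated at the junction
# and the remainder soft-clipped. Reads with < `min_anchor` aligned bases
# are reported unmapped.
hap_interval_to_ref <- function(elements, h1, h2, large_min = 50L,
                                min_anchor = 20L) {
  keep <- elements$hap_end >= h1 & elements$hap_start <= h2
  ov <- elements[keep, , drop = FALSE]
  if (nrow(ov) == 0L) return(list(pos = NA_integer_, cigar = "*", mapped = FALSE))
  ops <- character(0); lens <- integer(0); refs <- integer(0)
  prev_ref_end <- NA_integer_
  for (i in seq_len(nrow(ov))) {
    e <- ov[i, ]
    a <- max(e$hap_start, h1); b <- min(e$hap_end, h2)
    if (e$type == "M") {
      rs <- e$ref_start + (a - e$hap_start)
      if (!is.na(prev_ref_end)) {
        gap <- rs - prev_ref_end - 1L
        if (gap > 0L) { ops <- c(ops, "D"); lens <- c(lens, gap); refs <- c(refs, NA) }
      }
      ops <- c(ops, "M"); lens <- c(lens, b - a + 1L); refs <- c(refs, rs)
      prev_ref_end <- rs + (b - a)
    } else {
      ops <- c(ops, "I"); lens <- c(lens, b - a + 1L); refs <- c(refs, NA)
    }
  }
  # split at large indels: keep the side with more aligned bases
  repeat {
    big <- which((ops == "D" | ops == "I") & lens >= large_min)
    if (length(big) == 0L) break
    j <- big[1]
    left_m <- sum(lens[seq_len(j - 1L)][ops[seq_len(j - 1L)] == "M"])
    right_idx <- seq.int(j + 1L, length.out = length(ops) - j)
    right_m <- sum(lens[right_idx][ops[right_idx] == "M"])
    qcons <- ops %in% c("M", "I", "S") # ops consuming query bases
    if (left_m >= right_m) {
      drop <- c(j, right_idx)
      clip_q <- sum(lens[drop][qcons[drop]])
      ops <- ops[seq_len(j - 1L)]; refs <- refs[seq_len(j - 1L)]
      lens <- lens[seq_len(j - 1L)]
      if (clip_q > 0L) { ops <- c(ops, "S"); lens <- c(lens, clip_q); refs <- c(refs, NA) }
    } else {
      drop <- seq_len(j)
      clip_q <- sum(lens[drop][qcons[drop]])
      ops <- ops[right_idx]; refs <- refs[right_idx]; lens <- lens[right_idx]
      if (clip_q > 0L) { ops <- c("S", ops); lens <- c(clip_q, lens); refs <- c(NA, refs) }
    }
  }
  # edge I ops become soft clips (elements alternate M/I so at most one each)
  if (length(ops) && ops[1] == "I") ops[1] <- "S"
  if (length(ops) && ops[length(ops)] == "I") ops[length(ops)] <- "S"
  m_total <- sum(lens[ops == "M"])
  if (!any(ops == "M"))
    return(list(pos = NA_integer_, cigar = "*", mapped = FALSE))
  if (m_total < min_anchor)
    return(list(pos = NA_integer_, cigar = "*", mapped = FALSE))
  first_m <- which(ops == "M")[1]
  list(pos = refs[first_m],
       cigar = paste0(lens, ops, collapse = ""),
       mapped = TRUE)
}
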