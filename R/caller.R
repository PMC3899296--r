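#' Pooled caller configuration
#'
#' The caller scores each site by a likelihood ratio over a discrete
#' frequency grid `{0, 1/h, ..., 1}` given by the assumed haplotype number
#' `h` of the pool (default 10). `min_frequency` (default 5%) is the
#' detection floor, enforced on the maximum-likelihood grid frequency; the
#' reported `af` stays the continuous alternate read fraction, which the
#' grid cannot represent.
#'
#' @param haplotype_number Assumed number of distinct lineages `h`.
#' @param min_frequency Minimum grid frequency reported (detection floor).
#' @param per_base_error Assumed per-base error probability `e`.
#' @param min_score Minimum log-likelihood-ratio (natural log) vs. the
#'   no-variant model.
#' @param min_alt_reads Minimum alternate-supporting reads for a SNP call.
#' @param min_indel_support_reads,min_indel_support_fraction Minimum
#'   supporting reads / support fraction for an indel call ("indels
#'   supported by only a few reads" are rejected as putative FPs).
#' @return A `pv_callerconfig` list.
#' @export
caller_config <- function(haplotype_number = 10L, min_frequency = 0.05,
                          per_base_error = 0.001, min_score = 10,
                          min_alt_reads = 5L, min_indel_support_reads = 5L,
                          min_indel_support_fraction = 0.05) {
  h <- as.integer(haplotype_number)
  if (h <= 0L) stop("haplotype_number must be positive")
  if (min_frequency <= 0 || min_frequency > 1)
    stop("min_frequency must be in (0, 1]")
  if (min_score < 0 || min_alt_reads < 0) stop("thresholds must be non-negative")
  structure(list(haplotype_number = h, min_frequency = min_frequency,
                 per_base_error = per_base_error, min_score = min_score,
                 min_alt_reads = as.integer(min_alt_reads),
                 min_indel_support_reads = as.integer(min_indel_support_reads),
                 min_indel_support_fraction = min_indel_support_fraction),
            class = "pv_callerconfig")
}

# P(alt read | f), P(ref read | f) under the pooled error model: an
# observation is alt with probability f(1-e) + (1-f) e/3.
obs_probs <- function(f, e) {
  list(alt = f * (1 - e) + (1 - f) * e / 3,
       ref = (1 - f) * (1 - e) + f * e / 3)
}

xlogp <- function(x, p) ifelse(x == 0, 0, x * log(p))

loglik_counts <- function(n_ref, n_alt, f, e) {
  p <- obs_probs(f, e)
  xlogp(n_alt, p$alt) + xlogp(n_ref, p$ref)
}

# most frequent non-ref base; ties broken by summed quality, then by
# lexicographic base order
top_alt_base <- function(column) {
  tot <- rowSums(column$base_counts)
  tot[column$ref] <- -1
  mx <- max(tot)
  if (mx <= 0) return(NULL)
  cand <- names(tot)[tot == mx]
  if (length(cand) > 1L) {
    q <- column$quality_sums[cand]
    cand <- cand[order(-q, cand)]
  }
  cand[1]
}

#' Site log-likelihood under a pooled allele frequency
#'
#' Sums, in log space, per-observation probabilities over the retained
#' bases of a pileup column: alt with probability `f(1-e) + (1-f)e/3`,
#' ref with `(1-f)(1-e) + f e/3`. Only the two most frequent bases (the
#' reference base and the leading alternate) enter; other bases are
#' treated as error noise and ignored.
#'
#' @param column A `pv_column` ([pileup_column()] / [make_column()]).
#' @param f Pool allele frequency in `[0, 1]`.
#' @param e Per-base error probability.
#' @param alt Alternate base; default: most frequent non-reference base.
#' @return Log-likelihood (natural log).
#' @export
site_loglik <- function(column, f, e = 0.001, alt = NULL) {
  if (column$depth < 1) stop("site_loglik undefined at depth 0")
  if (f < 0 || f > 1) stop("f must be in [0, 1]")
  if (is.null(alt)) alt <- top_alt_base(column)
  n_ref <- sum(column$base_counts[column$ref, ])
  n_alt <- if (is.null(alt)) 0 else sum(column$base_counts[alt, ])
  loglik_counts(n_ref, n_alt, f, e)
}

# LLR detection score over the h-grid, from ref/alt counts
grid_score <- function(n_ref, n_alt, h, e) {
  grid <- seq(0, 1, by = 1 / h)
  ll <- vapply(grid, function(f) loglik_counts(n_ref, n_alt, f, e), numeric(1))
  i <- which.max(ll)
  list(score = ll[i] - ll[1], grid_freq = grid[i])
}

nearest_grid <- function(f, h) round(f * h) / h

empty_calls <- function() {
  data.frame(contig = character(), pos = integer(), ref = character(),
             alt = character(), kind = character(), af = numeric(),
             alt_count = integer(), total_count = integer(),
             score = numeric(), grid_freq = numeric(), filter = character(),
             founder_status = character(), stringsAsFactors = FALSE)
}

#' Call a pooled SNP at a single pileup column
#'
#' A call is emitted for each alternate base that independently satisfies
#' `score >= min_score`, `alt_count >= min_alt_reads` and maximum-likelihood
#' grid frequency `>= min_frequency` (so a tri-allelic site yields one call
#' per passing alternate). The reported `af` is the raw alternate read
#' fraction; `grid_freq` is the argmax grid point.
#'
#' @param column A `pv_column`.
#' @param config A `pv_callerconfig`.
#' @return A `pv_calls` data frame with zero or more rows.
#' @export
call_snp <- function(column, config = caller_config()) {
  out <- empty_calls()
  if (column$depth < 1) return(out)
  tot <- rowSums(column$base_counts)
  n_ref <- tot[[column$ref]]
  depth <- column$depth
  for (b in setdiff(BASES, column$ref)) {
    n_alt <- tot[[b]]
    if (n_alt < config$min_alt_reads) next
    g <- grid_score(n_ref, n_alt, config$haplotype_number,
                    config$per_base_error)
    if (g$score < config$min_score) next
    if (g$grid_freq < config$min_frequency) next
    out <- rbind(out, data.frame(
      contig = column$contig, pos = column$pos, ref = column$ref, alt = b,
      kind = "snp", af = n_alt / depth, alt_count = as.integer(n_alt),
      total_count = as.integer(depth), score = g$score,
      grid_freq = g$grid_freq, filter = "", founder_status = "unknown",
      stringsAsFactors = FALSE))
  }
  if (nrow(out) > 1L) {
    q <- column$quality_sums[out$alt]
    out <- out[order(-out$alt_count, -q, out$alt), , drop = FALSE]
  }
  out
}

#' Call a small indel from pileup evidence at one event
#'
#' The frequency is the counting estimate: reads showing the indel over
#' reads showing plus not showing it. Events with fewer than
#' `min_indel_support_reads` supporting reads (or support fraction below
#' `min_indel_support_fraction`) are rejected as putative false positives.
#'
#' @param support Reads showing the indel.
#' @param non_support Reads covering the site without the indel.
#' @param config A `pv_callerconfig`.
#' @return List with `af` and `emit` (logical), or `NULL` when there is no
#'   evidence at all.
#' @export
indel_counting_rule <- function(support, non_support,
                                config = caller_config()) {
  if (support + non_support == 0) return(NULL)
  af <- support / (support + non_support)
  list(af = af,
       emit = support >= config$min_indel_support_reads &&
         af >= config$min_indel_support_fraction)
}

#' Scan a pileup and call SNPs and small indels
#'
#' @param pileup A `pv_pileup`.
#' @param config A `pv_callerconfig`.
#' @param max_indel_len Indel events longer than this are left to the
#'   structural-variant stage (default 49 bp).
#' @return A `pv_calls` data frame (class `pv_calls`), one row per emitted
#'   variant call, sorted by position.
#' @export
call_variants <- function(pileup, config = caller_config(),
                          max_indel_len = 49L) {
  stopifnot(inherits(pileup, "pv_pileup"))
  res <- list()
  for (ctg in names(pileup$contigs)) {
    pc <- pileup$contigs[[ctg]]
    refseq <- pileup$reference$seq[[ctg]]
    ri <- match(strsplit(refseq, "")[[1]], BASES)
    tot <- pc$counts[, c(1, 3, 5, 7), drop = FALSE] +
      pc$counts[, c(2, 4, 6, 8), drop = FALSE]
    depth <- rowSums(tot)
    refcnt <- tot[cbind(seq_along(ri), ri)]
    altmax <- depth - refcnt # upper bound on any alt count
    cand <- which(altmax >= config$min_alt_reads &
                    matrixStats_rowMaxs(tot, ri) >= config$min_alt_reads)
    for (p in cand) {
      col <- pileup_column(pileup, ctg, p)
      res[[length(res) + 1L]] <- call_snp(col, config)
    }
    ev <- pc$events
    ev <- ev[ev$len <= max_indel_len, , drop = FALSE]
    for (i in seq_len(nrow(ev))) {
      s <- ev$support[i]
      if (ev$type[i] == "deletion") {
        d1 <- ev$pos[i]
        non <- depth[d1]
        vcf_pos <- d1 - 1L
        if (vcf_pos < 1L) next
        ref <- substr(refseq, vcf_pos, d1 + ev$len[i] - 1L)
        alt <- substr(refseq, vcf_pos, vcf_pos)
        kind <- "deletion"
      } else {
        a <- ev$pos[i]
        non <- max(depth[a] - s, 0)
        vcf_pos <- a
        ref <- substr(refseq, a, a)
        alt <- paste0(ref, ev$seq[i])
        kind <- "insertion"
      }
      r <- indel_counting_rule(s, non, config)
      if (is.null(r) || !r$emit) next
      g <- grid_score(non, s, config$haplotype_number, config$per_base_error)
      res[[length(res) + 1L]] <- data.frame(
        contig = ctg, pos = vcf_pos, ref = ref, alt = alt, kind = kind,
        af = r$af, alt_count = as.integer(s), total_count = as.integer(s + non),
        score = g$score, grid_freq = nearest_grid(r$af, config$haplotype_number),
        filter = "", founder_status = "unknown", stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else empty_calls()
  out <- out[order(out$contig, out$pos, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pv_calls", "data.frame")
  out
}

# max over alt bases (per row) of counts, excluding the reference base
matrixStats_rowMaxs <- function(tot, ri) {
  tot[cbind(seq_along(ri), ri)] <- -1L
  do.call(pmax, as.data.frame(tot))
}

#' @export
print.pv_calls <- function(x, ...) {
  cat("<pv_calls> ", nrow(x), " call(s)\n", sep = "")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 20))
  invisible(x)
}
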