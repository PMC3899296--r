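#' False-positive filter configuration
#'
#' Quantifies the three manual rejection rules applied to putative pooled
#' SNPs: strand-biased G/C mismatch context ("sequence specific error"),
#' read-end-only support ("alignment problem"), and proximity to a large
#' indel signature. "Many", "near" and "middle" become explicit numbers
#' here because the original rules were applied by eye.
#'
#' @param context_window Neighborhood half-width in bp for the strand rule.
#' @param min_biased_sites Biased G/C-mismatch sites (call site included)
#'   required to flag.
#' @param strand_bias_alpha Significance level of the two-sided exact
#'   conditional test on strand counts.
#' @param end_zone Fraction of the read length defining the terminal zone;
#'   a base is "mid-read" when at least `end_zone * read_length` from both
#'   ends.
#' @param min_mid_read_fraction Minimum fraction of alternate observations
#'   that must be mid-read.
#' @param sv_proximity Distance (bp, closed interval) to large-indel
#'   evidence that flags a SNP.
#' @param sv_support_min Combined indel+clip support defining "large indel
#'   signature" at a site.
#' @param founder_presence_threshold Minimum founder allele frequency for
#'   a call to count as present in the founder.
#' @return A `pv_filterconfig` list.
#' @export
filter_config <- function(context_window = 10L, min_biased_sites = 3L,
                          strand_bias_alpha = 0.01, end_zone = 0.25,
                          min_mid_read_fraction = 0.1, sv_proximity = 25L,
                          sv_support_min = 5L,
                          founder_presence_threshold = 0.05) {
  stopifnot(context_window > 0, min_biased_sites > 0, sv_proximity > 0,
            sv_support_min > 0, strand_bias_alpha > 0, strand_bias_alpha < 1,
            end_zone > 0, end_zone < 1, min_mid_read_fraction > 0,
            min_mid_read_fraction < 1)
  structure(list(context_window = as.integer(context_window),
                 min_biased_sites = as.integer(min_biased_sites),
                 strand_bias_alpha = strand_bias_alpha, end_zone = end_zone,
                 min_mid_read_fraction = min_mid_read_fraction,
                 sv_proximity = as.integer(sv_proximity),
                 sv_support_min = as.integer(sv_support_min),
                 founder_presence_threshold = founder_presence_threshold),
            class = "pv_filterconfig")
}

#' Two-sided exact conditional test for strand bias
#'
#' Conditions on the per-strand depths: under the null the
#' `k = alt_fwd + alt_rev` alternate observations are a hypergeometric
#' draw from `tot_fwd` forward and `tot_rev` reverse slots. The two-sided
#' p-value sums all tables with point probability at most that observed.
#'
#' @param alt_fwd,alt_rev Alternate observations per strand.
#' @param tot_fwd,tot_rev Total retained depth per strand.
#' @return p-value.
#' @export
strand_bias_p <- function(alt_fwd, alt_rev, tot_fwd, tot_rev) {
  k <- alt_fwd + alt_rev
  if (k == 0 || tot_fwd + tot_rev == 0) return(1)
  probs <- dhyper(0:k, tot_fwd, tot_rev, k)
  obs <- probs[alt_fwd + 1]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# biased G/C mismatch sites within [lo, hi] of a contig pileup
biased_gc_sites <- function(pc, ri, lo, hi, alpha, min_obs = 2L) {
  sites <- integer(0)
  for (p in lo:hi) {
    tf <- sum(pc$counts[p, c(1, 3, 5, 7)])
    tr <- sum(pc$counts[p, c(2, 4, 6, 8)])
    for (b in c(2L, 3L)) {        # C, G
      if (!is.na(ri[p]) && b == ri[p]) next
      bf <- pc$counts[p, (b - 1L) * 2L + 1L]
      br <- pc$counts[p, (b - 1L) * 2L + 2L]
      if (bf + br < min_obs) next
      if (strand_bias_p(bf, br, tf, tr) < alpha) {
        sites <- c(sites, p)
        break
      }
    }
  }
  sites
}

#' Strand-biased mismatch context rule
#'
#' Flags a SNP call when at least `min_biased_sites` positions within
#' `context_window` bp (call site included) carry G or C mismatches whose
#' strand split fails the exact test at `strand_bias_alpha`.
#'
#' @param call One-row `pv_calls` data frame.
#' @param pileup A `pv_pileup` providing the neighborhood columns.
#' @param config A `pv_filterconfig`.
#' @return `"STRAND_CTX"`, `"insufficient_context"`, or `NA` (pass).
#' @export
flag_strand_context <- function(call, pileup, config = filter_config()) {
  pc <- pileup$contigs[[call$contig]]
  if (is.null(pc)) return("insufficient_context")
  L <- nrow(pc$counts)
  w <- config$context_window
  lo <- max(1L, call$pos - w); hi <- min(L, call$pos + w)
  ri <- match(strsplit(substr(pileup$reference$seq[[call$contig]], lo, hi),
                       "")[[1]], BASES)
  ri_full <- rep(NA_integer_, L)
  ri_full[lo:hi] <- ri
  n_biased <- length(biased_gc_sites(pc, ri_full, lo, hi,
                                     config$strand_bias_alpha))
  if (n_biased >= config$min_biased_sites) "STRAND_CTX" else NA_character_
}

#' Read-position (mid-read depletion) rule
#'
#' Flags a SNP call when fewer than `min_mid_read_fraction` of its
#' alternate observations lie at least `end_zone * read_length` bp from
#' both read ends.
#'
#' @inheritParams flag_strand_context
#' @return `"READ_POS"`, `"insufficient_context"`, or `NA` (pass).
#' @export
flag_read_position <- function(call, pileup, config = filter_config()) {
  pc <- pileup$contigs[[call$contig]]
  if (is.null(pc)) return("insufficient_context")
  mm <- pc$mismatches
  offs <- mm$offset[mm$pos == call$pos & mm$base == call$alt]
  if (length(offs) == 0L) return("insufficient_context")
  mid_min <- config$end_zone * pileup$read_length
  if (mean(offs >= mid_min) < config$min_mid_read_fraction)
    "READ_POS" else NA_character_
}

#' Large-indel proximity rule
#'
#' Flags a SNP call within `sv_proximity` bp (closed interval) of a site
#' whose combined insertion, deletion and soft-clip support reaches
#' `sv_support_min`, or of a structural-variant candidate breakpoint.
#'
#' @inheritParams flag_strand_context
#' @param sv_candidates Optional `pv_svcalls` data frame.
#' @return `"NEAR_SV"` or `NA` (pass).
#' @export
flag_near_sv <- function(call, pileup, sv_candidates = NULL,
                         config = filter_config()) {
  pc <- pileup$contigs[[call$contig]]
  if (is.null(pc)) return(NA_character_)
  L <- nrow(pc$counts)
  lo <- max(1L, call$pos - config$sv_proximity)
  hi <- min(L, call$pos + config$sv_proximity)
  sup <- pc$ins_support[lo:hi] + pc$del_support[lo:hi] +
    pc$clip_lead[lo:hi] + pc$clip_trail[lo:hi]
  if (any(sup >= config$sv_support_min)) return("NEAR_SV")
  if (!is.null(sv_candidates) && nrow(sv_candidates)) {
    bp <- sv_candidates[sv_candidates$contig == call$contig, , drop = FALSE]
    d <- c(abs(bp$left_breakpoint - call$pos),
           abs(bp$right_breakpoint - call$pos))
    if (length(d) && any(d <= config$sv_proximity)) return("NEAR_SV")
  }
  NA_character_
}

#' Mark calls present in the founder population
#'
#' Calls matching a founder call (same contig, position and alternate
#' allele, founder frequency at least `founder_presence_threshold`) get
#' `founder_status = "in_founder"`; others `"novel"`. Nothing is removed:
#' downstream reports list novel calls by default. With `founder_calls =
#' NULL` every call is marked `"unknown"`.
#'
#' @param calls A `pv_calls` data frame.
#' @param founder_calls Data frame with contig, pos, alt, af (e.g. from
#'   [read_founder_calls()]), or `NULL`.
#' @param config A `pv_filterconfig`.
#' @return `calls` with `founder_status` set.
#' @export
subtract_founder <- function(calls, founder_calls,
                             config = filter_config()) {
  if (is.null(founder_calls) || nrow(founder_calls) == 0L) {
    calls$founder_status <- rep("unknown", nrow(calls))
    return(calls)
  }
  fk <- founder_calls[founder_calls$af >= config$founder_presence_threshold, ,
                      drop = FALSE]
  key <- paste(calls$contig, calls$pos, calls$alt)
  fkey <- paste(fk$contig, fk$pos, fk$alt)
  calls$founder_status <- ifelse(key %in% fkey, "in_founder", "novel")
  calls
}

#' Apply all false-positive filters to a call set
#'
#' Filters only annotate: sites and frequencies are unchanged, and the
#' `filter` column is recomputed from scratch (idempotent). The
#' strand-context, read-position and SV-proximity rules apply to SNP
#' calls; indel calls are guarded by their own support thresholds at call
#' time.
#'
#' @param calls A `pv_calls` data frame.
#' @param pileup The `pv_pileup` the calls came from.
#' @param config A `pv_filterconfig`.
#' @param sv_candidates Optional `pv_svcalls` for breakpoint proximity.
#' @param founder_calls Optional founder call table (see
#'   [subtract_founder()]).
#' @return `calls` with `filter` set to `"PASS"` or a `;`-joined flag set.
#' @export
apply_filters <- function(calls, pileup, config = filter_config(),
                          sv_candidates = NULL, founder_calls = NULL) {
  flags <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    call <- calls[i, ]
    fl <- character(0)
    if (call$kind == "snp") {
      fl <- c(fl, flag_strand_context(call, pileup, config),
              flag_read_position(call, pileup, config),
              flag_near_sv(call, pileup, sv_candidates, config))
    }
    fl <- fl[!is.na(fl)]
    flags[i] <- if (length(fl)) paste(unique(fl), collapse = ";") else "PASS"
  }
  calls$filter <- flags
  subtract_founder(calls, founder_calls, config)
}

#' Read founder calls from TSV or VCF
#'
#' TSV needs columns contig, pos, alt, af (extra columns kept). For VCF,
#' CHROM/POS/ALT and the INFO `AF=` field are used.
#'
#' @param path File path.
#' @return Data frame with contig, pos, alt, af.
#' @export
read_founder_calls <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "##fileformat=VCF")) {
    ln <- readLines(path)
    ln <- ln[!startsWith(ln, "#")]
    if (length(ln) == 0L)
      return(data.frame(contig = character(), pos = integer(),
                        alt = character(), af = numeric()))
    fx <- strsplit(ln, "\t")
    af <- vapply(fx, function(f) {
      m <- regmatches(f[8], regexpr("(?<=^AF=|;AF=)[0-9.eE+-]+", f[8],
                                    perl = TRUE))
      if (length(m)) as.numeric(m) else NA_real_
    }, numeric(1))
    data.frame(contig = vapply(fx, `[`, "", 1),
               pos = as.integer(vapply(fx, `[`, "", 2)),
               alt = vapply(fx, `[`, "", 5),
               af = af, stringsAsFactors = FALSE)
  } else {
    df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    stopifnot(all(c("contig", "pos", "alt", "af") %in% names(df)))
    df
  }
}
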