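#' Match calls against a simulation truth table
#'
#' A call matches a truth record iff same contig, same alternate allele,
#' and position within tolerance (0 for SNPs, 5 bp for indels by
#' default); matching is one-to-one, nearest position first.
#'
#' @param calls A `pv_calls` data frame.
#' @param truth Truth table ([pool_truth()] rows, needs contig, pos, alt,
#'   kind, realized_freq).
#' @param tol_snp,tol_indel Position tolerances in bp.
#' @param pass_only Only consider calls with filter `PASS` (or unset).
#' @return List: `matched` (data frame truth_idx, call_idx, dpos,
#'   af_error = call af minus realized truth), `fp_idx` (unmatched call
#'   rows), `fn_idx` (unmatched truth rows).
#' @export
match_calls <- function(calls, truth, tol_snp = 0L, tol_indel = 5L,
                        pass_only = FALSE) {
  if (pass_only && nrow(calls))
    calls <- calls[calls$filter %in% c("PASS", ""), , drop = FALSE]
  cand <- list()
  for (ti in seq_len(nrow(truth))) {
    tol <- if (truth$kind[ti] == "snp") tol_snp else tol_indel
    hit <- which(calls$contig == truth$contig[ti] &
                   calls$alt == truth$alt[ti] &
                   abs(calls$pos - truth$pos[ti]) <= tol)
    for (ci in hit)
      cand[[length(cand) + 1L]] <-
        data.frame(truth_idx = ti, call_idx = ci,
                   dpos = abs(calls$pos[ci] - truth$pos[ti]))
  }
  matched <- data.frame(truth_idx = integer(), call_idx = integer(),
                        dpos = integer(), af_error = numeric())
  if (length(cand)) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(cand$dpos), , drop = FALSE]
    used_t <- used_c <- integer(0)
    for (i in seq_len(nrow(cand))) {
      if (cand$truth_idx[i] %in% used_t || cand$call_idx[i] %in% used_c) next
      used_t <- c(used_t, cand$truth_idx[i])
      used_c <- c(used_c, cand$call_idx[i])
      matched <- rbind(matched, data.frame(
        truth_idx = cand$truth_idx[i], call_idx = cand$call_idx[i],
        dpos = cand$dpos[i],
        af_error = calls$af[cand$call_idx[i]] -
          truth$realized_freq[cand$truth_idx[i]]))
    }
  }
  list(matched = matched,
       fp_idx = setdiff(seq_len(nrow(calls)), matched$call_idx),
       fn_idx = setdiff(seq_len(nrow(truth)), matched$truth_idx))
}

#' Allele-frequency agreement fraction
#'
#' In-silico analogue of concordance with an orthogonal assay (qPCR): the fraction
#' of matched variants whose estimate is within `tolerance` of the
#' realized planted frequency.
#'
#' @param matched Matched table from [match_calls()].
#' @param tolerance Absolute frequency tolerance (default 0.05).
#' @return Fraction in `[0, 1]`.
#' @export
af_agreement <- function(matched, tolerance = 0.05) {
  m <- if (is.list(matched) && !is.data.frame(matched)) matched$matched else matched
  if (nrow(m) == 0L) stop("no matched variants: agreement undefined")
  mean(abs(m$af_error) <= tolerance)
}

#' Score a call set against truth
#'
#' @param calls A `pv_calls` data frame (after filtering).
#' @param truth Truth table with realized frequencies.
#' @param genome_size Reference size in bp (for the per-Mb FP rate).
#' @param af_tolerance Agreement tolerance.
#' @param pass_only Score only PASS calls (default TRUE).
#' @return A `pv_evalreport` list: n_true, n_called, true/false positives,
#'   false negatives, fpr_per_mb, fnr, af_errors, af_agreement_fraction,
#'   power_by_frequency (grouped by realized frequency).
#' @export
eval_report <- function(calls, truth, genome_size, af_tolerance = 0.05,
                        pass_only = TRUE) {
  realizable <- truth$realized_freq > 0
  tr <- truth[realizable, , drop = FALSE]
  m <- match_calls(calls, tr, pass_only = pass_only)
  tp <- nrow(m$matched)
  fp <- length(m$fp_idx)
  fn <- length(m$fn_idx)
  det <- tapply(seq_len(nrow(tr)) %in% m$matched$truth_idx,
                tr$realized_freq, mean)
  nfreq <- tapply(rep(1L, nrow(tr)), tr$realized_freq, sum)
  power <- data.frame(realized_freq = as.numeric(names(det)),
                      n = as.integer(nfreq), power = as.numeric(det))
  structure(list(
    n_true = nrow(tr), n_called = tp + fp,
    true_positives = tp, false_positives = fp, false_negatives = fn,
    fpr_per_mb = fp / (genome_size / 1e6),
    fnr = if (nrow(tr)) fn / nrow(tr) else 0,
    af_errors = m$matched$af_error,
    af_agreement_fraction = if (tp) mean(abs(m$matched$af_error) <=
                                           af_tolerance) else NA_real_,
    power_by_frequency = power,
    unrealized_truth = sum(!realizable)),
    class = "pv_evalreport")
}

#' @export
print.pv_evalreport <- function(x, ...) {
  cat("<pv_evalreport> TP ", x$true_positives, ", FP ", x$false_positives,
      ", FN ", x$false_negatives, " (FNR ", round(x$fnr, 3),
      "), FP/Mb ", round(x$fpr_per_mb, 3), "\n", sep = "")
  if (!is.na(x$af_agreement_fraction))
    cat("  AF agreement: ", round(100 * x$af_agreement_fraction, 1),
        "% within tolerance\n", sep = "")
  invisible(x)
}

#' Report as JSON
#' @param report A `pv_evalreport`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' End-to-end detection power by planted frequency
#'
#' For each replicate, a fresh reference is generated, one SNP per
#' requested frequency is planted at well-separated positions in a
#' discrete haplotype pool, reads are simulated, and the full
#' pileup-call-filter chain is run. Detection fractions are aggregated by
#' realized (post-rounding) pool frequency, which is the truth the caller
#' can actually see; requested frequencies that round to zero carriers
#' are reported separately as unrealizable. Replicate seeds are derived
#' from `seed` by fixed increments.
#'
#' @param frequencies Requested frequencies in (0, 1].
#' @param depth Mean fold coverage.
#' @param replicates Number of seeded replicates.
#' @param seed Master seed.
#' @param ref_length Reference length per replicate (bp).
#' @param n_haplotypes Pool size.
#' @param gc_fraction Reference GC content.
#' @param caller,filter Caller / filter configurations.
#' @param per_base_error Sequencing error rate.
#' @param read_length,mean_fragment,fragment_sd Read geometry.
#' @return Data frame (realized_freq, n, detected, power); attribute
#'   `planted` maps requested to realized frequencies, attribute `seeds`
#'   logs the replicate seeds.
#' @export
power_curve <- function(frequencies, depth = 285, replicates = 20L,
                        seed = 1L, ref_length = 1e5, n_haplotypes = 20L,
                        gc_fraction = 0.35, caller = caller_config(),
                        filter = filter_config(), per_base_error = 0.001,
                        read_length = 100L, mean_fragment = 230,
                        fragment_sd = 20) {
  frequencies <- sort(unique(frequencies))
  nf <- length(frequencies)
  margin <- 2000L
  pos <- as.integer(round(seq(margin, ref_length - margin,
                              length.out = nf)))
  det <- list()
  seeds <- seed + seq_len(replicates) * 1000L
  for (r in seq_len(replicates)) {
    sr <- seeds[r]
    ref <- generate_reference(1L, ref_length, gc_fraction, seed = sr)
    alt <- chartr("ACGT", "GTAC", vapply(pos, function(p)
      ref_base(ref, "contig01", p), character(1)))
    vars <- do.call(rbind, Map(function(p, a, f)
      plant_snp("contig01", p, a, f), pos, alt, frequencies))
    pool <- build_pool(ref, n_haplotypes, vars, seed = sr + 1L)
    sim <- simulate_reads(pool, simulation_config(
      depth = depth, read_length = read_length,
      mean_fragment = mean_fragment, fragment_sd = fragment_sd,
      per_base_error = per_base_error, seed = sr + 2L))
    pu <- build_pileup(sim, ref)
    calls <- apply_filters(call_variants(pu, caller), pu, filter)
    tr <- pool_truth(pool)
    m <- match_calls(calls, tr, pass_only = TRUE)
    det[[r]] <- data.frame(requested = tr$true_freq,
                           realized = tr$realized_freq,
                           detected = seq_len(nrow(tr)) %in%
                             m$matched$truth_idx,
                           replicate = r)
  }
  det <- do.call(rbind, det)
  realized <- det[det$realized > 0, , drop = FALSE]
  agg <- do.call(rbind, lapply(split(realized, realized$realized), function(g)
    data.frame(realized_freq = g$realized[1], n = nrow(g),
               detected = sum(g$detected), power = mean(g$detected))))
  rownames(agg) <- NULL
  attr(agg, "planted") <- unique(det[, c("requested", "realized")])
  attr(agg, "seeds") <- seeds
  agg
}

#' Smallest realized frequency reaching a target detection power
#'
#' @param power_tbl Output of [power_curve()].
#' @param min_power Target power (default 0.95).
#' @return Realized frequency (fraction), or `NA` if never reached.
#' @export
detection_floor <- function(power_tbl, min_power = 0.95) {
  ok <- power_tbl$realized_freq[power_tbl$power >= min_power]
  if (length(ok)) min(ok) else NA_real_
}
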