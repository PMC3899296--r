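#' Write calls as VCF 4.2
#'
#' INFO carries AF (continuous alternate read fraction), SCORE
#' (log-likelihood ratio), GRIDF (maximum-likelihood grid frequency),
#' ALTC, DP, KIND, FOUNDER, and — when present — GENE, REGION, EFFECT,
#' AACHANGE. Filter flags go in the FILTER column, `PASS` for clean calls.
#'
#' @param calls A `pv_calls` data frame.
#' @param path Output path.
#' @param reference Optional `pv_reference` for contig header lines.
#' @param config_echo Optional named list echoed as a `##poolvar_config`
#'   header line.
#' @param timestamp Include a `##fileDate` line (default TRUE; the only
#'   non-deterministic header line).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, reference = NULL, config_echo = NULL,
                      timestamp = TRUE) {
  hdr <- c("##fileformat=VCFv4.2",
           if (timestamp) paste0("##fileDate=", format(Sys.Date(), "%Y%m%d")),
           paste0("##source=poolvar-", as.character(packageVersion("poolvar"))))
  if (!is.null(reference))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(reference$seq), nchar(reference$seq)))
  if (!is.null(config_echo))
    hdr <- c(hdr, paste0("##poolvar_config=", jsonlite::toJSON(
      config_echo, auto_unbox = TRUE)))
  hdr <- c(hdr,
    '##INFO=<ID=AF,Number=1,Type=Float,Description="Alternate read fraction">',
    '##INFO=<ID=SCORE,Number=1,Type=Float,Description="Log-likelihood ratio vs no-variant">',
    '##INFO=<ID=GRIDF,Number=1,Type=Float,Description="ML frequency on the haplotype grid">',
    '##INFO=<ID=ALTC,Number=1,Type=Integer,Description="Alternate-supporting reads">',
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Retained depth">',
    '##INFO=<ID=KIND,Number=1,Type=String,Description="snp, insertion or deletion">',
    '##INFO=<ID=FOUNDER,Number=1,Type=String,Description="novel, in_founder or unknown">',
    '##FILTER=<ID=STRAND_CTX,Description="Strand-biased G/C mismatch context">',
    '##FILTER=<ID=READ_POS,Description="Alternate observations depleted mid-read">',
    '##FILTER=<ID=NEAR_SV,Description="Large insertion/deletion signature nearby">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- sprintf("AF=%s;SCORE=%s;GRIDF=%s;ALTC=%d;DP=%d;KIND=%s;FOUNDER=%s",
                  format(calls$af, digits = 6, trim = TRUE),
                  format(calls$score, digits = 6, trim = TRUE),
                  format(calls$grid_freq, digits = 6, trim = TRUE),
                  calls$alt_count, calls$total_count, calls$kind,
                  calls$founder_status)
  if ("effect" %in% names(calls) && nrow(calls)) {
    aach <- ifelse(is.na(calls$aa_pos), ".",
                   paste0(calls$aa_ref, calls$aa_pos, calls$aa_alt))
    info <- paste0(info, ";GENE=", gsub("[;=]", "_", calls$gene_id),
                   ";REGION=", calls$region, ";EFFECT=", calls$effect,
                   ";AACHANGE=", aach)
  }
  body <- sprintf("%s\t%d\t.\t%s\t%s\t%s\t%s\t%s",
                  calls$contig, calls$pos, calls$ref, calls$alt,
                  format(calls$score, digits = 6, trim = TRUE),
                  ifelse(calls$filter == "", ".", calls$filter), info)
  writeLines(c(hdr, if (nrow(calls)) body), path)
  invisible(path)
}

#' Write calls as a tab-separated table
#'
#' A spreadsheet-friendly mirror of the VCF (supplementary-table style:
#' position, change type, frequency, and gene context when annotated).
#'
#' @param calls A `pv_calls` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a poolvar VCF back into a call table
#'
#' Restores the columns written by [write_vcf()].
#'
#' @param path VCF path.
#' @return A `pv_calls` data frame.
#' @export
read_vcf_calls <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#")]
  out <- empty_calls()
  if (length(ln)) {
    fx <- do.call(rbind, strsplit(ln, "\t"))
    info <- fx[, 8]
    pick <- function(key) vapply(info, function(s) {
      m <- regmatches(s, regexpr(paste0("(?<=^", key, "=|;", key, "=)[^;]+"),
                                 s, perl = TRUE))
      if (length(m)) m else NA_character_
    }, character(1), USE.NAMES = FALSE)
    out <- data.frame(contig = fx[, 1], pos = as.integer(fx[, 2]),
                      ref = fx[, 4], alt = fx[, 5],
                      kind = pick("KIND"), af = as.numeric(pick("AF")),
                      alt_count = as.integer(pick("ALTC")),
                      total_count = as.integer(pick("DP")),
                      score = as.numeric(pick("SCORE")),
                      grid_freq = as.numeric(pick("GRIDF")),
                      filter = ifelse(fx[, 7] == ".", "", fx[, 7]),
                      founder_status = pick("FOUNDER"),
                      stringsAsFactors = FALSE)
  }
  class(out) <- c("pv_calls", "data.frame")
  out
}
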