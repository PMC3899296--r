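#' Construct a gene model
#'
#' @param gene_id Gene identifier (e.g. a locus tag).
#' @param contig Contig id.
#' @param strand `"+"` or `"-"`.
#' @param start,end 1-based inclusive CDS interval(s); vectors for
#'   multi-interval CDS (intervals must not overlap; joined length must be
#'   divisible by 3).
#' @param product Free-text product description.
#' @return One-or-more-row data frame (rbind-able into a gene model table).
#' @export
gene_model <- function(gene_id, contig, strand, start, end, product = "") {
  stopifnot(strand %in% c("+", "-"), length(start) == length(end),
            all(end >= start))
  if (sum(end - start + 1L) %% 3L != 0L)
    stop("joined CDS length must be divisible by 3 for gene ", gene_id)
  o <- order(start)
  data.frame(gene_id = gene_id, contig = contig, strand = strand,
             start = as.integer(start[o]), end = as.integer(end[o]),
             product = product, stringsAsFactors = FALSE)
}

#' Read gene models from GFF3
#'
#' Imports CDS features via [rtracklayer::import()]; the gene id is taken
#' from the first available of `locus_tag`, `gene`, `Name`, `ID`.
#'
#' @param path GFF3 file path.
#' @return Gene model data frame (gene_id, contig, strand, start, end,
#'   product).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "CDS"]
  md <- S4Vectors::mcols(gr)
  pick <- function(fields) {
    out <- rep(NA_character_, length(gr))
    for (f in fields) if (f %in% names(md)) {
      v <- as.character(md[[f]])
      out <- ifelse(is.na(out) & !is.na(v), v, out)
    }
    out
  }
  data.frame(gene_id = pick(c("locus_tag", "gene", "Name", "ID")),
             contig = as.character(GenomicRanges::seqnames(gr)),
             strand = as.character(GenomicRanges::strand(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             product = ifelse(is.na(pick("product")), "", pick("product")),
             stringsAsFactors = FALSE)
}

#' Classify the genomic region of a call
#'
#' `coding` when inside a CDS; `promoter_proximal` when within
#' `promoter_window` bp upstream of a gene start on that gene's strand;
#' otherwise `intergenic`, reporting the flanking genes (the gene to the
#' left on the reference listed first).
#'
#' @param call One-row call (needs `contig` and `pos`), or a list with
#'   those fields.
#' @param gene_models Gene model data frame.
#' @param promoter_window Upstream window in bp (default 150).
#' @return List with `region` and `gene_id` (character vector; for
#'   intergenic, the flanking gene ids).
#' @export
classify_region <- function(call, gene_models, promoter_window = 150L) {
  g <- gene_models[gene_models$contig == call$contig, , drop = FALSE]
  hit <- g$start <= call$pos & g$end >= call$pos
  if (any(hit))
    return(list(region = "coding", gene_id = unique(g$gene_id[hit])[1]))
  prom <- character(0)
  for (id in unique(g$gene_id)) {
    rows <- g[g$gene_id == id, , drop = FALSE]
    if (rows$strand[1] == "+") {
      gs <- min(rows$start)
      if (call$pos >= gs - promoter_window && call$pos <= gs - 1L)
        prom <- c(prom, id)
    } else {
      ge <- max(rows$end)
      if (call$pos >= ge + 1L && call$pos <= ge + promoter_window)
        prom <- c(prom, id)
    }
  }
  if (length(prom))
    return(list(region = "promoter_proximal", gene_id = prom))
  lend <- tapply(g$end, g$gene_id, max)
  lstart <- tapply(g$start, g$gene_id, min)
  left <- names(lend)[lend < call$pos]
  right <- names(lstart)[lstart > call$pos]
  fl <- c(if (length(left)) left[which.max(lend[left])],
          if (length(right)) right[which.min(lstart[right])])
  list(region = "intergenic",
       gene_id = if (length(fl)) fl else NA_character_)
}

# CDS sequence (coding strand) and the coding-strand offset of a genomic
# position within a gene model
cds_context <- function(gene, reference, pos) {
  segs <- Map(function(s, e) ref_base(reference, gene$contig[1], s, e - s + 1L),
              gene$start, gene$end)
  cds_fwd <- paste(unlist(segs), collapse = "")
  off_fwd <- 0L
  found <- FALSE
  for (i in seq_len(nrow(gene))) {
    if (pos >= gene$start[i] && pos <= gene$end[i]) {
      off_fwd <- off_fwd + (pos - gene$start[i] + 1L)
      found <- TRUE
      break
    }
    off_fwd <- off_fwd + (gene$end[i] - gene$start[i] + 1L)
  }
  if (!found) stop("position ", pos, " not inside CDS of ", gene$gene_id[1])
  if (gene$strand[1] == "+") {
    list(cds = cds_fwd, cds_pos = off_fwd)
  } else {
    list(cds = as.character(Biostrings::reverseComplement(
           Biostrings::DNAString(cds_fwd))),
         cds_pos = nchar(cds_fwd) - off_fwd + 1L)
  }
}

translate11 <- function(codon) {
  as.character(Biostrings::translate(
    Biostrings::DNAString(codon),
    genetic.code = Biostrings::getGeneticCode("11"),
    no.init.codon = TRUE))
}

#' Coding consequence of a call within a gene
#'
#' For SNPs, extracts the affected codon on the coding strand, applies
#' the substitution and translates both codons with genetic code table 11
#' (bacterial). Coding indels are `frameshift` when their length is not a
#' multiple of 3, else `in_frame_indel`. Amino-acid numbering starts at
#' the annotated start codon (position 1).
#'
#' @param call One-row call (contig, pos, ref, alt, kind).
#' @param gene Gene model rows for one gene (see [gene_model()]).
#' @param reference A `pv_reference`.
#' @return List: codon_ref, codon_alt, aa_ref, aa_pos, aa_alt, effect.
#' @export
codon_effect <- function(call, gene, reference) {
  cdslen <- sum(gene$end - gene$start + 1L)
  if (cdslen %% 3L != 0L)
    stop("CDS length of ", gene$gene_id[1], " not divisible by 3")
  if (call$kind != "snp") {
    ilen <- abs(nchar(call$ref) - nchar(call$alt))
    eff <- if (ilen %% 3L != 0L) "frameshift" else "in_frame_indel"
    return(list(codon_ref = NA_character_, codon_alt = NA_character_,
                aa_ref = NA_character_, aa_pos = NA_integer_,
                aa_alt = NA_character_, effect = eff))
  }
  cx <- cds_context(gene, reference, call$pos)
  obs <- substr(cx$cds, cx$cds_pos, cx$cds_pos)
  ref_b <- call$ref; alt_b <- call$alt
  if (gene$strand[1] == "-") {
    ref_b <- chartr("ACGT", "TGCA", ref_b)
    alt_b <- chartr("ACGT", "TGCA", alt_b)
  }
  if (obs != ref_b)
    stop("CDS inconsistent with reference at ", call$contig, ":", call$pos)
  ci <- (cx$cds_pos - 1L) %/% 3L
  within <- (cx$cds_pos - 1L) %% 3L + 1L
  codon_ref <- substr(cx$cds, ci * 3L + 1L, ci * 3L + 3L)
  codon_alt <- codon_ref
  substr(codon_alt, within, within) <- alt_b
  aa_ref <- translate11(codon_ref)
  aa_alt <- translate11(codon_alt)
  effect <- if (aa_ref == aa_alt) "synonymous"
    else if (aa_alt == "*") "nonsense" else "nonsynonymous"
  list(codon_ref = codon_ref, codon_alt = codon_alt, aa_ref = aa_ref,
       aa_pos = ci + 1L, aa_alt = aa_alt, effect = effect)
}

#' Annotate calls with region and coding consequence
#'
#' @param calls A `pv_calls` data frame.
#' @param gene_models Gene model table ([gene_model()] /
#'   [read_gene_models()]).
#' @param reference A `pv_reference`.
#' @param promoter_window Upstream window for `promoter_proximal` (bp).
#' @return `calls` with region, gene_id, codon_ref/alt, aa_ref/pos/alt and
#'   effect columns appended.
#' @export
annotate_calls <- function(calls, gene_models, reference,
                           promoter_window = 150L) {
  n <- nrow(calls)
  calls$region <- calls$gene_id <- calls$codon_ref <- calls$codon_alt <-
    calls$aa_ref <- calls$aa_alt <- rep(NA_character_, n)
  calls$aa_pos <- rep(NA_integer_, n)
  calls$effect <- rep("intergenic", n)
  for (i in seq_len(n)) {
    cl <- classify_region(calls[i, ], gene_models, promoter_window)
    calls$region[i] <- cl$region
    calls$gene_id[i] <- paste(cl$gene_id, collapse = ",")
    if (cl$region == "coding") {
      gene <- gene_models[gene_models$gene_id == cl$gene_id[1], , drop = FALSE]
      ce <- codon_effect(calls[i, ], gene, reference)
      calls$codon_ref[i] <- ce$codon_ref
      calls$codon_alt[i] <- ce$codon_alt
      calls$aa_ref[i] <- ce$aa_ref
      calls$aa_pos[i] <- ce$aa_pos
      calls$aa_alt[i] <- ce$aa_alt
      calls$effect[i] <- ce$effect
    }
  }
  calls
}
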