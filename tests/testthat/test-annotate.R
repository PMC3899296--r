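# A reference carrying one forward-strand gene whose CDS reproduces the
# codon changes the consequence rules must reproduce: ATG | GGA | TAT | CTG | TAC | ... | TAA
gene_fixture <- function() {
  cds <- paste0("ATG", "GGA", "TAT", "CTG", "TAC", "AAA", "CCC", "TAA")
  left <- random_seq(200, seed = 90)
  right <- random_seq(200, seed = 91)
  refseq <- paste0(left, cds, right)
  ref <- tiny_reference(refseq)
  gm <- gene_model("geneA", "contig01", "+", 201L, 200L + nchar(cds),
                   product = "fixture protein")
  list(ref = ref, gm = gm, cds_start = 201L)
}

snp_call <- function(pos, ref_b, alt_b, kind = "snp") {
  data.frame(contig = "contig01", pos = as.integer(pos), ref = ref_b,
             alt = alt_b, kind = kind, af = 0.9, alt_count = 100L,
             total_count = 110L, score = 100, grid_freq = 0.9, filter = "PASS",
             founder_status = "novel", stringsAsFactors = FALSE)
}

test_that("region classification follows the documented rules", {
  fx <- gene_fixture()
  inside <- classify_region(list(contig = "contig01", pos = 210L), fx$gm)
  expect_identical(inside$region, "coding")
  expect_identical(inside$gene_id, "geneA")

  prom <- classify_region(list(contig = "contig01", pos = fx$cds_start - 50L),
                          fx$gm, promoter_window = 150L)
  expect_identical(prom$region, "promoter_proximal")

  far <- classify_region(list(contig = "contig01", pos = 10L), fx$gm,
                         promoter_window = 20L)
  expect_identical(far$region, "intergenic")
})

test_that("equidistant intergenic positions report both flanks, left first", {
  gm <- rbind(gene_model("left", "contig01", "+", 101L, 200L + 1L - 1L + 2L),
              gene_model("right", "contig01", "+", 401L, 502L))
  # midpoint between end 202 and start 401 is 301.5; use 302 with window 50
  cl <- classify_region(list(contig = "contig01", pos = 302L), gm,
                        promoter_window = 50L)
  expect_identical(cl$region, "intergenic")
  expect_identical(cl$gene_id, c("left", "right"))
})

test_that("codon effects reproduce the confirmed substitutions", {
  fx <- gene_fixture()
  # GGA -> GAA: Gly -> Glu, nonsynonymous (codon 2, middle position)
  p <- fx$cds_start + 4L
  ce <- codon_effect(snp_call(p, "G", "A"), fx$gm, fx$ref)
  expect_identical(ce$codon_ref, "GGA")
  expect_identical(ce$codon_alt, "GAA")
  expect_identical(ce$aa_ref, "G")
  expect_identical(ce$aa_alt, "E")
  expect_identical(ce$effect, "nonsynonymous")
  expect_identical(ce$aa_pos, 2L)

  # TAT -> TCT: Tyr -> Ser (codon 3, middle position)
  p <- fx$cds_start + 7L
  ce <- codon_effect(snp_call(p, "A", "C"), fx$gm, fx$ref)
  expect_identical(ce$codon_ref, "TAT")
  expect_identical(ce$codon_alt, "TCT")
  expect_identical(c(ce$aa_ref, ce$aa_alt), c("Y", "S"))
  expect_identical(ce$effect, "nonsynonymous")

  # CTG -> TTG: Leu -> Leu, synonymous (codon 4, first position)
  p <- fx$cds_start + 9L
  ce <- codon_effect(snp_call(p, "C", "T"), fx$gm, fx$ref)
  expect_identical(ce$effect, "synonymous")

  # TAC -> TAA: nonsense (codon 5, third position)
  p <- fx$cds_start + 14L
  ce <- codon_effect(snp_call(p, "C", "A"), fx$gm, fx$ref)
  expect_identical(ce$effect, "nonsense")
  expect_identical(ce$aa_alt, "*")
})

test_that("coding indels classify by length modulo 3", {
  fx <- gene_fixture()
  del2 <- snp_call(210L, "GCA", "G", kind = "deletion")
  expect_identical(codon_effect(del2, fx$gm, fx$ref)$effect, "frameshift")
  ins3 <- snp_call(210L, "G", "GTTT", kind = "insertion")
  expect_identical(codon_effect(ins3, fx$gm, fx$ref)$effect, "in_frame_indel")
})

test_that("reverse-strand annotation matches the forward metamorphic copy", {
  cds <- paste0("ATG", "GGA", "TAT", "CTG", "AAA", "TAA")
  pad <- random_seq(60, seed = 92)
  fwd_ref <- tiny_reference(paste0(pad, cds, pad))
  fwd_gm <- gene_model("g", "contig01", "+", 61L, 60L + nchar(cds))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  rev_ref <- tiny_reference(paste0(pad, rc, pad))
  rev_gm <- gene_model("g", "contig01", "-", 61L, 60L + nchar(cds))
  L <- nchar(cds)
  for (off in c(4L, 7L, 10L)) {    # middle positions of codons 2..4
    p_fwd <- 60L + off + 1L
    b_ref <- substr(cds, off + 1L, off + 1L)
    b_alt <- other_base(b_ref)
    ce_f <- codon_effect(snp_call(p_fwd, b_ref, b_alt), fwd_gm, fwd_ref)
    # same base change seen from the reverse strand
    p_rev <- 60L + (L - off)
    ce_r <- codon_effect(snp_call(p_rev, chartr("ACGT", "TGCA", b_ref),
                                  chartr("ACGT", "TGCA", b_alt)),
                         rev_gm, rev_ref)
    expect_identical(ce_r[c("codon_ref", "codon_alt", "aa_ref", "aa_pos",
                            "aa_alt", "effect")],
                     ce_f[c("codon_ref", "codon_alt", "aa_ref", "aa_pos",
                            "aa_alt", "effect")])
  }
})

test_that("codon annotation agrees with a whole-protein translation oracle", {
  set.seed(93)
  n_codons <- 40L
  cds <- paste0("ATG", paste(sample(c("GCA", "GAA", "TGG", "CTG", "TAT",
                                      "AAA", "CCC", "AGT"), n_codons - 2L,
                                    replace = TRUE), collapse = ""), "TAA")
  pad <- random_seq(50, seed = 94)
  ref <- tiny_reference(paste0(pad, cds, pad))
  gm <- gene_model("g", "contig01", "+", 51L, 50L + nchar(cds))
  code <- Biostrings::getGeneticCode("11")
  for (i in 1:15) {
    off <- sample(seq_len(nchar(cds) - 3L), 1L)   # spare the stop codon
    b_ref <- substr(cds, off, off)
    b_alt <- other_base(b_ref)
    ce <- codon_effect(snp_call(50L + off, b_ref, b_alt), gm, ref)
    mut <- cds
    substr(mut, off, off) <- b_alt
    prot_ref <- strsplit(as.character(Biostrings::translate(
      Biostrings::DNAString(cds), genetic.code = code,
      no.init.codon = TRUE)), "")[[1]]
    prot_alt <- strsplit(as.character(Biostrings::translate(
      Biostrings::DNAString(mut), genetic.code = code,
      no.init.codon = TRUE)), "")[[1]]
    diff <- which(prot_ref != prot_alt)
    if (length(diff) == 0L) {
      expect_identical(ce$effect, "synonymous")
    } else {
      expect_identical(ce$aa_pos, diff[1])
      expect_identical(ce$aa_ref, prot_ref[diff[1]])
      expect_identical(ce$aa_alt, prot_alt[diff[1]])
    }
  }
})

test_that("gene models round-trip through GFF3", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    paste("contig01", "test", "gene", 201, 224, ".", "+", ".",
          "ID=gene1;locus_tag=PV_0001", sep = "\t"),
    paste("contig01", "test", "CDS", 201, 224, ".", "+", "0",
          "ID=cds1;Parent=gene1;locus_tag=PV_0001;product=test protein",
          sep = "\t")), gff)
  gm <- read_gene_models(gff)
  expect_identical(nrow(gm), 1L)
  expect_identical(gm$gene_id, "PV_0001")
  expect_identical(gm$strand, "+")
  expect_identical(c(gm$start, gm$end), c(201L, 224L))
})

test_that("annotate_calls appends consequence columns", {
  fx <- gene_fixture()
  calls <- rbind(snp_call(fx$cds_start + 4L, "G", "A"),
                 snp_call(10L, substr(fx$ref$seq[[1]], 10, 10),
                          other_base(substr(fx$ref$seq[[1]], 10, 10))))
  class(calls) <- c("pv_calls", "data.frame")
  ann <- annotate_calls(calls, fx$gm, fx$ref)
  expect_identical(ann$effect[1], "nonsynonymous")
  expect_identical(ann$aa_pos[1], 2L)
  expect_identical(ann$region[2], "intergenic")
})
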