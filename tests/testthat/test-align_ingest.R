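test_that("a single perfect read yields depth-1 reference columns", {
  refseq <- random_seq(300, seed = 1)
  ref <- tiny_reference(refseq)
  aln <- manual_read("r1", "contig01", 50, substr(refseq, 50, 149))
  pu <- build_pileup(aln, ref)
  dp <- rowSums(pu$contigs[[1]]$counts)
  expect_identical(which(dp > 0), 50:149)
  expect_true(all(dp[50:149] == 1))
  for (p in c(50, 100, 149)) {
    tot <- base_totals_at(pu, p)
    expect_identical(tot[[substr(refseq, p, p)]], 1L)
  }
})

test_that("overlapping mate pairs contribute once per site", {
  refseq <- random_seq(400, seed = 2)
  ref <- tiny_reference(refseq)
  # 150 bp fragment, 100 bp reads: overlap 101..150
  aln <- rbind(
    manual_read("p1", "contig01", 51, substr(refseq, 51, 150), "+", read1 = TRUE),
    manual_read("p1", "contig01", 101, substr(refseq, 101, 200), "-", read1 = FALSE))
  pu <- build_pileup(aln, ref)
  dp <- rowSums(pu$contigs[[1]]$counts)
  expect_true(all(dp[101:150] == 1))
  expect_true(all(dp[c(51:100, 151:200)] == 1))
})

test_that("higher-quality base wins in the mate overlap", {
  refseq <- strrep("A", 200)
  ref <- tiny_reference(refseq)
  seq1 <- strrep("A", 100)
  seq2 <- paste0(strrep("C", 50), strrep("A", 50))  # C over the overlap
  aln <- rbind(
    manual_read("p1", "contig01", 1, seq1, "+", qual_char = "5", read1 = TRUE),   # Q20
    manual_read("p1", "contig01", 51, seq2, "-", qual_char = "I", read1 = FALSE)) # Q40
  pu <- build_pileup(aln, ref)
  tot <- base_totals_at(pu, 60)
  expect_identical(tot[["C"]], 1L)   # the Q40 mate's base
  expect_identical(tot[["A"]], 0L)
})

test_that("pileup counts equal a brute-force recount on a mixed fixture", {
  refseq <- random_seq(500, seed = 3)
  ref <- tiny_reference(refseq)
  set.seed(4)
  rows <- list()
  for (i in 1:10) {
    p <- sample(1:380, 1)
    s <- substr(refseq, p, p + 99)
    # sprinkle mismatches
    for (k in sample(1:100, sample(0:3, 1)))
      substr(s, k, k) <- other_base(substr(s, k, k))
    rows[[i]] <- manual_read(paste0("r", i), "contig01", p, s,
                             strand = sample(c("+", "-"), 1),
                             qual_char = sample(c("I", "5", "#"), 1))
  }
  aln <- do.call(rbind, rows)
  pu <- build_pileup(aln, ref, min_mapping_quality = 20, min_base_quality = 20)
  expect_identical(pileup_counts_array(pu),
                   naive_recount(aln, refseq, 20L, 20L))
})

test_that("indel and clip evidence lands where the conventions say", {
  refseq <- random_seq(400, seed = 5)
  ref <- tiny_reference(refseq)
  # read with a 5 bp deletion of ref 151..155, anchored at 101
  del_seq <- paste0(substr(refseq, 101, 150), substr(refseq, 156, 205))
  # read with a 3 bp insertion after ref 220
  ins_seq <- paste0(substr(refseq, 181, 220), "TTT", substr(refseq, 221, 277))
  # read soft-clipped: aligned 301..360, clipped tail
  clip_seq <- paste0(substr(refseq, 301, 360), strrep("G", 40))
  aln <- rbind(
    manual_read("d1", "contig01", 101, del_seq, cigar = "50M5D50M"),
    manual_read("i1", "contig01", 181, ins_seq, cigar = "40M3I57M"),
    manual_read("c1", "contig01", 301, clip_seq, cigar = "60M40S"))
  pu <- build_pileup(aln, ref)
  pc <- pu$contigs[[1]]
  expect_true(all(pc$del_support[151:155] == 1L))
  expect_identical(sum(pc$del_support), 5L)
  expect_identical(pc$ins_support[220], 1L)
  expect_identical(pc$clip_trail[361], 1L)
  ev <- pc$events
  expect_identical(ev$pos[ev$type == "deletion"], 151L)
  expect_identical(ev$len[ev$type == "deletion"], 5L)
  expect_identical(ev$seq[ev$type == "insertion"], "TTT")
})

test_that("raising the base-quality cutoff never increases counts", {
  refseq <- random_seq(300, seed = 6)
  ref <- tiny_reference(refseq)
  set.seed(7)
  rows <- lapply(1:8, function(i) {
    p <- sample(1:200, 1)
    manual_read(paste0("r", i), "contig01", p, substr(refseq, p, p + 99),
                qual_char = sample(c("I", "5", "0", "#"), 1))
  })
  aln <- do.call(rbind, rows)
  prev <- Inf
  for (q in c(0, 15, 20, 30, 41)) {
    pu <- build_pileup(aln, ref, min_base_quality = q)
    tot <- sum(pu$contigs[[1]]$counts)
    expect_lte(tot, prev)
    prev <- tot
  }
})

test_that("depth conservation holds on indel-free alignments", {
  fx <- shared_sim()
  aln <- fx$sim$alignments
  simple <- grepl("^[0-9]+M$", aln$cigar) & !aln$unmapped
  expect_true(all(simple))
  pu <- build_pileup(aln, fx$ref, min_base_quality = 0)
  total_depth <- sum(as.numeric(pu$contigs[[1]]$counts))
  aligned <- sum(nchar(aln$seq))
  # overlapping mates dedup some bases, so depth <= aligned but close
  expect_lte(total_depth, aligned)
  expect_gt(total_depth / aligned, 0.9)
})

test_that("SAM round trip preserves the pileup", {
  ref <- generate_reference(1, 4000, 0.35, seed = 61)
  alt <- other_base(substr(ref$seq[[1]], 2000, 2000))
  pool <- build_pool(ref, 10, plant_snp("contig01", 2000, alt, 0.5), seed = 62)
  sim <- simulate_reads(pool, simulation_config(depth = 30, seed = 63))
  sam <- tempfile(fileext = ".sam")
  write_sam(sim, sam)
  back <- read_alignments(sam)
  pu1 <- build_pileup(sim, ref)
  pu2 <- build_pileup(back, ref)
  expect_identical(pu1$contigs[[1]]$counts, pu2$contigs[[1]]$counts)
  expect_identical(pu1$contigs[[1]]$del_support, pu2$contigs[[1]]$del_support)
})

test_that("pair statistics find the insert distribution and discordance", {
  refseq <- random_seq(5000, seed = 8)
  ref <- tiny_reference(refseq)
  mk_pair <- function(id, p1, insert, strand2 = "-") {
    p2 <- p1 + insert - 100
    rbind(manual_read(id, "contig01", p1, substr(refseq, p1, p1 + 99), "+",
                      read1 = TRUE),
          manual_read(id, "contig01", p2, substr(refseq, p2, p2 + 99), strand2,
                      read1 = FALSE))
  }
  rows <- do.call(rbind, lapply(1:20, function(i) mk_pair(paste0("p", i),
                                                          100 + 37 * i, 230)))
  ps <- collect_pair_stats(rows)
  expect_equal(ps$median_insert, 230)
  expect_identical(nrow(ps$discordant), 0L)

  # one pair implying a 1 kb larger insert
  rows2 <- rbind(rows, mk_pair("big", 2000, 1230))
  ps2 <- collect_pair_stats(rows2)
  expect_identical(nrow(ps2$discordant), 1L)
  expect_equal(ps2$discordant$implied_size, 1000)

  # same-strand orientation is discordant regardless of insert
  rows3 <- rbind(rows, mk_pair("ss", 3000, 230, strand2 = "+"))
  ps3 <- collect_pair_stats(rows3)
  expect_identical(ps3$discordant$orientation, "same_strand")

  expect_error(collect_pair_stats(rows[1, ]), "pair")
})
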