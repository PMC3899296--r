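test_that("generate_reference is deterministic and hits composition targets", {
  a <- generate_reference(2, c(500, 300), 0.4, seed = 42)
  b <- generate_reference(2, c(500, 300), 0.4, seed = 42)
  expect_identical(a$seq, b$seq)
  expect_false(identical(a$seq,
                         generate_reference(2, c(500, 300), 0.4, seed = 43)$seq))

  gconly <- generate_reference(1, 2000, 1.0, seed = 1)
  expect_false(grepl("[AT]", gconly$seq[[1]]))

  big <- generate_reference(1, 1e5, 0.5, seed = 7)
  gc <- sum(strsplit(big$seq[[1]], "")[[1]] %in% c("G", "C")) / 1e5
  expect_gte(gc, 0.48)
  expect_lte(gc, 0.52)

  expect_error(generate_reference(1, 0, 0.5, 1), "positive")
  expect_error(generate_reference(1, -5, 0.5, 1), "positive")
})

test_that("build_pool realizes frequencies on the haplotype grid", {
  ref <- tiny_reference(random_seq(1000, seed = 5))
  b <- function(p) substr(ref$seq[[1]], p, p)

  p10 <- build_pool(ref, 10, plant_snp("contig01", 100, other_base(b(100)), 0.10),
                    seed = 1)
  expect_length(p10$variants$carriers[[1]], 1L)

  pfix <- build_pool(ref, 10, plant_snp("contig01", 100, other_base(b(100)), 1.0),
                     seed = 1)
  expect_identical(pfix$variants$carriers[[1]], 1:10)
  expect_equal(pfix$variants$realized_freq, 1.0)

  p20 <- build_pool(ref, 20, plant_snp("contig01", 100, other_base(b(100)), 0.05),
                    seed = 1)
  expect_length(p20$variants$carriers[[1]], 1L)
  expect_equal(p20$variants$realized_freq, 0.05)

  expect_error(
    build_pool(ref, 10, plant_snp("contig01", 100, other_base(b(100)), 1.2)),
    "<= 1|\\(0, 1]")
})

test_that("carrier rounding matches an exhaustive nearest-fraction oracle", {
  for (n in c(7L, 10L, 20L)) {
    for (f in c(0.01, 0.025, 0.05, 1 / n, 1.5 / n, 0.25, 0.333, 0.5, 0.91, 1)) {
      # oracle: scan all k, keep the nearest fraction, ties to smaller k
      # (compare in carrier units so exact ties stay exact in floating point)
      err <- abs(f * n - (0:n))
      k_oracle <- (0:n)[which.min(err)]  # which.min takes first = smaller k
      k_impl <- as.integer(ceiling(f * n - 0.5))
      expect_identical(k_impl, k_oracle,
                       label = sprintf("n=%d f=%g impl", n, f))
    }
  }
})

test_that("build_pool refuses overlapping variants it cannot separate", {
  ref <- tiny_reference(random_seq(1000, seed = 6))
  v <- rbind(plant_deletion("contig01", 200, 10, 0.8),
             plant_deletion("contig01", 205, 10, 0.8))
  expect_error(build_pool(ref, 10, v, seed = 1), "conflict")
  # disjoint carriers fit: 0.5 + 0.5 on 10 haplotypes
  v2 <- rbind(plant_deletion("contig01", 200, 10, 0.5),
              plant_deletion("contig01", 205, 10, 0.5))
  pool <- build_pool(ref, 10, v2, seed = 1)
  expect_length(intersect(pool$variants$carriers[[1]],
                          pool$variants$carriers[[2]]), 0L)
})

test_that("noiseless fixed SNP appears in every covering read", {
  ref <- tiny_reference(random_seq(3000, seed = 8))
  alt <- other_base(substr(ref$seq[[1]], 1500, 1500))
  pool <- build_pool(ref, 10, plant_snp("contig01", 1500, alt, 1.0), seed = 2)
  sim <- simulate_reads(pool, simulation_config(depth = 60, per_base_error = 0,
                                                seed = 3))
  pu <- build_pileup(sim, ref)
  tot <- base_totals_at(pu, 1500)
  expect_gt(tot[[alt]], 0)
  expect_identical(sum(tot) - tot[[alt]], 0L)   # only alt observed
})

test_that("read pairing, truth completeness and depth concentration hold", {
  fx <- shared_sim()
  aln <- fx$sim$alignments
  expect_identical(nrow(aln), 2L * fx$sim$n_fragments)
  # every emitted read appears in the truth alignment exactly once
  expect_identical(anyDuplicated(paste(aln$qname, aln$read1)), 0L)
  expect_true(all(table(aln$qname) == 2L))
  dp <- rowSums(fx$pileup$contigs[[1]]$counts)
  inner <- dp[1000:99000]
  expect_lt(abs(mean(inner) - 285) / 285, 0.05)
})

test_that("simulated FASTQ output is byte-identical under a fixed seed", {
  ref <- generate_reference(1, 5000, 0.35, seed = 31)
  alt <- other_base(substr(ref$seq[[1]], 2500, 2500))
  pool <- build_pool(ref, 10, plant_snp("contig01", 2500, alt, 0.5), seed = 32)
  cfg <- simulation_config(depth = 40, seed = 33)
  f1 <- tempfile(); f2 <- tempfile(); g1 <- tempfile(); g2 <- tempfile()
  write_fastq(simulate_reads(pool, cfg), f1, f2)
  write_fastq(simulate_reads(pool, cfg), g1, g2)
  expect_identical(readLines(f1), readLines(g1))
  expect_identical(readLines(f2), readLines(g2))
})

test_that("noiseless alt read fraction tracks realized frequency", {
  ref <- generate_reference(1, 20000, 0.35, seed = 41)
  freqs <- c(0.1, 0.3, 0.5, 0.9)
  pos <- c(4000, 8000, 12000, 16000)
  alt <- other_base(vapply(pos, function(p) substr(ref$seq[[1]], p, p), ""))
  vars <- do.call(rbind, Map(function(p, a, f)
    plant_snp("contig01", p, a, f), pos, alt, freqs))
  pool <- build_pool(ref, 10, vars, seed = 42)
  sim <- simulate_reads(pool, simulation_config(depth = 200,
                                                per_base_error = 0, seed = 43))
  pu <- build_pileup(sim, ref)
  for (i in seq_along(pos)) {
    tot <- base_totals_at(pu, pos[i])
    depth <- sum(tot)
    frac <- tot[[alt[i]]] / depth
    sd3 <- 3 * sqrt(freqs[i] * (1 - freqs[i]) / depth)
    expect_lt(abs(frac - freqs[i]), sd3 + 1e-12,
              label = sprintf("freq %.2f frac %.3f", freqs[i], frac))
  }
})

test_that("artifact injection plants what it claims and nothing else", {
  ref <- generate_reference(1, 10000, 0.35, seed = 51)
  pool <- build_pool(ref, 10, NULL, seed = 52)
  base_cfg <- simulation_config(depth = 120, per_base_error = 0, seed = 53)
  clean <- simulate_reads(pool, base_cfg)

  # identity under an empty artifact spec
  expect_identical(inject_artifacts(clean, list(), seed = 1)$alignments,
                   clean$alignments)

  spec <- list(
    list(kind = "strand_biased_cluster", contig = "contig01",
         position = 3000, width = 10, intensity = 1.0),
    list(kind = "read_end_only", contig = "contig01",
         position = 7000, width = 10, intensity = 1.0))
  art <- inject_artifacts(clean, spec, seed = 54)
  expect_true(all(art$artifacts$realized))
  pu <- build_pileup(art, ref)
  mm <- pu$contigs[[1]]$mismatches

  # strand cluster: mismatches at its sites are forward-only
  sites <- art$artifacts$site[art$artifacts$kind == "strand_biased_cluster"]
  expect_gte(length(sites), 3L)
  for (s in sites) {
    obs <- mm[mm$pos == s, ]
    expect_gt(nrow(obs), 0)
    expect_true(all(obs$strand == "+"))
  }

  # read-end artifact: zero alt observations at mid-read offsets
  obs <- mm[mm$pos == 7000, ]
  expect_gt(nrow(obs), 0)
  expect_true(all(obs$offset < 10))
})

test_that("simulation config validates its arguments", {
  expect_error(simulation_config(depth = 0), "positive")
  expect_error(simulation_config(read_length = 300, mean_fragment = 230),
               "read_length")
  expect_error(simulation_config(per_base_error = 0.6), "per_base_error")
})
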