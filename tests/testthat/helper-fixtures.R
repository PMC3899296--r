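# Fixtures are built in code; medium-cost simulations are cached per test
# run so several test files can share them.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env))
    assign(name, build(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# alignment-table row(s) for hand-built reads (all-M unless cigar given)
manual_read <- function(qname, contig, pos, seq, strand = "+",
                        cigar = paste0(nchar(seq), "M"), qual_char = "I",
                        read1 = TRUE, mapq = 60L) {
  data.frame(qname = qname, read1 = read1, contig = contig, pos = pos,
             strand = strand, mapq = mapq, cigar = cigar, seq = seq,
             qual = strrep(qual_char, nchar(seq)), unmapped = FALSE,
             stringsAsFactors = FALSE)
}

# small reference with a fixed sequence
tiny_reference <- function(seq) new_reference(c(contig01 = seq))

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# transversion-ish alternate for a reference base
other_base <- function(b) chartr("ACGT", "GTAC", b)

# a 100 kb, 285x pooled simulation with SNPs at 5%..95% (20-haplotype
# pool, every planted frequency exactly representable); shared by several
# tests
shared_sim <- function() {
  fixture("shared_sim", function() {
    ref <- generate_reference(1, 1e5, 0.35, seed = 71)
    freqs <- seq(0.05, 0.95, by = 0.05)
    pos <- as.integer(round(seq(2000, 98000, length.out = length(freqs))))
    alt <- other_base(vapply(pos, function(p) substr(ref$seq[[1]], p, p), ""))
    vars <- do.call(rbind, Map(function(p, a, f)
      plant_snp("contig01", p, a, f), pos, alt, freqs))
    pool <- build_pool(ref, 20, vars, seed = 72)
    sim <- simulate_reads(pool, simulation_config(depth = 285, seed = 73))
    pileup <- build_pileup(sim, ref)
    list(ref = ref, pool = pool, sim = sim, pileup = pileup,
         truth = pool_truth(pool))
  })
}

# independent naive pileup recount: walks alignment records in R,
# M/I/D/S cigars, no mate-overlap handling (fixtures avoid overlap)
naive_recount <- function(aln, refseq, min_mapq = 20L, min_baseq = 20L) {
  L <- nchar(refseq)
  counts <- array(0L, dim = c(L, 4, 2),
                  dimnames = list(NULL, c("A", "C", "G", "T"), c("+", "-")))
  for (i in seq_len(nrow(aln))) {
    if (aln$unmapped[i] || aln$mapq[i] < min_mapq) next
    ops <- regmatches(aln$cigar[i], gregexpr("[0-9]+[MIDS]", aln$cigar[i]))[[1]]
    rp <- aln$pos[i]; qp <- 1L
    for (o in ops) {
      len <- as.integer(sub("[MIDS]", "", o))
      op <- sub("[0-9]+", "", o)
      if (op == "M") {
        for (k in 0:(len - 1L)) {
          b <- substr(aln$seq[i], qp + k, qp + k)
          q <- utf8ToInt(substr(aln$qual[i], qp + k, qp + k)) - 33L
          if (b %in% c("A", "C", "G", "T") && q >= min_baseq &&
                rp + k >= 1L && rp + k <= L)
            counts[rp + k, b, aln$strand[i]] <-
              counts[rp + k, b, aln$strand[i]] + 1L
        }
        rp <- rp + len; qp <- qp + len
      } else if (op == "I" || op == "S") qp <- qp + len
      else rp <- rp + len
    }
  }
  counts
}

# counts matrix of a pv_pileup contig reshaped to match naive_recount
pileup_counts_array <- function(pileup, contig = "contig01") {
  cc <- pileup$contigs[[contig]]$counts
  L <- nrow(cc)
  arr <- array(0L, dim = c(L, 4, 2),
               dimnames = list(NULL, c("A", "C", "G", "T"), c("+", "-")))
  for (b in 1:4) {
    arr[, b, 1] <- cc[, (b - 1L) * 2L + 1L]
    arr[, b, 2] <- cc[, (b - 1L) * 2L + 2L]
  }
  arr
}

# strand-summed base counts at one site
base_totals_at <- function(pileup, pos, contig = "contig01") {
  cc <- pileup$contigs[[contig]]$counts[pos, ]
  setNames(cc[c(1, 3, 5, 7)] + cc[c(2, 4, 6, 8)], c("A", "C", "G", "T"))
}

# per-observation log-likelihood oracle: multiplies individual
# observation probabilities in log space, one term per retained base
naive_site_loglik <- function(n_ref, n_alt, f, e) {
  p_alt <- f * (1 - e) + (1 - f) * e / 3
  p_ref <- (1 - f) * (1 - e) + f * e / 3
  ll <- 0
  for (i in seq_len(n_alt)) ll <- ll + log(p_alt)
  for (i in seq_len(n_ref)) ll <- ll + log(p_ref)
  ll
}
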