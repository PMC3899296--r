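fake_call <- function(pos, alt = "G", kind = "snp", contig = "contig01") {
  data.frame(contig = contig, pos = as.integer(pos), ref = "A", alt = alt,
             kind = kind, af = 0.5, alt_count = 20L, total_count = 40L,
             score = 50, grid_freq = 0.5, filter = "",
             founder_status = "unknown", stringsAsFactors = FALSE)
}

# pileup from hand-built reads clustered around position 500:
# `mismatch_sites` get base `alt` planted into covering reads (forward
# only when biased; reads whose site offset is outside `offset_window`
# are skipped when it is set)
context_pileup <- function(refseq, n_fwd = 20, n_rev = 20,
                           mismatch_sites = integer(0), alt = "G",
                           biased = TRUE, offset_window = NULL) {
  rows <- list()
  L <- nchar(refseq)
  for (i in seq_len(n_fwd + n_rev)) {
    fwd <- i <= n_fwd
    p <- 401L + ((i * 7L) %% 100L)
    s <- substr(refseq, p, p + 99)
    for (site in mismatch_sites) {
      q <- site - p + 1L
      if (q < 1L || q > 100L) next
      off <- min(q - 1L, 100L - q)
      if (!is.null(offset_window) && off >= offset_window) next
      if (fwd || !biased) substr(s, q, q) <- alt
    }
    rows[[i]] <- manual_read(paste0("r", i), "contig01", p, s,
                             strand = if (fwd) "+" else "-")
  }
  build_pileup(do.call(rbind, rows), tiny_reference(refseq))
}

test_that("strand-biased G/C mismatch context is flagged", {
  refseq <- paste0(strrep("A", 490), "TTTTTTTTTTTTTTTTTTTT", strrep("A", 490))
  sites <- c(495, 498, 501, 504)     # within +/- 10 bp of 500
  pu <- context_pileup(refseq, mismatch_sites = sites, alt = "G", biased = TRUE)
  flag <- flag_strand_context(fake_call(500), pu, filter_config())
  expect_identical(flag, "STRAND_CTX")
})

test_that("a balanced-strand call with a clean neighborhood passes", {
  refseq <- random_seq(1000, seed = 20)
  substr(refseq, 500, 500) <- "A"
  pu <- context_pileup(refseq, mismatch_sites = 500, alt = "G", biased = FALSE)
  expect_true(is.na(flag_strand_context(fake_call(500), pu, filter_config())))
})

test_that("exact strand test matches a hypergeometric enumeration oracle", {
  # oracle: enumerate all tables with the margins fixed, sum those no more
  # probable than the observed one
  oracle_p <- function(af, ar, tf, tr) {
    k <- af + ar
    tab <- vapply(0:k, function(j)
      choose(tf, j) * choose(tr, k - j) / choose(tf + tr, k), numeric(1))
    obs <- tab[af + 1]
    sum(tab[tab <= obs * (1 + 1e-7)])
  }
  set.seed(21)
  for (i in 1:25) {
    tf <- sample(5:15, 1); tr <- sample(5:15, 1)
    k <- sample(1:min(20, tf + tr), 1)
    af <- sample(0:min(k, tf), 1)
    ar <- min(k - af, tr)
    af <- k - ar   # keep the table consistent with the margins
    if (af > tf) next
    expect_equal(strand_bias_p(af, ar, tf, tr), oracle_p(af, ar, tf, tr),
                 tolerance = 1e-12)
  }
})

test_that("read-end-only alternate support is flagged, uniform support passes", {
  refseq <- random_seq(1000, seed = 22)
  substr(refseq, 500, 500) <- "A"
  pu_end <- context_pileup(refseq, mismatch_sites = 500, alt = "G",
                           biased = FALSE, offset_window = 10L)
  expect_identical(flag_read_position(fake_call(500), pu_end, filter_config()),
                   "READ_POS")
  pu_unif <- context_pileup(refseq, mismatch_sites = 500, alt = "G",
                            biased = FALSE)
  expect_true(is.na(flag_read_position(fake_call(500), pu_unif,
                                       filter_config())))
})

test_that("proximity to large-indel evidence is flagged on a closed interval", {
  refseq <- random_seq(1000, seed = 23)
  pu <- context_pileup(refseq)
  pc <- pu$contigs[[1]]
  pc$clip_lead[520] <- 20L          # strong clip signature at 520
  pu$contigs[[1]] <- pc
  cfg <- filter_config()            # sv_proximity 25
  expect_identical(flag_near_sv(fake_call(515), pu, NULL, cfg), "NEAR_SV")
  expect_identical(flag_near_sv(fake_call(495), pu, NULL, cfg), "NEAR_SV") # 25 bp
  expect_true(is.na(flag_near_sv(fake_call(494), pu, NULL, cfg)))          # 26 bp
  # breakpoint proximity from SV candidates
  svs <- data.frame(contig = "contig01", left_breakpoint = 100L,
                    right_breakpoint = 700L, kind = "deletion",
                    pair_support = 10L, clip_support = 0L,
                    implied_size = 600, refined = FALSE)
  expect_identical(flag_near_sv(fake_call(120), pu, svs, cfg), "NEAR_SV")
})

test_that("founder subtraction annotates without deleting", {
  calls <- rbind(fake_call(100), fake_call(200), fake_call(300))
  founder <- data.frame(contig = "contig01", pos = c(100L, 300L),
                        alt = c("G", "G"), af = c(0.99, 0.03))
  out <- subtract_founder(calls, founder, filter_config())
  expect_identical(out$founder_status, c("in_founder", "novel", "novel"))
  expect_identical(out$pos, calls$pos)
  # empty founder set: unknown, list unchanged
  out2 <- subtract_founder(calls, founder[0, ], filter_config())
  expect_identical(out2$founder_status, rep("unknown", 3))
  out3 <- subtract_founder(calls, NULL, filter_config())
  expect_identical(out3$founder_status, rep("unknown", 3))
})

test_that("filters only annotate and are idempotent", {
  fx <- shared_sim()
  calls <- call_variants(fx$pileup)
  f1 <- apply_filters(calls, fx$pileup)
  f2 <- apply_filters(f1, fx$pileup)
  expect_identical(f1, f2)
  expect_identical(f1$pos, calls$pos)
  expect_identical(f1$af, calls$af)
})

test_that("clean high-frequency variants carry no flags in simulation", {
  fx <- shared_sim()
  calls <- apply_filters(call_variants(fx$pileup), fx$pileup)
  tr <- fx$truth
  m <- match_calls(calls, tr)
  hi <- tr$realized_freq[m$matched$truth_idx] >= 0.10
  expect_true(all(calls$filter[m$matched$call_idx[hi]] == "PASS"))
})

test_that("filter configuration validates its arguments", {
  expect_error(filter_config(end_zone = 0), "end_zone|not")
  expect_error(filter_config(strand_bias_alpha = 1.5), "alpha|not")
  expect_error(filter_config(context_window = -1), "context_window|not")
})
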