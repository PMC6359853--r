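# independent per-window oracles on plain character vectors
gc_oracle <- function(seq_chars, center, w) {
  lo <- max(0L, center - w %/% 2L)
  hi <- min(length(seq_chars), center + w %/% 2L)
  sum(seq_chars[(lo + 1L):hi] %in% c("C", "G"))
}
cpg_oracle <- function(seq_chars, center, w) {
  # a CG whose C sits on the last position inside the window still counts
  lo <- max(0L, center - w %/% 2L)
  hi <- min(length(seq_chars) - 1L, center + w %/% 2L)
  sum(vapply((lo + 1L):hi, function(i) {
    seq_chars[i] == "C" && seq_chars[i + 1L] == "G"
  }, logical(1)))
}

test_that("window GC and CpG counts match naive scans", {
  g_all <- Biostrings::DNAStringSet(c(chrG = strrep("G", 400)))
  expect_equal(as.integer(window_gc(g_all, "chrG", 200)), 200L)
  g_at <- Biostrings::DNAStringSet(c(chrAT = strrep("AT", 200)))
  expect_equal(as.integer(window_gc(g_at, "chrAT", 200)), 0L)
  g_cg <- Biostrings::DNAStringSet(c(c1 = "CGCGCG"))
  expect_equal(as.integer(window_cpg(g_cg, "c1", 3, window_bp = 6)), 3L)
  g_gc <- Biostrings::DNAStringSet(c(c2 = strrep("GC", 100)))
  # "GC" repeats contain CG dinucleotides only at the junctions
  expect_equal(as.integer(window_cpg(g_gc, "c2", 100, window_bp = 10)),
               cpg_oracle(strsplit(strrep("GC", 100), "")[[1]], 100, 10))

  set.seed(31)
  chars <- sample(c("A", "C", "G", "T"), 600, replace = TRUE)
  genome <- Biostrings::DNAStringSet(
    stats::setNames(paste(chars, collapse = ""), "chrR"))
  for (center in c(5L, 100L, 300L, 595L)) {
    expect_equal(as.integer(window_gc(genome, "chrR", center)),
                 gc_oracle(chars, center, 200L))
    expect_equal(as.integer(window_cpg(genome, "chrR", center)),
                 cpg_oracle(chars, center, 200L))
  }
  expect_error(window_gc(genome, "chrR", 600), "outside")
})

test_that("a CG spanning the window edge counts iff its C is inside", {
  # C at position 9 (last inside a [0,10) window), G at 10 (outside)
  chars <- c(rep("A", 9), "C", "G", rep("A", 9))
  genome <- Biostrings::DNAStringSet(
    stats::setNames(paste(chars, collapse = ""), "c"))
  expect_equal(as.integer(window_cpg(genome, "c", 5, window_bp = 10)), 1L)
  # shift the window so the C sits just outside its right edge
  expect_equal(as.integer(window_cpg(genome, "c", 4, window_bp = 10)), 0L)
})

test_that("tolerance intervals reproduce the matching rules", {
  expect_identical(tolerance_interval(80, 0.05, "linear"), c(76, 84))
  expect_identical(tolerance_interval(1000, 0.05, "log10"), c(708, 1413))
  expect_identical(tolerance_interval(0, 0.05, "linear"), c(0, 0))
  expect_error(tolerance_interval(0, 0.05, "log10"), "log10")
})

test_that("distance regimes split at the near-TSS bins and use log10 farther out", {
  near_up <- distance_regime(-40)
  expect_equal(near_up$regime, "near_upstream")
  expect_equal(c(near_up$lo, near_up$hi), c(-100, 0))
  far <- distance_regime(1000)
  expect_equal(far$regime, "far")
  expect_equal(c(far$lo, far$hi), c(708, 1413))
  edge <- distance_regime(100)
  expect_equal(edge$regime, "near_downstream")
  expect_equal(distance_regime(-100)$regime, "near_upstream")
  up_far <- distance_regime(-1000)
  expect_equal(c(up_far$lo, up_far$hi), c(-1413, -708))
})

test_that("a candidate pool of exact duplicates is always fully matched", {
  set.seed(5)
  n <- 20
  # contexts spaced far beyond the 5% tolerances, so each traffic light
  # has exactly its own duplicate as an eligible control
  tl_ctx <- data.frame(chrom = "chr1", pos = seq(1000, by = 500,
                                                 length.out = n),
                       gc = round(50 * 1.2^(seq_len(n) %% 5)),
                       cpg = c(2L, 4L, 8L, 16L, 32L)[seq_len(n) %% 5 + 1L],
                       distance = round(200 * 2^(seq_len(n) %/% 2)) *
                         rep(c(-1L, 1L), n / 2),
                       anchor_gene = "G", sign = sample(c("negative",
                                                          "positive"), n,
                                                        replace = TRUE),
                       has_neg = TRUE, has_pos = TRUE)
  cand <- tl_ctx
  cand$pos <- cand$pos + 7L   # same context, different sites
  cand$has_neg <- cand$sign == "negative"
  cand$has_pos <- cand$sign == "positive"
  reps <- match_background(tl_ctx, cand,
                           matching_criteria(n_replicates = 5, seed = 2))
  expect_true(all(vapply(reps, function(r) all(r$matched), logical(1))))
  expect_equal(nrow(verify_background(reps, cand)), 0L)
})

test_that("matched replicates satisfy every criterion under an independent checker", {
  cfg <- tiny_config(seed = 41, n_samples = 48L)
  gs <- simulate_genome(cfg)
  pr <- simulate_profiles(cfg, gs)
  sites <- sim_sites(pr)
  pairs <- build_pairs(gs$genes, sites)
  tl <- call_traffic_lights(sites, pr$expr, pairs)
  tl_ctx <- site_context(gs$genome, tl$tl_sites, tl$pairs)
  all_key <- paste(sites$sites$chrom, sites$sites$pos)
  tl_key <- paste(tl$tl_sites$chrom, tl$tl_sites$pos)
  cand_tab <- sites$sites[!all_key %in% tl_key, c("chrom", "pos")]
  cand_ctx <- site_context(gs$genome, cand_tab, tl$pairs)
  crit <- matching_criteria(n_replicates = 10, seed = 3)
  reps <- match_background(tl_ctx, cand_ctx, crit)

  # test-local checker, written independently of verify_background
  seqs <- lapply(as.character(gs$genome), function(s) strsplit(s, "")[[1]])
  for (r in reps) {
    m <- r[r$matched, ]
    expect_false(anyDuplicated(paste(m$bg_chrom, m$bg_pos)) > 0)
    expect_false(any(paste(m$bg_chrom, m$bg_pos) %in% tl_key))
    for (i in seq_len(nrow(m))) {
      gc_tl <- gc_oracle(seqs[[m$tl_chrom[i]]], m$tl_pos[i], 200L)
      gc_bg <- gc_oracle(seqs[[m$bg_chrom[i]]], m$bg_pos[i], 200L)
      expect_true(gc_bg >= round(gc_tl * 0.95) &
                    gc_bg <= round(gc_tl * 1.05))
      cpg_tl <- cpg_oracle(seqs[[m$tl_chrom[i]]], m$tl_pos[i], 200L)
      cpg_bg <- cpg_oracle(seqs[[m$bg_chrom[i]]], m$bg_pos[i], 200L)
      expect_true(cpg_bg >= round(cpg_tl * 0.95) &
                    cpg_bg <= round(cpg_tl * 1.05))
      dtl <- m$dist_tl[i]; dbg <- m$dist_bg[i]
      if (dtl >= -100 && dtl < 0) {
        expect_true(dbg >= -100 && dbg <= 0)
      } else if (dtl >= 0 && dtl <= 100) {
        expect_true(dbg >= 0 && dbg <= 100)
      } else {
        expect_equal(sign(dbg), sign(dtl))
        lg <- log10(abs(dtl))
        expect_true(abs(dbg) >= round(10^(0.95 * lg)) - 0.5 &
                      abs(dbg) <= round(10^(1.05 * lg)) + 0.5)
      }
    }
  }
  expect_equal(nrow(verify_background(reps, cand_ctx)), 0L)

  # sign availability: every control has a pair of the required sign
  for (r in reps) {
    m <- r[r$matched, ]
    ck <- paste(m$bg_chrom, m$bg_pos)
    ci <- match(ck, paste(cand_ctx$chrom, cand_ctx$pos))
    avail <- ifelse(m$sign == "negative", cand_ctx$has_neg[ci],
                    cand_ctx$has_pos[ci])
    expect_true(all(avail))
  }

  # GC distributions of TL and background sets stay close on average
  gc_gap <- vapply(reps, function(r) {
    m <- r[r$matched, ]
    abs(mean(m$gc_tl) - mean(m$gc_bg))
  }, numeric(1))
  expect_lte(mean(gc_gap), 0.05 * mean(tl_ctx$gc))
})

test_that("background matching is deterministic under a fixed seed", {
  set.seed(6)
  n <- 15
  ctx <- data.frame(chrom = "chr1", pos = seq_len(n) * 100L,
                    gc = sample(70:90, n, replace = TRUE),
                    cpg = sample(3:10, n, replace = TRUE),
                    distance = sample(300:3000, n), anchor_gene = "G",
                    sign = "positive", has_neg = FALSE, has_pos = TRUE)
  cand <- do.call(rbind, lapply(1:4, function(i) {
    c2 <- ctx
    c2$pos <- c2$pos + i * 7L
    c2
  }))
  crit <- matching_criteria(n_replicates = 4, seed = 11)
  r1 <- match_background(ctx, cand, crit)
  r2 <- match_background(ctx, cand, crit)
  expect_identical(r1, r2)
})

test_that("infeasible matching fails loudly with a diagnostic", {
  ctx <- data.frame(chrom = "chr1", pos = c(100L, 200L), gc = c(80L, 90L),
                    cpg = c(5L, 6L), distance = c(1000, 2000),
                    anchor_gene = "G", sign = "positive", has_neg = FALSE,
                    has_pos = TRUE)
  cand <- ctx
  cand$pos <- cand$pos + 7L
  cand$gc <- c(10L, 200L)   # far outside every tolerance
  expect_error(match_background(ctx, cand, matching_criteria()),
               "infeasible")
})
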