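test_that("site-track overlap uses half-open semantics on the 2 bp CpG", {
  track <- data.frame(chrom = "chr1", start = 10L, end = 20L)
  expect_equal(overlap_count(data.frame(chrom = "chr1", pos = 10L), track),
               1L)
  expect_equal(overlap_count(data.frame(chrom = "chr1", pos = 19L), track),
               1L)
  expect_equal(overlap_count(data.frame(chrom = "chr1", pos = 20L), track),
               0L)
  # the G can reach into the interval even when the C is one base before
  expect_equal(overlap_count(data.frame(chrom = "chr1", pos = 9L), track),
               1L)

  set.seed(51)
  sites <- data.frame(chrom = sample(c("chr1", "chr2"), 1000,
                                     replace = TRUE),
                      pos = sample.int(5000, 1000, replace = TRUE))
  rnd_start <- sample.int(5000, 10)
  rnd <- data.frame(chrom = sample(c("chr1", "chr2"), 10, replace = TRUE),
                    start = rnd_start, end = rnd_start + sample.int(300, 10))
  expect_equal(overlap_count(sites, rnd), overlap_oracle(sites, rnd))
})

test_that("Fisher enrichment matches the hypergeometric tail-sum oracle", {
  expect_equal(fisher.test(matrix(c(8, 2, 2, 8), 2))$p.value,
               fisher_oracle(8, 2, 2, 8), tolerance = 1e-10)
  set.seed(52)
  for (trial in 1:40) {
    tab <- sample(0:10, 4, replace = TRUE)
    if (sum(tab) == 0 || sum(tab[c(1, 3)]) == 0) next
    got <- fisher.test(matrix(tab, 2))$p.value
    want <- fisher_oracle(tab[1], tab[2], tab[3], tab[4])
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("a track covering everything gives fold 1 and p 1", {
  sites <- data.frame(chrom = "chr1", pos = seq(100L, 2000L, by = 100L))
  bg <- list(data.frame(chrom = "chr1", pos = seq(150L, 2050L, by = 100L)))
  track <- data.frame(chrom = "chr1", start = 0L, end = 10000L)
  fe <- fisher_enrichment(sites, bg, track, name = "everything")
  expect_equal(fe$fold, 1)
  expect_equal(fe$p, 1)
  expect_equal(fe$a, nrow(sites))
})

test_that("planted annotation enrichment is recovered near its factor", {
  folds <- vapply(c(61, 62, 63), function(seed) {
    cfg <- simulate_config(seed = seed, n_chromosomes = 2L,
                           chrom_length = 250000L, n_genes = 40L,
                           cpg_density = 0.02, fraction_planted_tl = 0.02,
                           tracks = data.frame(name = "boost", factor = 3,
                                               cover = 0.1),
                           score_tracks = data.frame(name = "cons",
                                                     shift = 1),
                           n_epigenomes = 1L,
                           tfs = data.frame(name = "TFa",
                                            motif_length = 10L,
                                            n_hits = 40L))
    gs <- simulate_genome(cfg)
    pr <- simulate_profiles(cfg, gs)
    tr <- simulate_tracks(cfg, gs, pr)
    sites <- sim_sites(pr)
    pairs <- build_pairs(gs$genes, sites)
    tl <- call_traffic_lights(sites, pr$expr, pairs)
    tl_ctx <- site_context(gs$genome, tl$tl_sites, tl$pairs)
    cand <- sites$sites[!paste(sites$sites$chrom, sites$sites$pos) %in%
                          paste(tl_ctx$chrom, tl_ctx$pos),
                        c("chrom", "pos")]
    cand_ctx <- site_context(gs$genome, cand, tl$pairs)
    bg <- bg_sites(match_background(tl_ctx, cand_ctx,
                                    matching_criteria(n_replicates = 10,
                                                      seed = seed)))
    fisher_enrichment(tl$tl_sites, bg, tr$tracks$boost, "boost")$fold
  }, numeric(1))
  expect_true(mean(folds) >= 2.4 && mean(folds) <= 3.6)
})

test_that("sign-stratified enrichment counts sum to the unstratified counts", {
  set.seed(53)
  tl <- data.frame(chrom = "chr1", pos = sample.int(10000, 60),
                   sign = sample(c("negative", "positive"), 60,
                                 replace = TRUE))
  bg <- list(data.frame(chrom = "chr1", pos = sample.int(10000, 60),
                        sign = sample(c("negative", "positive"), 60,
                                      replace = TRUE)))
  st <- sample.int(10000, 30)
  tracks <- list(t1 = data.frame(chrom = "chr1", start = st,
                                 end = st + 100L))
  enr <- annotation_enrichment(tl, bg, tracks)
  byst <- split(enr, enr$stratum)
  expect_equal(byst$all$a, byst$negative$a + byst$positive$a)
  expect_equal(byst$all$c, byst$negative$c + byst$positive$c)
})

test_that("score thresholds are strict and direction-aware", {
  sites <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L))
  st <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L),
                   score = c(1.9, 2.0, 2.1))
  bg <- list(sites)
  fe <- score_threshold_enrichment(sites, bg, st, threshold = 2)
  expect_equal(fe$a, 1L)      # only 2.1 is strictly greater than 2
  low <- score_threshold_enrichment(sites, bg, st, threshold = 0)
  expect_equal(low$fold, 1)
  expect_equal(low$p, 1)
})

test_that("KS statistic matches the ECDF sweep oracle", {
  expect_equal(ks_two_sample(1:5, 1:5)$D, 0)
  expect_equal(ks_two_sample(1:5, 11:15)$D, 1)
  set.seed(54)
  for (trial in 1:20) {
    a <- rnorm(5)
    b <- rnorm(5, 1)
    expect_equal(ks_two_sample(a, b)$D, ks_oracle(a, b))
  }
  expect_error(ks_two_sample(numeric(0), 1:3), "empty")
})

test_that("state ratio matrix averages defined cells and flags planted states", {
  seg1 <- data.frame(chrom = "chr1", start = c(0L, 500L),
                     end = c(500L, 1000L), state = c("E1", "E2"))
  attr(seg1, "epigenome_id") <- "A"
  attr(seg1, "state_names") <- c("E1", "E2")
  seg2 <- seg1
  attr(seg2, "epigenome_id") <- "B"
  tl <- data.frame(chrom = "chr1", pos = c(100L, 200L, 600L, 700L))
  bg1 <- data.frame(chrom = "chr1", pos = c(150L, 250L, 650L, 800L))
  srm <- state_ratio_matrix(tl, list(bg1), list(seg1, seg2))
  expect_equal(unname(srm$ratio["E1", ]), c(1, 1))
  expect_equal(unname(srm$state_average), c(1, 1))
  # per-state average is the arithmetic mean over epigenomes
  bg2 <- data.frame(chrom = "chr1", pos = c(150L, 650L, 800L, 850L))
  srm2 <- state_ratio_matrix(tl, list(bg2),
                             list(seg1, seg2))
  expect_equal(unname(srm2$state_average["E2"]),
               mean(srm2$ratio["E2", ]))

  cfg <- tiny_config(seed = 71, n_samples = 48L, enrich_prob = 0.9)
  gs <- simulate_genome(cfg)
  pr <- simulate_profiles(cfg, gs)
  tr <- simulate_tracks(cfg, gs, pr)
  planted <- pr$manifest[, c("chrom", "pos")]
  others <- pr$sites[!paste(pr$sites$chrom, pr$sites$pos) %in%
                       paste(planted$chrom, planted$pos), ]
  set.seed(1)
  bg <- list(others[sample.int(nrow(others), nrow(planted)), ])
  srm3 <- state_ratio_matrix(planted, bg, tr$segmentations)
  expect_equal(names(which.max(srm3$state_average)), cfg$enriched_state)
})

test_that("gene-set enrichment matches the exhaustive hypergeometric oracle", {
  universe <- sprintf("g%02d", 1:20)
  tl_genes <- universe[1:8]
  gene_set <- universe[c(1:5, 15:18)]
  res <- gene_set_enrichment(tl_genes, universe, list(s = gene_set))
  expect_equal(res$expected, 9 * 8 / 20)
  obs <- res$observed
  expect_equal(res$fold, obs / (9 * 8 / 20))
  expect_equal(res$p, fisher_oracle(obs, 8 - obs, 9 - obs, 20 - 8 - 9 + obs),
               tolerance = 1e-8)
  # disjoint set
  res0 <- gene_set_enrichment(tl_genes, universe,
                              list(s = universe[15:20]))
  expect_equal(res0$observed, 0L)
  expect_equal(res0$fold, 0)
  # Bonferroni multiplies by the number of sets tested
  res2 <- gene_set_enrichment(tl_genes, universe,
                              list(a = gene_set, b = universe[9:14]))
  expect_equal(res2$p_bonferroni, pmin(1, res2$p * 2))
  expect_error(gene_set_enrichment(tl_genes, character(0), list(s = "x")),
               "empty")
})

test_that("TFBS offsets are strand-normalized with the CpG's 5' base", {
  # enumerated oracle: a CpG at plus-coordinate offset o inside a minus
  # hit of length L reports offset L - 2 - o
  hit_m <- data.frame(chrom = "chr1", start = 100L, end = 110L, tf = "T1",
                      strand = "-", motif_length = 10L)
  for (o in 0:8) {
    prof <- tfbs_position_profile(data.frame(chrom = "chr1",
                                             pos = 100L + o),
                                  list(data.frame(chrom = "chr1",
                                                  pos = 1L)),
                                  hit_m, shore_bp = 5L)
    expect_equal(prof$offset[prof$tl_count > 0], 10L - 2L - o)
  }
  # half-open shores on a plus hit: start - shore included, end + shore out
  hit_p <- data.frame(chrom = "chr1", start = 100L, end = 110L, tf = "T1",
                      strand = "+", motif_length = 10L)
  at_start <- tfbs_position_profile(data.frame(chrom = "chr1", pos = 95L),
                                    list(data.frame(chrom = "chr1",
                                                    pos = 1L)),
                                    hit_p, shore_bp = 5L)
  expect_equal(sum(at_start$tl_count), 1000 / 1)
  expect_equal(at_start$offset[at_start$tl_count > 0], -5L)
  past_end <- tfbs_position_profile(data.frame(chrom = "chr1", pos = 115L),
                                    list(data.frame(chrom = "chr1",
                                                    pos = 1L)),
                                    hit_p, shore_bp = 5L)
  expect_equal(sum(past_end$tl_count), 0)
})

test_that("position profiles are invariant under translation and global strand flip", {
  set.seed(55)
  hits <- data.frame(chrom = "chr1",
                     start = sort(sample.int(5000, 12)) + 0L,
                     tf = "T1", strand = sample(c("+", "-"), 12,
                                                replace = TRUE),
                     motif_length = 10L)
  hits$end <- hits$start + 10L
  tl <- data.frame(chrom = "chr1", pos = sample.int(5100, 200))
  bg <- list(data.frame(chrom = "chr1", pos = sample.int(5100, 200)))
  base <- tfbs_position_profile(tl, bg, hits, shore_bp = 20L)

  shift <- 1234L
  base_t <- tfbs_position_profile(
    transform(tl, pos = pos + shift),
    list(transform(bg[[1]], pos = pos + shift)),
    transform(hits, start = start + shift, end = end + shift),
    shore_bp = 20L)
  expect_equal(base_t, base)

  # flipping every hit's strand reverses each profile up to the 2 bp
  # CpG footprint: counts are conserved in total
  flip <- transform(hits, strand = ifelse(strand == "+", "-", "+"))
  base_f <- tfbs_position_profile(tl, bg, flip, shore_bp = 20L)
  expect_equal(sum(base_f$tl_count), sum(base$tl_count))
})

test_that("planted TFBS placements dominate the profile at the recorded offset", {
  cfg <- tiny_config(seed = 81, tfbs_planted_fraction = 0.9)
  gs <- simulate_genome(cfg)
  pr <- simulate_profiles(cfg, gs)
  tr <- simulate_tracks(cfg, gs, pr)
  planted <- pr$manifest[, c("chrom", "pos")]
  others <- pr$sites[!paste(pr$sites$chrom, pr$sites$pos) %in%
                       paste(planted$chrom, planted$pos), ]
  set.seed(2)
  bg <- list(others[sample.int(nrow(others), nrow(planted)), ])
  prof <- tfbs_position_profile(planted, bg, tr$tfbs, shore_bp = 50L,
                                tf = "TFa")
  expect_equal(prof$offset[which.max(prof$tl_count)], cfg$tfbs_offset)
})

test_that("per-TF summaries flag TFs with no CpG and are deterministic", {
  tl <- data.frame(chrom = "chr1", pos = c(100L, 300L))
  bg <- list(data.frame(chrom = "chr1", pos = c(150L, 350L)))
  hits <- data.frame(chrom = "chr1",
                     start = c(90L, 290L, 4000L, 4100L),
                     end = c(100L, 300L, 4010L, 4110L),
                     tf = c("near", "near", "far", "far"),
                     strand = "+", motif_length = 10L)
  s <- tf_scatter_summary(tl, bg, hits)
  expect_true(s$no_cpg[s$tf == "far"])
  expect_identical(s, tf_scatter_summary(tl, bg, hits))
})
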