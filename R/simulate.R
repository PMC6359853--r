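# Deterministic synthetic-data generator: a small genome with genes on both
# strands, CpG sites at a controlled density, per-sample beta-value and
# expression profiles with a minority of planted CpG-gene couplings, and
# annotation / score / chromatin-state / TFBS tracks enriched at the planted
# sites.  A ground-truth manifest records everything that was planted.

#' Build a simulation configuration
#'
#' Defaults describe the study conditions the pipeline targets: 48 samples,
#' beta values in `[0,1]` with 20% per-cell missingness, sites kept only when
#' at least 20 values are defined, RPKM-like log-normal expression, planted
#' CpG-gene couplings at |Spearman| 0.9 with an even sign mix.
#'
#' @param seed Integer seed; a fixed seed makes every emitted artifact
#'   byte-identical across runs.
#' @param n_chromosomes,chrom_length Genome shape (all chromosomes share one
#'   length, in bp).
#' @param base_composition Named probabilities for A/C/G/T.
#' @param cpg_density Target fraction of positions that start a CpG.
#' @param n_genes Number of genes (split evenly over chromosomes).
#' @param gene_length,intergenic_gap Ranges (bp) for gene lengths and gaps.
#' @param upstream_bp Pairing window upstream of the TSS.
#' @param n_samples Number of samples (k); `min_defined <= n_samples <= 48`
#'   for traffic-light calling.
#' @param fraction_planted_tl Fraction of CpGs given a planted coupling.
#' @param planted_effect_rho Target |Spearman| of planted pairs, in (0,1].
#' @param planted_sign_mix Fraction of planted pairs with negative sign.
#' @param missingness_rate Per-cell probability that a beta value is missing.
#' @param min_defined Minimum defined values for a site to be retained.
#' @param expr_meanlog,expr_sdlog Log-normal expression parameters.
#' @param coverage_mean Mean per-strand read coverage for the count dialect.
#' @param min_strand_cov Strand coverage threshold the count dialect is
#'   generated to exercise.
#' @param replicates Replicates per sample in the count dialect.
#' @param cpg_per_promoter When set, exactly this many CpGs are injected in
#'   each gene's promoter (used by the promoter-average comparison design).
#' @param plant_per_gene When `TRUE`, exactly one promoter CpG per gene is
#'   planted (instead of `fraction_planted_tl` genome-wide).
#' @param promoter_bounds Strand-aware promoter window around the TSS.
#' @param tracks data.frame (`name`, `factor`, `cover`): annotation tracks
#'   with planted enrichment factor `f` and background cover fraction `q`
#'   (planted sites fall inside with probability `f * q`).
#' @param score_tracks data.frame (`name`, `shift`): per-base score tracks;
#'   planted sites draw from a normal shifted by `shift`.
#' @param n_epigenomes,n_states,enriched_state,enrich_prob Chromatin-state
#'   segmentations; segments containing a planted site are relabelled to
#'   `enriched_state` with probability `enrich_prob`.
#' @param tfs data.frame (`name`, `motif_length`, `n_hits`) of TFBS tracks.
#' @param tfbs_planted_fraction Fraction of planted sites placed inside a
#'   TFBS hit at `tfbs_offset`.
#' @param tfbs_offset Motif offset (0-based, 5' of the motif) at which
#'   planted sites sit inside their TFBS hit.
#' @return A validated list of class `sim_config`.
#' @export
simulate_config <- function(seed = 1L,
                            n_chromosomes = 2L,
                            chrom_length = 250000L,
                            base_composition = c(A = 0.3, C = 0.2,
                                                 G = 0.2, T = 0.3),
                            cpg_density = 0.01,
                            n_genes = 40L,
                            gene_length = c(2000L, 6000L),
                            intergenic_gap = c(1000L, 4000L),
                            upstream_bp = 10000L,
                            n_samples = 48L,
                            fraction_planted_tl = 0.01,
                            planted_effect_rho = 0.9,
                            planted_sign_mix = 0.5,
                            missingness_rate = 0.2,
                            min_defined = 20L,
                            expr_meanlog = 1,
                            expr_sdlog = 1.5,
                            coverage_mean = 30,
                            min_strand_cov = 4L,
                            replicates = 1L,
                            cpg_per_promoter = NULL,
                            plant_per_gene = FALSE,
                            promoter_bounds = c(-1000L, 500L),
                            tracks = data.frame(
                              name = c("enhancer", "open_chromatin",
                                       "neutral"),
                              factor = c(3, 2, 1),
                              cover = c(0.10, 0.15, 0.20)),
                            score_tracks = data.frame(
                              name = c("conservation", "functional"),
                              shift = c(1, 0.5)),
                            n_epigenomes = 3L,
                            n_states = 5L,
                            enriched_state = "E2",
                            enrich_prob = 0.6,
                            tfs = data.frame(
                              name = c("TF1", "TF2"),
                              motif_length = c(10L, 12L),
                              n_hits = c(150L, 150L)),
                            tfbs_planted_fraction = 0.3,
                            tfbs_offset = 4L) {
  cfg <- as.list(environment())
  fracs <- c(cpg_density, fraction_planted_tl, planted_sign_mix,
             missingness_rate, tfbs_planted_fraction, enrich_prob)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0,1]")
  if (!(planted_effect_rho > 0 && planted_effect_rho <= 1)) {
    stop("planted_effect_rho must lie in (0, 1]")
  }
  if (n_samples < min_defined) stop("n_samples must be >= min_defined")
  if (any(tracks$factor * tracks$cover > 1)) {
    stop("track enrichment factor * cover exceeds 1")
  }
  if (tfbs_offset < 0 || tfbs_offset > min(tfs$motif_length) - 2L) {
    stop("tfbs_offset must leave the full CpG inside every motif")
  }
  stopifnot(abs(sum(base_composition) - 1) < 1e-8)
  structure(cfg, class = "sim_config")
}

# Scan a character vector of bases for CG dinucleotide starts (0-based).
scan_cpg_chars <- function(chars) {
  n <- length(chars)
  which(chars[-n] == "C" & chars[-1L] == "G") - 1L
}

#' Simulate a genome with genes and CpG sites
#'
#' Generates random chromosome sequences, adjusts the CpG dinucleotide count
#' toward `cpg_density`, lays out non-overlapping genes on both strands, and
#' guarantees at least one CpG inside every gene's pairing window (injecting
#' one near the TSS when needed).  When `cpg_per_promoter` is set, that many
#' CpGs are written into each promoter at distinct offsets.
#'
#' @param config A [simulate_config()] object.
#' @return List with `genome` ([Biostrings::DNAStringSet]), `genes`
#'   (data.frame: `gene_id`, `chrom`, `start`, `end`, `strand`, `tss`,
#'   `end3`; 0-based half-open interval, `tss`/`end3` 0-based positions),
#'   and `cpgs` (data.frame `chrom`, `pos` of every CpG's C).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_chrom <- config$n_chromosomes
  len <- config$chrom_length
  chrom_names <- paste0("chr", seq_len(n_chrom))
  bases <- names(config$base_composition)

  chrom_seqs <- vector("list", n_chrom)
  names(chrom_seqs) <- chrom_names
  for (ci in seq_len(n_chrom)) {
    chars <- sample(bases, len, replace = TRUE,
                    prob = config$base_composition)
    # push the CG dinucleotide count toward the configured density
    cg <- scan_cpg_chars(chars)
    target <- round(config$cpg_density * len)
    if (length(cg) > target) {
      kill <- sample(cg, length(cg) - target)
      chars[kill + 2L] <- sample(c("A", "T"), length(kill), replace = TRUE)
    } else if (length(cg) < target) {
      free <- setdiff(seq.int(1L, len - 2L), c(cg, cg + 1L))
      add <- sample(free, min(target - length(cg), length(free)))
      chars[add + 1L] <- "C"
      chars[add + 2L] <- "G"
    }
    chrom_seqs[[ci]] <- chars
  }

  # genes laid out sequentially with random gaps, round-robin chromosomes
  per_chrom <- rep(config$n_genes %/% n_chrom, n_chrom)
  extra <- config$n_genes %% n_chrom
  if (extra > 0) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L
  genes <- list()
  gid <- 0L
  for (ci in seq_len(n_chrom)) {
    cursor <- config$upstream_bp + 500L
    for (g in seq_len(per_chrom[ci])) {
      gap <- round(runif(1, config$intergenic_gap[1], config$intergenic_gap[2]))
      glen <- round(runif(1, config$gene_length[1], config$gene_length[2]))
      start <- cursor + gap
      end <- start + glen
      if (end + config$upstream_bp + 500L > len) {
        stop("chrom_length too small to place ", per_chrom[ci],
             " genes on ", chrom_names[ci])
      }
      strand <- sample(c("+", "-"), 1L)
      gid <- gid + 1L
      genes[[gid]] <- data.frame(
        gene_id = sprintf("G%03d", gid), chrom = chrom_names[ci],
        start = start, end = end, strand = strand,
        tss = if (strand == "+") start else end - 1L,
        end3 = if (strand == "+") end - 1L else start,
        stringsAsFactors = FALSE)
      cursor <- end
    }
  }
  genes <- do.call(rbind, genes)

  inject <- function(chrom, pos) {
    chars <- chrom_seqs[[chrom]]
    if (pos < 0L || pos + 2L > length(chars)) return(invisible(NULL))
    chars[pos + 1L] <- "C"
    chars[pos + 2L] <- "G"
    chrom_seqs[[chrom]] <<- chars
  }

  if (!is.null(config$cpg_per_promoter)) {
    pb <- config$promoter_bounds
    offsets_all <- seq.int(pb[1], pb[2] - 2L, by = 3L)
    for (i in seq_len(nrow(genes))) {
      off <- sort(sample(offsets_all, config$cpg_per_promoter))
      pos <- if (genes$strand[i] == "+") genes$tss[i] + off else
        genes$tss[i] - off
      for (p in pos) inject(genes$chrom[i], p)
    }
  }

  rescan <- function() {
    do.call(rbind, lapply(chrom_names, function(cn) {
      data.frame(chrom = cn, pos = scan_cpg_chars(chrom_seqs[[cn]]),
                 stringsAsFactors = FALSE)
    }))
  }
  cpgs <- rescan()

  # every gene must have >= 1 CpG inside its pairing window
  for (i in seq_len(nrow(genes))) {
    w <- gene_window(genes[i, ], config$upstream_bp)
    on_chr <- cpgs$pos[cpgs$chrom == genes$chrom[i]]
    if (!any(on_chr >= w[1] & on_chr <= w[2])) {
      p <- if (genes$strand[i] == "+") genes$tss[i] + 10L else
        genes$tss[i] - 10L
      inject(genes$chrom[i], p)
    }
  }
  cpgs <- rescan()

  genome <- Biostrings::DNAStringSet(
    vapply(chrom_seqs, paste0, character(1), collapse = ""))
  names(genome) <- chrom_names
  list(genome = genome, genes = genes, cpgs = cpgs, config = config)
}

# strand-aware pairing window [lo, hi] on 0-based C positions
gene_window <- function(gene, upstream_bp) {
  if (gene$strand == "+") {
    c(gene$tss - upstream_bp, gene$end3)
  } else {
    c(gene$end3, gene$tss + upstream_bp)
  }
}

#' Simulate methylation and expression profiles with planted couplings
#'
#' Expression is log-normal per gene and sample.  Non-planted CpGs draw
#' beta values from a bimodal Beta mixture, independent of all expression.
#' A planted pair couples the CpG's beta values to the gene's expression
#' ranks through a latent bivariate-normal link whose correlation is chosen
#' (Greiner's relation, `r = 2 sin(pi rho / 6)`) so the realized |Spearman|
#' concentrates at `planted_effect_rho`; at target 1 the link is exactly
#' monotone and the realized coefficient is exactly +/- 1.  Per-cell
#' missingness is applied afterwards and sites left with fewer than
#' `min_defined` values are dropped (never imputed); the manifest is
#' restricted to retained sites.
#'
#' @param config A [simulate_config()] object.
#' @param genome_sim Result of [simulate_genome()].
#' @return List with `sites` (chrom, pos), `beta` (sites x samples, `NA`
#'   for missing), `beta_full` (pre-missingness, used by the count dialect),
#'   `expr` (genes x samples RPKM-like), `samples`, and `manifest` -- a
#'   data.frame of planted pairs (`chrom`, `pos`, `gene_id`, `sign`,
#'   `rho_target`).
#' @export
simulate_profiles <- function(config, genome_sim) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  genes <- genome_sim$genes
  cpgs <- genome_sim$cpgs
  k <- config$n_samples
  samples <- sprintf("S%02d", seq_len(k))

  expr <- matrix(rlnorm(nrow(genes) * k, config$expr_meanlog,
                        config$expr_sdlog),
                 nrow = nrow(genes), ncol = k,
                 dimnames = list(genes$gene_id, samples))

  pairs0 <- build_pairs(genes, cpgs, upstream_bp = config$upstream_bp,
                        promoter_bounds = config$promoter_bounds)

  if (isTRUE(config$plant_per_gene)) {
    prom <- pairs0[pairs0$region == "promoter", , drop = FALSE]
    if (!all(genes$gene_id %in% prom$gene_id)) {
      stop("plant_per_gene requires a promoter CpG for every gene; ",
           "set cpg_per_promoter")
    }
    sel <- unlist(lapply(split(seq_len(nrow(prom)), prom$gene_id),
                         function(ix) ix[sample.int(length(ix), 1L)]))
    planted <- prom[sel, c("site_idx", "gene_id")]
  } else {
    paired_sites <- unique(pairs0$site_idx)
    n_pl <- round(config$fraction_planted_tl * nrow(cpgs))
    if (n_pl > length(paired_sites)) {
      stop("infeasible: ", n_pl, " planted sites requested but only ",
           length(paired_sites), " CpGs fall inside a pairing window")
    }
    sel_sites <- sample(paired_sites, n_pl)
    gene_of <- vapply(sel_sites, function(s) {
      cand <- pairs0[pairs0$site_idx == s, , drop = FALSE]
      cand$gene_id[which.min(abs(cand$distance))]
    }, character(1))
    planted <- data.frame(site_idx = sel_sites, gene_id = gene_of,
                          stringsAsFactors = FALSE)
  }
  n_pl <- nrow(planted)
  planted$sign <- ifelse(runif(n_pl) < config$planted_sign_mix, -1L, 1L)

  n_cpg <- nrow(cpgs)
  hi <- runif(n_cpg * k) < 0.7
  beta <- matrix(ifelse(hi, rbeta(n_cpg * k, 8, 2), rbeta(n_cpg * k, 2, 8)),
                 nrow = n_cpg, ncol = k)
  colnames(beta) <- samples

  rho <- config$planted_effect_rho
  r <- 2 * sin(pi * rho / 6)
  for (i in seq_len(n_pl)) {
    e <- expr[planted$gene_id[i], ]
    u <- qnorm((rank(e, ties.method = "average") - 0.5) / k)
    u <- (u - mean(u)) / stats::sd(u)
    z <- planted$sign[i] * r * u + sqrt(max(0, 1 - r^2)) * rnorm(k)
    beta[planted$site_idx[i], ] <- pnorm(z)
  }

  beta_full <- beta
  if (config$missingness_rate > 0) {
    mask <- matrix(runif(n_cpg * k) < config$missingness_rate, n_cpg, k)
    beta[mask] <- NA_real_
  }
  keep <- rowSums(!is.na(beta)) >= config$min_defined
  new_idx <- cumsum(keep)
  planted <- planted[keep[planted$site_idx], , drop = FALSE]
  planted$site_idx <- new_idx[planted$site_idx]

  sites <- cpgs[keep, , drop = FALSE]
  rownames(sites) <- NULL
  manifest <- data.frame(chrom = sites$chrom[planted$site_idx],
                         pos = sites$pos[planted$site_idx],
                         gene_id = planted$gene_id,
                         sign = planted$sign,
                         rho_target = rep(rho, nrow(planted)),
                         stringsAsFactors = FALSE)
  list(sites = sites,
       beta = beta[keep, , drop = FALSE],
       beta_full = beta_full[keep, , drop = FALSE],
       expr = expr, samples = samples, manifest = manifest,
       config = config)
}

#' Emit the strand-resolved count dialect for simulated profiles
#'
#' Produces a long table (`chrom`, `pos`, `sample`, `replicate`, `fwd_cov`,
#' `fwd_meth`, `rev_cov`, `rev_meth`) consistent with the profiles: cells
#' that are defined in the beta matrix receive coverage of at least
#' `min_strand_cov` on both strands in every replicate, missing cells get
#' sub-threshold coverage on one strand, so [filter_calls()] reconstructs
#' exactly the simulated missingness pattern.
#'
#' @param profiles Result of [simulate_profiles()].
#' @param config The same [simulate_config()].
#' @return Long data.frame in the count dialect.
#' @export
profiles_to_counts <- function(profiles, config) {
  set.seed(config$seed + 3L)
  n <- nrow(profiles$sites)
  k <- length(profiles$samples)
  reps <- config$replicates
  defined <- !is.na(profiles$beta)
  N <- n * k * reps
  site_i <- rep(rep(seq_len(n), times = k), times = reps)
  samp_i <- rep(rep(seq_len(k), each = n), times = reps)
  rep_i <- rep(seq_len(reps), each = n * k)
  def <- defined[cbind(site_i, samp_i)]
  bfull <- profiles$beta_full[cbind(site_i, samp_i)]

  lam <- config$coverage_mean
  fwd <- rpois(N, lam)
  rev <- rpois(N, lam)
  mc <- config$min_strand_cov
  fwd[def] <- pmax(fwd[def], mc)
  rev[def] <- pmax(rev[def], mc)
  # undefined cells: force one strand under the threshold
  low_on_fwd <- runif(N) < 0.5
  nd_f <- !def & low_on_fwd
  nd_r <- !def & !low_on_fwd
  fwd[nd_f] <- sample(0:(mc - 1L), sum(nd_f), replace = TRUE)
  rev[nd_r] <- sample(0:(mc - 1L), sum(nd_r), replace = TRUE)

  data.frame(chrom = profiles$sites$chrom[site_i],
             pos = profiles$sites$pos[site_i],
             sample = profiles$samples[samp_i],
             replicate = rep_i,
             fwd_cov = fwd, fwd_meth = rbinom(N, fwd, bfull),
             rev_cov = rev, rev_meth = rbinom(N, rev, bfull),
             stringsAsFactors = FALSE)
}

#' Simulate annotation, score, chromatin-state and TFBS tracks
#'
#' Each annotation track covers a background fraction `q` of the genome and
#' contains each planted site with probability `f * q` (Bernoulli per site;
#' background intervals keep clear of planted sites so the planting
#' probability is exact).  Tracks with `f = 1` are built with no reference
#' to planted sites at all.  Score tracks give every CpG a standard-normal
#' score, shifted by `shift` at planted sites.  Segmentations tile each
#' chromosome; segments holding a planted site are relabelled to the
#' enriched state with probability `enrich_prob`.  TFBS hits are placed so
#' a `tfbs_planted_fraction` subset of planted sites sits at motif offset
#' `tfbs_offset` (strand-normalized); remaining hits are random.
#'
#' @param config A [simulate_config()] object.
#' @param genome_sim Result of [simulate_genome()].
#' @param profiles Result of [simulate_profiles()].
#' @return List with `tracks` (named list of interval data.frames),
#'   `scores` (named list of score data.frames), `segmentations` (list of
#'   labelled interval data.frames with `epigenome_id`/`state_names`
#'   attributes), `tfbs` (hit data.frame) and `manifest` (planted track
#'   factors, score shifts, TFBS placements, enriched state).
#' @export
simulate_tracks <- function(config, genome_sim, profiles) {
  set.seed(config$seed + 2L)
  chrom_names <- names(genome_sim$genome)
  clen <- stats::setNames(Biostrings::width(genome_sim$genome), chrom_names)
  planted <- profiles$manifest
  n_pl <- nrow(planted)

  w_pl <- 50L   # width of the interval dropped onto a selected planted site
  w_bg <- 500L  # width of background cover intervals

  site_covered <- function(df, cn, p) {
    any(df$chrom == cn & df$start < p + 2L & df$end > p)
  }
  make_track <- function(f, q) {
    if (f * q > 1) stop("planted cover probability f*q exceeds 1")
    df <- do.call(rbind, lapply(chrom_names, function(cn) {
      n_iv <- round(q * clen[[cn]] / w_bg)
      starts <- sample.int(clen[[cn]] - w_bg, n_iv)
      data.frame(chrom = cn, start = starts, end = starts + w_bg,
                 stringsAsFactors = FALSE)
    }))
    if (f != 1 && n_pl > 0) {
      # per planted site an exact Bernoulli(f*q): add a covering marker
      # when the draw demands coverage, punch the 2 bp footprint out of
      # every overlapping interval when it demands none
      want <- runif(n_pl) < f * q
      add <- which(want & !vapply(seq_len(n_pl), function(i) {
        site_covered(df, planted$chrom[i], planted$pos[i])
      }, logical(1)))
      if (length(add)) {
        df <- rbind(df, data.frame(
          chrom = planted$chrom[add],
          start = pmax(0L, planted$pos[add] - w_pl %/% 2L),
          end = planted$pos[add] + w_pl %/% 2L,
          stringsAsFactors = FALSE))
      }
      for (i in which(!want)) {
        p <- planted$pos[i]
        cn <- planted$chrom[i]
        ov <- which(df$chrom == cn & df$start < p + 2L & df$end > p)
        if (length(ov) == 0L) next
        pieces <- do.call(rbind, lapply(ov, function(j) {
          keep <- list()
          if (df$start[j] < p) {
            keep[[1L]] <- data.frame(chrom = cn, start = df$start[j],
                                     end = p, stringsAsFactors = FALSE)
          }
          if (df$end[j] > p + 2L) {
            keep[[length(keep) + 1L]] <-
              data.frame(chrom = cn, start = p + 2L, end = df$end[j],
                         stringsAsFactors = FALSE)
          }
          if (length(keep)) do.call(rbind, keep) else NULL
        }))
        df <- rbind(df[-ov, , drop = FALSE], pieces)
      }
    }
    df <- df[order(df$chrom, df$start), , drop = FALSE]
    rownames(df) <- NULL
    df
  }

  tracks <- lapply(seq_len(nrow(config$tracks)), function(i) {
    make_track(config$tracks$factor[i], config$tracks$cover[i])
  })
  names(tracks) <- config$tracks$name

  is_planted <- paste(profiles$sites$chrom, profiles$sites$pos) %in%
    paste(planted$chrom, planted$pos)
  scores <- lapply(seq_len(nrow(config$score_tracks)), function(i) {
    data.frame(chrom = profiles$sites$chrom, pos = profiles$sites$pos,
               score = rnorm(nrow(profiles$sites)) +
                 config$score_tracks$shift[i] * is_planted,
               stringsAsFactors = FALSE)
  })
  names(scores) <- config$score_tracks$name

  state_names <- paste0("E", seq_len(config$n_states))
  segmentations <- lapply(seq_len(config$n_epigenomes), function(e) {
    seg <- do.call(rbind, lapply(chrom_names, function(cn) {
      brks <- c(0L, sort(sample.int(clen[[cn]] - 1L,
                                    round(clen[[cn]] / 2000))), clen[[cn]])
      data.frame(chrom = cn, start = brks[-length(brks)], end = brks[-1L],
                 state = sample(state_names, length(brks) - 1L,
                                replace = TRUE),
                 stringsAsFactors = FALSE)
    }))
    if (n_pl > 0) {
      hit <- runif(n_pl) < config$enrich_prob
      for (i in which(hit)) {
        j <- which(seg$chrom == planted$chrom[i] &
                     seg$start <= planted$pos[i] & seg$end > planted$pos[i])
        seg$state[j] <- config$enriched_state
      }
    }
    attr(seg, "epigenome_id") <- sprintf("EPI%02d", e)
    attr(seg, "state_names") <- state_names
    seg
  })

  # TFBS: planted placements at the recorded offset, plus random hits
  tf_tab <- config$tfs
  placed <- data.frame()
  hits <- list()
  if (n_pl > 0 && config$tfbs_planted_fraction > 0) {
    sel <- which(runif(n_pl) < config$tfbs_planted_fraction)
    if (length(sel)) {
      tf_i <- sample.int(nrow(tf_tab), length(sel), replace = TRUE)
      strand <- sample(c("+", "-"), length(sel), replace = TRUE)
      o <- config$tfbs_offset
      len <- tf_tab$motif_length[tf_i]
      start <- ifelse(strand == "+", planted$pos[sel] - o,
                      planted$pos[sel] + 2L + o - len)
      ok <- start >= 0 &
        start + len <= clen[planted$chrom[sel]]
      sel <- sel[ok]; tf_i <- tf_i[ok]; strand <- strand[ok]
      start <- start[ok]; len <- len[ok]
      hits[[1L]] <- data.frame(chrom = planted$chrom[sel], start = start,
                               end = start + len, tf = tf_tab$name[tf_i],
                               strand = strand, motif_length = len,
                               stringsAsFactors = FALSE)
      placed <- data.frame(chrom = planted$chrom[sel], pos = planted$pos[sel],
                           tf = tf_tab$name[tf_i], offset = o,
                           stringsAsFactors = FALSE)
    }
  }
  rand_hits <- do.call(rbind, lapply(seq_len(nrow(tf_tab)), function(i) {
    cn <- sample(chrom_names, tf_tab$n_hits[i], replace = TRUE)
    start <- vapply(cn, function(c1) {
      sample.int(clen[[c1]] - tf_tab$motif_length[i] - 1L, 1L)
    }, integer(1))
    data.frame(chrom = cn, start = start,
               end = start + tf_tab$motif_length[i],
               tf = tf_tab$name[i],
               strand = sample(c("+", "-"), tf_tab$n_hits[i], replace = TRUE),
               motif_length = tf_tab$motif_length[i],
               stringsAsFactors = FALSE)
  }))
  tfbs <- do.call(rbind, c(hits, list(rand_hits)))
  rownames(tfbs) <- NULL

  list(tracks = tracks, scores = scores, segmentations = segmentations,
       tfbs = tfbs,
       manifest = list(tracks = config$tracks,
                       scores = config$score_tracks,
                       tfbs_planted = placed,
                       enriched_state = config$enriched_state))
}

#' Simulate a complete dataset
#'
#' Runs [simulate_genome()], [simulate_profiles()], [profiles_to_counts()]
#' and [simulate_tracks()] under one seed and bundles the results with a
#' combined ground-truth manifest.
#'
#' @param config A [simulate_config()] object.
#' @param counts Also emit the strand-resolved count dialect.
#' @return List of class `cpgtl_sim`.
#' @export
simulate_dataset <- function(config, counts = TRUE) {
  gs <- simulate_genome(config)
  pr <- simulate_profiles(config, gs)
  tr <- simulate_tracks(config, gs, pr)
  structure(list(
    genome = gs$genome, genes = gs$genes,
    sites = pr$sites, beta = pr$beta, expr = pr$expr,
    samples = pr$samples,
    counts = if (counts) profiles_to_counts(pr, config) else NULL,
    tracks = tr$tracks, scores = tr$scores,
    segmentations = tr$segmentations, tfbs = tr$tfbs,
    manifest = c(list(planted = pr$manifest), tr$manifest),
    config = config), class = "cpgtl_sim")
}

#' Write a simulated dataset to disk in the formats the readers consume
#'
#' @param sim A `cpgtl_sim` object from [simulate_dataset()].
#' @param outdir Output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_dataset <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outdir, ...)
  Biostrings::writeXStringSet(sim$genome, p("genome.fa"))
  write_tsv(sim$genes, p("genes.tsv"))
  beta_df <- cbind(sim$sites, as.data.frame(sim$beta))
  write.table(beta_df, p("methylation_beta.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(sim$counts)) {
    write.table(sim$counts, p("methylation_counts.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  expr_df <- data.frame(gene_id = rownames(sim$expr), sim$expr,
                        check.names = FALSE)
  write.table(expr_df, p("expression.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (nm in names(sim$tracks)) {
    write_bed(sim$tracks[[nm]], p(paste0("track_", nm, ".bed")))
  }
  for (nm in names(sim$scores)) {
    write.table(sim$scores[[nm]], p(paste0("score_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (seg in sim$segmentations) {
    df <- data.frame(chrom = seg$chrom, start = seg$start, end = seg$end,
                     name = seg$state)
    write_bed(df, p(paste0("segmentation_",
                           attr(seg, "epigenome_id"), ".bed")))
  }
  tf_df <- data.frame(chrom = sim$tfbs$chrom, start = sim$tfbs$start,
                      end = sim$tfbs$end, name = sim$tfbs$tf, score = 0,
                      strand = sim$tfbs$strand,
                      motif_length = sim$tfbs$motif_length)
  write_bed(tf_df, p("tfbs.bed"))
  write_tsv(sim$manifest$planted, p("manifest_planted.tsv"))
  jsonlite::write_json(sim$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  yaml::write_yaml(unclass(sim$config)[!vapply(sim$config, is.data.frame,
                                               logical(1))],
                   p("config.yaml"))
  invisible(outdir)
}
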