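# Traffic-light vs background comparison statistics: annotation overlap
# Fisher tests, score-threshold enrichment, two-sample KS on score
# distributions, chromatin-state ratio matrices, gene-set enrichment, and
# per-position TFBS profiles.

#' Count sites overlapping an annotation track
#'
#' A CpG site (the 2 bp interval starting at the C) counts when it
#' intersects any interval of the track (half-open semantics: a site whose
#' C sits at the interval end is outside, one whose C is at the last base
#' inside counts).
#'
#' @param sites data.frame with `chrom`, `pos` (0-based C positions).
#' @param track data.frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return Integer count of overlapping sites.
#' @export
overlap_count <- function(sites, track) {
  if (nrow(sites) == 0L || nrow(track) == 0L) return(0L)
  hits <- GenomicRanges::countOverlaps(cpg_to_granges(sites$chrom,
                                                      sites$pos),
                                       intervals_to_granges(track))
  sum(hits > 0L)
}

#' Fisher enrichment of traffic lights over background in a track
#'
#' Background counts are computed per replicate; the rounded mean count
#' enters the 2x2 Fisher table (the replicate standard deviation is
#' reported separately, mirroring the mean +/- SD whisker convention).
#'
#' @param tl_sites data.frame (`chrom`, `pos`) of traffic lights.
#' @param bg_replicates list of background site data.frames
#'   ([bg_sites()]).
#' @param track Annotation track ([read_bed()] or simulated).
#' @param name Annotation label for the result row.
#' @return One-row data.frame: `annotation`, `a` (TL in), `b` (TL out),
#'   `c` (mean BG in, rounded), `d`, `fold` (TL fraction / BG fraction),
#'   `odds_ratio`, `p` (two-sided Fisher), `bg_sd`.
#' @export
fisher_enrichment <- function(tl_sites, bg_replicates, track,
                              name = attr(track, "name")) {
  if (nrow(tl_sites) == 0L) stop("empty traffic-light set")
  stopifnot(length(bg_replicates) >= 1L)
  a <- overlap_count(tl_sites, track)
  b <- nrow(tl_sites) - a
  cin <- vapply(bg_replicates, overlap_count, numeric(1), track = track)
  ntot <- vapply(bg_replicates, nrow, numeric(1))
  cc <- round(mean(cin))
  d <- round(mean(ntot - cin))
  ft <- fisher.test(matrix(c(a, b, cc, d), nrow = 2L))
  fold <- if (cc > 0) (a / (a + b)) / (cc / (cc + d)) else NA_real_
  data.frame(annotation = if (is.null(name)) NA_character_ else name,
             a = a, b = b, c = cc, d = d, fold = fold,
             odds_ratio = unname(ft$estimate), p = ft$p.value,
             bg_sd = if (length(cin) > 1L) stats::sd(cin) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Annotation enrichment battery with sign stratification
#'
#' Runs [fisher_enrichment()] for each track over all traffic lights and,
#' when a `sign` column is present, separately for the negatively and
#' positively correlating subsets (with the matching background subsets).
#'
#' @param tl_sites Traffic-light table with optional `sign` column.
#' @param bg_replicates list of background tables (with `sign` when
#'   stratifying).
#' @param tracks Named list of annotation tracks.
#' @return data.frame of [fisher_enrichment()] rows with a `stratum`
#'   column (`all`, `negative`, `positive`).
#' @export
annotation_enrichment <- function(tl_sites, bg_replicates, tracks) {
  strata <- list(all = function(df) df)
  if (!is.null(tl_sites$sign)) {
    strata$negative <- function(df) df[df$sign == "negative", , drop = FALSE]
    strata$positive <- function(df) df[df$sign == "positive", , drop = FALSE]
  }
  rows <- list()
  for (nm in names(tracks)) {
    for (st in names(strata)) {
      tl_s <- strata[[st]](tl_sites)
      bg_s <- lapply(bg_replicates, strata[[st]])
      if (nrow(tl_s) == 0L) next
      row <- fisher_enrichment(tl_s, bg_s, tracks[[nm]], name = nm)
      row$stratum <- st
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

# score lookup by (chrom, pos); NA where undefined
site_scores <- function(score_track, sites) {
  score_track$score[match(paste(sites$chrom, sites$pos),
                          paste(score_track$chrom, score_track$pos))]
}

#' Enrichment of sites exceeding a score threshold
#'
#' "Inside" means the site's score is strictly greater than `threshold`
#' (or strictly less, for `direction = "less"`).  Sites with no defined
#' score are excluded from the table and tallied.
#'
#' @param tl_sites,bg_replicates As in [fisher_enrichment()].
#' @param score_track data.frame `chrom`, `pos`, `score`
#'   ([read_score_track()]).
#' @param threshold Score threshold (strict inequality).
#' @param direction `"greater"` or `"less"`.
#' @param name Label for the result row.
#' @return One-row data.frame as [fisher_enrichment()], plus
#'   `n_tl_undefined`, `n_bg_undefined` (mean over replicates).
#' @export
score_threshold_enrichment <- function(tl_sites, bg_replicates, score_track,
                                       threshold, direction = c("greater",
                                                                "less"),
                                       name = "score") {
  direction <- match.arg(direction)
  cmp <- if (direction == "greater") `>` else `<`
  s_tl <- site_scores(score_track, tl_sites)
  if (all(is.na(s_tl))) stop("no traffic light has a defined score")
  a <- sum(cmp(s_tl, threshold), na.rm = TRUE)
  b <- sum(!is.na(s_tl)) - a
  stats_bg <- vapply(bg_replicates, function(bg) {
    s <- site_scores(score_track, bg)
    c(inside = sum(cmp(s, threshold), na.rm = TRUE),
      defined = sum(!is.na(s)), undef = sum(is.na(s)))
  }, numeric(3))
  cc <- round(mean(stats_bg["inside", ]))
  d <- round(mean(stats_bg["defined", ] - stats_bg["inside", ]))
  ft <- fisher.test(matrix(c(a, b, cc, d), nrow = 2L))
  fold <- if (cc > 0) (a / (a + b)) / (cc / (cc + d)) else NA_real_
  data.frame(annotation = name, a = a, b = b, c = cc, d = d, fold = fold,
             odds_ratio = unname(ft$estimate), p = ft$p.value,
             bg_sd = if (ncol(stats_bg) > 1L) stats::sd(stats_bg["inside", ])
             else NA_real_,
             n_tl_undefined = sum(is.na(s_tl)),
             n_bg_undefined = mean(stats_bg["undef", ]),
             stringsAsFactors = FALSE)
}

#' Two-sample Kolmogorov-Smirnov comparison of score distributions
#'
#' @param scores_a,scores_b Non-empty numeric samples (`NA` dropped).
#' @return List: `D` (sup of the ECDF difference), `p` (two-sided
#'   asymptotic).
#' @export
ks_two_sample <- function(scores_a, scores_b) {
  scores_a <- scores_a[!is.na(scores_a)]
  scores_b <- scores_b[!is.na(scores_b)]
  if (length(scores_a) == 0L || length(scores_b) == 0L) {
    stop("empty sample in KS comparison")
  }
  kt <- suppressWarnings(ks.test(scores_a, scores_b))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Traffic-light / background ratio per chromatin state and epigenome
#'
#' Cell (state, epigenome) holds the traffic-light count in that state
#' divided by the mean background count over replicates; cells with zero
#' mean background count are undefined and excluded from the per-state
#' average over epigenomes.  Absolute traffic-light counts are carried
#' alongside.
#'
#' @param tl_sites,bg_replicates As in [fisher_enrichment()].
#' @param segmentations List of segmentation data.frames
#'   ([read_segmentation()] or simulated), each with `epigenome_id` and
#'   `state_names` attributes.
#' @return List of class `state_ratio_matrix`: `ratio` (states x
#'   epigenomes), `tl_count` (same shape), `state_average` (mean defined
#'   ratio per state).
#' @export
state_ratio_matrix <- function(tl_sites, bg_replicates, segmentations) {
  if (length(segmentations) == 0L) stop("no epigenomes supplied")
  states <- attr(segmentations[[1L]], "state_names")
  epis <- vapply(segmentations, attr, character(1), "epigenome_id")
  assign_states <- function(sites, seg) {
    ov <- GenomicRanges::findOverlaps(
      GenomicRanges::GRanges(sites$chrom,
                             IRanges::IRanges(sites$pos + 1L, width = 1L)),
      intervals_to_granges(seg))
    st <- rep(NA_character_, nrow(sites))
    st[S4Vectors::queryHits(ov)] <- seg$state[S4Vectors::subjectHits(ov)]
    st
  }
  ratio <- tl_count <- matrix(NA_real_, length(states), length(epis),
                              dimnames = list(states, epis))
  for (e in seq_along(segmentations)) {
    seg <- segmentations[[e]]
    tl_tab <- table(factor(assign_states(tl_sites, seg), levels = states))
    bg_tab <- vapply(bg_replicates, function(bg) {
      as.numeric(table(factor(assign_states(bg, seg), levels = states)))
    }, numeric(length(states)))
    bg_mean <- rowMeans(bg_tab)
    tl_count[, e] <- as.numeric(tl_tab)
    r <- as.numeric(tl_tab) / bg_mean
    r[bg_mean == 0] <- NA_real_
    ratio[, e] <- r
  }
  structure(list(ratio = ratio, tl_count = tl_count,
                 state_average = rowMeans(ratio, na.rm = TRUE)),
            class = "state_ratio_matrix")
}

#' Fold enrichment as observed over expected
#'
#' @param observed Observed count.
#' @param expected Expected count under the null.
#' @return `observed / expected` (`NA` when `expected` is 0).
#' @export
fold_enrichment <- function(observed, expected) {
  ifelse(expected > 0, observed / expected, NA_real_)
}

#' Gene-set enrichment of traffic-light genes
#'
#' For each gene set, tests whether genes harbouring a traffic light are
#' over-represented: `expected = |set in universe| * |TL genes| /
#' |universe|`, fold = observed / expected, two-sided Fisher exact p on
#' the in-set/out-set x TL/non-TL table, Bonferroni over the number of
#' sets tested.
#'
#' @param tl_genes Character vector of traffic-light gene ids (subset of
#'   `universe`).
#' @param universe Character vector of all genes in the analysis.
#' @param gene_sets Named list of character vectors (intersected with the
#'   universe before testing).
#' @return data.frame: `set`, `set_size`, `observed`, `expected`, `fold`,
#'   `p`, `p_bonferroni`.
#' @export
gene_set_enrichment <- function(tl_genes, universe, gene_sets) {
  if (length(universe) == 0L) stop("empty gene universe")
  tl_genes <- intersect(tl_genes, universe)
  n_sets <- length(gene_sets)
  rows <- lapply(names(gene_sets), function(nm) {
    set_u <- intersect(gene_sets[[nm]], universe)
    obs <- length(intersect(tl_genes, set_u))
    exp_ <- length(set_u) * length(tl_genes) / length(universe)
    tab <- matrix(c(obs, length(tl_genes) - obs,
                    length(set_u) - obs,
                    length(universe) - length(tl_genes) -
                      length(set_u) + obs), nrow = 2L)
    p <- fisher.test(tab)$p.value
    data.frame(set = nm, set_size = length(set_u), observed = obs,
               expected = exp_,
               fold = if (exp_ > 0) obs / exp_ else NA_real_,
               p = p, p_bonferroni = min(1, p * n_sets),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# strand-normalized motif offset of a CpG's C within a hit: 0 is the
# motif's 5' position; the CpG occupies 2 bp, so on the minus strand the
# offset of its 5' base after reversal is (len - 2) - (pos - start)
motif_offset <- function(pos, start, end, strand) {
  ifelse(strand == "+", pos - start, (end - 2L) - pos)
}

#' Per-position traffic-light / background profile within TFBS and shores
#'
#' Projects each CpG overlapping a hit's window (`shore_bp` on both sides
#' of the motif, in motif coordinates: offsets `-shore .. len + shore - 1`)
#' to its strand-normalized motif offset, and reports per-offset
#' traffic-light counts, mean background counts over replicates, and
#' their ratio.  Counts are normalized per 1000 hits.
#'
#' @param tl_sites,bg_replicates Site tables as in [fisher_enrichment()].
#' @param tfbs_hits data.frame from [read_tfbs()] (`chrom`, `start`,
#'   `end`, `tf`, `strand`, `motif_length`).
#' @param shore_bp Shore width (typically 50 or 100).
#' @param tf Restrict to one TF (default: one profile per TF present).
#' @return data.frame: `tf`, `offset`, `tl_count`, `bg_mean`, `ratio`
#'   (`NA` where the mean background count is 0), counts per 1000 hits.
#' @export
tfbs_position_profile <- function(tl_sites, bg_replicates, tfbs_hits,
                                  shore_bp = 100L, tf = NULL) {
  tfs <- if (is.null(tf)) unique(tfbs_hits$tf) else tf
  rows <- lapply(tfs, function(t1) {
    hits <- tfbs_hits[tfbs_hits$tf == t1, , drop = FALSE]
    len <- unique(hits$motif_length)
    if (length(len) != 1L) {
      stop("inconsistent motif lengths for TF ", t1)
    }
    offsets <- seq.int(-shore_bp, len + shore_bp - 1L)
    count_profile <- function(sites) {
      if (nrow(sites) == 0L) return(numeric(length(offsets)))
      win <- GenomicRanges::GRanges(
        hits$chrom,
        IRanges::IRanges(start = hits$start - shore_bp - 1L,
                         end = hits$end + shore_bp + 2L))
      ov <- GenomicRanges::findOverlaps(
        GenomicRanges::GRanges(sites$chrom,
                               IRanges::IRanges(sites$pos + 1L,
                                                width = 1L)), win)
      si <- S4Vectors::queryHits(ov)
      hi <- S4Vectors::subjectHits(ov)
      off <- motif_offset(sites$pos[si], hits$start[hi], hits$end[hi],
                          hits$strand[hi])
      off <- off[off >= -shore_bp & off < len + shore_bp]
      tabulate(off + shore_bp + 1L, nbins = length(offsets))
    }
    tl_c <- count_profile(tl_sites) * 1000 / nrow(hits)
    bg_c <- rowMeans(vapply(bg_replicates, count_profile,
                            numeric(length(offsets)))) * 1000 / nrow(hits)
    data.frame(tf = t1, offset = offsets, tl_count = tl_c, bg_mean = bg_c,
               ratio = ifelse(bg_c > 0, tl_c / bg_c, NA_real_),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-TF enrichment summary within exact TFBS intervals
#'
#' One row per TF: overall traffic-light / background ratio and Fisher p
#' within the exact motif intervals (no shores).  TFs whose hits contain
#' no CpG at all are flagged with an undefined ratio.
#'
#' @param tl_sites,bg_replicates,tfbs_hits As in
#'   [tfbs_position_profile()].
#' @return data.frame: `tf`, `n_hits`, `a`..`d`, `fold`, `odds_ratio`,
#'   `p`, `bg_sd`, `no_cpg` flag.
#' @export
tf_scatter_summary <- function(tl_sites, bg_replicates, tfbs_hits) {
  rows <- lapply(unique(tfbs_hits$tf), function(t1) {
    hits <- tfbs_hits[tfbs_hits$tf == t1, c("chrom", "start", "end")]
    fe <- fisher_enrichment(tl_sites, bg_replicates, hits, name = t1)
    no_cpg <- fe$a == 0L && fe$c == 0L
    data.frame(tf = t1, n_hits = nrow(hits), fe[, -1L, drop = FALSE],
               no_cpg = no_cpg, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
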