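# Construction of matched background CpG sets: for every traffic-light CpG,
# a control CpG with similar local GC content, similar CpG content, similar
# (signed, log-scaled) distance to the TSS of its associated gene, and a
# correlation of the same sign with at least one associated gene.  The
# selection is repeated n_replicates times.

#' Matching criteria for background construction
#'
#' @param window_bp Width of the sequence window centred on the CpG.
#' @param gc_tolerance,cpg_tolerance Fractional tolerance on the GC and
#'   CpG counts of the window.
#' @param near_tss_bp Width of the near-TSS distance bins.
#' @param distance_tolerance Fractional tolerance on `log10(distance)` for
#'   sites farther than `near_tss_bp` from the TSS.
#' @param require_sign_match Require the control to correlate with the
#'   same sign as the traffic light.
#' @param n_replicates Number of background replicates.
#' @param seed Seed for the replicate sampling.
#' @return List of class `matching_criteria`.
#' @export
matching_criteria <- function(window_bp = 200L, gc_tolerance = 0.05,
                              cpg_tolerance = 0.05, near_tss_bp = 100L,
                              distance_tolerance = 0.05,
                              require_sign_match = TRUE,
                              n_replicates = 50L, seed = 1L) {
  stopifnot(window_bp > 0L, window_bp %% 2L == 0L,
            gc_tolerance > 0, gc_tolerance < 1,
            cpg_tolerance > 0, cpg_tolerance < 1,
            distance_tolerance > 0, distance_tolerance < 1)
  structure(as.list(environment()), class = "matching_criteria")
}

# clamp a 0-based window [lo, hi) to one chromosome; used by both window
# statistics so their truncation behaviour is identical
window_bounds <- function(chrom_len, center_pos, window_bp) {
  lo <- center_pos - window_bp %/% 2L
  hi <- center_pos + window_bp %/% 2L
  c(max(0L, lo), min(chrom_len, hi), lo < 0L || hi > chrom_len)
}

#' GC count in a window centred on a CpG
#'
#' Counts C plus G bases in the `window_bp` window centred on the given
#' 0-based position (the CpG's C).  Windows truncated by a chromosome end
#' are clamped and flagged via the `"truncated"` attribute.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param chrom Chromosome name.
#' @param center_pos 0-based position of the CpG's C.
#' @param window_bp Window width.
#' @return Integer count of C+G bases.
#' @export
window_gc <- function(genome, chrom, center_pos, window_bp = 200L) {
  len <- Biostrings::width(genome[chrom])
  if (center_pos < 0L || center_pos >= len) stop("center outside genome")
  wb <- window_bounds(len, center_pos, window_bp)
  v <- Biostrings::subseq(genome[[chrom]], wb[1] + 1L, wb[2])
  n <- as.integer(Biostrings::letterFrequency(v, letters = "CG"))
  attr(n, "truncated") <- as.logical(wb[3])
  n
}

#' CpG dinucleotide count in a window centred on a CpG
#'
#' Counts CG dinucleotides whose C lies inside the window (a CG spanning
#' the right window edge is counted; one whose C precedes the window is
#' not).
#'
#' @inheritParams window_gc
#' @return Integer count of CG dinucleotides.
#' @export
window_cpg <- function(genome, chrom, center_pos, window_bp = 200L) {
  len <- Biostrings::width(genome[chrom])
  if (center_pos < 0L || center_pos >= len) stop("center outside genome")
  wb <- window_bounds(len, center_pos, window_bp)
  hi <- min(len, wb[2] + 1L)   # one extra base so an edge-spanning CG counts
  v <- Biostrings::subseq(genome[[chrom]], wb[1] + 1L, hi)
  n <- Biostrings::countPattern("CG", v)
  attr(n, "truncated") <- as.logical(wb[3])
  n
}

# vectorized window statistics over many sites (same semantics as the
# scalar functions, no truncation attribute)
window_stats <- function(genome, chrom, pos, window_bp = 200L) {
  gc <- integer(length(pos))
  cpg <- integer(length(pos))
  for (cn in unique(chrom)) {
    ii <- which(chrom == cn)
    len <- Biostrings::width(genome[cn])
    lo <- pmax(0L, pos[ii] - window_bp %/% 2L)
    hi <- pmin(len, pos[ii] + window_bp %/% 2L)
    v <- Biostrings::Views(genome[[cn]], start = lo + 1L, end = hi)
    gc[ii] <- as.integer(Biostrings::letterFrequency(v, letters = "CG"))
    v2 <- Biostrings::Views(genome[[cn]], start = lo + 1L,
                            end = pmin(len, hi + 1L))
    cpg[ii] <- Biostrings::vcountPattern("CG", v2)
  }
  data.frame(gc = gc, cpg = cpg)
}

#' Tolerance interval for a matched quantity
#'
#' The interval of integer values within a fractional tolerance of
#' `value`: on the linear scale `[round(v(1-f)), round(v(1+f))]`; on the
#' log10 scale the tolerance applies to `log10(value)`, i.e.
#' `[round(10^((1-f) log10 v)), round(10^((1+f) log10 v))]`.
#'
#' @param value Non-negative number (at least 1 on the log10 scale).
#' @param frac Fractional tolerance.
#' @param scale `"linear"` or `"log10"`.
#' @return Integer vector `c(lo, hi)`.
#' @export
#' @examples
#' tolerance_interval(80, 0.05, "linear")   # 76..84
#' tolerance_interval(1000, 0.05, "log10")  # 708..1413
tolerance_interval <- function(value, frac = 0.05,
                               scale = c("linear", "log10")) {
  scale <- match.arg(scale)
  stopifnot(value >= 0)
  if (scale == "linear") {
    c(round(value * (1 - frac)), round(value * (1 + frac)))
  } else {
    if (value < 1) stop("log10 scale requires value >= 1")
    lg <- log10(value)
    c(round(10^((1 - frac) * lg)), round(10^((1 + frac) * lg)))
  }
}

#' Distance-matching regime for a signed TSS distance
#'
#' Sites within `near_tss_bp` of the TSS are matched within the same
#' near-TSS bin (`[-near, 0]` upstream, `[0, near]` downstream; a distance
#' of exactly 0 falls in the downstream bin).  Farther sites are matched
#' on `log10(|distance|)` within `frac` tolerance, on the same side of
#' the TSS.
#'
#' @param signed_distance Strand-aware signed distance to the TSS
#'   (negative = upstream).
#' @param near_tss_bp Near-TSS bin width.
#' @param frac Fractional tolerance on `log10(distance)` in the far
#'   regime.
#' @return List: `regime` (`"near_upstream"`, `"near_downstream"`,
#'   `"far"`), `lo`, `hi` -- signed bounds a control's distance must fall
#'   in (inclusive).
#' @export
distance_regime <- function(signed_distance, near_tss_bp = 100L,
                            frac = 0.05) {
  d <- signed_distance
  if (d >= -near_tss_bp && d < 0) {
    list(regime = "near_upstream", lo = -near_tss_bp, hi = 0L)
  } else if (d >= 0 && d <= near_tss_bp) {
    list(regime = "near_downstream", lo = 0L, hi = near_tss_bp)
  } else {
    iv <- tolerance_interval(abs(d), frac, "log10")
    if (d < 0) {
      list(regime = "far", lo = -iv[2], hi = -iv[1])
    } else {
      list(regime = "far", lo = iv[1], hi = iv[2])
    }
  }
}

#' Genomic and correlation context for matching
#'
#' Precomputes, for a set of CpG sites, the quantities the matching
#' criteria compare: window GC and CpG counts, the signed distance to the
#' TSS of the site's anchor gene (the gene of its most significant pair),
#' the sign of that anchor correlation, and whether the site has any
#' negatively / positively correlated associated gene.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param site_table data.frame with `chrom`, `pos` for the sites of
#'   interest.
#' @param pair_results The `pairs` component of a `tl_result` (per-pair
#'   `rho`, `p`, `distance`).
#' @param window_bp Window width for the sequence statistics.
#' @return data.frame: `chrom`, `pos`, `gc`, `cpg`, `distance`,
#'   `anchor_gene`, `sign`, `has_neg`, `has_pos`.
#' @export
site_context <- function(genome, site_table, pair_results,
                         window_bp = 200L) {
  key <- paste(site_table$chrom, site_table$pos)
  pr_key <- paste(pair_results$chrom, pair_results$pos)
  ws <- window_stats(genome, site_table$chrom, site_table$pos, window_bp)
  ord <- order(pr_key, pair_results$p)
  pr <- pair_results[ord, , drop = FALSE]
  first <- !duplicated(paste(pr$chrom, pr$pos))
  anchor <- pr[first, , drop = FALSE]
  ai <- match(key, paste(anchor$chrom, anchor$pos))
  has_neg <- tapply(pair_results$rho < 0, pr_key, any)
  has_pos <- tapply(pair_results$rho > 0, pr_key, any)
  data.frame(chrom = site_table$chrom, pos = site_table$pos,
             gc = ws$gc, cpg = ws$cpg,
             distance = anchor$distance[ai],
             anchor_gene = anchor$gene_id[ai],
             sign = ifelse(anchor$rho[ai] < 0, "negative", "positive"),
             has_neg = as.logical(has_neg[key]),
             has_pos = as.logical(has_pos[key]),
             stringsAsFactors = FALSE)
}

#' Construct matched background replicates
#'
#' For each replicate, traffic lights are visited in random order and each
#' receives a uniformly random control among the candidates that pass all
#' criteria (GC count, CpG count, distance regime, correlation sign when
#' required) and have not been used earlier in that replicate (sampling
#' without replacement within a replicate, with replacement across
#' replicates).  Unmatched traffic lights are flagged, never dropped.
#'
#' @param tl_ctx Context table ([site_context()]) for the traffic lights.
#' @param cand_ctx Context table for the candidate (non-TL) CpGs.
#' @param criteria A [matching_criteria()] object.
#' @return List of class `bg_replicates`: one data.frame per replicate
#'   (`tl_chrom`, `tl_pos`, `bg_chrom`, `bg_pos`, the compared values for
#'   both sites, `sign`, `matched`), with the criteria attached as an
#'   attribute.
#' @export
match_background <- function(tl_ctx, cand_ctx, criteria = matching_criteria()) {
  stopifnot(inherits(criteria, "matching_criteria"))
  n_tl <- nrow(tl_ctx)
  if (n_tl == 0L) stop("empty traffic-light set")
  # drop candidates that are themselves traffic lights
  overlap <- paste(cand_ctx$chrom, cand_ctx$pos) %in%
    paste(tl_ctx$chrom, tl_ctx$pos)
  cand <- cand_ctx[!overlap, , drop = FALSE]

  gc_iv <- t(vapply(tl_ctx$gc, tolerance_interval, numeric(2),
                    frac = criteria$gc_tolerance, scale = "linear"))
  cpg_iv <- t(vapply(tl_ctx$cpg, tolerance_interval, numeric(2),
                     frac = criteria$cpg_tolerance, scale = "linear"))
  dr <- lapply(tl_ctx$distance, distance_regime,
               near_tss_bp = criteria$near_tss_bp,
               frac = criteria$distance_tolerance)
  d_lo <- vapply(dr, `[[`, numeric(1), "lo")
  d_hi <- vapply(dr, `[[`, numeric(1), "hi")

  eligible <- lapply(seq_len(n_tl), function(i) {
    ok <- cand$gc >= gc_iv[i, 1] & cand$gc <= gc_iv[i, 2] &
      cand$cpg >= cpg_iv[i, 1] & cand$cpg <= cpg_iv[i, 2] &
      cand$distance >= d_lo[i] & cand$distance <= d_hi[i]
    if (criteria$require_sign_match) {
      ok <- ok & if (tl_ctx$sign[i] == "negative") cand$has_neg else
        cand$has_pos
    }
    which(ok)
  })
  n_elig <- lengths(eligible)
  if (mean(n_elig == 0L) > 0.5) {
    tab <- table(cut(n_elig, c(-1, 0, 1, 5, 20, Inf),
                     labels = c("0", "1", "2-5", "6-20", ">20")))
    stop("matching infeasible for ", sum(n_elig == 0L), " of ", n_tl,
         " traffic lights; eligible-candidate histogram: ",
         paste(names(tab), tab, sep = "=", collapse = ", "))
  }

  set.seed(criteria$seed)
  reps <- vector("list", criteria$n_replicates)
  for (r in seq_len(criteria$n_replicates)) {
    used <- logical(nrow(cand))
    bg_idx <- rep(NA_integer_, n_tl)
    for (i in sample.int(n_tl)) {
      el <- eligible[[i]]
      el <- el[!used[el]]
      if (length(el) == 0L) next
      pick <- el[sample.int(length(el), 1L)]
      bg_idx[i] <- pick
      used[pick] <- TRUE
    }
    matched <- !is.na(bg_idx)
    reps[[r]] <- data.frame(
      replicate = r,
      tl_chrom = tl_ctx$chrom, tl_pos = tl_ctx$pos,
      bg_chrom = ifelse(matched, cand$chrom[bg_idx], NA_character_),
      bg_pos = ifelse(matched, cand$pos[bg_idx], NA_integer_),
      gc_tl = tl_ctx$gc, gc_bg = ifelse(matched, cand$gc[bg_idx], NA),
      cpg_tl = tl_ctx$cpg, cpg_bg = ifelse(matched, cand$cpg[bg_idx], NA),
      dist_tl = tl_ctx$distance,
      dist_bg = ifelse(matched, cand$distance[bg_idx], NA),
      sign = tl_ctx$sign, matched = matched,
      stringsAsFactors = FALSE)
  }
  structure(reps, class = "bg_replicates", criteria = criteria)
}

#' Extract the background site tables from matched replicates
#'
#' @param replicates A `bg_replicates` object.
#' @return List of data.frames (`chrom`, `pos`, `sign`), one per
#'   replicate, containing only the matched controls.
#' @export
bg_sites <- function(replicates) {
  lapply(replicates, function(r) {
    m <- r[r$matched, , drop = FALSE]
    data.frame(chrom = m$bg_chrom, pos = m$bg_pos, sign = m$sign,
               stringsAsFactors = FALSE)
  })
}

#' Re-validate matched background replicates
#'
#' Checks every (traffic light, control) pair in every replicate against
#' all criteria, recomputing the tolerance intervals and distance regimes
#' from the reported values, and checks the without-replacement contract.
#'
#' @param replicates A `bg_replicates` object.
#' @param cand_ctx Candidate context table used in matching (for the sign
#'   availability check); optional.
#' @return data.frame of violations (empty when sound).
#' @export
verify_background <- function(replicates, cand_ctx = NULL) {
  criteria <- attr(replicates, "criteria")
  out <- list()
  for (r in replicates) {
    m <- r[r$matched, , drop = FALSE]
    if (nrow(m) == 0L) next
    for (i in seq_len(nrow(m))) {
      bad <- character()
      giv <- tolerance_interval(m$gc_tl[i], criteria$gc_tolerance, "linear")
      if (m$gc_bg[i] < giv[1] || m$gc_bg[i] > giv[2]) bad <- c(bad, "gc")
      civ <- tolerance_interval(m$cpg_tl[i], criteria$cpg_tolerance,
                                "linear")
      if (m$cpg_bg[i] < civ[1] || m$cpg_bg[i] > civ[2]) bad <- c(bad, "cpg")
      dr <- distance_regime(m$dist_tl[i], criteria$near_tss_bp,
                            criteria$distance_tolerance)
      if (m$dist_bg[i] < dr$lo || m$dist_bg[i] > dr$hi) {
        bad <- c(bad, "distance")
      }
      if (criteria$require_sign_match && !is.null(cand_ctx)) {
        j <- which(cand_ctx$chrom == m$bg_chrom[i] &
                     cand_ctx$pos == m$bg_pos[i])
        avail <- if (m$sign[i] == "negative") cand_ctx$has_neg[j] else
          cand_ctx$has_pos[j]
        if (!isTRUE(avail)) bad <- c(bad, "sign")
      }
      if (length(bad)) {
        out[[length(out) + 1L]] <- data.frame(
          replicate = m$replicate[i], tl_chrom = m$tl_chrom[i],
          tl_pos = m$tl_pos[i], failed = paste(bad, collapse = "+"),
          stringsAsFactors = FALSE)
      }
    }
    key <- paste(m$bg_chrom, m$bg_pos)
    if (anyDuplicated(key)) {
      out[[length(out) + 1L]] <- data.frame(
        replicate = m$replicate[1L], tl_chrom = NA, tl_pos = NA,
        failed = "duplicate_control", stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(replicate = integer(), tl_chrom = character(),
               tl_pos = integer(), failed = character())
}
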