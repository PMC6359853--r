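# Per-pair Spearman correlation, BH adjustment over the declared pair
# universe, traffic-light calling, region-average comparison, and the
# permutation null.

# cache of permutation index matrices for the exact small-k p-value
.perm_cache <- new.env(parent = emptyenv())

perm_matrix <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  gen <- function(v) {
    if (length(v) == 1L) return(matrix(v, 1L, 1L))
    do.call(rbind, lapply(seq_along(v), function(i) {
      cbind(v[i], gen(v[-i]))
    }))
  }
  m <- gen(seq_len(n))
  .perm_cache[[key]] <- m
  m
}

#' Spearman correlation between a methylation and an expression profile
#'
#' Midrank (average-rank) Spearman coefficient over pairwise-complete
#' samples.  The two-sided p-value uses the exact permutation distribution
#' (full enumeration over k! orderings) for `k_used <= exact_max`, and the
#' t approximation `t = rho * sqrt((k-2)/(1-rho^2))` with `k-2` degrees of
#' freedom otherwise.  Pairs with fewer than `min_k` complete samples, or a
#' zero-variance profile, are not tested; the reason is reported.
#'
#' @param meth,expr Numeric profiles over the same samples (`NA` allowed in
#'   either).
#' @param min_k Minimum pairwise-complete samples for a valid result.
#' @param exact_max Largest `k_used` for which the exact enumeration
#'   p-value is used.
#' @return List: `rho`, `p`, `k_used`, `reason` (`NA` when valid,
#'   otherwise `"k_below_min"` or `"zero_variance"`).
#' @export
spearman_test <- function(meth, expr, min_k = 20L, exact_max = 9L) {
  stopifnot(length(meth) == length(expr))
  ok <- !is.na(meth) & !is.na(expr)
  k <- sum(ok)
  if (k < min_k) {
    return(list(rho = NA_real_, p = NA_real_, k_used = k,
                reason = "k_below_min"))
  }
  x <- rank(meth[ok], ties.method = "average")
  y <- rank(expr[ok], ties.method = "average")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, k_used = k,
                reason = "zero_variance"))
  }
  rho <- cor(x, y)
  p <- spearman_p(rho, x, y, k, exact_max)
  list(rho = rho, p = p, k_used = k, reason = NA_character_)
}

spearman_p <- function(rho, x, y, k, exact_max = 9L) {
  if (k <= exact_max) {
    P <- perm_matrix(k)
    yp <- matrix(y[P], nrow = nrow(P))
    s <- as.vector(yp %*% x)
    mx <- mean(x); my <- mean(y)
    denom <- (k - 1) * stats::sd(x) * stats::sd(y)
    rho_perm <- (s - k * mx * my) / denom
    mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else {
    r2 <- min(rho^2, 1)
    if (r2 >= 1) return(0)
    tval <- rho * sqrt((k - 2) / (1 - r2))
    2 * pt(-abs(tval), df = k - 2)
  }
}

#' Benjamini-Hochberg adjustment over an explicit test universe
#'
#' Step-up adjusted values with enforced monotonicity, capped at 1.  The
#' denominator `m` is the declared size of the test universe and may
#' exceed the number of p-values supplied (e.g. when correction is over
#' all pairs but only a subset is being adjusted).
#'
#' @param p Numeric p-values in `[0,1]`.
#' @param m Size of the test universe; defaults to `length(p)`.
#' @return Adjusted q-values, same order as `p`.
#' @export
bh_adjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0,1]")
  if (m < length(p[!is.na(p)])) stop("m must be >= number of p-values")
  p.adjust(p, method = "BH", n = m)
}

#' Call CpG traffic lights over a pair universe
#'
#' Computes the Spearman statistic for every pair, adjusts over the number
#' of valid pairs (BH), and flags a pair as a traffic light when
#' `q < fdr` (strict, mirroring "FDR < 0.01").  A CpG site is a traffic
#' light when at least one of its pairs is flagged.
#'
#' @param sites A `cpg_sites` object ([filter_calls()]).
#' @param expr Expression matrix (genes x samples), columns aligned with
#'   `sites$beta`.
#' @param pairs Pair table from [build_pairs()].
#' @param fdr FDR threshold (strict inequality).
#' @param min_k Minimum pairwise-complete samples per pair.
#' @return List of class `tl_result`: `pairs` (with `rho`, `p`, `q`,
#'   `sign`, `is_tl`, `k_used`), `skipped` (untestable pairs and reasons),
#'   `gene_summary` (`gene_id`, `n_tl`, `best_q`, `has_tl`), `tl_sites`
#'   (unique traffic-light site table with anchor gene, distance and sign
#'   of the most significant pair), `m` (universe size), `fdr`.
#' @export
call_traffic_lights <- function(sites, expr, pairs, fdr = 0.01,
                                min_k = 20L) {
  if (nrow(pairs) == 0L) stop("empty pair universe")
  stopifnot(inherits(sites, "cpg_sites"))
  gene_idx <- match(pairs$gene_id, rownames(expr))
  if (anyNA(gene_idx)) stop("pairs reference genes absent from expr")

  n <- nrow(pairs)
  rho <- p <- numeric(n)
  k_used <- integer(n)
  reason <- character(n)
  beta <- sites$beta
  # precompute per-site defined masks and methylation ranks
  usite <- unique(pairs$site_idx)
  def_list <- rank_list <- vector("list", max(usite))
  for (s in usite) {
    d <- which(!is.na(beta[s, ]))
    def_list[[s]] <- d
    rank_list[[s]] <- rank(beta[s, d], ties.method = "average")
  }
  for (i in seq_len(n)) {
    s <- pairs$site_idx[i]
    d <- def_list[[s]]
    e <- expr[gene_idx[i], d]
    if (anyNA(e)) {                       # expression normally complete
      res <- spearman_test(beta[s, ], expr[gene_idx[i], ], min_k = min_k)
      rho[i] <- res$rho; p[i] <- res$p; k_used[i] <- res$k_used
      reason[i] <- ifelse(is.na(res$reason), "", res$reason)
      next
    }
    k <- length(d)
    if (k < min_k) {
      rho[i] <- NA; p[i] <- NA; k_used[i] <- k; reason[i] <- "k_below_min"
      next
    }
    x <- rank_list[[s]]
    y <- rank(e, ties.method = "average")
    sx <- stats::sd(x); sy <- stats::sd(y)
    if (sx == 0 || sy == 0) {
      rho[i] <- NA; p[i] <- NA; k_used[i] <- k; reason[i] <- "zero_variance"
      next
    }
    r <- (sum(x * y) - k * mean(x) * mean(y)) / ((k - 1) * sx * sy)
    rho[i] <- r
    p[i] <- spearman_p(r, x, y, k)
    k_used[i] <- k
    reason[i] <- ""
  }

  valid <- reason == ""
  res <- data.frame(pairs, rho = rho, p = p, k_used = k_used,
                    stringsAsFactors = FALSE)
  skipped <- data.frame(pairs[!valid, , drop = FALSE],
                        reason = reason[!valid], stringsAsFactors = FALSE)
  res <- res[valid, , drop = FALSE]
  m <- nrow(res)
  if (m == 0L) stop("no testable pairs")
  res$q <- bh_adjust(res$p, m = m)
  res$sign <- ifelse(res$rho < 0, "negative", "positive")
  res$is_tl <- res$q < fdr

  gene_ids <- unique(pairs$gene_id)
  agg_n <- tapply(res$is_tl, res$gene_id, sum)
  agg_q <- tapply(res$q, res$gene_id, min)
  gene_summary <- data.frame(
    gene_id = gene_ids,
    n_tl = as.integer(ifelse(is.na(agg_n[gene_ids]), 0L, agg_n[gene_ids])),
    best_q = as.numeric(agg_q[gene_ids]),
    stringsAsFactors = FALSE)
  gene_summary$has_tl <- gene_summary$n_tl >= 1L

  tl <- res[res$is_tl, , drop = FALSE]
  tl_sites <- data.frame()
  if (nrow(tl)) {
    best <- tl[order(tl$site_idx, tl$p), , drop = FALSE]
    best <- best[!duplicated(best$site_idx), , drop = FALSE]
    tl_sites <- data.frame(site_idx = best$site_idx, chrom = best$chrom,
                           pos = best$pos, gene_id = best$gene_id,
                           distance = best$distance, rho = best$rho,
                           q = best$q, sign = best$sign,
                           stringsAsFactors = FALSE)
    rownames(tl_sites) <- NULL
  }
  structure(list(pairs = res, skipped = skipped,
                 gene_summary = gene_summary, tl_sites = tl_sites,
                 m = m, fdr = fdr),
            class = "tl_result")
}

#' @export
print.tl_result <- function(x, ...) {
  cat("CpG traffic-light call:", x$m, "valid pairs,",
      sum(x$pairs$is_tl), "TL pairs,", nrow(x$tl_sites), "TL sites,",
      sum(x$gene_summary$has_tl), "genes with a TL (FDR <", x$fdr, ")\n")
  invisible(x)
}

#' Region-average correlation analysis
#'
#' For each gene, correlates the per-sample average methylation of a region
#' (promoter or gene body) with expression, adjusts over genes (BH) and
#' counts significant genes at each requested FDR level.  Counts are
#' reported under both correction conventions: `m` = genes actually tested,
#' and `m` = all genes supplied (genes without a covered CpG in the region
#' are excluded from testing either way and tallied).
#'
#' @param genes Gene table.
#' @param expr Expression matrix (genes x samples).
#' @param sites A `cpg_sites` object.
#' @param region `"promoter"` or `"gene_body"`.
#' @param fdr_levels FDR thresholds at which to count significant genes.
#' @param bounds Promoter window (see [region_profile()]).
#' @param min_k Minimum pairwise-complete samples.
#' @return List: `per_gene` (gene_id, rho, p, q under both conventions),
#'   `counts` (data.frame fdr x convention), `n_empty` (genes with no
#'   region CpG).
#' @export
region_average_analysis <- function(genes, expr, sites,
                                    region = c("promoter", "gene_body"),
                                    fdr_levels = c(0.001, 0.005, 0.01,
                                                   0.05, 0.1),
                                    bounds = c(-1000L, 500L),
                                    min_k = 20L) {
  region <- match.arg(region)
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    prof <- region_profile(genes[i, ], region, sites, bounds)
    if (is.null(prof)) return(NULL)
    st <- spearman_test(prof, expr[genes$gene_id[i], ], min_k = min_k)
    if (!is.na(st$reason)) return(NULL)
    data.frame(gene_id = genes$gene_id[i], rho = st$rho, p = st$p,
               k_used = st$k_used, stringsAsFactors = FALSE)
  })
  empty <- vapply(rows, is.null, logical(1))
  per_gene <- do.call(rbind, rows[!empty])
  n_empty <- sum(empty)
  if (is.null(per_gene)) stop("no gene has a testable ", region, " profile")
  per_gene$q_tested <- bh_adjust(per_gene$p, m = nrow(per_gene))
  per_gene$q_all <- bh_adjust(per_gene$p, m = nrow(genes))
  counts <- do.call(rbind, lapply(fdr_levels, function(f) {
    data.frame(fdr = f,
               n_significant_tested = sum(per_gene$q_tested < f),
               n_significant_all = sum(per_gene$q_all < f))
  }))
  list(per_gene = per_gene, counts = counts, n_empty = n_empty,
       region = region)
}

#' Permutation null for the traffic-light pipeline
#'
#' Decouples expression from methylation by applying one random permutation
#' of sample labels to the whole expression matrix per iteration (the
#' default scheme: preserves gene-gene and CpG-CpG correlation, breaks the
#' cross-coupling), reruns the full calling pipeline, and averages the
#' significant-gene count.  `scheme = "per_gene"` instead shuffles each
#' gene's profile independently.
#'
#' @param sites,expr,pairs,fdr,min_k As in [call_traffic_lights()].
#' @param n_perm Number of permutations.
#' @param seed Seed for the permutation draws.
#' @param scheme `"global"` (one sample-label permutation) or
#'   `"per_gene"`.
#' @param permutations Optional list of explicit permutation index vectors
#'   (overrides `n_perm`/`seed`; used for validation).
#' @return List: `gene_counts` per permutation, `mean_gene_count`,
#'   `tl_pair_counts`, `scheme`.
#' @export
permutation_null <- function(sites, expr, pairs, n_perm = 10L, fdr = 0.01,
                             seed = 1L, min_k = 20L,
                             scheme = c("global", "per_gene"),
                             permutations = NULL) {
  scheme <- match.arg(scheme)
  k <- ncol(expr)
  if (is.null(permutations)) {
    set.seed(seed)
    permutations <- replicate(n_perm, sample.int(k), simplify = FALSE)
  }
  gene_counts <- integer(length(permutations))
  tl_counts <- integer(length(permutations))
  for (i in seq_along(permutations)) {
    if (scheme == "global") {
      ep <- expr[, permutations[[i]], drop = FALSE]
    } else {
      ep <- t(apply(expr, 1L, function(r) r[sample.int(k)]))
    }
    colnames(ep) <- colnames(expr)
    res <- call_traffic_lights(sites, ep, pairs, fdr = fdr, min_k = min_k)
    gene_counts[i] <- sum(res$gene_summary$has_tl)
    tl_counts[i] <- sum(res$pairs$is_tl)
  }
  list(gene_counts = gene_counts,
       mean_gene_count = mean(gene_counts),
       tl_pair_counts = tl_counts, scheme = scheme)
}
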