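# Coverage filtering of methylation calls and construction of the
# CpG-gene pair universe.

#' Filter methylation calls into retained CpG sites
#'
#' Applies the calling filters: in the strand-resolved count dialect a
#' (CpG, sample, replicate) value is defined iff both strands are covered
#' by at least `min_strand_cov` reads ("not less than" -- the threshold is
#' inclusive); its beta value is the pooled methylated fraction over both
#' strands.  Replicate values are averaged into one value per sample (a
#' sample is defined when at least one replicate passes).  Sites with fewer
#' than `min_defined` defined samples are dropped.
#'
#' @param calls A `cpg_calls` object from [read_methylation_table()], or a
#'   list with the same structure.
#' @param min_strand_cov Minimum reads per strand (count dialect only).
#' @param min_defined Minimum defined samples for a site to be retained.
#' @param sample_ids Sample ordering for the output matrix; defaults to the
#'   order of appearance (counts) or the beta-table columns.
#' @return Object of class `cpg_sites`: list with `sites` (data.frame
#'   `chrom`, `pos`, `n_defined`) and `beta` (sites x samples matrix with
#'   `NA` for undefined cells).
#' @export
filter_calls <- function(calls, min_strand_cov = 4L, min_defined = 20L,
                         sample_ids = NULL) {
  stopifnot(is.list(calls), !is.null(calls$dialect))
  if (calls$dialect == "counts") {
    df <- calls$counts
    need <- c("fwd_cov", "rev_cov", "fwd_meth", "rev_meth")
    if (!all(need %in% names(df))) {
      stop("count dialect requires strand-resolved coverage columns")
    }
    if (is.null(sample_ids)) sample_ids <- unique(df$sample)
    ok <- df$fwd_cov >= min_strand_cov & df$rev_cov >= min_strand_cov
    beta_rep <- ifelse(ok, (df$fwd_meth + df$rev_meth) /
                         (df$fwd_cov + df$rev_cov), NA_real_)
    key <- paste(df$chrom, df$pos)
    ukey <- unique(key)
    si <- match(key, ukey)
    sj <- match(df$sample, sample_ids)
    # average defined replicate betas per (site, sample)
    cell <- (sj - 1L) * length(ukey) + si
    sums <- rowsum(ifelse(is.na(beta_rep), 0, beta_rep), cell)
    ns <- rowsum(as.numeric(!is.na(beta_rep)), cell)
    beta <- matrix(NA_real_, nrow = length(ukey), ncol = length(sample_ids),
                   dimnames = list(NULL, sample_ids))
    cells <- as.integer(rownames(sums))
    vals <- ifelse(ns[, 1L] > 0, sums[, 1L] / ns[, 1L], NA_real_)
    beta[cells] <- vals
    first <- !duplicated(key)
    sites <- data.frame(chrom = df$chrom[first], pos = df$pos[first],
                        stringsAsFactors = FALSE)
    # unique() on key preserves first-appearance order, matching `first`
  } else if (calls$dialect == "beta") {
    beta <- calls$beta
    if (!is.null(sample_ids)) beta <- beta[, sample_ids, drop = FALSE]
    sites <- calls$sites
  } else {
    stop("unknown methylation dialect: ", calls$dialect)
  }
  n_def <- rowSums(!is.na(beta))
  keep <- n_def >= min_defined
  out <- list(sites = data.frame(sites[keep, , drop = FALSE],
                                 n_defined = n_def[keep],
                                 row.names = NULL),
              beta = beta[keep, , drop = FALSE])
  class(out) <- "cpg_sites"
  out
}

#' Assemble a `cpg_sites` object from a site table and beta matrix
#'
#' Convenience constructor for sites that are already filtered (e.g. the
#' output of the synthetic generator): computes `n_defined` and attaches
#' the class used throughout the pipeline.
#'
#' @param site_table data.frame with `chrom`, `pos`.
#' @param beta Matrix of beta values (sites x samples, `NA` = missing).
#' @return Object of class `cpg_sites`.
#' @export
as_cpg_sites <- function(site_table, beta) {
  stopifnot(nrow(site_table) == nrow(beta),
            all(c("chrom", "pos") %in% names(site_table)))
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    stop("beta values outside [0,1]")
  }
  structure(list(sites = data.frame(site_table[, c("chrom", "pos")],
                                    n_defined = rowSums(!is.na(beta)),
                                    row.names = NULL),
                 beta = beta),
            class = "cpg_sites")
}

#' Construct the CpG-gene pair universe
#'
#' A CpG (addressed by the 0-based position of its C) is paired with a gene
#' when it lies within `upstream_bp` upstream of the TSS through the 3'
#' gene end, in strand-aware coordinates; both boundaries are inclusive.
#' One CpG may pair with several genes and vice versa.  The signed distance
#' is negative upstream of the TSS.  Region labels (relative to that
#' pair's gene only): `upstream` (distance below the promoter window),
#' `promoter` (within `promoter_bounds`), `gene_body` (beyond it).
#'
#' @param genes data.frame with `gene_id`, `chrom`, `strand`, `tss`,
#'   `end3` (0-based positions; `tss` is the upstream-most transcribed
#'   base, `end3` the 3'-most).
#' @param sites A `cpg_sites` object or a data.frame with `chrom`, `pos`.
#' @param upstream_bp Upstream extent of the pairing window.
#' @param promoter_bounds Strand-aware promoter window around the TSS,
#'   endpoints inclusive.
#' @return data.frame: `site_idx` (row in `sites`), `chrom`, `pos`,
#'   `gene_id`, `distance`, `region`.
#' @export
build_pairs <- function(genes, sites, upstream_bp = 10000L,
                        promoter_bounds = c(-1000L, 500L)) {
  site_df <- if (inherits(sites, "cpg_sites")) sites$sites else sites
  stopifnot(all(c("chrom", "pos") %in% names(site_df)))
  bad <- (genes$strand == "+" & genes$tss > genes$end3) |
    (genes$strand == "-" & genes$tss < genes$end3) |
    !genes$strand %in% c("+", "-")
  if (any(bad)) {
    stop("tss/end3 inconsistent with strand for gene(s): ",
         paste(genes$gene_id[bad], collapse = ", "))
  }
  lo <- ifelse(genes$strand == "+", genes$tss - upstream_bp, genes$end3)
  hi <- ifelse(genes$strand == "+", genes$end3, genes$tss + upstream_bp)
  win <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(start = lo + 1L,
                                                 end = hi + 1L))
  pt <- GenomicRanges::GRanges(site_df$chrom,
                               IRanges::IRanges(start = site_df$pos + 1L,
                                                width = 1L))
  ov <- GenomicRanges::findOverlaps(pt, win)
  si <- S4Vectors::queryHits(ov)
  gi <- S4Vectors::subjectHits(ov)
  dist <- ifelse(genes$strand[gi] == "+",
                 site_df$pos[si] - genes$tss[gi],
                 genes$tss[gi] - site_df$pos[si])
  region <- ifelse(dist < promoter_bounds[1], "upstream",
                   ifelse(dist <= promoter_bounds[2], "promoter",
                          "gene_body"))
  out <- data.frame(site_idx = si, chrom = site_df$chrom[si],
                    pos = site_df$pos[si], gene_id = genes$gene_id[gi],
                    distance = dist, region = region,
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$pos, out$gene_id), , drop = FALSE] ->
    out
  rownames(out) <- NULL
  out
}

#' Per-sample average methylation over a gene region
#'
#' Averages beta values of the CpGs falling in the strand-aware promoter
#' (`bounds[1]..bounds[2]` around the TSS) or gene body (`bounds[2]+1` to
#' the 3' end), per sample.  A sample is undefined when no CpG in the
#' region has a defined value there.
#'
#' @param gene One-row data.frame (a row of the `genes` table).
#' @param region `"promoter"` or `"gene_body"`.
#' @param sites A `cpg_sites` object.
#' @param bounds Promoter window endpoints (inclusive), defining the
#'   promoter/gene-body split.
#' @return Named numeric vector (one value per sample; `NA` when
#'   undefined) with attribute `n_cpg`, or `NULL` when the region holds no
#'   CpG.
#' @export
region_profile <- function(gene, region = c("promoter", "gene_body"),
                           sites, bounds = c(-1000L, 500L)) {
  region <- match.arg(region)
  on_chr <- which(sites$sites$chrom == gene$chrom)
  pos <- sites$sites$pos[on_chr]
  d <- if (gene$strand == "+") pos - gene$tss else gene$tss - pos
  sel <- if (region == "promoter") {
    d >= bounds[1] & d <= bounds[2]
  } else {
    d > bounds[2] & d <= abs(gene$end3 - gene$tss)
  }
  idx <- on_chr[sel]
  if (length(idx) == 0L) return(NULL)
  b <- sites$beta[idx, , drop = FALSE]
  prof <- colMeans(b, na.rm = TRUE)
  prof[is.nan(prof)] <- NA_real_
  attr(prof, "n_cpg") <- length(idx)
  prof
}
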