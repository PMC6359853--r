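# Readers/writers for the plain-text formats the pipeline touches, and the
# shared coordinate helpers.  Convention: every position in a cpgtl table is
# 0-based; intervals are half-open [start, end).  GRanges objects (1-based,
# closed) are produced only through the helpers below, which form the single
# conversion boundary.

#' Convert a 0-based half-open interval table to GRanges
#'
#' @param df data.frame with columns `chrom`, `start`, `end` and optionally
#'   `strand` (0-based half-open coordinates).
#' @return A [GenomicRanges::GRanges] object (1-based closed).
#' @keywords internal
intervals_to_granges <- function(df) {
  strand <- if ("strand" %in% names(df)) df$strand else "*"
  strand[is.na(strand) | strand == "."] <- "*"
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
}

#' Convert 0-based CpG positions (position of the C) to 2-bp GRanges
#' @param chrom,pos chromosome names and 0-based positions of the C.
#' @return GRanges of width 2.
#' @keywords internal
cpg_to_granges <- function(chrom, pos) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = pos + 1L, width = 2L))
}

#' Read a BED annotation track
#'
#' Reads BED3/BED6 into an annotation track: a data.frame of 0-based
#' half-open intervals.  Lines starting with `#`, `track` or `browser` are
#' skipped.  Column 4 (name) and column 6 (strand, when `with_strand`) are
#' kept when present.
#'
#' @param path Path to a BED file.
#' @param with_strand Parse strand from column 6 when present.
#' @param extra_cols Optional named character vector of classes for columns
#'   beyond the sixth (e.g. `c(motif_length = "integer")`).
#' @return data.frame with columns `chrom`, `start`, `end`, and optionally
#'   `name`, `score`, `strand`, plus any `extra_cols`; attribute `"name"`
#'   carries the track label (file base name).
#' @export
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines(c("# comment", "chr1\t10\t20", "chr1\t30\t40\tx\t0\t+"), f)
#' read_bed(f, with_strand = TRUE)
read_bed <- function(path, with_strand = FALSE, extra_cols = NULL) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  kept_idx <- which(keep)
  if (length(kept_idx) == 0L) {
    out <- data.frame(chrom = character(), start = integer(), end = integer())
    attr(out, "name") <- sub("\\.[^.]*$", "", basename(path))
    return(out)
  }
  fields <- strsplit(lines[kept_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    bad <- kept_idx[which(nf < 3L)[1L]]
    stop("malformed BED line ", bad, " in ", path, ": fewer than 3 fields")
  }
  ncol_use <- max(nf)
  m <- vapply(fields, function(x) {
    length(x) <- ncol_use      # pad short rows with NA
    x
  }, character(ncol_use))
  m <- if (ncol_use == 1L) matrix(m, nrow = 1L) else m
  start <- suppressWarnings(as.integer(m[2L, ]))
  end <- suppressWarnings(as.integer(m[3L, ]))
  if (anyNA(start) || anyNA(end)) {
    bad <- kept_idx[which(is.na(start) | is.na(end))[1L]]
    stop("malformed BED line ", bad, " in ", path, ": non-integer coordinates")
  }
  if (any(end <= start) || any(start < 0L)) {
    bad <- kept_idx[which(end <= start | start < 0L)[1L]]
    stop("invalid interval at line ", bad, " in ", path,
         ": need 0 <= start < end")
  }
  out <- data.frame(chrom = m[1L, ], start = start, end = end,
                    stringsAsFactors = FALSE)
  if (ncol_use >= 4L) out$name <- ifelse(is.na(m[4L, ]), ".", m[4L, ])
  if (ncol_use >= 5L) out$score <- suppressWarnings(as.numeric(m[5L, ]))
  if (with_strand && ncol_use >= 6L) {
    s <- ifelse(is.na(m[6L, ]), ".", m[6L, ])
    if (!all(s %in% c("+", "-", "."))) {
      stop("invalid strand in ", path)
    }
    out$strand <- s
  }
  if (!is.null(extra_cols)) {
    for (i in seq_along(extra_cols)) {
      col <- 6L + i
      if (ncol_use < col) stop("missing extra column ", names(extra_cols)[i],
                               " in ", path)
      out[[names(extra_cols)[i]]] <-
        if (extra_cols[[i]] == "integer") as.integer(m[col, ]) else
          if (extra_cols[[i]] == "numeric") as.numeric(m[col, ]) else m[col, ]
    }
  }
  attr(out, "name") <- sub("\\.[^.]*$", "", basename(path))
  out
}

#' Write an annotation track as BED
#'
#' @param track data.frame with `chrom`, `start`, `end` and optional
#'   `name`, `score`, `strand` columns (0-based half-open).
#' @param path Output path.
#' @export
write_bed <- function(track, path) {
  cols <- c("chrom", "start", "end")
  opt <- intersect(c("name", "score", "strand"), names(track))
  # BED columns are positional: pad the gaps when later columns are present
  if (length(opt)) {
    need <- c("name", "score", "strand")
    last <- max(match(opt, need))
    for (cn in need[seq_len(last)]) {
      if (is.null(track[[cn]])) {
        track[[cn]] <- if (cn == "score") 0 else "."
      }
    }
    cols <- c(cols, need[seq_len(last)])
  }
  extra <- setdiff(names(track), c(cols, "name", "score", "strand"))
  write.table(track[, c(cols, extra), drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a methylation call table
#'
#' Two dialects are supported, detected from the header:
#' \describe{
#'   \item{beta}{wide table `chrom  pos  <sample1> <sample2> ...` with beta
#'     values in `[0,1]` or `NA`.}
#'   \item{counts}{long, strand-resolved table with columns `chrom`, `pos`,
#'     `sample`, `replicate`, `fwd_cov`, `fwd_meth`, `rev_cov`, `rev_meth`.}
#' }
#' Missing cells are preserved as `NA`, never coerced to zero.
#'
#' @param path Path to a TSV file.
#' @return For the beta dialect, a list of class `cpg_calls` with
#'   `dialect = "beta"`, `sites` (chrom, pos) and `beta` matrix; for the
#'   counts dialect, `dialect = "counts"` and the long data.frame in
#'   `counts`.
#' @export
read_methylation_table <- function(path) {
  stopifnot(file.exists(path))
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  count_cols <- c("chrom", "pos", "sample", "replicate",
                  "fwd_cov", "fwd_meth", "rev_cov", "rev_meth")
  if (all(count_cols %in% names(df))) {
    num <- df[, c("fwd_cov", "fwd_meth", "rev_cov", "rev_meth")]
    if (any(num < 0, na.rm = TRUE)) stop("negative counts in ", path)
    if (any(df$fwd_meth > df$fwd_cov | df$rev_meth > df$rev_cov,
            na.rm = TRUE)) {
      stop("methylated counts exceed coverage in ", path)
    }
    return(structure(list(dialect = "counts", counts = df),
                     class = "cpg_calls"))
  }
  if (!all(c("chrom", "pos") %in% names(df)[1:2])) {
    stop("methylation table must start with chrom, pos columns: ", path)
  }
  samples <- names(df)[-(1:2)]
  beta <- as.matrix(df[, samples, drop = FALSE])
  storage.mode(beta) <- "double"
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    stop("beta values outside [0,1] in ", path)
  }
  structure(list(dialect = "beta",
                 sites = data.frame(chrom = df$chrom, pos = as.integer(df$pos)),
                 beta = beta),
            class = "cpg_calls")
}

#' Read a gene expression matrix (genes x samples, RPKM)
#'
#' @param path TSV with first column `gene_id` (unique) and one column per
#'   sample.
#' @param sample_ids Optional sample ordering; columns are realigned by
#'   name and all must be present.
#' @return Numeric matrix, rownames = gene ids, colnames = samples.
#' @export
read_expression_matrix <- function(path, sample_ids = NULL) {
  stopifnot(file.exists(path))
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  ids <- df[[1L]]
  if (anyDuplicated(ids)) stop("duplicate gene id in ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (any(!is.finite(m)) || any(m < 0)) {
    stop("expression values must be finite and non-negative: ", path)
  }
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, colnames(m))
    if (length(missing)) stop("samples missing from expression matrix: ",
                              paste(missing, collapse = ", "))
    m <- m[, sample_ids, drop = FALSE]
  }
  m
}

#' Read a per-base score track
#'
#' Expects a TSV with columns `chrom`, `pos` (0-based) and `score`; missing
#' positions are simply absent.  Scores must be finite.
#'
#' @param path TSV path.
#' @return data.frame `chrom`, `pos`, `score`.
#' @export
read_score_track <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "score") %in% names(df)))
  if (any(!is.finite(df$score))) stop("non-finite score in ", path)
  df$pos <- as.integer(df$pos)
  df
}

#' Read a chromatin-state segmentation (BED with state label in column 4)
#'
#' @param path BED path.
#' @param epigenome_id Label for the epigenome; defaults to the file name.
#' @param state_names Optional full state vocabulary (labels found in the
#'   file must be a subset).
#' @return data.frame `chrom`, `start`, `end`, `state` with attributes
#'   `epigenome_id` and `state_names`.
#' @export
read_segmentation <- function(path, epigenome_id = NULL, state_names = NULL) {
  bed <- read_bed(path)
  if (is.null(bed$name)) stop("segmentation BED needs a state label column: ",
                              path)
  out <- data.frame(chrom = bed$chrom, start = bed$start, end = bed$end,
                    state = bed$name, stringsAsFactors = FALSE)
  if (is.null(state_names)) state_names <- sort(unique(out$state))
  if (!all(out$state %in% state_names)) stop("unknown state label in ", path)
  ov <- GenomicRanges::findOverlaps(intervals_to_granges(out),
                                    drop.self = TRUE)
  if (length(ov)) stop("overlapping intervals within segmentation ", path)
  attr(out, "epigenome_id") <-
    if (is.null(epigenome_id)) sub("\\.[^.]*$", "", basename(path)) else
      epigenome_id
  attr(out, "state_names") <- state_names
  out
}

#' Read TFBS hits (BED6 plus a motif-length column)
#'
#' @param path BED path: chrom, start, end, tf name, score, strand,
#'   motif_length.
#' @return data.frame `chrom`, `start`, `end`, `tf`, `strand`,
#'   `motif_length`.
#' @export
read_tfbs <- function(path) {
  bed <- read_bed(path, with_strand = TRUE,
                  extra_cols = c(motif_length = "integer"))
  stopifnot(!is.null(bed$name), !is.null(bed$strand))
  if (any(bed$end - bed$start != bed$motif_length)) {
    stop("interval width disagrees with motif_length in ", path)
  }
  data.frame(chrom = bed$chrom, start = bed$start, end = bed$end,
             tf = bed$name, strand = bed$strand,
             motif_length = bed$motif_length, stringsAsFactors = FALSE)
}

#' Read a genome FASTA
#' @param path FASTA path.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) Biostrings::readDNAStringSet(path)

#' Write tab-separated results with a provenance header
#'
#' @param df data.frame to write.
#' @param path Output path.
#' @param header Named character vector written as `# key: value` lines.
#' @export
write_tsv <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) {
    writeLines(paste0("# ", names(header), ": ", unname(header)), con)
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path Input path.
#' @return data.frame (header comment lines skipped).
#' @export
read_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE)
}
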