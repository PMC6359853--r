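# End-to-end pipeline: simulate (optional) -> filter -> pair -> detect ->
# background -> enrich, driven by a single config, with a structured log
# and plain-TSV artifacts so every stage can be rerun independently.

#' Build a pipeline run configuration
#'
#' Defaults are the analysis constants of the method: pairing window
#' 10000 bp upstream of the TSS, strand coverage >= 4, >= 20 defined
#' samples, FDR < 0.01, 200 bp matching windows with 5% tolerances,
#' 100 bp near-TSS bins, 50 background replicates, 10 permutations.
#'
#' @param input_dir Directory holding the input files (as written by
#'   [write_dataset()]); ignored when `simulate` is `TRUE`.
#' @param outdir Output directory.
#' @param simulate Generate the inputs with [simulate_dataset()] first.
#' @param sim_config A [simulate_config()] for the simulate stage.
#' @param upstream_bp,min_strand_cov,min_defined,fdr Analysis thresholds.
#' @param window_bp,gc_tolerance,cpg_tolerance,near_tss_bp,
#'   distance_tolerance,n_replicates Background-matching parameters.
#' @param n_perm Permutations for the null.
#' @param shore_bp TFBS shore width.
#' @param promoter_bounds Promoter window for region labels and the
#'   region-average analysis.
#' @param seed Seed for every stochastic stage.
#' @param stages Character vector of stages to run, in order, among
#'   `simulate`, `filter`, `pair`, `detect`, `background`, `enrich`.
#' @return List of class `run_config`.
#' @export
run_config <- function(input_dir = NULL, outdir = tempfile("cpgtl_run_"),
                       simulate = is.null(input_dir),
                       sim_config = NULL,
                       upstream_bp = 10000L, min_strand_cov = 4L,
                       min_defined = 20L, fdr = 0.01,
                       window_bp = 200L, gc_tolerance = 0.05,
                       cpg_tolerance = 0.05, near_tss_bp = 100L,
                       distance_tolerance = 0.05, n_replicates = 50L,
                       n_perm = 10L, shore_bp = 100L,
                       promoter_bounds = c(-1000L, 500L), seed = 1L,
                       stages = c("simulate", "filter", "pair", "detect",
                                  "background", "enrich")) {
  cfg <- as.list(environment())
  if (!simulate) cfg$stages <- setdiff(stages, "simulate")
  if (simulate && is.null(cfg$sim_config)) {
    cfg$sim_config <- simulate_config(seed = seed)
  }
  structure(cfg, class = "run_config")
}

#' Run the pipeline
#'
#' Executes the enabled stages in order and writes all artifacts (pair
#' table, per-pair results, gene summary, background replicates,
#' enrichment tables, position profiles) as TSV under `config$outdir`,
#' together with a structured run log and the resolved configuration.
#'
#' @param config A [run_config()] object, or the path of a YAML file with
#'   the same fields.
#' @return Invisibly, a list with every in-memory result.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) {
    y <- yaml::read_yaml(config)
    config <- do.call(run_config, y)
  }
  stopifnot(inherits(config, "run_config"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  note <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  hdr <- c(package = paste0("cpgtl ",
                            as.character(utils::packageVersion("cpgtl"))),
           seed = config$seed)
  stages <- config$stages

  if ("simulate" %in% stages) {
    note("simulate: seed ", config$sim_config$seed)
    sim <- simulate_dataset(config$sim_config)
    write_dataset(sim, file.path(outdir, "inputs"))
    input_dir <- file.path(outdir, "inputs")
  } else {
    if (is.null(config$input_dir)) stop("input_dir required when not ",
                                        "simulating")
    input_dir <- config$input_dir
    missing <- setdiff(c("genome.fa", "genes.tsv", "expression.tsv"),
                       list.files(input_dir))
    if (length(missing)) stop("missing inputs: ",
                              paste(missing, collapse = ", "))
    sim <- NULL
  }

  genome <- read_genome(file.path(input_dir, "genome.fa"))
  genes <- read_tsv(file.path(input_dir, "genes.tsv"))
  expr <- read_expression_matrix(file.path(input_dir, "expression.tsv"))

  res <- list(config = config)
  sites <- NULL
  if ("filter" %in% stages) {
    meth_path <- file.path(input_dir, "methylation_counts.tsv")
    if (!file.exists(meth_path)) {
      meth_path <- file.path(input_dir, "methylation_beta.tsv")
    }
    calls <- read_methylation_table(meth_path)
    sites <- filter_calls(calls, min_strand_cov = config$min_strand_cov,
                          min_defined = config$min_defined,
                          sample_ids = colnames(expr))
    note("filter: ", nrow(sites$sites), " CpG sites retained (dialect ",
         calls$dialect, ")")
  }

  if ("pair" %in% stages) {
    pairs <- build_pairs(genes, sites, upstream_bp = config$upstream_bp,
                         promoter_bounds = config$promoter_bounds)
    note("pair: ", nrow(pairs), " CpG-gene pairs (",
         length(unique(pairs$site_idx)), " CpGs, ",
         length(unique(pairs$gene_id)), " genes)")
    write_tsv(pairs[, c("chrom", "pos", "gene_id", "distance", "region")],
              file.path(outdir, "pairs.tsv"), header = hdr)
    res$pairs <- pairs
  }

  if ("detect" %in% stages) {
    tl <- call_traffic_lights(sites, expr, pairs, fdr = config$fdr,
                              min_k = config$min_defined)
    note("detect: m = ", tl$m, " valid pairs, ", sum(tl$pairs$is_tl),
         " TL pairs, ", nrow(tl$tl_sites), " TL sites, ",
         sum(tl$gene_summary$has_tl), " genes (FDR < ", config$fdr, ")")
    write_tsv(tl$pairs[, c("chrom", "pos", "gene_id", "rho", "p", "q",
                           "sign", "is_tl", "k_used")],
              file.path(outdir, "pair_results.tsv"), header = hdr)
    write_tsv(tl$gene_summary, file.path(outdir, "gene_summary.tsv"),
              header = hdr)
    perm <- permutation_null(sites, expr, pairs, n_perm = config$n_perm,
                             fdr = config$fdr, seed = config$seed,
                             min_k = config$min_defined)
    note("detect: permutation null mean gene count ",
         round(perm$mean_gene_count, 2))
    res$tl <- tl
    res$permutation <- perm
  }

  if ("background" %in% stages) {
    if (nrow(res$tl$tl_sites) == 0L) {
      note("background: no traffic lights, stage skipped")
    } else {
      tl_ctx <- site_context(genome, res$tl$tl_sites, res$tl$pairs,
                             window_bp = config$window_bp)
      all_sites <- sites$sites[, c("chrom", "pos")]
      is_tl <- paste(all_sites$chrom, all_sites$pos) %in%
        paste(res$tl$tl_sites$chrom, res$tl$tl_sites$pos)
      cand_ctx <- site_context(genome, all_sites[!is_tl, , drop = FALSE],
                               res$tl$pairs, window_bp = config$window_bp)
      crit <- matching_criteria(
        window_bp = config$window_bp, gc_tolerance = config$gc_tolerance,
        cpg_tolerance = config$cpg_tolerance,
        near_tss_bp = config$near_tss_bp,
        distance_tolerance = config$distance_tolerance,
        n_replicates = config$n_replicates, seed = config$seed)
      bg <- match_background(tl_ctx, cand_ctx, crit)
      n_un <- sum(!bg[[1L]]$matched)
      note("background: ", length(bg), " replicates, ", n_un, " of ",
           nrow(tl_ctx), " TLs unmatched in replicate 1")
      write_tsv(do.call(rbind, bg), file.path(outdir, "background.tsv"),
                header = hdr)
      res$bg <- bg
      res$tl_ctx <- tl_ctx
      res$cand_ctx <- cand_ctx
    }
  }

  if ("enrich" %in% stages && !is.null(res$bg)) {
    tracks <- list()
    for (f in list.files(input_dir, pattern = "^track_.*\\.bed$")) {
      tr <- read_bed(file.path(input_dir, f))
      tracks[[sub("^track_", "", attr(tr, "name"))]] <- tr
    }
    bgs <- bg_sites(res$bg)
    tl_tab <- res$tl$tl_sites[, c("chrom", "pos", "sign")]
    if (length(tracks)) {
      enr <- annotation_enrichment(tl_tab, bgs, tracks)
      write_tsv(enr, file.path(outdir, "enrichment_annotations.tsv"),
                header = hdr)
      note("enrich: ", length(tracks), " annotation tracks")
      res$enrichment <- enr
    }
    seg_files <- list.files(input_dir, pattern = "^segmentation_.*\\.bed$")
    if (length(seg_files)) {
      segs <- lapply(file.path(input_dir, seg_files), read_segmentation)
      states <- sort(unique(unlist(lapply(segs, attr, "state_names"))))
      segs <- lapply(segs, function(s) {
        attr(s, "state_names") <- states
        s
      })
      srm <- state_ratio_matrix(tl_tab, bgs, segs)
      out <- data.frame(state = rownames(srm$ratio), srm$ratio,
                        average = srm$state_average, check.names = FALSE)
      write_tsv(out, file.path(outdir, "state_ratios.tsv"), header = hdr)
      res$state_ratios <- srm
    }
    score_files <- list.files(input_dir, pattern = "^score_.*\\.tsv$")
    if (length(score_files)) {
      score_rows <- lapply(score_files, function(f) {
        st <- read_score_track(file.path(input_dir, f))
        score_threshold_enrichment(tl_tab, bgs, st, threshold = 0.5,
                                   name = sub("^score_(.*)\\.tsv$", "\\1",
                                              f))
      })
      write_tsv(do.call(rbind, score_rows),
                file.path(outdir, "enrichment_scores.tsv"), header = hdr)
      res$score_enrichment <- do.call(rbind, score_rows)
    }
    tfbs_path <- file.path(input_dir, "tfbs.bed")
    if (file.exists(tfbs_path)) {
      tfbs <- read_tfbs(tfbs_path)
      prof <- tfbs_position_profile(tl_tab, bgs, tfbs,
                                    shore_bp = config$shore_bp)
      write_tsv(prof, file.path(outdir, "tfbs_profiles.tsv"), header = hdr)
      res$tfbs_profiles <- prof
      res$tf_summary <- tf_scatter_summary(tl_tab, bgs, tfbs)
      write_tsv(res$tf_summary, file.path(outdir, "tf_summary.tsv"),
                header = hdr)
    }
  }

  writeLines(log_lines, file.path(outdir, "run_log.txt"))
  resolved <- unclass(config)
  resolved$sim_config <- if (!is.null(config$sim_config)) {
    unclass(config$sim_config)[!vapply(config$sim_config, is.data.frame,
                                       logical(1))]
  }
  yaml::write_yaml(resolved, file.path(outdir, "resolved_config.yaml"))
  invisible(res)
}
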