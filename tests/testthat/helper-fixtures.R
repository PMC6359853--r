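# Shared fixtures: small simulation configs and hand-built inputs.

tiny_config <- function(...) {
  defaults <- list(
    n_chromosomes = 1L, chrom_length = 90000L,
    n_genes = 4L, cpg_density = 0.02, n_samples = 24L,
    fraction_planted_tl = 0.02,
    tracks = data.frame(name = c("enh", "neutral"), factor = c(3, 1),
                        cover = c(0.1, 0.2)),
    score_tracks = data.frame(name = "cons", shift = 1),
    n_epigenomes = 2L, tfs = data.frame(name = "TFa", motif_length = 10L,
                                        n_hits = 40L))
  do.call(simulate_config, utils::modifyList(defaults, list(...)))
}

# panel matching the parameter-recovery study conditions: 48 samples,
# ~20000 CpG-gene pairs, 200 planted couplings at |rho| 0.9,
# missingness 0.2
panel_config <- function(seed, ...) {
  simulate_config(seed = seed, n_chromosomes = 4L, chrom_length = 250000L,
                  n_genes = 80L, cpg_density = 0.02, ...)
}

sim_sites <- function(profiles) as_cpg_sites(profiles$sites, profiles$beta)

# one gene per strand for window arithmetic tests
two_genes <- function() {
  data.frame(gene_id = c("Gp", "Gm"), chrom = c("chr1", "chr2"),
             start = c(20000L, 20000L), end = c(30001L, 30001L),
             strand = c("+", "-"),
             tss = c(20000L, 30000L), end3 = c(30000L, 20000L),
             stringsAsFactors = FALSE)
}

# deterministic beta matrix with no missingness
const_sites <- function(pos, beta_rows, chrom = "chr1") {
  as_cpg_sites(data.frame(chrom = chrom, pos = pos), beta_rows)
}

write_lines <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
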