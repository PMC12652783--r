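# Stage orchestration: run the analysis as named subcommands over a single
# validated configuration, writing plain-text outputs plus a run log.
# All outputs are deterministic: reruns with identical inputs and config
# are byte-identical.

#' Build and validate a pipeline configuration
#'
#' @param fasta path to the genomes FASTA (ignored when `simulate = TRUE`).
#' @param gff optional annotation GFF3.
#' @param alignment path to the whole-genome aligned FASTA.
#' @param outdir output directory.
#' @param taxon_order optional taxon order; first taxon is the reference.
#' @param simulate when `TRUE`, the `simulate` stage generates inputs from
#'   `sim` (a [sim_config()]; defaults to `scale_preset(seed)`).
#' @param sim optional `sim_config` for the simulate stage.
#' @param seed seed for simulation and bootstrap.
#' @param window,step sliding-window parameters in bp.
#' @param min_ir_len minimum inverted-repeat length for structure detection.
#' @param min_indel_len minimum InDel length difference for marker
#'   candidates.
#' @param bootstrap_n bootstrap replicates for the phylogeny stage.
#' @param max_mismatch,three_prime_exact in-silico PCR annealing rules.
#' @param write_vcf also write variants as VCF 4.2.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(fasta = NULL, gff = NULL, alignment = NULL,
                            outdir = "plastmarker_out", taxon_order = NULL,
                            simulate = FALSE, sim = NULL, seed = 1L,
                            window = 1000L, step = 200L,
                            min_ir_len = 10000L, min_indel_len = 7L,
                            bootstrap_n = 100L, max_mismatch = 1L,
                            three_prime_exact = 3L, write_vcf = FALSE) {
  cfg <- as.list(environment())
  if (cfg$window < cfg$step || cfg$step < 1L)
    stop("invalid config: require window >= step >= 1")
  if (cfg$min_ir_len < 1000L) stop("invalid config: min_ir_len must be >= 1000")
  if (cfg$bootstrap_n < 1L) stop("invalid config: bootstrap_n must be >= 1")
  if (!cfg$simulate && is.null(cfg$fasta))
    stop("invalid config: need a genomes FASTA unless simulate = TRUE")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

pipeline_state <- function(cfg) {
  st <- new.env(parent = emptyenv())
  st$cfg <- cfg
  st
}

need <- function(st, what, from) {
  if (is.null(st[[what]]))
    stop("missing prerequisite for this stage: run the ", sQuote(from),
         " subcommand first (no ", what, " available)")
  st[[what]]
}

load_inputs <- function(st) {
  cfg <- st$cfg
  # a previous `simulate` invocation leaves its outputs under outdir/sim;
  # pick them up so subcommands compose across processes
  simdir <- file.path(cfg$outdir, "sim")
  if (is.null(cfg$fasta) && file.exists(file.path(simdir, "genomes.fasta"))) {
    cfg$fasta <- file.path(simdir, "genomes.fasta")
    cfg$gff <- cfg$gff %||% file.path(simdir, "features.gff3")
    cfg$alignment <- cfg$alignment %||% file.path(simdir, "alignment.fasta")
    st$cfg <- cfg
  }
  if (is.null(st$genomes)) {
    if (!is.null(cfg$fasta))
      st$genomes <- read_genomes(cfg$fasta, gff = cfg$gff)
  }
  if (is.null(st$aln) && !is.null(cfg$alignment))
    st$aln <- load_alignment(cfg$alignment, genomes = st$genomes,
                             taxon_order = cfg$taxon_order)
  invisible(st)
}

stage_simulate <- function(st) {
  cfg <- st$cfg
  sim <- cfg$sim %||% scale_preset(seed = cfg$seed)
  ts <- generate(sim)
  simdir <- file.path(cfg$outdir, "sim")
  write_truth_set(ts, simdir)
  st$truth_set <- ts
  st$genomes <- ts$genomes
  st$aln <- ts$alignment
  st$cfg$fasta <- file.path(simdir, "genomes.fasta")
  st$cfg$gff <- file.path(simdir, "features.gff3")
  st$cfg$alignment <- file.path(simdir, "alignment.fasta")
  invisible(st)
}

stage_structure <- function(st) {
  load_inputs(st)
  genomes <- need(st, "genomes", "simulate")
  cfg <- st$cfg
  st$partitions <- lapply(genomes, detect_inverted_repeats,
                          min_ir_len = cfg$min_ir_len)
  tab <- summarize_structure(genomes, st$partitions)
  write_tsv_with_meta(tab, file.path(cfg$outdir, "structure_summary.tsv"),
                      meta = list(stage = "structure",
                                  min_ir_len = cfg$min_ir_len))
  ref <- names(genomes)[1L]
  write_region_bed(st$partitions[[ref]],
                   file.path(cfg$outdir, "regions.bed"), chrom = ref)
  invisible(st)
}

stage_variants <- function(st) {
  load_inputs(st)
  aln <- need(st, "aln", "simulate")
  cfg <- st$cfg
  st$events <- extract_variants(aln)
  ref <- aln$taxa[1L]
  part <- if (!is.null(st$partitions)) st$partitions[[ref]] else NULL
  write_variant_table(st$events, file.path(cfg$outdir, "variants.tsv"),
                      partition = part, reference = ref,
                      meta = list(stage = "variants", reference = ref))
  if (isTRUE(cfg$write_vcf))
    write_variant_vcf(st$events, aln, file.path(cfg$outdir, "variants.vcf"),
                      reference = ref)
  invisible(st)
}

stage_stats <- function(st) {
  cfg <- st$cfg
  events <- need(st, "events", "variants")
  pm <- pairwise_matrix(events)
  long <- do.call(rbind, lapply(seq_along(pm$taxa), function(i)
    do.call(rbind, lapply(seq_along(pm$taxa), function(j) {
      if (j <= i) return(NULL)
      data.frame(taxon_a = pm$taxa[i], taxon_b = pm$taxa[j],
                 snps = pm$snp_counts[i, j],
                 indel_sites = pm$indel_site_counts[i, j],
                 indel_bp = pm$indel_total_bp[i, j],
                 stringsAsFactors = FALSE)
    }))))
  write_tsv_with_meta(long, file.path(cfg$outdir, "pairwise_variants.tsv"),
                      meta = list(stage = "stats"))
  ss <- species_specific(events)
  write_tsv_with_meta(ss, file.path(cfg$outdir, "species_specific.tsv"),
                      meta = list(stage = "stats"))
  st$pairwise <- pm
  st$specific <- ss
  invisible(st)
}

stage_windows <- function(st) {
  cfg <- st$cfg
  events <- need(st, "events", "variants")
  aln <- need(st, "aln", "variants")
  wp <- sliding_window(events, aln$ncol, window = cfg$window, step = cfg$step)
  write_tsv_with_meta(wp, file.path(cfg$outdir, "window_profile.tsv"),
                      meta = list(stage = "windows", window = cfg$window,
                                  step = cfg$step,
                                  coordinate_space = "alignment"))
  st$windows <- wp
  invisible(st)
}

stage_effects <- function(st) {
  cfg <- st$cfg
  genomes <- need(st, "genomes", "simulate")
  pseudo <- do.call(rbind, lapply(genomes, detect_pseudogenes))
  write_tsv_with_meta(pseudo, file.path(cfg$outdir, "pseudogenes.tsv"),
                      meta = list(stage = "effects"))
  st$ssrs <- lapply(genomes, find_ssrs)
  ref <- names(genomes)[1L]
  write_ssr_bed(st$ssrs[[ref]], file.path(cfg$outdir, "ssrs.bed"), chrom = ref)
  st$pseudogenes <- pseudo
  invisible(st)
}

stage_markers <- function(st) {
  cfg <- st$cfg
  events <- need(st, "events", "variants")
  genomes <- need(st, "genomes", "simulate")
  aln <- need(st, "aln", "variants")
  if (is.null(st$ssrs)) st$ssrs <- lapply(genomes, find_ssrs)
  ref <- aln$taxa[1L]
  cand <- select_candidates(events, genomes, ssrs = st$ssrs,
                            partition = if (!is.null(st$partitions))
                              st$partitions[[ref]] else NULL,
                            reference = ref,
                            min_indel_len = cfg$min_indel_len)
  st$markers <- design_markers(aln, cand, events)
  write_marker_table(st$markers, file.path(cfg$outdir, "markers.tsv"),
                     fasta = file.path(cfg$outdir, "primers.fasta"),
                     meta = list(stage = "markers",
                                 min_indel_len = cfg$min_indel_len,
                                 arms_policy = "offset3_purine_pyrimidine_swap"))
  st$candidates <- cand
  invisible(st)
}

stage_ipcr <- function(st) {
  cfg <- st$cfg
  markers <- need(st, "markers", "markers")
  genomes <- need(st, "genomes", "simulate")
  bt <- banding_table(markers, genomes, max_mismatch = cfg$max_mismatch,
                      three_prime_exact = cfg$three_prime_exact)
  write_banding_table(bt, file.path(cfg$outdir, "banding.tsv"),
                      meta = list(stage = "ipcr",
                                  max_mismatch = cfg$max_mismatch,
                                  three_prime_exact = cfg$three_prime_exact))
  st$banding <- bt
  invisible(st)
}

stage_phylo <- function(st) {
  cfg <- st$cfg
  aln <- need(st, "aln", "variants")
  D <- k2p_matrix(aln)
  write_distance_matrix(D, file.path(cfg$outdir, "k2p_distances.tsv"),
                        meta = list(stage = "phylo", model = "K2P",
                                    gaps = "pairwise_deletion"))
  tree <- bootstrap_support(aln, n_replicates = cfg$bootstrap_n,
                            seed = cfg$seed)
  ape::write.tree(tree, file.path(cfg$outdir, "nj_tree.nwk"))
  writeLines(c("# method: neighbor-joining over Kimura two-parameter distances",
               "# note: stands in for a full maximum-likelihood search",
               sprintf("# bootstrap_replicates: %d", cfg$bootstrap_n),
               sprintf("# seed: %d", cfg$seed)),
             file.path(cfg$outdir, "nj_tree.meta"))
  st$tree <- tree
  invisible(st)
}

PIPELINE_STAGES <- list(simulate = stage_simulate, structure = stage_structure,
                        variants = stage_variants, stats = stage_stats,
                        windows = stage_windows, effects = stage_effects,
                        markers = stage_markers, ipcr = stage_ipcr,
                        phylo = stage_phylo)

write_run_log <- function(st) {
  cfg <- st$cfg
  inputs <- Filter(function(p) !is.null(p) && file.exists(p),
                   list(fasta = cfg$fasta, gff = cfg$gff,
                        alignment = cfg$alignment))
  log <- list(package = "plastmarker",
              version = as.character(utils::packageVersion("plastmarker")),
              seed = cfg$seed,
              parameters = cfg[c("window", "step", "min_ir_len",
                                 "min_indel_len", "bootstrap_n",
                                 "max_mismatch", "three_prime_exact")],
              input_md5 = lapply(inputs, function(p) unname(tools::md5sum(p))))
  yaml::write_yaml(log, file.path(cfg$outdir, "run_log.yaml"))
}

#' Run one pipeline subcommand
#'
#' Stages: `structure`, `variants`, `stats`, `windows`, `effects`,
#' `markers`, `ipcr`, `phylo`, `simulate`, or `all` (every stage in
#' topological order, starting with `simulate` when
#' `config$simulate = TRUE`). Stage prerequisites are resolved in-memory
#' within one call; a stage whose prerequisite stage has not run raises an
#' error naming that subcommand.
#'
#' @param name subcommand name.
#' @param config `pipeline_config`.
#' @param state optional state from a previous call (to chain subcommands).
#' @return the (invisible) pipeline state environment.
#' @export
run_subcommand <- function(name, config, state = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  st <- state %||% pipeline_state(config)
  if (name == "all") {
    stages <- names(PIPELINE_STAGES)
    if (!config$simulate) stages <- setdiff(stages, "simulate")
    for (s in stages) st <- PIPELINE_STAGES[[s]](st)
  } else {
    fn <- PIPELINE_STAGES[[name]]
    if (is.null(fn)) stop("unknown subcommand ", sQuote(name))
    st <- fn(st)
  }
  write_run_log(st)
  invisible(st)
}

#' Run the whole pipeline
#'
#' Convenience wrapper for `run_subcommand("all", config)`.
#'
#' @param config `pipeline_config`.
#' @return invisible pipeline state.
#' @export
run_pipeline <- function(config) run_subcommand("all", config)
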