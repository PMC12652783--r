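# Truth-tracked synthetic plastome generator.
#
# Builds a quadripartite ancestor (LSC + IRb + SSC + IRa, IRa the exact
# reverse complement of IRb) carrying protein-coding/tRNA/rRNA genes and
# planted SSR tracts, then derives four species by planting SNPs and InDels
# with full gap bookkeeping, so the true alignment and the true variant
# list are emitted alongside the genomes. Planting is positional, not a
# Markov substitution process: the point is exact, recoverable truth.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Simulation configuration
#'
#' Defaults reproduce the scale of the four-species plastome comparison the
#' package is built around: a ~155 kb architecture (LSC 84,500 / SSC 18,700
#' / IR 26,000 bp), 79/29/4 protein-coding/tRNA/rRNA genes, 497 planted SNP
#' events (per-taxon species-specific counts 118/109/148/96 plus 26 SNPs
#' shared by a pair of taxa) and 187 InDel events (49/50/51/37 per taxon),
#' InDel lengths drawn from a short/long mixture so both excluded (< 7 bp,
#' SSR-associated) and qualifying marker candidates exist, SNPs biased to
#' the single-copy regions with a small mirrored IR fraction, and one
#' premature-stop plus one frameshift pseudogene.
#'
#' @param seed RNG seed; the whole generation is reproducible from it.
#' @param lsc_len,ssc_len,ir_len region lengths of the ancestor in bp.
#' @param n_genes named counts for `protein_coding`, `tRNA`, `rRNA`.
#' @param cds_len_range protein-coding CDS length range in bp (multiples of
#'   3 are drawn from it).
#' @param intron_frac fraction of protein-coding genes given two exons.
#' @param gc ancestral GC fraction.
#' @param n_ssr number of planted SSR tracts.
#' @param taxa four taxon labels.
#' @param snp_counts per-taxon species-specific SNP event counts.
#' @param shared_snps number of SNPs whose derived allele is shared by a
#'   taxon pair (split between taxa 1+2 and 3+4).
#' @param indel_counts per-taxon species-specific InDel event counts.
#' @param ir_snp_frac fraction of each taxon's SNPs planted (as mirrored
#'   complement pairs) in the inverted repeat.
#' @param frac_genic fraction of single-copy SNPs placed inside CDS exons.
#' @param frac_nonsyn fraction of genic SNPs forced nonsynonymous.
#' @param frac_stop fraction of genic SNPs forced stop-introducing.
#' @param indel_short_frac probability an InDel length is drawn from 1-6 bp
#'   (otherwise 7-30 bp).
#' @param ssr_indels_per_taxon InDels planted inside SSR tracts per taxon.
#' @param marker_indels_per_taxon guaranteed clean (>= 7 bp, non-SSR,
#'   conserved-flank) species-specific InDels per taxon.
#' @param pseudogene_stop,pseudogene_frameshift `list(taxon=, gene=)` or
#'   `NULL`; plant a premature-stop SNP / 1 bp frameshift insertion in the
#'   named gene.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       lsc_len = 84500L, ssc_len = 18700L, ir_len = 26000L,
                       n_genes = c(protein_coding = 79L, tRNA = 29L, rRNA = 4L),
                       cds_len_range = c(300L, 1200L),
                       intron_frac = 0.08,
                       gc = 0.369,
                       n_ssr = 30L,
                       taxa = c("A_coreana", "A_gorovoii", "A_nipponica", "A_pilosa"),
                       snp_counts = c(118L, 109L, 148L, 96L),
                       shared_snps = 26L,
                       indel_counts = c(49L, 50L, 51L, 37L),
                       ir_snp_frac = 0.06,
                       frac_genic = 0.25,
                       frac_nonsyn = 0.5,
                       frac_stop = 0.02,
                       indel_short_frac = 0.8,
                       ssr_indels_per_taxon = 2L,
                       marker_indels_per_taxon = 1L,
                       pseudogene_stop = list(taxon = "A_nipponica", gene = "infA"),
                       pseudogene_frameshift = list(taxon = "A_pilosa", gene = "rps16")) {
  cfg <- as.list(environment())
  stopifnot(length(cfg$taxa) == 4L,
            length(cfg$snp_counts) == 4L, length(cfg$indel_counts) == 4L,
            all(cfg$snp_counts >= 0L), all(cfg$indel_counts >= 0L),
            cfg$shared_snps >= 0L)
  class(cfg) <- "sim_config"
  cfg
}

#' Realistic-scale preset configuration
#'
#' The default [sim_config()] at a chosen seed: ~155 kb architecture,
#' 497 SNP and 187 InDel events across 4 taxa, with at least one
#' qualifying (>= 7 bp, non-SSR) species-specific InDel per taxon so marker
#' design succeeds for all four species.
#'
#' @param seed RNG seed.
#' @return `sim_config`.
#' @export
scale_preset <- function(seed = 1L) sim_config(seed = seed)

random_codons <- function(k) {
  all_cod <- as.vector(outer(as.vector(outer(DNA_BASES4, DNA_BASES4, paste0)),
                             DNA_BASES4, paste0))
  sense <- setdiff(all_cod, STOP_CODONS)
  paste(sample(sense, k, replace = TRUE), collapse = "")
}

make_cds <- function(len) {
  stopifnot(len %% 3L == 0L, len >= 9L)
  paste0("ATG", random_codons(len / 3L - 2L), "TAA")
}

# one gene's genomic segment plus local exon rows
make_gene_segment <- function(gene, kind, len, strand, two_exon = FALSE,
                              intron_len = 0L, force_codon = NULL) {
  if (kind == "protein_coding") {
    cds <- make_cds(len)
    if (!is.null(force_codon)) {
      # guarantee a specific codon at a given codon index (1-based)
      ci <- force_codon$index
      substr(cds, (ci - 1L) * 3L + 1L, ci * 3L) <- force_codon$codon
    }
    if (two_exon && intron_len > 0L) {
      cut <- 3L * sample(2:(len / 3L - 2L), 1L)    # codon boundary
      e1 <- substr(cds, 1L, cut)
      e2 <- substr(cds, cut + 1L, len)
      intron <- random_dna(intron_len)
      plus_seg <- paste0(e1, intron, e2)
      if (strand == "+") {
        seg <- plus_seg
        ex <- data.frame(start = c(1L, cut + intron_len + 1L),
                         end = c(cut, nchar(plus_seg)))
      } else {
        seg <- revcomp(plus_seg)
        l2 <- nchar(e2)
        ex <- data.frame(start = c(1L, l2 + intron_len + 1L),
                         end = c(l2, nchar(plus_seg)))
      }
    } else {
      seg <- if (strand == "+") cds else revcomp(cds)
      ex <- data.frame(start = 1L, end = len)
    }
  } else {
    seg <- random_dna(len)
    ex <- data.frame(start = 1L, end = len)
  }
  list(seq = seg, exons = ex, gene = gene, kind = kind, strand = strand)
}

SSR_MOTIFS <- list(`1` = c("A", "T"), `2` = c("AT", "TA", "AG", "TC"),
                   `3` = c("AAT", "ATT", "AAG"), `4` = c("AATT", "AAAT"))

make_ssr <- function() {
  m <- sample(c(1L, 1L, 2L, 2L, 3L, 4L), 1L)      # mono/di-rich, like plastomes
  motif <- sample(SSR_MOTIFS[[as.character(m)]], 1L)
  units <- switch(as.character(m), `1` = sample(10:14, 1L),
                  `2` = sample(6:9, 1L), `3` = sample(5:7, 1L),
                  `4` = sample(5:6, 1L))
  list(motif = motif, units = units, seq = strrep(motif, units))
}

# random spacer, optionally embedding an SSR tract with non-extendable flanks:
# the base adjacent to each tract boundary is forced to break the tandem
# period, so the planted tract is exactly the maximal one
make_spacer <- function(len, ssr = NULL, gc = 0.369) {
  if (is.null(ssr)) return(list(seq = random_dna(len, gc), ssr = NULL))
  tlen <- nchar(ssr$seq)
  m <- nchar(ssr$motif)
  lpad <- max(2L, (len - tlen) %/% 2L)
  rpad <- max(2L, len - tlen - lpad)
  lv <- strsplit(random_dna(lpad, gc), "", fixed = TRUE)[[1L]]
  lv[length(lv)] <- setdiff(DNA_BASES4, substr(ssr$motif, m, m))[1L]
  rv <- strsplit(random_dna(rpad, gc), "", fixed = TRUE)[[1L]]
  rv[1L] <- setdiff(DNA_BASES4, substr(ssr$motif, 1L, 1L))[1L]
  left <- paste(lv, collapse = ""); right <- paste(rv, collapse = "")
  list(seq = paste0(left, ssr$seq, right),
       ssr = list(motif = ssr$motif, units = ssr$units,
                  start = nchar(left) + 1L, end = nchar(left) + tlen))
}

# assemble one region from alternating spacers and genes; returns sequence,
# feature rows and ssr rows in region-local coordinates
build_region <- function(target_len, gene_specs, n_ssr, gc,
                         spacer_range = c(150L, 400L)) {
  pieces <- character(0)
  feats <- list(); ssrs <- list()
  pos <- 0L
  ssr_left <- n_ssr
  gi <- 0L
  for (spec in gene_specs) {
    sp_len <- sample(spacer_range[1L]:spacer_range[2L], 1L)
    ssr <- NULL
    if (ssr_left > 0L && runif(1) < 0.6) {
      ssr <- make_ssr()
      sp_len <- max(sp_len, nchar(ssr$seq) + 30L)
      ssr_left <- ssr_left - 1L
    }
    glen <- nchar(spec$seq)
    if (pos + sp_len + glen + 60L > target_len) break
    sp <- make_spacer(sp_len, ssr, gc)
    if (!is.null(sp$ssr)) {
      ssrs[[length(ssrs) + 1L]] <- data.frame(
        motif = sp$ssr$motif, unit_count = sp$ssr$units,
        start = pos + sp$ssr$start, end = pos + sp$ssr$end,
        stringsAsFactors = FALSE)
    }
    pieces <- c(pieces, sp$seq)
    pos <- pos + nchar(sp$seq)
    feats[[length(feats) + 1L]] <- data.frame(
      gene = spec$gene, kind = spec$kind, strand = spec$strand,
      start = pos + spec$exons$start, end = pos + spec$exons$end,
      stringsAsFactors = FALSE)
    pieces <- c(pieces, spec$seq)
    pos <- pos + glen
    gi <- gi + 1L
  }
  if (gi < length(gene_specs))
    stop("architecture too small for requested gene load (placed ", gi,
         " of ", length(gene_specs), " genes)")
  # trailing pad; embed leftover SSR quota here
  while (ssr_left > 0L && target_len - pos > 200L) {
    ssr <- make_ssr()
    sp <- make_spacer(nchar(ssr$seq) + 40L, ssr, gc)
    ssrs[[length(ssrs) + 1L]] <- data.frame(
      motif = sp$ssr$motif, unit_count = sp$ssr$units,
      start = pos + sp$ssr$start, end = pos + sp$ssr$end,
      stringsAsFactors = FALSE)
    pieces <- c(pieces, sp$seq)
    pos <- pos + nchar(sp$seq)
    ssr_left <- ssr_left - 1L
  }
  if (pos < target_len) pieces <- c(pieces, random_dna(target_len - pos, gc))
  list(seq = paste(pieces, collapse = ""),
       features = if (length(feats)) do.call(rbind, feats) else NULL,
       ssrs = if (length(ssrs)) do.call(rbind, ssrs) else NULL)
}

real_gene_names <- function(n_pcg, n_trna, n_rrna, special = c("infA", "rps16")) {
  base_pcg <- c("psbA", "matK", "rps16", "psbK", "psbI", "atpA", "atpF",
                "atpH", "atpI", "rps2", "rpoC2", "rpoC1", "rpoB", "petN",
                "psbM", "psbD", "psbC", "psaB", "psaA", "ycf3", "rps4",
                "ndhJ", "ndhK", "ndhC", "atpE", "atpB", "rbcL", "accD",
                "psaI", "ycf4", "cemA", "petA", "psbJ", "psbL", "psbF",
                "psbE", "petL", "petG", "psaJ", "rpl33", "rps18", "rpl20",
                "rps12", "clpP", "psbB", "psbT", "psbN", "psbH", "petB",
                "petD", "rpoA", "rps11", "rpl36", "infA", "rps8", "rpl14",
                "rpl16", "rps3", "rpl22", "rps19", "rpl2", "rpl23", "ycf2",
                "ndhB", "rps7", "ycf1", "ndhF", "rpl32", "ccsA", "ndhD",
                "psaC", "ndhE", "ndhG", "ndhI", "ndhA", "ndhH", "rps15",
                "sprA", "pbf1")
  pcg <- unique(c(special, base_pcg))
  if (n_pcg > length(pcg)) pcg <- c(pcg, sprintf("orf%03d", seq_len(n_pcg)))
  trna <- sprintf("trn%s", c("H", "K", "Q", "S", "G", "R", "C", "D", "Y",
                             "E", "T", "S2", "G2", "M", "V", "F", "L", "W",
                             "P", "I", "A", "N", "L2", "V2", "I2", "R2",
                             "N2", "L3", "M2"))
  if (n_trna > length(trna)) trna <- c(trna, sprintf("trnX%02d", seq_len(n_trna)))
  rrna <- c("rrn16", "rrn23", "rrn4.5", "rrn5")
  if (n_rrna > length(rrna)) rrna <- c(rrna, sprintf("rrnX%02d", seq_len(n_rrna)))
  list(pcg = pcg[seq_len(n_pcg)], trna = trna[seq_len(n_trna)],
       rrna = rrna[seq_len(n_rrna)])
}

# ---- event planning -------------------------------------------------------

# sample a start position whose [p - margin, p + len - 1 + margin] window
# (plus an optional clear zone) is fully available, then reserve the window
pick_window <- function(avail, len, margin = 2L, clear = 0L) {
  w <- len + 2L * (margin + clear)
  n <- length(avail)
  if (w > n) return(NULL)
  cs <- cumsum(!avail)
  a_first <- which(cs[seq.int(w, n)] - c(0L, cs)[seq.int(1L, n - w + 1L)] == 0L)
  if (!length(a_first)) return(NULL)
  a <- a_first[sample.int(length(a_first), 1L)]      # window start
  p <- a + margin + clear
  list(p = p, reserve = c(a, a + w - 1L))
}

indel_length <- function(short_frac) {
  if (runif(1) < short_frac) sample(1:6, 1L) else sample(7:30, 1L)
}

# choose an alternate base at a genic position forcing a wanted category
forced_alt <- function(anc_rec, pos, want, code = "11") {
  ref <- substr(anc_rec$sequence, pos, pos)
  for (alt in setdiff(DNA_BASES4, ref)) {
    eff <- tryCatch(classify_snp(anc_rec, pos, alt, code = code),
                    error = function(e) NULL)
    if (!is.null(eff) && identical(eff$category, want))
      return(list(alt = alt, gene = eff$gene))
  }
  NULL
}

#' Generate a truth-tracked synthetic plastome set
#'
#' Builds the quadripartite ancestor, plants per-species variants with full
#' gap bookkeeping, and returns the four derived genomes together with the
#' true alignment, the true variant list, and a manifest of independently
#' recounted tallies. Fully reproducible from `config$seed`; the caller's
#' RNG stream is left untouched.
#'
#' @param config `sim_config`.
#' @return list of class `truth_set`: `config`, `ancestor`
#'   (`genome_record`), `partition` (ancestral `region_partition`),
#'   `genomes` (`genome_set`), `alignment` (`plastome_alignment`), `truth`
#'   (`variant_table` with extra `donor`, `region`, `tag` columns),
#'   `ssrs` (planted tracts, ancestor coordinates), `manifest` (list).
#' @export
generate <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_preserved_rng(config$seed, generate_impl(config))
}

generate_impl <- function(cfg) {
  taxa <- cfg$taxa
  ng <- cfg$n_genes
  nm <- real_gene_names(ng[["protein_coding"]], ng[["tRNA"]], ng[["rRNA"]])
  ps_stop <- cfg$pseudogene_stop
  if (!is.null(ps_stop) &&
      (!ps_stop$taxon %in% taxa || !ps_stop$gene %in% nm$pcg)) ps_stop <- NULL
  ps_fs <- cfg$pseudogene_frameshift
  if (!is.null(ps_fs) &&
      (!ps_fs$taxon %in% taxa || !ps_fs$gene %in% nm$pcg)) ps_fs <- NULL
  specials <- c(if (!is.null(ps_stop)) ps_stop$gene,
                if (!is.null(ps_fs)) ps_fs$gene)

  # --- gene specs ----------------------------------------------------------
  lens3 <- function(k) 3L * sample((cfg$cds_len_range[1L] %/% 3L):
                                     (cfg$cds_len_range[2L] %/% 3L), k,
                                   replace = TRUE)
  pcg_specs <- lapply(seq_along(nm$pcg), function(i) {
    g <- nm$pcg[i]
    len <- max(lens3(1L), 120L)
    special <- g %in% specials
    strand <- if (special) "+" else sample(c("+", "-"), 1L)
    two_exon <- !special && runif(1) < cfg$intron_frac
    force_codon <- if (!is.null(ps_stop) && g == ps_stop$gene)
      list(index = 10L, codon = "CAA") else NULL
    make_gene_segment(g, "protein_coding", len, strand, two_exon,
                      intron_len = sample(150:300, 1L),
                      force_codon = force_codon)
  })
  trna_specs <- lapply(nm$trna, function(g)
    make_gene_segment(g, "tRNA", sample(72:90, 1L), sample(c("+", "-"), 1L)))
  rrna_lens <- c(1491L, 2810L, 121L, 103L)
  rrna_specs <- lapply(seq_along(nm$rrna), function(i)
    make_gene_segment(nm$rrna[i], "rRNA",
                      rrna_lens[((i - 1L) %% 4L) + 1L], "+"))
  # SSC takes a slice of non-special protein-coding genes, everything else
  # (plus the tRNAs) goes to the LSC; rRNAs live in the IR
  non_special <- which(!vapply(pcg_specs, function(s) s$gene %in% specials,
                               TRUE))
  n_ssc <- min(length(non_special),
               max(0L, round(length(pcg_specs) * cfg$ssc_len /
                               (cfg$ssc_len + cfg$lsc_len))))
  ssc_idx <- if (n_ssc > 0L) sort(sample(non_special, n_ssc)) else integer(0)
  lsc_specs <- c(pcg_specs[setdiff(seq_along(pcg_specs), ssc_idx)], trna_specs)
  lsc_specs <- lsc_specs[sample.int(length(lsc_specs))]
  ssc_specs <- pcg_specs[ssc_idx]

  n_ssr_lsc <- round(0.7 * cfg$n_ssr)
  lsc <- build_region(cfg$lsc_len, lsc_specs, n_ssr_lsc, cfg$gc)
  ssc <- build_region(cfg$ssc_len, ssc_specs, cfg$n_ssr - n_ssr_lsc, cfg$gc)
  irb <- build_region(cfg$ir_len, rrna_specs, 0L, cfg$gc)

  off_irb <- cfg$lsc_len
  off_ssc <- cfg$lsc_len + cfg$ir_len
  shift <- function(df, off) {
    if (is.null(df)) return(NULL)
    df$start <- df$start + off; df$end <- df$end + off
    df
  }
  features <- do.call(rbind, Filter(Negate(is.null),
    list(lsc$features, shift(irb$features, off_irb), shift(ssc$features, off_ssc))))
  if (is.null(features))
    features <- data.frame(gene = character(), kind = character(),
                           strand = character(), start = integer(),
                           end = integer(), stringsAsFactors = FALSE)
  ssrs <- do.call(rbind, Filter(Negate(is.null),
    list(lsc$ssrs, shift(ssc$ssrs, off_ssc))))
  if (is.null(ssrs)) ssrs <- data.frame(motif = character(),
                                        unit_count = integer(),
                                        start = integer(), end = integer(),
                                        stringsAsFactors = FALSE)

  anc <- paste0(lsc$seq, irb$seq, ssc$seq, revcomp(irb$seq))
  n <- nchar(anc)
  # guard the IRb|SSC / SSC|IRa junctions against spurious IR extension
  ssc_first <- off_ssc + 1L; ssc_last <- off_ssc + cfg$ssc_len
  if (substr(anc, ssc_first, ssc_first) ==
      complement_base(substr(anc, ssc_last, ssc_last))) {
    repl <- setdiff(DNA_BASES4,
                    complement_base(substr(anc, ssc_first, ssc_first)))[1L]
    substr(anc, ssc_last, ssc_last) <- repl
  }
  anc_rec <- genome_record("ancestor", anc, accession = "SYN_ANC",
                           features = features)
  partition <- region_partition(c(lsc = cfg$lsc_len, irb = cfg$ir_len,
                                  ssc = cfg$ssc_len, ira = cfg$ir_len))

  # --- position pools ------------------------------------------------------
  avail <- logical(n)
  avail[1:cfg$lsc_len] <- TRUE
  avail[ssc_first:ssc_last] <- TRUE
  bd <- 60L
  avail[1:min(bd, n)] <- FALSE
  avail[max(1L, cfg$lsc_len - bd):cfg$lsc_len] <- FALSE
  avail[ssc_first:min(n, ssc_first + bd)] <- FALSE
  avail[max(1L, ssc_last - bd):ssc_last] <- FALSE
  if (nrow(features)) for (i in seq_len(nrow(features)))
    avail[max(1L, features$start[i] - 3L):min(n, features$end[i] + 3L)] <- FALSE
  if (nrow(ssrs)) for (i in seq_len(nrow(ssrs)))
    avail[max(1L, ssrs$start[i] - 2L):min(n, ssrs$end[i] + 2L)] <- FALSE

  irb_avail <- logical(n)
  irb_avail[(off_irb + bd):(off_irb + cfg$ir_len - bd)] <- TRUE
  if (nrow(features)) for (i in seq_len(nrow(features)))
    irb_avail[max(1L, features$start[i] - 3L):min(n, features$end[i] + 3L)] <- FALSE

  genic_pool <- integer(0)
  sc_pcg <- features[features$kind == "protein_coding" &
                       features$end <= off_irb | features$start >= ssc_first, ,
                     drop = FALSE]
  sc_pcg <- sc_pcg[sc_pcg$kind == "protein_coding" &
                     !sc_pcg$gene %in% specials, , drop = FALSE]
  for (i in seq_len(nrow(sc_pcg))) {
    a <- sc_pcg$start[i] + 6L; b <- sc_pcg$end[i] - 6L
    if (b > a) genic_pool <- c(genic_pool, a:b)
  }

  events <- list()
  add_event <- function(type, p, len, donors, alt = NA_character_,
                        ins_seq = NA_character_, tag = "") {
    events[[length(events) + 1L]] <<- list(type = type, p = as.integer(p),
                                           len = as.integer(len),
                                           donors = donors, alt = alt,
                                           ins_seq = ins_seq, tag = tag)
  }
  take_window <- function(len, margin = 2L, clear = 0L, pool = "sc") {
    vec <- if (pool == "sc") avail else irb_avail
    w <- pick_window(vec, len, margin, clear)
    if (is.null(w)) stop("config error: no room left to plant a ", len,
                         " bp event (architecture too small for variant load)")
    if (pool == "sc") avail[w$reserve[1L]:w$reserve[2L]] <<- FALSE
    else irb_avail[w$reserve[1L]:w$reserve[2L]] <<- FALSE
    w$p
  }
  random_alt <- function(p) sample(setdiff(DNA_BASES4, substr(anc, p, p)), 1L)

  # --- pseudogene lesions --------------------------------------------------
  if (!is.null(ps_stop)) {
    f <- features[features$gene == ps_stop$gene, , drop = FALSE]
    pos <- f$start[1L] + 27L                       # codon 10, first position
    add_event("snp", pos, 1L, ps_stop$taxon, alt = "T", tag = "pseudogene_stop")
  }
  if (!is.null(ps_fs)) {
    f <- features[features$gene == ps_fs$gene, , drop = FALSE]
    pos <- f$start[1L] + 30L                       # inside the CDS
    add_event("ins", pos, 1L, ps_fs$taxon,
              ins_seq = sample(DNA_BASES4, 1L), tag = "pseudogene_frameshift")
  }

  # --- per-taxon InDels ----------------------------------------------------
  ssr_free <- seq_len(nrow(ssrs))               # each tract hosts <= 1 InDel
  for (k in seq_along(taxa)) {
    t <- taxa[k]
    budget <- cfg$indel_counts[k]
    if (!is.null(ps_fs) && ps_fs$taxon == t) budget <- budget - 1L
    n_marker <- min(cfg$marker_indels_per_taxon, max(budget, 0L))
    budget <- budget - n_marker
    n_ssr_i <- min(cfg$ssr_indels_per_taxon, max(budget, 0L), length(ssr_free))
    budget <- budget - n_ssr_i
    for (q in seq_len(n_marker)) {
      len <- sample(8:25, 1L)
      if (runif(1) < 0.5) {
        p <- take_window(len, margin = 2L, clear = 80L)
        add_event("del", p, len, t, tag = "marker")
      } else {
        p <- take_window(1L, margin = 2L, clear = 80L)
        add_event("ins", p, len, t, ins_seq = random_dna(len, cfg$gc),
                  tag = "marker")
      }
    }
    if (n_ssr_i > 0L) {
      use <- ssr_free[sample.int(length(ssr_free), n_ssr_i)]
      ssr_free <- setdiff(ssr_free, use)
      for (q in use) {
        m <- nchar(ssrs$motif[q])
        units_del <- min(max(1L, if (m == 1L) 8L else 2L),
                         ssrs$unit_count[q] - 2L)
        if (units_del < 1L) units_del <- 1L
        len <- m * units_del
        add_event("del", ssrs$start[q], len, t, tag = "ssr_assoc")
      }
    }
    for (q in seq_len(max(budget, 0L))) {
      len <- indel_length(cfg$indel_short_frac)
      if (runif(1) < 0.5) {
        p <- take_window(len)
        add_event("del", p, len, t, tag = "")
      } else {
        p <- take_window(1L)
        add_event("ins", p, len, t, ins_seq = random_dna(len, cfg$gc), tag = "")
      }
    }
  }

  # --- per-taxon SNPs ------------------------------------------------------
  for (k in seq_along(taxa)) {
    t <- taxa[k]
    total <- cfg$snp_counts[k]
    ir_pairs <- floor(cfg$ir_snp_frac * total / 2)
    rest <- total - 2L * ir_pairs
    n_genic <- if (length(genic_pool) > 50L) round(cfg$frac_genic * rest) else 0L
    n_stop <- if (n_genic > 0L) round(cfg$frac_stop * n_genic) else 0L
    if (!is.null(ps_stop) && ps_stop$taxon == t) {
      if (n_stop > 0L) n_stop <- n_stop - 1L else n_genic <- max(n_genic - 1L, 0L)
      rest <- rest - 1L                            # the planted stop SNP
    }
    n_nonsyn <- if (n_genic > 0L) round(cfg$frac_nonsyn * n_genic) else 0L
    n_free_genic <- max(n_genic - n_nonsyn - n_stop, 0L)
    n_genic <- n_nonsyn + n_stop + n_free_genic
    place_genic <- function(count, want) {
      placed <- 0L
      guard <- 0L
      while (placed < count && guard < 50L * count + 50L &&
             length(genic_pool) > 0L) {
        guard <- guard + 1L
        p <- genic_pool[sample.int(length(genic_pool), 1L)]
        if (is.null(want)) {
          genic_pool <<- setdiff(genic_pool, p)
          add_event("snp", p, 1L, t, alt = random_alt(p), tag = "genic")
          placed <- placed + 1L
        } else {
          fa <- forced_alt(anc_rec, p, want)
          if (!is.null(fa)) {
            genic_pool <<- setdiff(genic_pool, p)
            add_event("snp", p, 1L, t, alt = fa$alt, tag = paste0("forced_", want))
            placed <- placed + 1L
          }
        }
      }
      placed
    }
    placed <- place_genic(n_nonsyn, "nonsynonymous") +
      place_genic(n_stop, "stop_gained") +
      place_genic(n_free_genic, NULL)
    # any genic deficit falls back to intergenic so per-taxon totals are exact
    n_intergenic <- max(rest - placed, 0L)
    for (q in seq_len(n_intergenic)) {
      p <- take_window(1L)
      add_event("snp", p, 1L, t, alt = random_alt(p), tag = "")
    }
    for (q in seq_len(ir_pairs)) {
      w <- pick_window(irb_avail, 1L, margin = 2L)
      if (is.null(w)) stop("config error: no room in the IR for mirrored SNPs")
      irb_avail[w$reserve[1L]:w$reserve[2L]] <- FALSE
      p <- w$p
      alt <- random_alt(p)
      pm <- off_ssc + cfg$ssc_len + (off_irb + cfg$ir_len + 1L - p) # mirror in IRa
      add_event("snp", p, 1L, t, alt = alt, tag = "ir_mirror")
      add_event("snp", pm, 1L, t, alt = complement_base(alt), tag = "ir_mirror")
    }
  }

  # --- shared (non-specific) SNPs ------------------------------------------
  if (cfg$shared_snps > 0L) {
    pairs <- list(taxa[c(1L, 2L)], taxa[c(3L, 4L)])
    counts <- c(cfg$shared_snps %/% 2L, cfg$shared_snps - cfg$shared_snps %/% 2L)
    for (pi in seq_along(pairs)) {
      for (q in seq_len(counts[pi])) {
        p <- take_window(1L)
        add_event("snp", p, 1L, pairs[[pi]], alt = random_alt(p), tag = "shared")
      }
    }
  }

  # --- emission: build true alignment --------------------------------------
  ord <- order(vapply(events, function(e)
    e$p + if (e$type == "ins") 0.5 else 0, 0))
  events <- events[ord]
  if (length(events) > 1L) {
    fp_start <- vapply(events, function(e)
      as.integer(e$p) + if (e$type == "ins") 1L else 0L, 0L)
    fp_end <- vapply(events, function(e)
      as.integer(e$p) + if (e$type == "del") e$len - 1L else 0L, 0L)
    if (any(fp_start[-1L] <= fp_end[-length(events)]))
      stop("internal error: planted events overlap")
  }
  nt <- length(taxa)
  pieces <- replicate(nt, list(), simplify = FALSE)
  seg_anc <- integer(0); seg_col <- integer(0); seg_len <- integer(0)
  cur <- 1L; col <- 1L
  ev_cols <- matrix(0L, nrow = length(events), ncol = 2L)
  emit_conserved <- function(a, b) {
    if (b < a) return(invisible(NULL))
    chunk <- substr(anc, a, b)
    for (i in seq_len(nt)) pieces[[i]][[length(pieces[[i]]) + 1L]] <<- chunk
    seg_anc <<- c(seg_anc, a); seg_col <<- c(seg_col, col)
    seg_len <<- c(seg_len, b - a + 1L)
    col <<- col + (b - a + 1L)
  }
  for (ei in seq_along(events)) {
    e <- events[[ei]]
    if (e$type == "ins") {
      emit_conserved(cur, e$p)
      cur <- e$p + 1L
      ev_cols[ei, ] <- c(col, col + e$len - 1L)
      for (i in seq_len(nt)) {
        piece <- if (taxa[i] %in% e$donors) e$ins_seq else strrep("-", e$len)
        pieces[[i]][[length(pieces[[i]]) + 1L]] <- piece
      }
      col <- col + e$len
    } else if (e$type == "del") {
      emit_conserved(cur, e$p - 1L)
      cur <- e$p + e$len
      ev_cols[ei, ] <- c(col, col + e$len - 1L)
      chunk <- substr(anc, e$p, e$p + e$len - 1L)
      for (i in seq_len(nt)) {
        piece <- if (taxa[i] %in% e$donors) strrep("-", e$len) else chunk
        pieces[[i]][[length(pieces[[i]]) + 1L]] <- piece
      }
      seg_anc <- c(seg_anc, e$p); seg_col <- c(seg_col, col)
      seg_len <- c(seg_len, e$len)
      col <- col + e$len
    } else {                                        # snp
      emit_conserved(cur, e$p - 1L)
      cur <- e$p + 1L
      ev_cols[ei, ] <- c(col, col)
      ref <- substr(anc, e$p, e$p)
      for (i in seq_len(nt)) {
        piece <- if (taxa[i] %in% e$donors) e$alt else ref
        pieces[[i]][[length(pieces[[i]]) + 1L]] <- piece
      }
      seg_anc <- c(seg_anc, e$p); seg_col <- c(seg_col, col)
      seg_len <- c(seg_len, 1L)
      col <- col + 1L
    }
  }
  emit_conserved(cur, n)
  rows <- vapply(pieces, function(pl) paste(unlist(pl), collapse = ""), "")
  aln <- alignment_from_seqs(setNames(rows, taxa))

  anc2col <- integer(n)
  for (i in seq_along(seg_anc))
    anc2col[seg_anc[i]:(seg_anc[i] + seg_len[i] - 1L)] <-
      seg_col[i]:(seg_col[i] + seg_len[i] - 1L)

  # --- truth variant table -------------------------------------------------
  ev_list <- lapply(seq_along(events), function(ei) {
    e <- events[[ei]]
    ref <- if (e$type == "del") substr(anc, e$p, e$p + e$len - 1L)
           else substr(anc, e$p, e$p)
    al <- vapply(taxa, function(t) {
      if (e$type == "snp") { if (t %in% e$donors) e$alt else ref }
      else if (e$type == "del") { if (t %in% e$donors) strrep("-", e$len) else ref }
      else { if (t %in% e$donors) e$ins_seq else strrep("-", e$len) }
    }, "")
    list(kind = if (e$type == "snp") "SNP" else "InDel",
         s = ev_cols[ei, 1L], e = ev_cols[ei, 2L], alleles = al)
  })
  truth <- variant_table(ev_list, aln)
  # variant_table sorts by start column; carry metadata through that order
  meta_ord <- order(ev_cols[, 1L])
  truth$donor <- vapply(events[meta_ord], function(e)
    paste(e$donors, collapse = ","), "")
  truth$region <- region_of(partition,
                            vapply(events[meta_ord], function(e) e$p, 0L))
  truth$tag <- vapply(events[meta_ord], function(e) e$tag, "")

  # --- derived genomes and per-taxon features ------------------------------
  cum <- cum_base_matrix(aln)
  genomes <- lapply(seq_along(taxa), function(i) {
    f <- features
    if (nrow(f)) {
      f$start <- cum[i, anc2col[features$start]]
      f$end <- cum[i, anc2col[features$end]]
    }
    genome_record(taxa[i], gsub("-", "", aln$seqs[[i]], fixed = TRUE),
                  accession = sprintf("SYN%04d", i), features = f)
  })
  names(genomes) <- taxa
  class(genomes) <- "genome_set"

  manifest <- build_manifest(cfg, taxa, events, partition, features, ssrs,
                             genomes, ps_stop, ps_fs)
  structure(list(config = cfg, ancestor = anc_rec, partition = partition,
                 genomes = genomes, alignment = aln, truth = truth,
                 ssrs = ssrs, manifest = manifest),
            class = "truth_set")
}

# independent recount of all tallies straight from the planted event list
build_manifest <- function(cfg, taxa, events, partition, features, ssrs,
                           genomes, ps_stop, ps_fs) {
  is_snp <- vapply(events, function(e) e$type == "snp", TRUE)
  lens <- vapply(events, function(e) if (e$type == "snp") 0L else e$len, 0L)
  donors <- lapply(events, `[[`, "donors")
  single <- vapply(donors, length, 0L) == 1L
  regions <- region_of(partition, vapply(events, `[[`, 0L, "p"))
  sp_snp <- sp_ind <- sp_bp <- setNames(integer(length(taxa)), taxa)
  for (k in seq_along(taxa)) {
    sel <- single & vapply(donors, function(d) d[1L] == taxa[k], TRUE)
    sp_snp[k] <- sum(sel & is_snp)
    sp_ind[k] <- sum(sel & !is_snp)
    sp_bp[k] <- sum(lens[sel & !is_snp])
  }
  nt <- length(taxa)
  pw_snp <- pw_ind <- pw_bp <- matrix(0L, nt, nt, dimnames = list(taxa, taxa))
  for (i in seq_len(nt - 1L)) for (j in (i + 1L):nt) {
    differs <- vapply(donors, function(d)
      xor(taxa[i] %in% d, taxa[j] %in% d), TRUE)
    pw_snp[i, j] <- pw_snp[j, i] <- sum(differs & is_snp)
    pw_ind[i, j] <- pw_ind[j, i] <- sum(differs & !is_snp)
    pw_bp[i, j] <- pw_bp[j, i] <- sum(lens[differs & !is_snp])
  }
  # per-taxon region lengths: ancestral length +/- planted InDels by region
  reg_len <- lapply(seq_along(taxa), function(k) {
    net <- function(reg) {
      sel <- vapply(donors, function(d) taxa[k] %in% d, TRUE) & !is_snp &
        regions == reg
      ins <- vapply(events, function(e) e$type == "ins", TRUE)
      sum(lens[sel & ins]) - sum(lens[sel & !ins])
    }
    c(lsc = unname(partition$lengths[["lsc"]]) + net("LSC"),
      ir = unname(partition$lengths[["irb"]]),
      ssc = unname(partition$lengths[["ssc"]]) + net("SSC"),
      total = nchar(genomes[[k]]$sequence))
  })
  names(reg_len) <- taxa
  qual <- vapply(events, function(e)
    e$type != "snp" && e$len >= 7L && length(e$donors) == 1L &&
      e$tag %in% c("marker", ""), TRUE)
  qual_by_taxon <- vapply(taxa, function(t)
    sum(qual & vapply(donors, function(d) d[1L] == t, TRUE)), 0L)
  pseudo <- list()
  if (!is.null(ps_stop)) pseudo[[length(pseudo) + 1L]] <-
    list(gene = ps_stop$gene, taxon = ps_stop$taxon, reason = "premature_stop",
         stop_position = 10L)
  if (!is.null(ps_fs)) pseudo[[length(pseudo) + 1L]] <-
    list(gene = ps_fs$gene, taxon = ps_fs$taxon, reason = "frameshift",
         stop_position = NA_integer_)
  list(taxa = taxa, seed = cfg$seed,
       ancestral_lengths = as.list(partition$lengths),
       region_lengths = reg_len,
       gene_counts = list(
         total = length(unique(features$gene)),
         protein_coding = length(unique(features$gene[features$kind == "protein_coding"])),
         tRNA = length(unique(features$gene[features$kind == "tRNA"])),
         rRNA = length(unique(features$gene[features$kind == "rRNA"]))),
       n_feature_rows = nrow(features),
       n_ssr = nrow(ssrs),
       totals = list(snp = sum(is_snp), indel = sum(!is_snp),
                     variable_sites = length(events),
                     indel_bp = sum(lens)),
       species_specific = list(snp = as.list(sp_snp), indel = as.list(sp_ind),
                               indel_bp = as.list(sp_bp),
                               total = as.list(sp_snp + sp_ind)),
       pairwise = list(snp = pw_snp, indel_sites = pw_ind, indel_bp = pw_bp),
       qualifying_marker_indels = as.list(qual_by_taxon),
       pseudogenes = pseudo)
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("<truth_set> %d taxa, ancestor %s bp, %d planted events (%d SNP / %d InDel)\n",
              length(x$genomes), format(nchar(x$ancestor$sequence), big.mark = ","),
              nrow(x$truth), sum(x$truth$kind == "SNP"),
              sum(x$truth$kind == "InDel")))
  invisible(x)
}

#' Write a truth set to disk
#'
#' Writes `genomes.fasta`, `features.gff3`, `alignment.fasta`,
#' `truth_variants.tsv` and `manifest.json` into `dir`. Reruns with the
#' same config are byte-identical.
#'
#' @param ts `truth_set`; @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_truth_set <- function(ts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gseq <- Biostrings::DNAStringSet(vapply(ts$genomes, `[[`, "", "sequence"))
  names(gseq) <- names(ts$genomes)
  Biostrings::writeXStringSet(gseq, file.path(dir, "genomes.fasta"))
  aseq <- Biostrings::BStringSet(ts$alignment$seqs)
  Biostrings::writeXStringSet(aseq, file.path(dir, "alignment.fasta"))
  feats <- do.call(rbind, lapply(ts$genomes, function(g) {
    if (!nrow(g$features)) return(NULL)
    cbind(seqid = g$id, g$features)
  }))
  if (!is.null(feats)) {
    type_map <- c(protein_coding = "CDS", tRNA = "tRNA", rRNA = "rRNA")
    gr <- GenomicRanges::GRanges(feats$seqid,
                                 IRanges::IRanges(feats$start, feats$end),
                                 strand = feats$strand)
    gr$type <- unname(type_map[feats$kind])
    # exons are cut at codon boundaries, so CDS phase is always 0
    gr$phase <- ifelse(feats$kind == "protein_coding", 0L, NA_integer_)
    gr$gene <- feats$gene
    gr$ID <- sprintf("%s_%s_%d", feats$seqid, feats$gene, seq_len(nrow(feats)))
    rtracklayer::export(gr, file.path(dir, "features.gff3"), format = "gff3")
  }
  write_variant_table(ts$truth, file.path(dir, "truth_variants.tsv"),
                      partition = ts$partition,
                      meta = list(seed = ts$config$seed))
  jsonlite::write_json(ts$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Expand a truth set to several individuals per species
#'
#' Duplicates each taxon's alignment row `k` times and plants a few private
#' SNPs per individual at event-free conserved columns, yielding a
#' population-style alignment (used for phylogeny tests: conspecific
#' individuals should come out as sisters).
#'
#' @param ts `truth_set`.
#' @param k individuals per species.
#' @param n_private private SNPs per individual.
#' @param seed RNG seed.
#' @return `plastome_alignment` with `k * length(taxa)` rows labelled
#'   `<taxon>_1 ... <taxon>_k`.
#' @export
expand_individuals <- function(ts, k = 2L, n_private = 3L, seed = 1L) {
  aln <- ts$alignment
  m <- aln_matrix(aln)
  free <- which(colSums(m == "-" | m == "N") == 0L)
  if (nrow(ts$truth))
    free <- setdiff(free, unlist(mapply(seq, ts$truth$start_col,
                                        ts$truth$end_col, SIMPLIFY = FALSE)))
  with_preserved_rng(seed, {
    rows <- list()
    for (t in aln$taxa) {
      for (i in seq_len(k)) {
        v <- strsplit(aln$seqs[[t]], "", fixed = TRUE)[[1L]]
        cols <- sample(free, n_private)
        free <- setdiff(free, cols)
        for (cc in cols) v[cc] <- sample(setdiff(DNA_BASES4, v[cc]), 1L)
        rows[[paste0(t, "_", i)]] <- paste(v, collapse = "")
      }
    }
    alignment_from_seqs(unlist(rows))
  })
}
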