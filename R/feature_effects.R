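# Codon-aware SNP effect classification, pseudogene flagging, and
# microsatellite (SSR) detection.
#
# Plastid protein-coding genes are translated with the bacterial/plastid
# genetic code (NCBI table 11) by default; the table is configurable.

# concatenated CDS sequence of one gene (exons in genomic order; minus-strand
# genes are reverse complemented after concatenation), plus a map from CDS
# position to genome position
gene_cds <- function(genome, gene) {
  f <- genome$features
  f <- f[f$gene == gene & f$kind == "protein_coding", , drop = FALSE]
  if (!nrow(f)) stop("no protein_coding feature for gene ", sQuote(gene))
  f <- f[order(f$start), , drop = FALSE]
  pos <- unlist(lapply(seq_len(nrow(f)), function(i) f$start[i]:f$end[i]))
  seq <- paste(substring(genome$sequence, f$start, f$end), collapse = "")
  strand <- f$strand[1L]
  if (strand == "-") {
    seq <- revcomp(seq)
    pos <- rev(pos)
  }
  list(seq = seq, pos = pos, strand = strand)
}

translate_cds <- function(seq, code = "11") {
  as.character(Biostrings::translate(Biostrings::DNAString(seq),
                                     genetic.code = Biostrings::getGeneticCode(code),
                                     if.fuzzy.codon = "X"))
}

#' Classify a SNP against gene annotations
#'
#' Locates a substitution in gene space and reports its coding effect.
#' Positions inside a protein-coding gene's exons are translated reference
#' vs alternate; positions between exons of the same gene are `intronic`;
#' everything else (including tRNA/rRNA genes, which have no listed coding
#' category) is `intergenic`.
#'
#' @param genome `genome_record` carrying the reference allele at `pos`.
#' @param pos 1-based genome position of the SNP.
#' @param alt alternate base (a single character in `ACGT`).
#' @param code genetic code table id for [Biostrings::getGeneticCode()]
#'   (default `"11"`, bacterial/plastid).
#' @return list with `category` (one of `intergenic`, `intronic`,
#'   `synonymous`, `nonsynonymous`, `stop_gained`, `stop_lost`), `gene`,
#'   `codon_index`, `ref_aa`, `alt_aa`.
#' @export
classify_snp <- function(genome, pos, alt, code = "11") {
  stopifnot(inherits(genome, "genome_record"))
  n <- nchar(genome$sequence)
  if (pos < 1L || pos > n) stop("SNP position outside genome")
  if (!alt %in% DNA_BASES4) stop("alternate allele must be one of A/C/G/T")
  f <- genome$features
  out <- list(category = "intergenic", gene = NA_character_,
              codon_index = NA_integer_, ref_aa = NA_character_,
              alt_aa = NA_character_)
  if (!nrow(f)) return(out)
  pc <- f[f$kind == "protein_coding", , drop = FALSE]
  for (g in unique(pc$gene)) {
    fg <- pc[pc$gene == g, , drop = FALSE]
    if (pos < min(fg$start) || pos > max(fg$end)) next
    in_exon <- any(pos >= fg$start & pos <= fg$end)
    if (!in_exon) {
      out$category <- "intronic"; out$gene <- g
      return(out)
    }
    cds <- gene_cds(genome, g)
    if (nchar(cds$seq) %% 3L != 0L) {
      warning("CDS of gene ", sQuote(g), " is not a multiple of 3; effect not classified")
      out$category <- NA_character_; out$gene <- g
      return(out)
    }
    k <- match(pos, cds$pos)
    ref_base <- substr(cds$seq, k, k)
    alt_base <- if (cds$strand == "-") complement_base(alt) else alt
    if (alt_base == ref_base)
      stop("alternate allele equals the reference base at position ", pos)
    ci <- (k - 1L) %/% 3L + 1L
    codon <- substr(cds$seq, (ci - 1L) * 3L + 1L, ci * 3L)
    off <- (k - 1L) %% 3L + 1L
    alt_codon <- codon
    substr(alt_codon, off, off) <- alt_base
    gc_tab <- Biostrings::getGeneticCode(code)
    ref_aa <- unname(gc_tab[codon]); alt_aa <- unname(gc_tab[alt_codon])
    cat_ <- if (identical(ref_aa, alt_aa)) "synonymous"
    else if (identical(alt_aa, "*")) "stop_gained"
    else if (identical(ref_aa, "*")) "stop_lost"
    else "nonsynonymous"
    return(list(category = cat_, gene = g, codon_index = ci,
                ref_aa = ref_aa, alt_aa = alt_aa))
  }
  out
}

#' Detect pseudogenes from premature stops and frameshifts
#'
#' Translates every annotated protein-coding gene. A stop codon strictly
#' before the final codon yields a `premature_stop` call (with the codon
#' index of the first such stop); a CDS whose length is not a multiple of 3
#' yields a `frameshift` call.
#'
#' @param genome `genome_record`.
#' @param code genetic code table id.
#' @return `data.frame` with columns `gene`, `taxon`, `reason`,
#'   `stop_position`, `n_codons` (empty when all genes are clean).
#' @export
detect_pseudogenes <- function(genome, code = "11") {
  f <- genome$features
  genes <- unique(f$gene[f$kind == "protein_coding"])
  rows <- list()
  for (g in genes) {
    cds <- gene_cds(genome, g)
    len <- nchar(cds$seq)
    if (len %% 3L != 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, taxon = genome$id, reason = "frameshift",
        stop_position = NA_integer_, n_codons = len %/% 3L,
        stringsAsFactors = FALSE)
      next
    }
    aa <- translate_cds(cds$seq, code)
    ncod <- nchar(aa)
    stops <- which(strsplit(aa, "", fixed = TRUE)[[1L]] == "*")
    early <- stops[stops < ncod]
    if (length(early)) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, taxon = genome$id, reason = "premature_stop",
        stop_position = early[1L], n_codons = ncod, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(gene = character(), taxon = character(),
                      reason = character(), stop_position = integer(),
                      n_codons = integer(), stringsAsFactors = FALSE))
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Find perfect microsatellite (SSR) tracts
#'
#' Reports all maximal perfect tandem repeats of 1-6 bp motifs meeting the
#' per-motif-length unit-count thresholds. The canonical motif is the
#' lexicographically smallest rotation of the repeat unit; tracts whose
#' motif is itself periodic (e.g. `AA`, `ATAT`) are suppressed in favor of
#' the shortest motif explaining the tract. Tracts containing `N` are not
#' reported.
#'
#' @param genome `genome_record` or plain DNA string.
#' @param thresholds named integer vector of minimum unit counts for motif
#'   lengths 1-6 (defaults follow common plastome-SSR practice).
#' @return `data.frame`: `motif` (canonical), `unit_count`, `start`, `end`,
#'   `taxon`.
#' @export
find_ssrs <- function(genome,
                      thresholds = c(`1` = 10L, `2` = 6L, `3` = 5L,
                                     `4` = 5L, `5` = 4L, `6` = 4L)) {
  s <- if (inherits(genome, "genome_record")) genome$sequence else toupper(genome)
  taxon <- if (inherits(genome, "genome_record")) genome$id else NA_character_
  v <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(v)
  rows <- list()
  for (m in as.integer(names(thresholds))) {
    if (n < 2L * m) next
    eq <- v[seq_len(n - m)] == v[(m + 1L):n] & v[seq_len(n - m)] != "N"
    r <- rle(eq)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (q in which(r$values)) {
      run <- r$lengths[q]
      tract_len <- run + m
      units <- tract_len %/% m
      if (units < thresholds[[as.character(m)]]) next
      start <- starts[q]
      motif <- paste(v[start:(start + m - 1L)], collapse = "")
      if (minimal_period(motif) < m) next     # shorter motif explains it
      end <- start + units * m - 1L           # whole repeat units only
      rows[[length(rows) + 1L]] <- data.frame(
        motif = canonical_rotation(motif), unit_count = units,
        start = start, end = end, taxon = taxon, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(motif = character(), unit_count = integer(),
                      start = integer(), end = integer(),
                      taxon = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out[order(out$start, out$end), , drop = FALSE]
}

minimal_period <- function(motif) {
  m <- nchar(motif)
  for (p in seq_len(m - 1L)) {
    if (m %% p == 0L &&
        identical(strrep(substr(motif, 1L, p), m %/% p), motif)) return(p)
  }
  m
}

canonical_rotation <- function(motif) {
  m <- nchar(motif)
  rots <- vapply(seq_len(m), function(i)
    paste0(substr(motif, i, m), substr(motif, 1L, i - 1L)), "")
  sort(rots)[1L]
}

#' Flag SSR-associated InDel events
#'
#' An InDel event is SSR-associated when its footprint overlaps a reported
#' SSR tract by at least 1 bp in any taxon (gapped taxa contribute their
#' flanking-pair positions).
#'
#' @param events `variant_table`.
#' @param ssrs named list of SSR tables (one per taxon, from [find_ssrs()]).
#' @return logical vector over events (`FALSE` for SNPs).
#' @export
ssr_associated <- function(events, ssrs) {
  taxa <- variant_taxa(events)
  out <- rep(FALSE, nrow(events))
  if (!nrow(events)) return(out)
  idx <- which(events$kind == "InDel")
  for (i in idx) {
    for (t in taxa) {
      tab <- ssrs[[t]]
      if (is.null(tab) || !nrow(tab)) next
      ps <- events[[paste0("pos_", t)]][i]
      if (grepl("/", ps, fixed = TRUE)) {
        ab <- as.integer(strsplit(ps, "/", fixed = TRUE)[[1L]])
      } else if (grepl("-", ps, fixed = TRUE)) {
        ab <- as.integer(strsplit(ps, "-", fixed = TRUE)[[1L]])
      } else ab <- rep(as.integer(ps), 2L)
      if (any(tab$start <= ab[2L] & tab$end >= ab[1L])) {
        out[i] <- TRUE
        break
      }
    }
  }
  out
}

#' Write SSR tracts as BED (0-based half-open)
#' @param ssrs SSR table from [find_ssrs()].
#' @param path output path.
#' @param chrom sequence name.
#' @return the path, invisibly.
#' @export
write_ssr_bed <- function(ssrs, path, chrom = NULL) {
  chrom <- chrom %||% (if (nrow(ssrs)) ssrs$taxon[1L] else "plastome")
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = ssrs$start, end = ssrs$end),
                               name = sprintf("(%s)%d", ssrs$motif, ssrs$unit_count))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
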