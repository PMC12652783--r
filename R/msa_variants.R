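# Whole-genome multiple alignment ingestion and SNP/InDel event extraction.
#
# Event model: a gap-free polymorphic column (ignoring N) is one SNP; a
# maximal run of consecutive columns sharing an identical per-taxon gap
# pattern, in which at least one taxon is gapped, is one InDel event.
# Substitutions inside an InDel footprint are absorbed into the event so
# that SNPs stay pure single-base substitutions.

#' Construct a multiple alignment object
#'
#' @param seqs named character vector of equal-length gapped sequences over
#'   `{A,C,G,T,N,-}`; names are the taxon labels.
#' @return object of class `plastome_alignment` with elements `taxa`, `seqs`,
#'   `ncol`.
#' @export
alignment_from_seqs <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), length(seqs) >= 2L)
  seqs <- toupper(seqs)
  w <- nchar(seqs)
  if (length(unique(w)) != 1L)
    stop("ragged alignment: row lengths ", paste(unique(w), collapse = ", "))
  for (i in seq_along(seqs))
    validate_dna(seqs[[i]], allow_gap = TRUE, what = paste0("alignment row ", names(seqs)[i]))
  structure(list(taxa = names(seqs), seqs = seqs, ncol = unname(w[1L])),
            class = "plastome_alignment")
}

#' @export
print.plastome_alignment <- function(x, ...) {
  cat(sprintf("<plastome_alignment> %d taxa x %s columns (%s)\n",
              length(x$taxa), format(x$ncol, big.mark = ","),
              paste(x$taxa, collapse = ", ")))
  invisible(x)
}

#' Load an aligned FASTA file
#'
#' Validates row lengths and, when the source genomes are supplied, checks
#' that ungapping each row reproduces the corresponding genome sequence
#' exactly.
#'
#' @param path aligned FASTA.
#' @param genomes optional `genome_set` used for the ungap integrity check.
#' @param taxon_order optional character vector giving the row order to
#'   normalize to.
#' @return `plastome_alignment`.
#' @export
load_alignment <- function(path, genomes = NULL, taxon_order = NULL) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- setNames(toupper(as.character(ss)), sub("\\s.*$", "", names(ss)))
  aln <- alignment_from_seqs(seqs)
  if (!is.null(taxon_order)) {
    if (!setequal(taxon_order, aln$taxa))
      stop("taxon_order does not match alignment taxa")
    aln <- alignment_from_seqs(aln$seqs[taxon_order])
  }
  if (!is.null(genomes)) {
    for (t in aln$taxa) {
      if (is.null(genomes[[t]]))
        stop("alignment taxon ", sQuote(t), " not present in genomes")
      ung <- gsub("-", "", aln$seqs[[t]], fixed = TRUE)
      if (!identical(ung, genomes[[t]]$sequence))
        stop("alignment integrity error: ungapped row ", sQuote(t),
             " does not equal its genome sequence")
    }
  }
  aln
}

aln_matrix <- function(aln) seqs_to_matrix(aln$seqs)

#' Project an alignment column onto a taxon's genome coordinates
#'
#' If the taxon has a base at the column, its 1-based genome position is
#' returned as `"p"`; if it is gapped, the flanking pair `"p/p+1"` of the
#' nearest bases is returned (`"0/1"` for a leading gap).
#'
#' @param aln `plastome_alignment`.
#' @param taxon taxon label.
#' @param aln_col 1-based column index (vectorized).
#' @return character vector of positions or flanking pairs.
#' @export
project_position <- function(aln, taxon, aln_col) {
  if (!taxon %in% aln$taxa) stop("unknown taxon ", sQuote(taxon))
  if (any(aln_col < 1L | aln_col > aln$ncol)) stop("column beyond alignment")
  row <- strsplit(aln$seqs[[taxon]], "", fixed = TRUE)[[1L]]
  cum <- cumsum(row != "-")
  ifelse(row[aln_col] != "-", as.character(cum[aln_col]),
         paste0(cum[aln_col], "/", cum[aln_col] + 1L))
}

# per-taxon cumulative base counts (taxa x ncol), shared by several callers
cum_base_matrix <- function(aln) {
  m <- aln_matrix(aln)
  t(apply(m != "-", 1L, cumsum))
}

#' Extract SNP and InDel events from a multiple alignment
#'
#' Scans columns left to right. A gap-free column that is polymorphic after
#' ignoring `N` emits one SNP event. A maximal run of consecutive columns
#' with an identical per-taxon gap pattern in which at least one taxon is
#' gapped emits one InDel event whose `length_bp` is the difference between
#' the longest and shortest ungapped allele. Events are disjoint in columns
#' and ordered by start column. Columns containing only gaps raise an
#' alignment-integrity error. Terminal runs of gap-containing columns
#' (overhangs from rotating circular genomes to a common origin) are trimmed
#' before extraction when `trim_terminal = TRUE`.
#'
#' @param aln `plastome_alignment`.
#' @param trim_terminal drop gap-containing runs touching either alignment
#'   end before extraction.
#' @return `data.frame` of class `variant_table`: columns `kind`,
#'   `start_col`, `end_col`, `length_bp`, one `allele_<taxon>` and one
#'   `pos_<taxon>` column per taxon. Attribute `taxa` records taxon order.
#' @export
extract_variants <- function(aln, trim_terminal = TRUE) {
  m <- aln_matrix(aln)
  nt <- nrow(m); nc <- ncol(m)
  gap <- m == "-"
  if (any(colSums(gap) == nt))
    stop("alignment integrity error: column with only gaps")
  anygap <- colSums(gap) > 0L
  keep <- rep(TRUE, nc)
  if (trim_terminal && any(anygap)) {
    i <- 1L
    while (i <= nc && anygap[i]) { keep[i] <- FALSE; i <- i + 1L }
    i <- nc
    while (i >= 1L && anygap[i]) { keep[i] <- FALSE; i <- i - 1L }
  }
  # SNP columns: no gap, >= 2 distinct bases among non-N taxa
  base_cols <- which(!anygap & keep)
  is_snp <- logical(nc)
  if (length(base_cols)) {
    sub <- m[, base_cols, drop = FALSE]
    present <- vapply(DNA_BASES4, function(b) colSums(sub == b) > 0L,
                      logical(length(base_cols)))
    poly <- rowSums(present) >= 2L
    is_snp[base_cols[poly]] <- TRUE
  }
  # InDel runs: consecutive columns with identical gap pattern
  pat <- integer(nc)
  if (any(anygap & keep)) {
    codes <- colSums(gap * 2L^(seq_len(nt) - 1L))
    pat[anygap & keep] <- codes[anygap & keep]
  }
  events <- list()
  # runs over the full column index so adjacency is positional
  r <- rle(ifelse(keep, ifelse(is_snp, -1L, pat), 0L))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  taxa <- aln$taxa
  for (q in seq_along(r$values)) {
    v <- r$values[q]
    if (v == -1L) {                                   # run of SNP columns
      for (cc in starts[q]:ends[q]) {
        al <- m[, cc]
        events[[length(events) + 1L]] <-
          list(kind = "SNP", s = cc, e = cc, alleles = al)
      }
    } else if (v > 0L) {                              # one InDel event
      al <- apply(m[, starts[q]:ends[q], drop = FALSE], 1L, paste, collapse = "")
      events[[length(events) + 1L]] <-
        list(kind = "InDel", s = starts[q], e = ends[q], alleles = al)
    }
  }
  variant_table(events, aln, m = m)
}

variant_table <- function(events, aln, m = NULL) {
  taxa <- aln$taxa
  if (!length(events)) {
    df <- data.frame(kind = character(), start_col = integer(),
                     end_col = integer(), length_bp = integer(),
                     stringsAsFactors = FALSE)
    for (t in taxa) df[[paste0("allele_", t)]] <- character()
    for (t in taxa) df[[paste0("pos_", t)]] <- character()
    attr(df, "taxa") <- taxa
    class(df) <- c("variant_table", "data.frame")
    return(df)
  }
  kind <- vapply(events, `[[`, "", "kind")
  s <- vapply(events, `[[`, 0L, "s")
  e <- vapply(events, `[[`, 0L, "e")
  alle <- do.call(rbind, lapply(events, function(ev) ev$alleles))
  ung <- nchar(gsub("-", "", alle, fixed = TRUE))
  dim(ung) <- dim(alle)
  len <- ifelse(kind == "InDel",
                apply(ung, 1L, max) - apply(ung, 1L, min), 0L)
  df <- data.frame(kind = kind, start_col = s, end_col = e,
                   length_bp = as.integer(len), stringsAsFactors = FALSE)
  for (i in seq_along(taxa)) df[[paste0("allele_", taxa[i])]] <- alle[, i]
  # projected coordinates: single position, range, or flanking pair
  if (is.null(m)) m <- aln_matrix(aln)
  cum <- t(apply(m != "-", 1L, cumsum))
  gapm <- m == "-"
  for (i in seq_along(taxa)) {
    ps <- cum[i, s]; pe <- cum[i, e]
    gs <- gapm[i, s]; ge <- gapm[i, e]
    first_base <- ifelse(gs, NA_integer_, ps)
    pos <- character(length(s))
    for (j in seq_along(s)) {
      if (!gs[j] || !ge[j]) {          # taxon has >= 1 base inside the event
        a <- if (gs[j]) ps[j] + 1L else ps[j]
        b <- pe[j]
        pos[j] <- if (a == b) as.character(a) else paste0(a, "-", b)
      } else {                          # fully gapped: flanking pair
        pos[j] <- paste0(ps[j], "/", ps[j] + 1L)
      }
    }
    df[[paste0("pos_", taxa[i])]] <- pos
  }
  o <- order(df$start_col)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "taxa") <- taxa
  class(df) <- c("variant_table", "data.frame")
  df
}

variant_taxa <- function(events) {
  attr(events, "taxa") %||%
    sub("^allele_", "", grep("^allele_", names(events), value = TRUE))
}

allele_matrix <- function(events) {
  taxa <- variant_taxa(events)
  as.matrix(as.data.frame(events)[paste0("allele_", taxa)])
}

#' Write a variant event table as TSV
#'
#' @param events `variant_table`.
#' @param path output path.
#' @param partition optional `region_partition` of the reference taxon; adds
#'   a `region` column (event anchored at its first column projected to
#'   reference coordinates).
#' @param reference reference taxon label (defaults to the first taxon).
#' @param meta named list written as `# key: value` header comments.
#' @return the path, invisibly.
#' @export
write_variant_table <- function(events, path, partition = NULL,
                                reference = NULL, meta = list()) {
  df <- as.data.frame(events)
  taxa <- variant_taxa(events)
  if (!is.null(partition)) {
    reference <- reference %||% taxa[1L]
    if (!reference %in% taxa) stop("unknown reference taxon ", sQuote(reference))
    p <- as.integer(sub("[/-].*$", "", df[[paste0("pos_", reference)]]))
    p[p < 1L] <- 1L
    df$region <- if (nrow(df)) region_of(partition, p) else character()
  }
  write_tsv_with_meta(df, path, meta)
}

#' Read back a variant TSV written by [write_variant_table()]
#' @param path TSV path.
#' @return `variant_table`.
#' @export
read_variant_table <- function(path) {
  df <- read_tsv_with_meta(path)
  attr(df, "taxa") <- sub("^allele_", "", grep("^allele_", names(df), value = TRUE))
  class(df) <- c("variant_table", "data.frame")
  df
}

#' Write variant events as a minimal VCF 4.2
#'
#' Records are expressed against a chosen reference taxon with the standard
#' anchor-base convention for InDels (the base immediately left of the event
#' in reference coordinates is prepended to REF and every ALT).
#'
#' @param events `variant_table`.
#' @param aln the source `plastome_alignment` (provides anchor bases).
#' @param path output path.
#' @param reference reference taxon (defaults to the first taxon).
#' @return the path, invisibly.
#' @export
write_variant_vcf <- function(events, aln, path, reference = NULL) {
  taxa <- variant_taxa(events)
  reference <- reference %||% taxa[1L]
  ref_seq <- gsub("-", "", aln$seqs[[reference]], fixed = TRUE)
  alle <- allele_matrix(events)
  samples <- setdiff(taxa, reference)
  con <- file(path, "wt"); on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##reference=%s", reference),
               paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                      paste(samples, collapse = "\t"))), con)
  if (!nrow(events)) return(invisible(path))
  df <- as.data.frame(events)
  for (i in seq_len(nrow(df))) {
    al <- setNames(alle[i, ], taxa)
    ung <- setNames(gsub("-", "", al, fixed = TRUE), taxa)
    refpos <- df[[paste0("pos_", reference)]][i]
    if (df$kind[i] == "SNP") {
      pos <- as.integer(refpos)
      ref <- ung[[reference]]
      alts <- setdiff(unique(ung[samples]), ref)
    } else {
      p_left <- as.integer(sub("[/-].*$", "", refpos))
      if (grepl("/", refpos, fixed = TRUE)) pos <- p_left else pos <- p_left - 1L
      if (pos < 1L) next                     # no left anchor available
      anchor <- substr(ref_seq, pos, pos)
      ref <- paste0(anchor, ung[[reference]])
      alts <- setdiff(unique(paste0(anchor, ung[samples])), ref)
    }
    if (!length(alts)) next
    gt <- vapply(samples, function(t) {
      a <- if (df$kind[i] == "SNP") ung[[t]] else paste0(substr(ref, 1, 1), ung[[t]])
      if (a == ref) "0" else as.character(match(a, alts))
    }, "")
    writeLines(paste(reference, pos, ".", ref, paste(alts, collapse = ","),
                     ".", "PASS", paste0("TYPE=", df$kind[i]), "GT",
                     paste(gt, collapse = "\t"), sep = "\t"), con)
  }
  invisible(path)
}
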