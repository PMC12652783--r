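# Genome and annotation IO, quadripartite structure detection, and
# structural summary statistics.

#' Construct a genome record
#'
#' A genome record holds one species' complete (circular) plastome sequence
#' plus its gene annotations.
#'
#' @param id short unique taxon label.
#' @param sequence uppercase DNA string over `{A,C,G,T,N}`.
#' @param accession optional accession string.
#' @param circular logical; plastomes are circular.
#' @param features `data.frame` with columns `gene`, `kind` (one of
#'   `protein_coding`, `tRNA`, `rRNA`), `strand` (`+`/`-`), `start`, `end`
#'   (1-based inclusive exon intervals; one row per exon, ordered by
#'   position within each gene).
#' @return object of class `genome_record`.
#' @export
genome_record <- function(id, sequence, accession = NA_character_,
                          circular = TRUE, features = NULL) {
  stopifnot(is.character(id), nzchar(id))
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) stop("empty sequence for record ", sQuote(id))
  validate_dna(sequence, allow_gap = FALSE, what = paste0("sequence of ", id))
  if (is.null(features)) {
    features <- data.frame(gene = character(), kind = character(),
                           strand = character(), start = integer(),
                           end = integer(), stringsAsFactors = FALSE)
  }
  validate_features(features, nchar(sequence), id)
  structure(list(id = id, accession = accession, sequence = sequence,
                 circular = circular, features = features),
            class = "genome_record")
}

validate_features <- function(features, genome_len, id) {
  req <- c("gene", "kind", "strand", "start", "end")
  if (!all(req %in% names(features)))
    stop("features for ", sQuote(id), " must have columns ",
         paste(req, collapse = ", "))
  if (!nrow(features)) return(invisible(TRUE))
  if (!all(features$kind %in% c("protein_coding", "tRNA", "rRNA")))
    stop("unknown feature kind in record ", sQuote(id))
  if (any(features$start < 1L) || any(features$end > genome_len))
    stop("feature interval outside sequence in record ", sQuote(id))
  if (any(features$start > features$end))
    stop("feature with start > end in record ", sQuote(id))
  # exon intervals must not overlap within a gene
  for (g in unique(features$gene)) {
    f <- features[features$gene == g, , drop = FALSE]
    f <- f[order(f$start), , drop = FALSE]
    if (nrow(f) > 1L && any(f$start[-1L] <= f$end[-nrow(f)]))
      stop("overlapping exon intervals for gene ", sQuote(g),
           " in record ", sQuote(id))
  }
  invisible(TRUE)
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s (%s): %s bp, %d feature rows, %s\n",
              x$id, x$accession, format(nchar(x$sequence), big.mark = ","),
              nrow(x$features), if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Read genomes from FASTA with optional GFF3 annotations
#'
#' One `genome_record` is created per FASTA record; features from the GFF3
#' file (types `CDS`, `tRNA`, `rRNA`) are attached by matching the GFF3
#' `seqid` to the FASTA record id. Unknown residues are preserved as `N`.
#'
#' @param fasta path to a (multi-record) FASTA file.
#' @param gff optional path to a GFF3 annotation file covering any subset of
#'   the records.
#' @param circular logical, applied to all records.
#' @return named list of `genome_record` (class `genome_set`).
#' @export
read_genomes <- function(fasta, gff = NULL, circular = TRUE) {
  if (!file.exists(fasta)) stop("FASTA file not found: ", fasta)
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) == 0L) stop("empty FASTA file: ", fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate record ids in ", fasta, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  feats <- if (!is.null(gff)) read_gff_features(gff) else NULL
  recs <- lapply(seq_along(seqs), function(i) {
    f <- if (!is.null(feats)) feats[feats$seqid == ids[i], -1L] else NULL
    genome_record(ids[i], as.character(seqs[[i]]), circular = circular,
                  features = f)
  })
  names(recs) <- ids
  structure(recs, class = "genome_set")
}

# GFF3 -> flat exon table (seqid, gene, kind, strand, start, end)
read_gff_features <- function(gff) {
  gr <- rtracklayer::import(gff, format = "gff3")
  kind_map <- c(CDS = "protein_coding", tRNA = "tRNA", rRNA = "rRNA")
  gr <- gr[as.character(gr$type) %in% names(kind_map)]
  meta <- S4Vectors::mcols(gr)
  gene <- if ("gene" %in% names(meta)) as.character(meta$gene) else NA
  if (all(is.na(gene)) && "Name" %in% names(meta)) gene <- as.character(meta$Name)
  if (all(is.na(gene)) && "ID" %in% names(meta)) gene <- as.character(meta$ID)
  data.frame(seqid = as.character(GenomicRanges::seqnames(gr)),
             gene = gene,
             kind = unname(kind_map[as.character(meta$type)]),
             strand = as.character(BiocGenerics::strand(gr)),
             start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
             stringsAsFactors = FALSE)
}

#' GC content of a genome
#'
#' `(#G + #C) / (#A + #C + #G + #T)`; `N` is excluded from the denominator.
#'
#' @param genome a `genome_record` or a plain DNA string.
#' @return fraction in `[0, 1]`.
#' @export
gc_content <- function(genome) {
  s <- if (inherits(genome, "genome_record")) genome$sequence else toupper(genome)
  g <- gc_fraction(s)
  if (is.na(g)) stop("undefined GC content: sequence has no A/C/G/T bases")
  g
}

#' Detect the quadripartite plastome structure
#'
#' Finds the maximal-length pair of disjoint intervals whose sequences are
#' reverse complements of each other (the inverted repeats IRb/IRa), and the
#' two single-copy regions between them; the longer single-copy region is the
#' LSC. Detection anchors unique k-mers shared between the sequence and its
#' reverse complement, groups them by diagonal, and extends the best seed
#' base-by-base. With `max_mismatch_frac = 0` (the default, appropriate for
#' the near-identical IRs of chloroplast genomes) the match is exact; `N`
#' never matches. Among equal-length candidates the pair with the smallest
#' start coordinate is chosen.
#'
#' @param genome `genome_record` (assumed oriented so that no IR copy spans
#'   the sequence origin; see [rotate_genome()]).
#' @param min_ir_len minimum IR length in bp (default 10000).
#' @param max_mismatch_frac allowed mismatch fraction during seed extension.
#' @param k anchor k-mer size.
#' @return object of class `region_partition`: list with 1-based inclusive
#'   intervals `lsc`, `irb`, `ssc`, `ira` (in canonical coordinates, LSC
#'   starting at position 1), `lengths`, and `rotation` (left-rotation in bp
#'   that maps the input genome onto canonical coordinates).
#' @export
detect_inverted_repeats <- function(genome, min_ir_len = 10000,
                                    max_mismatch_frac = 0, k = 31L) {
  stopifnot(inherits(genome, "genome_record"))
  if (min_ir_len < 1000) stop("min_ir_len must be >= 1000")
  s <- genome$sequence
  n <- nchar(s)
  if (n < 2L * min_ir_len + 2L)
    stop("no quadripartite structure: sequence shorter than two IR copies")
  r <- revcomp(s)
  cand <- best_revcomp_repeat(s, r, n, k, min_ir_len, max_mismatch_frac)
  if (is.null(cand))
    stop("no quadripartite structure: no inverted repeat >= ", min_ir_len, " bp")
  # map the reverse-complement interval back to forward coordinates
  a <- c(cand$i0, cand$i1)
  b <- c(n - cand$j1 + 1L, n - cand$j0 + 1L)
  if (a[1L] > b[1L]) { tmp <- a; a <- b; b <- tmp }
  if (a[2L] >= b[1L])
    stop("overlapping candidate repeats: inverted repeat copies overlap")
  irb <- a; ira <- b
  sc1 <- c(irb[2L] + 1L, ira[1L] - 1L)              # between the two copies
  sc1_len <- sc1[2L] - sc1[1L] + 1L
  sc2_len <- n - (ira[2L] - ira[1L] + 1L) - (irb[2L] - irb[1L] + 1L) - sc1_len
  if (sc1_len <= 0L || sc2_len <= 0L)
    stop("no quadripartite structure: a single-copy region is empty")
  ir_len <- irb[2L] - irb[1L] + 1L
  if (sc1_len >= sc2_len) {
    lsc_len <- sc1_len; ssc_len <- sc2_len
    lsc_start <- sc1[1L]
  } else {
    lsc_len <- sc2_len; ssc_len <- sc1_len
    lsc_start <- if (ira[2L] == n) 1L else ira[2L] + 1L
  }
  rotation <- lsc_start - 1L
  lengths <- c(lsc = lsc_len, irb = ir_len, ssc = ssc_len, ira = ir_len)
  region_partition(lengths, rotation = rotation, genome_length = n)
}

region_partition <- function(lengths, rotation = 0L, genome_length = sum(lengths)) {
  stopifnot(sum(lengths) == genome_length)
  cs <- unname(cumsum(lengths))
  iv <- function(i) c(if (i == 1L) 1L else cs[i - 1L] + 1L, cs[i])
  structure(list(lsc = iv(1L), irb = iv(2L), ssc = iv(3L), ira = iv(4L),
                 lengths = lengths, rotation = as.integer(rotation),
                 genome_length = as.integer(genome_length)),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf("<region_partition> LSC %s | IRb %s | SSC %s | IRa %s bp (rotation %d)\n",
              x$lengths[["lsc"]], x$lengths[["irb"]], x$lengths[["ssc"]],
              x$lengths[["ira"]], x$rotation))
  invisible(x)
}

# longest (approximately) reverse-complement repeat between s and r = revcomp(s).
# Returns 1-based [i0,i1] in s and [j0,j1] in r, equal lengths, or NULL.
best_revcomp_repeat <- function(s, r, n, k, min_len, tol) {
  ks <- substring(s, 1:(n - k + 1L), k:n)
  kr <- substring(r, 1:(n - k + 1L), k:n)
  # unique-in-both anchors (MUM style) keep the diagonal signal clean
  us <- !(duplicated(ks) | duplicated(ks, fromLast = TRUE)) & !grepl("N", ks, fixed = TRUE)
  ur <- !(duplicated(kr) | duplicated(kr, fromLast = TRUE))
  idx <- match(ks, ifelse(ur, kr, NA))
  hit <- which(us & !is.na(idx))
  if (!length(hit)) return(NULL)
  i <- hit; j <- idx[hit]
  d <- i - j
  o <- order(d, i)
  i <- i[o]; j <- j[o]; d <- d[o]
  # cluster anchors on the same diagonal with gaps <= k (exact repeats give
  # wall-to-wall unique anchors; small gaps only arise from tolerated noise)
  brk <- c(TRUE, diff(d) != 0L | diff(i) > k)
  grp <- cumsum(brk)
  sv <- strsplit(s, "", fixed = TRUE)[[1L]]
  rv <- strsplit(r, "", fixed = TRUE)[[1L]]
  best <- NULL
  for (g in unique(grp)) {
    ii <- i[grp == g]; jj <- j[grp == g]
    span <- ii[length(ii)] + k - 1L - ii[1L] + 1L
    if (span < min_len %/% 2L) next
    ext <- extend_match(sv, rv, ii[1L], jj[1L], ii[length(ii)] + k - 1L,
                        jj[length(jj)] + k - 1L, tol)
    len <- ext$i1 - ext$i0 + 1L
    if (len < min_len) next
    if (is.null(best) || len > best$len ||
        (len == best$len && min(ext$i0, nchar(s) - ext$j1 + 1L) <
           min(best$i0, nchar(s) - best$j1 + 1L))) {
      best <- c(ext, len = len)
    }
  }
  best
}

# extend an exact seed [i0,i1]x[j0,j1] outward; mismatches tolerated while the
# running mismatch fraction stays <= tol; N counts as mismatch
extend_match <- function(sv, rv, i0, j0, i1, j1, tol) {
  n <- length(sv)
  mism <- sum(sv[i0:i1] != rv[j0:j1] | sv[i0:i1] == "N")
  repeat {
    moved <- FALSE
    if (i0 > 1L && j0 > 1L) {
      m <- (sv[i0 - 1L] != rv[j0 - 1L]) || sv[i0 - 1L] == "N"
      len <- i1 - i0 + 2L
      if (!m || (mism + 1) / len <= tol) {
        i0 <- i0 - 1L; j0 <- j0 - 1L; mism <- mism + m; moved <- TRUE
      }
    }
    if (i1 < n && j1 < n) {
      m <- (sv[i1 + 1L] != rv[j1 + 1L]) || sv[i1 + 1L] == "N"
      len <- i1 - i0 + 2L
      if (!m || (mism + m) / len <= tol) {
        i1 <- i1 + 1L; j1 <- j1 + 1L; mism <- mism + m; moved <- TRUE
      }
    }
    if (!moved) break
  }
  # trim mismatching flanks so reported copies are identical at tol = 0
  while (i1 >= i0 && (sv[i0] != rv[j0] || sv[i0] == "N")) { i0 <- i0 + 1L; j0 <- j0 + 1L }
  while (i1 >= i0 && (sv[i1] != rv[j1] || sv[i1] == "N")) { i1 <- i1 - 1L; j1 <- j1 - 1L }
  list(i0 = i0, i1 = i1, j0 = j0, j1 = j1)
}

#' Rotate a genome to canonical quadripartite orientation
#'
#' Left-rotates the circular sequence so that the LSC starts at position 1
#' (order LSC, IRb, SSC, IRa), shifting feature coordinates accordingly.
#' Features that would span the new origin raise an error.
#'
#' @param genome `genome_record`.
#' @param partition `region_partition` from [detect_inverted_repeats()].
#' @return list with rotated `genome` and `partition` (rotation 0).
#' @export
rotate_genome <- function(genome, partition) {
  rot <- partition$rotation
  if (rot == 0L) return(list(genome = genome, partition = partition))
  s <- genome$sequence
  n <- nchar(s)
  s2 <- paste0(substr(s, rot + 1L, n), substr(s, 1L, rot))
  f <- genome$features
  if (nrow(f)) {
    ns <- ((f$start - 1L - rot) %% n) + 1L
    ne <- ((f$end - 1L - rot) %% n) + 1L
    if (any(ne < ns)) stop("feature spans the new origin after rotation")
    f$start <- ns; f$end <- ne
  }
  g2 <- genome_record(genome$id, s2, genome$accession, genome$circular, f)
  p2 <- region_partition(partition$lengths, rotation = 0L,
                         genome_length = partition$genome_length)
  list(genome = g2, partition = p2)
}

#' Region label of a genome position
#'
#' @param partition `region_partition`.
#' @param pos integer vector of 1-based positions (canonical coordinates).
#' @return character vector over `{"LSC","IR","SSC"}`.
#' @export
region_of <- function(partition, pos) {
  cs <- cumsum(partition$lengths)
  lab <- c("LSC", "IR", "SSC", "IR")
  lab[findInterval(pos - 1L, c(0L, cs[-4L]))]
}

#' Summarize plastome structure
#'
#' Per-genome LSC/SSC/IR/total lengths, gene-class counts, and GC percent.
#'
#' @param genomes `genome_set` (or list of `genome_record`).
#' @param partitions optional named list of `region_partition`; computed with
#'   defaults when missing.
#' @param ... passed to [detect_inverted_repeats()].
#' @return `data.frame`, one row per genome.
#' @export
summarize_structure <- function(genomes, partitions = NULL, ...) {
  rows <- lapply(genomes, function(g) {
    p <- partitions[[g$id]] %||% detect_inverted_repeats(g, ...)
    f <- g$features
    ngene <- length(unique(f$gene))
    kinds <- vapply(c("protein_coding", "tRNA", "rRNA"), function(k)
      length(unique(f$gene[f$kind == k])), integer(1))
    data.frame(id = g$id, accession = g$accession,
               lsc_bp = unname(p$lengths[["lsc"]]),
               ssc_bp = unname(p$lengths[["ssc"]]),
               ir_bp = unname(p$lengths[["irb"]]),
               total_bp = nchar(g$sequence),
               genes = ngene, protein_coding = kinds[[1L]],
               tRNA = kinds[[2L]], rRNA = kinds[[3L]],
               gc_pct = round(100 * gc_content(g), 2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Write a region BED file (0-based half-open, BED convention)
#'
#' @param partition `region_partition`.
#' @param path output path.
#' @param chrom sequence name to use.
#' @return the path, invisibly.
#' @export
write_region_bed <- function(partition, path, chrom = "plastome") {
  iv <- rbind(partition$lsc, partition$irb, partition$ssc, partition$ira)
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = iv[, 1L], end = iv[, 2L]),
                               name = c("LSC", "IRb", "SSC", "IRa"))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
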