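# In-silico PCR: primer binding-site scan, amplicon prediction, banding
# table and species calling.
#
# Annealing rule: the primer's 3'-terminal window (default last 3 bases)
# must match the template exactly; up to `max_mismatch` mismatches are
# tolerated outside that window. This implements dominant (ARMS) marker
# logic: a 3' SNP mismatch kills amplification.

#' Scan a template for primer binding sites
#'
#' Finds all sites on both strands of a (circular) template where the primer
#' anneals under the mismatch rules. Sites spanning the origin of a circular
#' template are included once, reported at their start position modulo the
#' genome length.
#'
#' @param template `genome_record` or DNA string.
#' @param primer primer sequence, 5' to 3', length >= 10.
#' @param max_mismatch mismatches allowed outside the 3' window (default 1).
#' @param three_prime_exact size of the exactly matched 3' window (default 3).
#' @return `data.frame`: `start`, `end` (template coordinates of the site,
#'   forward-strand orientation), `strand`, `mismatches`,
#'   `three_prime_pos` (template position paired with the primer 3' end).
#' @export
scan_primer <- function(template, primer, max_mismatch = 1L,
                        three_prime_exact = 3L) {
  s <- if (inherits(template, "genome_record")) template$sequence else toupper(template)
  circular <- if (inherits(template, "genome_record")) template$circular else TRUE
  primer <- toupper(primer)
  if (nchar(primer) < 10L) stop("primer must be at least 10 bp")
  validate_dna(primer, what = "primer")
  n <- nchar(s)
  plen <- nchar(primer)
  subj <- if (circular && n > plen) paste0(s, substr(s, 1L, plen - 1L)) else s
  subj_dna <- Biostrings::DNAString(subj)
  hits <- list()
  scan_one <- function(query, strand) {
    mp <- Biostrings::matchPattern(query, subj_dna,
                                   max.mismatch = max_mismatch + three_prime_exact,
                                   with.indels = FALSE)
    if (!length(mp)) return(NULL)
    st <- BiocGenerics::start(mp)
    qv <- strsplit(query, "", fixed = TRUE)[[1L]]
    keep <- st <= n                       # dedup circular wrap duplicates
    st <- st[keep]
    if (!length(st)) return(NULL)
    out <- list()
    for (p0 in st) {
      site <- substr(subj, p0, p0 + plen - 1L)
      sv <- strsplit(site, "", fixed = TRUE)[[1L]]
      mm <- which(sv != qv | sv == "N")
      # offset-from-3' of each mismatch in primer orientation
      off <- if (strand == "+") plen - mm else mm - 1L
      if (any(off < three_prime_exact)) next
      if (length(mm) > max_mismatch) next
      out[[length(out) + 1L]] <- data.frame(
        start = p0, end = p0 + plen - 1L, strand = strand,
        mismatches = length(mm),
        three_prime_pos = if (strand == "+") p0 + plen - 1L else p0,
        stringsAsFactors = FALSE)
    }
    if (length(out)) do.call(rbind, out) else NULL
  }
  hp <- scan_one(primer, "+")
  hm <- scan_one(revcomp(primer), "-")
  res <- rbind(hp, hm)
  if (is.null(res))
    return(data.frame(start = integer(), end = integer(), strand = character(),
                      mismatches = integer(), three_prime_pos = integer(),
                      stringsAsFactors = FALSE))
  res[order(res$start, res$strand), , drop = FALSE]
}

#' Predict PCR products of a primer pair on one template
#'
#' Every combination of a plus-strand site of one primer with a downstream
#' minus-strand site of the other (proper inward orientation) with a span at
#' most `max_len` yields a product. The product length is the standard PCR
#' convention: from the 5' end of the forward site through the 5' end of the
#' reverse site, inclusive. On circular templates products may span the
#' origin; rotated duplicates are suppressed.
#'
#' @param template `genome_record` or DNA string.
#' @param pair `primer_pair` (or list with `forward`/`reverse`).
#' @param max_len maximum product span in bp (default 2000).
#' @param max_mismatch,three_prime_exact annealing rules, see [scan_primer()].
#' @return sorted integer vector of product lengths (possibly empty).
#' @export
predict_amplicons <- function(template, pair, max_len = 2000L,
                              max_mismatch = 1L, three_prime_exact = 3L) {
  s <- if (inherits(template, "genome_record")) template$sequence else toupper(template)
  circular <- if (inherits(template, "genome_record")) template$circular else TRUE
  n <- nchar(s)
  hitsF <- scan_primer(template, pair$forward, max_mismatch, three_prime_exact)
  hitsR <- scan_primer(template, pair$reverse, max_mismatch, three_prime_exact)
  products <- integer(0)
  combine <- function(ha, hb) {
    # ha plus-strand sites, hb minus-strand sites
    pa <- ha$start[ha$strand == "+"]
    pb <- hb$end[hb$strand == "-"]
    if (!length(pa) || !length(pb)) return(NULL)
    keyed <- character(0)
    out <- integer(0)
    for (a in pa) {
      ends <- pb
      if (circular) ends <- c(ends, pb + n)
      ends <- ends[ends >= a + 1L]
      len <- ends - a + 1L
      len <- len[len <= max_len & len >= 1L]
      for (l in len) {
        key <- paste0((a - 1L) %% n, ":", l)
        if (!key %in% keyed) { keyed <- c(keyed, key); out <- c(out, l) }
      }
    }
    out
  }
  products <- c(combine(hitsF, hitsR), combine(hitsR, hitsF))
  sort(unique(products))
}

#' In-silico banding table and marker classification
#'
#' Runs every marker against every genome and classifies marker behavior:
#' `codominant` if all taxa amplify and the target taxon's product set is
#' unique; `dominant` if only the target amplifies; `ambiguous` otherwise.
#' Each sample genome is then called as the unique reference taxon whose
#' banding pattern it matches across all markers (`"unresolved"` when zero
#' or several match).
#'
#' @param markers named list of `primer_pair`.
#' @param genomes `genome_set` of samples to genotype.
#' @param reference optional `genome_set` providing the expected per-species
#'   patterns (defaults to `genomes`).
#' @param max_len,max_mismatch,three_prime_exact see [predict_amplicons()].
#' @return list of class `banding_table`: `bands` (marker x taxon character
#'   matrix of product sizes), `classification` (named character),
#'   `species_call` (named character, one per sample).
#' @export
banding_table <- function(markers, genomes, reference = NULL,
                          max_len = 2000L, max_mismatch = 1L,
                          three_prime_exact = 3L) {
  if (!length(markers)) stop("need at least one marker")
  if (!length(genomes)) stop("need at least one genome")
  band_of <- function(gset) {
    sapply(gset, function(g) vapply(markers, function(p) {
      pr <- predict_amplicons(g, p, max_len, max_mismatch, three_prime_exact)
      if (!length(pr)) "-" else paste(pr, collapse = ",")
    }, ""))
  }
  bands <- band_of(genomes)
  if (is.null(dim(bands))) bands <- matrix(bands, nrow = length(markers),
                                           dimnames = list(names(markers),
                                                           names(genomes)))
  ref_bands <- if (is.null(reference)) bands else band_of(reference)
  ref_taxa <- colnames(ref_bands)
  classification <- vapply(names(markers), function(nm) {
    tgt <- markers[[nm]]$target_taxon
    if (!tgt %in% ref_taxa) return("ambiguous")
    row <- ref_bands[nm, ]
    amplified <- row != "-"
    if (all(amplified) && !row[[tgt]] %in% row[names(row) != tgt]) "codominant"
    else if (amplified[[tgt]] && !any(amplified[names(row) != tgt])) "dominant"
    else "ambiguous"
  }, "")
  species_call <- vapply(colnames(bands), function(sm) {
    match_taxa <- ref_taxa[colSums(ref_bands != bands[, sm]) == 0L]
    if (length(match_taxa) == 1L) match_taxa else "unresolved"
  }, "")
  structure(list(bands = bands, classification = classification,
                 species_call = species_call),
            class = "banding_table")
}

#' @export
print.banding_table <- function(x, ...) {
  cat("<banding_table>\n")
  print(x$bands, quote = FALSE)
  cat("classification:", paste(sprintf("%s=%s", names(x$classification),
                                       x$classification), collapse = " "), "\n")
  cat("species calls:", paste(sprintf("%s->%s", names(x$species_call),
                                      x$species_call), collapse = " "), "\n")
  invisible(x)
}

#' Write the banding table and species calls as TSV
#' @param bt `banding_table`; @param path output path; @param meta metadata.
#' @return the path, invisibly.
#' @export
write_banding_table <- function(bt, path, meta = list()) {
  df <- data.frame(marker = rownames(bt$bands),
                   classification = unname(bt$classification[rownames(bt$bands)]),
                   as.data.frame(bt$bands, stringsAsFactors = FALSE),
                   check.names = FALSE)
  meta$species_calls <- paste(sprintf("%s=%s", names(bt$species_call),
                                      bt$species_call), collapse = " ")
  write_tsv_with_meta(df, path, meta)
}
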