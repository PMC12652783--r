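# Pairwise variant matrices, species-specific tallies, sliding windows.

ungapped_len <- function(a) nchar(gsub("-", "", a, fixed = TRUE))

#' Pairwise SNP/InDel matrices
#'
#' For every unordered pair of taxa: the SNP count is the number of SNP
#' events whose two alleles differ (alleles containing `N` are excluded for
#' that pair); the InDel site count is the number of InDel events whose
#' alleles differ; the InDel bp total sums the pair's allele length
#' differences over those events.
#'
#' @param events `variant_table`.
#' @param taxa taxon labels (defaults to the table's taxa).
#' @return list of class `pairwise_variant_matrix` with symmetric matrices
#'   `snp_counts`, `indel_site_counts`, `indel_total_bp`.
#' @export
pairwise_matrix <- function(events, taxa = NULL) {
  taxa <- taxa %||% variant_taxa(events)
  missing <- setdiff(taxa, variant_taxa(events))
  if (length(missing))
    stop("taxon missing from events: ", paste(missing, collapse = ", "))
  n <- length(taxa)
  zero <- matrix(0, n, n, dimnames = list(taxa, taxa))
  snp <- ind <- bp <- zero
  if (nrow(events)) {
    alle <- allele_matrix(events)[, paste0("allele_", taxa), drop = FALSE]
    is_snp <- events$kind == "SNP"
    lens <- matrix(ungapped_len(alle), nrow = nrow(alle))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      a <- alle[, i]; b <- alle[, j]
      ok <- !grepl("N", a, fixed = TRUE) & !grepl("N", b, fixed = TRUE)
      diff <- a != b & ok
      snp[i, j] <- snp[j, i] <- sum(diff & is_snp)
      ind[i, j] <- ind[j, i] <- sum(diff & !is_snp)
      bp[i, j] <- bp[j, i] <- sum(abs(lens[, i] - lens[, j])[diff & !is_snp])
    }
  }
  structure(list(taxa = taxa, snp_counts = snp, indel_site_counts = ind,
                 indel_total_bp = bp),
            class = "pairwise_variant_matrix")
}

#' @export
print.pairwise_variant_matrix <- function(x, ...) {
  cat("<pairwise_variant_matrix>\nSNP counts:\n")
  print(x$snp_counts)
  cat("InDel sites:\n")
  print(x$indel_site_counts)
  cat("InDel total bp:\n")
  print(x$indel_total_bp)
  invisible(x)
}

# taxon an event is specific to, or NA: that taxon's allele differs from the
# allele shared identically by ALL other taxa; any N disqualifies the event
specific_taxon <- function(events, taxa = NULL) {
  taxa <- taxa %||% variant_taxa(events)
  if (!nrow(events)) return(character(0))
  alle <- allele_matrix(events)[, paste0("allele_", taxa), drop = FALSE]
  out <- rep(NA_character_, nrow(alle))
  hasN <- rowSums(matrix(grepl("N", alle, fixed = TRUE), nrow = nrow(alle))) > 0L
  for (r in which(!hasN)) {
    al <- alle[r, ]
    for (i in seq_along(taxa)) {
      others <- al[-i]
      if (length(unique(others)) == 1L && al[i] != others[1L]) {
        out[r] <- taxa[i]
        break
      }
    }
  }
  out
}

#' Species-specific variant tallies
#'
#' An event is specific to taxon `t` iff `t`'s allele differs from the
#' allele shared identically by all other taxa (strict definition). Requires
#' at least three taxa.
#'
#' @param events `variant_table`.
#' @param taxa taxon labels.
#' @return `data.frame` with one row per taxon: `snp_count`, `indel_count`,
#'   `indel_bp`, `total`.
#' @export
species_specific <- function(events, taxa = NULL) {
  taxa <- taxa %||% variant_taxa(events)
  if (length(taxa) < 3L)
    stop("species-specific tallies are undefined for fewer than 3 taxa")
  sp <- specific_taxon(events, taxa)
  out <- data.frame(taxon = taxa, snp_count = 0L, indel_count = 0L,
                    indel_bp = 0L, total = 0L, stringsAsFactors = FALSE)
  if (nrow(events)) {
    alle <- allele_matrix(events)[, paste0("allele_", taxa), drop = FALSE]
    lens <- matrix(ungapped_len(alle), nrow = nrow(alle))
    for (i in seq_along(taxa)) {
      sel <- !is.na(sp) & sp == taxa[i]
      out$snp_count[i] <- sum(sel & events$kind == "SNP")
      isel <- sel & events$kind == "InDel"
      out$indel_count[i] <- sum(isel)
      if (any(isel)) {
        other <- if (length(taxa) > 1L) lens[isel, -i, drop = FALSE][, 1L] else 0L
        out$indel_bp[i] <- sum(abs(lens[isel, i] - other))
      }
    }
  }
  out$total <- out$snp_count + out$indel_count
  out
}

#' Sliding-window variant profile
#'
#' Counts events whose anchor (first alignment column, or its projection to
#' reference coordinates) falls in each window. Windows start at 1 and
#' advance by `step`; the final partial window is included. A window larger
#' than the sequence yields a single degenerate window.
#'
#' @param events `variant_table`.
#' @param length total length of the coordinate space (alignment columns or
#'   reference genome bp).
#' @param window window size in bp (default 1000).
#' @param step step size in bp (default 200).
#' @param coordinate_space `"alignment"` (anchor = `start_col`) or
#'   `"reference"` (anchor = projected position on `reference`).
#' @param aln alignment, required for `coordinate_space = "reference"`.
#' @param reference reference taxon for projection.
#' @return `data.frame` of class `window_profile`: `start`, `end`,
#'   `snp_count`, `indel_count`.
#' @export
sliding_window <- function(events, length, window = 1000L, step = 200L,
                           coordinate_space = c("alignment", "reference"),
                           aln = NULL, reference = NULL) {
  coordinate_space <- match.arg(coordinate_space)
  if (step < 1L || window < step) stop("require window >= step >= 1")
  L <- as.integer(length)
  nwin <- if (window >= L) 1L else ceiling((L - window) / step) + 1L
  starts <- 1L + step * (seq_len(nwin) - 1L)
  ends <- pmin(starts + window - 1L, L)
  anchors <- if (!nrow(events)) integer(0) else {
    if (coordinate_space == "alignment") events$start_col
    else {
      if (is.null(aln)) stop("reference coordinate space needs the alignment")
      reference <- reference %||% variant_taxa(events)[1L]
      as.integer(sub("[/-].*$", "", events[[paste0("pos_", reference)]]))
    }
  }
  kinds <- events$kind
  cnt <- function(sel) {
    a <- sort(anchors[sel])
    findInterval(ends, a) - findInterval(starts - 1L, a)
  }
  out <- data.frame(start = starts, end = ends,
                    snp_count = cnt(kinds == "SNP"),
                    indel_count = cnt(kinds == "InDel"))
  class(out) <- c("window_profile", "data.frame")
  attr(out, "window") <- window
  attr(out, "step") <- step
  out
}
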