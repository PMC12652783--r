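# Authentication-marker design: co-dominant InDel markers and dominant
# allele-specific (ARMS) SNP markers, with nearest-neighbor melting
# temperatures.

default_primer_constraints <- function() {
  list(primer_len = c(18L, 30L), gc = c(0.30, 0.70), tm = c(56, 65),
       max_amplicon = 500L, search_span = 300L)
}

#' Nearest-neighbor primer melting temperature
#'
#' Unified nearest-neighbor thermodynamics (SantaLucia 1998 parameter set):
#' `Tm = dH * 1000 / (dS + R * ln(C/4)) - 273.15`, with `R = 1.987`
#' cal/(K*mol), primer concentration `C` (default 500 nM), and the entropic
#' salt correction `dS + 0.368 * (N-1) * ln([Na+])` at 50 mM monovalent
#' salt. Values are reported to 0.1 degC and are reproducible bit-for-bit.
#'
#' @param primer DNA string over `{A,C,G,T}`, length >= 8.
#' @param conc_nM primer concentration in nM.
#' @param na_mM monovalent salt in mM.
#' @return melting temperature in degrees Celsius.
#' @export
melting_temperature <- function(primer, conc_nM = 500, na_mM = 50) {
  primer <- toupper(primer)
  if (!grepl("^[ACGT]+$", primer)) stop("primer must contain only A/C/G/T")
  n <- nchar(primer)
  if (n < 8L) stop("primer too short for nearest-neighbor Tm (need >= 8 nt)")
  dh <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4, CT = -7.8,
          GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
          TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2, CC = -8.0)
  ds <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
          CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
          TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
          CC = -19.9)
  nn <- substring(primer, 1:(n - 1L), 2:n)
  H <- sum(dh[nn]); S <- sum(ds[nn])
  # initiation with terminal G.C / A.T
  for (b in c(substr(primer, 1L, 1L), substr(primer, n, n))) {
    if (b %in% c("G", "C")) { H <- H + 0.1; S <- S - 2.8 }
    else                    { H <- H + 2.3; S <- S + 4.1 }
  }
  S <- S + 0.368 * (n - 1L) * log(na_mM / 1000)
  tm <- H * 1000 / (S + 1.987 * log(conc_nM * 1e-9 / 4)) - 273.15
  round(tm, 1)
}

#' Select marker candidates from species-specific events
#'
#' Species-specific InDel events with a target-vs-others length difference
#' of at least `min_indel_len` bp and no SSR overlap in any taxon become
#' co-dominant InDel candidates. Species-specific SNPs classified
#' nonsynonymous (or stop-gained) become dominant allele-specific
#' candidates. Each candidate carries a region label and a flanking-gene
#' locus derived from the reference annotation.
#'
#' @param events `variant_table`.
#' @param genomes `genome_set`.
#' @param ssrs named list of per-taxon SSR tables ([find_ssrs()]); computed
#'   when `NULL`.
#' @param partition `region_partition` of the reference taxon.
#' @param reference reference taxon for region/locus labels (default first).
#' @param min_indel_len minimum length difference in bp (default 7).
#' @param code genetic code table id for SNP effect classification.
#' @return `data.frame` of candidates: `event`, `target_taxon`, `kind`,
#'   `region`, `locus`, `category`.
#' @export
select_candidates <- function(events, genomes, ssrs = NULL, partition = NULL,
                              reference = NULL, min_indel_len = 7L,
                              code = "11") {
  taxa <- variant_taxa(events)
  reference <- reference %||% taxa[1L]
  if (is.null(ssrs)) ssrs <- lapply(genomes, find_ssrs)
  sp <- specific_taxon(events)
  ssr_hit <- ssr_associated(events, ssrs)
  rows <- list()
  if (nrow(events)) {
    alle <- allele_matrix(events)
    lens <- matrix(ungapped_len(alle), nrow = nrow(alle))
    colnames(lens) <- taxa
    for (i in seq_len(nrow(events))) {
      t <- sp[i]
      if (is.na(t)) next
      if (events$kind[i] == "InDel") {
        diff <- abs(lens[i, t] - lens[i, setdiff(taxa, t)[1L]])
        if (diff < min_indel_len || ssr_hit[i]) next
        kind <- "indel_codominant"; cat_ <- NA_character_
      } else {
        # classify on a background genome carrying the shared allele
        bg <- setdiff(taxa, t)[1L]
        pos <- suppressWarnings(as.integer(events[[paste0("pos_", bg)]][i]))
        if (is.na(pos)) next
        eff <- tryCatch(classify_snp(genomes[[bg]], pos,
                                     alle[i, match(t, taxa)], code = code),
                        error = function(e) NULL)
        if (is.null(eff) || is.na(eff$category) ||
            !eff$category %in% c("nonsynonymous", "stop_gained")) next
        kind <- "snp_dominant"; cat_ <- eff$category
      }
      refpos <- as.integer(sub("[/-].*$", "", events[[paste0("pos_", reference)]][i]))
      region <- if (!is.null(partition)) region_of(partition, max(refpos, 1L))
                else NA_character_
      rows[[length(rows) + 1L]] <- data.frame(
        event = i, target_taxon = t, kind = kind, region = region,
        locus = locus_label(genomes[[reference]], refpos),
        category = cat_, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(event = integer(), target_taxon = character(),
                      kind = character(), region = character(),
                      locus = character(), category = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, c(rows, make.row.names = FALSE))
}

# containing gene, or "left-right" flanking gene label
locus_label <- function(genome, pos) {
  f <- genome$features
  if (!nrow(f)) return(NA_character_)
  spans <- do.call(rbind, lapply(split(f, f$gene), function(x)
    data.frame(gene = x$gene[1L], start = min(x$start), end = max(x$end))))
  hit <- spans$gene[pos >= spans$start & pos <= spans$end]
  if (length(hit)) return(hit[1L])
  left <- spans[spans$end < pos, , drop = FALSE]
  right <- spans[spans$start > pos, , drop = FALSE]
  lg <- if (nrow(left)) left$gene[which.max(left$end)] else "."
  rg <- if (nrow(right)) right$gene[which.min(right$start)] else "."
  paste0(lg, "-", rg)
}

# columns where all taxa carry the same base (no gap, no N)
conserved_columns <- function(aln) {
  m <- aln_matrix(aln)
  ok <- colSums(m == "-" | m == "N") == 0L
  same <- colSums(m != m[rep(1L, nrow(m)), , drop = FALSE]) == 0L
  ok & same
}

primer_pair <- function(name, forward, reverse, target_taxon, kind,
                        f_cols, r_cols, predicted_sizes,
                        modified = NULL, annealing_temp = NA_real_,
                        locus = NA_character_, region = NA_character_) {
  structure(list(name = name, forward = forward, reverse = reverse,
                 target_taxon = target_taxon, kind = kind,
                 f_cols = f_cols, r_cols = r_cols,
                 predicted_sizes = predicted_sizes,
                 modified_positions = modified %||%
                   data.frame(primer = character(), offset3 = integer(),
                              template = character(), primer_base = character(),
                              stringsAsFactors = FALSE),
                 annealing_temp = annealing_temp, locus = locus,
                 region = region),
            class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  sizes <- paste(sprintf("%s=%s", names(x$predicted_sizes),
                         ifelse(is.na(x$predicted_sizes), "-", x$predicted_sizes)),
                 collapse = " ")
  cat(sprintf("<primer_pair> %s (%s, target %s)\n  F 5'-%s-3'\n  R 5'-%s-3'\n  Ta %.1f degC; predicted sizes: %s\n",
              x$name, x$kind, x$target_taxon, x$forward, x$reverse,
              x$annealing_temp, sizes))
  invisible(x)
}

# enumerate valid primer windows on one side of an event.
# side = "left": windows end at column <= limit_col; returns data.frame of
# (start_col, end_col, seq) sorted so the amplicon-minimizing candidate
# comes first (ties: lexicographically smallest sequence).
side_candidates <- function(cons, colseq, limit_col, side, constraints) {
  lens <- constraints$primer_len[1L]:constraints$primer_len[2L]
  span <- constraints$search_span
  out <- list()
  if (side == "left") {
    ends <- seq(limit_col, max(1L, limit_col - span), by = -1L)
  } else {
    ends <- seq(limit_col, min(length(cons), limit_col + span), by = 1L)
  }
  for (e in ends) {
    for (l in lens) {
      a <- if (side == "left") e - l + 1L else e
      b <- if (side == "left") e else e + l - 1L
      if (a < 1L || b > length(cons)) next
      if (!all(cons[a:b])) next
      seq <- paste(colseq[a:b], collapse = "")
      gcf <- gc_fraction(seq)
      if (gcf < constraints$gc[1L] || gcf > constraints$gc[2L]) next
      tm <- melting_temperature(seq)
      if (tm < constraints$tm[1L] || tm > constraints$tm[2L]) next
      out[[length(out) + 1L]] <- data.frame(start_col = a, end_col = b,
                                            seq = seq, tm = tm,
                                            stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(NULL)
  df <- do.call(rbind, out)
  if (side == "left") df[order(-df$start_col, df$seq), , drop = FALSE]
  else df[order(df$end_col, df$seq), , drop = FALSE]
}

# no 3'-anchored complementarity >= k bases between the two primers
primer_dimer_ok <- function(fwd, rev, k = 8L) {
  tails <- c(substr(fwd, nchar(fwd) - k + 1L, nchar(fwd)),
             substr(rev, nchar(rev) - k + 1L, nchar(rev)))
  for (tl in tails) {
    if (nchar(tl) < k) next
    rc <- revcomp(tl)
    if (grepl(rc, fwd, fixed = TRUE) || grepl(rc, rev, fixed = TRUE))
      return(FALSE)
  }
  TRUE
}

# per-taxon amplicon sizes implied by primer window columns; cum is the
# cumulative base matrix (computed once per design call)
projected_sizes <- function(aln, f_start_col, r_end_col, cum = NULL) {
  if (is.null(cum)) cum <- cum_base_matrix(aln)
  sizes <- cum[, r_end_col] - cum[, f_start_col] + 1L
  setNames(as.numeric(sizes), aln$taxa)
}

#' Design a co-dominant primer pair around an InDel candidate
#'
#' Picks conserved flanking windows (columns identical and gap-free across
#' all taxa) bracketing the event; primers satisfy the length, GC, and Tm
#' constraints; the smallest amplicon satisfying all constraints is chosen,
#' with a lexicographic tie-break on the forward primer. The per-taxon
#' predicted sizes differ by the planted length difference by construction.
#'
#' @param aln `plastome_alignment` over all taxa.
#' @param candidate one row of [select_candidates()].
#' @param events the `variant_table` the candidate indexes into.
#' @param name marker name.
#' @param constraints list from `default_primer_constraints()` (overridable
#'   entries: `primer_len`, `gc`, `tm` in degC, `max_amplicon`,
#'   `search_span`).
#' @return `primer_pair`.
#' @export
design_primer_pair <- function(aln, candidate, events, name = NULL,
                               constraints = list()) {
  constraints <- utils::modifyList(default_primer_constraints(), constraints)
  ev <- events[candidate$event, , drop = FALSE]
  cons <- conserved_columns(aln)
  colseq <- strsplit(aln$seqs[[1L]], "", fixed = TRUE)[[1L]]  # conserved cols equal everywhere
  left <- side_candidates(cons, colseq, ev$start_col - 1L, "left", constraints)
  right <- side_candidates(cons, colseq, ev$end_col + 1L, "right", constraints)
  if (is.null(left) || is.null(right))
    stop("design-failure: no conserved flank satisfying primer constraints ",
         "(length/GC/Tm) next to event at columns ",
         ev$start_col, "-", ev$end_col)
  cum <- cum_base_matrix(aln)
  for (i in seq_len(min(nrow(left), 25L))) {
    for (j in seq_len(min(nrow(right), 25L))) {
      sizes <- projected_sizes(aln, left$start_col[i], right$end_col[j], cum)
      if (max(sizes) > constraints$max_amplicon) next
      fwd <- left$seq[i]
      rev <- revcomp(right$seq[j])
      if (!primer_dimer_ok(fwd, rev)) next
      ta <- max(constraints$tm[1L],
                min(constraints$tm[2L], floor(min(left$tm[i], right$tm[j])) - 3))
      return(primer_pair(name %||% paste0(candidate$target_taxon, "_InDel"),
                         fwd, rev, candidate$target_taxon, "indel_codominant",
                         c(left$start_col[i], left$end_col[i]),
                         c(right$start_col[j], right$end_col[j]),
                         sizes, annealing_temp = ta,
                         locus = candidate$locus, region = candidate$region))
    }
  }
  stop("design-failure: no primer combination met the amplicon/dimer constraints")
}

#' Design a dominant allele-specific (ARMS) primer pair for a SNP candidate
#'
#' The allele-specific primer's 3'-terminal base sits on the diagnostic SNP
#' and equals the target taxon's allele; one additional deliberate mismatch
#' is introduced at `mismatch_offset` bases from the 3' end (default 3) by a
#' purine-pyrimidine swap, sharpening refractoriness in non-target
#' templates. The companion primer is a conventional conserved primer.
#' Non-target taxa are predicted not to amplify (their template mismatches
#' the primer 3' end), so predicted sizes for non-targets are `NA`.
#'
#' @param aln `plastome_alignment`.
#' @param candidate one row of [select_candidates()] with
#'   `kind == "snp_dominant"`.
#' @param events the `variant_table`.
#' @param name marker name.
#' @param mismatch_offset offset from the 3' end (0 = terminal base) of the
#'   deliberate extra mismatch.
#' @param constraints as in [design_primer_pair()].
#' @return `primer_pair`.
#' @export
design_allele_specific <- function(aln, candidate, events, name = NULL,
                                   mismatch_offset = 3L, constraints = list()) {
  constraints <- utils::modifyList(default_primer_constraints(), constraints)
  ev <- events[candidate$event, , drop = FALSE]
  taxa <- variant_taxa(events)
  t <- candidate$target_taxon
  target_allele <- ev[[paste0("allele_", t)]]
  other_alleles <- unlist(ev[paste0("allele_", setdiff(taxa, t))])
  if (any(other_alleles == target_allele))
    stop("SNP is not diagnostic: target allele present in a non-target taxon")
  col <- ev$start_col
  cons <- conserved_columns(aln)
  colseq <- strsplit(aln$seqs[[1L]], "", fixed = TRUE)[[1L]]
  cum <- cum_base_matrix(aln)
  swap <- c(A = "C", C = "A", G = "T", T = "G")   # purine <-> pyrimidine
  for (orient in c("forward", "reverse")) {
    lens <- constraints$primer_len[1L]:constraints$primer_len[2L]
    as_primer <- NULL
    for (l in lens) {
      if (orient == "forward") {
        a <- col - l + 1L; b <- col - 1L
        if (a < 1L || !all(cons[a:b])) next
        seq <- paste(c(colseq[a:b], target_allele), collapse = "")
      } else {
        a <- col + 1L; b <- col + l - 1L
        if (b > aln$ncol || !all(cons[a:b])) next
        seq <- revcomp(paste(c(target_allele, colseq[a:b]), collapse = ""))
      }
      pos <- l - mismatch_offset
      if (pos < 1L) next
      template_base <- substr(seq, pos, pos)
      mod <- seq
      substr(mod, pos, pos) <- unname(swap[template_base])
      gcf <- gc_fraction(mod)
      if (gcf < constraints$gc[1L] || gcf > constraints$gc[2L]) next
      tm <- melting_temperature(mod)
      if (tm < constraints$tm[1L] || tm > constraints$tm[2L]) next
      as_primer <- list(seq = mod, len = l, tm = tm,
                        template_base = template_base)
      break
    }
    if (is.null(as_primer)) next
    comp_side <- if (orient == "forward") "right" else "left"
    limit <- if (orient == "forward") col + 1L else col - 1L
    comp <- side_candidates(cons, colseq, limit, comp_side, constraints)
    if (is.null(comp)) next
    for (j in seq_len(min(nrow(comp), 25L))) {
      if (orient == "forward") {
        f_cols <- c(col - as_primer$len + 1L, col)
        r_cols <- c(comp$start_col[j], comp$end_col[j])
        fwd <- as_primer$seq; rev <- revcomp(comp$seq[j])
        sizes <- projected_sizes(aln, f_cols[1L], r_cols[2L], cum)
        as_name <- "F"
      } else {
        f_cols <- c(comp$start_col[j], comp$end_col[j])
        r_cols <- c(col, col + as_primer$len - 1L)
        fwd <- comp$seq[j]; rev <- as_primer$seq
        sizes <- projected_sizes(aln, f_cols[1L], r_cols[2L], cum)
        as_name <- "R"
      }
      if (max(sizes) > constraints$max_amplicon) next
      if (!primer_dimer_ok(fwd, rev)) next
      sizes[setdiff(taxa, t)] <- NA_real_
      mod_tab <- data.frame(primer = as_name, offset3 = mismatch_offset,
                            template = as_primer$template_base,
                            primer_base = unname(swap[as_primer$template_base]),
                            stringsAsFactors = FALSE)
      ta <- max(constraints$tm[1L],
                min(constraints$tm[2L], floor(min(as_primer$tm, comp$tm[j])) - 3))
      return(primer_pair(name %||% paste0(t, "_SNP"), fwd, rev, t,
                         "snp_dominant", f_cols, r_cols, sizes,
                         modified = mod_tab, annealing_temp = ta,
                         locus = candidate$locus, region = candidate$region))
    }
  }
  stop("design-failure: SNP context does not admit an allele-specific primer ",
       "under the length/GC/Tm constraints")
}

#' Design markers for every taxon's best candidates
#'
#' Convenience wrapper: for each taxon, designs primer pairs for its
#' candidates (InDel candidates first, then SNP fallbacks) until `per_taxon`
#' markers succeed.
#'
#' @param aln alignment; @param candidates from [select_candidates()];
#' @param events `variant_table`; @param per_taxon markers per taxon;
#' @param constraints primer constraints.
#' @return named list of `primer_pair`.
#' @export
design_markers <- function(aln, candidates, events, per_taxon = 1L,
                           constraints = list()) {
  out <- list()
  for (t in unique(candidates$target_taxon)) {
    cand <- candidates[candidates$target_taxon == t, , drop = FALSE]
    cand <- cand[order(cand$kind != "indel_codominant"), , drop = FALSE]
    made <- 0L
    for (i in seq_len(nrow(cand))) {
      if (made >= per_taxon) break
      nm <- sprintf("%s_%s%02d", t,
                    if (cand$kind[i] == "indel_codominant") "InDel" else "SNP",
                    made + 1L)
      pp <- tryCatch({
        if (cand$kind[i] == "indel_codominant")
          design_primer_pair(aln, cand[i, ], events, name = nm,
                             constraints = constraints)
        else design_allele_specific(aln, cand[i, ], events, name = nm,
                                    constraints = constraints)
      }, error = function(e) NULL)
      if (!is.null(pp)) {
        out[[nm]] <- pp
        made <- made + 1L
      }
    }
  }
  out
}

#' Write a marker table (TSV) and primers FASTA
#'
#' @param markers named list of `primer_pair`.
#' @param path TSV output path.
#' @param fasta optional primers FASTA path.
#' @param meta header metadata.
#' @return the TSV path, invisibly.
#' @export
write_marker_table <- function(markers, path, fasta = NULL, meta = list()) {
  rows <- lapply(markers, function(p) {
    sz <- p$predicted_sizes
    tgt <- sz[[p$target_taxon]]
    oth <- sz[setdiff(names(sz), p$target_taxon)]
    data.frame(name = p$name, target = p$target_taxon, kind = p$kind,
               region = p$region, locus = p$locus,
               forward = p$forward, reverse = p$reverse,
               annealing_temp = p$annealing_temp,
               size_target = tgt,
               size_others = paste(ifelse(is.na(oth), "-", oth), collapse = "/"),
               modified = if (nrow(p$modified_positions))
                 sprintf("%s:offset%d:%s>%s", p$modified_positions$primer[1L],
                         p$modified_positions$offset3[1L],
                         p$modified_positions$template[1L],
                         p$modified_positions$primer_base[1L]) else ".",
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(rows, make.row.names = FALSE))
  write_tsv_with_meta(df, path, meta)
  if (!is.null(fasta)) {
    seqs <- unlist(lapply(markers, function(p)
      setNames(c(p$forward, p$reverse), paste0(p$name, c("_F", "_R")))))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fasta)
  }
  invisible(path)
}
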