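# Independent brute-force oracles and small fixture builders. These are
# deliberately written as plain per-element loops, independent of the
# vectorized implementations they check.

toy_alignment <- function(...) alignment_from_seqs(c(...))

# per-column enumeration of SNP and InDel events
bf_variants <- function(aln) {
  m <- do.call(rbind, strsplit(unname(aln$seqs), "", fixed = TRUE))
  rownames(m) <- aln$taxa
  nc <- ncol(m)
  out <- list()
  cc <- 1L
  while (cc <= nc) {
    col <- m[, cc]
    if (any(col == "-")) {
      pat <- paste(which(col == "-"), collapse = ",")
      e <- cc
      while (e < nc && any(m[, e + 1L] == "-") &&
             paste(which(m[, e + 1L] == "-"), collapse = ",") == pat) e <- e + 1L
      alle <- apply(m[, cc:e, drop = FALSE], 1L, paste, collapse = "")
      out[[length(out) + 1L]] <- list(kind = "InDel", s = cc, e = e,
                                      alleles = alle)
      cc <- e + 1L
    } else {
      bases <- col[col != "N"]
      if (length(unique(bases)) >= 2L)
        out[[length(out) + 1L]] <- list(kind = "SNP", s = cc, e = cc,
                                        alleles = col)
      cc <- cc + 1L
    }
  }
  out
}

# random gapped alignment with no all-gap columns and no terminal gaps
random_alignment <- function(ntaxa = 4L, ncol = 60L, gap_p = 0.06,
                             sub_p = 0.08, n_p = 0.01) {
  anc <- sample(c("A", "C", "G", "T"), ncol, replace = TRUE)
  m <- matrix(rep(anc, each = ntaxa), nrow = ntaxa)
  for (i in seq_len(ntaxa)) {
    for (j in seq_len(ncol)) {
      r <- runif(1)
      if (r < gap_p) m[i, j] <- "-"
      else if (r < gap_p + sub_p) m[i, j] <- sample(setdiff(c("A", "C", "G", "T"),
                                                            m[i, j]), 1L)
      else if (r < gap_p + sub_p + n_p) m[i, j] <- "N"
    }
  }
  # repair all-gap columns and terminal gap columns
  for (j in c(1L, ncol)) m[m[, j] == "-", j] <- anc[j]
  for (j in seq_len(ncol)) if (all(m[, j] == "-")) m[1L, j] <- anc[j]
  alignment_from_seqs(setNames(apply(m, 1L, paste, collapse = ""),
                               paste0("t", seq_len(ntaxa))))
}

# maximal perfect tandem repeats by direct checking, O(n^2)
bf_ssrs <- function(s, thresholds = c(`1` = 10L, `2` = 6L, `3` = 5L,
                                      `4` = 5L, `5` = 4L, `6` = 4L)) {
  v <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(v)
  found <- list()
  for (m in as.integer(names(thresholds))) {
    for (i in seq_len(max(n - 2L * m + 1L, 0L))) {
      motif <- paste(v[i:(i + m - 1L)], collapse = "")
      if (grepl("N", motif, fixed = TRUE)) next
      # minimal period must be m
      is_prim <- TRUE
      for (p in seq_len(m - 1L))
        if (m %% p == 0L &&
            identical(strrep(paste(v[i:(i + p - 1L)], collapse = ""), m %/% p),
                      motif)) { is_prim <- FALSE; break }
      if (!is_prim) next
      u <- 1L
      while (i + (u + 1L) * m - 1L <= n &&
             identical(paste(v[(i + u * m):(i + (u + 1L) * m - 1L)],
                             collapse = ""), motif)) u <- u + 1L
      if (u < thresholds[[as.character(m)]]) next
      # maximal: not preceded by the same motif (otherwise found earlier)
      if (i > m && identical(paste(v[(i - m):(i - 1L)], collapse = ""), motif))
        next
      # nor preceded by a partial-period continuation shifting the run left
      if (i > 1L && v[i - 1L] == v[i + m - 1L]) next
      found[[length(found) + 1L]] <- data.frame(
        motif = motif, unit_count = u, start = i, end = i + u * m - 1L,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(found))
    return(data.frame(motif = character(), unit_count = integer(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, found)
  # canonical rotation of the motif
  out$motif <- vapply(out$motif, function(mo) {
    k <- nchar(mo)
    sort(vapply(seq_len(k), function(i)
      paste0(substr(mo, i, k), substr(mo, 1L, i - 1L)), ""))[1L]
  }, "")
  out[order(out$start, out$end), , drop = FALSE]
}

# per-site transition / transversion recount
bf_ts_tv <- function(x, y) {
  xv <- strsplit(x, "", fixed = TRUE)[[1L]]
  yv <- strsplit(y, "", fixed = TRUE)[[1L]]
  ts <- tv <- usable <- 0L
  pur <- c("A", "G")
  for (i in seq_along(xv)) {
    a <- xv[i]; b <- yv[i]
    if (!a %in% c("A", "C", "G", "T") || !b %in% c("A", "C", "G", "T")) next
    usable <- usable + 1L
    if (a != b) {
      if ((a %in% pur) == (b %in% pur)) ts <- ts + 1L else tv <- tv + 1L
    }
  }
  list(ts = ts, tv = tv, usable = usable)
}

# a small config the whole suite shares for end-to-end checks
small_sim_config <- function(seed = 11L, ...) {
  args <- list(seed = seed, lsc_len = 11000L, ssc_len = 3000L, ir_len = 2600L,
               n_genes = c(protein_coding = 8L, tRNA = 3L, rRNA = 1L),
               n_ssr = 6L, snp_counts = c(14L, 12L, 16L, 10L),
               shared_snps = 4L, indel_counts = c(6L, 6L, 6L, 6L),
               ir_snp_frac = 0.3,
               pseudogene_stop = list(taxon = "A_nipponica", gene = "infA"),
               pseudogene_frameshift = list(taxon = "A_pilosa", gene = "rps16"))
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

cached_small_truth <- local({
  ts <- NULL
  function() {
    if (is.null(ts)) ts <<- generate(small_sim_config())
    ts
  }
})
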