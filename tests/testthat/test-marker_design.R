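# Candidate selection, primer design (co-dominant and allele-specific),
# nearest-neighbor melting temperatures.

test_that("Tm follows GC monotonicity and duplex symmetry", {
  expect_lt(melting_temperature("AAAAAAAAAA"),
            melting_temperature("GCGCGCGCGC"))
  set.seed(13)
  for (rep in 1:10) {
    p <- paste(sample(c("A", "C", "G", "T"), sample(12:28, 1),
                      replace = TRUE), collapse = "")
    expect_equal(melting_temperature(p), melting_temperature(revcomp(p)))
  }
  expect_error(melting_temperature("ACGTACGN"), "A/C/G/T")
  expect_error(melting_temperature("ACGT"), "too short")
})

test_that("Tm equals spreadsheet arithmetic over the published NN table", {
  # ACGT x 5: stacks AC x5, CG x5, GT x5, TA x4; both termini A/T
  dH <- 5 * (-8.4) + 5 * (-10.6) + 5 * (-8.4) + 4 * (-7.2) + 2 * 2.3
  dS <- 5 * (-22.4) + 5 * (-27.2) + 5 * (-22.4) + 4 * (-21.3) + 2 * 4.1
  dS_salt <- dS + 0.368 * 19 * log(0.05)
  tm <- dH * 1000 / (dS_salt + 1.987 * log(500e-9 / 4)) - 273.15
  expect_equal(melting_temperature("ACGTACGTACGTACGTACGT"), round(tm, 1))
  # GC-rich 12-mer: GG x4, GC x4, CG x3; both termini G/C
  dH2 <- 4 * (-8.0) + 4 * (-9.8) + 3 * (-10.6) + 2 * 0.1
  dS2 <- 4 * (-19.9) + 4 * (-24.4) + 3 * (-27.2) + 2 * (-2.8) +
    0.368 * 11 * log(0.05)
  tm2 <- dH2 * 1000 / (dS2 + 1.987 * log(500e-9 / 4)) - 273.15
  expect_equal(melting_temperature("GGCGGCGGCGGC"), round(tm2, 1))
})

test_that("candidate selection applies the length and SSR rules", {
  ts <- cached_small_truth()
  ev <- extract_variants(ts$alignment)
  ssrs <- lapply(ts$genomes, find_ssrs)
  part <- ts$partition
  cand <- select_candidates(ev, ts$genomes, ssrs = ssrs, partition = part)
  # every selected InDel candidate is species-specific, >= 7 bp, non-SSR
  hit <- ssr_associated(ev, ssrs)
  for (i in which(cand$kind == "indel_codominant")) {
    e <- cand$event[i]
    expect_gte(ev$length_bp[e], 7)
    expect_false(hit[e])
  }
  # the guaranteed marker InDels are among the candidates
  marker_rows <- which(ts$truth$tag == "marker" & ts$truth$length_bp >= 7)
  expect_true(all(marker_rows %in% cand$event[cand$kind == "indel_codominant"]))
  # planted SSR-associated long InDels are excluded
  ssr_rows <- which(ts$truth$tag == "ssr_assoc" & ts$truth$length_bp >= 7)
  expect_false(any(ssr_rows %in% cand$event))
  # monotone filter: raising the threshold never adds candidates
  cand10 <- select_candidates(ev, ts$genomes, ssrs = ssrs, partition = part,
                              min_indel_len = 10)
  ind7 <- cand$event[cand$kind == "indel_codominant"]
  ind10 <- cand10$event[cand10$kind == "indel_codominant"]
  expect_true(all(ind10 %in% ind7))
})

test_that("SNP candidates are nonsynonymous or stop-introducing", {
  ts <- cached_small_truth()
  ev <- extract_variants(ts$alignment)
  cand <- select_candidates(ev, ts$genomes, partition = ts$partition)
  snp_cand <- cand[cand$kind == "snp_dominant", ]
  expect_gt(nrow(snp_cand), 0)
  expect_true(all(snp_cand$category %in% c("nonsynonymous", "stop_gained")))
  forced <- which(ts$truth$tag %in% c("forced_nonsynonymous", "forced_stop_gained",
                                      "pseudogene_stop"))
  expect_true(all(forced %in% snp_cand$event))
})

test_that("co-dominant designs reproduce the planted length difference in silico", {
  ts <- cached_small_truth()
  ev <- extract_variants(ts$alignment)
  ssrs <- lapply(ts$genomes, find_ssrs)
  cand <- select_candidates(ev, ts$genomes, ssrs = ssrs,
                            partition = ts$partition)
  ind <- cand[cand$kind == "indel_codominant", ]
  done <- 0
  for (i in seq_len(nrow(ind))) {
    pp <- tryCatch(design_primer_pair(ts$alignment, ind[i, ], ev),
                   error = function(e) NULL)
    if (is.null(pp)) next
    done <- done + 1
    tgt <- ind$target_taxon[i]
    for (t in names(ts$genomes)) {
      prods <- predict_amplicons(ts$genomes[[t]], pp)
      expect_equal(prods, unname(pp$predicted_sizes[[t]]),
                   info = paste(tgt, t))
    }
    others <- setdiff(names(ts$genomes), tgt)
    diffs <- pp$predicted_sizes[tgt] - pp$predicted_sizes[others]
    expect_true(all(abs(diffs) >= 7))
    if (done >= 3) break
  }
  expect_gte(done, 1)
})

test_that("design fails cleanly when no conserved flank exists", {
  # event at column 2: no room for an 18-30 nt conserved flank
  aln <- toy_alignment(a = paste0("A-", strrep("ACGT", 10)),
                       b = paste0("AT", strrep("ACGT", 10)),
                       c = paste0("AT", strrep("ACGT", 10)))
  ev <- extract_variants(aln, trim_terminal = FALSE)
  cand <- data.frame(event = 1, target_taxon = "a", kind = "indel_codominant",
                     region = NA, locus = NA, category = NA,
                     stringsAsFactors = FALSE)
  expect_error(design_primer_pair(aln, cand, ev), "design-failure")
})

test_that("allele-specific designs anchor the 3' end on the diagnostic SNP", {
  ts <- cached_small_truth()
  ev <- extract_variants(ts$alignment)
  cand <- select_candidates(ev, ts$genomes, partition = ts$partition)
  snp_cand <- cand[cand$kind == "snp_dominant", ]
  done <- 0
  for (i in seq_len(nrow(snp_cand))) {
    pp <- tryCatch(design_allele_specific(ts$alignment, snp_cand[i, ], ev),
                   error = function(e) NULL)
    if (is.null(pp)) next
    done <- done + 1
    tgt <- pp$target_taxon
    e <- snp_cand$event[i]
    target_allele <- ev[[paste0("allele_", tgt)]][e]
    # exactly one deliberate modification, at the stated 3' offset
    expect_equal(nrow(pp$modified_positions), 1)
    expect_equal(pp$modified_positions$offset3, 3)
    as_primer <- if (pp$modified_positions$primer == "F") pp$forward else pp$reverse
    # 3'-terminal base sits on the SNP and equals the target allele
    last <- substr(as_primer, nchar(as_primer), nchar(as_primer))
    expect_true(last %in% c(target_allele,
                            chartr("ACGT", "TGCA", target_allele)))
    # dominant behavior: target amplifies, others do not
    for (t in names(ts$genomes)) {
      prods <- predict_amplicons(ts$genomes[[t]], pp)
      if (t == tgt) expect_gt(length(prods), 0) else expect_length(prods, 0)
    }
    if (done >= 2) break
  }
  expect_gte(done, 1)
})

test_that("non-diagnostic SNPs are rejected for allele-specific design", {
  aln <- toy_alignment(a = paste0(strrep("ACGT", 15), "A", strrep("TGCA", 15)),
                       b = paste0(strrep("ACGT", 15), "G", strrep("TGCA", 15)),
                       c = paste0(strrep("ACGT", 15), "A", strrep("TGCA", 15)))
  ev <- extract_variants(aln, trim_terminal = FALSE)
  cand <- data.frame(event = 1, target_taxon = "c", kind = "snp_dominant",
                     region = NA, locus = NA, category = "nonsynonymous",
                     stringsAsFactors = FALSE)
  expect_error(design_allele_specific(aln, cand, ev), "not diagnostic")
})

test_that("marker tables and primer FASTA are written", {
  ts <- cached_small_truth()
  ev <- extract_variants(ts$alignment)
  cand <- select_candidates(ev, ts$genomes, partition = ts$partition)
  mk <- design_markers(ts$alignment, cand, ev)
  expect_gt(length(mk), 0)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_marker_table(mk, tsv, fasta = fa)
  tab <- read.table(tsv, sep = "\t", header = TRUE, comment.char = "#")
  expect_equal(nrow(tab), length(mk))
  seqs <- Biostrings::readDNAStringSet(fa)
  expect_length(seqs, 2 * length(mk))
})
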