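# Alignment ingestion, SNP/InDel event extraction, coordinate projection.

test_that("a 30-column toy alignment yields the planted 2 SNPs + one 5 bp InDel", {
  base <- strsplit("ACGTACGTACGTACGTACGTACGTACGTAC", "")[[1]]
  r1 <- r2 <- r3 <- r4 <- base
  r2[5] <- "T"                       # SNP 1
  r4[12] <- "A"                      # SNP 2
  r3[20:24] <- "-"                   # one 5-column gap
  aln <- toy_alignment(a = paste(r1, collapse = ""), b = paste(r2, collapse = ""),
                       c = paste(r3, collapse = ""), d = paste(r4, collapse = ""))
  ev <- extract_variants(aln)
  expect_equal(nrow(ev), 3)
  expect_equal(ev$kind, c("SNP", "SNP", "InDel"))
  expect_equal(ev$start_col, c(5, 12, 20))
  expect_equal(ev$end_col, c(5, 12, 24))
  expect_equal(ev$length_bp, c(0, 0, 5))
  expect_equal(ev$allele_b[1], "T")
  expect_equal(ev$allele_c[3], "-----")
})

test_that("identical rows give an empty event list", {
  aln <- toy_alignment(a = "ACGTACGTAC", b = "ACGTACGTAC")
  ev <- extract_variants(aln)
  expect_equal(nrow(ev), 0)
})

test_that("columns of only gaps are an integrity error", {
  aln <- toy_alignment(a = "AC-T", b = "AC-T")
  expect_error(extract_variants(aln), "only gaps")
})

test_that("extraction equals brute-force enumeration on random alignments", {
  set.seed(101)
  for (rep in 1:40) {
    aln <- random_alignment(ntaxa = sample(3:5, 1), ncol = sample(30:200, 1))
    got <- extract_variants(aln, trim_terminal = FALSE)
    want <- bf_variants(aln)
    expect_equal(nrow(got), length(want))
    if (!length(want)) next
    expect_equal(got$kind, vapply(want, `[[`, "", "kind"))
    expect_equal(got$start_col, vapply(want, `[[`, 0L, "s"))
    expect_equal(got$end_col, vapply(want, `[[`, 0L, "e"))
    for (k in seq_along(want)) {
      expect_equal(unname(unlist(got[k, paste0("allele_", aln$taxa)])),
                   unname(want[[k]]$alleles))
    }
  }
})

test_that("events are disjoint, maximal, and cover every polymorphic column", {
  set.seed(202)
  for (rep in 1:20) {
    aln <- random_alignment(ncol = 120)
    ev <- extract_variants(aln, trim_terminal = FALSE)
    if (!nrow(ev)) next
    cols <- unlist(mapply(seq, ev$start_col, ev$end_col, SIMPLIFY = FALSE))
    expect_false(any(duplicated(cols)))            # disjoint
    m <- do.call(rbind, strsplit(unname(aln$seqs), "", fixed = TRUE))
    gapped <- colSums(m == "-") > 0
    poly <- vapply(seq_len(ncol(m)), function(j) {
      v <- m[, j]; v <- v[v != "N" & v != "-"]
      length(unique(v)) >= 2
    }, TRUE)
    # completeness: every polymorphic or gapped column is inside an event
    expect_true(all(which(gapped | poly) %in% cols))
    # maximality: extending an InDel one column changes its gap pattern
    for (k in which(ev$kind == "InDel")) {
      pat <- paste(which(m[, ev$start_col[k]] == "-"), collapse = ",")
      if (ev$start_col[k] > 1) {
        left <- paste(which(m[, ev$start_col[k] - 1] == "-"), collapse = ",")
        expect_false(identical(left, pat))
      }
      if (ev$end_col[k] < ncol(m)) {
        right <- paste(which(m[, ev$end_col[k] + 1] == "-"), collapse = ",")
        expect_false(identical(right, pat))
      }
    }
  }
})

test_that("N-only polymorphism is not a variant and N taxa are ignored", {
  aln <- toy_alignment(a = "ACNT", b = "ACGT", c = "ACGT")
  expect_equal(nrow(extract_variants(aln)), 0)
  aln2 <- toy_alignment(a = "ACNT", b = "ACGT", c = "ACTT")
  ev <- extract_variants(aln2)
  expect_equal(nrow(ev), 1)                         # b vs c still polymorphic
  expect_equal(ev$allele_a, "N")
})

test_that("terminal gap-containing runs are trimmed as rotation overhangs", {
  aln <- toy_alignment(a = "--GTACGTAC", b = "ACGTACGTAC", c = "ACGTACGT--")
  ev <- extract_variants(aln, trim_terminal = TRUE)
  expect_equal(nrow(ev), 0)
  ev2 <- extract_variants(aln, trim_terminal = FALSE)
  expect_equal(sum(ev2$kind == "InDel"), 2)
})

test_that("project_position returns bases and flanking pairs", {
  aln <- toy_alignment(a = "AC-GT", b = "ACAGT")
  expect_equal(project_position(aln, "a", 3), "2/3")
  expect_equal(project_position(aln, "a", 5), "4")
  expect_equal(project_position(aln, "b", 5), "5")
  expect_error(project_position(aln, "a", 6), "beyond")
  expect_error(project_position(aln, "zz", 1), "unknown taxon")
})

test_that("projecting all base columns reproduces 1..L in order", {
  set.seed(5)
  for (rep in 1:10) {
    v <- sample(c("A", "C", "G", "T", "-"), 50, replace = TRUE,
                prob = c(0.22, 0.22, 0.22, 0.22, 0.12))
    if (v[1] == "-") v[1] <- "A"
    row <- paste(v, collapse = "")
    aln <- toy_alignment(a = row, b = gsub("-", "A", row))
    bases <- which(v != "-")
    got <- as.integer(project_position(aln, "a", bases))
    expect_equal(got, seq_along(bases))
  }
})

test_that("load_alignment validates shape and genome integrity", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "aln.fasta")
  writeLines(c(">a", "AC-GT", ">b", "ACAGT"), f)
  aln <- load_alignment(f)
  expect_equal(aln$ncol, 5)
  aln2 <- load_alignment(f, taxon_order = c("b", "a"))
  expect_equal(aln2$taxa, c("b", "a"))
  writeLines(c(">a", "AC-GT", ">b", "ACAGTT"), f)
  expect_error(load_alignment(f), "ragged")
  writeLines(c(">a", "AC-GT", ">b", "ACAGT"), f)
  gs <- list(a = genome_record("a", "ACGT"), b = genome_record("b", "ACAGT"))
  expect_silent(load_alignment(f, genomes = gs))
  gs$a <- genome_record("a", "ACTT")
  expect_error(load_alignment(f, genomes = gs), "integrity")
})

test_that("ungapping the generated truth alignment reproduces each genome", {
  ts <- cached_small_truth()
  for (t in names(ts$genomes)) {
    expect_identical(gsub("-", "", ts$alignment$seqs[[t]], fixed = TRUE),
                     ts$genomes[[t]]$sequence)
  }
})

test_that("variant TSV writes with region labels and reads back", {
  ts <- cached_small_truth()
  ev <- extract_variants(ts$alignment)
  part <- detect_inverted_repeats(ts$genomes[[1]], min_ir_len = 1000)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(ev, f, partition = part, meta = list(note = "test"))
  back <- read_variant_table(f)
  expect_equal(nrow(back), nrow(ev))
  expect_equal(back$start_col, ev$start_col)
  expect_true(all(back$region %in% c("LSC", "SSC", "IR")))
  # IR-planted SNPs are labelled IR via the reference projection
  ir_truth <- ts$truth$tag == "ir_mirror"
  expect_true(all(back$region[ir_truth] == "IR"))
})

test_that("written VCF parses and regenerates the event alleles", {
  skip_if_not_installed("vcfR")
  ts <- cached_small_truth()
  ev <- extract_variants(ts$alignment)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_variant_vcf(ev, ts$alignment, f)
  v <- suppressWarnings(vcfR::read.vcfR(f, verbose = FALSE))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v)
  taxa <- attr(ev, "taxa")
  ref_taxon <- taxa[1]
  ref_seq <- ts$genomes[[ref_taxon]]$sequence
  for (i in seq_len(nrow(fix))) {
    pos <- as.integer(fix$POS[i])
    alleles <- c(fix$REF[i], strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]])
    # REF allele must equal the reference genome at POS
    expect_identical(substr(ref_seq, pos, pos + nchar(fix$REF[i]) - 1L),
                     fix$REF[i])
    for (sm in colnames(gt)) {
      a <- alleles[as.integer(gt[i, sm]) + 1L]
      expect_true(!is.na(a) && nzchar(a))
    }
  }
  expect_equal(nrow(fix), sum(ev$kind == "SNP") +
                 sum(ev$kind == "InDel"))
})
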