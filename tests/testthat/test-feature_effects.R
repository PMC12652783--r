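# SNP effect classification, pseudogene detection, SSR scanning.

toy_gene_genome <- function(cds, strand = "+", pad = 30) {
  set.seed(9)
  left <- paste(sample(c("A", "C", "G", "T"), pad, replace = TRUE), collapse = "")
  right <- paste(sample(c("A", "C", "G", "T"), pad, replace = TRUE), collapse = "")
  seg <- if (strand == "+") cds else revcomp(cds)
  genome_record("toy", paste0(left, seg, right),
                features = data.frame(gene = "g1", kind = "protein_coding",
                                      strand = strand, start = pad + 1,
                                      end = pad + nchar(cds)))
}

test_that("classification matches codon arithmetic on a plus-strand CDS", {
  cds <- paste0("ATG", "GGA", "ATG", "CAA", "TAA")  # M G M Q *
  g <- toy_gene_genome(cds)
  # third position GGA -> GGG: synonymous
  eff <- classify_snp(g, 30 + 6, "G")
  expect_equal(eff$category, "synonymous")
  # first position of an internal ATG -> TTG: nonsynonymous
  eff <- classify_snp(g, 30 + 7, "T")
  expect_equal(eff$category, "nonsynonymous")
  expect_equal(eff$gene, "g1")
  # CAA -> TAA mid-gene: stop gained
  eff <- classify_snp(g, 30 + 10, "T")
  expect_equal(eff$category, "stop_gained")
  expect_equal(eff$codon_index, 4)
  # outside the gene: intergenic
  expect_equal(classify_snp(g, 3, "A")$category, "intergenic")
  expect_error(classify_snp(g, 10000, "A"), "outside genome")
  expect_error(classify_snp(g, 30 + 6, "A"), "equals the reference")
})

test_that("classification agrees with whole-CDS translation for random SNPs", {
  code <- Biostrings::getGeneticCode("11")
  set.seed(77)
  for (rep in 1:25) {
    ncod <- sample(10:100, 1)
    cds <- paste0("ATG",
                  paste(sample(setdiff(names(code), c("TAA", "TAG", "TGA")),
                               ncod - 2, replace = TRUE), collapse = ""),
                  "TAA")
    strand <- sample(c("+", "-"), 1)
    g <- toy_gene_genome(cds, strand = strand)
    pos <- sample(seq(31, 30 + nchar(cds)), 1)
    ref <- substr(g$sequence, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    eff <- classify_snp(g, pos, alt)
    # oracle: substitute in the genome, re-extract and translate the CDS
    mut <- g$sequence
    substr(mut, pos, pos) <- alt
    cds_mut <- substr(mut, 31, 30 + nchar(cds))
    if (strand == "-") cds_mut <- revcomp(cds_mut)
    aa_ref <- strsplit(as.character(Biostrings::translate(
      Biostrings::DNAString(cds), genetic.code = code)), "")[[1]]
    aa_mut <- strsplit(as.character(Biostrings::translate(
      Biostrings::DNAString(cds_mut), genetic.code = code)), "")[[1]]
    k <- which(aa_ref != aa_mut)
    want <- if (!length(k)) "synonymous"
    else if (aa_mut[k] == "*") "stop_gained"
    else if (aa_ref[k] == "*") "stop_lost"
    else "nonsynonymous"
    expect_equal(eff$category, want,
                 info = sprintf("rep %d strand %s pos %d", rep, strand, pos))
    if (length(k)) expect_equal(eff$codon_index, k)
  }
})

test_that("minus-strand classification equals classifying the complement", {
  cds <- paste0("ATG", "CAA", "GGA", "TAA")
  gp <- toy_gene_genome(cds, strand = "+")
  gm <- toy_gene_genome(cds, strand = "-")
  # CDS position k on + maps to genome position (30 + L + 1 - k) on -
  L <- nchar(cds)
  for (k in c(4, 5, 8)) {
    ref_p <- substr(gp$sequence, 30 + k, 30 + k)
    alt_p <- setdiff(c("A", "C", "G", "T"), ref_p)[1]
    eff_p <- classify_snp(gp, 30 + k, alt_p)
    eff_m <- classify_snp(gm, 30 + L + 1 - k, chartr("ACGT", "TGCA", alt_p))
    expect_equal(eff_m$category, eff_p$category)
    expect_equal(eff_m$codon_index, eff_p$codon_index)
  }
})

test_that("intronic positions and broken frames are handled", {
  set.seed(10)
  e1 <- "ATGGGA"; intron <- "GTAAGTTTTAG"; e2 <- "CAATAA"
  g <- genome_record("toy", paste0("CCCCC", e1, intron, e2, "CCCCC"),
                     features = data.frame(gene = "g1",
                                           kind = "protein_coding",
                                           strand = "+",
                                           start = c(6, 6 + 6 + 11),
                                           end = c(11, 5 + 6 + 11 + 6)))
  expect_equal(classify_snp(g, 14, "A")$category, "intronic")
  expect_equal(classify_snp(g, 8, "A")$category, "nonsynonymous")
  bad <- genome_record("toy2", "CCCCATGGGAACCCC",
                       features = data.frame(gene = "gx",
                                             kind = "protein_coding",
                                             strand = "+", start = 5, end = 11))
  expect_warning(eff <- classify_snp(bad, 6, "A"), "multiple of 3")
  expect_true(is.na(eff$category))
})

test_that("pseudogene detection flags premature stops and frameshifts", {
  clean <- toy_gene_genome(paste0("ATG", strrep("GGA", 58), "TAA"))
  expect_equal(nrow(detect_pseudogenes(clean)), 0)
  # TAA planted at codon 10 of 60
  broken <- toy_gene_genome(paste0("ATG", strrep("GGA", 8), "TAA",
                                   strrep("GGA", 49), "TAA"))
  call <- detect_pseudogenes(broken)
  expect_equal(call$reason, "premature_stop")
  expect_equal(call$stop_position, 10)
  expect_equal(call$n_codons, 60)
  # 1 bp insertion breaks the frame
  fs <- toy_gene_genome(paste0("ATG", "G", strrep("GGA", 58), "TAA"))
  call2 <- detect_pseudogenes(fs)
  expect_equal(call2$reason, "frameshift")
})

test_that("generated pseudogene lesions are called in the right taxa", {
  ts <- cached_small_truth()
  calls <- do.call(rbind, lapply(ts$genomes, detect_pseudogenes))
  expect_equal(nrow(calls), 2)
  expect_setequal(paste(calls$gene, calls$taxon, calls$reason),
                  c("infA A_nipponica premature_stop",
                    "rps16 A_pilosa frameshift"))
  expect_equal(calls$stop_position[calls$reason == "premature_stop"], 10)
})

test_that("SSR detection handles the canonical examples", {
  set.seed(11)
  bg <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
  s <- paste0(substr(bg, 1, 30), "G", strrep("A", 12), "C", substr(bg, 31, 60))
  hits <- find_ssrs(s)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$motif, "A")
  expect_equal(hits$unit_count, 12)
  expect_equal(hits$end - hits$start + 1, 12)
  # 12 bp of AT is one di tract of 6 units, not a mono tract
  s2 <- paste0("CC", "ATATATATATAT", "CC")
  hits2 <- find_ssrs(s2)
  expect_equal(nrow(hits2), 1)
  expect_equal(hits2$motif, "AT")
  expect_equal(hits2$unit_count, 6)
})

test_that("SSR scan equals the brute-force oracle on random sequences", {
  set.seed(88)
  for (rep in 1:30) {
    # seed short repeats in random backgrounds to exercise all motif sizes
    parts <- c(paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
                     collapse = ""),
               strrep(sample(c("A", "T", "AT", "AG", "AAT", "AATC"), 1),
                      sample(4:12, 1)),
               paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
                     collapse = ""))
    s <- paste(parts, collapse = "")
    got <- find_ssrs(s)
    want <- bf_ssrs(s)
    expect_equal(got$start, want$start, info = s)
    expect_equal(got$motif, want$motif, info = s)
    expect_equal(got$unit_count, want$unit_count, info = s)
  }
})

test_that("a shuffled repeat-free sequence yields no tracts", {
  set.seed(12)
  s <- paste(rep(c("A", "C", "G", "T"), 250)[sample(1000)], collapse = "")
  expect_identical(nrow(find_ssrs(s)), nrow(bf_ssrs(s)))
})

test_that("planted SSR tracts are all recovered from the ancestor", {
  ts <- cached_small_truth()
  found <- find_ssrs(ts$ancestor)
  for (i in seq_len(nrow(ts$ssrs))) {
    j <- which(found$start == ts$ssrs$start[i])
    expect_length(j, 1)
    expect_equal(found$unit_count[j], ts$ssrs$unit_count[i])
    expect_equal(found$end[j], ts$ssrs$end[i])
  }
})

test_that("SSR-overlapping InDels are flagged in any taxon", {
  ts <- cached_small_truth()
  ev <- extract_variants(ts$alignment)
  ssrs <- lapply(ts$genomes, find_ssrs)
  hit <- ssr_associated(ev, ssrs)
  planted <- ts$truth$tag == "ssr_assoc"
  expect_true(all(hit[planted]))
  expect_false(any(hit[ev$kind == "SNP"]))
  marker <- ts$truth$tag == "marker"
  expect_false(any(hit[marker]))
})
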