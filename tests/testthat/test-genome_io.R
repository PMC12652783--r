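# Genome IO, quadripartite structure detection, structural statistics.

test_that("gc_content matches direct counting and excludes N", {
  expect_equal(gc_content("GGCC"), 1)
  expect_equal(gc_content("ATGC"), 0.5)
  expect_equal(gc_content("ATGCNNNN"), 0.5)   # N out of the denominator
  expect_error(gc_content("NNNN"), "undefined")
})

test_that("gc_content is invariant under reverse complement and rotation", {
  set.seed(42)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
               collapse = "")
    expect_equal(gc_content(s), gc_content(revcomp(s)))
    k <- sample(199, 1)
    rot <- paste0(substr(s, k + 1, 200), substr(s, 1, k))
    expect_equal(gc_content(s), gc_content(rot))
  }
})

test_that("inverted repeats are recovered exactly from a built genome", {
  set.seed(7)
  lsc <- paste(sample(c("A", "C", "G", "T"), 6000, replace = TRUE), collapse = "")
  ssc <- paste(sample(c("A", "C", "G", "T"), 1500, replace = TRUE), collapse = "")
  ir <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE), collapse = "")
  # guard the IRb|SSC junction so the repeat cannot extend by chance
  substr(ssc, 1500, 1500) <- setdiff(c("A", "C", "G", "T"),
                                     chartr("ACGT", "TGCA",
                                            substr(ssc, 1, 1)))[1]
  g <- genome_record("toy", paste0(lsc, ir, ssc, revcomp(ir)))
  p <- detect_inverted_repeats(g, min_ir_len = 1000)
  expect_equal(unname(p$lengths), c(6000, 2000, 1500, 2000))
  expect_equal(p$lsc, c(1, 6000))
  expect_equal(p$irb, c(6001, 8000))
  expect_equal(p$ssc, c(8001, 9500))
  expect_equal(p$ira, c(9501, 11500))
  # partition tiling and IR symmetry at zero tolerance
  expect_equal(sum(p$lengths), nchar(g$sequence))
  irb_seq <- substr(g$sequence, p$irb[1], p$irb[2])
  ira_seq <- substr(g$sequence, p$ira[1], p$ira[2])
  expect_identical(revcomp(ira_seq), irb_seq)
})

test_that("sequences without a long inverted repeat are rejected", {
  set.seed(8)
  s <- paste(sample(c("A", "C", "G", "T"), 12000, replace = TRUE), collapse = "")
  expect_error(detect_inverted_repeats(genome_record("x", s), min_ir_len = 1000),
               "no quadripartite structure")
  expect_error(detect_inverted_repeats(genome_record("y", "ACGT"),
                                       min_ir_len = 1000),
               "no quadripartite structure")
  expect_error(detect_inverted_repeats(genome_record("z", s), min_ir_len = 10),
               "min_ir_len")
})

test_that("generator-built genomes yield exact boundary recovery", {
  ts <- cached_small_truth()
  for (t in names(ts$genomes)) {
    p <- detect_inverted_repeats(ts$genomes[[t]], min_ir_len = 1000)
    want <- ts$manifest$region_lengths[[t]]
    expect_equal(unname(p$lengths[["lsc"]]), unname(want[["lsc"]]), info = t)
    expect_equal(unname(p$lengths[["ssc"]]), unname(want[["ssc"]]), info = t)
    expect_equal(unname(p$lengths[["irb"]]), unname(want[["ir"]]), info = t)
    expect_equal(sum(p$lengths), nchar(ts$genomes[[t]]$sequence), info = t)
  }
})

test_that("FASTA + GFF3 round trip preserves sequences and features", {
  ts <- cached_small_truth()
  dir <- withr::local_tempdir()
  write_truth_set(ts, dir)
  gs <- read_genomes(file.path(dir, "genomes.fasta"),
                     gff = file.path(dir, "features.gff3"))
  expect_setequal(names(gs), names(ts$genomes))
  for (t in names(gs)) {
    expect_identical(gs[[t]]$sequence, ts$genomes[[t]]$sequence)
    expect_equal(nrow(gs[[t]]$features), ts$manifest$n_feature_rows)
    expect_setequal(unique(gs[[t]]$features$gene),
                    unique(ts$genomes[[t]]$features$gene))
  }
  tab <- summarize_structure(gs, min_ir_len = 1000)
  expect_equal(tab$genes, rep(ts$manifest$gene_counts$total, 4))
  expect_equal(tab$protein_coding,
               rep(ts$manifest$gene_counts$protein_coding, 4))
})

test_that("read_genomes validates input", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "one.fasta")
  writeLines(c(">r1", "ACGT"), f)
  gs <- read_genomes(f)
  expect_length(gs, 1)
  expect_equal(nchar(gs[["r1"]]$sequence), 4)
  expect_equal(nrow(gs[["r1"]]$features), 0)
  writeLines(c(">a", "ACGT", ">a", "GGCC"), f)
  expect_error(read_genomes(f), "duplicate")
  writeLines(character(), f)
  expect_error(read_genomes(f))
  expect_error(genome_record("x", ""), "empty")
  expect_error(genome_record("x", "ACGT",
                             features = data.frame(gene = "g", kind = "tRNA",
                                                   strand = "+", start = 2,
                                                   end = 9)),
               "outside")
})

test_that("summarize_structure produces one row per genome", {
  ts <- cached_small_truth()
  tab <- summarize_structure(ts$genomes, min_ir_len = 1000)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$total_bp,
               vapply(ts$genomes, function(g) nchar(g$sequence), 0,
                      USE.NAMES = FALSE))
  # intergenic GC tracks the configured 36.9%; uniform-codon genes pull the
  # genome-wide value a few points higher
  expect_true(all(tab$gc_pct > 30 & tab$gc_pct < 48))
})

test_that("region BED export uses 0-based half-open convention", {
  p <- detect_inverted_repeats(cached_small_truth()$genomes[[1]],
                               min_ir_len = 1000)
  f <- withr::local_tempfile(fileext = ".bed")
  write_region_bed(p, f, chrom = "g1")
  bed <- read.table(f, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(nrow(bed), 4)
  expect_equal(bed$V2[1], 0)                        # LSC starts at 0
  expect_equal(bed$V3 - bed$V2, unname(p$lengths))  # half-open widths
})
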