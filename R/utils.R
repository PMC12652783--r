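# Shared low-level helpers. Sequences are plain uppercase character scalars
# over {A,C,G,T,N} ('-' additionally allowed inside alignments); Biostrings
# containers are used at IO and pattern-matching boundaries.

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_BASES4 <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' @param x character scalar over `{A,C,G,T,N,-}`.
#' @return character scalar.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  chartr("ACGTN-", "TGCAN-", paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]),
                                   collapse = ""))
}

complement_base <- function(b) chartr("ACGTN", "TGCAN", b)

# split a set of equal-length sequences into a (taxa x columns) character matrix
seqs_to_matrix <- function(seqs) {
  m <- do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
  rownames(m) <- names(seqs)
  m
}

validate_dna <- function(x, allow_gap = FALSE, what = "sequence") {
  ok <- if (allow_gap) "^[ACGTN-]*$" else "^[ACGTN]*$"
  if (!grepl(ok, x)) {
    bad <- setdiff(unique(strsplit(x, "", fixed = TRUE)[[1L]]),
                   c(DNA_BASES4, "N", if (allow_gap) "-"))
    stop(sprintf("invalid %s: disallowed characters %s", what,
                 paste(sQuote(bad), collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

# run generator code under a seed without clobbering the caller's RNG stream
with_preserved_rng <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

random_dna <- function(n, gc = 0.369) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES4, n, replace = TRUE, prob = p), collapse = "")
}

# fraction of G+C among A/C/G/T characters of a plain string
gc_fraction <- function(x) {
  v <- strsplit(x, "", fixed = TRUE)[[1L]]
  v <- v[v %in% DNA_BASES4]
  if (!length(v)) return(NA_real_)
  mean(v %in% c("G", "C"))
}

# header-comment metadata block used by all TSV writers so reruns are
# byte-identical and self-describing
write_tsv_with_meta <- function(df, path, meta = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in names(meta)) {
    writeLines(sprintf("# %s: %s", k, paste(meta[[k]], collapse = " ")), con)
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_with_meta <- function(path) {
  read.table(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE)
}
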