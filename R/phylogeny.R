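# Kimura two-parameter distances, neighbor-joining, bootstrap support.
#
# The published analysis fits a maximum-likelihood tree under the K2P
# model; here the distance form of K2P with canonical Saitou-Nei
# neighbor-joining stands in, and that substitution is recorded in all
# outputs. Gapped sites are handled by pairwise deletion.

PURINES <- c("A", "G")

#' Kimura two-parameter distance between two aligned rows
#'
#' Sites with a gap or `N` in either row are excluded (pairwise deletion).
#' `P` and `Q` are the proportions of transitions and transversions among
#' usable sites and `d = -1/2 * ln((1 - 2P - Q) * sqrt(1 - 2Q))`.
#'
#' @param x,y equal-length gapped sequences (strings or character vectors).
#' @return list of class `k2p_distance`: `P`, `Q`, `d`, `usable_sites`.
#' @export
k2p_distance <- function(x, y) {
  if (length(x) == 1L) x <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
  if (length(y) == 1L) y <- strsplit(toupper(y), "", fixed = TRUE)[[1L]]
  if (length(x) != length(y)) stop("sequences must have equal length")
  ok <- x %in% DNA_BASES4 & y %in% DNA_BASES4
  u <- sum(ok)
  if (u == 0L) stop("no usable sites for K2P distance")
  xs <- x[ok]; ys <- y[ok]
  diff <- xs != ys
  ts <- diff & ((xs %in% PURINES) == (ys %in% PURINES))
  P <- sum(ts) / u
  Q <- sum(diff & !ts) / u
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0)
    stop("K2P distance undefined (substitution saturation)")
  d <- -0.5 * log(arg1 * sqrt(arg2))
  structure(list(P = P, Q = Q, d = d, usable_sites = u),
            class = "k2p_distance")
}

#' @export
print.k2p_distance <- function(x, ...) {
  cat(sprintf("<k2p_distance> d = %.6f (P = %.4f, Q = %.4f, %d usable sites)\n",
              x$d, x$P, x$Q, x$usable_sites))
  invisible(x)
}

#' Pairwise K2P distance matrix for an alignment
#'
#' @param aln `plastome_alignment` (or named character vector of rows).
#' @return symmetric numeric matrix with zero diagonal.
#' @export
k2p_matrix <- function(aln) {
  seqs <- if (inherits(aln, "plastome_alignment")) aln$seqs else aln
  k2p_matrix_from_mat(seqs_to_matrix(seqs))
}

k2p_matrix_from_mat <- function(m) {
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    D[i, j] <- D[j, i] <- k2p_distance(m[i, ], m[j, ])$d
  }
  D
}

#' Neighbor-joining tree
#'
#' Canonical Saitou-Nei neighbor joining with deterministic tie-breaking by
#' taxon order. Negative branch lengths are clamped to zero with the
#' deficit transferred to the adjacent (sister) branch so that the path
#' length between the joined pair is preserved.
#'
#' @param D symmetric distance matrix with zero diagonal, `n >= 3`, with
#'   taxon dimnames.
#' @return an [ape::read.tree()] `phylo` object (unrooted).
#' @export
nj_tree <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix must be symmetric")
  labs <- rownames(D) %||% paste0("t", seq_len(n))
  nwk <- labs
  fmt <- function(x) sprintf("%.10g", max(x, 0))
  while (n > 3L) {
    r <- rowSums(D)
    Qm <- (n - 2) * D - outer(r, r, "+")
    diag(Qm) <- Inf
    # smallest Q; ties resolved by smallest (i, j) in current order
    best <- which(Qm == min(Qm), arr.ind = TRUE)
    best <- best[best[, 1L] < best[, 2L], , drop = FALSE]
    best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE]
    i <- best[1L, 1L]; j <- best[1L, 2L]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new_nwk <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt(li), nwk[j], fmt(lj))
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    nwk <- c(nwk[keep], new_nwk)
    rownames(D2) <- colnames(D2) <- NULL
    D <- D2
    n <- n - 1L
  }
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", nwk[1], fmt(la), nwk[2], fmt(lb),
                 nwk[3], fmt(lc))
  ape::read.tree(text = txt)
}

#' Neighbor-joining tree with bootstrap support
#'
#' Resamples alignment columns with replacement, rebuilds the K2P + NJ tree
#' per replicate, and reports for each internal edge of the original tree
#' the percentage of replicates containing the same bipartition (stored in
#' `node.label`). Replicates with undefined distances are dropped with a
#' warning and counted.
#'
#' @param aln `plastome_alignment`.
#' @param n_replicates number of bootstrap replicates (>= 1).
#' @param seed RNG seed (recorded in the result).
#' @return `phylo` with `node.label` supports in percent; attributes
#'   `n_replicates`, `n_dropped`, `seed`.
#' @export
bootstrap_support <- function(aln, n_replicates = 100L, seed = 1L) {
  stopifnot(n_replicates >= 1L)
  m <- aln_matrix(aln)
  nc <- ncol(m)
  build <- function(mat) nj_tree(k2p_matrix_from_mat(mat))
  main <- build(m)
  boots <- list()
  dropped <- 0L
  with_preserved_rng(seed, {
    for (b in seq_len(n_replicates)) {
      cols <- sample.int(nc, nc, replace = TRUE)
      tr <- tryCatch(build(m[, cols, drop = FALSE]), error = function(e) NULL)
      if (is.null(tr)) dropped <- dropped + 1L else boots[[length(boots) + 1L]] <- tr
    }
  })
  if (dropped > 0L)
    warning(dropped, " bootstrap replicate(s) dropped (undefined distances)")
  used <- length(boots)
  counts <- if (used) ape::prop.clades(main, boots, rooted = FALSE) else
    rep(0L, main$Nnode)
  counts[is.na(counts)] <- 0L
  support <- round(100 * counts / max(used, 1L), 1)
  main$node.label <- as.character(support)
  attr(main, "n_replicates") <- n_replicates
  attr(main, "n_dropped") <- dropped
  attr(main, "seed") <- seed
  main
}

#' Write a PHYLIP-style square distance matrix TSV
#' @param D distance matrix; @param path output path; @param meta metadata.
#' @return the path, invisibly.
#' @export
write_distance_matrix <- function(D, path, meta = list()) {
  df <- data.frame(taxon = rownames(D), round(D, 8), check.names = FALSE)
  write_tsv_with_meta(df, path, meta)
}
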