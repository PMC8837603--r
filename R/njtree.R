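# Neighbor-joining on nucleotide p-distances, with deterministic label-order
# tie-breaking, serialized as Newick.

#' Pairwise p-distance matrix from a multiple alignment
#'
#' Mismatch fraction over column pairs where both rows are ungapped
#' (pairwise deletion).
#'
#' @param aln named character vector of equal-length gapped rows.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(aln) {
  stopifnot(!is.null(names(aln)), length(unique(nchar(aln))) == 1L)
  ch <- do.call(rbind, strsplit(toupper(aln), ""))
  rownames(ch) <- names(aln)
  n <- nrow(ch)
  D <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- ch[i, ] != "-" & ch[j, ] != "-"
      if (!any(ok)) {
        stop(sprintf("no shared ungapped columns between '%s' and '%s'",
                     names(aln)[i], names(aln)[j]), call. = FALSE)
      }
      D[i, j] <- D[j, i] <- mean(ch[i, ok] != ch[j, ok])
    }
  }
  D
}

fmt_len <- function(x) sprintf("%.10g", x)

#' Neighbor-joining tree from a distance matrix
#'
#' Classic NJ with deterministic tie-breaking: taxa start in label-sorted
#' order, merged nodes are appended at the end of the working order, and the
#' minimal Q-matrix entry with the smallest (row, column) pair wins ties.
#' The 3-taxon terminal case uses the closed-form star branch lengths.
#'
#' @param d symmetric distance matrix with labels, >= 2 taxa.
#' @return unrooted tree as a Newick string.
#' @export
nj_from_dist <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d), nrow(d) >= 2L,
            !is.null(rownames(d)))
  ord <- order(rownames(d))
  d <- d[ord, ord, drop = FALSE]
  labels <- rownames(d)
  frags <- labels
  if (length(labels) == 2L) {
    h <- d[1, 2] / 2
    return(sprintf("(%s:%s,%s:%s);", frags[1], fmt_len(h),
                   frags[2], fmt_len(h)))
  }
  while (nrow(d) > 3L) {
    n <- nrow(d)
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    best <- c(1L, 2L)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (q[i, j] < q[best[1], best[2]] - 1e-12) best <- c(i, j)
      }
    }
    i <- best[1]; j <- best[2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    new_frag <- sprintf("(%s:%s,%s:%s)", frags[i], fmt_len(li),
                        frags[j], fmt_len(lj))
    keep <- setdiff(seq_len(n), c(i, j))
    du <- (d[i, keep] + d[j, keep] - d[i, j]) / 2
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], du), c(du, 0))
    frags <- c(frags[keep], new_frag)
    rownames(d2) <- colnames(d2) <- sprintf("node%d", seq_len(n - 1L))
    d <- d2
  }
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  sprintf("(%s:%s,%s:%s,%s:%s);", frags[1], fmt_len(la),
          frags[2], fmt_len(lb), frags[3], fmt_len(lc))
}

#' Neighbor-joining tree from a multiple alignment
#'
#' p-distances with pairwise deletion, then [nj_from_dist()].
#'
#' @param aln named character vector of equal-length gapped rows, >= 3.
#' @return unrooted tree as a Newick string.
#' @export
nj_tree <- function(aln) {
  if (length(aln) < 3L) {
    stop("need at least 3 aligned rows for a tree", call. = FALSE)
  }
  nj_from_dist(p_distance_matrix(aln))
}
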