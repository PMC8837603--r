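# Deterministic progressive multiple alignment: guide tree from k-mer
# Jaccard distances (UPGMA), pairwise profile-profile global merges. Stands
# in for the external MUSCLE step of the original workflow; an externally
# computed alignment in FASTA can be supplied downstream instead.

kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(seq)
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

kmer_dist_matrix <- function(seqs, k = 4L) {
  sets <- lapply(seqs, kmer_set, k = k)
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      inter <- length(intersect(sets[[i]], sets[[j]]))
      uni <- length(union(sets[[i]], sets[[j]]))
      D[i, j] <- D[j, i] <- 1 - inter / max(uni, 1L)
    }
  }
  D
}

profile_of <- function(rows) {
  ch <- do.call(rbind, strsplit(rows, ""))
  L <- ncol(ch)
  P <- matrix(0, 5L, L)
  syms <- c("A", "C", "G", "T", "-")
  for (s in seq_along(syms)) P[s, ] <- colMeans(ch == syms[s])
  # unknown symbols (e.g. N) contribute nothing
  P
}

merge_profiles <- function(rows_a, rows_b, match = 1, mismatch = -1,
                           gap = -2) {
  path <- .nw_profile(profile_of(rows_a), profile_of(rows_b),
                      match, mismatch, gap)
  expand <- function(rows, idx) {
    ch <- do.call(rbind, strsplit(rows, ""))
    out <- matrix("-", nrow(ch), ncol(path))
    out[, idx > 0L] <- ch[, idx[idx > 0L], drop = FALSE]
    stats::setNames(apply(out, 1L, paste, collapse = ""), names(rows))
  }
  c(expand(rows_a, path[1, ]), expand(rows_b, path[2, ]))
}

#' Progressive multiple alignment of labeled sequences
#'
#' Deterministic: input rows are processed in label-sorted order, the guide
#' tree comes from k-mer Jaccard distances with average-linkage clustering,
#' and profile merges break DP ties in a fixed order. The result has at
#' least as many columns as the longest input.
#'
#' @param seqs named character vector of (unaligned) nucleotide sequences,
#'   length >= 2.
#' @param k k-mer size for the guide distances.
#' @return named character vector of equal-length gapped rows, in
#'   label-sorted order.
#' @export
align_progressive <- function(seqs, k = 4L) {
  if (length(seqs) < 2L) {
    stop("need at least 2 sequences to align", call. = FALSE)
  }
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  seqs <- toupper(seqs[order(names(seqs))])
  if (length(seqs) == 2L) {
    ali <- merge_profiles(seqs[1], seqs[2])
    return(ali[order(names(ali))])
  }
  D <- kmer_dist_matrix(seqs, k)
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  groups <- lapply(seq_along(seqs), function(i) seqs[i])
  merged <- vector("list", nrow(hc$merge))
  for (m in seq_len(nrow(hc$merge))) {
    pick <- function(x) if (x < 0) groups[[-x]] else merged[[x]]
    merged[[m]] <- merge_profiles(pick(hc$merge[m, 1]),
                                  pick(hc$merge[m, 2]))
  }
  ali <- merged[[length(merged)]]
  ali[order(names(ali))]
}
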