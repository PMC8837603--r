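# Greedy centroid clustering of trimmed amplicon reads into natural product
# sequence tags (NPSTs), the 95%-identity A-domain markers of the screening
# pipeline.

#' Clustering configuration
#' @param identity_threshold global-alignment identity threshold in (0, 1];
#'   default 0.95, the pipeline's published clustering identity.
#' @param order_rule read processing order; only `"length_then_lex"` (length
#'   descending, then sequence lexicographic ascending) is defined.
#' @return object of class `cluster_config`.
#' @export
cluster_config <- function(identity_threshold = 0.95,
                           order_rule = "length_then_lex") {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  order_rule <- match.arg(order_rule, "length_then_lex")
  structure(list(identity_threshold = identity_threshold,
                 order_rule = order_rule),
            class = "cluster_config")
}

#' Global-alignment identity between two nucleotide sequences
#'
#' Needleman-Wunsch with match +1 / mismatch -1 / gap -2 (linear); identity
#' is matches over alignment columns.
#'
#' @param a,b nucleotide strings.
#' @return numeric identity in `[0, 1]`.
#' @export
alignment_identity <- function(a, b) {
  if (a == b) return(1)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = TRUE),
    gapOpening = 0, gapExtension = 2
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  sum(pa == pb & pa != "-") / length(pa)
}

#' Cluster amplicon reads into NPSTs
#'
#' Greedy centroid clustering: reads are sorted by (length descending,
#' sequence lexicographic ascending); each read joins the first existing
#' centroid with global-alignment identity at or above the threshold,
#' otherwise it founds a new centroid. An NPST's pools are the union of its
#' members' pools.
#'
#' @param reads data.frame with columns `read_id`, `pool_id`, `seq`
#'   (e.g. `debarcode_and_trim()$assigned`), or a named character vector.
#' @param config a [cluster_config()].
#' @return list of objects of class `npst`, each with `npst_id`, `centroid`,
#'   `members` (read ids) and `pools`.
#' @export
cluster_npst <- function(reads, config = cluster_config()) {
  if (is.character(reads)) {
    reads <- data.frame(read_id = names(reads), pool_id = NA_character_,
                        seq = unname(reads), stringsAsFactors = FALSE)
  }
  if (nrow(reads) == 0L) stop("no reads to cluster", call. = FALSE)
  ord <- order(-nchar(reads$seq), reads$seq, reads$read_id)
  reads <- reads[ord, , drop = FALSE]
  centroids <- character(0)
  members <- list()
  pools <- list()
  for (i in seq_len(nrow(reads))) {
    s <- reads$seq[i]
    joined <- FALSE
    for (k in seq_along(centroids)) {
      if (alignment_identity(s, centroids[k]) >= config$identity_threshold) {
        members[[k]] <- c(members[[k]], reads$read_id[i])
        pools[[k]] <- union(pools[[k]], reads$pool_id[i])
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      centroids <- c(centroids, s)
      members[[length(centroids)]] <- reads$read_id[i]
      pools[[length(centroids)]] <- reads$pool_id[i]
    }
  }
  lapply(seq_along(centroids), function(k) {
    structure(
      list(npst_id = sprintf("NPST_%03d", k), centroid = centroids[k],
           members = members[[k]],
           pools = sort(pools[[k]][!is.na(pools[[k]])])),
      class = "npst"
    )
  })
}

#' Summarize a list of NPSTs as a data.frame
#' @param npsts list of `npst` objects.
#' @return data.frame with one row per NPST.
#' @export
npst_summary <- function(npsts) {
  data.frame(
    npst_id = vapply(npsts, `[[`, "", "npst_id"),
    n_members = vapply(npsts, function(x) length(x$members), 0L),
    n_pools = vapply(npsts, function(x) length(x$pools), 0L),
    centroid_len = vapply(npsts, function(x) nchar(x$centroid), 0L),
    stringsAsFactors = FALSE
  )
}

#' Write NPST centroids as FASTA
#' @param npsts list of `npst` objects.
#' @param file output path (or `NULL` to return text).
#' @return FASTA text, invisibly when written to file.
#' @export
write_npst_fasta <- function(npsts, file = NULL) {
  seqs <- vapply(npsts, `[[`, "", "centroid")
  names(seqs) <- vapply(npsts, function(x) {
    sprintf("%s members=%d pools=%s", x$npst_id, length(x$members),
            paste(x$pools, collapse = ","))
  }, "")
  write_fasta(seqs, file)
}

#' @export
print.npst <- function(x, ...) {
  cat(sprintf("<npst> %s  %d members, %d nt centroid, pools [%s]\n",
              x$npst_id, length(x$members), nchar(x$centroid),
              paste(x$pools, collapse = ",")))
  invisible(x)
}
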