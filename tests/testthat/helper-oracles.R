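# Independent test oracles and shared fixtures. The oracles deliberately
# avoid the code paths they check: brute-force IUPAC expansion instead of
# Biostrings matching, edge-recursion instead of prop.part, ape/cophenetic
# instead of the package's NJ.

IUPAC_ORACLE <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# all concrete expansions of an IUPAC pattern (only for small patterns)
iupac_expand <- function(pattern) {
  ch <- strsplit(pattern, "")[[1]]
  out <- ""
  for (c in ch) out <- as.vector(outer(out, IUPAC_ORACLE[[c]], paste0))
  out
}

oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# brute-force degenerate matcher: window-by-window minimum Hamming distance
# to any concrete expansion of the pattern, both strands
brute_match_degenerate <- function(seq, pattern, max_mm) {
  exps <- iupac_expand(pattern)
  w <- nchar(pattern)
  scan <- function(s, strand) {
    L <- nchar(s)
    hits <- data.frame(offset = integer(), strand = character(),
                       mismatches = integer(), stringsAsFactors = FALSE)
    if (L < w) return(hits)
    for (st in 1:(L - w + 1L)) {
      win <- substr(s, st, st + w - 1L)
      d <- min(vapply(exps, oracle_hamming, 0L, b = win))
      if (d <= max_mm) {
        off <- if (strand == "+") st - 1L else nchar(seq) - st - w + 1L
        hits <- rbind(hits, data.frame(offset = off, strand = strand,
                                       mismatches = d,
                                       stringsAsFactors = FALSE))
      }
    }
    hits
  }
  out <- rbind(scan(seq, "+"), scan(oracle_revcomp(seq), "-"))
  out[order(out$offset, out$strand), , drop = FALSE]
}

random_dna_chr <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force novel-clade oracle: recursion over the edge matrix
oracle_novel_clades <- function(tree, label_class, min_npst = 2L) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  tips <- tree$tip.label
  ntip <- length(tips)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  below <- function(nd) {
    if (nd <= ntip) return(tips[nd])
    unlist(lapply(kids[[as.character(nd)]], below))
  }
  sides <- list()
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    if (child <= ntip) next  # pendant edge: not an internal bipartition
    s <- sort(below(child))
    sides <- c(sides, list(s), list(sort(setdiff(tips, s))))
  }
  sides <- unique(sides)
  keep <- Filter(function(s) {
    length(s) >= 2L && sum(label_class[s] == "npst") >= min_npst &&
      !any(label_class[s] == "reference")
  }, sides)
  if (length(keep) == 0L) return(list())
  maximal <- Filter(function(s) {
    !any(vapply(keep, function(t) {
      length(t) > length(s) && all(s %in% t)
    }, NA))
  }, keep)
  maximal[order(vapply(maximal, paste, "", collapse = ","))]
}

# shared small fixtures (built once per test run)
.fixture_cache <- new.env(parent = emptyenv())

small_panel <- function() {
  if (is.null(.fixture_cache$panel)) {
    .fixture_cache$panel <- generate_reference_panel(3, 5, 7)
  }
  .fixture_cache$panel
}

small_fixture <- function() {
  if (is.null(.fixture_cache$fixture)) {
    panel <- small_panel()
    ids <- vapply(panel, `[[`, "", "id")
    .fixture_cache$fixture <- plant_amplicons(
      panel, 3,
      planted = list(pool01 = ids[c(1, 4, 5)], pool02 = ids[c(2, 3, 6)],
                     pool03 = ids[7:8]),
      seed = 11, insert_len = 4000)
  }
  .fixture_cache$fixture
}

amplicon_of <- function(ref) {
  span <- amplicon_span()
  substr(ref$nt_seq, span[1], span[2])
}
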