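# Novel-clade calling: metagenome-only (reference-free) sides of internal
# tree bipartitions flag candidate new BGC families.

#' Call metagenome-only clades on a tree
#'
#' Enumerates the leaf bipartitions of every internal edge and emits a call
#' for each *maximal* reference-free side containing at least `min_npst`
#' NPST leaves (maximal: not contained in a larger reference-free side).
#' Calls are invariant to leaf rotation and re-rooting.
#'
#' @param tree Newick string or `ape::phylo` object.
#' @param label_class named character vector mapping every leaf label to
#'   `"reference"` or `"npst"`.
#' @param min_npst minimum NPST leaves per called clade (default 2).
#' @return list of clade calls, each a list with `clade_leaves` (sorted
#'   labels), `n_npst`, `is_novel` (always `TRUE` for emitted calls) and
#'   `support_note`.
#' @export
call_novel_clades <- function(tree, label_class, min_npst = 2L) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  missing <- setdiff(tips, names(label_class))
  if (length(missing)) {
    stop("unlabeled leaf/leaves: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cls <- label_class[tips]
  if (!all(cls %in% c("reference", "npst"))) {
    stop("label classes must be 'reference' or 'npst'", call. = FALSE)
  }
  ntip <- length(tips)
  # sides of internal edges: tip sets below each internal (non-root) child,
  # plus their complements
  parts <- ape::prop.part(tree)
  root <- ntip + 1L
  internal_children <- unique(tree$edge[, 2][tree$edge[, 2] > ntip])
  sides <- list()
  for (nd in internal_children) {
    below <- tips[parts[[nd - ntip]]]
    sides[[length(sides) + 1L]] <- sort(below)
    sides[[length(sides) + 1L]] <- sort(setdiff(tips, below))
  }
  sides <- unique(sides)
  is_candidate <- vapply(sides, function(s) {
    length(s) >= 2L &&
      sum(label_class[s] == "npst") >= min_npst &&
      !any(label_class[s] == "reference")
  }, NA)
  cand <- sides[is_candidate]
  if (length(cand) == 0L) return(list())
  maximal <- vapply(seq_along(cand), function(i) {
    !any(vapply(seq_along(cand), function(j) {
      j != i && length(cand[[j]]) > length(cand[[i]]) &&
        all(cand[[i]] %in% cand[[j]])
    }, NA))
  }, NA)
  cand <- cand[maximal]
  cand <- cand[order(vapply(cand, function(s) paste(s, collapse = ","), ""))]
  lapply(cand, function(s) {
    list(clade_leaves = s,
         n_npst = sum(label_class[s] == "npst"),
         is_novel = TRUE,
         support_note = "maximal reference-free bipartition side")
  })
}

#' Summarize clade calls as a data.frame
#' @param calls result of [call_novel_clades()].
#' @return data.frame with one row per call.
#' @export
clade_call_summary <- function(calls) {
  data.frame(
    clade_id = sprintf("clade_%02d", seq_along(calls)),
    leaves = vapply(calls, function(x) paste(x$clade_leaves,
                                             collapse = ","), ""),
    n_leaves = vapply(calls, function(x) length(x$clade_leaves), 0L),
    n_npst = vapply(calls, `[[`, 0L, "n_npst"),
    is_novel = vapply(calls, `[[`, NA, "is_novel"),
    stringsAsFactors = FALSE
  )
}
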