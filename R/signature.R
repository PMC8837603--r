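# The PABA-family degenerate nucleotide signature: fixed IUPAC blocks at
# exact spacer distances, screened as presence/absence on both strands.

#' Parse a degenerate signature pattern string
#'
#' Accepts the `"BLOCK (Nk) BLOCK ..."` dialect, e.g.
#' `"ARAARA (N11) TTYGCNRT (N7) AARGAR"`: fixed IUPAC blocks separated by
#' exact-length spacers.
#'
#' @param pattern_string character scalar.
#' @return object of class `signature_pattern` with `blocks` (character
#'   vector of fixed IUPAC blocks), `spacers` (integer vector, one fewer than
#'   blocks) and `span` (total matched width in nt).
#' @export
parse_signature <- function(pattern_string) {
  stopifnot(is.character(pattern_string), length(pattern_string) == 1L)
  tokens <- strsplit(trimws(pattern_string), "\\s+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) stop("empty signature pattern", call. = FALSE)
  blocks <- character()
  spacers <- integer()
  expect_block <- TRUE
  for (tok in tokens) {
    if (grepl("^\\(N\\d+\\)$", tok)) {
      if (expect_block) {
        stop("signature pattern must start with a fixed block", call. = FALSE)
      }
      spacers <- c(spacers, as.integer(sub("^\\(N(\\d+)\\)$", "\\1", tok)))
      expect_block <- TRUE
    } else {
      tok <- toupper(tok)
      if (!is_iupac(tok)) {
        stop(sprintf("non-IUPAC character in signature block '%s'", tok),
             call. = FALSE)
      }
      if (!expect_block) {
        stop("two adjacent fixed blocks without a spacer", call. = FALSE)
      }
      blocks <- c(blocks, tok)
      expect_block <- FALSE
    }
  }
  if (expect_block) {
    stop("signature pattern must end with a fixed block", call. = FALSE)
  }
  if (any(spacers <= 0L)) stop("spacer lengths must be > 0", call. = FALSE)
  structure(
    list(blocks = blocks, spacers = spacers,
         span = sum(nchar(blocks)) + sum(spacers)),
    class = "signature_pattern"
  )
}

# collapse a parsed signature into one IUPAC string (spacers become N runs)
signature_iupac <- function(pattern) {
  stopifnot(inherits(pattern, "signature_pattern"))
  out <- pattern$blocks[1]
  for (i in seq_along(pattern$spacers)) {
    out <- paste0(out, strrep("N", pattern$spacers[i]), pattern$blocks[i + 1])
  }
  out
}

#' @export
print.signature_pattern <- function(x, ...) {
  cat(sprintf("<signature_pattern> %d blocks, spacers [%s], span %d nt\n",
              length(x$blocks), paste(x$spacers, collapse = ", "), x$span))
  invisible(x)
}

#' Screen a nucleotide sequence for the PABA signature
#'
#' True iff the concatenated pattern (fixed blocks at exact spacer
#' distances) occurs on either strand with at most `max_mismatch` positions
#' falling outside their IUPAC class in the fixed blocks (default 0, the
#' presence/absence screen).
#'
#' @param npst_nt nucleotide character scalar (an NPST centroid or any
#'   sequence to screen).
#' @param pattern a `signature_pattern` or pattern string
#'   (default [paba_signature()]).
#' @param max_mismatch mismatches tolerated in fixed blocks.
#' @return list with `match` (logical), `offset` (0-based forward-strand
#'   offset of the first hit, or `NA`), `strand` (`"+"`, `"-"` or `NA`).
#' @export
signature_filter <- function(npst_nt, pattern = paba_signature(),
                             max_mismatch = 0L) {
  if (is.character(pattern)) pattern <- parse_signature(pattern)
  pat <- signature_iupac(pattern)
  hits <- match_degenerate(npst_nt, pat, max_mismatch = max_mismatch)
  if (nrow(hits) == 0L) {
    return(list(match = FALSE, offset = NA_integer_, strand = NA_character_))
  }
  hits <- hits[order(hits$offset, hits$strand), , drop = FALSE]
  list(match = TRUE, offset = hits$offset[1], strand = hits$strand[1])
}
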