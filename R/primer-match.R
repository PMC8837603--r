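# Degenerate primer matching and in-silico PCR against the conserved A3/A7
# regions of NRPS adenylation domains.

#' Construct a degenerate primer
#' @param name primer name.
#' @param iupac_seq IUPAC nucleotide pattern (length >= 10).
#' @return object of class `degenerate_primer`.
#' @export
degenerate_primer <- function(name, iupac_seq) {
  iupac_seq <- toupper(iupac_seq)
  if (!is_iupac(iupac_seq)) {
    stop(sprintf("primer '%s' contains non-IUPAC characters", name),
         call. = FALSE)
  }
  if (nchar(iupac_seq) < 10L) {
    stop("primer must be at least 10 nt", call. = FALSE)
  }
  structure(list(name = name, iupac_seq = iupac_seq),
            class = "degenerate_primer")
}

primer_seq <- function(p) {
  if (inherits(p, "degenerate_primer")) p$iupac_seq else toupper(p)
}

#' Default A3/A7 primer pair
#' @return list with elements `fw` and `rv` (`degenerate_primer`).
#' @export
default_primers <- function() {
  list(fw = degenerate_primer("AD-FW", ad_fw_primer()),
       rv = degenerate_primer("AD-RV", ad_rv_primer()))
}

# mismatches of a concrete window vs an IUPAC pattern (positions outside the
# IUPAC class)
iupac_mismatches <- function(window, pattern) {
  w <- strsplit(window, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  sum(!mapply(function(b, cls) b %in% IUPAC_CLASSES[[cls]], w, p))
}

#' Find degenerate pattern matches on both strands
#'
#' Reports every position, on both strands, where `pattern` matches `seq`
#' with at most `max_mismatch` positions falling outside the pattern's IUPAC
#' character classes. Offsets are 0-based on the forward strand and refer to
#' the leftmost base of the matched region.
#'
#' @param seq concrete nucleotide string.
#' @param pattern IUPAC pattern (string or `degenerate_primer`).
#' @param max_mismatch non-negative mismatch allowance.
#' @return data.frame with columns `offset`, `strand` (`"+"`/`"-"`),
#'   `mismatches`.
#' @export
match_degenerate <- function(seq, pattern, max_mismatch = 0L) {
  pattern <- primer_seq(pattern)
  if (!is_iupac(pattern)) {
    stop("invalid IUPAC character in pattern", call. = FALSE)
  }
  stopifnot(max_mismatch >= 0L)
  empty <- data.frame(offset = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE)
  L <- nchar(seq)
  w <- nchar(pattern)
  if (L < w) return(empty)
  scan <- function(subject_chr, strand) {
    m <- Biostrings::matchPattern(
      Biostrings::DNAString(pattern), Biostrings::DNAString(subject_chr),
      max.mismatch = max_mismatch, with.indels = FALSE, fixed = "subject"
    )
    if (length(m) == 0L) return(empty)
    st <- Biostrings::start(m)
    off <- if (strand == "+") st - 1L else L - st - w + 1L
    mm <- vapply(st, function(s) {
      iupac_mismatches(substr(subject_chr, s, s + w - 1L), pattern)
    }, 0L)
    data.frame(offset = off, strand = strand, mismatches = mm,
               stringsAsFactors = FALSE)
  }
  out <- rbind(scan(toupper(seq), "+"), scan(revcomp(seq), "-"))
  out[order(out$offset, out$strand), , drop = FALSE]
}

#' In-silico PCR with degenerate primers
#'
#' Returns every substring of `contig` delimited by a forward-strand `fw`
#' site and a downstream reverse-complement `rv` site, inclusive of both
#' primer sites, with total length in `[min_len, max_len]`. Both orientations
#' of the contig are searched and all (possibly overlapping) site pairs are
#' reported. Products are reported 5'->3' from the forward primer.
#'
#' @param contig nucleotide string.
#' @param fw,rv primers (strings or `degenerate_primer`); default A3/A7 pair.
#' @param max_mismatch per-primer mismatch allowance (default 2).
#' @param min_len,max_len product length window in bp (primer sites
#'   included). Defaults bracket the ~0.9 kb A3-A7 amplicon and exclude
#'   cross-template products between co-planted A-domains.
#' @return character vector of amplicon sequences (empty when no site pair).
#' @export
insilico_pcr <- function(contig, fw = default_primers()$fw,
                         rv = default_primers()$rv, max_mismatch = 2L,
                         min_len = 100L, max_len = 1500L) {
  stopifnot(min_len < max_len)
  fw <- primer_seq(fw)
  rv <- primer_seq(rv)
  rc_rv <- revcomp(rv)
  one_orientation <- function(s) {
    hf <- match_degenerate(s, fw, max_mismatch)
    hf <- hf[hf$strand == "+", , drop = FALSE]
    if (nrow(hf) == 0L) return(character())
    hr <- match_degenerate(s, rc_rv, max_mismatch)
    hr <- hr[hr$strand == "+", , drop = FALSE]
    if (nrow(hr) == 0L) return(character())
    out <- character()
    for (i in hf$offset) {
      for (j in hr$offset) {
        end <- j + nchar(rc_rv)        # 0-based exclusive end
        len <- end - i
        if (j >= i + nchar(fw) && len >= min_len && len <= max_len) {
          out <- c(out, substr(s, i + 1L, end))
        }
      }
    }
    out
  }
  c(one_orientation(toupper(contig)), one_orientation(revcomp(contig)))
}
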