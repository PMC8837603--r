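#' @useDynLib npstminer, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import Biostrings
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generators do not disturb the
#' caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC nucleotide classes, used for degenerate primer/signature handling
IUPAC_CLASSES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

is_iupac <- function(x) {
  all(strsplit(toupper(x), "")[[1]] %in% names(IUPAC_CLASSES))
}

#' Reverse complement of a nucleotide string
#' @param seq nucleotide character scalar (IUPAC codes allowed).
#' @return character scalar.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Translate an in-frame nucleotide string
#' @param nt nucleotide character scalar; trailing partial codon is dropped.
#' @return amino-acid character scalar ('*' marks stops).
#' @export
translate_nt <- function(nt) {
  n <- nchar(nt) - nchar(nt) %% 3L
  if (n < 3L) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(substr(nt, 1L, n)),
    if.fuzzy.codon = "X"
  ))
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# all 61 non-stop codons
non_stop_codons <- function() {
  cod <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1L, paste,
               collapse = "")
  setdiff(cod, c("TAA", "TAG", "TGA"))
}

# sample one concrete expansion of an IUPAC pattern
sample_iupac <- function(pattern) {
  ch <- strsplit(toupper(pattern), "")[[1]]
  paste(vapply(ch, function(x) sample(IUPAC_CLASSES[[x]], 1L), ""),
        collapse = "")
}

#' Write named sequences as FASTA text
#'
#' @param seqs named character vector of sequences.
#' @param file path, or `NULL` to return the FASTA text invisibly.
#' @param width line wrap width.
#' @return character scalar of FASTA text (invisibly when `file` given).
#' @export
write_fasta <- function(seqs, file = NULL, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  recs <- vapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    lines <- substring(s, seq(1L, nchar(s), width),
                       pmin(seq(1L, nchar(s), width) + width - 1L, nchar(s)))
    paste0(">", names(seqs)[i], "\n", paste(lines, collapse = "\n"))
  }, "")
  txt <- paste0(paste(recs, collapse = "\n"), "\n")
  if (is.null(file)) return(txt)
  writeLines(sub("\n$", "", txt), file)
  invisible(txt)
}

#' Read a FASTA file into a named character vector
#' @param file path to a FASTA (nucleotide or protein) file.
#' @return named character vector.
#' @export
read_fasta <- function(file) {
  x <- Biostrings::readBStringSet(file)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}
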