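# De-barcoding and primer trimming of amplicon reads.

#' De-barcode reads and trim primer termini
#'
#' Assigns each read to the unique pool whose barcode is an exact prefix,
#' strips the barcode, and removes the forward-primer segment at the 5'
#' terminus and the reverse-complemented reverse-primer segment at the 3'
#' terminus (matched degenerately with `max_mismatch` tolerance).
#' Unassignable reads are reported separately, never silently dropped.
#'
#' @param reads named character vector of reads, or a `read_set`.
#' @param barcodes named character vector pool id -> barcode (pairwise
#'   distinct, none a prefix of another), or a `library_fixture`.
#' @param fw,rv primers; default A3/A7 pair.
#' @param max_mismatch primer mismatch allowance for trimming (default 2).
#' @return list with `assigned` (data.frame `read_id`, `pool_id`, `seq`,
#'   `trimmed`) and `unassigned` (data.frame `read_id`, `seq`).
#' @export
debarcode_and_trim <- function(reads, barcodes,
                               fw = default_primers()$fw,
                               rv = default_primers()$rv,
                               max_mismatch = 2L) {
  if (inherits(reads, "read_set")) reads <- reads$reads
  if (inherits(barcodes, "library_fixture")) barcodes <- barcode_map(barcodes)
  if (anyDuplicated(barcodes)) {
    stop("duplicate barcodes in barcode map", call. = FALSE)
  }
  for (i in seq_along(barcodes)) {
    for (j in seq_along(barcodes)) {
      if (i != j && startsWith(barcodes[[j]], barcodes[[i]])) {
        stop("barcode '", barcodes[[i]], "' is a prefix of another barcode",
             call. = FALSE)
      }
    }
  }
  fw <- primer_seq(fw)
  rc_rv <- revcomp(primer_seq(rv))
  assigned <- data.frame(read_id = character(), pool_id = character(),
                         seq = character(), trimmed = logical(),
                         stringsAsFactors = FALSE)
  unassigned <- data.frame(read_id = character(), seq = character(),
                           stringsAsFactors = FALSE)
  for (k in seq_along(reads)) {
    s <- reads[[k]]
    rid <- names(reads)[k]
    hit <- which(vapply(barcodes, function(b) startsWith(s, b), NA))
    if (length(hit) != 1L) {
      unassigned <- rbind(unassigned, data.frame(
        read_id = rid, seq = s, stringsAsFactors = FALSE))
      next
    }
    pid <- names(barcodes)[hit]
    s <- substr(s, nchar(barcodes[[hit]]) + 1L, nchar(s))
    # forward primer at the 5' terminus
    h5 <- match_degenerate(s, fw, max_mismatch)
    cut5 <- nrow(h5) > 0L && any(h5$offset == 0L & h5$strand == "+")
    if (cut5) s <- substr(s, nchar(fw) + 1L, nchar(s))
    # reverse-complemented reverse primer at the 3' terminus
    h3 <- match_degenerate(s, rc_rv, max_mismatch)
    tail_off <- nchar(s) - nchar(rc_rv)
    cut3 <- nrow(h3) > 0L && any(h3$offset == tail_off & h3$strand == "+")
    if (cut3) s <- substr(s, 1L, tail_off)
    assigned <- rbind(assigned, data.frame(
      read_id = rid, pool_id = pid, seq = s, trimmed = cut5 && cut3,
      stringsAsFactors = FALSE))
  }
  list(assigned = assigned, unassigned = unassigned)
}
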