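# Synthetic pooled cosmid-library fixtures: planted A-domain amplicons in
# random background contigs, plus a MiSeq-style substitution-error read
# simulator. Pools emulate arrayed sub-pools of a soil eDNA cosmid library
# (the real arrays hold ~25,000 clones of ~40 kb inserts per pool; tests use
# scaled-down insert lengths and clone counts).

DEFAULT_CLONES_PER_POOL <- 25000L
DEFAULT_INSERT_LEN <- 40000L

make_barcodes <- function(n, len = 8L) {
  out <- character(0)
  while (length(out) < n) {
    b <- random_dna(len)
    if (!b %in% out) out <- c(out, b)
  }
  out
}

#' Plant reference A-domain amplicons into pooled background contigs
#'
#' Each planted reference contributes its A3-A7 amplicon region (primer
#' sites inclusive) embedded at a random position in a pool's background
#' contig of uniform i.i.d. ACGT sequence. The truth table records every
#' plant.
#'
#' @param panel list of `reference_adomain` objects
#'   (from [generate_reference_panel()]).
#' @param n_pools number of pools.
#' @param clones_per_pool documented pool density (metadata only; default
#'   25,000 as in the emulated arrayed libraries).
#' @param planted named list: pool id (`"pool01"`, ...) -> character vector
#'   of reference ids to plant there.
#' @param seed integer seed.
#' @param insert_len background contig length per pool (bp); scaled down in
#'   tests, 40 kb-scale by default.
#' @return object of class `library_fixture`: `pools` (each with `pool_id`,
#'   `barcode`, `contigs`, `insert_len`, `clones_per_pool`), `truth`
#'   (data.frame `amplicon_id`, `reference_id`, `pool_id`, `amplicon`) and
#'   `seed`.
#' @export
plant_amplicons <- function(panel, n_pools, clones_per_pool =
                              DEFAULT_CLONES_PER_POOL,
                            planted = list(), seed = 1L,
                            insert_len = DEFAULT_INSERT_LEN) {
  ids <- vapply(panel, `[[`, "", "id")
  pool_ids <- sprintf("pool%02d", seq_len(n_pools))
  bad_pool <- setdiff(names(planted), pool_ids)
  if (length(bad_pool)) {
    stop("unknown pool id(s): ", paste(bad_pool, collapse = ", "),
         call. = FALSE)
  }
  bad_ref <- setdiff(unlist(planted), ids)
  if (length(bad_ref)) {
    stop("unknown reference id(s): ", paste(bad_ref, collapse = ", "),
         call. = FALSE)
  }
  span <- amplicon_span()
  with_seed(seed, {
    barcodes <- make_barcodes(n_pools)
    pools <- list()
    truth <- data.frame(amplicon_id = character(), reference_id = character(),
                        pool_id = character(), amplicon = character(),
                        stringsAsFactors = FALSE)
    for (p in seq_len(n_pools)) {
      pid <- pool_ids[p]
      refs_here <- planted[[pid]] %||% character(0)
      amps <- vapply(refs_here, function(r) {
        substr(panel[[match(r, ids)]]$nt_seq, span[1], span[2])
      }, "")
      need <- sum(nchar(amps)) + 100L * (length(amps) + 1L)
      len <- max(insert_len, need)
      # background segments between plants partition the leftover length
      n_gap <- length(amps) + 1L
      leftover <- len - sum(nchar(amps))
      cuts <- if (n_gap > 1L) sort(sample.int(leftover - n_gap, n_gap - 1L))
              else integer(0)
      gaps <- diff(c(0L, cuts, leftover - n_gap)) + 1L
      pieces <- character(0)
      for (k in seq_along(amps)) {
        pieces <- c(pieces, random_dna(gaps[k]), amps[[k]])
      }
      contig <- paste(c(pieces, random_dna(gaps[n_gap])), collapse = "")
      if (length(amps)) {
        truth <- rbind(truth, data.frame(
          amplicon_id = sprintf("%s_amp%02d", pid, seq_along(amps)),
          reference_id = refs_here, pool_id = pid,
          amplicon = unname(amps), stringsAsFactors = FALSE))
      }
      pools[[pid]] <- list(pool_id = pid, barcode = barcodes[p],
                           contigs = contig, insert_len = len,
                           clones_per_pool = clones_per_pool)
    }
    structure(list(pools = pools, truth = truth, seed = seed),
              class = "library_fixture")
  })
}

#' Barcode map of a library fixture
#' @param fixture a `library_fixture`.
#' @return named character vector pool id -> barcode.
#' @export
barcode_map <- function(fixture) {
  vapply(fixture$pools, `[[`, "", "barcode")
}

apply_substitutions <- function(seq, error_rate) {
  if (error_rate == 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(ch)) < error_rate)
  for (i in hit) ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1L)
  paste(ch, collapse = "")
}

#' Simulate barcoded amplicon reads from a library fixture
#'
#' Emulates amplicon sequencing of each pool: every planted amplicon yields
#' `reads_per_amplicon` reads with independent per-base substitution errors.
#' The pool barcode is prefixed error-free (demultiplexing is exact by
#' design), and read ids preserve the truth linkage.
#'
#' @param fixture a `library_fixture`.
#' @param error_rate per-base substitution probability in `[0, 0.25)`.
#' @param seed integer seed.
#' @param reads_per_amplicon read depth per planted amplicon.
#' @return object of class `read_set`: `reads` (named character vector,
#'   barcode-prefixed) and `truth` (data.frame `read_id`, `reference_id`,
#'   `pool_id`).
#' @export
simulate_reads <- function(fixture, error_rate, seed = 1L,
                           reads_per_amplicon = 10L) {
  stopifnot(inherits(fixture, "library_fixture"))
  if (!is.numeric(error_rate) || error_rate < 0 || error_rate >= 0.25) {
    stop("error_rate must be in [0, 0.25)", call. = FALSE)
  }
  bc <- barcode_map(fixture)
  with_seed(seed, {
    reads <- character(0)
    truth <- data.frame(read_id = character(), reference_id = character(),
                        pool_id = character(), stringsAsFactors = FALSE)
    tt <- fixture$truth
    for (i in seq_len(nrow(tt))) {
      for (j in seq_len(reads_per_amplicon)) {
        rid <- sprintf("%s_r%03d", tt$amplicon_id[i], j)
        reads[[rid]] <- paste0(bc[[tt$pool_id[i]]],
                               apply_substitutions(tt$amplicon[i],
                                                   error_rate))
        truth <- rbind(truth, data.frame(
          read_id = rid, reference_id = tt$reference_id[i],
          pool_id = tt$pool_id[i], stringsAsFactors = FALSE))
      }
    }
    structure(list(reads = reads, truth = truth, error_rate = error_rate,
                   seed = seed),
              class = "read_set")
  })
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %d reads, %d pools, error_rate=%g\n",
              length(x$reads), length(unique(x$truth$pool_id)),
              x$error_rate))
  invisible(x)
}

#' @export
print.library_fixture <- function(x, ...) {
  cat(sprintf("<library_fixture> %d pools, %d planted amplicons, seed=%d\n",
              length(x$pools), nrow(x$truth), x$seed))
  invisible(x)
}
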