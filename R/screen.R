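# Two-step PABA-specific NPST screen: (1) translated Smith-Waterman against
# characterized PABA A-domains with a Karlin-Altschul E-value threshold
# (default 1e-25); (2) the degenerate nucleotide signature filter.

#' Screen configuration
#'
#' Scoring is Smith-Waterman with BLOSUM62 (gap open 11, extend 1) and
#' Karlin-Altschul E-values `E = K * m * n * exp(-lambda * S)` using the
#' published gapped constants (lambda = 0.267, K = 0.041); `m` is the
#' translated query length, `n` the summed reference protein length.
#'
#' @param evalue_threshold primary-hit threshold (default 1e-25).
#' @param gap_opening,gap_extension gap penalties.
#' @param lambda,K Karlin-Altschul parameters.
#' @param signature signature pattern string for step two.
#' @param signature_max_mismatch fixed-block mismatch allowance (default 0:
#'   presence/absence).
#' @return object of class `screen_config`.
#' @export
screen_config <- function(evalue_threshold = 1e-25, gap_opening = 11,
                          gap_extension = 1, lambda = 0.267, K = 0.041,
                          signature = paba_signature(),
                          signature_max_mismatch = 0L) {
  stopifnot(evalue_threshold > 0)
  structure(
    list(evalue_threshold = evalue_threshold, matrix = "BLOSUM62",
         gap_opening = gap_opening, gap_extension = gap_extension,
         lambda = lambda, K = K, signature = signature,
         signature_max_mismatch = signature_max_mismatch),
    class = "screen_config"
  )
}

# six-frame translations of a nucleotide string
translate_frames <- function(nt) {
  rc <- revcomp(nt)
  frames <- c(lapply(1:3, function(f) substr(nt, f, nchar(nt))),
              lapply(1:3, function(f) substr(rc, f, nchar(rc))))
  names(frames) <- c("+1", "+2", "+3", "-1", "-2", "-3")
  vapply(frames, translate_nt, "")
}

# a frame is usable when it has no internal stop codon
stop_free <- function(prot) {
  nchar(prot) > 0L && !grepl("\\*", substr(prot, 1L, nchar(prot) - 1L))
}

#' Best reference hit of an NPST (E-value screen, step one)
#'
#' Translates the centroid in all six frames, keeps stop-free frames, and
#' locally aligns each against every reference protein; the maximum-bitscore
#' hit wins (ties broken by frame index, then reference order).
#'
#' @param npst an `npst` object or nucleotide string.
#' @param refs list of `reference_adomain` objects (the characterized PABA
#'   A-domain panel).
#' @param config a [screen_config()].
#' @return list with `npst_id`, `untranslatable`, `reason`, `best_ref`,
#'   `frame`, `score`, `bitscore`, `evalue`, `passed_evalue`.
#' @export
best_hit <- function(npst, refs, config = screen_config()) {
  stopifnot(length(refs) > 0L)
  nt <- if (inherits(npst, "npst")) npst$centroid else npst
  id <- if (inherits(npst, "npst")) npst$npst_id else NA_character_
  prots <- translate_frames(nt)
  ok <- vapply(prots, stop_free, NA)
  if (!any(ok)) {
    return(list(npst_id = id, untranslatable = TRUE,
                reason = "no stop-free reading frame",
                best_ref = NA_character_, frame = NA_character_,
                score = NA_real_, bitscore = NA_real_, evalue = NA_real_,
                passed_evalue = FALSE))
  }
  ref_prots <- vapply(refs, `[[`, "", "protein_seq")
  ref_ids <- vapply(refs, `[[`, "", "id")
  n_total <- sum(nchar(ref_prots))
  best <- NULL
  for (f in names(prots)[ok]) {
    q <- Biostrings::AAString(prots[[f]])
    for (r in seq_along(refs)) {
      s <- Biostrings::pairwiseAlignment(
        q, Biostrings::AAString(ref_prots[r]), type = "local",
        substitutionMatrix = "BLOSUM62",
        gapOpening = config$gap_opening, gapExtension = config$gap_extension,
        scoreOnly = TRUE
      )
      if (is.null(best) || s > best$score) {
        best <- list(frame = f, ref = ref_ids[r], score = s,
                     m = nchar(prots[[f]]))
      }
    }
  }
  evalue <- config$K * best$m * n_total * exp(-config$lambda * best$score)
  bitscore <- (config$lambda * best$score - log(config$K)) / log(2)
  list(npst_id = id, untranslatable = FALSE, reason = NA_character_,
       best_ref = best$ref, frame = best$frame, score = best$score,
       bitscore = bitscore, evalue = evalue,
       passed_evalue = evalue < config$evalue_threshold)
}

#' Two-step PABA-specific NPST screen
#'
#' Applies the E-value filter ([best_hit()]) to every NPST and the signature
#' filter ([signature_filter()]) to primary hits only. Every input NPST
#' receives a record; the final PABA call is
#' `passed_evalue AND passed_signature`.
#'
#' @param npsts list of `npst` objects.
#' @param refs characterized PABA A-domain panel.
#' @param config a [screen_config()].
#' @return data.frame (one row per NPST, ordered by `npst_id`) with columns
#'   `npst_id`, `best_ref`, `frame`, `bitscore`, `evalue`, `passed_evalue`,
#'   `passed_signature`, `signature_offset`, `final_call`, `reason`.
#' @export
two_step_screen <- function(npsts, refs, config = screen_config()) {
  rows <- lapply(npsts, function(np) {
    bh <- best_hit(np, refs, config)
    passed_sig <- NA
    sig_off <- NA_integer_
    if (isTRUE(bh$passed_evalue)) {
      sig <- signature_filter(np$centroid, config$signature,
                              config$signature_max_mismatch)
      passed_sig <- sig$match
      sig_off <- sig$offset
    }
    data.frame(
      npst_id = np$npst_id, best_ref = bh$best_ref, frame = bh$frame,
      bitscore = bh$bitscore, evalue = bh$evalue,
      passed_evalue = bh$passed_evalue, passed_signature = passed_sig,
      signature_offset = sig_off,
      final_call = isTRUE(bh$passed_evalue) && isTRUE(passed_sig),
      reason = if (isTRUE(bh$untranslatable)) bh$reason else NA_character_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(npst_id = character(), best_ref = character(),
                      frame = character(), bitscore = numeric(),
                      evalue = numeric(), passed_evalue = logical(),
                      passed_signature = logical(),
                      signature_offset = integer(), final_call = logical(),
                      reason = character(), stringsAsFactors = FALSE)
  }
  out[order(out$npst_id), , drop = FALSE]
}
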