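# Extraction of the 10-residue substrate-binding-pocket (Stachelhaus) code,
# nearest-code substrate prediction, and A-domain activity calling.
#
# Coordinate convention: the pocket positions (235, 236, 239, 278, 299, 301,
# 322, 330, 331, 517) are interpreted in the numbering of the bundled anchor
# A-domain; query sequences are mapped into that frame by pairwise
# alignment. Position 299 (slot 5 of the sorted 10-tuple) is the known most
# variable pocket position and is annotated, never auto-matched.

#' Binding-pocket position map in the anchor coordinate frame
#' @return object of class `code_position_map` with `positions`,
#'   `reference_id` and `anchor_seq`.
#' @export
code_position_map <- function() {
  anchor <- anchor_adomain()
  structure(
    list(positions = code_positions(), reference_id = anchor$id,
         anchor_seq = anchor$protein_seq),
    class = "code_position_map"
  )
}

VARIABLE_POSITION_SLOT <- 5L  # position 299

# global-in-query alignment against the anchor; returns aligned strings,
# the anchor coordinate preceding the aligned window, and identity stats
align_to_anchor <- function(protein_seq, anchor_seq) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(protein_seq), Biostrings::AAString(anchor_seq),
    type = "global-local", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1
  )
  qa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  list(qa = qa, sa = sa,
       anchor_offset = Biostrings::start(Biostrings::subject(aln)) - 1L,
       identity = sum(qa == sa & qa != "-") / length(qa),
       columns = length(qa))
}

#' Extract the 10-residue specificity code from an A-domain protein
#'
#' Aligns the query to the anchor and reads the query residue in each
#' anchor-coordinate pocket column; a gap (or a pocket position outside the
#' aligned span, e.g. position 517 on a partial A3-A7 amplicon) yields `'-'`
#' and reduces coverage.
#'
#' @param protein_seq amino-acid string.
#' @param map a [code_position_map()].
#' @param min_identity,min_columns acceptance floor for the anchor
#'   alignment; below it the input is rejected as not an A-domain.
#' @param source_id identifier carried into the result.
#' @return object of class `specificity_code` with `residues` (10
#'   characters), `source_id`, `coverage`.
#' @export
extract_code <- function(protein_seq, map = code_position_map(),
                         min_identity = 0.4, min_columns = 200L,
                         source_id = NA_character_) {
  stopifnot(inherits(map, "code_position_map"))
  al <- align_to_anchor(protein_seq, map$anchor_seq)
  if (al$identity < min_identity || al$columns < min_columns) {
    stop(sprintf(
      "not an A-domain: anchor alignment identity %.2f over %d columns is below the %.2f/%d floor",
      al$identity, al$columns, min_identity, min_columns), call. = FALSE)
  }
  res <- rep("-", length(map$positions))
  anchor_pos <- al$anchor_offset
  for (col in seq_along(al$sa)) {
    if (al$sa[col] != "-") {
      anchor_pos <- anchor_pos + 1L
      hit <- match(anchor_pos, map$positions)
      if (!is.na(hit)) res[hit] <- al$qa[col]  # '-' when query gapped
    }
  }
  structure(
    list(residues = paste(res, collapse = ""), source_id = source_id,
         coverage = sum(res != "-")),
    class = "specificity_code"
  )
}

code_string <- function(code) {
  if (inherits(code, "specificity_code")) code$residues else code
}

#' Predict the substrate of a specificity code by nearest-code matching
#'
#' Hamming distance over the code's non-gap positions against a table of
#' characterized codes; all minimal-distance substrates are reported as
#' ties (sorted), never silently broken.
#'
#' @param code a `specificity_code` or 10-character string (`'-'` = gap).
#' @param table data.frame with columns `id`, `substrate`, `code`
#'   (default [specificity_code_table()]), or a list of
#'   `reference_adomain` objects.
#' @return object of class `substrate_call` with `substrate`, `distance`,
#'   `ties`, `paba_type` (Ala in the position-235 slot) and
#'   `variable_pos_mismatch` (all mismatches confined to the position-299
#'   slot).
#' @export
predict_substrate <- function(code, table = specificity_code_table()) {
  if (is.list(table) && !is.data.frame(table)) {
    table <- data.frame(
      id = vapply(table, `[[`, "", "id"),
      substrate = vapply(table, `[[`, "", "substrate"),
      code = vapply(table, `[[`, "", "code"),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(nrow(table) > 0L, all(nchar(table$code) == 10L))
  ch <- strsplit(code_string(code), "")[[1]]
  stopifnot(length(ch) == 10L)
  usable <- which(ch != "-")
  if (length(usable) == 0L) {
    stop("all-gap specificity code is uncallable", call. = FALSE)
  }
  dists <- vapply(seq_len(nrow(table)), function(i) {
    tc <- strsplit(table$code[i], "")[[1]]
    sum(ch[usable] != tc[usable])
  }, 0L)
  dmin <- min(dists)
  ties <- sort(unique(table$substrate[dists == dmin]))
  best_row <- which(dists == dmin & table$substrate == ties[1])[1]
  tc <- strsplit(table$code[best_row], "")[[1]]
  mism <- usable[ch[usable] != tc[usable]]
  structure(
    list(substrate = ties[1], distance = dmin, ties = ties,
         paba_type = ch[1] == "A",
         variable_pos_mismatch = dmin >= 1L &&
           all(mism == VARIABLE_POSITION_SLOT)),
    class = "substrate_call"
  )
}

#' Default A-domain core motifs used for activity calling
#'
#' The A3 and A7 core consensus motifs (the degenerate-primer landing
#' regions) with their anchor-frame start coordinates.
#' @return named list of `list(consensus, anchor_start)`.
#' @export
default_activity_motifs <- function() {
  list(
    A3 = list(consensus = "AYLIYTSG", anchor_start = 200L),
    A7 = list(consensus = "YRTGDV", anchor_start = 508L)
  )
}

#' Call A-domain activity from conserved core motifs
#'
#' An A-domain is called active iff every motif occurs (within
#' `max_mismatch` substitutions) inside its expected anchor-coordinate
#' window (motif span plus/minus 10 columns).
#'
#' @param protein_seq amino-acid string.
#' @param motif_set named list of `list(consensus, anchor_start)`
#'   (default [default_activity_motifs()]).
#' @param map a [code_position_map()].
#' @param max_mismatch substitutions tolerated per motif (default 2).
#' @return object of class `activity_call` with `active` and
#'   `missing_motifs`.
#' @export
call_activity <- function(protein_seq, motif_set = default_activity_motifs(),
                          map = code_position_map(), max_mismatch = 2L) {
  stopifnot(length(motif_set) > 0L)
  al <- align_to_anchor(protein_seq, map$anchor_seq)
  anchor_coord <- integer(length(al$sa))
  pos <- al$anchor_offset
  for (col in seq_along(al$sa)) {
    if (al$sa[col] != "-") pos <- pos + 1L
    anchor_coord[col] <- pos  # coordinate of this or the previous anchor res
  }
  missing <- character(0)
  for (nm in names(motif_set)) {
    m <- motif_set[[nm]]
    len <- nchar(m$consensus)
    win <- anchor_coord >= (m$anchor_start - 10L) &
      anchor_coord <= (m$anchor_start + len - 1L + 10L)
    qres <- al$qa[win]
    qres <- qres[qres != "-"]
    found <- FALSE
    if (length(qres) >= len) {
      qs <- paste(qres, collapse = "")
      for (s in 1:(length(qres) - len + 1L)) {
        if (hamming(substr(qs, s, s + len - 1L), m$consensus) <=
            max_mismatch) {
          found <- TRUE
          break
        }
      }
    }
    if (!found) missing <- c(missing, nm)
  }
  structure(list(active = length(missing) == 0L, missing_motifs = missing),
            class = "activity_call")
}

#' @export
print.specificity_code <- function(x, ...) {
  cat(sprintf("<specificity_code> %s  coverage=%d/10  source=%s\n",
              x$residues, x$coverage, x$source_id))
  invisible(x)
}

#' @export
print.substrate_call <- function(x, ...) {
  cat(sprintf(
    "<substrate_call> %s (distance %d%s)%s%s\n", x$substrate, x$distance,
    if (length(x$ties) > 1L) sprintf(", ties: %s",
                                     paste(x$ties, collapse = "/")) else "",
    if (x$paba_type) " [PABA-type pocket]" else "",
    if (x$variable_pos_mismatch) " [mismatch only at position 299]" else ""))
  invisible(x)
}
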