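# Synthetic reference A-domain panel.
#
# Real characterized A-domain sequences (albicidin/cystobactamid family and
# standard alpha-amino-acid loaders) cannot be bundled, so the package ships a
# seeded synthetic stand-in panel that preserves the structural conventions
# the pipeline relies on: a ~530-aa A-domain scaffold with the conserved A3
# and A7 core motifs (the degenerate primer landing sites), the 10
# substrate-binding-pocket positions (235, 236, 239, 278, 299, 301, 322, 330,
# 331, 517) in a fixed anchor coordinate frame, Asp at position 235 for
# alpha-amino-acid loaders vs Ala for the PABA family, Lys at 517, and the
# PABA-family-only degenerate nucleotide signature inside the A3-A7 amplicon.

#' Degenerate A-domain primers (A3 forward, A7 reverse)
#' @return character scalar IUPAC pattern.
#' @export
ad_fw_primer <- function() "GCSTACSYSATSTACACSTCSGG"

#' @rdname ad_fw_primer
#' @export
ad_rv_primer <- function() "SASGTCVCCSGTSCGGTA"

#' PABA-family degenerate nucleotide signature
#'
#' Three conserved blocks at exact spacings, unique to PABA-specific
#' A-domains; the Ala-235 codon family is covered by the first block.
#' @return character scalar in the `"BLOCK (Nk) BLOCK"` dialect.
#' @export
paba_signature <- function() "ARAARA (N11) TTYGCNRT (N7) AARGAR"

#' Binding-pocket positions of the specificity code (anchor coordinates)
#' @return integer vector of length 10.
#' @export
code_positions <- function() {
  c(235L, 236L, 239L, 278L, 299L, 301L, 322L, 330L, 331L, 517L)
}

# one canonical codon per amino acid (used when planting specific residues)
AA_CODON <- c(
  A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT", Q = "CAA",
  E = "GAA", G = "GGT", H = "CAT", I = "ATT", L = "CTT", K = "AAA",
  M = "ATG", F = "TTT", P = "CCT", S = "TCT", T = "ACT", W = "TGG",
  Y = "TAT", V = "GTT"
)

# concrete, stop-free expansions of the primers used by the synthetic anchor
FW_CONCRETE <- "GCCTACCTCATCTACACCTCCGG"   # + pad "T" -> 8 codons, AYLIYTSG
RV_CONCRETE <- "CACGTCACCCGTCCGGTA"        # rc on the coding strand: YRTGDV

ANCHOR_LEN    <- 530L   # aa
FW_AA         <- 200L:207L   # A3 block (codon-aligned, 24 nt)
SIG_AA        <- 250L:262L   # signature window (39 nt) in PABA-family members
RV_AA         <- 508L:513L   # A7 block (18 nt)
ANCHOR_CODE   <- "DAWTIAAICK"  # synthetic Phe-type anchor pocket

aa_to_nt <- function(aa) c((aa[1] - 1L) * 3L + 1L, aa[length(aa)] * 3L)

#' Amplicon span on the anchor scaffold (nt, primer sites inclusive)
#' @return integer vector `c(start, end)` in anchor nucleotide coordinates.
#' @export
amplicon_span <- function() c(aa_to_nt(FW_AA)[1], aa_to_nt(RV_AA)[2])

set_codon <- function(nt, aa_pos, codon) {
  substr(nt, (aa_pos - 1L) * 3L + 1L, aa_pos * 3L) <- codon
  nt
}

get_codon <- function(nt, aa_pos) {
  substr(nt, (aa_pos - 1L) * 3L + 1L, aa_pos * 3L)
}

set_code_codons <- function(nt, code) {
  pos <- code_positions()
  ch <- strsplit(code, "")[[1]]
  for (i in seq_along(pos)) nt <- set_codon(nt, pos[i], AA_CODON[[ch[i]]])
  nt
}

#' Table of characterized specificity codes (synthetic stand-ins)
#'
#' Ten-residue binding-pocket codes keyed by substrate. Alpha-amino-acid
#' loaders carry Asp in the first slot (position 235); the PABA family
#' carries Ala there; position 517 is the conserved Lys in all of them.
#'
#' @return data.frame with columns `id`, `substrate`, `code`,
#'   `is_paba_family`.
#' @export
specificity_code_table <- function() {
  tab <- data.frame(
    substrate = c("Phe", "Ala", "Ser", "Cys", "Asn", "Gly", "Val", "Leu",
                  "PABA", "AHIBA"),
    code = c("DAWTIAAICK", "DLFNNALTYK", "DVWHFSLVDK", "DHESDVGITK",
             "DLTKLGEVGK", "DILQLGLIWK", "DAFWLGGTFK", "DAWFLGNVVK",
             "AHVSLGVATK", "AHVSLGIATK"),
    stringsAsFactors = FALSE
  )
  tab$id <- paste0("code_", tab$substrate)
  tab$is_paba_family <- tab$substrate %in% c("PABA", "AHIBA")
  tab[, c("id", "substrate", "code", "is_paba_family")]
}

build_scaffold_nt <- function() {
  codons <- sample(non_stop_codons(), ANCHOR_LEN, replace = TRUE)
  nt <- paste(codons, collapse = "")
  substr(nt, aa_to_nt(FW_AA)[1], aa_to_nt(FW_AA)[2]) <- paste0(FW_CONCRETE, "T")
  substr(nt, aa_to_nt(RV_AA)[1], aa_to_nt(RV_AA)[2]) <- revcomp(RV_CONCRETE)
  nt
}

#' The bundled synthetic anchor A-domain
#'
#' Defines the coordinate frame for the binding-pocket positions. The anchor
#' is a fixed 530-aa Phe-type A-domain: it carries the A3/A7 primer sites and
#' the anchor pocket code, but not the PABA signature.
#'
#' @return list with `id`, `protein_seq`, `nt_seq`, `code`.
#' @export
anchor_adomain <- function() {
  nt <- with_seed(19581L, {
    x <- build_scaffold_nt()
    set_code_codons(x, ANCHOR_CODE)
  })
  prot <- translate_nt(nt)
  stopifnot(!grepl("\\*", prot))
  list(id = "anchor_ADom", protein_seq = prot, nt_seq = nt,
       code = ANCHOR_CODE)
}

# replace `frac` of the non-protected codons with random non-stop codons
mutate_codons <- function(nt, frac, protected_aa) {
  eligible <- setdiff(seq_len(ANCHOR_LEN), protected_aa)
  k <- round(frac * length(eligible))
  if (k == 0L) return(nt)
  idx <- sample(eligible, k)
  pool <- non_stop_codons()
  for (i in idx) {
    cur <- get_codon(nt, i)
    nt <- set_codon(nt, i, sample(setdiff(pool, cur), 1L))
  }
  nt
}

# sample a concrete 39-nt (13-codon) expansion of the signature, stop-free
sample_signature_block <- function() {
  pat <- parse_signature(paba_signature())
  repeat {
    sig <- sample_iupac(signature_iupac(pat))
    block <- paste0(sig, sample(c("A", "C", "G", "T"), 1L))
    if (!grepl("\\*", translate_nt(block))) return(block)
  }
}

new_reference_adomain <- function(id, substrate, nt, is_paba) {
  prot <- translate_nt(nt)
  stopifnot(!grepl("\\*", prot))
  code <- specificity_code_table()
  code <- code$code[match(substrate, code$substrate)]
  structure(
    list(id = id, substrate = substrate, protein_seq = prot, nt_seq = nt,
         code = code, is_paba_family = is_paba),
    class = "reference_adomain"
  )
}

#' Generate a seeded synthetic reference A-domain panel
#'
#' PABA-family members derive from a common PABA ancestor (so they form their
#' own clade), carry Ala-235-type pocket codes and an instance of the
#' degenerate signature in the A3-A7 amplicon region. Non-PABA members are
#' more divergent alpha-amino-acid loaders without the signature. All members
#' keep exact A3/A7 primer sites, so every panel entry is amplifiable.
#'
#' @param n_paba number of PABA-family references.
#' @param n_other number of non-PABA references.
#' @param seed integer seed; output is byte-identical for identical calls.
#' @return list of `reference_adomain` objects.
#' @export
generate_reference_panel <- function(n_paba, n_other, seed) {
  if (n_paba < 0 || n_other < 0) {
    stop("reference counts must be non-negative", call. = FALSE)
  }
  anchor <- anchor_adomain()
  protected_core <- c(FW_AA, RV_AA, code_positions())
  with_seed(seed, {
    panel <- list()
    if (n_paba > 0) {
      sig_block <- sample_signature_block()
      paba_base <- mutate_codons(anchor$nt_seq, 0.15,
                                 c(protected_core, SIG_AA))
      substr(paba_base, aa_to_nt(SIG_AA)[1], aa_to_nt(SIG_AA)[2]) <- sig_block
      for (i in seq_len(n_paba)) {
        nt <- mutate_codons(paba_base, 0.10, c(protected_core, SIG_AA))
        nt <- set_code_codons(nt, specificity_code_table()$code[
          specificity_code_table()$substrate == "PABA"])
        stopifnot(signature_filter(nt)$match)
        panel[[length(panel) + 1L]] <- new_reference_adomain(
          sprintf("PABAref_%02d", i), "PABA", nt, TRUE)
      }
    }
    if (n_other > 0) {
      substrates <- rep(c("Ala", "Ser", "Cys", "Asn", "Gly", "Val", "Leu"),
                        length.out = n_other)
      for (i in seq_len(n_other)) {
        repeat {
          nt <- mutate_codons(anchor$nt_seq, 0.25, protected_core)
          nt <- set_code_codons(nt, specificity_code_table()$code[
            specificity_code_table()$substrate == substrates[i]])
          if (!signature_filter(nt)$match) break  # never in practice
        }
        panel[[length(panel) + 1L]] <- new_reference_adomain(
          sprintf("REFref_%02d", i), substrates[i], nt, FALSE)
      }
    }
    panel
  })
}

#' Summarize a reference panel as a data.frame
#' @param panel list of `reference_adomain` objects.
#' @return data.frame with one row per reference.
#' @export
panel_summary <- function(panel) {
  data.frame(
    id = vapply(panel, `[[`, "", "id"),
    substrate = vapply(panel, `[[`, "", "substrate"),
    code = vapply(panel, `[[`, "", "code"),
    is_paba_family = vapply(panel, `[[`, NA, "is_paba_family"),
    nt_len = vapply(panel, function(r) nchar(r$nt_seq), 0L),
    stringsAsFactors = FALSE
  )
}

#' @export
print.reference_adomain <- function(x, ...) {
  cat(sprintf("<reference_adomain> %s  substrate=%s  code=%s  paba=%s\n",
              x$id, x$substrate, x$code, x$is_paba_family))
  invisible(x)
}
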