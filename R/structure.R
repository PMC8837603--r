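# Rule engine: annotated NRPS gene-cluster architecture -> monomer-level
# product prediction (lipo-initiation, trans-complemented A-domains,
# thiazoline/thiazole heterocycles, PABA tailoring, TE termination).

VALID_DOMAINS <- c("Cs", "C", "Cy", "A", "T", "E", "TE", "Ox")
TAILORING_TAGS <- c("fmn_oxidase", "hydroxylase", "o_methyltransferase",
                    "isomethyl", "other")
METHYLATION_TAGS <- c("o_methyltransferase", "isomethyl")

new_module <- function(module_id, domains, substrate = NA_character_,
                       a_domain_active = TRUE) {
  stopifnot(all(domains %in% VALID_DOMAINS))
  list(module_id = module_id, domains = domains, substrate = substrate,
       a_domain_active = a_domain_active, ring_state = "none",
       trans_complemented = FALSE)
}

#' Construct an annotated NRPS architecture
#'
#' @param proteins list of `list(protein_id, modules)`; each module is
#'   `list(module_id, domains, substrate, a_domain_active)` with module
#'   order N->C within a protein.
#' @param tailoring_genes data.frame with columns `gene_id`, `fun`
#'   (one of fmn_oxidase, hydroxylase, o_methyltransferase, isomethyl,
#'   other).
#' @param standalone_adomains list of `list(protein_id, substrate)` for
#'   module-less trans-acting A-domain proteins.
#' @param protein_order optional character vector fixing the assembly-line
#'   order of internal proteins (Cs/TE proteins are always placed
#'   first/last).
#' @return object of class `nrps_architecture`.
#' @export
nrps_architecture <- function(proteins, tailoring_genes = NULL,
                              standalone_adomains = list(),
                              protein_order = NULL) {
  if (is.null(tailoring_genes)) {
    tailoring_genes <- data.frame(gene_id = character(), fun = character(),
                                  stringsAsFactors = FALSE)
  }
  stopifnot(all(tailoring_genes$fun %in% TAILORING_TAGS))
  # normalize modules so raw lists gain ring_state/trans_complemented slots
  proteins <- lapply(proteins, function(p) {
    p$modules <- lapply(p$modules, function(m) {
      mod <- new_module(m$module_id, m$domains,
                        m$substrate %||% NA_character_,
                        m$a_domain_active %||% TRUE)
      mod$ring_state <- m$ring_state %||% mod$ring_state
      mod$trans_complemented <- m$trans_complemented %||%
        mod$trans_complemented
      mod
    })
    p
  })
  has_dom <- function(p, d) any(vapply(p$modules,
                                       function(m) d %in% m$domains, NA))
  cs <- vapply(proteins, has_dom, NA, d = "Cs")
  te <- vapply(proteins, has_dom, NA, d = "TE")
  if (sum(cs) > 1L || sum(te) > 1L) {
    stop("at most one protein may carry a Cs domain and one a TE domain",
         call. = FALSE)
  }
  for (p in proteins) {
    for (k in seq_along(p$modules)) {
      if ("Cs" %in% p$modules[[k]]$domains && k != 1L) {
        stop("Cs domain only allowed in the first module of a protein",
             call. = FALSE)
      }
    }
  }
  structure(
    list(proteins = proteins, tailoring_genes = tailoring_genes,
         standalone_adomains = standalone_adomains,
         protein_order = protein_order, warnings = character(0),
         notes = character(0)),
    class = "nrps_architecture"
  )
}

#' The transcribed lap BGC architecture fixture
#'
#' Five NRPS proteins plus the standalone trans-acting A-domain protein
#' LapB: LapM initiates with a condensation-starter (Cs) domain and carries
#' AD1 (Ala), AD2 (Ser), AD3 (Ala); LapL carries AD4 (PABA); LapK carries
#' AD5/AD6 (Cys, both with heterocyclization Cy domains), the inactive AD7
#' (complemented in trans by LapB's Asn-loading A-domain) and AD8 (PABA);
#' LapH carries AD9 (AHIBA) and AD10 (PABA) and terminates with the TE
#' domain. Tailoring genes: lapI (FMN oxidase, thiazoline -> thiazole) and
#' lapD/lapF/lapG/lapC (PABA hydroxylation/methylation/isomethylation
#' supporting the AHIBA call). How the 10 modules partition over the
#' internal proteins is a fixture choice; all summary counts are
#' partition-invariant.
#'
#' @return object of class `nrps_architecture`.
#' @export
lap_architecture_fixture <- function() {
  proteins <- list(
    list(protein_id = "LapH", modules = list(
      new_module("AD9", c("C", "A", "T"), "AHIBA"),
      new_module("AD10", c("C", "A", "T", "TE"), "PABA")
    )),
    list(protein_id = "LapK", modules = list(
      new_module("AD5", c("Cy", "A", "T"), "Cys"),
      new_module("AD6", c("Cy", "A", "T"), "Cys"),
      new_module("AD7", c("C", "A", "T"), NA_character_,
                 a_domain_active = FALSE),
      new_module("AD8", c("C", "A", "T"), "PABA")
    )),
    list(protein_id = "LapL", modules = list(
      new_module("AD4", c("C", "A", "T"), "PABA")
    )),
    list(protein_id = "LapM", modules = list(
      new_module("AD1", c("Cs", "A", "T"), "Ala"),
      new_module("AD2", c("C", "A", "T"), "Ser"),
      new_module("AD3", c("C", "A", "T"), "Ala")
    ))
  )
  tailoring <- data.frame(
    gene_id = c("lapI", "lapD", "lapF", "lapG", "lapC"),
    fun = c("fmn_oxidase", "hydroxylase", "o_methyltransferase",
            "isomethyl", "other"),
    stringsAsFactors = FALSE
  )
  nrps_architecture(
    proteins, tailoring,
    standalone_adomains = list(list(protein_id = "LapB",
                                    substrate = "Asn")),
    protein_order = c("LapM", "LapL", "LapK", "LapH")
  )
}

#' Order the proteins of an architecture into the assembly line
#'
#' The Cs-bearing protein is placed first and the TE-bearing protein last;
#' internal proteins follow `protein_order` when given, otherwise the input
#' order (a logged heuristic: every internal protein starts with a C-type
#' domain, so domain content alone cannot order them).
#'
#' @param arch an `nrps_architecture`.
#' @return the architecture with `proteins` reordered and an ordering note
#'   appended to `notes`.
#' @export
order_proteins <- function(arch) {
  stopifnot(inherits(arch, "nrps_architecture"))
  mods <- vapply(arch$proteins, function(p) length(p$modules) > 0L, NA)
  ids <- vapply(arch$proteins, `[[`, "", "protein_id")
  has_dom <- function(p, d) any(vapply(p$modules,
                                       function(m) d %in% m$domains, NA))
  cs <- which(mods & vapply(arch$proteins, has_dom, NA, d = "Cs"))
  te <- which(mods & vapply(arch$proteins, has_dom, NA, d = "TE"))
  if (length(cs) != 1L) {
    stop("need exactly one Cs-bearing protein; found: ",
         paste(ids[cs], collapse = ", "), call. = FALSE)
  }
  if (length(te) != 1L) {
    stop("need exactly one TE-bearing protein; found: ",
         paste(ids[te], collapse = ", "), call. = FALSE)
  }
  if (cs == te && sum(mods) > 1L) {
    stop("Cs and TE on the same protein in a multi-protein architecture",
         call. = FALSE)
  }
  internal <- setdiff(which(mods), c(cs, te))
  if (!is.null(arch$protein_order)) {
    pos <- match(ids[internal], arch$protein_order)
    internal <- internal[order(pos, internal)]
    note <- "internal protein order from explicit configuration"
  } else {
    note <- "internal protein order from input order (heuristic fallback)"
  }
  idx <- c(cs, internal, if (te != cs) te)
  arch$proteins <- c(arch$proteins[idx], arch$proteins[!mods])
  arch$notes <- c(arch$notes, note)
  arch$ordered <- TRUE
  arch
}

#' Complement inactive modules with trans-acting standalone A-domains
#'
#' Each module with an inactive A-domain and no substrate receives the
#' substrate of the next unclaimed standalone A-domain (one-to-one, in
#' list order); leftover inactive modules are flagged in `warnings`, unused
#' standalone A-domains in `notes`.
#'
#' @param arch an `nrps_architecture`.
#' @return the updated architecture.
#' @export
complement_trans <- function(arch) {
  stopifnot(inherits(arch, "nrps_architecture"))
  pool <- arch$standalone_adomains
  claimed <- 0L
  for (p in seq_along(arch$proteins)) {
    for (m in seq_along(arch$proteins[[p]]$modules)) {
      mod <- arch$proteins[[p]]$modules[[m]]
      if (!mod$a_domain_active &&
          (is.na(mod$substrate) || mod$substrate == "unknown")) {
        if (claimed < length(pool)) {
          claimed <- claimed + 1L
          mod$substrate <- pool[[claimed]]$substrate
          mod$trans_complemented <- TRUE
          arch$notes <- c(arch$notes, sprintf(
            "module %s complemented in trans by %s (%s)", mod$module_id,
            pool[[claimed]]$protein_id, mod$substrate))
        } else {
          arch$warnings <- c(arch$warnings, sprintf(
            "module %s has an inactive A-domain and no trans complement",
            mod$module_id))
        }
        arch$proteins[[p]]$modules[[m]] <- mod
      }
    }
  }
  if (claimed < length(pool)) {
    arch$notes <- c(arch$notes, sprintf(
      "%d standalone A-domain(s) unused", length(pool) - claimed))
  }
  arch
}

#' Apply heterocyclization rules
#'
#' Cys-loading modules whose condensation slot is a Cy domain form
#' thiazolines; if any tailoring gene is tagged `fmn_oxidase`, all
#' thiazolines are oxidized to thiazoles. Cy domains on non-Cys modules are
#' flagged as anomalies.
#'
#' @param arch an `nrps_architecture` (ordered).
#' @param tailoring_genes tailoring table (default: the architecture's own).
#' @return the updated architecture.
#' @export
apply_heterocycle_rules <- function(arch,
                                    tailoring_genes = arch$tailoring_genes) {
  stopifnot(inherits(arch, "nrps_architecture"))
  oxidase <- any(tailoring_genes$fun == "fmn_oxidase")
  for (p in seq_along(arch$proteins)) {
    for (m in seq_along(arch$proteins[[p]]$modules)) {
      mod <- arch$proteins[[p]]$modules[[m]]
      if ("Cy" %in% mod$domains) {
        if (identical(mod$substrate, "Cys")) {
          mod$ring_state <- if (oxidase) "thiazole" else "thiazoline"
        } else {
          arch$warnings <- c(arch$warnings, sprintf(
            "module %s has a Cy domain but loads %s, not Cys",
            mod$module_id, mod$substrate))
        }
      }
      arch$proteins[[p]]$modules[[m]] <- mod
    }
  }
  arch
}

#' Apply PABA tailoring rules
#'
#' A module annotated with the tailored PABA substrate AHIBA keeps it only
#' when both a hydroxylase and a methylation-class tailoring gene are
#' present; otherwise the substrate is downgraded to plain PABA with a
#' warning.
#'
#' @param arch an `nrps_architecture` (ordered).
#' @param tailoring_genes tailoring table (default: the architecture's own).
#' @return the updated architecture.
#' @export
apply_paba_tailoring <- function(arch,
                                 tailoring_genes = arch$tailoring_genes) {
  stopifnot(inherits(arch, "nrps_architecture"))
  ok <- any(tailoring_genes$fun == "hydroxylase") &&
    any(tailoring_genes$fun %in% METHYLATION_TAGS)
  n_mod <- 0L
  for (p in seq_along(arch$proteins)) {
    for (m in seq_along(arch$proteins[[p]]$modules)) {
      mod <- arch$proteins[[p]]$modules[[m]]
      if (identical(mod$substrate, "AHIBA")) {
        if (ok) {
          n_mod <- n_mod + 1L
        } else {
          mod$substrate <- "PABA"
          arch$warnings <- c(arch$warnings, sprintf(
            "module %s: AHIBA annotation without hydroxylase+methylation tailoring support; downgraded to PABA",
            mod$module_id))
        }
      }
      arch$proteins[[p]]$modules[[m]] <- mod
    }
  }
  arch$notes <- c(arch$notes, sprintf("modified aryl monomers: %d", n_mod))
  arch
}

monomer_class <- function(base, ring_state) {
  if (ring_state != "none") "heterocycle"
  else if (base %in% c("PABA", "AHIBA")) "paba_family"
  else "proteinogenic"
}

#' Predict the monomer-level product of an NRPS architecture
#'
#' Composes [order_proteins()], [complement_trans()],
#' [apply_heterocycle_rules()] and [apply_paba_tailoring()], emits the
#' monomers in assembly-line order, attaches the beta-hydroxy lipid iff a
#' Cs starter domain is present, and terminates at the TE domain.
#'
#' @param arch an `nrps_architecture`.
#' @param lipid_chain lipid chain length in carbons, within 10-14
#'   (default 14, mirroring the most common beta-hydroxy lipid choice).
#' @return object of class `predicted_structure`: `monomers` (data.frame
#'   `module_id`, `base`, `ring_state`, `class`, `d_config`), `n_residues`,
#'   `counts` (named vector over monomer classes), `lipid`,
#'   `monomer_string`, `warnings`, `notes`.
#' @export
predict_structure <- function(arch, lipid_chain = 14L) {
  arch <- order_proteins(arch)
  arch <- complement_trans(arch)
  arch <- apply_heterocycle_rules(arch)
  arch <- apply_paba_tailoring(arch)
  has_cs <- any(vapply(arch$proteins, function(p) {
    any(vapply(p$modules, function(m) "Cs" %in% m$domains, NA))
  }, NA))
  rows <- list()
  for (p in arch$proteins) {
    for (mod in p$modules) {
      if (is.na(mod$substrate) || mod$substrate == "unknown") {
        arch$warnings <- c(arch$warnings, sprintf(
          "module %s contributes no residue (unresolved substrate)",
          mod$module_id))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        module_id = mod$module_id, base = mod$substrate,
        ring_state = mod$ring_state,
        class = monomer_class(mod$substrate, mod$ring_state),
        d_config = "E" %in% mod$domains, stringsAsFactors = FALSE)
    }
  }
  monomers <- if (length(rows)) do.call(rbind, rows) else
    data.frame(module_id = character(), base = character(),
               ring_state = character(), class = character(),
               d_config = logical(), stringsAsFactors = FALSE)
  lipid <- NULL
  if (has_cs) {
    if (lipid_chain < 10L || lipid_chain > 14L) {
      stop("lipid_chain must lie in the characterized 10-14 carbon range",
           call. = FALSE)
    }
    lipid <- list(kind = "beta-hydroxy fatty acid",
                  chain_range = c(10L, 14L),
                  chosen_chain = as.integer(lipid_chain),
                  stereo = "racemic")
  }
  counts <- c(proteinogenic = sum(monomers$class == "proteinogenic"),
              paba_family = sum(monomers$class == "paba_family"),
              heterocycle = sum(monomers$class == "heterocycle"))
  tokens <- ifelse(monomers$ring_state == "none", monomers$base,
                   sprintf("%s(%s)", monomers$base, monomers$ring_state))
  if (!is.null(lipid)) {
    tokens <- c(sprintf("C%d:b-OH", lipid$chosen_chain), tokens)
  }
  structure(
    list(monomers = monomers, n_residues = nrow(monomers), counts = counts,
         lipid = lipid, monomer_string = paste(tokens, collapse = "--"),
         warnings = arch$warnings, notes = arch$notes),
    class = "predicted_structure"
  )
}

#' @export
print.predicted_structure <- function(x, ...) {
  cat(sprintf("<predicted_structure> %d residues%s\n", x$n_residues,
              if (!is.null(x$lipid)) ", N-acylated" else ""))
  cat("  ", x$monomer_string, "\n", sep = "")
  cat(sprintf("  counts: %s\n",
              paste(sprintf("%s=%d", names(x$counts), x$counts),
                    collapse = ", ")))
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' Serialize a predicted structure as a JSON report
#' @param ps a `predicted_structure`.
#' @param file optional output path.
#' @return JSON text (invisibly when written to file).
#' @export
structure_report_json <- function(ps, file = NULL) {
  stopifnot(inherits(ps, "predicted_structure"))
  obj <- list(
    n_residues = ps$n_residues,
    monomers = ps$monomers,
    counts = as.list(ps$counts),
    lipid = ps$lipid,
    monomer_string = ps$monomer_string,
    warnings = ps$warnings,
    notes = ps$notes
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                          null = "null")
  if (is.null(file)) return(as.character(txt))
  writeLines(txt, file)
  invisible(as.character(txt))
}

#' Write an architecture as annotation-table JSON
#' @param arch an `nrps_architecture`.
#' @param file output path (or `NULL` for text).
#' @return JSON text (invisibly when written to file).
#' @export
write_architecture_json <- function(arch, file = NULL) {
  stopifnot(inherits(arch, "nrps_architecture"))
  obj <- list(
    proteins = lapply(arch$proteins, function(p) {
      list(protein_id = p$protein_id, modules = lapply(p$modules, function(m) {
        list(module_id = m$module_id, domains = as.list(m$domains),
             substrate = if (is.na(m$substrate)) NULL else m$substrate,
             a_domain_active = m$a_domain_active)
      }))
    }),
    tailoring_genes = arch$tailoring_genes,
    standalone_adomains = arch$standalone_adomains,
    protein_order = arch$protein_order
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE,
                          null = "null")
  if (is.null(file)) return(as.character(txt))
  writeLines(txt, file)
  invisible(as.character(txt))
}

#' Read an architecture from annotation-table JSON
#' @param file path or JSON text.
#' @return an `nrps_architecture`.
#' @export
read_architecture_json <- function(file) {
  obj <- jsonlite::fromJSON(file, simplifyVector = FALSE)
  proteins <- lapply(obj$proteins, function(p) {
    list(protein_id = p$protein_id, modules = lapply(p$modules, function(m) {
      new_module(m$module_id, unlist(m$domains),
                 m$substrate %||% NA_character_,
                 isTRUE(m$a_domain_active %||% TRUE))
    }))
  })
  tg <- obj$tailoring_genes
  tailoring <- if (length(tg)) {
    data.frame(gene_id = vapply(tg, `[[`, "", "gene_id"),
               fun = vapply(tg, `[[`, "", "fun"), stringsAsFactors = FALSE)
  } else NULL
  nrps_architecture(
    proteins, tailoring,
    standalone_adomains = lapply(obj$standalone_adomains, function(s) {
      list(protein_id = s$protein_id, substrate = s$substrate)
    }),
    protein_order = if (length(obj$protein_order))
      unlist(obj$protein_order) else NULL
  )
}
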