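test_that("order_proteins places Cs first, TE last, honors config order", {
  arch <- lap_architecture_fixture()
  ordered <- order_proteins(arch)
  ids <- vapply(ordered$proteins, `[[`, "", "protein_id")
  expect_identical(ids[1:4], c("LapM", "LapL", "LapK", "LapH"))
  # single-protein architecture: identity ordering
  solo <- nrps_architecture(list(list(protein_id = "P1", modules = list(
    list(module_id = "M1", domains = c("Cs", "A", "T", "TE"),
         substrate = "Gly", a_domain_active = TRUE)))))
  expect_identical(
    vapply(order_proteins(solo)$proteins, `[[`, "", "protein_id"), "P1")
  # zero Cs proteins -> architecture error
  no_cs <- nrps_architecture(list(
    list(protein_id = "P1", modules = list(
      list(module_id = "M1", domains = c("C", "A", "T"),
           substrate = "Ala", a_domain_active = TRUE))),
    list(protein_id = "P2", modules = list(
      list(module_id = "M2", domains = c("C", "A", "T", "TE"),
           substrate = "Gly", a_domain_active = TRUE)))))
  expect_error(order_proteins(no_cs), "exactly one Cs-bearing")
})

test_that("internal protein order permutes monomers but not counts", {
  mk <- function(order) {
    arch <- lap_architecture_fixture()
    arch$protein_order <- order
    predict_structure(arch)
  }
  a <- mk(c("LapM", "LapL", "LapK", "LapH"))
  b <- mk(c("LapM", "LapK", "LapL", "LapH"))
  expect_false(identical(a$monomers$module_id, b$monomers$module_id))
  expect_identical(sort(a$monomers$base), sort(b$monomers$base))
  expect_identical(a$counts, b$counts)
  expect_identical(a$n_residues, b$n_residues)
})

test_that("complement_trans resolves inactive modules one-to-one", {
  arch <- complement_trans(lap_architecture_fixture())
  mods <- unlist(lapply(arch$proteins, `[[`, "modules"), recursive = FALSE)
  ad7 <- mods[[which(vapply(mods, `[[`, "", "module_id") == "AD7")]]
  expect_identical(ad7$substrate, "Asn")
  expect_true(ad7$trans_complemented)
  # no inactive modules: standalone reported unused, architecture unchanged
  arch2 <- lap_architecture_fixture()
  for (p in seq_along(arch2$proteins)) {
    for (m in seq_along(arch2$proteins[[p]]$modules)) {
      arch2$proteins[[p]]$modules[[m]]$a_domain_active <- TRUE
      if (is.na(arch2$proteins[[p]]$modules[[m]]$substrate)) {
        arch2$proteins[[p]]$modules[[m]]$substrate <- "Gly"
      }
    }
  }
  out2 <- complement_trans(arch2)
  expect_true(any(grepl("unused", out2$notes)))
  expect_length(out2$warnings, 0L)
  # two inactive modules, one standalone: one resolved, one flagged
  arch3 <- lap_architecture_fixture()
  arch3$proteins[[1]]$modules[[1]]$a_domain_active <- FALSE
  arch3$proteins[[1]]$modules[[1]]$substrate <- NA_character_
  out3 <- complement_trans(arch3)
  mods3 <- unlist(lapply(out3$proteins, `[[`, "modules"), recursive = FALSE)
  resolved <- sum(vapply(mods3, `[[`, NA, "trans_complemented"))
  expect_identical(resolved, 1L)
  expect_length(out3$warnings, 1L)
  expect_match(out3$warnings, "no trans complement")
})

test_that("heterocycle rules: Cy + Cys -> thiazoline, oxidase -> thiazole", {
  arch <- apply_heterocycle_rules(lap_architecture_fixture())
  mods <- unlist(lapply(arch$proteins, `[[`, "modules"), recursive = FALSE)
  rings <- vapply(mods, `[[`, "", "ring_state")
  names(rings) <- vapply(mods, `[[`, "", "module_id")
  expect_identical(unname(rings[c("AD5", "AD6")]),
                   c("thiazole", "thiazole"))
  expect_true(all(rings[!names(rings) %in% c("AD5", "AD6")] == "none"))
  # without the FMN oxidase the rings stay thiazolines
  arch2 <- lap_architecture_fixture()
  arch2$tailoring_genes <- arch2$tailoring_genes[
    arch2$tailoring_genes$fun != "fmn_oxidase", ]
  mods2 <- unlist(lapply(apply_heterocycle_rules(arch2)$proteins,
                         `[[`, "modules"), recursive = FALSE)
  rings2 <- vapply(mods2, `[[`, "", "ring_state")
  expect_identical(sum(rings2 == "thiazoline"), 2L)
  expect_identical(sum(rings2 == "thiazole"), 0L)
  # a Cy domain on a non-Cys module is an anomaly, not a ring
  arch3 <- lap_architecture_fixture()
  arch3$proteins[[3]]$modules[[1]]$domains <- c("Cy", "A", "T")  # AD4, PABA
  out3 <- apply_heterocycle_rules(arch3)
  expect_match(out3$warnings, "not Cys")
})

test_that("PABA tailoring: AHIBA needs hydroxylase + methylation support", {
  arch <- apply_paba_tailoring(lap_architecture_fixture())
  mods <- unlist(lapply(arch$proteins, `[[`, "modules"), recursive = FALSE)
  expect_identical(sum(vapply(mods, `[[`, "", "substrate") == "AHIBA",
                       na.rm = TRUE), 1L)
  expect_length(arch$warnings, 0L)
  # without tailoring genes AHIBA is downgraded with a warning
  arch2 <- lap_architecture_fixture()
  arch2$tailoring_genes <- arch2$tailoring_genes[0, ]
  out2 <- apply_paba_tailoring(arch2)
  mods2 <- unlist(lapply(out2$proteins, `[[`, "modules"), recursive = FALSE)
  expect_false(any(vapply(mods2, `[[`, "", "substrate") == "AHIBA",
                   na.rm = TRUE))
  expect_match(out2$warnings, "downgraded to PABA")
})

test_that("predict_structure reproduces the lap worked example", {
  ps <- predict_structure(lap_architecture_fixture())
  expect_identical(ps$n_residues, 10L)
  expect_false(is.null(ps$lipid))
  expect_identical(ps$lipid$kind, "beta-hydroxy fatty acid")
  expect_identical(ps$lipid$chosen_chain, 14L)
  expect_identical(unname(ps$counts["paba_family"]), 4L)
  expect_identical(unname(ps$counts["heterocycle"]), 2L)
  expect_identical(unname(ps$counts["proteinogenic"]), 4L)
  expect_identical(sum(ps$counts), ps$n_residues)
  expect_identical(
    ps$monomers$base,
    c("Ala", "Ser", "Ala", "PABA", "Cys", "Cys", "Asn", "PABA", "AHIBA",
      "PABA"))
  expect_identical(ps$monomers$module_id, paste0("AD", 1:10))
  # idempotence: byte-identical JSON on a second run
  expect_identical(structure_report_json(ps),
                   structure_report_json(
                     predict_structure(lap_architecture_fixture())))
})

test_that("rule ablations change exactly the targeted attribute", {
  base <- predict_structure(lap_architecture_fixture())
  # oxidase removal flips ring states only
  arch <- lap_architecture_fixture()
  arch$tailoring_genes <- arch$tailoring_genes[
    arch$tailoring_genes$fun != "fmn_oxidase", ]
  no_ox <- predict_structure(arch)
  expect_identical(no_ox$monomers$base, base$monomers$base)
  expect_identical(no_ox$counts, base$counts)
  expect_identical(unique(no_ox$monomers$ring_state[
    no_ox$monomers$base == "Cys"]), "thiazoline")
  # Cs removal removes the lipid only
  arch2 <- lap_architecture_fixture()
  lapm <- which(vapply(arch2$proteins, `[[`, "", "protein_id") == "LapM")
  arch2$proteins[[lapm]]$modules[[1]]$domains <- c("A", "T")
  expect_error(predict_structure(arch2), "exactly one Cs-bearing")
  arch2$proteins[[lapm]]$modules[[1]]$domains <- c("Cs", "A", "T")
  with_cs <- predict_structure(arch2)
  expect_false(is.null(with_cs$lipid))
  # minimal single-module lipopeptide
  solo <- nrps_architecture(list(list(protein_id = "P1", modules = list(
    list(module_id = "M1", domains = c("Cs", "A", "T", "TE"),
         substrate = "Gly", a_domain_active = TRUE)))))
  ps1 <- predict_structure(solo)
  expect_identical(ps1$n_residues, 1L)
  expect_false(is.null(ps1$lipid))
  expect_identical(ps1$monomers$base, "Gly")
  # lipid chain outside the characterized range is rejected
  expect_error(predict_structure(solo, lipid_chain = 16), "10-14")
})

test_that("residue conservation and count partition hold under unresolved modules", {
  arch <- lap_architecture_fixture()
  arch$standalone_adomains <- list()  # AD7 stays unresolved
  ps <- predict_structure(arch)
  expect_identical(ps$n_residues, 9L)
  expect_identical(sum(ps$counts), 9L)
  expect_match(ps$warnings, "AD7", all = FALSE)
  expect_false("AD7" %in% ps$monomers$module_id)
})

test_that("architecture JSON round-trips through the annotation schema", {
  arch <- lap_architecture_fixture()
  tmp <- tempfile(fileext = ".json")
  write_architecture_json(arch, tmp)
  back <- read_architecture_json(tmp)
  expect_identical(predict_structure(back)$monomer_string,
                   predict_structure(arch)$monomer_string)
  expect_identical(structure_report_json(predict_structure(back)),
                   structure_report_json(predict_structure(arch)))
})
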