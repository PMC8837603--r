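test_that("match_degenerate finds primer expansions and N-patterns", {
  fw <- ad_fw_primer()
  concrete <- "GCCTACCTCATCTACACCTCCGG"  # one expansion of AD-FW
  hits <- match_degenerate(concrete, fw, 0)
  expect_identical(hits$offset[hits$strand == "+"], 0L)
  expect_identical(hits$mismatches[hits$strand == "+"], 0L)
  seq <- random_dna_chr(50)
  hits_n <- match_degenerate(seq, strrep("N", 8), 0)
  expect_identical(sum(hits_n$strand == "+"), 43L)
  expect_identical(sum(hits_n$strand == "-"), 43L)
  expect_error(match_degenerate("ACGT", "AXGT", 0), "IUPAC")
})

test_that("match_degenerate equals the brute-force expansion oracle", {
  set.seed(401)
  for (rep in 1:8) {
    seq <- random_dna_chr(200)
    # random IUPAC pattern, <= 10 nt, a few degenerate positions
    len <- sample(6:10, 1)
    pat <- strsplit(random_dna_chr(len), "")[[1]]
    ndeg <- sample(1:3, 1)
    pat[sample(len, ndeg)] <- sample(c("R", "Y", "S", "W", "N", "V"), ndeg,
                                     replace = TRUE)
    pat <- paste(pat, collapse = "")
    for (mm in 0:1) {
      got <- match_degenerate(seq, pat, mm)
      want <- brute_match_degenerate(seq, pat, mm)
      rownames(got) <- rownames(want) <- NULL
      expect_identical(got, want, label = sprintf("pattern %s mm %d", pat, mm))
    }
  }
})

test_that("insilico_pcr recovers planted site pairs on both orientations", {
  set.seed(402)
  fwx <- "GCCTACCTCATCTACACCTCCGG"      # AD-FW expansion
  rvx_rc <- oracle_revcomp("CACGTCACCCGTCCGGTA")  # rc of an AD-RV expansion
  template <- paste0(fwx, random_dna_chr(300), rvx_rc)
  contig <- paste0(random_dna_chr(150), template, random_dna_chr(120))
  prods <- insilico_pcr(contig, max_mismatch = 0)
  expect_identical(prods, template)
  # reverse-complemented contig yields the same canonical product
  prods_rc <- insilico_pcr(oracle_revcomp(contig), max_mismatch = 0)
  expect_identical(prods_rc, template)
})

test_that("insilico_pcr product count equals site-pair enumeration", {
  set.seed(403)
  fwx <- "GCCTACCTCATCTACACCTCCGG"
  rvx_rc <- oracle_revcomp("CACGTCACCCGTCCGGTA")
  # two forward sites upstream of one reverse site: both pairings in window
  contig <- paste0(random_dna_chr(50), fwx, random_dna_chr(100), fwx,
                   random_dna_chr(100), rvx_rc, random_dna_chr(50))
  prods <- insilico_pcr(contig, max_mismatch = 0, min_len = 100,
                        max_len = 5000)
  expect_length(prods, 2L)
  expect_true(all(startsWith(prods, fwx)))
  expect_true(all(endsWith(prods, rvx_rc)))
  # length window excludes the long product
  short <- insilico_pcr(contig, max_mismatch = 0, min_len = 100,
                        max_len = 200)
  expect_length(short, 1L)
  expect_error(insilico_pcr(contig, min_len = 10, max_len = 10), "min_len")
})

test_that("debarcode_and_trim assigns, trims and conserves reads", {
  fwx <- "GCCTACCTCATCTACACCTCCGG"
  rvx_rc <- oracle_revcomp("CACGTCACCCGTCCGGTA")
  set.seed(404)
  inner <- random_dna_chr(200)
  template <- paste0(fwx, inner, rvx_rc)
  reads <- c(r1 = paste0("AAAAAAAA", template),
             r2 = paste0("CCCCCCCC", template),
             r3 = paste0("GGGGTTTT", template))  # unknown barcode
  bcs <- c(pool01 = "AAAAAAAA", pool02 = "CCCCCCCC")
  dm <- debarcode_and_trim(reads, bcs)
  expect_identical(nrow(dm$assigned) + nrow(dm$unassigned), 3L)
  expect_identical(dm$unassigned$read_id, "r3")
  expect_identical(dm$assigned$seq, rep(inner, 2))
  expect_true(all(dm$assigned$trimmed))
  expect_identical(dm$assigned$pool_id, c("pool01", "pool02"))
  expect_error(debarcode_and_trim(reads, c(a = "AAAA", b = "AAAA")),
               "duplicate")
  expect_error(debarcode_and_trim(reads, c(a = "AAAA", b = "AAAAC")),
               "prefix")
})

test_that("demultiplexed per-pool counts match the fixture truth table", {
  fx <- small_fixture()
  sim <- simulate_reads(fx, 0.01, seed = 31, reads_per_amplicon = 4)
  dm <- debarcode_and_trim(sim, fx)
  expect_identical(nrow(dm$unassigned), 0L)
  got <- table(dm$assigned$pool_id)
  want <- table(sim$truth$pool_id)
  expect_identical(as.vector(got[names(want)]), as.vector(want))
  # assignment agrees with truth read-by-read
  m <- match(dm$assigned$read_id, sim$truth$read_id)
  expect_identical(dm$assigned$pool_id, sim$truth$pool_id[m])
})

test_that("cluster_npst: identity thresholding and membership soundness", {
  reads5 <- data.frame(read_id = paste0("r", 1:5), pool_id = "p1",
                       seq = strrep("ACGT", 30), stringsAsFactors = FALSE)
  np <- cluster_npst(reads5)
  expect_length(np, 1L)
  expect_length(np[[1]]$members, 5L)
  # constructed pair at ~90% identity splits at 0.95, merges at 0.85
  set.seed(405)
  a <- random_dna_chr(200)
  b <- strsplit(a, "")[[1]]
  pos <- sample(200, 20)
  for (i in pos) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1)
  b <- paste(b, collapse = "")
  expect_lt(alignment_identity(a, b), 0.95)
  expect_gt(alignment_identity(a, b), 0.85)
  pair <- data.frame(read_id = c("x", "y"), pool_id = c("p1", "p2"),
                     seq = c(a, b), stringsAsFactors = FALSE)
  expect_length(cluster_npst(pair, cluster_config(0.95)), 2L)
  merged <- cluster_npst(pair, cluster_config(0.85))
  expect_length(merged, 1L)
  expect_identical(merged[[1]]$pools, c("p1", "p2"))
  expect_error(cluster_npst(pair[0, ]), "no reads")
  # default threshold is the published 95%
  expect_identical(cluster_config()$identity_threshold, 0.95)
})

test_that("NPST invariants on fixture reads: soundness, conservation, monotonicity", {
  fx <- small_fixture()
  sim <- simulate_reads(fx, 0.02, seed = 32, reads_per_amplicon = 3)
  dm <- debarcode_and_trim(sim, fx)
  counts <- integer(0)
  for (thr in c(0.97, 0.95, 0.90, 0.80)) {
    np <- cluster_npst(dm$assigned, cluster_config(thr))
    # membership soundness, re-checked post hoc
    for (x in np) {
      for (rid in x$members) {
        s <- dm$assigned$seq[dm$assigned$read_id == rid]
        expect_gte(alignment_identity(s, x$centroid), thr)
      }
      expect_true(x$centroid %in% dm$assigned$seq[
        dm$assigned$read_id %in% x$members])
    }
    expect_identical(sum(vapply(np, function(x) length(x$members), 0L)),
                     nrow(dm$assigned))
    counts <- c(counts, length(np))
  }
  # lowering the threshold never increases the NPST count
  expect_true(all(diff(counts) <= 0))
})
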