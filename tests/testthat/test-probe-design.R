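test_that("candidate enumeration yields L - k + 1 thirty-mers per gene", {
  seqs <- c(TRBV901 = strrep("ACGT", 25),                   # L = 100
            TRBV902 = substr(strrep("ACGT", 8), 1, 29),     # L = 29
            TRBV903 = strrep("AC", 15))                     # L = 30
  cand <- enumerateCandidates(seqs)
  expect_equal(sum(cand$gene == "TRBV901"), 71L)
  expect_equal(sum(cand$gene == "TRBV902"), 0L)
  expect_equal(sum(cand$gene == "TRBV903"), 1L)
  one <- cand[cand$gene == "TRBV903", ]
  expect_equal(one$offset, 0L)
  expect_equal(one$seq30, strrep("AC", 15))
  expect_equal(one$gc_fraction, 0.5)
  expect_equal(one$max_homopolymer, 1L)
  expect_equal(one$pos16_base, "C")
  # slices match the source sequence
  first <- cand[cand$gene == "TRBV901", ][1, ]
  expect_equal(first$seq30, substr(seqs[["TRBV901"]], 1, 30))
})

test_that("ambiguity codes in gene sequences are a hard error", {
  expect_error(enumerateCandidates(c(TRBV901 = paste0(strrep("ACGT", 10),
                                                      "N"))),
               "TRBV901.*41|41.*TRBV901")
})

test_that("composition filter encodes the padlock criteria", {
  base <- strrep("AC", 15)
  poly <- paste0("AAAA", substr(strrep("GC", 13), 1, 26))
  cand <- enumerateCandidates(c(TRBV901 = base, TRBV902 = poly,
                                TRBV903 = "ACGTACGTACGTACGTACGTACGTACGTAC"))
  cand <- compositionFilter(cand)
  expect_true(cand$comp_pass[cand$gene == "TRBV901"])
  expect_true("homopolymer" %in%
                cand$comp_reasons[[which(cand$gene == "TRBV902")]])
  # pos16 of the literal ACGT repeat is T: fails the G/C junction rule only
  r3 <- cand[cand$gene == "TRBV903", ]
  expect_false(r3$comp_pass)
  expect_equal(r3$comp_reasons[[1]], "pos16")
  expect_equal(r3$gc_fraction, 0.5)
})

test_that("composition filter agrees with a regex oracle on random 30-mers", {
  withr::with_seed(42, {
    mers <- vapply(seq_len(10000), function(i)
      paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE,
                   prob = c(0.3, 0.2, 0.2, 0.3)), collapse = ""),
      character(1))
  })
  cand <- enumerateCandidates(stats::setNames(mers, sprintf("TRBV9%04d",
                                                            seq_along(mers))))
  cand <- compositionFilter(cand)
  expect_equal(cand$comp_pass,
               unname(oracleComposition(cand$seq30)))
})

test_that("identical genes are mutually cross-reactive; singletons are not", {
  s <- substr(strrep("ACGGT", 20), 1, 60)
  cand <- uniquenessScreen(enumerateCandidates(c(TRBV901 = s, TRBV902 = s)))
  expect_true(all(lengths(cand$cross_reactive_with) == 1L))
  expect_equal(unique(unlist(cand$cross_reactive_with[cand$gene == "TRBV901"])),
               "TRBV902")
  solo <- uniquenessScreen(enumerateCandidates(c(TRBV901 = s)))
  expect_true(all(lengths(solo$cross_reactive_with) == 0L))
})

test_that("cross-reactivity screen equals the exhaustive alignment oracle", {
  fam <- generateGeneFamily(5, length = 60, mutation_rate = 0.04, seed = 5)
  cand <- uniquenessScreen(enumerateCandidates(fam))
  oracle <- oracleCrossReactive(cand$seq30, cand$gene)
  got <- lapply(cand$cross_reactive_with, sort)
  expect_equal(got, lapply(oracle, sort))
  # symmetry at the gene level
  for (i in seq_len(nrow(cand))) {
    for (g in cand$cross_reactive_with[[i]]) {
      expect_true(cand$gene[i] %in%
                    unlist(cand$cross_reactive_with[cand$gene == g]))
    }
  }
})

test_that("divergent family shows no cross-reactivity at 0.80 identity", {
  fam <- generateGeneFamily(5, length = 80, mutation_rate = 0.5, seed = 9)
  cand <- uniquenessScreen(enumerateCandidates(fam))
  oracle <- oracleCrossReactive(cand$seq30, cand$gene)
  expect_equal(lapply(cand$cross_reactive_with, sort), lapply(oracle, sort))
  expect_true(all(lengths(cand$cross_reactive_with) == 0L))
})

test_that("transcriptome screen finds verbatim and reverse-complement hits", {
  s <- substr(strrep("ACGGT", 20), 1, 30)
  cand <- enumerateCandidates(c(TRBV901 = s))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  tx_fwd <- c(TX1 = paste0("AAAA", s, "GGGG"))
  tx_rc <- c(TX1 = paste0("AAAA", rc, "GGGG"))
  expect_gte(transcriptomeScreen(cand, tx_fwd)$offtarget_hits, 1L)
  expect_gte(transcriptomeScreen(cand, tx_rc)$offtarget_hits, 1L)
  expect_equal(transcriptomeScreen(cand, character(0))$offtarget_hits, 0L)
  # TCR records are excluded by id prefix
  expect_equal(transcriptomeScreen(cand, c(TRBV19 = tx_fwd[[1]]))$offtarget_hits,
               0L)
})

test_that("transcriptome screen is reverse-complement invariant", {
  fam <- generateGeneFamily(3, length = 50, mutation_rate = 0.2, seed = 2)
  cand <- enumerateCandidates(fam)
  withr::with_seed(3, {
    tx <- vapply(1:5, function(i)
      paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = ""),
      character(1))
  })
  tx[2] <- paste0(substr(tx[2], 1, 40), as.character(fam[[1]]))  # plant a hit
  names(tx) <- paste0("TX", 1:5)
  rc_tx <- stats::setNames(as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(tx))), names(tx))
  h1 <- transcriptomeScreen(cand, tx)$offtarget_hits
  h2 <- transcriptomeScreen(cand, rc_tx)$offtarget_hits
  expect_equal(h1, h2)
  expect_true(any(h1 > 0))
  # ambiguity-coded records are skipped with a count
  tx_amb <- c(tx, TX9 = paste0(strrep("ACGT", 10), "N"))
  out <- transcriptomeScreen(cand, tx_amb)
  expect_equal(attr(out, "n_ambiguous_skipped"), 1L)
})

test_that("design pipeline groups indistinguishable genes and reports chain", {
  fam <- generateGeneFamily(3, length = 80, mutation_rate = 0.35, seed = 4)
  seqs <- stats::setNames(as.character(fam), names(fam))
  seqs[3] <- seqs[2]  # B and C identical, A distinct
  rep <- designPanel(seqs)
  expect_s4_class(rep, "DesignReport")
  grp <- rep@groups
  bc <- grp$group_name[grp$member_gene == names(seqs)[2]]
  expect_equal(sort(grp$member_gene[grp$group_name == bc]),
               sort(names(seqs)[2:3]))
  expect_equal(grp$group_name[grp$member_gene == names(seqs)[1]],
               names(seqs)[1])
  # filter-chain monotonicity
  pg <- rep@perGene
  expect_true(all(pg$n_candidates >= pg$n_after_uniqueness))
  expect_true(all(pg$n_after_uniqueness >= pg$n_after_composition))
  expect_true(all(pg$n_after_composition >= pg$n_after_transcriptome))
})

test_that("genes with no surviving candidates are reported untargetable", {
  # all-AT sequence: GC = 0 fails composition everywhere
  rep <- designPanel(c(TRBV901 = strrep("AT", 30)))
  expect_equal(rep@untargetable, "TRBV901")
  expect_equal(nrow(rep@targets), 0L)
})

test_that("per-stage survivor counts match a brute-force oracle on a family", {
  fam <- generateGeneFamily(7, length = 90, mutation_rate = 0.05, seed = 6)
  cand <- enumerateCandidates(fam)
  cand <- uniquenessScreen(cand)
  cand <- compositionFilter(cand)
  oracle_cross <- oracleCrossReactive(cand$seq30, cand$gene)
  oracle_comp <- oracleComposition(cand$seq30)
  for (g in unique(cand$gene)) {
    idx <- cand$gene == g
    expect_equal(sum(idx & lengths(cand$cross_reactive_with) == 0L),
                 sum(idx & lengths(oracle_cross) == 0L))
    expect_equal(sum(idx & lengths(cand$cross_reactive_with) == 0L &
                       cand$comp_pass),
                 sum(idx & lengths(oracle_cross) == 0L & oracle_comp))
  }
})

test_that("design is deterministic (no RNG) and rank prefers mid-GC", {
  fam <- generateGeneFamily(4, length = 70, mutation_rate = 0.2, seed = 8)
  r1 <- designPanel(fam)
  r2 <- designPanel(fam)
  expect_identical(r1@targets$seq30, r2@targets$seq30)
  for (g in unique(r1@targets$gene)) {
    sel <- r1@targets[r1@targets$gene == g, ]
    pool <- compositionFilter(uniquenessScreen(enumerateCandidates(fam)))
    pool <- pool[pool$gene == g & pool$comp_pass &
                   lengths(pool$cross_reactive_with) == 0L, ]
    if (nrow(pool) > 0 && nrow(sel) > 0)
      expect_lte(min(abs(sel$gc_fraction - 0.5)),
                 min(abs(pool$gc_fraction - 0.5)) + 1e-12)
  }
})
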