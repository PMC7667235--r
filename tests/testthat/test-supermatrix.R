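test_that("longest ORF handles constructed cases and strand symmetry", {
  res <- longestOrf("TTTATGAAATAAGG")
  expect_equal(res$protein, "MK")
  expect_equal(res$cds, "ATGAAATAA")
  expect_equal(res$strand, "+")
  expect_equal(res$start, 3L)
  expect_equal(res$end, 12L)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("TTTATGAAATAAGG")))
  res2 <- longestOrf(rc)
  expect_equal(res2$protein, "MK")
  expect_equal(res2$strand, "-")
  expect_equal(nchar("TTTATGAAATAAGG") - res2$end, res$start)  # mirrored coords
  # two ORFs, the longer wins
  seq2 <- paste0("ATG", strrep("AAA", 9), "TAACC",
                 "ATG", strrep("GGG", 24), "TAA")
  expect_equal(nchar(longestOrf(seq2)$protein), 25L)
  expect_error(longestOrf("CCCCCC"), "no open reading frame")
  expect_error(longestOrf("AC"), "shorter")
})

test_that("longest ORF agrees with the exhaustive 6-frame oracle", {
  set.seed(101)
  for (i in 1:1000) {
    s <- randomDna(sample(30:600, 1))
    want <- bruteLongestOrfLength(s)
    if (want == 0) {
      expect_error(longestOrf(s), "no open reading frame")
    } else {
      got <- longestOrf(s)
      expect_equal(nchar(got$protein), want)
      # returned CDS is internally consistent: starts ATG, stop-free protein
      expect_equal(substr(got$cds, 1, 3), "ATG")
      expect_false(grepl("\\*", got$protein))
      # forward-strand coordinates slice back to the CDS
      sub <- substr(s, got$start + 1, got$end)
      if (got$strand == "-") {
        sub <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(sub)))
      }
      expect_equal(sub, got$cds)
    }
  }
  # stop-to-stop mode finds ORFs a start-codon scan misses
  s3 <- paste0("TTT", strrep("GCT", 30), "TAA")
  expect_error(longestOrf(s3, require_start = TRUE))
  expect_equal(nchar(longestOrf(s3, require_start = FALSE)$protein),
               bruteLongestOrfLength(s3, require_start = FALSE))
  set.seed(102)
  for (i in 1:100) {
    s <- randomDna(sample(30:300, 1))
    expect_equal(nchar(longestOrf(s, require_start = FALSE)$protein),
                 bruteLongestOrfLength(s, require_start = FALSE))
  }
})

test_that("aligned overlap is the shared-column fraction over the shorter row", {
  a <- paste0(strrep("A", 50), strrep("-", 50))
  b <- paste0(strrep("-", 55), strrep("C", 45))
  expect_equal(alignedOverlap(a, b), 0)
  c1 <- paste0(strrep("A", 50), strrep("-", 50))
  c2 <- paste0(strrep("-", 30), strrep("C", 60), strrep("-", 10))
  expect_equal(alignedOverlap(c1, c2), 20 / 50)
  expect_equal(alignedOverlap(c1, c2), alignedOverlap(c2, c1))
  expect_equal(alignedOverlap(c1, c1), 1)
  expect_error(alignedOverlap(c1, strrep("-", 100)), "entirely gaps")
  expect_error(alignedOverlap("AA", "AAA"), "different alignments")
})

test_that("multicopy resolution merges fragments and drops paralogs", {
  f1 <- "MKL-------"
  f2 <- "------VWYH"
  r <- resolveMulticopy(c(a = f1, b = f2))
  expect_equal(r$action, "merged")
  expect_equal(r$row, "MKL---VWYH")
  # doubly-covered column takes the earlier-starting fragment's residue
  g1 <- "MKLAA-----"
  g2 <- "----CVWYH-"
  r2 <- resolveMulticopy(c(a = g1, b = g2), threshold = 0.5)
  expect_equal(substr(r2$row, 5, 5), "A")
  # overlapping pair -> paralogs -> drop
  p <- resolveMulticopy(c(a = "MKLMKLMKL-", b = "-KLMKLMKLV"))
  expect_equal(p$action, "dropped")
  # three fragments where one pair overlaps: all dropped
  t3 <- resolveMulticopy(c(a = "MK--------", b = "-KLM------", c = "------WYHV"))
  expect_equal(t3$action, "dropped")
  expect_error(resolveMulticopy("MK"), "at least 2")
})

test_that("orthogroup filter applies presence, multicopy and length rules in order", {
  roster <- sprintf("sp%02d", 1:53)
  mkOg <- function(id, n_present, n_multi = 0, len = 150) {
    memb <- stats::setNames(vector("list", 53), roster)
    rows <- character(0)
    prot <- strrep("M", len)
    for (i in seq_len(n_present)) {
      sp <- roster[i]
      if (i <= n_multi) {
        ids <- paste0(sp, "_", id, c("_x1", "_x2"))
        # overlapping pair -> paralogs
        rows[ids] <- c(prot, prot)
        memb[[sp]] <- ids
      } else {
        idx <- paste0(sp, "_", id)
        rows[idx] <- prot
        memb[[sp]] <- idx
      }
    }
    Orthogroup(id, memb, alignment = Biostrings::AAStringSet(rows))
  }
  ogs <- list(mkOg("OG_ok", 45),
              mkOg("OG_few", 39),
              mkOg("OG_multi", 50, n_multi = 6),
              mkOg("OG_short", 45, len = 99))
  res <- filterOrthogroups(ogs, filterConfig(), roster = roster)
  rep <- res$report
  expect_equal(rep$decision[rep$og_id == "OG_ok"], "kept")
  expect_equal(rep$reason[rep$og_id == "OG_few"], "too_few_species")
  expect_equal(rep$reason[rep$og_id == "OG_multi"], "too_many_multicopy")
  expect_equal(rep$reason[rep$og_id == "OG_short"], "too_short")
  # 40 of 53 present passes the presence rule (boundary)
  res40 <- filterOrthogroups(list(mkOg("OG_40", 40)), filterConfig(),
                             roster = roster)
  expect_equal(res40$report$decision, "kept")
  # every input orthogroup accounted for exactly once
  expect_setequal(rep$og_id, vapply(ogs, ogId, ""))
  # order independence
  res_rev <- filterOrthogroups(rev(ogs), filterConfig(), roster = roster)
  expect_setequal(paste(res_rev$report$og_id, res_rev$report$decision),
                  paste(rep$og_id, rep$decision))
})

test_that("resolution recovers generator truth on 500 families", {
  fam <- simulateGeneFamilies(n_species = 10, n_families = 500,
                              fragment_prob = 0.2, paralog_prob = 0.15,
                              protein_length = c(60, 150), seed = 314)
  res <- filterOrthogroups(fam$orthogroups,
                           filterConfig(min_species_present = 0.3,
                                        max_multi_frac = 1))
  merged <- merge(fam$truth, res$resolutions, by = c("og_id", "species"))
  expect_equal(nrow(merged), nrow(fam$truth))
  map <- c(single = "single", fragments = "merged_fragments",
           paralogs = "dropped_paralogs")
  expect_equal(mean(merged$resolution == map[merged$status]), 1)
})

test_that("back-translation substitutes codons and validates translations", {
  aln <- Biostrings::AAStringSet(c(s1 = "M-K", s2 = "MLK"))
  cod <- backtranslate(aln, c(s1 = "ATGAAA", s2 = "ATGCTGAAGTAA"))
  expect_equal(as.character(cod[["s1"]]), "ATG---AAA")
  expect_equal(as.character(cod[["s2"]]), "ATGCTGAAG")   # trailing stop stripped
  expect_error(backtranslate(aln, c(s1 = "ATGAGA", s2 = "ATGCTGAAG")),
               "mismatch for s1 at residue 2")
  expect_error(backtranslate(aln, c(s1 = "ATGAAA")), "no CDS")
  expect_error(backtranslate(aln, c(s1 = "ATGAAACCC", s2 = "ATGCTGAAG")),
               "length")
})

test_that("codon trimming keeps frame, honors the boundary, is idempotent", {
  aln <- Biostrings::DNAStringSet(c(
    a = "ATGAAACCC", b = "ATGAAACCC", c = "ATG---CCC", d = "ATG------"))
  tr <- trimCodonColumns(aln, 0.5)
  # codon 2 has 2/4 non-gap = 0.5 -> kept (boundary inclusive); codon 3 has 3/4
  expect_equal(tr$kept_codons, c(1L, 2L, 3L))
  tr2 <- trimCodonColumns(aln, 0.6)
  expect_equal(tr2$kept_codons, c(1L, 3L))
  expect_equal(as.character(tr2$alignment[["a"]]), "ATGCCC")
  # limits
  expect_equal(length(trimCodonColumns(aln, 0)$kept_codons), 3L)
  expect_equal(trimCodonColumns(aln, 1)$kept_codons, 1L)
  expect_error(trimCodonColumns(Biostrings::DNAStringSet(c(x = "ACGT")), 0.5),
               "multiple of 3")
  # idempotence on random gappy codon alignments
  set.seed(55)
  for (i in 1:20) {
    n_seq <- sample(3:8, 1); n_cod <- sample(5:40, 1)
    rows <- vapply(seq_len(n_seq), function(j) {
      paste(ifelse(runif(n_cod) < 0.4, "---",
                   vapply(seq_len(n_cod), function(k)
                     paste(sample(c("A","C","G","T"), 3, TRUE), collapse = ""),
                     "")), collapse = "")
    }, "")
    names(rows) <- paste0("s", seq_len(n_seq))
    x <- Biostrings::DNAStringSet(rows)
    once <- trimCodonColumns(x, 0.5)$alignment
    twice <- trimCodonColumns(once, 0.5)$alignment
    expect_equal(as.character(twice), as.character(once))
  }
})

test_that("concatenation pads absentees and slices back exactly", {
  a1 <- Biostrings::DNAStringSet(c(sp1 = strrep("ACG", 100),
                                   sp2 = strrep("GTA", 100)))
  a2 <- Biostrings::DNAStringSet(c(sp2 = strrep("TTG", 50),
                                   sp3 = strrep("CCA", 50)))
  pm <- concatenateAlignments(list(og1 = a1, og2 = a2),
                              roster = c("sp1", "sp2", "sp3"))
  expect_equal(unname(Biostrings::width(alignment(pm))), rep(450L, 3))
  expect_equal(partitions(pm)$start, c(1L, 301L))
  expect_equal(partitions(pm)$end, c(300L, 450L))
  row3 <- as.character(alignment(pm)[["sp3"]])
  expect_equal(substr(row3, 1, 300), strrep("-", 300))
  expect_equal(substr(row3, 301, 450), strrep("CCA", 50))
  for (og in c("og1", "og2")) {
    back <- extractPartition(pm, og)
    orig <- if (og == "og1") a1 else a2
    expect_setequal(names(back), names(orig))
    expect_equal(as.character(back)[names(orig)], as.character(orig))
  }
  expect_error(concatenateAlignments(list(og1 = a1), roster = "sp1"),
               "not in roster")
})

test_that("random supermatrices round-trip through disk and slicing", {
  set.seed(77)
  for (i in 1:5) {
    n_og <- sample(2:5, 1)
    roster <- paste0("t", 1:sample(3:6, 1))
    alns <- lapply(seq_len(n_og), function(j) {
      present <- sample(roster, sample(2:length(roster), 1))
      w <- sample(1:30, 1) * 3
      rows <- vapply(present, function(s)
        paste(sample(c("A", "C", "G", "T"), w, TRUE), collapse = ""), "")
      Biostrings::DNAStringSet(rows)
    })
    names(alns) <- sprintf("og%02d", seq_len(n_og))
    pm <- concatenateAlignments(alns, roster = roster)
    p <- partitions(pm)
    expect_equal(sum(p$end - p$start + 1),
                 unname(Biostrings::width(alignment(pm))[1]))
    base <- withr::local_tempfile()
    writeSupermatrix(pm, base)
    pm2 <- readSupermatrix(base)
    expect_equal(as.character(alignment(pm2)), as.character(alignment(pm)))
    expect_equal(partitions(pm2), partitions(pm))
    for (og in names(alns)) {
      expect_equal(as.character(extractPartition(pm2, og))[names(alns[[og]])],
                   as.character(alns[[og]]))
    }
  }
})
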