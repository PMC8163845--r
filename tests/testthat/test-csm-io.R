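test_that("CSM tables read with TT/TD/DD classes derived from flags", {
  tsv <- tempfile(fileext = ".tsv")
  df <- toy_csms()[c(1, 3, 6), ]
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  cs <- readCsmTable(tsv)
  expect_s4_class(cs, "CSMSet")
  expect_equal(length(cs), 3L)
  expect_equal(tdClass(cs), c("TT", "TD", "DD"))
})

test_that("fraction values outside the configured range are rejected by row", {
  df <- toy_csms()
  df$scx_fraction[2] <- 0L
  expect_error(CSMSet(df, nScx = 9L), "scx_fraction.*rows: 2")
  df2 <- toy_csms()
  df2$hsax_fraction[4] <- 11L
  expect_error(CSMSet(df2, nHsax = 10L), "hsax_fraction")
})

test_that("CSM table write-then-read is a lossless round trip", {
  sim <- sim_small()
  sub <- sim$csms[1:50]
  tsv <- tempfile(fileext = ".tsv")
  writeCsmTable(sub, tsv)
  back <- readCsmTable(tsv, nScx = nFractions(sub)["scx"],
                       nHsax = nFractions(sub)["hsax"])
  expect_equal(csmData(back), csmData(sub))
})

test_that("dialect maps source column names; missing mandatory ones error", {
  tsv <- tempfile(fileext = ".csv")
  df <- toy_csms()[1:2, ]
  names(df)[names(df) == "peptide_a"] <- "PepSeq1"
  names(df)[names(df) == "score"] <- "match_score"
  utils::write.table(df, tsv, sep = ",", quote = FALSE, row.names = FALSE)
  cs <- readCsmTable(tsv, dialect = c(peptide_a = "PepSeq1",
                                      score = "match_score"))
  expect_equal(csmData(cs)$peptide_a, toy_csms()$peptide_a[1:2])
  expect_error(readCsmTable(tsv), "mandatory column")
  expect_error(readCsmTable(tsv, dialect = c(peptide_a = "NoSuchCol")),
               "missing column")
})

test_that("empty CSM table yields an empty set with a warning", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(paste(csmColumns(), collapse = "\t"), tsv)
  expect_warning(cs <- readCsmTable(tsv), "no rows")
  expect_equal(length(cs), 0L)
})

test_that("peptide parsing handles modifications and crosslink sites", {
  expect_equal(parsePeptide("KMoxR", c("ox")), c("K", "Mox", "R"))
  expect_equal(parsePeptide("PEPTIDE"), strsplit("PEPTIDE", "")[[1]])
  expect_equal(parsePeptide("KAR", link_pos = 1L), c("Kxl", "A", "R"))
  expect_error(parsePeptide("KMzzR", c("ox")), "unknown modification.*zz")
  expect_error(parsePeptide("KAR", link_pos = 5L), "outside peptide")
  expect_equal(parsePeptide(""), character())
})

test_that("tokenization is injective across modification states", {
  variants <- list(
    list(seq = "MKCR", pos = NA), list(seq = "MoxKCR", pos = NA),
    list(seq = "MKCcmR", pos = NA), list(seq = "MoxKCcmR", pos = NA),
    list(seq = "MKCR", pos = 2L), list(seq = "MoxKCcmR", pos = 2L)
  )
  toks <- lapply(variants, function(v) {
    paste(parsePeptide(v$seq, c("ox", "cm"), v$pos), collapse = " ")
  })
  expect_equal(anyDuplicated(unlist(toks)), 0L)
  # reconstructable: concatenating tokens (minus link marker) gives the string
  for (v in variants) {
    tk <- parsePeptide(v$seq, c("ox", "cm"), v$pos)
    expect_equal(paste(sub("xl$", "", tk), collapse = ""), v$seq)
  }
})

test_that("FASTA I/O round trips and rejects malformed input", {
  fa <- tempfile(fileext = ".fasta")
  seqs <- c(prot1 = "MKTAYIAKQR", prot2 = "GDSLKWENNVR")
  writeFastaFile(seqs, fa)
  back <- readFastaFile(fa)
  expect_equal(back, seqs)
  bad <- tempfile(fileext = ".fasta")
  writeLines(c("MKTAYIAKQR", ">p1"), bad)
  expect_error(readFastaFile(bad), "malformed FASTA")
  empty_seq <- tempfile(fileext = ".fasta")
  writeLines(c(">p1", "MKT", ">p2", "", ">p3", "AAA"), empty_seq)
  expect_error(readFastaFile(empty_seq), "empty sequence")
})

test_that("alpha/beta assignment is deterministic and order-free", {
  expect_equal(assignAlphaBeta("LONGPEPK", "SHRT"), c(alpha = 1L, beta = 2L))
  expect_equal(assignAlphaBeta("SHRT", "LONGPEPK"), c(alpha = 2L, beta = 1L))
  expect_equal(assignAlphaBeta("ABCK", "ABDK"), c(alpha = 1L, beta = 2L))
  expect_equal(assignAlphaBeta("ABDK", "ABCK"), c(alpha = 2L, beta = 1L))
})
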