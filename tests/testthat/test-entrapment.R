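test_that("tryptic digest follows the K/R-not-before-P rule", {
  expect_setequal(trypticDigest("AKRG", missed_cleavages = 0L),
                  c("AK", "R", "G"))
  expect_setequal(trypticDigest("AKPG"), "AKPG")
  expect_setequal(trypticDigest("AKGR", missed_cleavages = 1L),
                  c("AK", "GR", "AKGR"))
  expect_setequal(trypticDigest("AKGR", missed_cleavages = 0L), c("AK", "GR"))
  expect_equal(trypticDigest(""), character())
  # peptides above max_len are discarded
  long <- paste(rep("A", 30), collapse = "")
  expect_equal(trypticDigest(paste0(long, "K", long), max_len = 20L),
               character())
  # terminal K/R does not create an empty fragment
  expect_setequal(trypticDigest("GGK", missed_cleavages = 0L), "GGK")
})

test_that("homology filter removes exact tryptic-peptide sharing, monotonically", {
  targets <- c(t1 = "MGGWDDSAEIKAAGLDDTR")
  shared <- c(c1 = "LLLKAAGLDDTRVVVEEK")     # shares AAGLDDTR
  clean <- c(c2 = "MNNNQQQWEEKSSSFFFR")
  kept <- homologyFilter(targets, c(shared, clean))
  expect_named(kept, "c2")
  # adding targets never brings a removed candidate back
  targets2 <- c(targets, t2 = "MNNPLLWWK")
  kept2 <- homologyFilter(targets2, c(shared, clean))
  expect_true(all(names(kept2) %in% names(kept)))
})

test_that("greedy matching is deterministic and assigns without replacement", {
  # candidate with identical (kr_count, length) is a zero-distance match
  targets <- c(tA = "MKKRAAAAAA")           # kr 3, len 10
  cands <- c(cX = "GKRKGGGGGG",             # kr 3, len 10 -> exact
             cY = "GGGGGGGGGGGGGGGGGGGGK") # far
  res <- matchEntrapment(targets, cands)
  expect_equal(res$assignment$entrapment, "cX")
  expect_length(res$combined, 2L)

  # contested nearest neighbour: longer target is served first, the other
  # receives the next-nearest unused candidate (verified by an independent
  # mini-oracle below)
  targets2 <- c(
    long = paste(rep("A", 30), collapse = ""),
    short = paste(rep("A", 28), collapse = "")
  )
  cands2 <- c(
    c30 = paste(rep("G", 30), collapse = ""),
    c29 = paste(rep("G", 29), collapse = ""),
    c10 = paste(rep("G", 10), collapse = ""),
    c50 = paste(rep("G", 50), collapse = "")
  )
  res2 <- matchEntrapment(targets2, cands2)
  # oracle: standardise over the candidate pool, greedy by descending length
  st <- proteinStats(unname(cands2))
  mu <- c(mean(st$kr_count), mean(st$length))
  sd_ <- pmax(c(stats::sd(st$kr_count), stats::sd(st$length)), 1e-8)
  z <- function(kr, len) (c(kr, len) - mu) / sd_
  tz <- lapply(c(30, 28), function(L) z(0, L))
  cz <- lapply(c(30, 29, 10, 50), function(L) z(0, L))
  d <- function(a, b) sqrt(sum((a - b)^2))
  used <- logical(4)
  pick <- integer(2)
  for (i in 1:2) {  # targets already in descending length order
    dd <- vapply(cz, d, numeric(1), a = tz[[i]])
    dd[used] <- Inf
    pick[i] <- which.min(dd)
    used[pick[i]] <- TRUE
  }
  expect_equal(res2$assignment$entrapment[match(c("long", "short"),
                                               res2$assignment$target)],
               names(cands2)[pick])
  expect_equal(anyDuplicated(res2$assignment$entrapment), 0L)
  # deterministic
  expect_identical(matchEntrapment(targets2, cands2), res2)
  expect_error(matchEntrapment(targets2, cands2[1]), "smaller than")
})

test_that("combined database interleaves targets with matches, size 2N", {
  set.seed(5)
  prot <- simulateProteins(simConfig(n_proteins = 12L,
                                     n_entrapment_proteins = 20L, seed = 5L))
  targets <- stats::setNames(prot$sequence[!prot$is_entrapment],
                             prot$accession[!prot$is_entrapment])
  cands <- stats::setNames(prot$sequence[prot$is_entrapment],
                           prot$accession[prot$is_entrapment])
  res <- buildEntrapmentDb(targets, cands)
  expect_length(res$combined, 2L * length(targets))
  expect_equal(names(res$combined)[seq(1, 23, 2)], names(targets))
  # no entrapment protein shares a tryptic peptide with any target
  tpeps <- unlist(lapply(targets, trypticDigest))
  tpeps <- tpeps[nchar(tpeps) >= 6]
  for (acc in res$assignment$entrapment) {
    cpeps <- trypticDigest(cands[[acc]])
    cpeps <- cpeps[nchar(cpeps) >= 6]
    expect_equal(length(intersect(cpeps, tpeps)), 0L)
  }
})

test_that("protein statistics are consistent", {
  st <- proteinStats(c("MKKR", "AAAA"))
  expect_equal(st$kr_count, c(3L, 0L))
  expect_equal(st$length, c(4L, 4L))
  expect_equal(unname(rowSums(st$comp)), c(1, 1))
})
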