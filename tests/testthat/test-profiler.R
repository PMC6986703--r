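test_that("fragment extraction centres the target", {
  g <- GenomeRecord("g", randomSeq(10000, seed = 1), circular = FALSE)
  fr <- extractTargetFragment(g, 5000, 5038, 600)
  expect_equal(c(fr$fragmentStart, fr$fragmentEnd), c(4719, 5319))
  expect_equal(fr$targetOffset, 281)
  expect_equal(nchar(fr$fragmentSeq), 600)

  fr0 <- extractTargetFragment(g, 5000, 5000, 600)
  expect_equal(c(fr0$fragmentStart, fr0$fragmentEnd), c(4700, 5300))

  gc <- GenomeRecord("gc", randomSeq(10000, seed = 2), circular = TRUE)
  frw <- extractTargetFragment(gc, 10, 48, 600)
  expect_equal(nchar(frw$fragmentSeq), 600)
  # wrapped fragment equals tail + head of the genome
  expect_identical(frw$fragmentSeq,
                   paste0(substr(genomeSeq(gc), 10000 - 271 + 1, 10000),
                          substr(genomeSeq(gc), 1, 329)))

  lin <- GenomeRecord("lin", randomSeq(400, seed = 3), circular = FALSE)
  expect_warning(frl <- extractTargetFragment(lin, 10, 48, 600), "clipped")
  expect_lt(nchar(frl$fragmentSeq), 600)
  expect_error(extractTargetFragment(g, 100, 900, 600), "longer")
})

test_that("read recruitment keeps matching reads and rejects noise", {
  g <- GenomeRecord("g", randomSeq(2000, seed = 4), circular = FALSE)
  fr <- extractTargetFragment(g, 1000, 1040, 600)
  inRead <- substr(fr$fragmentSeq, 101, 350)        # exact 250 bp piece
  rcRead <- rcOracle(substr(fr$fragmentSeq, 201, 450))
  noise <- randomSeq(250, seed = 5)
  rs <- ReadSet("sp", c(a = inRead, b = rcRead, z = noise))
  rec <- recruitReads(fr, rs)
  expect_setequal(names(readSequences(rec)), c("a", "b"))
  # orientation-normalised: the reverse read comes back fragment-strand
  expect_identical(unname(readSequences(rec)["b"]),
                   substr(fr$fragmentSeq, 201, 450))
})

test_that("recruitment decisions agree with an alignment-score oracle", {
  g <- GenomeRecord("g", randomSeq(800, seed = 6), circular = FALSE)
  fr <- extractTargetFragment(g, 380, 420, 200)
  set.seed(7)
  reads <- character(0)
  for (i in 1:8) {                      # clean 80 bp substrings
    s <- sample(100, 1)
    reads <- c(reads, substr(fr$fragmentSeq, s, s + 79))
  }
  for (i in 1:6) {                      # 10% diverged copies
    s <- sample(100, 1)
    rd <- substr(fr$fragmentSeq, s, s + 79)
    for (p in sample(80, 8)) {
      old <- substr(rd, p, p)
      substr(rd, p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    }
    reads <- c(reads, rd)
  }
  for (i in 1:6) reads <- c(reads, randomSeq(80, seed = 70 + i))
  names(reads) <- sprintf("q%02d", seq_along(reads))
  rec <- recruitReads(fr, ReadSet("sp", reads),
                      minIdentity = 0.8, minHitLen = 50)
  got <- names(reads) %in% names(readSequences(rec))
  # oracle: best affine local score; a >= 50-col alignment at >= 80%
  # identity scores at least 50*(2*0.8 - 1) = 30 while 80 bp of random
  # sequence stays far below
  oracleScore <- vapply(reads, function(rd)
    max(swScoreOracle(rd, fr$fragmentSeq),
        swScoreOracle(rcOracle(rd), fr$fragmentSeq)), 0)
  expect_identical(got, unname(oracleScore >= 30))
  expect_identical(got, rep(c(TRUE, TRUE, FALSE), c(8, 6, 6)))
})

test_that("allele tabulation counts spanning reads and orders records", {
  g <- GenomeRecord("g", randomSeq(2000, seed = 8), circular = FALSE)
  fr <- extractTargetFragment(g, 990, 1020, 600)
  dom <- substr(fr$fragmentSeq, 201, 450)
  varA <- dom; substr(varA, 100, 100) <- setdiff(c("A", "C"),
                                                 substr(dom, 100, 100))[1]
  varB <- dom
  substr(varB, 110, 110) <- setdiff(c("G", "T"), substr(dom, 110, 110))[1]
  reads <- c(rep(dom, 5), rep(varA, 3), rep(varB, 2))
  names(reads) <- sprintf("r%02d", seq_along(reads))
  rs <- ReadSet("sp", reads)
  tab <- tabulateAlleles(rs, fr)
  expect_equal(totalMapped(tab), 10)
  expect_equal(alleleRecords(tab)$count, c(5, 3, 2))
  expect_equal(alleleRecords(tab)$share, c(0.5, 0.3, 0.2))

  # minCount filters records but not the total
  tab2 <- tabulateAlleles(rs, fr, minCount = 3)
  expect_equal(totalMapped(tab2), 10)
  expect_equal(alleleRecords(tab2)$count, c(5, 3))
  expect_equal(alleleRecords(tab2)$share, c(0.5, 0.3))

  # input order does not matter
  tab3 <- tabulateAlleles(ReadSet("sp", rev(reads)), fr)
  expect_equal(alleleRecords(tab3), alleleRecords(tab))
})

test_that("deletion alleles appear as gapped strings and partial reads drop", {
  g <- GenomeRecord("g", randomSeq(2000, seed = 9), circular = FALSE)
  fr <- extractTargetFragment(g, 990, 1020, 600)
  t1 <- fr$targetOffset + 1
  dom <- substr(fr$fragmentSeq, 101, 500)
  del <- paste0(substr(fr$fragmentSeq, 101, t1 + 9),
                substr(fr$fragmentSeq, t1 + 15, 500))  # 5 bp deletion
  partial <- substr(fr$fragmentSeq, t1 + 5, 500)       # starts inside target
  rs <- ReadSet("sp", c(a = dom, b = del, p = partial))
  tab <- tabulateAlleles(rs, fr)
  expect_equal(totalMapped(tab), 2)
  rec <- alleleRecords(tab)
  expect_true(any(grepl("-", rec$allele)))
  expect_equal(sum(rec$count), 2)
})

test_that("allele counts are conserved for simulated heteroplasmic pools", {
  g <- GenomeRecord("g", randomSeq(1500, seed = 10), circular = TRUE)
  pool <- list(
    major = list(edits = list(), freq = 0.8),
    minor = list(edits = list(list(type = "sub", pos = 748L, bases = "A")),
                 freq = 0.2))
  base <- substr(genomeSeq(g), 749, 749)
  if (base == "A")
    pool$minor$edits[[1]]$bases <- "G"
  sim <- simulateHeteroplasmicReads(g, depth = 60, readLength = 150,
                                    errorRate = 0, allelePool = pool,
                                    seed = 13L)
  fr <- extractTargetFragment(g, 740, 760, 400)
  rec <- recruitReads(fr, sim$reads)
  tab <- tabulateAlleles(rec, fr)
  # conservation: record counts sum to the spanning total
  expect_equal(sum(alleleRecords(tab)$count), totalMapped(tab))
  # the dominant allele matches the simulator truth log's majority
  truthMajor <- names(which.max(table(sim$truth$reads$allele)))
  expect_equal(truthMajor, "major")
  expect_identical(alleleRecords(tab)$allele[1],
                   substr(genomeSeq(g), 741, 760))
  # recovered shares inside a 99% binomial interval around 0.8 / 0.2
  n <- totalMapped(tab)
  phat <- dominantShare(tab, 1)
  expect_lt(abs(phat - 0.8), 2.58 * sqrt(0.8 * 0.2 / n))
})

test_that("dominant shares are counts over the pre-filter total", {
  rec <- data.frame(allele = c("AA", "AC", "AG"), count = c(6L, 3L, 1L),
                    share = c(0.6, 0.3, 0.1))
  tab <- new("AlleleTable", speciesLabel = "s", totalMapped = 10L,
             records = rec)
  expect_equal(dominantShare(tab, 2), c(0.6, 0.3))
  one <- new("AlleleTable", speciesLabel = "s", totalMapped = 4L,
             records = data.frame(allele = "AA", count = 4L, share = 1))
  expect_equal(dominantShare(one), 1)
  empty <- new("AlleleTable", speciesLabel = "s", totalMapped = 0L,
               records = rec[0, ])
  expect_error(dominantShare(empty), "undefined")
})
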