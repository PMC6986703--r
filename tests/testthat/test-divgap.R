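test_that("error-free tiling reads give clean single-base pileup columns", {
  ref <- GenomeRecord("ref", randomSeq(1000, seed = 5), circular = FALSE)
  starts <- seq(1, 751, by = 75)
  rds <- substring(genomeSeq(ref), starts, starts + 249)
  rs <- ReadSet("sp", setNames(rds, sprintf("r%02d", seq_along(rds))))
  pl <- pileupFromReads(rs, ref)
  expect_equal(pl@nReadsMapped, length(rds))
  cnt <- pileupCounts(pl)
  covered <- which(colSums(cnt) > 0)
  # every covered column has exactly one base type, and it is the
  # reference base
  expect_true(all(colSums(cnt[, covered] > 0) == 1))
  refChars <- strsplit(genomeSeq(ref), "")[[1]]
  calls <- rownames(cnt)[apply(cnt[, covered], 2, which.max)]
  expect_identical(calls, refChars[covered])
  # coverage as constructed
  expected <- rep(0L, 1000)
  for (s in starts) expected[s:(s + 249)] <- expected[s:(s + 249)] + 1L
  expect_equal(unname(pileupCoverage(pl)), expected)
})

test_that("unrelated reads are discarded below the identity floor", {
  ref <- GenomeRecord("ref", randomSeq(1000, seed = 6), circular = FALSE)
  junk <- randomSeq(250, seed = 99)
  rs <- ReadSet("sp", c(r1 = junk))
  pl <- pileupFromReads(rs, ref)
  expect_equal(pl@nReadsMapped, 0L)
  expect_equal(pl@nReadsDiscarded, 1L)
  expect_warning(pileupFromReads(ReadSet("none", character(0)), ref),
                 "empty")
})

test_that("reverse-strand and wrapped reads are placed correctly", {
  ref <- GenomeRecord("ref", randomSeq(600, seed = 8), circular = TRUE)
  fwd <- substr(genomeSeq(ref), 101, 250)
  rev <- rcOracle(substr(genomeSeq(ref), 301, 450))
  wrap <- paste0(substr(genomeSeq(ref), 551, 600),
                 substr(genomeSeq(ref), 1, 100))
  rs <- ReadSet("sp", c(f = fwd, r = rev, w = wrap))
  pl <- pileupFromReads(rs, ref)
  expect_equal(pl@nReadsMapped, 3L)
  cov <- pileupCoverage(pl)
  expect_true(all(cov[101:250] >= 1))
  expect_true(all(cov[301:450] >= 1))
  expect_true(all(cov[c(551:600, 1:100)] >= 1))
})

test_that("SAM-derived pileup equals the internally mapped pileup", {
  ref <- GenomeRecord("ref1", randomSeq(1000, seed = 5), circular = FALSE)
  starts <- seq(1, 751, by = 50)
  rds <- substring(genomeSeq(ref), starts, starts + 249)
  ids <- sprintf("r%02d", seq_along(rds))
  rs <- ReadSet("sp", setNames(rds, ids))
  pl1 <- pileupFromReads(rs, ref)
  sam <- tempfile(fileext = ".sam")
  writeSamFixture(sam, "ref1", 1000, ids, starts, rds)
  pl2 <- pileupFromSam(sam, ref)
  expect_identical(pileupCounts(pl1), pileupCounts(pl2))
  expect_identical(pileupDeletions(pl1), pileupDeletions(pl2))
})

test_that("SAM CIGAR deletions, insertions and clips are honoured", {
  ref <- GenomeRecord("refc", randomSeq(300, seed = 12), circular = FALSE)
  seq <- genomeSeq(ref)
  # read with a 3 bp deletion of ref 61..63 and 2 bp soft clip
  rd <- paste0("GG", substr(seq, 21, 60), substr(seq, 64, 110))
  sam <- tempfile(fileext = ".sam")
  writeSamFixture(sam, "refc", 300, "d1", 21L, rd, "2S40M3D47M")
  pl <- pileupFromSam(sam, ref)
  expect_equal(unname(pileupDeletions(pl)[61:63]), c(1L, 1L, 1L))
  expect_equal(sum(pileupCounts(pl)), 87)
  # read with a 2 bp insertion after ref position 50
  rd2 <- paste0(substr(seq, 31, 50), "CC", substr(seq, 51, 80))
  writeSamFixture(sam, "refc", 300, "i1", 31L, rd2, "20M2I30M")
  pl2 <- pileupFromSam(sam, ref)
  expect_equal(unname(pl2@insertions[50]), 1L)
  expect_equal(sum(pileupCounts(pl2)), 50)
})

test_that("interspecific pi averages pairwise mismatch over usable sites", {
  rows <- c(a = strrep("A", 100), b = strrep("A", 100))
  aln <- GenomeAlignment(rows)
  expect_equal(interspecificDiversity(aln, 0, 100)$piInter, 0)

  r2 <- rows
  substr(r2["b"], 50, 50) <- "G"
  expect_equal(interspecificDiversity(GenomeAlignment(r2), 0, 100)$piInter,
               0.01)

  # 3 rows with pairwise mismatch counts 1, 2, 3 over 100 sites
  r3 <- c(a = strrep("A", 100), b = strrep("A", 100), c = strrep("A", 100))
  substr(r3["b"], 10, 10) <- "C"             # ab 1, bc +1
  substr(r3["c"], 20, 21) <- "GG"            # ac 2, bc +2
  res <- interspecificDiversity(GenomeAlignment(r3), 0, 100)
  expect_equal(res$piInter, (1 + 2 + 3) / 3 / 100)
  expect_equal(res$usableSites, 100)

  # gap/N columns are excluded; too few usable sites -> NA
  r4 <- c(a = "ACGTACGTAC", b = "AC-TACNTAC")
  out <- interspecificDiversity(GenomeAlignment(r4), 0, 10, minSites = 20)
  expect_true(is.na(out$piInter))
  expect_equal(out$usableSites, 8)
})

test_that("intraspecific pi equals the brute-force read-pair oracle", {
  mkPile <- function(counts, dels) {
    new("Pileup", refId = "x", refLength = ncol(counts), counts = counts,
        deletions = dels, insertions = integer(ncol(counts)),
        nReadsMapped = 0L, nReadsDiscarded = 0L)
  }
  # worked examples
  cnt <- matrix(0L, 4, 2, dimnames = list(c("A", "C", "G", "T"), NULL))
  cnt["A", 1] <- 9L; cnt["G", 1] <- 1L
  cnt["A", 2] <- 5L; cnt["G", 2] <- 5L
  pl <- mkPile(cnt, integer(2))
  expect_equal(intraspecificDiversity(pl, 0, 1, minSites = 1)$piIntra,
               9 / 45)
  expect_equal(intraspecificDiversity(pl, 1, 2, minSites = 1)$piIntra,
               25 / 45)
  # all single-base columns -> 0
  cnt0 <- matrix(0L, 4, 30, dimnames = list(c("A", "C", "G", "T"), NULL))
  cnt0["T", ] <- 12L
  expect_equal(intraspecificDiversity(mkPile(cnt0, integer(30)),
                                      0, 30)$piIntra, 0)

  # random pileups vs oracle (deletions included in coverage)
  for (seed in 1:10) {
    set.seed(seed)
    L <- 40L
    cnt <- matrix(0L, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
    for (i in seq_len(L))
      cnt[, i] <- as.integer(stats::rmultinom(1, sample(0:30, 1),
                                              c(.7, .1, .1, .1)))
    dels <- as.integer(sample(0:3, L, replace = TRUE))
    pl <- mkPile(cnt, dels)
    h <- piIntraOracle(cnt, dels, minCov = 10L)
    ours <- intraspecificDiversity(pl, 0, L, minCov = 10L, minSites = 1L)
    expect_equal(ours$piIntra, mean(h, na.rm = TRUE), info = seed)
    expect_equal(ours$usableSites, sum(!is.na(h)), info = seed)
  }
})

test_that("the gap score is pi_inter minus aggregated pi_intra", {
  expect_equal(diversityGap(0.05, c(0.01, 0.002, 0)), 0.04)
  expect_equal(diversityGap(0.05, c(0.05, 0.01)), 0)
  expect_equal(diversityGap(0, c(0, 0, 0)), 0)
  expect_equal(diversityGap(0.05, c(0.01, 0.02), aggregate = "mean"),
               0.05 - 0.015)
  expect_true(is.na(diversityGap(NA, c(0.01))))
  expect_true(is.na(diversityGap(0.05, c(0.01, NA))))
})

test_that("pi values stay in [0,1] and are invariant to relabeling", {
  for (seed in 1:5) {
    set.seed(seed)
    rows <- vapply(1:3, function(i) randomSeq(300, seed = 10 * seed + i), "")
    names(rows) <- c("a", "b", "c")
    aln <- GenomeAlignment(rows)
    p1 <- interspecificDiversity(aln, 0, 300)$piInter
    expect_gte(p1, 0); expect_lte(p1, 1)
    p2 <- interspecificDiversity(GenomeAlignment(rows[c(2, 3, 1)]),
                                 0, 300)$piInter
    expect_equal(p1, p2)
  }
})

test_that("substitutions in a window never decrease its pi_inter", {
  base <- randomSeq(200, seed = 31)
  rows <- c(a = base, b = base, c = base)
  prev <- interspecificDiversity(GenomeAlignment(rows), 0, 200)$piInter
  set.seed(32)
  mutable <- rows
  for (i in 1:15) {
    p <- sample(200, 1)
    old <- substr(mutable["b"], p, p)
    substr(mutable["b"], p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                                 old), 1)
    cur <- interspecificDiversity(GenomeAlignment(mutable), 0, 200)$piInter
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("window ranking recovers an implanted divergent window", {
  trio <- simulateGenomeTrio(genomeLength = 4000L, mu = 0.005, seed = 1L,
                             implants = defaultImplant(4000L))
  reads <- lapply(trio$genomes, function(g)
    simulateHeteroplasmicReads(g, depth = 25, errorRate = 0,
                               seed = 17L)$reads)
  pls <- lapply(names(trio$genomes), function(sp)
    pileupFromReads(reads[[sp]], trio$genomes[[sp]]))
  names(pls) <- names(trio$genomes)
  rk <- rankWindows(trio$alignment, pls)
  im <- trio$truth$implants[[1]]
  expect_gt(nrow(rk$candidates), 0)
  top <- rk$candidates[1, ]
  expect_lt(top$start, im$end)
  expect_gt(top$end, im$start)
})

test_that("identical genomes yield no candidates and homopolymers are screened", {
  g <- randomSeq(2000, seed = 41)
  aln <- GenomeAlignment(c(a = g, b = g, c = g))
  cnt <- matrix(0L, 4, 2000, dimnames = list(c("A", "C", "G", "T"), NULL))
  cnt["A", ] <- 20L
  pl <- new("Pileup", refId = "x", refLength = 2000L, counts = cnt,
            deletions = integer(2000), insertions = integer(2000),
            nReadsMapped = 0L, nReadsDiscarded = 0L)
  pls <- list(a = pl, b = pl, c = pl)
  expect_warning(rk <- rankWindows(aln, pls), "no window")
  expect_equal(nrow(rk$candidates), 0)

  # a strongly divergent window is excluded when it holds an A-run >= 8
  g2 <- g
  set.seed(42)
  for (p in seq(1005, 1195, by = 10))
    substr(g2, p, p) <- c(A = "C", C = "G", G = "T", T = "A")[
      substr(g2, p, p)]
  substr(g2, 1100, 1107) <- "AAAAAAAA"
  aln2 <- GenomeAlignment(c(a = g, b = g2, c = g))
  rk2 <- suppressWarnings(rankWindows(aln2, pls))
  inWin <- rk2$windows$start <= 1100 & rk2$windows$end >= 1107
  expect_true(all(rk2$windows$homopolymer[inWin]))
  expect_true(all(!(rk2$candidates$start <= 1100 &
                      rk2$candidates$end >= 1107)))
})

test_that("read-pair pi_intra tracks the sequencing error rate", {
  # single intracellular allele: expected per-site heterozygosity is
  # 2e(1-e) + 2e^2/3 from independent substitution errors
  eps <- 0.01
  vals <- vapply(1:6, function(seed) {
    g <- GenomeRecord(paste0("g", seed), randomSeq(1500, seed = 50 + seed),
                      circular = TRUE)
    sim <- simulateHeteroplasmicReads(g, depth = 40, errorRate = eps,
                                      seed = 60 + seed)
    pl <- pileupFromReads(sim$reads, g, minIdentity = 0.9)
    intraspecificDiversity(pl, 0, 1500)$piIntra
  }, 0)
  expected <- 2 * eps * (1 - eps) + 2 * eps^2 / 3
  se <- stats::sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - expected), 3 * se + 1e-4)
})
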