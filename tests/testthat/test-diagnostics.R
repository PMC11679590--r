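test_that("global alignment is optimal and deterministic", {
  g <- globalAlignPair("ACGT", "ACGT")
  expect_equal(g$score, 4)
  m <- alignmentMatrix(g$alignment)
  expect_false(any(m == "-"))
  expect_equal(alignmentWidth(g$alignment), 4L)

  g2 <- globalAlignPair("ACGT", "ACTT")
  expect_equal(g2$score, 3 * 1 - 1)
  expect_equal(alignmentWidth(g2$alignment), 4L)

  ## exhaustive-recursion oracle on short random pairs
  set.seed(7)
  for (i in 1:25) {
    a <- random_dna(sample(2:6, 1)); b <- random_dna(sample(2:6, 1))
    expect_equal(globalAlignPair(a, b)$score, oracle_nw_score(a, b),
                 info = paste(a, b))
  }
})

test_that("global alignment agrees with Biostrings on longer pairs", {
  set.seed(19)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  for (i in 1:10) {
    a <- random_dna(sample(30:80, 1)); b <- random_dna(sample(30:80, 1))
    ref <- Biostrings::pairwiseAlignment(
      a, b, type = "global", substitutionMatrix = mat,
      gapOpening = 0, gapExtension = 2, scoreOnly = TRUE)
    expect_equal(globalAlignPair(a, b)$score, ref, info = paste(a, b))
  }
})

test_that("substitution-only pairs align gap-free when gaps cost more than mismatches", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(40:120, 1)
    a <- random_dna(n)
    av <- strsplit(a, "")[[1]]
    mut <- sample(n, rbinom(1, n, 0.1))
    av[mut] <- vapply(av[mut], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
    b <- paste(av, collapse = "")
    g <- globalAlignPair(a, b, match = 1, mismatch = -1, gap = -2)
    expect_false(any(alignmentMatrix(g$alignment) == "-"))
  }
})

test_that("percent identity follows the gap-aware column arithmetic", {
  aln <- barcodeAlignment(c(a = "ACGT", b = "ACGT"), species = c("x", "y"))
  expect_equal(percentIdentity(aln, c("a", "b")), 100)

  ## 657 columns, 56 mismatches -> 100 * 601 / 657
  set.seed(5)
  x <- strsplit(random_dna(657), "")[[1]]
  y <- x
  mut <- sample(657, 56)
  y[mut] <- vapply(y[mut], function(ch)
    sample(setdiff(c("A", "C", "G", "T"), ch), 1), character(1))
  aln <- barcodeAlignment(c(a = paste(x, collapse = ""),
                            b = paste(y, collapse = "")),
                          species = c("x", "y"))
  pid <- percentIdentity(aln, c("a", "b"))
  expect_equal(pid, 100 * 601 / 657)
  expect_equal(round(pid, 2), 91.48)
  ## symmetry
  expect_equal(percentIdentity(aln, c("b", "a")), pid)
  expect_error(percentIdentity(aln, c("a", "zz")), "unknown")

  ## gap columns leave the denominator
  aln2 <- barcodeAlignment(c(a = "AC-T", b = "ACGT"), species = c("x", "y"))
  expect_equal(percentIdentity(aln2, c("a", "b")), 100)
})

test_that("within-species variation counts variable columns", {
  five <- setNames(rep("ACGTACGT", 5), paste0("r", 1:5))
  aln <- barcodeAlignment(five, species = rep("sp", 5))
  expect_equal(withinSpeciesVariation(aln), 0)

  aln1 <- barcodeAlignment(c(r1 = "ACGT", r2 = "ACTT"),
                           species = rep("sp", 2))
  expect_equal(withinSpeciesVariation(aln1), 1)

  mixed <- barcodeAlignment(c(r1 = "ACGT", r2 = "ACGT"),
                            species = c("sp1", "sp2"))
  expect_error(withinSpeciesVariation(mixed), "mixed")
})

test_that("diagnostic sites match a brute-force column scan", {
  ## all rows identical -> no diagnostics
  aln0 <- barcodeAlignment(setNames(rep("ACGTACGTAC", 3), paste0("r", 1:3)),
                           species = paste0("sp", 1:3))
  expect_equal(nrow(findDiagnosticSites(aln0, "sp1")), 0L)

  ## toy 3-species alignment with 2 seeded sp1-unique columns (3 and 8)
  aln <- barcodeAlignment(
    c(r1 = "ACTTACGTCC", r2 = "ACGTACGACC", r3 = "ACGTACGACC"),
    species = c("sp1", "sp2", "sp3"))
  got <- findDiagnosticSites(aln, "sp1")
  expect_equal(got$column, c(3L, 8L))
  expect_equal(got$column,
               oracle_diag_columns(alignmentMatrix(aln),
                                   c("sp1", "sp2", "sp3"), "sp1"))

  ## degenerate overlap is not diagnostic: A vs R share the A base
  alnD <- barcodeAlignment(c(r1 = "AAAAAAAAAAAA", r2 = "ARAAAAAAAAAA",
                             r3 = "ACAAAAAAAAAA"),
                           species = c("s1", "s2", "s3"))
  expect_equal(nrow(findDiagnosticSites(alnD, "s1")), 0L)

  ## oracle equivalence on seeded random panels
  for (seed in 1:4) {
    rp <- makeRandomPanel(nSpecies = 5, length = 300, divergence = 0.08,
                          seed = seed)
    m <- alignmentMatrix(rp$alignment)
    sp <- unname(rowSpecies(rp$alignment))
    for (s in unique(sp)) {
      expect_equal(findDiagnosticSites(rp$alignment, s)$column,
                   oracle_diag_columns(m, sp, s),
                   info = paste("seed", seed, s))
    }
  }
  expect_error(findDiagnosticSites(aln, "absent"), "not in alignment")
})

test_that("conserved windows are maximal gap-free runs", {
  L <- 30L
  aln <- barcodeAlignment(setNames(rep(strrep("ACT", 10), 3),
                                   paste0("r", 1:3)),
                          species = paste0("sp", 1:3))
  w <- findConservedWindows(aln, 1)
  expect_equal(IRanges::start(w), 1L)
  expect_equal(IRanges::end(w), L)

  ## one divergent column at position k splits the run
  k <- 12L
  rows <- rep(strrep("A", L), 3)
  sub <- strsplit(rows[3], "")[[1]]; sub[k] <- "G"
  rows[3] <- paste(sub, collapse = "")
  aln2 <- barcodeAlignment(setNames(rows, paste0("r", 1:3)),
                           species = paste0("sp", 1:3))
  w2 <- findConservedWindows(aln2, 5)
  expect_equal(IRanges::start(w2), c(1L, k + 1L))
  expect_equal(IRanges::end(w2), c(k - 1L, L))

  ## diagnostic sites never fall inside an all-species conserved window
  rp <- makeRandomPanel(nSpecies = 4, length = 400, divergence = 0.05,
                        seed = 9)
  wins <- findConservedWindows(rp$alignment, 1)
  cons_cols <- unlist(lapply(seq_along(wins), function(i)
    IRanges::start(wins)[i]:IRanges::end(wins)[i]))
  for (s in unique(rowSpecies(rp$alignment))) {
    d <- findDiagnosticSites(rp$alignment, s)$column
    expect_length(intersect(d, cons_cols), 0)
  }
})

test_that("the synthetic study panel exposes the published geometry", {
  aln <- makePaperPanel(seed = 1)
  ## conserved window for the common reverse covers columns 357-379
  w <- findConservedWindows(aln, 22)
  covering <- any(IRanges::start(w) <= 357 & IRanges::end(w) >= 379)
  expect_true(covering)
  ## diagnostic sites inside the published forward windows
  ci <- findDiagnosticSites(aln, "C. includens")$column
  rn <- findDiagnosticSites(aln, "R. nu")$column
  expect_true(any(ci >= 181 & ci <= 207))
  expect_true(any(rn >= 81 & rn <= 102))
})
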