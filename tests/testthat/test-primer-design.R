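paper_seqs <- primerSequences(paperPrimers())

test_that("default constraints enclose the published diagnostic primers", {
  cons <- designConstraints()
  for (p in c("MMRC_1955", "MMRC_1964", "MMRC_1988")) {
    s <- unname(paper_seqs[p])
    expect_true(nchar(s) >= cons@lengthRange[1] &&
                nchar(s) <= cons@lengthRange[2], info = p)
    expect_true(gcContent(s) >= cons@gcRange[1] &&
                gcContent(s) <= cons@gcRange[2], info = p)
    expect_true(wallaceTm(s) >= cons@tmRange[1] &&
                wallaceTm(s) <= cons@tmRange[2], info = p)
  }
})

test_that("candidate enumeration is exhaustive, ordered and windowed", {
  aln <- makePaperPanel(seed = 1)
  loose <- designConstraints(lengthRange = c(18L, 22L), gcRange = c(0, 100),
                             tmRange = c(0, 200), maxHomopolymer = 100L)
  ## counting oracle: a 30-nt window holds sum_len (30 - len + 1) candidates
  cand <- enumerateCandidates(aln, c(400, 429), "forward", loose,
                              species = "R. nu")
  expect_equal(nrow(cand), sum(vapply(18:22, function(l) 30 - l + 1,
                                      numeric(1))))
  ## deterministic (start, then length) order
  expect_true(!is.unsorted(cand$start))
  ## window shorter than the minimum length -> empty
  tiny <- enumerateCandidates(aln, c(400, 410), "forward", loose,
                              species = "R. nu")
  expect_equal(nrow(tiny), 0L)
  ## window outside the alignment -> error
  expect_error(enumerateCandidates(aln, c(650, 700), "forward", loose),
               "outside")
})

test_that("the published forward primer is recovered from its printed window", {
  aln <- makePaperPanel(seed = 1)
  pinned <- designConstraints(lengthRange = c(27L, 27L), gcRange = c(0, 100),
                              tmRange = c(0, 200), maxHomopolymer = 100L)
  cand <- enumerateCandidates(aln, c(181, 207), "forward", pinned,
                              species = "C. includens")
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$sequence, unname(paper_seqs["MMRC_1964"]))

  ## and the common reverse from its conserved window
  pinned23 <- designConstraints(lengthRange = c(23L, 23L),
                                gcRange = c(0, 100), tmRange = c(0, 200),
                                maxHomopolymer = 100L)
  rev <- enumerateCandidates(aln, c(357, 379), "reverse", pinned23)
  expect_equal(nrow(rev), 1L)
  expect_equal(rev$sequence, unname(paper_seqs["MMRC_1955"]))
})

test_that("printed coordinates pinned into a panel give the printed sizes", {
  ## spans: 357-379 = 23 nt, 181-207 = 27 nt, 81-102 = 22 nt
  expect_equal(379 - 357 + 1, nchar(paper_seqs[["MMRC_1955"]]))
  expect_equal(207 - 181 + 1, nchar(paper_seqs[["MMRC_1964"]]))
  expect_equal(102 - 81 + 1, nchar(paper_seqs[["MMRC_1988"]]))
  ## end - start + 1 reproduces the two product sizes
  expect_equal(379 - 181 + 1, 199)
  expect_equal(379 - 81 + 1, 299)
  panel <- paperAssayPanel()
  expect_equal(expectedSizes(panel),
               c("C. includens" = 199, "R. nu" = 299))
})

test_that("assay assembly finds a feasible, specific, reproducible panel", {
  aln <- makePaperPanel(seed = 1)
  design <- assembleAssay(aln, c("C. includens", "R. nu"))
  panel <- design$panel

  ## expected-size arithmetic against recorded coordinates
  cc <- as.data.frame(panel@coords)
  rev_end <- cc$end[cc$primer == names(panel@commonReverse)]
  for (i in seq_along(panel@forwards)) {
    sp <- panel@forwardSpecies[i]
    fs <- cc$start[cc$primer == names(panel@forwards)[i]]
    expect_equal(unname(expectedSizes(panel)[sp]), rev_end - fs + 1)
  }
  ## pairwise separation
  sz <- expectedSizes(panel)
  expect_true(min(dist(sz)) >= 50)

  ## design/simulation consistency: simulated sizes equal expected sizes
  seqs <- rowSequences(aln)
  for (i in seq_along(panel@forwards)) {
    sp <- panel@forwardSpecies[i]
    row <- names(seqs)[unname(rowSpecies(aln)) == sp][1]
    amp <- simulatePCR(panel@forwards[i], panel@commonReverse, seqs[row])
    expect_equal(amp$length, unname(expectedSizes(panel)[sp]), info = sp)
  }
  ## specificity across all five fixture species
  expect_true(isSpecific(panel, aln))

  ## row-order invariance
  perm <- rev(seq_along(rowIds(aln)))
  aln2 <- barcodeAlignment(rowSequences(aln)[perm],
                           species = unname(rowSpecies(aln))[perm])
  design2 <- assembleAssay(aln2, c("R. nu", "C. includens"))
  expect_equal(unname(design2$panel@commonReverse),
               unname(panel@commonReverse))
  expect_equal(sort(unname(design2$panel@forwards)),
               sort(unname(panel@forwards)))
})

test_that("infeasible designs fail with an explicit constraint report", {
  aln <- makePaperPanel(seed = 1)
  ## single species cannot be discriminated
  expect_error(assembleAssay(aln, "C. includens"),
               class = "coiDiag_infeasible")
  ## an impossible amplicon range empties the search
  expect_error(
    assembleAssay(aln, c("C. includens", "R. nu"),
                  designConstraints(ampliconRange = c(2000L, 3000L))),
    class = "coiDiag_infeasible")
  ## identical rows have no diagnostic sites
  flat <- barcodeAlignment(setNames(rep(rowSequences(aln)[1], 2),
                                    c("a", "b")),
                           species = c("sp1", "sp2"))
  err <- tryCatch(assembleAssay(flat, c("sp1", "sp2")),
                  coiDiag_infeasible = function(e) conditionMessage(e))
  expect_match(err, "diagnostic site")
})

test_that("3' cross-dimer scores match the brute-force scan", {
  d <- crossDimer3p("AAAA", "TTTT", max3prime = 3)
  expect_equal(d$score, 4)
  expect_false(d$pass)

  d2 <- crossDimer3p("ACGT", "ACGT", max3prime = 4)
  expect_equal(d2$score, oracle_dimer("ACGT", "ACGT"))
  expect_equal(d2$pass, d2$score <= 4)

  ## regression value for the published pair, frozen from the oracle
  expect_equal(crossDimer3p(paper_seqs[["MMRC_1955"]],
                            paper_seqs[["MMRC_1964"]])$score,
               oracle_dimer(paper_seqs[["MMRC_1955"]],
                            paper_seqs[["MMRC_1964"]]))

  set.seed(61)
  for (i in 1:20) {
    a <- random_dna(sample(10:25, 1)); b <- random_dna(sample(10:25, 1))
    expect_equal(crossDimer3p(a, b)$score, oracle_dimer(a, b),
                 info = paste(a, b))
  }
})

test_that("panel validity rejects broken size arithmetic and tight tolerances", {
  expect_error(assayPanel(c(r = "CAGATCTACCACCATGAGCAATA"),
                          c(f = "GGATTTGGTAATTGACTTGTACCTCTT"),
                          "sp1", c(sp1 = 199),
                          coords = data.frame(primer = c("r", "f"),
                                              start = c(357, 181),
                                              end = c(379, 207)),
                          minSeparation = 50) , NA)
  ## wrong expected size vs coordinates
  expect_error(assayPanel(c(r = "CAGATCTACCACCATGAGCAATA"),
                          c(f = "GGATTTGGTAATTGACTTGTACCTCTT"),
                          "sp1", c(sp1 = 200),
                          coords = data.frame(primer = c("r", "f"),
                                              start = c(357, 181),
                                              end = c(379, 207))),
               "arithmetic")
  ## tolerance must stay below half the separation
  expect_error(assayPanel(c(r = "CAGATCTACCACCATGAGCAATA"),
                          c(f = "GGATTTGGTAATTGACTTGTACCTCTT",
                            g = "TCCTGGATCTTTAATTGGAGAT"),
                          c("sp1", "sp2"), c(sp1 = 199, sp2 = 299),
                          tolerance = 60, minSeparation = 50),
               "tolerance")
})
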