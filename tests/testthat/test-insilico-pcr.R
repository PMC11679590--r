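paper_seqs <- primerSequences(paperPrimers())

test_that("an exactly embedded primer yields one mismatch-free site", {
  set.seed(3)
  primer <- "ACGTTGCAGGTCAT"
  tpl <- paste0(random_dna(50), primer, random_dna(50))
  sites <- findBindingSites(primer, c(t1 = tpl), bindingModel(0, 0))
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$strand, "+")
  expect_equal(sites$start, 51L)
  expect_equal(sites$end, 50L + nchar(primer))
  expect_equal(sites$mismatches, 0L)
})

test_that("binding-site search equals the brute-force scan", {
  set.seed(31)
  models <- list(c(0L, 0L), c(2L, 5L), c(3L, 2L))
  for (rep in 1:6) {
    tpl <- random_dna(500)
    ## plant a near-match of a random primer to make hits likely
    primer <- substr(tpl, 101, 122)
    pv <- strsplit(primer, "")[[1]]
    pos <- sample(3:12, 2)
    pv[pos] <- vapply(pv[pos], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
    primer <- paste(pv, collapse = "")
    for (mdl in models) {
      got <- findBindingSites(primer, c(t = tpl),
                              bindingModel(mdl[1], mdl[2]))
      ora <- oracle_sites(primer, tpl, mdl[1], mdl[2])
      expect_equal(as.data.frame(got)[, c("strand", "start", "end",
                                          "mismatches")],
                   ora, ignore_attr = TRUE,
                   info = paste("rep", rep, "mm", mdl[1]))
    }
  }
  ## degenerate codes on both sides
  set.seed(32)
  tpl <- random_dna(300, alphabet = c("A", "C", "G", "T", "N", "R", "Y"))
  primer <- "ACRTGNACYTGA"
  got <- findBindingSites(primer, c(t = tpl), bindingModel(2, 3))
  ora <- oracle_sites(primer, tpl, 2, 3)
  expect_equal(as.data.frame(got)[, c("strand", "start", "end",
                                      "mismatches")],
               ora, ignore_attr = TRUE)
})

test_that("the common reverse binds the fixture at columns 357-379 on the minus strand", {
  aln <- makePaperPanel(seed = 1)
  tpl <- rowSequences(aln)["Cincludens_1"]
  sites <- findBindingSites(paper_seqs["MMRC_1955"], tpl)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$strand, "-")
  expect_equal(sites$start, 357L)
  expect_equal(sites$end, 379L)
})

test_that("PCR simulation reproduces the two published amplicon sizes", {
  aln <- makePaperPanel(seed = 1)
  seqs <- rowSequences(aln)
  for (model in list(bindingModel(0, 0), bindingModel())) {
    ci <- simulatePCR(paper_seqs["MMRC_1964"], paper_seqs["MMRC_1955"],
                      seqs["Cincludens_1"], model)
    expect_equal(nrow(ci), 1L)
    expect_equal(ci$length, 199L)
    expect_equal(nchar(ci$product), 199L)
    expect_equal(ci$product, substr(seqs[["Cincludens_1"]], 181, 379))
    rn <- simulatePCR(paper_seqs["MMRC_1988"], paper_seqs["MMRC_1955"],
                      seqs["Rnu_1"], model)
    expect_equal(rn$length, 299L)
  }
  ## negative control: no binding sites -> no product
  neg <- simulatePCR(paper_seqs["MMRC_1964"], paper_seqs["MMRC_1955"],
                     c(water = random_dna(400)))
  expect_equal(nrow(neg), 0L)
})

test_that("simulation is strand-consistent", {
  aln <- makePaperPanel(seed = 2)
  seqs <- rowSequences(aln)
  fwd <- paper_seqs["MMRC_1964"]; rev <- paper_seqs["MMRC_1955"]
  a1 <- simulatePCR(fwd, rev, seqs["Cincludens_1"])
  ## on the reverse-complement template the primers swap roles
  a2 <- simulatePCR(rev, fwd, c(rc = revComp(seqs[["Cincludens_1"]])))
  expect_equal(sort(a1$length), sort(a2$length))
})

test_that("relaxing the mismatch budget never removes a binding site", {
  set.seed(47)
  for (rep in 1:5) {
    tpl <- random_dna(400)
    primer <- substr(tpl, 201, 220)
    pv <- strsplit(primer, "")[[1]]
    pv[5] <- sample(setdiff(c("A", "C", "G", "T"), pv[5]), 1)
    primer <- paste(pv, collapse = "")
    prev <- NULL
    for (mm in 0:3) {
      s <- findBindingSites(primer, c(t = tpl), bindingModel(mm, 3))
      key <- paste(s$strand, s$start)
      if (!is.null(prev)) expect_true(all(prev %in% key))
      prev <- key
    }
  }
})

test_that("specificity matrix separates the two species and honors the 3' rule", {
  aln <- makePaperPanel(seed = 1)
  panel <- paperAssayPanel()
  m <- specificityMatrix(panel, aln)
  expect_equal(m["C. includens", "MMRC_1964"], "199")
  expect_equal(m["R. nu", "MMRC_1988"], "299")
  expect_equal(m["C. includens", "MMRC_1988"], "")
  expect_equal(m["R. nu", "MMRC_1964"], "")
  expect_true(all(m[c("T. ni", "A. gamma", "A. egena"), ] == ""))
  expect_true(isSpecific(panel, aln))

  ## deleting the forward site empties the row
  seqs <- rowSequences(aln)
  cut <- paste0(substr(seqs[["Cincludens_1"]], 1, 180),
                substr(seqs[["Cincludens_1"]], 208, 657))
  amp <- simulatePCR(primerSequences(paperPrimers())["MMRC_1964"],
                     primerSequences(paperPrimers())["MMRC_1955"],
                     c(cut = cut))
  expect_equal(nrow(amp), 0L)

  ## mutating the forward's 3'-terminal base abolishes the diagonal cell
  tpl <- strsplit(seqs[["Cincludens_1"]], "")[[1]]
  tpl[207] <- setdiff(c("A", "C", "G", "T"), tpl[207])[1]
  amp2 <- simulatePCR(primerSequences(paperPrimers())["MMRC_1964"],
                      primerSequences(paperPrimers())["MMRC_1955"],
                      c(mut = paste(tpl, collapse = "")))
  expect_equal(nrow(amp2), 0L)
})

test_that("amplicon length arithmetic holds for every reported product", {
  set.seed(53)
  for (rep in 1:5) {
    tpl <- random_dna(600)
    f <- substr(tpl, 41, 62)
    r <- revComp(substr(tpl, 341, 364))
    amp <- simulatePCR(c(f = f), c(r = r), c(t = tpl), bindingModel(0, 0))
    expect_true(nrow(amp) >= 1)
    expect_equal(amp$length, amp$end - amp$start + 1L)
    expect_equal(amp$length[1], 364L - 41L + 1L)
  }
})
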