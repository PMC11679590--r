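## Independent oracles, written from first principles so they share no code
## with the package internals.

## IUPAC base sets, spelled out by hand
ORACLE_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

## complement partner of every code, spelled out by hand
ORACLE_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N")

oracle_compat <- function(a, b) {
  length(intersect(ORACLE_SETS[[a]], ORACLE_SETS[[b]])) > 0
}

oracle_revcomp <- function(s) {
  paste(rev(unname(ORACLE_COMPLEMENT[strsplit(s, "")[[1]]])), collapse = "")
}

## brute-force binding-site search: slide the primer over every offset on
## both strands and count incompatible positions character by character
oracle_sites <- function(primer, template, max_mm, exact3) {
  pv <- strsplit(primer, "")[[1]]
  tv <- strsplit(template, "")[[1]]
  lp <- length(pv); lt <- length(tv)
  res <- data.frame(strand = character(0), start = integer(0),
                    end = integer(0), mismatches = integer(0),
                    stringsAsFactors = FALSE)
  scan1 <- function(pat, strand) {
    for (off in seq_len(lt - length(pat) + 1L)) {
      mm <- 0L; mm3 <- 0L
      for (i in seq_along(pat)) {
        if (!oracle_compat(pat[i], tv[off + i - 1L])) {
          mm <- mm + 1L
          ## the primer 3' end is the right end on '+', the left end on '-'
          in3 <- if (strand == "+") i > length(pat) - exact3
            else i <= exact3
          if (in3) mm3 <- mm3 + 1L
        }
      }
      if (mm <= max_mm && mm3 == 0L)
        res[nrow(res) + 1L, ] <<- list(strand, off,
                                       off + length(pat) - 1L, mm)
    }
  }
  scan1(pv, "+")
  scan1(strsplit(oracle_revcomp(primer), "")[[1]], "-")
  res[order(res$start, res$strand), , drop = FALSE]
}

## brute-force longest complementary run anchored at either 3' end
oracle_dimer <- function(a, b) {
  run_anchor <- function(anchor, other) {
    av <- rev(strsplit(anchor, "")[[1]])            # anchor 3' -> 5'
    ov <- strsplit(other, "")[[1]]                  # other 5' -> 3'
    best <- 0L
    for (j in seq_along(ov)) {
      run <- 0L
      for (i in seq_along(av)) {
        if (j + i - 1L > length(ov)) break
        base_other <- ov[j + i - 1L]
        if (oracle_compat(av[i], ORACLE_COMPLEMENT[[base_other]]))
          run <- run + 1L
        else break
      }
      best <- max(best, run)
    }
    best
  }
  max(run_anchor(a, b), run_anchor(b, a))
}

## exhaustive-recursion optimal global alignment score (linear gaps)
oracle_nw_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  rec <- function(i, j) {
    if (i == 0L) return(gap * j)
    if (j == 0L) return(gap * i)
    av <- substr(a, i, i); bv <- substr(b, j, j)
    max(rec(i - 1L, j - 1L) + if (av == bv) match else mismatch,
        rec(i - 1L, j) + gap,
        rec(i, j - 1L) + gap)
  }
  rec(nchar(a), nchar(b))
}

## per-column diagnostic scan written as a plain loop
oracle_diag_columns <- function(mat, species, target) {
  tgt <- which(species == target)
  oth <- which(species != target)
  cols <- integer(0)
  for (j in seq_len(ncol(mat))) {
    tb <- unique(mat[tgt, j])
    if (length(tb) != 1L || tb == "-") next
    ok <- TRUE
    for (i in oth) {
      ob <- mat[i, j]
      if (ob == "-" || oracle_compat(tb, ob)) { ok <- FALSE; break }
    }
    if (ok) cols <- c(cols, j)
  }
  cols
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_iupac <- function(n) {
  random_dna(n, alphabet = names(ORACLE_SETS))
}

table1_path <- function() {
  system.file("extdata", "table1_primers.tsv", package = "coiDiag")
}

fig4_lanes_path <- function() {
  system.file("extdata", "field_gel_lanes.tsv", package = "coiDiag")
}
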