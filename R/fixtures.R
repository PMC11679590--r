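## Synthetic barcode panels with known ground truth.
##
## The default panel emulates the study system: five Plusiinae COI
## barcodes of 657 gap-free columns, the published diagnostic primers
## embedded verbatim at their published alignment coordinates, and exactly
## 56 substitution columns between the two focal species (601/657 =
## 91.48% identity). Everything is seeded and bit-reproducible.

.TABLE1 <- list(
  name = c("LCO 1490", "HCO 2198", "MMRC_1955", "MMRC_1964", "MMRC_1988"),
  sequence = c("GGTCAACAAATCATAAAGATATTGG",
               "TAAACTTCAGGGTGACCAAAAAATCA",
               "CAGATCTACCACCATGAGCAATA",
               "GGATTTGGTAATTGACTTGTACCTCTT",
               "TCCTGGATCTTTAATTGGAGAT"),
  role = c("barcoding", "barcoding", "common_reverse", "species_forward",
           "species_forward"),
  target_species = c(NA, NA, NA, "C. includens", "R. nu"))

## published binding coordinates (1-based inclusive alignment columns)
.PAPER_COORDS <- data.frame(
  primer = c("MMRC_1955", "MMRC_1964", "MMRC_1988"),
  start = c(357L, 181L, 81L),
  end = c(379L, 207L, 102L),
  stringsAsFactors = FALSE)

.PAPER_SPECIES <- c("C. includens", "R. nu", "T. ni", "A. gamma", "A. egena")
.BARCODE_LEN <- 657L
.FOCAL_DIFFS <- 56L   # 657 - 56 = 601 identical columns -> 91.48%

## run code under a seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' The published diagnostic primer set
#'
#' The two universal barcoding primers, the common reverse (MMRC_1955) and
#' the two species-specific forwards (MMRC_1964 for C. includens,
#' MMRC_1988 for R. nu).
#'
#' @return A [PrimerSet-class].
#' @export
paperPrimers <- function() {
  primerSet(setNames(.TABLE1$sequence, .TABLE1$name),
            role = .TABLE1$role, targetSpecies = .TABLE1$target_species)
}

#' The published two-species assay panel
#'
#' MMRC_1955 (common reverse, alignment columns 357-379) paired with
#' MMRC_1964 (C. includens forward, 181-207) and MMRC_1988 (R. nu forward,
#' 81-102). Expected amplicon sizes are computed from the coordinates as
#' reverse end - forward start + 1: 199 bp for C. includens and 299 bp for
#' R. nu.
#'
#' @param tolerance Band-call tolerance (default 10 nt).
#' @return An [AssayPanel-class].
#' @export
paperAssayPanel <- function(tolerance = 10) {
  cc <- .PAPER_COORDS
  seqs <- setNames(.TABLE1$sequence, .TABLE1$name)
  rev_end <- cc$end[cc$primer == "MMRC_1955"]
  sizes <- c(
    "C. includens" = rev_end - cc$start[cc$primer == "MMRC_1964"] + 1L,
    "R. nu" = rev_end - cc$start[cc$primer == "MMRC_1988"] + 1L)
  assayPanel(
    commonReverse = seqs["MMRC_1955"],
    forwards = seqs[c("MMRC_1964", "MMRC_1988")],
    forwardSpecies = c("C. includens", "R. nu"),
    expectedSizes = sizes, coords = cc, tolerance = tolerance,
    minSeparation = 50)
}

.sample_bases <- function(n, weights = c(A = 0.35, C = 0.15, G = 0.15,
                                         T = 0.35)) {
  sample(names(weights), n, replace = TRUE, prob = weights)
}

.other_base <- function(b) {
  vapply(b, function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1L),
         character(1))
}

#' Generate the paper-faithful five-species barcode panel
#'
#' Builds a 657-column gap-free alignment of five species-labelled COI-like
#' barcodes around an A/T-rich random ancestor:
#' \itemize{
#'   \item the reverse complement of MMRC_1955 sits verbatim at columns
#'     357-379 in every row (the conserved reverse-primer region);
#'   \item the C. includens row carries MMRC_1964 verbatim at 181-207, the
#'     R. nu row carries MMRC_1988 verbatim at 81-102;
#'   \item every non-target row differs from each forward motif at a column
#'     inside the motif's 3'-terminal five positions (one shared contrast
#'     base, making that column species-diagnostic);
#'   \item exactly 56 columns differ between the C. includens and R. nu
#'     rows, reproducing the 91.48 percent between-species identity.
#' }
#'
#' @param seed Integer seed; the panel is bit-reproducible given the seed.
#' @param replicates Copies per species (ids suffixed \code{_1 ... _n});
#'   replicates are identical, emulating zero within-species variation.
#' @return A [BarcodeAlignment-class] of \code{5 * replicates} rows.
#' @export
makePaperPanel <- function(seed = 1L, replicates = 1L) {
  .with_seed(seed, {
    L <- .BARCODE_LEN
    anc <- .sample_bases(L)
    rows <- list()
    for (s in .PAPER_SPECIES) rows[[s]] <- anc

    seqs <- setNames(.TABLE1$sequence, .TABLE1$name)
    rc1955 <- .char_vec(revComp(unname(seqs["MMRC_1955"])))
    m1964 <- .char_vec(unname(seqs["MMRC_1964"]))
    m1988 <- .char_vec(unname(seqs["MMRC_1988"]))
    cc <- .PAPER_COORDS
    span <- function(p) {
      i <- cc$primer == p
      cc$start[i]:cc$end[i]
    }
    for (s in .PAPER_SPECIES) rows[[s]][span("MMRC_1955")] <- rc1955
    rows[["C. includens"]][span("MMRC_1964")] <- m1964
    rows[["R. nu"]][span("MMRC_1988")] <- m1988

    ## one shared contrast base inside each forward's 3'-terminal 5 columns:
    ## abolishes extension on non-target templates and makes the column
    ## species-diagnostic
    ci_col <- cc$end[cc$primer == "MMRC_1964"] - 2L        # column 205
    rn_col <- cc$end[cc$primer == "MMRC_1988"] - 2L        # column 100
    ci_base <- rows[["C. includens"]][ci_col]
    contrast_ci <- sample(setdiff(c("A", "C", "G", "T"), ci_base), 1L)
    for (s in setdiff(.PAPER_SPECIES, "C. includens"))
      rows[[s]][ci_col] <- contrast_ci
    rn_base <- rows[["R. nu"]][rn_col]
    contrast_rn <- sample(setdiff(c("A", "C", "G", "T"), rn_base), 1L)
    for (s in setdiff(.PAPER_SPECIES, "R. nu"))
      rows[[s]][rn_col] <- contrast_rn

    ## top the focal-pair divergence up to exactly 56 columns
    protected <- c(span("MMRC_1955"), span("MMRC_1964"), span("MMRC_1988"))
    d0 <- which(rows[["C. includens"]] != rows[["R. nu"]])
    need <- .FOCAL_DIFFS - length(d0)
    if (need < 0L)
      stop("internal: motif placement exceeds the target divergence")
    free <- setdiff(seq_len(L), c(protected, d0))
    extra <- sort(sample(free, need))
    rows[["R. nu"]][extra] <- .other_base(rows[["R. nu"]][extra])

    ## background divergence for the three outgroup-like rows, away from
    ## every primer footprint so the assay geometry stays untouched
    free_bg <- setdiff(seq_len(L), protected)
    for (s in c("T. ni", "A. gamma", "A. egena")) {
      k <- rbinom(1L, length(free_bg), 0.06)
      mut <- sample(free_bg, k)
      rows[[s]][mut] <- .other_base(rows[[s]][mut])
    }

    ids <- character(0); sp <- character(0); out <- character(0)
    for (s in .PAPER_SPECIES) {
      tag <- gsub("[^A-Za-z]+", "", s)
      for (r in seq_len(replicates)) {
        ids <- c(ids, sprintf("%s_%d", tag, r))
        sp <- c(sp, s)
        out <- c(out, paste(rows[[s]], collapse = ""))
      }
    }
    barcodeAlignment(setNames(out, ids), species = sp)
  })
}

#' Generate a random substitution-only panel with a diagnostic ledger
#'
#' All rows descend from one random ancestor by per-column substitutions
#' (no indels). The returned ledger lists, for every species, the columns
#' where its base differs from every other row — computed by direct
#' bookkeeping on the generated matrix, independently of
#' [findDiagnosticSites()], so it can serve as an oracle.
#'
#' @param nSpecies Number of species (one row each unless
#'   \code{replicates} > 1).
#' @param length Alignment length (>= 100).
#' @param divergence Per-column substitution probability per species, in
#'   \eqn{[0, 1)}.
#' @param seed Integer seed.
#' @param replicates Identical copies per species.
#' @return A list: \code{alignment} (a [BarcodeAlignment-class]) and
#'   \code{ledger} (named list, species -> integer diagnostic columns).
#' @export
makeRandomPanel <- function(nSpecies = 3L, length = 500L, divergence = 0.05,
                            seed = 1L, replicates = 1L) {
  if (length < 100L) stop("length must be >= 100", call. = FALSE)
  if (divergence < 0 || divergence >= 1)
    stop("divergence must be in [0, 1)", call. = FALSE)
  .with_seed(seed, {
    anc <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
    species <- sprintf("sp%02d", seq_len(nSpecies))
    m <- matrix(rep(anc, nSpecies), nrow = nSpecies, byrow = TRUE)
    rownames(m) <- species
    if (divergence > 0) {
      for (i in seq_len(nSpecies)) {
        mut <- which(runif(length) < divergence)
        if (base::length(mut)) m[i, mut] <- .other_base(m[i, mut])
      }
    }
    ## bookkeeping: a column is diagnostic for row i iff its base differs
    ## from the base of every other row
    ledger <- setNames(vector("list", nSpecies), species)
    for (i in seq_len(nSpecies)) {
      others <- m[-i, , drop = FALSE]
      diffall <- colSums(others == matrix(m[i, ], nrow = nSpecies - 1L,
                                          ncol = length,
                                          byrow = TRUE)) == 0L
      ledger[[i]] <- which(diffall)
    }
    ids <- character(0); sp <- character(0); out <- character(0)
    for (i in seq_len(nSpecies)) {
      for (r in seq_len(replicates)) {
        ids <- c(ids, sprintf("%s_%d", species[i], r))
        sp <- c(sp, species[i])
        out <- c(out, paste(m[i, ], collapse = ""))
      }
    }
    list(alignment = barcodeAlignment(setNames(out, ids), species = sp),
         ledger = ledger)
  })
}

#' Generate a synthetic field batch of lanes with truth labels
#'
#' One lane per individual carrying the species' expected band size,
#' optionally jittered to emulate gel sizing noise. Truth labels are
#' returned separately so classification can be scored.
#'
#' @param composition Named integer vector, species -> individual count.
#'   The default is the study composition: 3 C. includens and 16 R. nu.
#' @param panel An [AssayPanel-class] (default [paperAssayPanel()]).
#' @param seed Integer seed.
#' @param jitter Maximum absolute band-size jitter (nt); drawn uniformly
#'   from \code{-jitter..jitter}. Keep below tolerance/2 for guaranteed
#'   recovery.
#' @return A list: \code{lanes} (data.frame with \code{sample_id},
#'   \code{sizes}) and \code{truth} (named character, sample -> species).
#' @export
makeFieldBatch <- function(composition = c("C. includens" = 3L,
                                           "R. nu" = 16L),
                           panel = paperAssayPanel(), seed = 1L,
                           jitter = 0L) {
  bad <- setdiff(names(composition), panelSpecies(panel))
  if (length(bad))
    stop("composition species not in panel: ", paste(bad, collapse = ", "),
         call. = FALSE)
  .with_seed(seed, {
    species <- rep(names(composition), times = composition)
    n <- length(species)
    if (!n)
      return(list(lanes = data.frame(sample_id = character(0),
                                     sizes = character(0),
                                     stringsAsFactors = FALSE),
                  truth = setNames(character(0), character(0))))
    sizes <- unname(panel@expectedSizes[species])
    if (jitter > 0L)
      sizes <- sizes + sample(seq.int(-jitter, jitter), n, replace = TRUE)
    ids <- sprintf("lane%02d", seq_len(n))
    list(lanes = data.frame(sample_id = ids, sizes = as.character(sizes),
                            stringsAsFactors = FALSE),
         truth = setNames(species, ids))
  })
}
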