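#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' Multiple alignment of species-labelled barcode sequences
#'
#' A gap-aware, equal-width alignment of DNA barcode sequences (e.g. the
#' ~657-bp COI Folmer region) in which every row carries a species label.
#' Columns are addressed 1-based inclusive throughout the package.
#'
#' @slot seqs A [Biostrings::DNAStringSet] of equal-width gapped or gap-free
#'   rows; names are the row ids.
#' @slot species Character vector, one species label per row.
#'
#' @seealso [barcodeAlignment()], [findDiagnosticSites()],
#'   [findConservedWindows()], [percentIdentity()]
#' @export
setClass("BarcodeAlignment",
  representation(seqs = "DNAStringSet", species = "character"))

setValidity("BarcodeAlignment", function(object) {
  s <- object@seqs
  if (length(s) < 2L)
    return("alignment needs at least 2 rows")
  if (length(unique(Biostrings::width(s))) != 1L)
    return("all rows must have equal width")
  if (is.null(names(s)) || anyNA(names(s)) || any(names(s) == ""))
    return("every row must have a non-empty id")
  if (anyDuplicated(names(s)))
    return("row ids must be unique")
  if (length(object@species) != length(s))
    return("species labels must match the number of rows")
  TRUE
})

#' A table of PCR primers with assay roles
#'
#' Holds named oligonucleotides together with their role in the assay:
#' \code{barcoding} (universal amplification/sequencing primers),
#' \code{common_reverse} (binds a region conserved across all panel
#' species) or \code{species_forward} (binds a species-diagnostic region;
#' requires a target species).
#'
#' @slot primers A [Biostrings::DNAStringSet], names are primer names,
#'   sequences written 5'->3'.
#' @slot role Character vector over \code{c("barcoding", "common_reverse",
#'   "species_forward")}.
#' @slot targetSpecies Character vector; \code{NA} unless the role is
#'   \code{species_forward}.
#'
#' @seealso [primerSet()], [readPrimerTable()], [paperPrimers()]
#' @export
setClass("PrimerSet",
  representation(primers = "DNAStringSet", role = "character",
                 targetSpecies = "character"))

.PRIMER_ROLES <- c("barcoding", "common_reverse", "species_forward")

setValidity("PrimerSet", function(object) {
  p <- object@primers
  if (length(p) == 0L) return("empty primer set")
  if (is.null(names(p)) || anyDuplicated(names(p)))
    return("primers must have unique names")
  w <- Biostrings::width(p)
  if (any(w < 10L | w > 40L))
    return("primer lengths must be in [10, 40] nt")
  if (length(object@role) != length(p) ||
      !all(object@role %in% .PRIMER_ROLES))
    return(sprintf("role must be one of %s for every primer",
                   paste(.PRIMER_ROLES, collapse = ", ")))
  if (length(object@targetSpecies) != length(p))
    return("targetSpecies must have one entry per primer")
  fw <- object@role == "species_forward"
  if (any(fw & (is.na(object@targetSpecies) | object@targetSpecies == "")))
    return("species_forward primers require a target species")
  TRUE
})

#' Mismatch-tolerance model for in silico primer binding
#'
#' Governs when a primer is considered to bind a template: at most
#' \code{maxMismatch} incompatible positions overall, none of them within
#' the \code{threePrimeExact} 3'-terminal nucleotides (the polymerase
#' extension end), degenerate codes matching whenever their base sets
#' intersect, and no gaps. Product lengths outside \code{productRange} are
#' discarded by the PCR simulator.
#'
#' @slot maxMismatch Integer, total mismatches tolerated (default 2).
#' @slot threePrimeExact Integer, 3'-terminal run that must match exactly
#'   (default 5).
#' @slot productRange Integer length-2, allowed amplicon size range.
#'
#' @seealso [bindingModel()], [findBindingSites()], [simulatePCR()]
#' @export
setClass("BindingModel",
  representation(maxMismatch = "integer", threePrimeExact = "integer",
                 productRange = "integer"))

setValidity("BindingModel", function(object) {
  if (length(object@maxMismatch) != 1L || object@maxMismatch < 0L)
    return("maxMismatch must be a single non-negative integer")
  if (length(object@threePrimeExact) != 1L || object@threePrimeExact < 0L)
    return("threePrimeExact must be a single non-negative integer")
  if (length(object@productRange) != 2L ||
      object@productRange[1L] > object@productRange[2L] ||
      object@productRange[1L] < 1L)
    return("productRange must be an increasing positive length-2 range")
  TRUE
})

#' Primer QC and panel feasibility constraints for assay design
#'
#' @slot lengthRange Integer length-2, allowed primer lengths (nt).
#' @slot gcRange Numeric length-2, allowed GC content (percent).
#' @slot tmRange Numeric length-2, allowed Wallace-rule melting
#'   temperature (degrees Celsius).
#' @slot maxHomopolymer Integer, longest tolerated single-base run.
#' @slot threePrimeDiagnostic Integer k: a species-forward must cover at
#'   least one diagnostic site within its 3'-terminal k nt.
#' @slot ampliconRange Integer length-2, allowed amplicon sizes (nt).
#' @slot minSeparation Integer, minimum pairwise difference between the
#'   panel's expected amplicon sizes (nt).
#'
#' @seealso [designConstraints()], [assembleAssay()]
#' @export
setClass("DesignConstraints",
  representation(lengthRange = "integer", gcRange = "numeric",
                 tmRange = "numeric", maxHomopolymer = "integer",
                 threePrimeDiagnostic = "integer", ampliconRange = "integer",
                 minSeparation = "integer"))

setValidity("DesignConstraints", function(object) {
  rng <- function(x) length(x) == 2L && x[1L] <= x[2L]
  if (!rng(object@lengthRange)) return("invalid lengthRange")
  if (!rng(object@gcRange)) return("invalid gcRange")
  if (!rng(object@tmRange)) return("invalid tmRange")
  if (!rng(object@ampliconRange)) return("invalid ampliconRange")
  if (object@maxHomopolymer < 1L) return("maxHomopolymer must be >= 1")
  if (object@threePrimeDiagnostic < 1L)
    return("threePrimeDiagnostic must be >= 1")
  if (object@minSeparation < 1L) return("minSeparation (delta) must be >= 1")
  TRUE
})

#' A species-discriminating PCR assay panel
#'
#' One reverse primer common to all panel species plus one species-specific
#' forward primer per species; each species is expected to yield an amplicon
#' of a distinct size, so a sample's species is read off the band size.
#' Expected size for species s is \code{reverseEnd - forwardStart(s) + 1}
#' (both primer footprints included).
#'
#' @slot commonReverse Named character of length 1 (primer name = name,
#'   sequence 5'->3' = value).
#' @slot forwards Named character, one primer per species (names are primer
#'   names); parallel to \code{forwardSpecies}.
#' @slot forwardSpecies Character, target species per forward.
#' @slot expectedSizes Named numeric, species -> expected amplicon size (nt).
#' @slot coords Optional [S4Vectors::DataFrame] with columns \code{primer},
#'   \code{start}, \code{end} (1-based inclusive alignment columns); empty
#'   when the panel was entered by hand without coordinates.
#' @slot tolerance Numeric, band-size call tolerance (nt).
#' @slot minSeparation Numeric, the pairwise size separation the panel
#'   guarantees.
#'
#' @seealso [assayPanel()], [assembleAssay()], [paperAssayPanel()],
#'   [callSpecies()], [specificityMatrix()]
#' @export
setClass("AssayPanel",
  representation(commonReverse = "character", forwards = "character",
                 forwardSpecies = "character", expectedSizes = "numeric",
                 coords = "DataFrame", tolerance = "numeric",
                 minSeparation = "numeric"))

setValidity("AssayPanel", function(object) {
  if (length(object@commonReverse) != 1L ||
      is.null(names(object@commonReverse)))
    return("commonReverse must be a single named sequence")
  n <- length(object@forwards)
  if (n < 1L) return("panel needs at least one forward primer")
  if (length(object@forwardSpecies) != n)
    return("forwardSpecies must parallel forwards")
  if (anyDuplicated(object@forwardSpecies))
    return("one forward primer per species")
  if (!setequal(names(object@expectedSizes), object@forwardSpecies))
    return("expectedSizes must be keyed by the forward target species")
  if (any(object@expectedSizes <= 0))
    return("expected sizes must be positive")
  sz <- object@expectedSizes
  if (length(sz) > 1L) {
    d <- abs(outer(sz, sz, "-"))
    minsep <- min(d[upper.tri(d)])
    if (minsep < object@minSeparation)
      return(sprintf(
        "expected sizes separated by %d nt < required minimum %d nt",
        as.integer(minsep), as.integer(object@minSeparation)))
    if (object@tolerance >= minsep / 2)
      return("tolerance must be < half the minimum size separation")
  }
  ## coordinate arithmetic, when coordinates were recorded
  cc <- object@coords
  if (nrow(cc) > 0L) {
    rev_end <- cc$end[match(names(object@commonReverse), cc$primer)]
    for (i in seq_len(n)) {
      fs <- cc$start[match(names(object@forwards)[i], cc$primer)]
      if (is.na(rev_end) || is.na(fs)) next
      expect <- rev_end - fs + 1
      got <- object@expectedSizes[[object@forwardSpecies[i]]]
      if (expect != got)
        return(sprintf(
          "size arithmetic violated for %s: end - start + 1 = %d but expectedSizes says %d",
          object@forwardSpecies[i], as.integer(expect), as.integer(got)))
    }
  }
  TRUE
})

#' Batch species-composition report from amplicon-size calls
#'
#' @slot calls [S4Vectors::DataFrame] with one row per sample: sample id,
#'   call, matched expected size, deviation (nt).
#' @slot counts Named integer: per-species counts plus \code{no_call} and
#'   \code{ambiguous}.
#' @slot n Integer, number of samples.
#' @slot percentExact Named numeric, exact percentages (100 * count / n).
#' @slot percentDisplay Named numeric, percentages rounded half away from
#'   zero to integers for display.
#'
#' @seealso [classifyBatch()]
#' @export
setClass("ClassificationReport",
  representation(calls = "DataFrame", counts = "integer", n = "integer",
                 percentExact = "numeric", percentDisplay = "numeric"))

setValidity("ClassificationReport", function(object) {
  if (sum(object@counts) != object@n)
    return("counts must sum to n")
  TRUE
})
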