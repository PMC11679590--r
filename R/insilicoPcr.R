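## In silico PCR: primer binding-site search under a mismatch-tolerance
## model, amplicon prediction, and panel specificity matrices.
##
## Matching semantics: a primer position is compatible with a template
## position iff the IUPAC base sets intersect (bitwise AND of 4-bit masks
## is non-zero). A site binds when total mismatches <= maxMismatch and the
## threePrimeExact terminal nucleotides at the primer's 3' end are all
## compatible — the extension-blocking rule that makes a single 3'-terminal
## diagnostic substitution abolish amplification.

#' Construct a binding model
#'
#' @param maxMismatch Total mismatches tolerated anywhere in the primer
#'   (default 2).
#' @param threePrimeExact Number of 3'-terminal positions that must match
#'   exactly (default 5).
#' @param productRange Allowed amplicon length range (default 40..5000 nt).
#' @return A [BindingModel-class].
#' @examples
#' bindingModel()                # the default model
#' bindingModel(0, 0)            # exact matching only
#' @export
bindingModel <- function(maxMismatch = 2L, threePrimeExact = 5L,
                         productRange = c(40L, 5000L)) {
  new("BindingModel", maxMismatch = as.integer(maxMismatch),
      threePrimeExact = as.integer(threePrimeExact),
      productRange = as.integer(productRange))
}

#' @export
setMethod("show", "BindingModel", function(object) {
  cat(sprintf(
    "BindingModel: <=%d mismatches, 3'-terminal %d nt exact, products %d-%d nt\n",
    object@maxMismatch, object@threePrimeExact,
    object@productRange[1L], object@productRange[2L]))
  invisible(NULL)
})

## Scan one pattern along the template plus strand.
## exact_end: "right" = the pattern's 3' end is its right end (a forward
## primer); "left" = its right-to-left orientation puts the 3' end at the
## left end of the plus-strand match (a reverse primer scanned as its
## reverse complement).
.scan_pattern <- function(pattern, template, max_mm, exact_len, exact_end) {
  pm <- .mask_of(pattern)
  tm <- .mask_of(template)
  lp <- length(pm); lt <- length(tm)
  if (lp > lt) return(list(start = integer(0), mism = list()))
  n_off <- lt - lp + 1L
  mm_total <- integer(n_off)
  mm_exact <- integer(n_off)
  if (exact_len > lp) exact_len <- lp
  exact_pos <- if (exact_len == 0L) integer(0)
    else if (exact_end == "right") (lp - exact_len + 1L):lp
    else seq_len(exact_len)
  mism_mat <- matrix(FALSE, nrow = lp, ncol = n_off)
  for (i in seq_len(lp)) {
    bad <- bitwAnd(pm[i], tm[i:(i + n_off - 1L)]) == 0L
    mism_mat[i, ] <- bad
    mm_total <- mm_total + bad
    if (i %in% exact_pos) mm_exact <- mm_exact + bad
  }
  hit <- which(mm_total <= max_mm & mm_exact == 0L)
  list(start = hit,
       mism = lapply(hit, function(o) which(mism_mat[, o])))
}

#' Find primer binding sites on a template
#'
#' Reports all plus-strand matches of the primer (strand \code{+}) and all
#' plus-strand matches of its reverse complement (reported as strand
#' \code{-}), under the binding model. Coordinates are 1-based inclusive on
#' the template plus strand.
#'
#' @param primer Primer sequence 5'->3' (character), optionally named, or a
#'   named length-1 character vector.
#' @param template Template sequence (character, ungapped), optionally
#'   named, or a single-record [Biostrings::DNAStringSet].
#' @param model A [BindingModel-class] (default [bindingModel()]).
#' @param primerName,templateId Labels used in the output when the inputs
#'   are unnamed.
#' @return A [S4Vectors::DataFrame] sorted by start with columns
#'   \code{primer}, \code{template}, \code{strand}, \code{start},
#'   \code{end}, \code{mismatches}, \code{mismatch_positions}
#'   (comma-separated primer 5'->3' positions).
#' @examples
#' findBindingSites("ACGTAC", "TTACGTACTT", bindingModel(0, 0))
#' @export
findBindingSites <- function(primer, template, model = bindingModel(),
                             primerName = NULL, templateId = NULL) {
  if (is(template, "DNAStringSet")) {
    templateId <- templateId %||% names(template)[1L]
    template <- as.character(template[[1L]])
  }
  primerName <- primerName %||% names(primer) %||% "primer"
  templateId <- templateId %||% names(template) %||% "template"
  primer <- .normalize_residues(unname(primer))
  template <- .normalize_residues(unname(template))
  .stop_bad_residue(primer, primerName)
  if (grepl("-", template, fixed = TRUE))
    stop("template must be ungapped", call. = FALSE)
  .stop_bad_residue(template, templateId)
  lp <- nchar(primer)

  plus <- .scan_pattern(primer, template, model@maxMismatch,
                        model@threePrimeExact, "right")
  minus <- .scan_pattern(revComp(primer), template, model@maxMismatch,
                         model@threePrimeExact, "left")

  mk <- function(hits, strand) {
    if (!length(hits$start))
      return(NULL)
    ## mismatch positions are reported in primer 5'->3' coordinates
    mpos <- if (strand == "+") hits$mism
      else lapply(hits$mism, function(p) sort(lp - p + 1L))
    data.frame(primer = primerName, template = templateId, strand = strand,
               start = hits$start, end = hits$start + lp - 1L,
               mismatches = lengths(mpos),
               mismatch_positions = vapply(mpos, paste, character(1),
                                           collapse = ","),
               stringsAsFactors = FALSE)
  }
  out <- rbind(mk(plus, "+"), mk(minus, "-"))
  if (is.null(out))
    out <- data.frame(primer = character(0), template = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), mismatches = integer(0),
                      mismatch_positions = character(0),
                      stringsAsFactors = FALSE)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  S4Vectors::DataFrame(out)
}

#' Simulate PCR on a template
#'
#' Every pairing of a forward plus-strand site with a reverse minus-strand
#' site located 3' of it (forward end < reverse start, non-overlapping)
#' whose product length falls within the model's bounds yields one
#' amplicon. All combinations are reported — extra bands a gel would show
#' are not hidden. An empty result is the in silico negative control.
#'
#' @param forwards Named character vector of forward primer sequences (or a
#'   [PrimerSet-class], in which case its species-forward primers are
#'   used).
#' @param reverse Named length-1 character vector, the reverse primer (when
#'   \code{forwards} is a PrimerSet its common-reverse primer is the
#'   default).
#' @param template Template sequence (named character or single-record
#'   [Biostrings::DNAStringSet]).
#' @param model A [BindingModel-class].
#' @param templateId Template label for the output.
#' @return A [S4Vectors::DataFrame] of amplicons sorted by (start, length):
#'   \code{template}, \code{forward}, \code{reverse}, \code{start},
#'   \code{end}, \code{length}, \code{product}.
#' @examples
#' tpl <- c(t1 = paste0("AAAA", "ACGTACGTAC",
#'                      paste(rep("T", 40), collapse = ""),
#'                      revComp("GGATCCGGAT"), "AAAA"))
#' simulatePCR(c(f = "ACGTACGTAC"), c(r = "GGATCCGGAT"), tpl,
#'             bindingModel(0, 0))
#' @export
simulatePCR <- function(forwards, reverse = NULL, template,
                        model = bindingModel(), templateId = NULL) {
  if (is(forwards, "PrimerSet")) {
    ps <- forwards
    forwards <- primerSequences(ps)[primerRoles(ps) == "species_forward"]
    if (is.null(reverse)) {
      reverse <- primerSequences(ps)[primerRoles(ps) == "common_reverse"]
      if (length(reverse) != 1L)
        stop("PrimerSet must contain exactly one common_reverse primer",
             call. = FALSE)
    }
  }
  if (is.null(reverse)) stop("reverse primer required", call. = FALSE)
  if (is(template, "DNAStringSet")) {
    templateId <- templateId %||% names(template)[1L]
    template <- setNames(as.character(template[[1L]]), templateId)
  }
  templateId <- templateId %||% names(template) %||% "template"
  tpl <- .normalize_residues(unname(template))

  rsites <- findBindingSites(reverse, tpl, model,
                             primerName = names(reverse) %||% "reverse",
                             templateId = templateId)
  rsites <- rsites[rsites$strand == "-", , drop = FALSE]

  res <- list()
  for (k in seq_along(forwards)) {
    fname <- names(forwards)[k] %||% paste0("forward", k)
    fsites <- findBindingSites(forwards[k], tpl, model,
                               primerName = fname, templateId = templateId)
    fsites <- fsites[fsites$strand == "+", , drop = FALSE]
    if (!nrow(fsites) || !nrow(rsites)) next
    for (i in seq_len(nrow(fsites))) for (j in seq_len(nrow(rsites))) {
      fs <- fsites[i, ]; rs <- rsites[j, ]
      if (fs$end >= rs$start) next
      len <- rs$end - fs$start + 1L
      if (len < model@productRange[1L] || len > model@productRange[2L]) next
      res[[length(res) + 1L]] <- data.frame(
        template = templateId, forward = fs$primer, reverse = rs$primer,
        start = fs$start, end = rs$end, length = len,
        product = substr(tpl, fs$start, rs$end),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) {
    out <- data.frame(template = character(0), forward = character(0),
                      reverse = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      product = character(0), stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, res)
    out <- out[order(out$start, out$length), , drop = FALSE]
    rownames(out) <- NULL
  }
  S4Vectors::DataFrame(out)
}

#' Panel specificity matrix
#'
#' Cross-tests every species-forward of a panel (each paired with the
#' common reverse) against one or more templates per species. The panel is
#' specific iff every diagonal cell is non-empty and every off-diagonal
#' cell is empty.
#'
#' @param panel An [AssayPanel-class].
#' @param templates A [Biostrings::DNAStringSet] with species labels in
#'   \code{mcols()$species} (or a [BarcodeAlignment-class]; gaps are
#'   dropped from rows before simulation).
#' @param model A [BindingModel-class].
#' @return A character matrix (species x forward primer) whose cells are
#'   comma-joined sorted amplicon lengths, \code{""} when no product forms.
#' @seealso [isSpecific()]
#' @export
specificityMatrix <- function(panel, templates, model = bindingModel()) {
  if (is(templates, "BarcodeAlignment")) {
    sp <- templates@species
    seqs <- setNames(gsub("-", "", rowSequences(templates), fixed = TRUE),
                     rowIds(templates))
  } else {
    sp <- as.character(mcols(templates)$species)
    seqs <- setNames(as.character(templates), names(templates))
  }
  fwd <- panel@forwards
  rev <- panel@commonReverse
  species <- unique(sp)
  out <- matrix("", nrow = length(species), ncol = length(fwd),
                dimnames = list(species, names(fwd)))
  for (s in species) {
    for (k in seq_along(fwd)) {
      lens <- integer(0)
      for (idx in which(sp == s)) {
        amp <- simulatePCR(fwd[k], rev, seqs[idx], model,
                           templateId = names(seqs)[idx])
        lens <- c(lens, amp$length)
      }
      out[s, k] <- paste(sort(unique(lens)), collapse = ",")
    }
  }
  out
}

#' @describeIn specificityMatrix TRUE iff each forward amplifies its own
#'   species (diagonal non-empty) and nothing else (off-diagonal empty).
#' @export
isSpecific <- function(panel, templates, model = bindingModel()) {
  m <- specificityMatrix(panel, templates, model)
  tgt <- panel@forwardSpecies
  ok <- TRUE
  for (k in seq_along(tgt)) {
    if (!tgt[k] %in% rownames(m)) return(FALSE)
    diag_cell <- m[tgt[k], k]
    off <- m[setdiff(rownames(m), tgt[k]), k]
    ok <- ok && nzchar(diag_cell) && all(!nzchar(off))
  }
  ok
}

#' Write an amplicon table as TSV (optionally products as FASTA)
#'
#' @param amplicons Output of [simulatePCR()].
#' @param path TSV output path.
#' @param fastaPath Optional path for a product FASTA.
#' @param header Optional \code{#}-prefixed provenance lines.
#' @return Invisibly, \code{path}.
#' @export
writeAmpliconTable <- function(amplicons, path, fastaPath = NULL,
                               header = NULL) {
  tab <- as.data.frame(amplicons)
  con <- file(path, "w")
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(tab[, setdiff(names(tab), "product"), drop = FALSE], con,
              sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  if (!is.null(fastaPath) && nrow(tab)) {
    prods <- setNames(tab$product,
                      sprintf("%s_%s_%s_%dbp", tab$template, tab$forward,
                              tab$reverse, tab$length))
    writeBarcodes(DNAStringSet(prods), fastaPath)
  }
  invisible(path)
}
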