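## Species-diagnostic site scanning and conserved-window discovery.
##
## A diagnostic site for species s is an alignment column where every row
## of s shares one base that differs from the base of every other row,
## under strict (non-degenerate) comparison: if either character is
## degenerate and the IUPAC base sets intersect, the column is treated as
## non-diagnostic (conservative specificity).

#' Find species-diagnostic alignment columns
#'
#' Scans every column for positions where all rows of the target species
#' agree on one residue and every non-target row carries a residue whose
#' IUPAC base set does not intersect the target's. Columns containing gaps
#' are never diagnostic.
#'
#' @param alignment A [BarcodeAlignment-class] with at least one row of the
#'   target species and one of another species.
#' @param targetSpecies Species label to find diagnostics for.
#' @return A [S4Vectors::DataFrame] sorted by column, with \code{column}
#'   (1-based), \code{target_species}, \code{target_base} and
#'   \code{contrast_bases} (a per-species summary string like
#'   \code{"R. nu=G; T. ni=G"}).
#' @examples
#' aln <- barcodeAlignment(c(a = "AAAT", b = "AACT", c = "AACT"),
#'                         species = c("x", "y", "z"))
#' findDiagnosticSites(aln, "x")$column  # column 3
#' @export
findDiagnosticSites <- function(alignment, targetSpecies) {
  sp <- alignment@species
  if (!targetSpecies %in% sp)
    stop("target species not in alignment: ", targetSpecies, call. = FALSE)
  if (all(sp == targetSpecies))
    stop("alignment has no non-target rows", call. = FALSE)
  m <- alignmentMatrix(alignment)
  tgt <- m[sp == targetSpecies, , drop = FALSE]
  oth <- m[sp != targetSpecies, , drop = FALSE]
  oth_sp <- sp[sp != targetSpecies]

  tmask <- matrix(.iupac_mask[utf8ToInt(paste(t(tgt), collapse = "")) + 1L],
                  nrow = nrow(tgt), byrow = TRUE)
  omask <- matrix(.iupac_mask[utf8ToInt(paste(t(oth), collapse = "")) + 1L],
                  nrow = nrow(oth), byrow = TRUE)

  ## target rows must agree exactly and carry a real (non-gap) residue
  agree <- apply(tgt, 2L, function(col) length(unique(col)) == 1L) &
    tgt[1L, ] != "-"
  ## no gap among contrasts, and no base-set overlap with the target
  no_gap <- colSums(oth == "-") == 0L
  trow <- matrix(tmask[1L, ], nrow = nrow(oth), ncol = ncol(oth),
                 byrow = TRUE)
  hits <- bitwAnd(as.integer(omask), as.integer(trow)) > 0L
  dim(hits) <- dim(omask)
  diag_col <- which(agree & no_gap & colSums(hits) == 0L)

  contrast <- vapply(diag_col, function(j) {
    per <- vapply(split(oth[, j], oth_sp), function(b)
      paste(sort(unique(b)), collapse = "/"), character(1))
    paste(paste0(names(per), "=", per), collapse = "; ")
  }, character(1))

  S4Vectors::DataFrame(column = diag_col,
                       target_species = rep(targetSpecies, length(diag_col)),
                       target_base = unname(tgt[1L, diag_col]),
                       contrast_bases = contrast)
}

#' Find maximal conserved gap-free windows
#'
#' Runs of consecutive columns in which every row carries the identical
#' non-gap residue — the regions where a primer common to all panel
#' species can sit.
#'
#' @param alignment A [BarcodeAlignment-class].
#' @param minLength Minimum window length in columns (>= 1).
#' @return An [IRanges::IRanges] of maximal conserved windows (1-based
#'   inclusive), sorted by start.
#' @examples
#' aln <- barcodeAlignment(c(a = "ACGTACGT", b = "ACGAACGT"),
#'                         species = c("x", "y"))
#' findConservedWindows(aln, 4)  # columns 5..8
#' @export
findConservedWindows <- function(alignment, minLength = 1L) {
  stopifnot(minLength >= 1L)
  m <- alignmentMatrix(alignment)
  conserved <- apply(m, 2L, function(col)
    length(unique(col)) == 1L && col[1L] != "-")
  r <- rle(conserved)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= minLength
  IRanges::IRanges(start = starts[keep], end = ends[keep])
}

#' Export diagnostic sites or conserved windows as TSV
#'
#' @param x A DataFrame from [findDiagnosticSites()] or an IRanges from
#'   [findConservedWindows()].
#' @param path Output path.
#' @param bed Logical; also write 0-based half-open coordinates (BED-like
#'   \code{start0}, \code{end} columns) alongside the 1-based ones.
#' @param header Optional \code{#}-prefixed provenance lines.
#' @return Invisibly, \code{path}.
#' @export
writeSiteTable <- function(x, path, bed = FALSE, header = NULL) {
  if (is(x, "IRanges")) {
    tab <- data.frame(start = IRanges::start(x), end = IRanges::end(x),
                      width = IRanges::width(x))
    if (bed) { tab$start0 <- tab$start - 1L }
  } else {
    tab <- as.data.frame(x)
    if (bed && "column" %in% names(tab)) {
      tab$start0 <- tab$column - 1L
      tab$end <- tab$column
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
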