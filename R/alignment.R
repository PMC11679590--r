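## Alignment container, pairwise global alignment, identity statistics.

#' Construct a BarcodeAlignment
#'
#' @param seqs Named character vector or [Biostrings::DNAStringSet] of
#'   equal-width (gapped) rows.
#' @param species Character vector of species labels, one per row; defaults
#'   to the \code{species} column of \code{mcols(seqs)} when present.
#' @return A [BarcodeAlignment-class] object.
#' @examples
#' aln <- barcodeAlignment(c(a = "ACGT", b = "ACTT"),
#'                         species = c("sp1", "sp2"))
#' alignmentWidth(aln)
#' @export
barcodeAlignment <- function(seqs, species = NULL) {
  if (is.character(seqs)) {
    s <- .normalize_residues(seqs)
    for (i in seq_along(s))
      .stop_bad_residue(s[i], names(s)[i] %||% i, allow_gap = TRUE)
    x <- DNAStringSet(s)
    names(x) <- names(seqs)
  } else {
    x <- seqs
  }
  if (is.null(species)) {
    mc <- mcols(x)
    if (!is.null(mc) && "species" %in% colnames(mc)) {
      species <- as.character(mc$species)
    } else {
      stop("species labels required (argument or mcols(seqs)$species)",
           call. = FALSE)
    }
  }
  new("BarcodeAlignment", seqs = x, species = as.character(species))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an aligned FASTA into a BarcodeAlignment
#'
#' @param path Aligned FASTA with \code{species=} keys in the descriptions.
#' @return A [BarcodeAlignment-class].
#' @export
readAlignment <- function(path) {
  s <- readBarcodes(path, aligned = TRUE)
  barcodeAlignment(s)
}

#' Write a BarcodeAlignment as aligned FASTA
#'
#' Species labels are serialized as \code{species=} keys so
#' [readAlignment()] recovers them.
#'
#' @param x A [BarcodeAlignment-class].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeAlignment <- function(x, path) {
  s <- x@seqs
  mcols(s) <- S4Vectors::DataFrame(species = x@species,
                                   description = "")
  writeBarcodes(s, path)
}

#' @describeIn barcodeAlignment Number of columns.
#' @param x,object A [BarcodeAlignment-class].
#' @export
alignmentWidth <- function(x) Biostrings::width(x@seqs)[1L]

#' @describeIn barcodeAlignment Row ids.
#' @export
rowIds <- function(x) names(x@seqs)

#' @describeIn barcodeAlignment Species label per row.
#' @export
rowSpecies <- function(x) setNames(x@species, names(x@seqs))

#' @describeIn barcodeAlignment Alignment as a character matrix
#'   (rows x columns).
#' @export
alignmentMatrix <- function(x) {
  m <- do.call(rbind, strsplit(as.character(x@seqs), "", fixed = TRUE))
  rownames(m) <- names(x@seqs)
  m
}

#' @describeIn barcodeAlignment Row sequences as a named character vector.
#' @export
rowSequences <- function(x) setNames(as.character(x@seqs), names(x@seqs))

#' @export
setMethod("show", "BarcodeAlignment", function(object) {
  cat(sprintf("BarcodeAlignment: %d rows x %d columns\n",
              length(object@seqs), alignmentWidth(object)))
  sp <- object@species
  for (i in seq_along(object@seqs)) {
    s <- as.character(object@seqs[[i]])
    prev <- if (nchar(s) > 40) paste0(substr(s, 1, 40), "...") else s
    cat(sprintf("  %-14s [%s] %s\n", names(object@seqs)[i], sp[i], prev))
  }
  invisible(NULL)
})

#' Needleman-Wunsch global alignment of two sequences
#'
#' Optimal global alignment under a linear gap penalty with deterministic
#' traceback: on score ties the diagonal (match/mismatch) move is preferred,
#' then the vertical (gap in \code{b}), then the horizontal (gap in
#' \code{a}).
#'
#' @param a,b Ungapped sequences (character strings) or single-record
#'   named character vectors.
#' @param match Match score (default 1).
#' @param mismatch Mismatch score (default -1).
#' @param gap Gap score per gapped column (default -2; more costly than a
#'   mismatch, so substitution-only divergence aligns without gaps).
#' @param ids Row ids for the returned alignment.
#' @param species Species labels for the returned alignment.
#' @return A list with \code{alignment} (a [BarcodeAlignment-class]) and
#'   \code{score}.
#' @examples
#' globalAlignPair("ACGT", "ACTT")$score  # 3*1 + 1*(-1) = 2
#' @export
globalAlignPair <- function(a, b, match = 1, mismatch = -1, gap = -2,
                            ids = c("a", "b"),
                            species = c("a", "b")) {
  a <- .normalize_residues(a); b <- .normalize_residues(b)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  if (grepl("-", paste0(a, b), fixed = TRUE))
    stop("inputs must be ungapped", call. = FALSE)
  av <- .char_vec(a); bv <- .char_vec(b)
  n <- length(av); m <- length(bv)
  ## score matrix S[(n+1) x (m+1)], pointers: 1 diag, 2 up (gap in b), 3 left
  S <- matrix(0, n + 1L, m + 1L)
  P <- matrix(0L, n + 1L, m + 1L)
  S[, 1L] <- gap * (0:n); S[1L, ] <- gap * (0:m)
  P[, 1L] <- 2L; P[1L, ] <- 3L; P[1L, 1L] <- 0L
  for (i in seq_len(n)) {
    subst <- ifelse(av[i] == bv, match, mismatch)
    prev <- S[i, ]       # row i-1 (1-based offset)
    cur <- numeric(m + 1L); ptr <- integer(m + 1L)
    cur[1L] <- prev[1L] + gap; ptr[1L] <- 2L
    for (j in seq_len(m)) {
      d <- prev[j] + subst[j]
      u <- prev[j + 1L] + gap
      l <- cur[j] + gap
      best <- max(d, u, l)
      cur[j + 1L] <- best
      ptr[j + 1L] <- if (d == best) 1L else if (u == best) 2L else 3L
    }
    S[i + 1L, ] <- cur; P[i + 1L, ] <- ptr
  }
  ## traceback
  i <- n + 1L; j <- m + 1L
  ga <- character(0); gb <- character(0)
  while (i > 1L || j > 1L) {
    p <- P[i, j]
    if (p == 1L) {
      ga <- c(av[i - 1L], ga); gb <- c(bv[j - 1L], gb)
      i <- i - 1L; j <- j - 1L
    } else if (p == 2L) {
      ga <- c(av[i - 1L], ga); gb <- c("-", gb)
      i <- i - 1L
    } else {
      ga <- c("-", ga); gb <- c(bv[j - 1L], gb)
      j <- j - 1L
    }
  }
  aln <- barcodeAlignment(
    setNames(c(paste(ga, collapse = ""), paste(gb, collapse = "")), ids),
    species = species)
  list(alignment = aln, score = S[n + 1L, m + 1L])
}

#' Percent identity between two alignment rows
#'
#' 100 x identical columns / columns where neither row has a gap. The exact
#' value is returned; round to two decimals for presentation.
#'
#' @param alignment A [BarcodeAlignment-class].
#' @param pair Character vector of two row ids.
#' @return Percent identity in \eqn{[0, 100]}.
#' @examples
#' aln <- barcodeAlignment(c(a = "ACGT", b = "ACTT"), species = c("x", "y"))
#' percentIdentity(aln, c("a", "b"))  # 75
#' @export
percentIdentity <- function(alignment, pair) {
  stopifnot(length(pair) == 2L)
  ids <- rowIds(alignment)
  missing <- setdiff(pair, ids)
  if (length(missing))
    stop("unknown row id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  m <- alignmentMatrix(alignment)
  x <- m[pair[1L], ]; y <- m[pair[2L], ]
  keep <- x != "-" & y != "-"
  if (!any(keep)) stop("no gap-free columns shared by the pair",
                       call. = FALSE)
  100 * sum(x[keep] == y[keep]) / sum(keep)
}

#' Count variable columns among conspecific sequences
#'
#' @param alignment A [BarcodeAlignment-class] whose rows all carry the
#'   same species label (>= 2 rows).
#' @return Number of columns with more than one distinct residue.
#' @export
withinSpeciesVariation <- function(alignment) {
  sp <- unique(alignment@species)
  if (length(sp) != 1L)
    stop("rows carry mixed species labels: ", paste(sp, collapse = ", "),
         call. = FALSE)
  m <- alignmentMatrix(alignment)
  sum(apply(m, 2L, function(col) length(unique(col)) > 1L))
}
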