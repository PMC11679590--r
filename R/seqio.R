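#' coiDiag: species-diagnostic PCR panels from COI barcodes
#'
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom S4Vectors DataFrame
#' @importFrom Biostrings DNAStringSet DNAString readDNAStringSet
#'   writeXStringSet width subseq
#' @importFrom S4Vectors mcols mcols<-
#' @importFrom stats setNames dist rbinom runif
#' @importFrom utils read.delim write.table
"_PACKAGE"

## ---- FASTA ------------------------------------------------------------

#' Read barcode sequences from a FASTA file
#'
#' Residues are case-folded to upper case and U is normalized to T, so a
#' single canonical IUPAC alphabet flows through the package. A species
#' label is parsed from an optional \code{species=<name>} key in the FASTA
#' description and stored in \code{mcols()}. Gap characters are rejected
#' unless \code{aligned = TRUE} (aligned-FASTA dialect).
#'
#' @param path Path to a FASTA file (wrapped or single-line).
#' @param aligned Logical; keep \code{-} gap characters (default FALSE).
#' @return A [Biostrings::DNAStringSet]; names are record ids, and
#'   \code{mcols()} carries \code{species} and \code{description}.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">x species=Toy sp.", "ACGT"), tf)
#' s <- readBarcodes(tf)
#' S4Vectors::mcols(s)$species
#' @export
readBarcodes <- function(path, aligned = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty FASTA file: ", path, call. = FALSE)
  hdr <- grepl("^>", lines)
  if (!hdr[1L]) stop("not FASTA-formatted (no leading '>'): ", path,
                     call. = FALSE)
  rec <- cumsum(hdr)
  headers <- sub("^>", "", lines[hdr])
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) stop("record with empty id", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  seqs <- vapply(split(lines[!hdr], rec[!hdr]),
                 function(x) paste(x, collapse = ""), character(1))
  if (length(seqs) != length(ids) || any(!nzchar(seqs)))
    stop("record with empty sequence", call. = FALSE)
  seqs <- .normalize_residues(unname(seqs))
  for (i in seq_along(seqs)) {
    if (!aligned && grepl("-", seqs[i], fixed = TRUE))
      stop(sprintf(
        "gap character in sequence '%s'; use aligned = TRUE for aligned FASTA",
        ids[i]), call. = FALSE)
    .stop_bad_residue(seqs[i], ids[i], allow_gap = aligned)
  }
  out <- DNAStringSet(seqs)
  names(out) <- ids
  species <- ifelse(grepl("species=", desc),
                    sub('.*species=([^;]+).*', "\\1", desc), NA_character_)
  mcols(out) <- S4Vectors::DataFrame(species = trimws(species),
                                     description = desc)
  out
}

#' Write barcode sequences to FASTA
#'
#' The inverse of [readBarcodes()]: a \code{species} column in
#' \code{mcols()} is serialized as a \code{species=<name>} key in the
#' description so the label round-trips.
#'
#' @param x A [Biostrings::DNAStringSet] (or named character vector).
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return Invisibly, \code{path}.
#' @export
writeBarcodes <- function(x, path, width = 70L) {
  if (is.character(x)) x <- DNAStringSet(x)
  sp <- if (!is.null(mcols(x)) && "species" %in% colnames(mcols(x)))
    mcols(x)$species else rep(NA_character_, length(x))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(x)) {
    hdr <- names(x)[i]
    if (!is.na(sp[i]) && nzchar(sp[i]))
      hdr <- paste0(hdr, " species=", sp[i])
    writeLines(paste0(">", hdr), con)
    s <- as.character(x[[i]])
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

## ---- primer tables ----------------------------------------------------

#' Construct a primer set
#'
#' @param sequences Named character vector of primer sequences (5'->3').
#' @param role Character vector over \code{c("barcoding", "common_reverse",
#'   "species_forward")}, recycled if length 1.
#' @param targetSpecies Character vector of target species (NA except for
#'   species-forward primers).
#' @return A [PrimerSet-class] object.
#' @examples
#' primerSet(c(fwd = "GGATTTGGTAATTGACTTGTACCTCTT"),
#'           role = "species_forward", targetSpecies = "C. includens")
#' @export
primerSet <- function(sequences, role,
                      targetSpecies = rep(NA_character_, length(sequences))) {
  seqs <- .normalize_residues(sequences)
  for (i in seq_along(seqs)) .stop_bad_residue(seqs[i], names(seqs)[i])
  p <- DNAStringSet(seqs)
  names(p) <- names(sequences)
  new("PrimerSet", primers = p,
      role = rep(role, length.out = length(p)),
      targetSpecies = as.character(targetSpecies))
}

#' Read a primer table (TSV)
#'
#' Expected columns: \code{name}, \code{sequence}, \code{role},
#' \code{target_species} (empty unless the role is species_forward).
#' Lines starting with \code{#} are treated as comments.
#'
#' @param path Path to the TSV file.
#' @return A [PrimerSet-class] object.
#' @seealso [writePrimerTable()], [paperPrimers()]
#' @export
readPrimerTable <- function(path) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("name", "sequence", "role")
  if (!all(need %in% names(tab)))
    stop("primer table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  ts <- if ("target_species" %in% names(tab)) {
    x <- trimws(as.character(tab$target_species))
    ifelse(is.na(x) | x == "", NA_character_, x)
  } else rep(NA_character_, nrow(tab))
  primerSet(setNames(tab$sequence, tab$name), role = tab$role,
            targetSpecies = ts)
}

#' Write a primer set as TSV
#'
#' @param x A [PrimerSet-class].
#' @param path Output path.
#' @param header Optional character vector of \code{#}-prefixed provenance
#'   lines written above the table.
#' @return Invisibly, \code{path}.
#' @export
writePrimerTable <- function(x, path, header = NULL) {
  tab <- data.frame(name = names(x@primers),
                    sequence = as.character(x@primers),
                    role = x@role,
                    target_species = ifelse(is.na(x@targetSpecies), "",
                                            x@targetSpecies),
                    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- PrimerSet accessors ----------------------------------------------

#' @describeIn primerSet Primer names.
#' @param x,object A [PrimerSet-class].
#' @export
primerNames <- function(x) names(x@primers)

#' @describeIn primerSet Primer sequences as a named character vector.
#' @export
primerSequences <- function(x) setNames(as.character(x@primers),
                                        names(x@primers))

#' @describeIn primerSet Assay roles.
#' @export
primerRoles <- function(x) setNames(x@role, names(x@primers))

#' @describeIn primerSet Target species (NA unless species-forward).
#' @export
primerTargets <- function(x) setNames(x@targetSpecies, names(x@primers))

#' @export
setMethod("show", "PrimerSet", function(object) {
  cat(sprintf("PrimerSet with %d primers\n", length(object@primers)))
  w <- Biostrings::width(object@primers)
  for (i in seq_along(object@primers)) {
    tgt <- if (is.na(object@targetSpecies[i])) "" else
      paste0(" -> ", object@targetSpecies[i])
    cat(sprintf("  %-12s %-30s %2d nt  %s%s\n",
                names(object@primers)[i],
                as.character(object@primers[[i]]), w[i],
                object@role[i], tgt))
  }
  invisible(NULL)
})

## ---- alphabet operations ----------------------------------------------

#' Reverse complement honoring IUPAC degenerate codes
#'
#' @param seq A character string of IUPAC nucleotide codes (or a
#'   [Biostrings::DNAStringSet]/DNAString).
#' @return The reverse complement, same type as the input (character in,
#'   character out). Applying twice returns the input.
#' @examples
#' revComp("ACGT")  # self-reverse-complementary
#' revComp("RN")    # degenerate codes: "NY"
#' @export
revComp <- function(seq) {
  if (is.character(seq)) {
    vapply(seq, function(s) {
      s <- .normalize_residues(s)
      .stop_bad_residue(s, "input")
      as.character(Biostrings::reverseComplement(DNAString(s)))
    }, character(1), USE.NAMES = !is.null(names(seq)))
  } else {
    Biostrings::reverseComplement(seq)
  }
}

#' GC content with fractional weights for degenerate codes
#'
#' Each IUPAC code contributes the mean G+C probability of its base set
#' (S = 1, W = 0, N = 0.5, ...), an unbiased default for ambiguous
#' positions.
#'
#' @param seq Character string over the IUPAC alphabet.
#' @return GC percentage in \eqn{[0, 100]}.
#' @examples
#' gcContent("GGCC")  # 100
#' gcContent("ATAT")  # 0
#' @export
gcContent <- function(seq) {
  seq <- .normalize_residues(seq)
  .stop_bad_residue(seq, "input")
  ch <- .char_vec(seq)
  if (!length(ch)) stop("empty sequence", call. = FALSE)
  100 * mean(.gc_weight[ch])
}

#' Wallace-rule melting temperature
#'
#' Tm = 2 (#A + #T) + 4 (#G + #C) degrees Celsius; the quick estimate
#' used for short oligos. Degenerate codes are an error unless
#' \code{resolve = "mean"}, which scores each code by its expected A/T vs
#' G/C composition.
#'
#' @param seq Character string over the IUPAC alphabet.
#' @param resolve \code{"error"} (default) or \code{"mean"}.
#' @return Tm in degrees Celsius.
#' @examples
#' wallaceTm("AT")  # 4
#' wallaceTm("GC")  # 8
#' @export
wallaceTm <- function(seq, resolve = c("error", "mean")) {
  resolve <- match.arg(resolve)
  seq <- .normalize_residues(seq)
  .stop_bad_residue(seq, "input")
  ch <- .char_vec(seq)
  if (any(!ch %in% c("A", "C", "G", "T")) && resolve == "error")
    stop("degenerate bases present; pass resolve = \"mean\" to score them",
         call. = FALSE)
  gc <- .gc_weight[ch]
  sum(2 * (1 - gc) + 4 * gc)
}
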