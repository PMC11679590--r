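## IUPAC nucleotide machinery shared by all modules.
##
## Bases are encoded as 4-bit masks (A=1, C=2, G=4, T=8); a degenerate code
## is the bitwise OR of its base set, so two codes are compatible iff the
## AND of their masks is non-zero. Gaps ('-') carry mask 0 and are therefore
## compatible with nothing.

.IUPAC_LETTERS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                    "B", "D", "H", "V", "N")

.iupac_mask <- local({
  m <- integer(256)
  base <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  codes <- Biostrings::IUPAC_CODE_MAP   # e.g. R -> "AG"
  for (code in names(codes)) {
    bits <- sum(base[strsplit(codes[[code]], "")[[1]]])
    m[utf8ToInt(code) + 1L] <- as.integer(bits)
  }
  m
})

## character string -> integer mask vector (one element per residue)
.mask_of <- function(x) {
  .iupac_mask[utf8ToInt(x) + 1L]
}

.char_vec <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' @importFrom Biostrings IUPAC_CODE_MAP
.normalize_residues <- function(x) {
  x <- toupper(x)
  gsub("U", "T", x, fixed = TRUE)
}

## validate residues; returns NULL or the 1-based position of the first
## offending character
.first_bad_residue <- function(x, allow_gap = FALSE) {
  ok <- .IUPAC_LETTERS
  if (allow_gap) ok <- c(ok, "-")
  bad <- which(!.char_vec(x) %in% ok)
  if (length(bad)) bad[1L] else NULL
}

.stop_bad_residue <- function(x, id, allow_gap = FALSE) {
  pos <- .first_bad_residue(x, allow_gap = allow_gap)
  if (!is.null(pos)) {
    stop(sprintf("non-IUPAC character '%s' at position %d in sequence '%s'",
                 substr(x, pos, pos), pos, id), call. = FALSE)
  }
  invisible(TRUE)
}

## G+C probability weight of each IUPAC code: mean over the code's base set
.gc_weight <- local({
  codes <- Biostrings::IUPAC_CODE_MAP
  w <- vapply(codes, function(s) {
    b <- strsplit(s, "")[[1]]
    mean(b %in% c("G", "C"))
  }, numeric(1))
  names(w) <- names(codes)
  w
})

## round half away from zero (base round() is round-half-even)
.round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

.longest_homopolymer <- function(seq) {
  r <- rle(.char_vec(seq))
  max(r$lengths)
}
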