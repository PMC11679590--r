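## Virtual gel calling: observed band sizes -> species calls and batch
## composition reports.

#' Call a species from observed band sizes
#'
#' A band matches a species when it lies within \code{tolerance} of that
#' species' expected amplicon size. The call is the single matched species
#' when exactly one species is matched across all bands, \code{no_call}
#' when no band matches anything (including an empty lane), and
#' \code{ambiguous} when bands match two or more species or one band is
#' within tolerance of two expected sizes.
#'
#' @param sizes Numeric vector of observed band sizes (nt); may be empty.
#' @param panel An [AssayPanel-class].
#' @param tolerance Band tolerance in nt; defaults to the panel's.
#' @return A one-row [S4Vectors::DataFrame]: \code{call},
#'   \code{matched_size}, \code{deviation}.
#' @examples
#' p <- paperAssayPanel()
#' callSpecies(199, p)$call        # "C. includens"
#' callSpecies(numeric(0), p)$call # "no_call"
#' @export
callSpecies <- function(sizes, panel, tolerance = panel@tolerance) {
  .check_tolerance(panel, tolerance)
  sizes <- sizes[!is.na(sizes)]
  if (length(sizes) && any(sizes <= 0))
    stop("band sizes must be positive", call. = FALSE)
  exp <- panel@expectedSizes
  matched <- character(0)
  best_size <- NA_real_; best_dev <- NA_real_
  for (b in sizes) {
    hit <- names(exp)[abs(exp - b) <= tolerance]
    if (length(hit) >= 2L) {                 # one band, two species
      return(S4Vectors::DataFrame(call = "ambiguous",
                                  matched_size = NA_real_,
                                  deviation = NA_real_))
    }
    if (length(hit) == 1L) {
      matched <- union(matched, hit)
      dev <- abs(exp[[hit]] - b)
      if (is.na(best_dev) || dev < best_dev) {
        best_dev <- dev; best_size <- exp[[hit]]
      }
    }
  }
  if (length(matched) == 0L)
    return(S4Vectors::DataFrame(call = "no_call", matched_size = NA_real_,
                                deviation = NA_real_))
  if (length(matched) > 1L)
    return(S4Vectors::DataFrame(call = "ambiguous", matched_size = NA_real_,
                                deviation = NA_real_))
  S4Vectors::DataFrame(call = matched, matched_size = best_size,
                       deviation = best_dev)
}

.check_tolerance <- function(panel, tolerance) {
  exp <- panel@expectedSizes
  if (length(exp) > 1L) {
    d <- abs(outer(exp, exp, "-"))
    minsep <- min(d[upper.tri(d)])
    if (tolerance >= minsep / 2)
      stop(sprintf(paste(
        "configuration error: tolerance %g >= half the minimum expected-size",
        "separation %g"), tolerance, minsep), call. = FALSE)
  }
  invisible(TRUE)
}

#' Classify a batch of lanes into a composition report
#'
#' Applies [callSpecies()] to every lane and aggregates counts. Exact
#' percentages (100 x count / n) are retained; display percentages are
#' rounded half away from zero to integers.
#'
#' @param lanes A data.frame with columns \code{sample_id} and \code{sizes}
#'   (comma-separated band sizes, empty string = no amplification), e.g.
#'   from [readLaneTable()] or [makeFieldBatch()].
#' @param panel An [AssayPanel-class].
#' @param tolerance Band tolerance in nt; defaults to the panel's.
#' @return A [ClassificationReport-class].
#' @examples
#' lanes <- data.frame(sample_id = c("s1", "s2"), sizes = c("199", "299"))
#' classifyBatch(lanes, paperAssayPanel())
#' @export
classifyBatch <- function(lanes, panel, tolerance = panel@tolerance) {
  stopifnot(nrow(lanes) >= 1L, all(c("sample_id", "sizes") %in% names(lanes)))
  calls <- lapply(seq_len(nrow(lanes)), function(i) {
    sz <- .parse_sizes(lanes$sizes[i])
    cbind(S4Vectors::DataFrame(sample_id = lanes$sample_id[i]),
          callSpecies(sz, panel, tolerance))
  })
  calls <- do.call(rbind, calls)
  n <- nrow(calls)
  lev <- c(panel@forwardSpecies, "no_call", "ambiguous")
  counts <- table(factor(calls$call, levels = lev))
  counts <- setNames(as.integer(counts), names(counts))
  pct <- 100 * counts / n
  new("ClassificationReport", calls = calls, counts = counts,
      n = as.integer(n), percentExact = pct,
      percentDisplay = .round_half_away(pct))
}

.parse_sizes <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(numeric(0))
  as.numeric(strsplit(trimws(x), "[,;]\\s*")[[1]])
}

#' @describeIn classifyBatch Per-sample calls as a DataFrame.
#' @param x,object A [ClassificationReport-class].
#' @export
sampleCalls <- function(x) x@calls

#' @describeIn classifyBatch Named per-category counts.
#' @export
callCounts <- function(x) x@counts

#' @describeIn classifyBatch Display percentages (integers, half away from
#'   zero).
#' @export
displayPercent <- function(x) x@percentDisplay

#' @describeIn classifyBatch Exact percentages.
#' @export
exactPercent <- function(x) x@percentExact

#' @export
setMethod("show", "ClassificationReport", function(object) {
  cat(sprintf("ClassificationReport: %d samples\n", object@n))
  for (k in names(object@counts)) {
    if (object@counts[[k]] == 0L && k %in% c("no_call", "ambiguous")) next
    cat(sprintf("  %-16s %3d  (%d%%)\n", k, object@counts[[k]],
                as.integer(object@percentDisplay[[k]])))
  }
  invisible(NULL)
})

#' Read a lane table (TSV)
#'
#' Columns: \code{sample_id} and \code{sizes} (comma-separated band sizes,
#' empty = no amplification). \code{#} lines are comments.
#'
#' @param path Path to the TSV.
#' @return A data.frame suitable for [classifyBatch()].
#' @export
readLaneTable <- function(path) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = "character")
  if (!all(c("sample_id", "sizes") %in% names(tab)))
    stop("lane table needs columns sample_id, sizes", call. = FALSE)
  tab
}

#' Write a classification report as TSV and/or JSON
#'
#' @param report A [ClassificationReport-class].
#' @param tsvPath,jsonPath Output paths (either may be NULL).
#' @param header Optional \code{#}-prefixed provenance lines for the TSV.
#' @return Invisibly, the first non-NULL path.
#' @export
writeClassificationReport <- function(report, tsvPath = NULL,
                                      jsonPath = NULL, header = NULL) {
  if (!is.null(tsvPath)) {
    con <- file(tsvPath, "w")
    if (!is.null(header)) writeLines(paste0("# ", header), con)
    write.table(as.data.frame(report@calls), con, sep = "\t", quote = FALSE,
                row.names = FALSE)
    close(con)
  }
  if (!is.null(jsonPath)) {
    jsonlite::write_json(
      list(n = report@n, counts = as.list(report@counts),
           percent_exact = as.list(report@percentExact),
           percent_display = as.list(report@percentDisplay),
           calls = as.data.frame(report@calls)),
      jsonPath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(tsvPath %||% jsonPath)
}
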