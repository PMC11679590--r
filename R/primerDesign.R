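## Assay panel design: candidate enumeration under QC constraints and a
## lexicographic search for one common reverse + per-species forwards with
## size-separated amplicons.

#' Construct design constraints
#'
#' Defaults enclose typical diagnostic COI primers: length 18-28 nt, GC
#' 30-60 percent, Wallace Tm 50-75 C (A/T-rich insect mtDNA pushes long
#' diagnostic primers toward the warm end), homopolymer runs of at most 4,
#' at
#' least one diagnostic site within the 3'-terminal 5 nt of a
#' species-forward, amplicons 80-1000 nt, and pairwise amplicon-size
#' separation of at least 50 nt.
#'
#' @param lengthRange,gcRange,tmRange,maxHomopolymer,threePrimeDiagnostic,ampliconRange,minSeparation
#'   See [DesignConstraints-class].
#' @return A [DesignConstraints-class].
#' @export
designConstraints <- function(lengthRange = c(18L, 28L),
                              gcRange = c(30, 60),
                              tmRange = c(50, 75),
                              maxHomopolymer = 4L,
                              threePrimeDiagnostic = 5L,
                              ampliconRange = c(80L, 1000L),
                              minSeparation = 50L) {
  new("DesignConstraints",
      lengthRange = as.integer(lengthRange), gcRange = as.numeric(gcRange),
      tmRange = as.numeric(tmRange),
      maxHomopolymer = as.integer(maxHomopolymer),
      threePrimeDiagnostic = as.integer(threePrimeDiagnostic),
      ampliconRange = as.integer(ampliconRange),
      minSeparation = as.integer(minSeparation))
}

#' @export
setMethod("show", "DesignConstraints", function(object) {
  cat(sprintf(paste0(
    "DesignConstraints: length %d-%d nt, GC %.0f-%.0f%%, Tm %.0f-%.0f C,\n",
    "  homopolymer <= %d, 3' diagnostic within %d nt, amplicon %d-%d nt,\n",
    "  min size separation %d nt\n"),
    object@lengthRange[1L], object@lengthRange[2L],
    object@gcRange[1L], object@gcRange[2L],
    object@tmRange[1L], object@tmRange[2L],
    object@maxHomopolymer, object@threePrimeDiagnostic,
    object@ampliconRange[1L], object@ampliconRange[2L],
    object@minSeparation))
  invisible(NULL)
})

## QC margin: distance of (GC, Tm) to the nearest constraint bound; larger
## is safer. Used as the secondary lexicographic objective.
.qc_margin <- function(gc, tm, constraints) {
  min(gc - constraints@gcRange[1L], constraints@gcRange[2L] - gc,
      tm - constraints@tmRange[1L], constraints@tmRange[2L] - tm)
}

#' Enumerate primer candidates within an alignment window
#'
#' All subsequences of the allowed lengths whose span lies inside the
#' window and that pass the GC / Tm / homopolymer filters, taken from one
#' species' row. Forward candidates are the plus-strand slice; reverse
#' candidates are the reverse complement of the slice. Candidates are
#' returned in deterministic (start, then length) order.
#'
#' @param alignment A [BarcodeAlignment-class].
#' @param window Length-2 integer (start, end), 1-based inclusive columns,
#'   or an [IRanges::IRanges] of length 1.
#' @param strand \code{"forward"} or \code{"reverse"}.
#' @param constraints A [DesignConstraints-class].
#' @param species Row selector; defaults to the first row whose window
#'   slice is gap-free.
#' @param diagnosticSites Optional output of [findDiagnosticSites()]; when
#'   supplied, the covered diagnostic columns are recorded per candidate.
#' @return A [S4Vectors::DataFrame]: \code{sequence}, \code{start},
#'   \code{end}, \code{strand}, \code{gc}, \code{tm}, \code{homopolymer},
#'   \code{qc_margin}, \code{diagnostic_columns} (comma-separated),
#'   \code{diag_in_3prime} (count within the 3'-terminal k nt).
#' @export
enumerateCandidates <- function(alignment, window, strand = c("forward",
                                "reverse"), constraints = designConstraints(),
                                species = NULL, diagnosticSites = NULL) {
  strand <- match.arg(strand)
  if (is(window, "IRanges"))
    window <- c(IRanges::start(window)[1L], IRanges::end(window)[1L])
  w0 <- as.integer(window[1L]); w1 <- as.integer(window[2L])
  L <- alignmentWidth(alignment)
  if (w0 < 1L || w1 > L || w0 > w1)
    stop(sprintf("window [%d, %d] outside alignment of %d columns",
                 w0, w1, L), call. = FALSE)
  m <- alignmentMatrix(alignment)
  if (is.null(species)) {
    gapless <- which(apply(m[, w0:w1, drop = FALSE], 1L,
                           function(r) all(r != "-")))
    if (!length(gapless))
      stop("window is gap-free for no row", call. = FALSE)
    row <- gapless[1L]
  } else {
    row <- which(alignment@species == species)[1L]
    if (is.na(row)) stop("species not in alignment: ", species,
                         call. = FALSE)
  }
  rowseq <- m[row, ]
  diag_cols <- if (is.null(diagnosticSites)) integer(0)
    else as.integer(diagnosticSites$column)

  out <- list()
  k <- constraints@threePrimeDiagnostic
  for (start in w0:w1) {
    for (len in constraints@lengthRange[1L]:constraints@lengthRange[2L]) {
      end <- start + len - 1L
      if (end > w1) break
      slice <- rowseq[start:end]
      if (any(slice == "-")) next
      plus <- paste(slice, collapse = "")
      seq <- if (strand == "forward") plus else revComp(plus)
      gc <- gcContent(seq)
      tm <- wallaceTm(seq, resolve = "mean")
      hp <- .longest_homopolymer(seq)
      if (gc < constraints@gcRange[1L] || gc > constraints@gcRange[2L]) next
      if (tm < constraints@tmRange[1L] || tm > constraints@tmRange[2L]) next
      if (hp > constraints@maxHomopolymer) next
      covered <- diag_cols[diag_cols >= start & diag_cols <= end]
      ## the 3' end sits at `end` for a forward, at `start` for a reverse
      three_prime <- if (strand == "forward")
        covered[covered > end - k] else covered[covered < start + k]
      out[[length(out) + 1L]] <- data.frame(
        sequence = seq, start = start, end = end, strand = strand,
        gc = gc, tm = tm, homopolymer = hp,
        qc_margin = .qc_margin(gc, tm, constraints),
        diagnostic_columns = paste(covered, collapse = ","),
        diag_in_3prime = length(three_prime), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    tab <- data.frame(sequence = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      gc = numeric(0), tm = numeric(0),
                      homopolymer = integer(0), qc_margin = numeric(0),
                      diagnostic_columns = character(0),
                      diag_in_3prime = integer(0), stringsAsFactors = FALSE)
  } else {
    tab <- do.call(rbind, out)
    tab <- tab[order(tab$start, tab$end - tab$start), , drop = FALSE]
    rownames(tab) <- NULL
  }
  S4Vectors::DataFrame(tab)
}

#' Construct an assay panel by hand
#'
#' @param commonReverse Named length-1 character (primer name = sequence).
#' @param forwards Named character of forward sequences, parallel to
#'   \code{forwardSpecies}.
#' @param forwardSpecies Target species per forward.
#' @param expectedSizes Named numeric, species -> expected amplicon (nt).
#' @param coords Optional data.frame with \code{primer}, \code{start},
#'   \code{end} (1-based inclusive); when present the size arithmetic
#'   \code{reverse end - forward start + 1} is validated.
#' @param tolerance Band-size tolerance for calling (default 10 nt).
#' @param minSeparation Guaranteed pairwise size separation (default 50).
#' @return An [AssayPanel-class].
#' @export
assayPanel <- function(commonReverse, forwards, forwardSpecies,
                       expectedSizes, coords = NULL, tolerance = 10,
                       minSeparation = 50) {
  cc <- if (is.null(coords))
    S4Vectors::DataFrame(primer = character(0), start = integer(0),
                         end = integer(0))
  else S4Vectors::DataFrame(coords)
  new("AssayPanel", commonReverse = commonReverse, forwards = forwards,
      forwardSpecies = forwardSpecies, expectedSizes = expectedSizes,
      coords = cc, tolerance = as.numeric(tolerance),
      minSeparation = as.numeric(minSeparation))
}

#' @describeIn assayPanel Expected amplicon sizes (named by species).
#' @param x,object An [AssayPanel-class].
#' @export
expectedSizes <- function(x) x@expectedSizes

#' @describeIn assayPanel Species covered by the panel.
#' @export
panelSpecies <- function(x) unname(x@forwardSpecies)

#' @describeIn assayPanel All panel primers as a [PrimerSet-class].
#' @export
panelPrimers <- function(x) {
  primerSet(c(x@commonReverse, x@forwards),
            role = c("common_reverse",
                     rep("species_forward", length(x@forwards))),
            targetSpecies = c(NA_character_, x@forwardSpecies))
}

#' @export
setMethod("show", "AssayPanel", function(object) {
  cat("AssayPanel\n")
  cat(sprintf("  common reverse : %s (%s)\n",
              names(object@commonReverse), object@commonReverse))
  for (i in seq_along(object@forwards)) {
    sp <- object@forwardSpecies[i]
    cat(sprintf("  forward [%s]: %s (%s) -> %d bp\n", sp,
                names(object@forwards)[i], object@forwards[i],
                as.integer(object@expectedSizes[[sp]])))
  }
  cat(sprintf("  call tolerance +/- %g nt, min size separation %g nt\n",
              object@tolerance, object@minSeparation))
  invisible(NULL)
})

#' 3'-end cross-dimer check for a primer pair
#'
#' Score = the longest perfect Watson-Crick complementary run anchored at
#' either primer's 3' terminus against any position of the other primer
#' (both orientations of annealing are covered by anchoring each 3' end in
#' turn). Fails when the score exceeds the threshold.
#'
#' @param a,b Primer sequences 5'->3' (character).
#' @param max3prime Longest tolerated anchored complementary run
#'   (default 4).
#' @return A list with \code{score} and \code{pass}.
#' @examples
#' crossDimer3p("AAAA", "TTTT", max3prime = 3)  # score 4, fail
#' @export
crossDimer3p <- function(a, b, max3prime = 4L) {
  a <- .normalize_residues(a); b <- .normalize_residues(b)
  score <- max(.anchored_run(a, b), .anchored_run(b, a))
  list(score = score, pass = score <= max3prime)
}

## Longest complementary run anchored at the 3' end of `anchor` against
## every annealing register of `other`. Antiparallel duplex: the anchor
## read 3'->5' pairs against the other primer read 5'->3', so position i
## from the anchor's 3' end must complement other[j + i - 1] for a run to
## extend. Degenerate codes pair when the base sets intersect.
.anchored_run <- function(anchor, other) {
  am <- rev(.mask_of(anchor))          # anchor 3' -> 5'
  cm <- .mask_of(as.character(
    Biostrings::complement(DNAString(other))))  # complement, 5' -> 3'
  best <- 0L
  for (j in seq_along(cm)) {
    run <- 0L
    i <- 1L
    while (i <= length(am) && j + i - 1L <= length(cm) &&
           bitwAnd(am[i], cm[j + i - 1L]) > 0L) {
      run <- run + 1L
      i <- i + 1L
    }
    best <- max(best, run)
  }
  best
}

#' Assemble a species-discriminating assay panel
#'
#' Automates the design procedure: the common reverse primer is drawn from
#' conserved gap-free windows (as the reverse complement of the plus
#' strand), each species-forward from regions covering at least one
#' diagnostic site for its species within the 3'-terminal k nt, and the
#' combination is chosen lexicographically — first maximizing the minimum
#' pairwise amplicon-size separation (which must meet the constraint
#' minimum), then the minimum per-primer QC margin. Ties break toward
#' smaller start coordinate, then shorter primer, making the search
#' deterministic and invariant to input row order.
#'
#' @param alignment A [BarcodeAlignment-class].
#' @param targetSpecies Character vector (>= 2) of species to discriminate.
#' @param constraints A [DesignConstraints-class].
#' @param tolerance Band-call tolerance stored in the panel (default 10).
#' @param nAlternatives Number of ranked runner-up panels to return.
#' @param verify Logical; confirm the winning panel by in silico PCR
#'   against the alignment rows and refuse non-specific panels
#'   (default TRUE).
#' @return A list with \code{panel} (an [AssayPanel-class]) and
#'   \code{alternatives} (list of the same shape). If no feasible panel
#'   exists an error of class \code{coiDiag_infeasible} is thrown whose
#'   message names the first constraint that emptied the search.
#' @export
assembleAssay <- function(alignment, targetSpecies,
                          constraints = designConstraints(), tolerance = 10,
                          nAlternatives = 3L, verify = TRUE) {
  if (length(targetSpecies) < 2L)
    .infeasible("need at least two target species to discriminate")
  missing <- setdiff(targetSpecies, alignment@species)
  if (length(missing))
    .infeasible(paste("species not in alignment:",
                      paste(missing, collapse = ", ")))

  minlen <- constraints@lengthRange[1L]
  windows <- findConservedWindows(alignment, minlen)
  if (!length(windows))
    .infeasible(sprintf(
      "no conserved window of >= %d columns for a common reverse primer",
      minlen))

  ## reverse candidates from every conserved window
  revs <- do.call(rbind, lapply(seq_along(windows), function(i) {
    as.data.frame(enumerateCandidates(
      alignment, windows[i], "reverse", constraints))
  }))
  if (is.null(revs) || !nrow(revs))
    .infeasible("no conserved-window reverse candidate passes primer QC")

  ## forward candidates per species, 3'-anchored on diagnostic sites;
  ## only ends within k of a diagnostic column can qualify, so enumerate
  ## just those. Candidates sharing a start give the same amplicon size:
  ## keep the one with the best QC margin (ties: shorter primer).
  fwd_by_sp <- list()
  for (s in targetSpecies) {
    sites <- findDiagnosticSites(alignment, s)
    if (!nrow(sites))
      .infeasible(paste("no diagnostic site for species", s))
    cand <- .forward_candidates(alignment, s, sites, constraints)
    if (!nrow(cand))
      .infeasible(paste("no forward candidate with a 3'-terminal",
                        "diagnostic site passes QC for species", s))
    ord <- order(cand$start, -cand$qc_margin, cand$end - cand$start)
    cand <- cand[ord, , drop = FALSE]
    fwd_by_sp[[s]] <- cand[!duplicated(cand$start), , drop = FALSE]
  }

  ## search: for each reverse candidate, pick one forward per species;
  ## per reverse only the few best combos are retained, then all retained
  ## solutions are ranked globally
  amp0 <- constraints@ampliconRange[1L]; amp1 <- constraints@ampliconRange[2L]
  delta <- constraints@minSeparation
  keep_per_rev <- max(nAlternatives + 1L, 4L)
  solutions <- list()
  revs <- revs[order(revs$start, revs$end - revs$start), , drop = FALSE]
  for (r in seq_len(nrow(revs))) {
    rv <- revs[r, ]
    feas <- lapply(targetSpecies, function(s) {
      f <- fwd_by_sp[[s]]
      sz <- rv$end - f$start + 1L
      keep <- f$end < rv$start & sz >= amp0 & sz <= amp1
      cbind(f[keep, , drop = FALSE], size = sz[keep])
    })
    names(feas) <- targetSpecies
    if (any(vapply(feas, nrow, integer(1)) == 0L)) next
    combos <- .combo_grid(lapply(feas, function(f) f$size), delta)
    if (!nrow(combos)) next
    ## vectorized combo metrics
    sizes_mat <- vapply(seq_along(feas), function(k)
      feas[[k]]$size[combos[, k]], numeric(nrow(combos)))
    margin_mat <- vapply(seq_along(feas), function(k)
      feas[[k]]$qc_margin[combos[, k]], numeric(nrow(combos)))
    start_mat <- vapply(seq_along(feas), function(k)
      feas[[k]]$start[combos[, k]], numeric(nrow(combos)))
    len_mat <- vapply(seq_along(feas), function(k) {
      f <- feas[[k]]
      (f$end - f$start + 1)[combos[, k]]
    }, numeric(nrow(combos)))
    if (nrow(combos) == 1L) {
      dim(sizes_mat) <- dim(margin_mat) <- dim(start_mat) <-
        dim(len_mat) <- c(1L, length(feas))
    }
    minsep <- apply(sizes_mat, 1L, function(sz)
      if (length(sz) > 1L) min(dist(sz)) else Inf)
    margin <- pmin(rv$qc_margin, apply(margin_mat, 1L, min))
    ord <- order(-minsep, -margin, rowSums(start_mat), rowSums(len_mat))
    take <- utils::head(ord, keep_per_rev)
    for (i in take) {
      cm <- lapply(seq_along(feas), function(k)
        as.list(feas[[k]][combos[i, k], ]))
      names(cm) <- targetSpecies
      solutions[[length(solutions) + 1L]] <-
        list(reverse = rv, forwards = cm, sizes = sizes_mat[i, ],
             minsep = minsep[i], margin = margin[i],
             key = c(-minsep[i], -margin[i], rv$start,
                     rv$end - rv$start, sum(start_mat[i, ]),
                     sum(len_mat[i, ])))
    }
  }
  if (!length(solutions))
    .infeasible(sprintf(paste(
      "no combination satisfies amplicon range [%d, %d] with pairwise",
      "size separation >= %d"), amp0, amp1, delta))

  ## lexicographic ranking with deterministic tie-breaks
  key <- vapply(solutions, `[[`, numeric(6), "key")
  ord <- do.call(order, as.data.frame(t(key)))
  solutions <- solutions[ord]

  build <- function(sol) {
    rv <- sol$reverse
    fnames <- paste0("fwd_",
                     gsub("[^A-Za-z0-9]+", "_", names(sol$forwards)))
    fseq <- setNames(vapply(sol$forwards, function(x) x$sequence,
                            character(1)), fnames)
    coords <- data.frame(
      primer = c("rev_common", fnames),
      start = c(rv$start, vapply(sol$forwards, function(x) x$start,
                                 numeric(1))),
      end = c(rv$end, vapply(sol$forwards, function(x) x$end, numeric(1))))
    assayPanel(setNames(rv$sequence, "rev_common"), fseq,
               names(sol$forwards),
               setNames(sol$sizes, names(sol$forwards)), coords = coords,
               tolerance = tolerance, minSeparation = delta)
  }

  panel <- build(solutions[[1L]])
  if (verify) {
    sub <- .subset_alignment(alignment,
                             alignment@species %in% targetSpecies)
    consistent <- isSpecific(panel, sub)
    if (!consistent) {
      ## fall through ranked solutions until one verifies
      found <- FALSE
      for (i in seq_along(solutions)[-1L]) {
        panel <- build(solutions[[i]])
        if (isSpecific(panel, sub)) { found <- TRUE; break }
      }
      if (!found)
        .infeasible("no ranked panel verifies as specific by in silico PCR")
    }
  }
  alts <- lapply(utils::head(solutions[-1L], nAlternatives), build)
  list(panel = panel, alternatives = alts)
}

## forward candidates for one species: every (end, length) with the 3' end
## within k columns of a diagnostic site, gap-free slice, QC passed
.forward_candidates <- function(alignment, species, sites, constraints) {
  k <- constraints@threePrimeDiagnostic
  L <- alignmentWidth(alignment)
  m <- alignmentMatrix(alignment)
  row <- which(alignment@species == species)[1L]
  rowstr <- paste(m[row, ], collapse = "")
  diag_cols <- as.integer(sites$column)
  ends <- sort(unique(unlist(lapply(diag_cols, function(dc)
    dc:(dc + k - 1L)))))
  ends <- ends[ends <= L]
  out <- list()
  for (end in ends) {
    for (len in constraints@lengthRange[1L]:constraints@lengthRange[2L]) {
      start <- end - len + 1L
      if (start < 1L) next
      ## require a diagnostic column in the 3'-terminal k positions
      covered <- diag_cols[diag_cols >= start & diag_cols <= end]
      three_prime <- covered[covered > end - k]
      if (!length(three_prime)) next
      seq <- substr(rowstr, start, end)
      if (grepl("-", seq, fixed = TRUE)) next
      gc <- gcContent(seq)
      tm <- wallaceTm(seq, resolve = "mean")
      hp <- .longest_homopolymer(seq)
      if (gc < constraints@gcRange[1L] || gc > constraints@gcRange[2L]) next
      if (tm < constraints@tmRange[1L] || tm > constraints@tmRange[2L]) next
      if (hp > constraints@maxHomopolymer) next
      out[[length(out) + 1L]] <- data.frame(
        sequence = seq, start = start, end = end, strand = "forward",
        gc = gc, tm = tm, homopolymer = hp,
        qc_margin = .qc_margin(gc, tm, constraints),
        diagnostic_columns = paste(covered, collapse = ","),
        diag_in_3prime = length(three_prime), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(sequence = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      gc = numeric(0), tm = numeric(0),
                      homopolymer = integer(0), qc_margin = numeric(0),
                      diagnostic_columns = character(0),
                      diag_in_3prime = integer(0)))
  tab <- do.call(rbind, out)
  tab[order(tab$start, tab$end - tab$start), , drop = FALSE]
}

## all index combinations (one candidate per species) whose sizes are
## pairwise separated by >= delta; built species-by-species with pruning
.combo_grid <- function(sizes_list, delta, cap = 50000L) {
  combos <- matrix(seq_along(sizes_list[[1L]]), ncol = 1L)
  sizes <- matrix(sizes_list[[1L]], ncol = 1L)
  for (k in seq_along(sizes_list)[-1L]) {
    szk <- sizes_list[[k]]
    n0 <- nrow(combos); n1 <- length(szk)
    if (n0 * n1 > cap) {
      ## deterministic truncation under combinatorial blow-up
      keep <- seq_len(max(1L, cap %/% n1))
      combos <- combos[keep, , drop = FALSE]
      sizes <- sizes[keep, , drop = FALSE]
      n0 <- nrow(combos)
    }
    left <- combos[rep(seq_len(n0), times = n1), , drop = FALSE]
    sz_left <- sizes[rep(seq_len(n0), times = n1), , drop = FALSE]
    right <- rep(seq_len(n1), each = n0)
    sz_right <- szk[right]
    ok <- rowSums(abs(sz_left - sz_right) < delta) == 0L
    combos <- cbind(left[ok, , drop = FALSE], right[ok])
    sizes <- cbind(sz_left[ok, , drop = FALSE], sz_right[ok])
  }
  combos
}

.subset_alignment <- function(alignment, keep) {
  barcodeAlignment(rowSequences(alignment)[keep],
                   species = alignment@species[keep])
}

.infeasible <- function(msg) {
  stop(structure(class = c("coiDiag_infeasible", "error", "condition"),
                 list(message = paste("infeasible design:", msg),
                      call = NULL)))
}

#' Write a design report as JSON
#'
#' @param design Output of [assembleAssay()].
#' @param path Output path.
#' @param seed Optional seed recorded in the provenance block.
#' @return Invisibly, \code{path}.
#' @export
writeDesignReport <- function(design, path, seed = NULL) {
  as_rec <- function(p) list(
    common_reverse = list(name = names(p@commonReverse),
                          sequence = unname(p@commonReverse)),
    forwards = lapply(seq_along(p@forwards), function(i) list(
      name = names(p@forwards)[i], sequence = unname(p@forwards[i]),
      target_species = p@forwardSpecies[i])),
    expected_sizes = as.list(p@expectedSizes),
    coords = as.data.frame(p@coords),
    tolerance = p@tolerance, min_separation = p@minSeparation)
  rep <- list(provenance = list(package = "coiDiag",
                                version = as.character(
                                  utils::packageVersion("coiDiag")),
                                seed = seed),
              panel = as_rec(design$panel),
              alternatives = lapply(design$alternatives, as_rec))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
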