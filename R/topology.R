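## Consensus hydropathy profiling, TMD segmentation and topology orientation.

#' Consensus hydropathy profile on reference coordinates
#'
#' Computes, for every reference position, the mean Kyte-Doolittle hydropathy
#' over the non-gap, non-X residues of the column (`raw`), a centered sliding
#' mean with windows shrinking at the termini (`smoothed`), and the fraction
#' of sequences contributing a residue (`coverage`). This consensus profile is
#' the package's transmembrane-propensity trace: like an MSA-based predictor
#' it averages over homologs, so individual outlier sequences do not move the
#' segmentation.
#'
#' All-gap columns have no defined mean; they are imputed at the scale minimum
#' (-4.5) and flagged (`imputed`). Positions with coverage below 0.5 are
#' flagged (`low_coverage`) but still contribute to smoothing.
#'
#' @param family An `aligned_family` degapped to the reference
#'   (see [degap_to_reference()]).
#' @param window Odd smoothing window (>= 5) in residues; default 19, the
#'   scale of a membrane-spanning helix.
#' @return A data frame of class `hydropathy_profile` with columns
#'   `position`, `raw`, `smoothed`, `coverage`, `imputed`, `low_coverage`.
#' @export
hydropathy_profile <- function(family, window = 19L) {
  window <- as.integer(window)
  if (window < 5L || window %% 2L == 0L) {
    stop("window must be an odd integer >= 5", call. = FALSE)
  }
  if (is.null(family$column_map)) stop("reference not set", call. = FALSE)
  if (anyNA(family$column_map)) {
    stop("family contains gap-in-reference columns; degap_to_reference() first",
         call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(family$seqs, ""))
  L <- ncol(mat)
  kd <- .kd
  vals <- matrix(kd[mat], nrow(mat), L)      # NA for '-' and 'X'
  n_res <- colSums(!is.na(vals))
  raw <- colMeans(vals, na.rm = TRUE)
  imputed <- n_res == 0L
  raw[imputed] <- min(kd)
  coverage <- colSums(mat != GAP_CHAR) / nrow(mat)
  smoothed <- .shrinking_mean(raw, window)
  out <- data.frame(position = seq_len(L), raw = raw, smoothed = smoothed,
                    coverage = coverage, imputed = imputed,
                    low_coverage = coverage < 0.5)
  class(out) <- c("hydropathy_profile", "data.frame")
  attr(out, "window") <- window
  attr(out, "n_seqs") <- nrow(mat)
  attr(out, "reference_id") <- family$reference_id
  out
}

## centered moving mean; the window shrinks symmetrically-by-truncation at the
## ends (positions near a terminus average over what is available)
.shrinking_mean <- function(x, window) {
  half <- (window - 1L) %/% 2L
  L <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(L) - half, 1L)
  hi <- pmin(seq_len(L) + half, L)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Segment a hydropathy profile into transmembrane helices
#'
#' Takes maximal runs of positions with `smoothed >= threshold`, discards runs
#' shorter than `min_tm`, and splits runs longer than `max_tm` in two at the
#' interior smoothed-hydropathy minimum (margins of `min_tm` positions at both
#' run ends are excluded from the split search; ties go to the leftmost
#' position), recursing while parts still exceed `max_tm`. This reproduces the
#' treatment of over-long hydrophobic stretches in which two adjacent helices
#' separated by a tiny loop appear as a single run and are marked as two TMDs.
#'
#' Runs whose length lies in `(max_tm, 2*min_tm)` admit no split with both
#' parts >= `min_tm`; they are emitted unsplit and listed in the
#' `"unsplittable"` attribute.
#'
#' @param profile A `hydropathy_profile`.
#' @param threshold Hydropathy threshold in Kyte-Doolittle units (default 1.5).
#' @param min_tm,max_tm Minimum and maximum helix length (defaults 15 and 28).
#' @return Data frame with columns `index`, `start`, `end` (1-based,
#'   inclusive, on reference coordinates); zero rows if nothing crosses the
#'   threshold.
#' @export
segment_tmds <- function(profile, threshold = 1.5, min_tm = 15L,
                         max_tm = 28L) {
  if (min_tm >= max_tm) stop("min_tm must be < max_tm", call. = FALSE)
  sm <- profile$smoothed
  above <- sm >= threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts, ends)[r$values, , drop = FALSE]
  segs <- list()
  unsplittable <- integer(0)
  split_run <- function(s, e) {
    len <- e - s + 1L
    if (len < min_tm) return(invisible(NULL))
    if (len <= max_tm) { segs[[length(segs) + 1L]] <<- c(s, e); return(invisible(NULL)) }
    cand <- seq.int(s + min_tm, e - min_tm)
    cand <- cand[cand >= s + min_tm & cand <= e - min_tm]
    if (length(cand) == 0L) {
      segs[[length(segs) + 1L]] <<- c(s, e)
      unsplittable <<- c(unsplittable, s)
      return(invisible(NULL))
    }
    m <- cand[which.min(sm[cand])]
    split_run(s, m - 1L)
    split_run(m, e)
  }
  for (i in seq_len(nrow(runs))) split_run(runs[i, 1L], runs[i, 2L])
  out <- if (length(segs)) {
    sg <- do.call(rbind, segs)
    sg <- sg[order(sg[, 1L]), , drop = FALSE]
    dimnames(sg) <- NULL
    data.frame(index = seq_len(nrow(sg)), start = sg[, 1L], end = sg[, 2L])
  } else {
    data.frame(index = integer(0), start = integer(0), end = integer(0))
  }
  attr(out, "unsplittable") <- unsplittable
  out
}

#' Refine transmembrane segments by constrained two-state decoding
#'
#' Windowed smoothing cannot resolve loops much shorter than half the window,
#' and threshold crossings on a smoothed trace locate boundaries only to
#' within a few residues. This refinement finds the segment configuration
#' maximizing the summed raw-profile excess over `threshold` across all
#' transmembrane positions, subject to every segment length lying in
#' `[min_tm, max_tm]` and segments being separated by at least `min_loop`
#' positions -- a small dynamic program equivalent to Viterbi decoding of a
#' two-state model with per-position score `raw - threshold`. On consensus
#' profiles of homolog families the raw trace is already strongly averaged,
#' which is what makes per-position decoding reliable.
#'
#' @param profile A `hydropathy_profile`.
#' @inheritParams segment_tmds
#' @param min_loop Minimum separation between consecutive segments (default 2).
#' @return Data frame with columns `index`, `start`, `end`.
#' @export
refine_tmds <- function(profile, threshold = 1.5, min_tm = 15L, max_tm = 28L,
                        min_loop = 2L) {
  if (min_tm >= max_tm) stop("min_tm must be < max_tm", call. = FALSE)
  x <- profile$raw - threshold
  L <- length(x)
  S <- cumsum(c(0, x))
  lens <- seq.int(min_tm, max_tm)
  Fbest <- numeric(L + 1L)          # Fbest[i+1] = best score within 1..i
  lastend <- integer(L + 1L)        # position of last segment end achieving Fbest
  endbest <- rep(-Inf, L + 1L)
  choice <- integer(L + 1L)
  for (i in seq_len(L)) {
    ls <- lens[lens <= i]
    if (length(ls)) {
      prev <- pmax(i - ls - min_loop, 0L)
      vals <- Fbest[prev + 1L] + (S[i + 1L] - S[i - ls + 1L])
      b <- which.max(vals)
      endbest[i + 1L] <- vals[b]
      choice[i + 1L] <- ls[b]
    }
    if (endbest[i + 1L] > Fbest[i]) {
      Fbest[i + 1L] <- endbest[i + 1L]
      lastend[i + 1L] <- i
    } else {
      Fbest[i + 1L] <- Fbest[i]
      lastend[i + 1L] <- lastend[i]
    }
  }
  segs <- list()
  j <- lastend[L + 1L]
  while (j > 0L) {
    len <- choice[j + 1L]
    segs[[length(segs) + 1L]] <- c(j - len + 1L, j)
    j <- lastend[max(j - len - min_loop, 0L) + 1L]
  }
  if (length(segs) == 0L) {
    return(data.frame(index = integer(0), start = integer(0),
                      end = integer(0)))
  }
  sg <- do.call(rbind, rev(segs))
  data.frame(index = seq_len(nrow(sg)), start = sg[, 1L], end = sg[, 2L])
}

#' Apply user-supplied forced-loop intervals
#'
#' Regions known from structural evidence to be loops (e.g. a hydrophobic
#' luminal loop that sequence alone would call membrane-spanning) can be
#' forced out of the segmentation. Segments fully inside a forced interval are
#' dropped; partial overlaps are trimmed. Every intervention is reported as a
#' conflict so that disagreement between the sequence-based segmentation and
#' the structural prior is visible rather than silent.
#'
#' @param segments Segment data frame (`index`, `start`, `end`).
#' @param intervals Data frame or matrix with columns `start`, `end`.
#' @param min_tm Segments trimmed below this length are dropped (default 15).
#' @return List with `segments` (renumbered) and `conflicts` (data frame).
#' @export
force_loops <- function(segments, intervals, min_tm = 15L) {
  intervals <- as.data.frame(intervals)
  conflicts <- list()
  keep <- segments
  for (r in seq_len(nrow(intervals))) {
    fs <- intervals$start[r]; fe <- intervals$end[r]
    out <- list()
    for (i in seq_len(nrow(keep))) {
      s <- keep$start[i]; e <- keep$end[i]
      if (e < fs || s > fe) { out[[length(out) + 1L]] <- c(s, e); next }
      conflicts[[length(conflicts) + 1L]] <-
        data.frame(segment_start = s, segment_end = e,
                   forced_start = fs, forced_end = fe)
      if (s < fs && fs - s >= min_tm) out[[length(out) + 1L]] <- c(s, fs - 1L)
      if (e > fe && e - fe >= min_tm) out[[length(out) + 1L]] <- c(fe + 1L, e)
    }
    keep <- if (length(out)) {
      sg <- do.call(rbind, out)
      data.frame(index = seq_len(nrow(sg)), start = sg[, 1], end = sg[, 2])
    } else {
      data.frame(index = integer(0), start = integer(0), end = integer(0))
    }
  }
  list(segments = keep,
       conflicts = if (length(conflicts)) do.call(rbind, conflicts)
                   else data.frame())
}

#' Orient a segmented topology
#'
#' Chooses which face of the membrane the N-terminus is on. The positive-inside
#' rule counts reference Lys+Arg residues in all loops (termini included) under
#' both candidate orientations and keeps the one placing more K/R on the
#' cytoplasmic side. A C-terminal dilysine ER-retrieval signal overrides this:
#' when present, the C-terminus is forced cytoplasmic whatever the K/R tally.
#' An exact tie with no dilysine defaults to a cytoplasmic N-terminus, the
#' orientation shared by every GT-C family model.
#'
#' @param segments Segment data frame from [segment_tmds()] or
#'   [refine_tmds()]; at least one segment.
#' @param family The degapped `aligned_family` (reference set); K/R counts and
#'   the dilysine check use the reference sequence.
#' @param check_dilysine Logical; set `FALSE` to disable the override.
#' @return An object of class `topology_model`: list with `segments`,
#'   `n_term_side`, `length`, `loops` (data frame: `loop_index`, `start`,
#'   `end`, `length`, `side`, `label`), `decided_by` and the two K/R tallies.
#' @export
orient <- function(segments, family, check_dilysine = TRUE) {
  if (nrow(segments) == 0L) stop("cannot orient zero segments", call. = FALSE)
  refseq <- reference_sequence(family)
  L <- nchar(refseq)
  if (max(segments$end) > L) stop("segments exceed reference length",
                                  call. = FALSE)
  chars <- strsplit(refseq, "")[[1]]
  n <- nrow(segments)
  loop_bounds <- .loop_bounds(segments, L)
  kr_in <- vapply(seq_len(nrow(loop_bounds)), function(i) {
    s <- loop_bounds$start[i]; e <- loop_bounds$end[i]
    if (s > e) 0L else sum(chars[s:e] %in% c("K", "R"))
  }, integer(1))
  even_loop <- loop_bounds$loop_index %% 2L == 0L
  kr_cyto_if_ncyto <- sum(kr_in[even_loop])
  kr_cyto_if_nlum <- sum(kr_in[!even_loop])
  dily <- check_dilysine && has_dilysine(refseq)
  if (dily) {
    ## C-tail is loop n; side must be cytoplasmic
    n_term_side <- if (n %% 2L == 0L) "cytoplasmic" else "luminal"
    decided_by <- "dilysine"
  } else if (kr_cyto_if_ncyto >= kr_cyto_if_nlum) {
    n_term_side <- "cytoplasmic"
    decided_by <- if (kr_cyto_if_ncyto == kr_cyto_if_nlum) "tie-default"
                  else "positive-inside"
  } else {
    n_term_side <- "luminal"
    decided_by <- "positive-inside"
  }
  model <- topology_model(segments, n_term_side, L)
  model$decided_by <- decided_by
  model$kr_counts <- c(cytoplasmic_if_n_cyto = kr_cyto_if_ncyto,
                       cytoplasmic_if_n_lum = kr_cyto_if_nlum)
  model
}

## loops including termini: loop i sits after helix i (loop 0 = N-tail)
.loop_bounds <- function(segments, L) {
  n <- nrow(segments)
  starts <- c(1L, segments$end + 1L)
  ends <- c(segments$start - 1L, L)
  data.frame(loop_index = 0L:n, start = starts, end = ends,
             length = pmax(ends - starts + 1L, 0L))
}

#' Build a topology model from segments and an orientation
#'
#' Loop sides strictly alternate; loop `i` (after helix `i`; loop 0 is the
#' N-terminal tail) is on the N-terminal side when `i` is even. Luminal loops
#' are labelled `EL1..` in N-to-C order and cytoplasmic loops `CL1..`,
#' termini included.
#'
#' @param segments Segment data frame (`index`, `start`, `end`).
#' @param n_term_side `"cytoplasmic"` or `"luminal"`.
#' @param length Reference sequence length.
#' @return A `topology_model`.
#' @export
topology_model <- function(segments, n_term_side = c("cytoplasmic", "luminal"),
                           length) {
  n_term_side <- match.arg(n_term_side)
  loops <- .loop_bounds(segments, length)
  other <- if (n_term_side == "cytoplasmic") "luminal" else "cytoplasmic"
  loops$side <- ifelse(loops$loop_index %% 2L == 0L, n_term_side, other)
  loops$label <- NA_character_
  lum <- loops$side == "luminal"
  loops$label[lum] <- paste0("EL", seq_len(sum(lum)))
  loops$label[!lum] <- paste0("CL", seq_len(sum(!lum)))
  structure(list(segments = segments, n_term_side = n_term_side,
                 length = length, loops = loops),
            class = "topology_model")
}

#' @export
print.topology_model <- function(x, ...) {
  cat("Topology model: ", nrow(x$segments), " TMDs over ", x$length,
      " residues; N-terminus ", x$n_term_side, sep = "")
  if (!is.null(x$decided_by)) cat(" (", x$decided_by, ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Export a hydropathy profile as TSV
#' @param profile A `hydropathy_profile`.
#' @param path Output path.
#' @param segments Optional segment data frame; adds an `in_tmd` column.
#' @return Invisibly, `path`.
#' @export
write_profile_tsv <- function(profile, path, segments = NULL) {
  df <- as.data.frame(profile)
  df$in_tmd <- FALSE
  if (!is.null(segments) && nrow(segments)) {
    for (i in seq_len(nrow(segments))) {
      df$in_tmd[segments$start[i]:segments$end[i]] <- TRUE
    }
  }
  utils::write.table(format(df, digits = 6), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export segments as BED-like TSV
#'
#' Coordinates in the file are 0-based half-open (BED convention); the
#' package-internal `start`/`end` are 1-based inclusive, so `start` is written
#' as `start - 1`. The conversion is stated in the file header.
#'
#' @param segments Segment data frame.
#' @param path Output path.
#' @param ref_name Name written in the first column.
#' @return Invisibly, `path`.
#' @export
write_segments_tsv <- function(segments, path, ref_name = "reference") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# BED-like segment export: 0-based half-open intervals",
               "# (internal coordinates are 1-based inclusive: bed_start = start - 1, bed_end = end)"),
             con)
  if (nrow(segments)) {
    utils::write.table(
      data.frame(ref_name, segments$start - 1L, segments$end,
                 paste0("TMD", segments$index)),
      con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
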