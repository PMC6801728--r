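## Alignment I/O, reference numbering and diverse-subset selection.

.valid_residue_regex <- "^[ACDEFGHIKLMNPQRSTVWYX-]+$"

.check_residues <- function(ids, seqs, allow_gaps = TRUE) {
  pat <- if (allow_gaps) .valid_residue_regex else "^[ACDEFGHIKLMNPQRSTVWYX]+$"
  bad <- which(!grepl(pat, seqs))
  if (length(bad)) {
    stop("malformed input: record '", ids[bad[1]],
         "' contains characters outside the amino-acid alphabet", call. = FALSE)
  }
  if (any(nchar(seqs) == 0L)) {
    stop("malformed input: record '", ids[which(nchar(seqs) == 0L)[1]],
         "' is empty", call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct an aligned protein family
#'
#' An `aligned_family` holds equal-length aligned residue strings (gaps as
#' `-`), an optional designated reference sequence and, once
#' [set_reference()] has been called, a column-to-reference-position map.
#'
#' @param ids Character vector of unique record identifiers.
#' @param seqs Character vector of aligned residue strings (upper case,
#'   `-` for gaps, `X` tolerated).
#' @return An object of class `aligned_family`.
#' @export
aligned_family <- function(ids, seqs) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs)) stop("ids and seqs differ in length")
  if (anyDuplicated(ids)) stop("duplicate record identifiers")
  .check_residues(ids, seqs)
  len <- nchar(seqs)
  if (length(unique(len)) != 1L) {
    off <- ids[which(len != len[1])[1]]
    stop("malformed input: ragged alignment, record '", off,
         "' has a different aligned length", call. = FALSE)
  }
  structure(list(ids = ids, seqs = seqs, reference_id = NULL,
                 column_map = NULL),
            class = "aligned_family")
}

#' @export
print.aligned_family <- function(x, ...) {
  cat("Aligned family: ", length(x$ids), " records, ",
      nchar(x$seqs[1]), " columns", sep = "")
  if (!is.null(x$reference_id)) {
    cat(", reference '", x$reference_id, "' (",
        sum(!is.na(x$column_map)), " reference positions)", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Number of alignment columns
#' @param family An `aligned_family`.
#' @return Integer alignment width.
#' @export
alignment_width <- function(family) nchar(family$seqs[1])

#' Read a protein multiple alignment
#'
#' Parses FASTA, Stockholm or Clustal alignments. The reference is left unset;
#' call [set_reference()] afterwards.
#'
#' @param path File path.
#' @param format One of `"fasta"`, `"stockholm"`, `"clustal"`.
#' @return An `aligned_family` with records in file order.
#' @export
read_alignment <- function(path, format = c("fasta", "stockholm", "clustal")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unknown alignment format '",
                                              format[1], "'", call. = FALSE))
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    fam <- aligned_family(names(set), as.character(set))
  } else {
    aln <- tryCatch(
      Biostrings::readAAMultipleAlignment(path, format = format),
      error = function(e) stop("malformed ", format, " alignment in '", path,
                               "': ", conditionMessage(e), call. = FALSE))
    um <- Biostrings::unmasked(aln)
    fam <- aligned_family(names(um), as.character(um))
  }
  fam
}

#' Write a protein multiple alignment
#'
#' Writes the family in the named dialect. Round-trips with
#' [read_alignment()] byte-exactly on ids and residues.
#'
#' @param family An `aligned_family`.
#' @param path Output file path.
#' @param format One of `"fasta"`, `"stockholm"`, `"clustal"`.
#' @return Invisibly, `path`.
#' @export
write_alignment <- function(family, path,
                            format = c("fasta", "stockholm", "clustal")) {
  format <- match.arg(format)
  if (format == "fasta") {
    set <- Biostrings::BStringSet(stats::setNames(family$seqs, family$ids))
    Biostrings::writeXStringSet(set, path, width = 60L)
  } else if (format == "stockholm") {
    pad <- formatC(family$ids, width = max(nchar(family$ids)), flag = "-")
    writeLines(c("# STOCKHOLM 1.0",
                 paste(pad, family$seqs),
                 "//"), path)
  } else {
    ## mafft-style clustal block layout (the dialect Biostrings re-reads)
    width <- 60L
    namew <- max(nchar(family$ids)) + 3L
    pad <- formatC(family$ids, width = namew, flag = "-")
    lines <- c("CLUSTAL format alignment (gtctopo)", "", "")
    total <- alignment_width(family)
    for (from in seq(1L, total, by = width)) {
      to <- min(from + width - 1L, total)
      block <- paste0(pad, substr(family$seqs, from, to))
      lines <- c(lines, block, "")
    }
    writeLines(lines, path)
  }
  invisible(path)
}

#' Designate the reference sequence and build the column map
#'
#' The k-th non-gap column of the reference receives reference position `k`
#' (1-based); columns where the reference has a gap are marked `NA`
#' ("gap-in-reference"). Reference numbering lets every downstream coordinate
#' be reported on the (human) reference enzyme.
#'
#' @param family An `aligned_family`.
#' @param ref_id Identifier of the reference record.
#' @return The family with `reference_id` and `column_map` set.
#' @export
set_reference <- function(family, ref_id) {
  idx <- match(ref_id, family$ids)
  if (is.na(idx)) stop("reference id '", ref_id, "' not found", call. = FALSE)
  chars <- strsplit(family$seqs[idx], "")[[1]]
  nongap <- chars != GAP_CHAR
  map <- rep(NA_integer_, length(chars))
  map[nongap] <- seq_len(sum(nongap))
  family$reference_id <- ref_id
  family$column_map <- map
  family
}

#' Restrict an alignment to reference columns
#'
#' Drops every column where the reference has a gap ("inserted amino acids
#' present in some other sequences"), so that alignment columns coincide with
#' reference residue numbering. Residues in retained columns are unchanged.
#'
#' @param family An `aligned_family` with the reference set.
#' @return An `aligned_family` of width equal to the ungapped reference length.
#' @export
degap_to_reference <- function(family) {
  if (is.null(family$column_map)) {
    stop("reference not set; call set_reference() first", call. = FALSE)
  }
  keep <- which(!is.na(family$column_map))
  mat <- do.call(rbind, strsplit(family$seqs, ""))
  seqs <- apply(mat[, keep, drop = FALSE], 1L, paste, collapse = "")
  out <- aligned_family(family$ids, seqs)
  out$reference_id <- family$reference_id
  out$column_map <- seq_along(keep)
  out
}

#' Ungapped reference sequence
#' @param family An `aligned_family` with the reference set.
#' @return Character scalar: the reference residues with gaps removed.
#' @export
reference_sequence <- function(family) {
  if (is.null(family$reference_id)) stop("reference not set", call. = FALSE)
  gsub("-", "", family$seqs[match(family$reference_id, family$ids)],
       fixed = TRUE)
}

#' Pairwise identity distances
#'
#' Distance between two records is `1 - identities / compared`, where
#' positions are compared only when both records are non-gap and neither is
#' `X`. Pairs with no comparable position get distance 1.
#'
#' @param family An `aligned_family` (or equal-length unaligned records via
#'   [aligned_family()]).
#' @return Symmetric numeric matrix with zero diagonal, dimnames = ids.
#' @export
identity_distance <- function(family) {
  mat <- do.call(rbind, strsplit(family$seqs, ""))
  n <- nrow(mat)
  ok <- mat != GAP_CHAR & mat != "X"
  d <- matrix(0, n, n, dimnames = list(family$ids, family$ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- ok[i, ] & ok[j, ]
      nc <- sum(comp)
      d[i, j] <- d[j, i] <-
        if (nc == 0L) 1 else 1 - sum(mat[i, comp] == mat[j, comp]) / nc
    }
  }
  d
}

#' Select a maximally diverse subset of records
#'
#' Greedy maximin (farthest-point) selection on identity distance: start from
#' `seed_id` (default: the most distant pair), then repeatedly add the record
#' whose minimum distance to the chosen set is largest. Ties are broken by
#' lexicographically smallest id, so the result does not depend on input
#' order. `must_include` records are seeded into the selection first (e.g.
#' paralogs that have to be represented).
#'
#' @param family An `aligned_family` holding the candidate records.
#' @param k Number of records to select (`k <= n`).
#' @param seed_id Optional identifier to start from.
#' @param must_include Optional character vector of ids forced into the set.
#' @return Character vector of `k` selected identifiers, in selection order.
#' @export
select_diverse <- function(family, k, seed_id = NULL, must_include = NULL) {
  ids <- family$ids
  n <- length(ids)
  if (k < 1L || k > n) stop("k must be between 1 and the number of records",
                            call. = FALSE)
  d <- identity_distance(family)
  chosen <- character(0)
  if (!is.null(must_include)) {
    miss <- setdiff(must_include, ids)
    if (length(miss)) stop("must_include ids not found: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    chosen <- unique(must_include)
  }
  if (!is.null(seed_id)) {
    if (!seed_id %in% ids) stop("seed id '", seed_id, "' not found",
                                call. = FALSE)
    chosen <- unique(c(chosen, seed_id))
  }
  if (length(chosen) == 0L && k >= 2L) {
    ## start from the pair at maximal distance; lexicographic tie-break
    best <- NULL; bestd <- -Inf
    ord <- order(ids)
    for (a in seq_len(n - 1L)) {
      for (b in (a + 1L):n) {
        i <- ord[a]; j <- ord[b]
        if (d[i, j] > bestd + 1e-15) { bestd <- d[i, j]; best <- c(i, j) }
      }
    }
    chosen <- ids[best]
  }
  if (length(chosen) == 0L) chosen <- sort(ids)[1]
  chosen <- chosen[seq_len(min(length(chosen), k))]
  while (length(chosen) < k) {
    rest <- setdiff(ids, chosen)
    mind <- vapply(rest, function(id) min(d[id, chosen]), numeric(1))
    mx <- max(mind)
    cand <- sort(rest[mind >= mx - 1e-15])
    chosen <- c(chosen, cand[1])
  }
  chosen
}

#' Export the column map as TSV
#'
#' @param family An `aligned_family` with the reference set.
#' @param path Output TSV path (columns: `column`, `reference_position`;
#'   gap-in-reference columns have an empty reference position).
#' @return Invisibly, `path`.
#' @export
write_column_map <- function(family, path) {
  if (is.null(family$column_map)) stop("reference not set", call. = FALSE)
  df <- data.frame(column = seq_along(family$column_map),
                   reference_position = family$column_map)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
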