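## Per-position conservation (information content) and logo matrices.

#' Per-position conservation profile
#'
#' For every reference position, residue frequencies are computed over the
#' contributing residues of the column -- gaps and `X` are excluded from the
#' denominator, since the alignment has already been degapped to the reference
#' and logos are drawn on reference numbering. Information content is
#' `log2(20) - H` with Shannon entropy `H` in bits, the standard sequence-logo
#' stack height (0 to ~4.322 bits).
#'
#' No small-sample correction is applied by default, matching ordinary logo
#' output for families of a few dozen sequences; `correct = TRUE` subtracts
#' the Miller-Madow bias term `(20 - 1) / (2 ln(2) n_eff)` (truncated at 0).
#'
#' @param family An `aligned_family` degapped to the reference, >= 2 records
#'   (a single-record family is allowed with a warning; every residue position
#'   then has the maximal 4.32 bits).
#' @param correct Logical, apply small-sample bias correction (default FALSE).
#' @return Object of class `conservation_profile`: list with `positions`,
#'   `freq` (20 x L matrix), `ic` (bits), `n_eff`, `flagged` (n_eff == 0).
#' @export
conservation_profile <- function(family, correct = FALSE) {
  if (length(family$ids) < 2L) {
    warning("single-record family: information content is maximal everywhere")
  }
  mat <- do.call(rbind, strsplit(family$seqs, ""))
  L <- ncol(mat)
  counts <- vapply(seq_len(L), function(j) {
    tabulate(factor(mat[, j], levels = AA_ALPHABET), nbins = 20L)
  }, integer(20))
  rownames(counts) <- AA_ALPHABET
  n_eff <- colSums(counts)
  freq <- counts
  nz <- n_eff > 0L
  freq[, nz] <- sweep(counts[, nz, drop = FALSE], 2L, n_eff[nz], "/")
  freq[, !nz] <- 0
  H <- apply(freq, 2L, function(p) {
    p <- p[p > 0]
    if (length(p) == 0L) return(LOG2_20)  # empty column -> ic 0
    -sum(p * log2(p))
  })
  ic <- LOG2_20 - H
  if (correct) {
    ic[nz] <- pmax(0, ic[nz] - (20 - 1) / (2 * log(2) * n_eff[nz]))
  }
  structure(list(positions = seq_len(L), freq = freq, ic = ic,
                 n_eff = n_eff, flagged = !nz),
            class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat("Conservation profile: ", length(x$positions), " positions, mean IC ",
      round(mean(x$ic), 3), " bits\n", sep = "")
  invisible(x)
}

#' Default residue classes for conserved-position calling
#'
#' Acidic (D/E), basic (K/R) and amide (N/Q) residues are merged -- within the
#' GT-C motifs an aspartate may be replaced by a glutamate and an arginine by
#' a lysine -- and every other residue forms its own class.
#'
#' @return Named list of character vectors partitioning the alphabet.
#' @export
default_residue_classes <- function() {
  singles <- setdiff(AA_ALPHABET, c("D", "E", "K", "R", "N", "Q"))
  c(list(DE = c("D", "E"), KR = c("K", "R"), NQ = c("N", "Q")),
    stats::setNames(as.list(singles), singles))
}

#' Call conserved positions
#'
#' Mode `"ic"` calls positions whose information content reaches `cutoff`
#' (bits). Mode `"class_freq"` calls positions where one residue class
#' (default classes: [default_residue_classes()]) reaches a summed frequency
#' of at least `cutoff`, and reports which class fired.
#'
#' @param profile A `conservation_profile`.
#' @param mode `"ic"` or `"class_freq"`.
#' @param cutoff Bits for `"ic"`; a fraction in (0, 1] for `"class_freq"`
#'   (default 0.8).
#' @param classes Partition of the alphabet for `"class_freq"`.
#' @return Data frame with `position` and, for class mode, `class`.
#' @export
call_conserved <- function(profile, mode = c("class_freq", "ic"),
                           cutoff = if (match.arg(mode) == "ic") 3 else 0.8,
                           classes = default_residue_classes()) {
  mode <- match.arg(mode)
  if (mode == "ic") {
    if (!is.numeric(cutoff) || cutoff < 0 || cutoff > LOG2_20) {
      stop("ic cutoff must lie in [0, log2(20)]", call. = FALSE)
    }
    return(data.frame(position = profile$positions[profile$ic >= cutoff]))
  }
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff > 1) {
    stop("class_freq cutoff must lie in (0, 1]", call. = FALSE)
  }
  cf <- vapply(classes, function(cl) {
    colSums(profile$freq[cl, , drop = FALSE])
  }, numeric(length(profile$positions)))
  cf <- matrix(cf, ncol = length(classes),
               dimnames = list(NULL, names(classes)))
  hit <- which(apply(cf, 1L, max) >= cutoff & profile$n_eff > 0L)
  data.frame(position = profile$positions[hit],
             class = names(classes)[apply(cf[hit, , drop = FALSE], 1L,
                                          which.max)])
}

#' Sequence-logo letter heights
#'
#' Letter height is `frequency x information content`, the WebLogo
#' convention: the column's letters stack to exactly the column IC.
#'
#' @param profile A `conservation_profile`.
#' @return 20 x L matrix of heights (rows = residues).
#' @export
logo_matrix <- function(profile) {
  sweep(profile$freq, 2L, profile$ic, "*")
}

#' Export a logo matrix as long-format TSV
#' @param profile A `conservation_profile`.
#' @param path Output path (columns: position, residue, height; zero heights
#'   omitted).
#' @return Invisibly, `path`.
#' @export
write_logo_tsv <- function(profile, path) {
  m <- logo_matrix(profile)
  idx <- which(m > 0, arr.ind = TRUE)
  df <- data.frame(position = profile$positions[idx[, 2L]],
                   residue = AA_ALPHABET[idx[, 1L]],
                   height = m[idx])
  df <- df[order(df$position, -df$height), ]
  utils::write.table(format(df, digits = 6), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a conservation profile as TSV
#' @param profile A `conservation_profile`.
#' @param path Output path (columns: position, ic, n_eff, consensus).
#' @return Invisibly, `path`.
#' @export
write_conservation_tsv <- function(profile, path) {
  consensus <- ifelse(profile$n_eff > 0L,
                      AA_ALPHABET[apply(profile$freq, 2L, which.max)],
                      "-")
  df <- data.frame(position = profile$positions,
                   ic = round(profile$ic, 4),
                   n_eff = profile$n_eff,
                   consensus = consensus)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Consensus sequence of a family
#'
#' Most frequent residue per position (ties to the alphabetically first);
#' positions with no contributing residue yield `X`.
#'
#' @param profile A `conservation_profile`.
#' @return Character scalar.
#' @export
consensus_sequence <- function(profile) {
  res <- ifelse(profile$n_eff > 0L,
                AA_ALPHABET[apply(profile$freq, 2L, which.max)],
                "X")
  paste(res, collapse = "")
}
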