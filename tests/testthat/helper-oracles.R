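## Independent oracles used to freeze expected values. These deliberately use
## different machinery from the implementation (set membership instead of
## regex, elemental composition instead of residue-mass tables, exhaustive
## enumeration instead of greedy/DP search).

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(n, alphabet = AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

## --- motif scanning oracle -------------------------------------------------
## Exhaustive enumeration over every (start, width-assignment) pair, testing
## per-offset residue-set membership on a character matrix (rows = sequences).
oracle_scan_matrix <- function(M, pattern) {
  elements <- pattern$elements
  n_seq <- nrow(M)
  L <- ncol(M)
  assignments <- expand.grid(lapply(elements, function(e) e$min:e$max),
                             KEEP.OUT.ATTRS = FALSE)
  hits <- list()
  for (g in seq_len(nrow(assignments))) {
    ws <- as.integer(assignments[g, ])
    W <- sum(ws)
    if (W == 0L || W > L) next
    n_start <- L - W + 1L
    ok <- matrix(TRUE, n_seq, n_start)
    cum <- 0L
    for (e in seq_along(ws)) {
      res <- elements[[e]]$residues
      if (ws[e] > 0L) {
        for (r in seq_len(ws[e])) {
          sub <- M[, (cum + r):(cum + r + n_start - 1L), drop = FALSE]
          ok <- ok & matrix(sub %in% res, n_seq)
        }
      }
      cum <- cum + ws[e]
    }
    if (pattern$anchored) {
      keep <- rep(FALSE, n_start)
      keep[n_start] <- TRUE
      ok <- ok & matrix(keep, n_seq, n_start, byrow = TRUE)
    }
    idx <- which(ok, arr.ind = TRUE)
    if (nrow(idx)) {
      hits[[length(hits) + 1L]] <-
        data.frame(seq = idx[, 1L], start = idx[, 2L],
                   end = idx[, 2L] + W - 1L)
    }
  }
  if (!length(hits)) {
    return(data.frame(seq = integer(0), start = integer(0), end = integer(0)))
  }
  out <- unique(do.call(rbind, hits))
  out[order(out$seq, out$start, out$end), , drop = FALSE]
}

oracle_scan_one <- function(sequence, pattern) {
  M <- matrix(strsplit(sequence, "")[[1]], nrow = 1)
  h <- oracle_scan_matrix(M, pattern)
  h[, c("start", "end")]
}

## --- peptide mass oracle ---------------------------------------------------
## Monoisotopic mass from summed elemental composition.
.element_mass <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
                   O = 15.9949146221, S = 31.97207069)

## residue (dehydrated) formulas: counts of C,H,N,O,S
.residue_formula <- list(
  G = c(2, 3, 1, 1, 0),  A = c(3, 5, 1, 1, 0),  S = c(3, 5, 1, 2, 0),
  P = c(5, 7, 1, 1, 0),  V = c(5, 9, 1, 1, 0),  T = c(4, 7, 1, 2, 0),
  C = c(3, 5, 1, 1, 1),  L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
  N = c(4, 6, 2, 2, 0),  D = c(4, 5, 1, 3, 0),  Q = c(5, 8, 2, 2, 0),
  K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0),  M = c(5, 9, 1, 1, 1),
  H = c(6, 7, 3, 1, 0),  F = c(9, 9, 1, 1, 0),  R = c(6, 12, 4, 1, 0),
  Y = c(9, 9, 1, 2, 0),  W = c(11, 10, 2, 1, 0))

oracle_peptide_mass <- function(sequence, n_carbamidomethyl = 0L,
                                n_hexose = 0L) {
  atoms <- Reduce(`+`, .residue_formula[strsplit(sequence, "")[[1]]])
  atoms <- atoms + c(0, 2, 0, 1, 0)                     # + H2O
  atoms <- atoms + n_carbamidomethyl * c(2, 3, 1, 1, 0) # + C2H3NO each
  atoms <- atoms + n_hexose * c(6, 10, 0, 5, 0)         # + C6H10O5 each
  sum(atoms * .element_mass)
}

## --- tryptic site-counting oracle ------------------------------------------
oracle_cleavage_sites <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  sum(vapply(seq_len(L - 1L), function(i) {
    chars[i] %in% c("K", "R") && chars[i + 1L] != "P"
  }, logical(1)))
}

## --- small fixture builders ------------------------------------------------
## single-sequence family (already degapped) from a residue string
profile_family <- function(seqs, ids = sprintf("s%02d", seq_along(seqs))) {
  fam <- aligned_family(ids, seqs)
  fam <- set_reference(fam, ids[1])
  if (anyNA(fam$column_map)) fam <- degap_to_reference(fam)
  fam
}

## random gapped alignment whose first record is the reference
random_gapped_family <- function(n_seq = 5, n_col = 40, gap_p = 0.15) {
  mat <- matrix(sample(AA20, n_seq * n_col, replace = TRUE), n_seq)
  gaps <- matrix(runif(n_seq * n_col) < gap_p, n_seq)
  mat[gaps] <- "-"
  all_gap <- colSums(mat != "-") == 0
  mat[1, all_gap] <- "A"   # keep no column entirely empty
  fam <- aligned_family(sprintf("r%02d", 1:n_seq),
                        apply(mat, 1, paste, collapse = ""))
  set_reference(fam, "r01")
}

## a hydropathy_profile built directly from a vector of smoothed values
## (raw = smoothed), bypassing sequence input, for segmentation unit tests
manual_profile <- function(values) {
  out <- data.frame(position = seq_along(values), raw = values,
                    smoothed = values, coverage = 1,
                    imputed = FALSE, low_coverage = FALSE)
  class(out) <- c("hydropathy_profile", "data.frame")
  out
}

## independent re-segmentation: threshold runs + recursive margin-respecting
## split at the interior smoothed minimum
oracle_segment <- function(values, threshold, min_tm, max_tm) {
  above <- values >= threshold
  out <- list()
  split_rec <- function(s, e) {
    len <- e - s + 1
    if (len < min_tm) return()
    if (len <= max_tm) { out[[length(out) + 1]] <<- c(s, e); return() }
    cand <- (s + min_tm):(e - min_tm)
    cand <- cand[cand <= e - min_tm & cand >= s + min_tm]
    if (!length(cand)) { out[[length(out) + 1]] <<- c(s, e); return() }
    m <- cand[which.min(values[cand])]
    split_rec(s, m - 1)
    split_rec(m, e)
  }
  i <- 1
  while (i <= length(values)) {
    if (above[i]) {
      j <- i
      while (j < length(values) && above[j + 1]) j <- j + 1
      split_rec(i, j)
      i <- j + 1
    } else i <- i + 1
  }
  if (!length(out)) return(data.frame(start = integer(0), end = integer(0)))
  sg <- do.call(rbind, out)
  data.frame(start = sg[, 1], end = sg[, 2])
}
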