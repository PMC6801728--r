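## Tryptic digestion and monoisotopic m/z of C-mannosylated glycopeptides.

#' In silico tryptic digestion
#'
#' Cleaves after Lys or Arg except when the next residue is Pro, and emits all
#' peptides containing up to `missed_cleavages` internal sites. Positions are
#' 1-based on the parent sequence; at zero missed cleavages the peptides tile
#' the parent exactly.
#'
#' @param sequence Protein residue string.
#' @param missed_cleavages Non-negative integer (default 0).
#' @return Data frame with `peptide`, `start`, `end`, `missed`.
#' @export
tryptic_digest <- function(sequence, missed_cleavages = 0L) {
  if (!nzchar(sequence)) stop("empty sequence", call. = FALSE)
  if (missed_cleavages < 0L) stop("missed_cleavages must be >= 0",
                                  call. = FALSE)
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  ## cleavage after position i
  sites <- which(chars %in% c("K", "R"))
  sites <- sites[sites < L & chars[pmin(sites + 1L, L)] != "P"]
  bounds <- c(0L, sites, L)
  n_frag <- length(bounds) - 1L
  out <- list()
  for (i in seq_len(n_frag)) {
    for (m in 0:missed_cleavages) {
      j <- i + m
      if (j > n_frag) break
      s <- bounds[i] + 1L
      e <- bounds[j + 1L]
      out[[length(out) + 1L]] <-
        data.frame(peptide = substr(sequence, s, e), start = s, end = e,
                   missed = m)
    }
  }
  do.call(rbind, out)
}

#' Construct a modified peptide
#'
#' @param sequence Peptide residue string (20-letter alphabet).
#' @param hexoses Number of hexose (mannose) modifications, each
#'   +162.052824 Da; must not exceed the tryptophan count, since
#'   C-mannosylation targets Trp.
#' @param charge Positive integer charge state.
#' @param carbamidomethyl Logical: apply +57.021464 Da to every Cys. Applied
#'   by default -- reduced/alkylated cysteines are the standard preparation,
#'   and the published glycopeptide ions are reproduced only with it.
#' @param fixed_mods Optional extra fixed modifications: named numeric vector
#'   of mass deltas (Da) keyed by residue letter, applied per occurrence.
#' @return Object of class `modified_peptide`.
#' @export
modified_peptide <- function(sequence, hexoses = 0L, charge = 1L,
                             carbamidomethyl = TRUE, fixed_mods = NULL) {
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", sequence)) {
    stop("invalid residue in peptide '", sequence, "'", call. = FALSE)
  }
  n_w <- lengths(regmatches(sequence, gregexpr("W", sequence)))
  if (hexoses > n_w) {
    stop("hexose count (", hexoses, ") exceeds tryptophan count (", n_w, ")",
         call. = FALSE)
  }
  if (charge < 1L) stop("charge must be >= 1", call. = FALSE)
  structure(list(sequence = sequence, hexoses = as.integer(hexoses),
                 charge = as.integer(charge),
                 carbamidomethyl = isTRUE(carbamidomethyl),
                 fixed_mods = fixed_mods),
            class = "modified_peptide")
}

#' Monoisotopic mass of a modified peptide
#'
#' Sum of monoisotopic residue masses plus one water, plus fixed
#' modifications, plus `hexoses x 162.052824` Da.
#'
#' @param p A `modified_peptide`.
#' @param constants Mass table, see [mass_constants()].
#' @return Mass in Da.
#' @export
monoisotopic_mass <- function(p, constants = mass_constants()) {
  chars <- strsplit(p$sequence, "")[[1]]
  mass <- sum(constants$residues[chars]) + constants$water
  if (p$carbamidomethyl) {
    mass <- mass + sum(chars == "C") * constants$carbamidomethyl
  }
  if (!is.null(p$fixed_mods)) {
    for (res in names(p$fixed_mods)) {
      mass <- mass + sum(chars == res) * p$fixed_mods[[res]]
    }
  }
  mass + p$hexoses * constants$hexose
}

#' Mass-to-charge ratio
#'
#' `(M + z * 1.007276) / z` for the `[M+zH]^z+` ion.
#'
#' @param mass Neutral monoisotopic mass (Da).
#' @param z Positive integer charge.
#' @param constants Mass table.
#' @return m/z value.
#' @export
mz <- function(mass, z, constants = mass_constants()) {
  if (any(z < 1L)) stop("charge must be >= 1", call. = FALSE)
  (mass + z * constants$proton) / z
}

#' Hexose ladder of a glycopeptide
#'
#' Cartesian table of m/z values for 0..`max_hex` hexoses across the given
#' charge states: the ion series expected for an unmodified, mono- and
#' di-C-mannosylated tryptic peptide.
#'
#' @param peptide Peptide residue string.
#' @param max_hex Maximum hexose count (must not exceed the Trp count).
#' @param charges Integer vector of charge states.
#' @param carbamidomethyl Passed to [modified_peptide()].
#' @return Data frame with `hexoses`, `z`, `mass`, `mz`.
#' @export
hexose_ladder <- function(peptide, max_hex, charges,
                          carbamidomethyl = TRUE) {
  rows <- expand.grid(hexoses = 0:max_hex, z = as.integer(charges),
                      KEEP.OUT.ATTRS = FALSE)
  rows$mass <- vapply(rows$hexoses, function(h) {
    monoisotopic_mass(modified_peptide(peptide, hexoses = h,
                                       carbamidomethyl = carbamidomethyl))
  }, numeric(1))
  rows$mz <- mz(rows$mass, rows$z)
  rows
}
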