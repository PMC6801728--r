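## Synthetic membrane-protein families with known topology and planted
## luminal conserved areas, so every pipeline stage has ground truth.

## Region residue distributions. Transmembrane positions draw from a strongly
## hydrophobic alphabet (Kyte-Doolittle >= 1.8 for every member, mean ~3.6);
## loops draw from the complementary hydrophilic alphabet (KD <= -0.4). The
## separation makes ground-truth TMD boundaries well-defined -- see the
## methods vignette for what this deliberately idealizes away.
.TM_DIST <- c(I = 0.26, L = 0.24, V = 0.20, F = 0.14, A = 0.09, M = 0.07)
.LOOP_ALPHABET <- c("G", "T", "S", "W", "Y", "P", "H", "E", "Q", "D", "N",
                    "K", "R")

.loop_probs <- function(side, positive_inside_bias) {
  p <- stats::setNames(rep(1 / 13, 13), .LOOP_ALPHABET)
  if (side == "cytoplasmic") {
    ## positive-inside: additive K/R frequency boost, then renormalized
    p[c("K", "R")] <- p[c("K", "R")] + positive_inside_bias
  } else {
    ## translocated loops are K/R-depleted
    p[c("K", "R")] <- p[c("K", "R")] * 0.25
  }
  p / sum(p)
}

#' Specify a synthetic GT-C-like family
#'
#' Defaults emulate the statistical structure the topology inference relies
#' on: a fixed helix architecture (11/12/13/14 TMDs with large luminal loops
#' after helix 1 and before the C-terminal cluster), hydrophobic
#' membrane-spanning segments, K/R-enriched cytoplasmic loops
#' (positive-inside), near-invariant conserved areas planted in every luminal
#' loop, column-wise substitution noise, and an optional C-terminal dilysine
#' signal for even helix counts. The N-terminus is cytoplasmic by
#' construction, as in every GT-C family model.
#'
#' Planted motifs are given as `list(instance =, rank =, side =)`: the
#' instance string is written into the `rank`-th loop on `side` (N-to-C
#' order, termini included); `x` characters leave the drawn background
#' residue in place and are not motif-defining. Defaults plant the GT-C
#' vocabulary (acidic EL1 pair, EL2 `Rx6LRE`/`Rx4D`, conserved EL3 Lys, the
#' `RxnP` motif of the C-terminal cluster, and conserved areas in the large
#' loops and luminal C-terminus).
#'
#' @param n_tmds Number of helices (>= 3; default 13).
#' @param tm_len_range,loop_short,loop_large Length ranges (residues);
#'   defaults 18-25, 5-15, 40-90.
#' @param large_after Helix indices followed by a large luminal loop; default
#'   `c(1, 9)` for 13 helices, `c(1, 7)` for the 11-helix core architectures
#'   (11/12/14).
#' @param planted_motifs List as above, or `NULL` for architecture defaults.
#' @param n_seqs Sequences per family (default 25, a diverse-homolog set).
#' @param sub_rate Per-position substitution probability outside
#'   motif-defining residues (default 0.25).
#' @param motif_sub_rate Substitution probability at motif-defining residues
#'   (default 0.02).
#' @param positive_inside_bias Additive K/R frequency boost in cytoplasmic
#'   loops (default 0.15).
#' @param dilysine Plant a C-terminal KKxx signal; default `TRUE` for even
#'   `n_tmds` (cytoplasmic C-terminus), else `FALSE`.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @param name Id prefix for the generated records.
#' @return Object of class `family_spec`.
#' @export
family_spec <- function(n_tmds = 13L, tm_len_range = c(18L, 25L),
                        loop_short = c(5L, 15L), loop_large = c(40L, 90L),
                        large_after = NULL, planted_motifs = NULL,
                        n_seqs = 25L, sub_rate = 0.25, motif_sub_rate = 0.02,
                        positive_inside_bias = 0.15, dilysine = NULL,
                        seed = 1L, name = "synthetic") {
  n_tmds <- as.integer(n_tmds)
  if (n_tmds < 3L) stop("n_tmds must be >= 3", call. = FALSE)
  for (r in list(sub_rate, motif_sub_rate)) {
    if (r < 0 || r > 1) stop("substitution rates must lie in [0, 1]",
                             call. = FALSE)
  }
  if (is.null(large_after)) {
    large_after <- if (n_tmds == 13L) c(1L, 9L)
                   else if (n_tmds %in% c(11L, 12L, 14L)) c(1L, 7L)
                   else {
                     h <- n_tmds - 4L
                     if (h %% 2L == 0L) h <- h - 1L
                     unique(c(1L, max(3L, h)))
                   }
  }
  if (any(large_after < 1L | large_after >= n_tmds)) {
    stop("large_after indices must name internal loops (1..n_tmds-1)",
         call. = FALSE)
  }
  if (any(large_after %% 2L == 0L)) {
    stop("large_after must follow odd helices (luminal loops under a cytoplasmic N-terminus)",
         call. = FALSE)
  }
  if (is.null(dilysine)) dilysine <- n_tmds %% 2L == 0L
  if (is.null(planted_motifs)) {
    planted_motifs <- .default_planted(n_tmds, large_after)
  }
  for (m in planted_motifs) {
    if (!grepl("^[ACDEFGHIKLMNPQRSTVWYx]+$", m$instance)) {
      stop("invalid planted motif instance '", m$instance, "'", call. = FALSE)
    }
  }
  spec <- structure(list(
    n_tmds = n_tmds, tm_len_range = as.integer(tm_len_range),
    loop_short = as.integer(loop_short), loop_large = as.integer(loop_large),
    large_after = as.integer(large_after), planted_motifs = planted_motifs,
    n_seqs = as.integer(n_seqs), sub_rate = sub_rate,
    motif_sub_rate = motif_sub_rate,
    positive_inside_bias = positive_inside_bias,
    dilysine = isTRUE(dilysine), seed = as.integer(seed), name = name),
    class = "family_spec")
  .check_motif_capacity(spec)
  spec
}

## luminal conserved areas planted by default, one per luminal loop
.default_planted <- function(n_tmds, large_after) {
  lum <- seq(1L, n_tmds, by = 2L)          # loops after odd helices
  if (n_tmds %% 2L == 0L) lum <- lum[lum < n_tmds]  # even count: C-tail cyto
  area_for <- function(k, after) {
    if (after == 1L) return("EWExGDQNA")
    if (after %in% large_after) return("EDGWSDYQE")
    if (after == 3L) {
      return(if (n_tmds >= 13L) "NRxxxxxxLRE" else "NRxxxxD")
    }
    if (after == 5L) return("YKN")
    ## the luminal loop inside the C-terminal four-helix cluster carries RxnP
    cluster_loop <- if (n_tmds >= 13L) 11L else 9L
    if (after == cluster_loop) {
      return(if (n_tmds >= 13L) "GRxxxxPY" else "GRxxxxxxxxPY")
    }
    if (after == n_tmds) return("WNPDE")   # luminal C-terminus
    c("DWGSE", "WNPDE", "DYE")[(k %% 3L) + 1L]
  }
  lapply(seq_along(lum), function(k) {
    list(instance = area_for(k, lum[k]), rank = k, side = "luminal")
  })
}

## loop ranks on each side, N->C, termini included (loop i follows helix i)
.side_of_loop <- function(i) ifelse(i %% 2L == 0L, "cytoplasmic", "luminal")

.motifs_by_loop <- function(spec) {
  idx <- 0:spec$n_tmds
  sides <- .side_of_loop(idx)
  by_loop <- vector("list", length(idx))
  for (m in spec$planted_motifs) {
    side_loops <- idx[sides == m$side]
    if (m$rank < 1L || m$rank > length(side_loops)) {
      stop("planted motif rank ", m$rank, " exceeds the number of ",
           m$side, " loops", call. = FALSE)
    }
    li <- side_loops[m$rank] + 1L
    by_loop[[li]] <- c(by_loop[[li]], m$instance)
  }
  by_loop
}

.check_motif_capacity <- function(spec) {
  by_loop <- .motifs_by_loop(spec)
  for (i in seq_along(by_loop)) {
    if (is.null(by_loop[[i]])) next
    need <- sum(nchar(by_loop[[i]])) + length(by_loop[[i]]) - 1L
    loop_idx <- i - 1L
    cap <- if (loop_idx %in% spec$large_after) spec$loop_large[2]
           else spec$loop_short[2]
    if (need > cap) {
      stop("loop after helix ", loop_idx, " is too short for its planted ",
           "motifs (need ", need, " residues, capacity ", cap, ")",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Flip planted motifs to the opposite membrane side
#'
#' Involutive spec transform: each planted motif keeps its rank but moves to
#' the same-rank loop on the opposite side. Used to build
#' cytoplasmically-conserved control families.
#'
#' @param spec A `family_spec`.
#' @return A `family_spec` with every motif side flipped.
#' @export
flip_spec_sides <- function(spec) {
  spec$planted_motifs <- lapply(spec$planted_motifs, function(m) {
    m$side <- if (m$side == "luminal") "cytoplasmic" else "luminal"
    m
  })
  .check_motif_capacity(spec)
  spec
}

#' Generate a synthetic family with ground truth
#'
#' Draws one template per spec -- hydrophobic helices, side-conditional loop
#' composition, planted motif instances, optional dilysine tail -- and derives
#' `n_seqs` records by independent per-position substitution (rate
#' `sub_rate`, or `motif_sub_rate` at motif-defining positions) from the
#' region-appropriate residue distribution. The first record is the unmutated
#' template and serves as the reference; the alignment is gapless by
#' construction, so columns coincide with reference positions. Deterministic
#' given the spec (including its seed).
#'
#' @param spec A `family_spec`.
#' @return List with `family` (an `aligned_family`, reference set) and
#'   `truth` (template, segment table, loop table with sides, planted motif
#'   coordinates, defining-position index).
#' @export
generate_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  withr::with_seed(spec$seed, .generate_impl(spec))
}

.generate_impl <- function(spec) {
  n <- spec$n_tmds
  tm_len <- sample(spec$tm_len_range[1]:spec$tm_len_range[2], n,
                   replace = TRUE)
  by_loop <- .motifs_by_loop(spec)
  loop_len <- integer(n + 1L)
  for (i in 0:n) {
    rng <- if (i %in% spec$large_after) spec$loop_large else spec$loop_short
    lb <- rng[1]
    if (!is.null(by_loop[[i + 1L]])) {
      need <- sum(nchar(by_loop[[i + 1L]])) + length(by_loop[[i + 1L]]) - 1L
      lb <- max(lb, need)
    }
    if (spec$dilysine && i == n) lb <- max(lb, 5L)
    if (lb > rng[2]) {
      stop("loop after helix ", i, " too short for planted motifs",
           call. = FALSE)
    }
    loop_len[i + 1L] <- sample(lb:rng[2], 1L)
  }
  lum_p <- .loop_probs("luminal", spec$positive_inside_bias)
  cyt_p <- .loop_probs("cytoplasmic", spec$positive_inside_bias)
  template <- character(0)
  region <- character(0)            # "tm" / "luminal" / "cytoplasmic"
  seg_start <- integer(n); seg_end <- integer(n)
  loop_start <- integer(n + 1L); loop_end <- integer(n + 1L)
  for (i in 0:n) {
    side <- .side_of_loop(i)
    p <- if (side == "cytoplasmic") cyt_p else lum_p
    loop_start[i + 1L] <- length(template) + 1L
    template <- c(template, sample(.LOOP_ALPHABET, loop_len[i + 1L],
                                   replace = TRUE, prob = p))
    region <- c(region, rep(side, loop_len[i + 1L]))
    loop_end[i + 1L] <- length(template)
    if (i < n) {
      seg_start[i + 1L] <- length(template) + 1L
      template <- c(template, sample(names(.TM_DIST), tm_len[i + 1L],
                                     replace = TRUE, prob = .TM_DIST))
      region <- c(region, rep("tm", tm_len[i + 1L]))
      seg_end[i + 1L] <- length(template)
    }
  }
  L <- length(template)
  defining <- logical(L)
  motif_rows <- list()
  for (i in 0:n) {
    inst <- by_loop[[i + 1L]]
    if (is.null(inst)) next
    need <- sum(nchar(inst)) + length(inst) - 1L
    at <- loop_start[i + 1L] + (loop_len[i + 1L] - need) %/% 2L
    for (m in inst) {
      chars <- strsplit(m, "")[[1]]
      for (k in seq_along(chars)) {
        if (chars[k] != "x") {
          template[at + k - 1L] <- chars[k]
          defining[at + k - 1L] <- TRUE
        }
      }
      motif_rows[[length(motif_rows) + 1L]] <-
        data.frame(instance = m, loop_index = i, start = at,
                   end = at + nchar(m) - 1L, side = .side_of_loop(i))
      at <- at + nchar(m) + 1L
    }
  }
  if (spec$dilysine) {
    template[c(L - 3L, L - 2L)] <- "K"
    defining[c(L - 3L, L - 2L)] <- TRUE
  }
  ## per-position substitution rate and replacement distribution
  rate <- ifelse(defining, spec$motif_sub_rate, spec$sub_rate)
  seqs <- matrix(rep(template, each = spec$n_seqs), nrow = spec$n_seqs)
  if (spec$n_seqs > 1L) {
    nmut <- spec$n_seqs - 1L
    repl <- matrix(NA_character_, nmut, L)
    for (rg in c("tm", "luminal", "cytoplasmic")) {
      cols <- which(region == rg)
      if (!length(cols)) next
      repl[, cols] <- switch(rg,
        tm = sample(names(.TM_DIST), nmut * length(cols), replace = TRUE,
                    prob = .TM_DIST),
        luminal = sample(.LOOP_ALPHABET, nmut * length(cols), replace = TRUE,
                         prob = lum_p),
        cytoplasmic = sample(.LOOP_ALPHABET, nmut * length(cols),
                             replace = TRUE, prob = cyt_p))
    }
    mut <- matrix(stats::runif(nmut * L), nmut, L) <
      matrix(rate, nmut, L, byrow = TRUE)
    body <- seqs[-1L, , drop = FALSE]
    body[mut] <- repl[mut]
    seqs[-1L, ] <- body
  }
  ids <- sprintf("%s%03d", spec$name, seq_len(spec$n_seqs))
  fam <- aligned_family(ids, apply(seqs, 1L, paste, collapse = ""))
  fam <- set_reference(fam, ids[1])
  segments <- data.frame(index = seq_len(n), start = seg_start,
                         end = seg_end)
  truth_model <- topology_model(segments, "cytoplasmic", L)
  truth <- list(
    template = paste(template, collapse = ""),
    segments = segments,
    loops = truth_model$loops,
    motifs = if (length(motif_rows)) do.call(rbind, motif_rows)
             else data.frame(),
    defining = which(defining),
    n_term_side = "cytoplasmic",
    dilysine = spec$dilysine,
    spec = spec)
  list(family = fam, truth = truth)
}

#' Generate a cytoplasmically-conserved control family
#'
#' Identical generator with every planted motif moved to the same-rank
#' cytoplasmic loop: emulates an ER enzyme catalyzing on the cytoplasmic
#' face, whose conservation asymmetry statistic should invert its sign.
#'
#' @param spec A `family_spec`.
#' @return As [generate_family()].
#' @export
control_family <- function(spec) {
  generate_family(flip_spec_sides(spec))
}

#' Write a synthetic family and its truth to disk
#'
#' @param sim Result of [generate_family()].
#' @param dir Output directory (created if needed); writes
#'   `<name>.aln.fasta` and `<name>.truth.json`.
#' @return Invisibly, the two paths.
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  name <- sim$truth$spec$name
  fa <- file.path(dir, paste0(name, ".aln.fasta"))
  js <- file.path(dir, paste0(name, ".truth.json"))
  write_alignment(sim$family, fa, "fasta")
  truth <- sim$truth
  truth$spec <- unclass(truth$spec)
  jsonlite::write_json(truth, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(fa, js))
}
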