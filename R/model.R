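## Family model assembly: organization class, conservation asymmetry test,
## and the consolidated report.

#' Topology-organization string
#'
#' Partitions the helices of a topology model at its large luminal loops and
#' reports the group sizes as `"a-b-c[-d]"`. With the canonical GT-C
#' landmarks -- a large luminal loop after helix 1 and another before the
#' C-terminal helix cluster -- this yields `1-6-4` (11 helices), `1-8-4`
#' (13), and, when extra C-terminal helices follow the canonical last four
#' behind short loops, `1-6-5` or `1-6-7` (12 / 14 helices).
#'
#' @param model A `topology_model` with at least 3 segments.
#' @param large_loop_min Minimum luminal loop length (residues) counting as an
#'   organization landmark; default 40 (the landmark loops are ~40-90
#'   residues, ordinary inter-helix loops < 15).
#' @return Character scalar, e.g. `"1-8-4"`; `NA` with a `reason` attribute
#'   when fewer than 3 segments are present.
#' @export
organization_string <- function(model, large_loop_min = 40L) {
  n <- nrow(model$segments)
  if (n < 3L) {
    return(structure(NA_character_, reason = "fewer than 3 segments"))
  }
  ## internal loops only (loop i sits after helix i, i in 1..n-1)
  loops <- model$loops
  internal <- loops[loops$loop_index >= 1L & loops$loop_index < n, ]
  brk <- internal$loop_index[internal$side == "luminal" &
                             internal$length >= large_loop_min]
  parts <- diff(c(0L, sort(brk), n))
  paste(parts, collapse = "-")
}

#' Luminal-versus-cytoplasmic conservation asymmetry test
#'
#' The observed statistic is the mean information content over all
#' luminal-loop positions minus the mean over all cytoplasmic-loop positions
#' (termini included, membrane-spanning positions excluded). Catalytic GT-C
#' families concentrate conservation in luminal loops (positive statistic); a
#' cytoplasmically active control such as DPAGT1 inverts the sign.
#'
#' The null distribution reassigns the side label of each loop at random (a
#' permutation of the observed labels across loops), preserving loop lengths
#' and within-loop IC autocorrelation while dropping the alternation
#' constraint. The one-sided p-value uses the add-one correction
#' `(1 + #(null >= observed)) / (n_perm + 1)`, so it can never be zero.
#'
#' @param model A `topology_model` with at least two loops on each side.
#' @param profile A `conservation_profile` on the same reference length.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed; the test is deterministic given `(seed, n_perm)`.
#' @return Object of class `asymmetry_result`: `statistic` (bits), `p_value`,
#'   `n_perm`, `seed`, and the per-loop summary used.
#' @export
asymmetry_test <- function(model, profile, n_perm = 1000L, seed = 1L) {
  if (model$length != length(profile$positions)) {
    stop("model and profile disagree on reference length", call. = FALSE)
  }
  loops <- model$loops[model$loops$length > 0L, ]
  if (sum(loops$side == "luminal") < 2L ||
      sum(loops$side == "cytoplasmic") < 2L) {
    stop("insufficient structure: need >= 2 loops on each side",
         call. = FALSE)
  }
  ic <- profile$ic
  s <- vapply(seq_len(nrow(loops)),
              function(i) sum(ic[loops$start[i]:loops$end[i]]), numeric(1))
  len <- loops$length
  lum <- loops$side == "luminal"
  stat_for <- function(mask) {
    sum(s[mask]) / sum(len[mask]) - sum(s[!mask]) / sum(len[!mask])
  }
  observed <- stat_for(lum)
  null <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(k) stat_for(sample(lum)), numeric(1))
  })
  p <- (1 + sum(null >= observed)) / (n_perm + 1)
  structure(list(statistic = observed, p_value = p, n_perm = as.integer(n_perm),
                 seed = as.integer(seed),
                 loop_summary = data.frame(label = loops$label,
                                           side = loops$side,
                                           length = len,
                                           mean_ic = s / len)),
            class = "asymmetry_result")
}

#' @export
print.asymmetry_result <- function(x, ...) {
  cat(sprintf(
    "Conservation asymmetry (luminal - cytoplasmic): %.3f bits, one-sided p = %.4g (%d permutations)\n",
    x$statistic, x$p_value, x$n_perm))
  invisible(x)
}

#' Assemble an annotated family model report
#'
#' Cross-checks the observed topology against a registry expectation and the
#' motif hits against their expected membrane side, and bundles topology,
#' organization, conservation asymmetry and hits into one report. Raised
#' flags: `count_mismatch` (observed vs expected TMD number),
#' `dilysine_not_cytoplasmic` (a dilysine hit whose C-terminal loop is not on
#' the cytoplasmic face cannot act as an ER-retrieval signal), and
#' `motif_side:<name>` for any library motif found only on the wrong side.
#'
#' @param family_name Name for the report (registry key when available).
#' @param family The degapped `aligned_family`.
#' @param model A `topology_model`.
#' @param profile A `conservation_profile`.
#' @param hits Motif hits (will be passed through [assign_loops()]).
#' @param registry_entry Optional single-row data frame from
#'   [gtc_family_registry()].
#' @param library Motif library used for expected-side checks (default
#'   [gtc_motif_library()]).
#' @param asymmetry Optional precomputed `asymmetry_result`; computed with
#'   `n_perm`/`seed` when `NULL` and the model has enough loops.
#' @param n_perm,seed Passed to [asymmetry_test()] when computing it here.
#' @param conserved_cutoff Class-frequency cutoff for the conserved-position
#'   table (default 0.8).
#' @param large_loop_min Passed to [organization_string()].
#' @return Object of class `family_report`.
#' @export
build_report <- function(family_name, family, model, profile, hits,
                         registry_entry = NULL, library = gtc_motif_library(),
                         asymmetry = NULL, n_perm = 1000L, seed = 1L,
                         conserved_cutoff = 0.8, large_loop_min = 40L) {
  L <- nchar(reference_sequence(family))
  if (model$length != L || length(profile$positions) != L) {
    stop("family, model and profile disagree on reference length",
         call. = FALSE)
  }
  hits <- assign_loops(hits, model)
  conserved <- call_conserved(profile, mode = "class_freq",
                              cutoff = conserved_cutoff)
  if (nrow(conserved)) {
    conserved <- .attach_sides(conserved, model)
  }
  if (is.null(asymmetry)) {
    loops <- model$loops[model$loops$length > 0L, ]
    if (sum(loops$side == "luminal") >= 2L &&
        sum(loops$side == "cytoplasmic") >= 2L) {
      asymmetry <- asymmetry_test(model, profile, n_perm = n_perm,
                                  seed = seed)
    }
  }
  flags <- character(0)
  expected_tmds <- NA_integer_
  if (!is.null(registry_entry) && nrow(registry_entry) == 1L) {
    expected_tmds <- registry_entry$n_tmds
    if (expected_tmds != nrow(model$segments)) flags <- c(flags, "count_mismatch")
  }
  if (nrow(hits)) {
    expected_sides <- list()
    for (entry in library) expected_sides[[entry$name]] <- entry$expected_side
    dily <- grepl("^dilysine", hits$name)
    if (any(dily)) {
      if (!any(hits$side[dily] == "cytoplasmic", na.rm = TRUE)) {
        flags <- c(flags, "dilysine_not_cytoplasmic")
      }
    }
    for (nm in unique(hits$name[!dily])) {
      exp_side <- expected_sides[[nm]]
      if (is.null(exp_side) || exp_side == "either") next
      ok <- any(hits$side[hits$name == nm] == exp_side, na.rm = TRUE)
      if (!ok) flags <- c(flags, paste0("motif_side:", nm))
    }
  }
  structure(list(
    family = family_name,
    reference_id = family$reference_id,
    n_tmds = nrow(model$segments),
    expected_tmds = expected_tmds,
    organization = organization_string(model, large_loop_min = large_loop_min),
    n_term_side = model$n_term_side,
    orientation_decided_by = model$decided_by,
    model = model,
    hits = hits,
    conserved = conserved,
    asymmetry = asymmetry,
    flags = flags,
    parameters = list(n_perm = n_perm, seed = seed,
                      conserved_cutoff = conserved_cutoff,
                      large_loop_min = large_loop_min)
  ), class = "family_report")
}

.attach_sides <- function(conserved, model) {
  conserved$loop <- NA_character_
  conserved$side <- NA_character_
  seg <- model$segments
  loops <- model$loops
  for (i in seq_len(nrow(conserved))) {
    p <- conserved$position[i]
    if (any(seg$start <= p & seg$end >= p)) {
      conserved$loop[i] <- paste0("TMD-embedded:TMD",
                                  seg$index[which(seg$start <= p &
                                                  seg$end >= p)[1]])
    } else {
      lp <- which(loops$start <= p & loops$end >= p)
      conserved$loop[i] <- loops$label[lp[1]]
      conserved$side[i] <- loops$side[lp[1]]
    }
  }
  conserved
}

#' @export
print.family_report <- function(x, ...) {
  cat("Family model report: ", x$family, "\n", sep = "")
  cat("  TMDs: ", x$n_tmds,
      if (!is.na(x$expected_tmds)) paste0(" (expected ", x$expected_tmds, ")"),
      "; organization ", x$organization,
      "; N-terminus ", x$n_term_side, "\n", sep = "")
  if (!is.null(x$asymmetry)) {
    cat("  ")
    print(x$asymmetry)
  }
  cat("  Motif hits: ", nrow(x$hits), "; flags: ",
      if (length(x$flags)) paste(x$flags, collapse = ", ") else "none",
      "\n", sep = "")
  invisible(x)
}

#' Serialize a family report to JSON
#'
#' All thresholds and seeds used are echoed so that a run can be reproduced
#' from its own report. Deterministic field order; no timestamps.
#'
#' @param report A `family_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report_json <- function(report, path) {
  out <- list(
    schema = "gtctopo-family-report/1",
    family = report$family,
    reference_id = report$reference_id,
    n_tmds = report$n_tmds,
    expected_tmds = report$expected_tmds,
    organization = as.character(report$organization),
    n_term_side = report$n_term_side,
    orientation_decided_by = report$orientation_decided_by,
    segments = report$model$segments,
    loops = report$model$loops,
    hits = report$hits,
    conserved = report$conserved,
    asymmetry = if (!is.null(report$asymmetry)) {
      list(statistic = report$asymmetry$statistic,
           p_value = report$asymmetry$p_value,
           n_perm = report$asymmetry$n_perm,
           seed = report$asymmetry$seed)
    },
    flags = as.list(report$flags),
    parameters = report$parameters
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Flat TSV summary of a family report
#' @param report A `family_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report_tsv <- function(report, path) {
  df <- data.frame(
    family = report$family,
    n_tmds = report$n_tmds,
    expected_tmds = report$expected_tmds,
    organization = as.character(report$organization),
    n_term_side = report$n_term_side,
    asymmetry_statistic = if (!is.null(report$asymmetry))
      report$asymmetry$statistic else NA_real_,
    asymmetry_p = if (!is.null(report$asymmetry))
      report$asymmetry$p_value else NA_real_,
    n_hits = nrow(report$hits),
    flags = paste(report$flags, collapse = ","))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
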