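## End-to-end orchestration: alignment -> topology -> conservation -> motifs
## -> family report, plus the glycopeptide ladder entry point.

#' Recover a topology model from a degapped family
#'
#' Profile, segmentation and orientation in one step: consensus hydropathy
#' ([hydropathy_profile()]), threshold segmentation ([segment_tmds()])
#' followed by default boundary refinement ([refine_tmds()]), optional
#' forced-loop intervals, and orientation ([orient()]).
#'
#' @param family Degapped `aligned_family` with reference set.
#' @param window,threshold,min_tm,max_tm See [hydropathy_profile()] and
#'   [segment_tmds()].
#' @param refine Use the dynamic-programming boundary refinement
#'   (default TRUE).
#' @param forced_loops Optional data frame of `start`/`end` intervals forced
#'   to be loops.
#' @param check_dilysine Passed to [orient()].
#' @return List with `profile`, `segments`, `model`, `conflicts`.
#' @export
recover_topology <- function(family, window = 19L, threshold = 1.5,
                             min_tm = 15L, max_tm = 28L, refine = TRUE,
                             forced_loops = NULL, check_dilysine = TRUE) {
  profile <- hydropathy_profile(family, window = window)
  segments <- if (refine) {
    refine_tmds(profile, threshold = threshold, min_tm = min_tm,
                max_tm = max_tm)
  } else {
    segment_tmds(profile, threshold = threshold, min_tm = min_tm,
                 max_tm = max_tm)
  }
  conflicts <- data.frame()
  if (!is.null(forced_loops) && nrow(forced_loops)) {
    fl <- force_loops(segments, forced_loops, min_tm = min_tm)
    segments <- fl$segments
    conflicts <- fl$conflicts
  }
  model <- orient(segments, family, check_dilysine = check_dilysine)
  list(profile = profile, segments = segments, model = model,
       conflicts = conflicts)
}

#' Build a run configuration
#'
#' Collects every tunable of a family run; [run_family()] echoes the full
#' configuration into its report so a run is reproducible from its own
#' output.
#'
#' @param alignment Path to the input alignment.
#' @param format Alignment dialect (`"fasta"`, `"stockholm"`, `"clustal"`).
#' @param reference_id Identifier of the reference sequence (mandatory).
#' @param family Optional registry key (e.g. `"STT3"`); enables expected-TMD
#'   cross-checks.
#' @param window,threshold,min_tm,max_tm,refine Topology parameters.
#' @param conserved_cutoff Class-frequency cutoff for conserved calls.
#' @param large_loop_min Organization landmark threshold (residues).
#' @param n_perm,seed Permutation-test parameters (seed mandatory).
#' @param out_dir Output directory for artifacts.
#' @return List of class `run_config`.
#' @export
family_config <- function(alignment, format = "fasta", reference_id,
                          family = NULL, window = 19L, threshold = 1.5,
                          min_tm = 15L, max_tm = 28L, refine = TRUE,
                          conserved_cutoff = 0.8, large_loop_min = 40L,
                          n_perm = 1000L, seed = 1L, out_dir = NULL) {
  if (missing(reference_id) || is.null(reference_id)) {
    stop("usage error: reference_id is required", call. = FALSE)
  }
  if (window < 5L || window %% 2L == 0L) stop("window must be odd >= 5",
                                              call. = FALSE)
  if (min_tm >= max_tm) stop("min_tm must be < max_tm", call. = FALSE)
  if (conserved_cutoff <= 0 || conserved_cutoff > 1) {
    stop("conserved_cutoff must lie in (0, 1]", call. = FALSE)
  }
  if (n_perm > 0L && is.null(seed)) {
    stop("usage error: seed is required when permutations are requested",
         call. = FALSE)
  }
  structure(list(alignment = alignment, format = format,
                 reference_id = reference_id, family = family,
                 window = as.integer(window), threshold = threshold,
                 min_tm = as.integer(min_tm), max_tm = as.integer(max_tm),
                 refine = isTRUE(refine), conserved_cutoff = conserved_cutoff,
                 large_loop_min = as.integer(large_loop_min),
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full family pipeline
#'
#' Reads the alignment, sets the reference and degaps to it, recovers the
#' topology, profiles conservation, scans the motif library within the
#' model, runs the asymmetry test and assembles the report. When
#' `config$out_dir` is set, writes `profile.tsv`, `segments.tsv`,
#' `logo.tsv`, `conservation.tsv`, `hits.tsv` and `report.json` there.
#' Re-running an identical configuration reproduces the artifacts
#' byte-identically (no timestamps are written).
#'
#' @param config A `run_config` from [family_config()].
#' @param library Motif library (default [gtc_motif_library()]).
#' @return A `family_report`.
#' @export
run_family <- function(config, library = gtc_motif_library()) {
  stopifnot(inherits(config, "run_config"))
  fam <- read_alignment(config$alignment, config$format)
  fam <- set_reference(fam, config$reference_id)
  fam <- degap_to_reference(fam)
  topo <- recover_topology(fam, window = config$window,
                           threshold = config$threshold,
                           min_tm = config$min_tm, max_tm = config$max_tm,
                           refine = config$refine)
  if (nrow(topo$segments) == 0L) {
    stop("pipeline stage 'topology': no transmembrane segment found",
         call. = FALSE)
  }
  profile <- conservation_profile(fam)
  refseq <- reference_sequence(fam)
  hits <- scan_library(refseq, library, family = config$family)
  registry_entry <- NULL
  if (!is.null(config$family)) {
    reg <- gtc_family_registry()
    registry_entry <- reg[reg$family == config$family, ]
    if (nrow(registry_entry) == 0L) {
      stop("unknown registry family '", config$family, "'", call. = FALSE)
    }
  }
  report <- build_report(
    family_name = if (is.null(config$family)) config$reference_id
                  else config$family,
    family = fam, model = topo$model, profile = profile, hits = hits,
    registry_entry = registry_entry, library = library,
    n_perm = config$n_perm, seed = config$seed,
    conserved_cutoff = config$conserved_cutoff,
    large_loop_min = config$large_loop_min)
  report$config <- unclass(config)
  report$conflicts <- topo$conflicts
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_profile_tsv(topo$profile,
                      file.path(config$out_dir, "profile.tsv"),
                      segments = topo$segments)
    write_segments_tsv(topo$segments,
                       file.path(config$out_dir, "segments.tsv"),
                       ref_name = fam$reference_id)
    write_logo_tsv(profile, file.path(config$out_dir, "logo.tsv"))
    write_conservation_tsv(profile,
                           file.path(config$out_dir, "conservation.tsv"))
    write_hits_tsv(report$hits, file.path(config$out_dir, "hits.tsv"))
    write_report_json(report, file.path(config$out_dir, "report.json"))
  }
  report
}

#' Glycopeptide m/z ladder entry point
#'
#' Computes the hexose ladder for a peptide and optionally writes it as TSV.
#'
#' @param peptide Peptide residue string.
#' @param max_hex Maximum hexose count.
#' @param charges Integer vector of charge states.
#' @param carbamidomethyl Fixed Cys alkylation (default TRUE).
#' @param out Optional TSV output path.
#' @return The ladder data frame (invisibly when `out` is given).
#' @export
run_mz <- function(peptide, max_hex, charges, carbamidomethyl = TRUE,
                   out = NULL) {
  ladder <- hexose_ladder(peptide, max_hex, charges,
                          carbamidomethyl = carbamidomethyl)
  if (!is.null(out)) {
    utils::write.table(format(ladder, digits = 10), out, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    return(invisible(ladder))
  }
  ladder
}
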