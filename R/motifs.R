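## Degenerate motif grammar, scanning, loop assignment and the GT-C library.

#' Compile a degenerate motif pattern
#'
#' The grammar is PROSITE-like: a literal residue matches itself, `[DE]`
#' matches a residue class, `x` is a wildcard over the 20-letter alphabet, an
#' element may carry a bounded repeat `{m}` / `{m,n}` or an optional marker
#' `?` (i.e. `{0,1}`), and a trailing `$` anchors the match to the C-terminus.
#' Examples from the GT-C motif vocabulary: `"[DE]x?[DE]"` (the EL1 acidic
#' pair, matching DD, DxE, ExE, ...), `"Rx{6}LRE"`, `"Rx{4,14}P"`, `"KKxx$"`.
#'
#' @param pattern Grammar string.
#' @param name Optional pattern name (defaults to the pattern string).
#' @param expected_side Where the motif is expected on a topology model:
#'   `"luminal"`, `"cytoplasmic"` or `"either"`.
#' @return An object of class `motif_pattern` with the canonical element list
#'   and a `normalized` string; `compile_motif(normalize)` is idempotent.
#' @export
compile_motif <- function(pattern, name = pattern,
                          expected_side = c("either", "luminal",
                                            "cytoplasmic")) {
  expected_side <- match.arg(expected_side)
  chars <- strsplit(pattern, "")[[1]]
  n <- length(chars)
  elements <- list()
  anchored <- FALSE
  i <- 1L
  syntax_error <- function(pos, msg) {
    stop(sprintf("motif syntax error at position %d of '%s': %s",
                 pos, pattern, msg), call. = FALSE)
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch == "$") {
      if (i != n) syntax_error(i, "'$' is only valid at the end")
      anchored <- TRUE
      i <- i + 1L
      next
    }
    if (anchored) syntax_error(i, "elements after '$'")
    if (ch == "x") {
      res <- AA_ALPHABET
      i <- i + 1L
    } else if (ch == "[") {
      j <- i + 1L
      res <- character(0)
      while (j <= n && chars[j] != "]") {
        if (!chars[j] %in% AA_ALPHABET) {
          syntax_error(j, paste0("invalid residue '", chars[j], "' in class"))
        }
        res <- c(res, chars[j])
        j <- j + 1L
      }
      if (j > n) syntax_error(i, "unterminated '['")
      if (length(res) == 0L) syntax_error(i, "empty residue class")
      i <- j + 1L
    } else if (ch %in% AA_ALPHABET) {
      res <- ch
      i <- i + 1L
    } else {
      syntax_error(i, paste0("unexpected character '", ch, "'"))
    }
    lo <- 1L; hi <- 1L
    if (i <= n && chars[i] == "?") {
      lo <- 0L
      i <- i + 1L
    } else if (i <= n && chars[i] == "{") {
      j <- i + 1L
      while (j <= n && chars[j] != "}") j <- j + 1L
      if (j > n) syntax_error(i, "unterminated '{'")
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      if (!grepl("^[0-9]+(,[0-9]+)?$", body)) {
        syntax_error(i + 1L, "repeat must be {m} or {m,n}")
      }
      parts <- as.integer(strsplit(body, ",")[[1]])
      lo <- parts[1]
      hi <- if (length(parts) == 2L) parts[2] else parts[1]
      if (lo > hi) syntax_error(i + 1L, sprintf("m > n in {%s}", body))
      i <- j + 1L
    }
    elements[[length(elements) + 1L]] <-
      list(residues = sort(unique(res)), min = lo, max = hi)
  }
  if (length(elements) == 0L) {
    stop("motif syntax error: empty pattern", call. = FALSE)
  }
  obj <- structure(list(name = name, pattern = pattern,
                        elements = elements, anchored = anchored,
                        expected_side = expected_side),
                   class = "motif_pattern")
  obj$normalized <- .normalize_motif(obj)
  obj
}

.normalize_motif <- function(p) {
  parts <- vapply(p$elements, function(el) {
    base <- if (length(el$residues) == 20L) "x"
            else if (length(el$residues) == 1L) el$residues
            else paste0("[", paste(el$residues, collapse = ""), "]")
    quant <- if (el$min == 1L && el$max == 1L) ""
             else if (el$min == 0L && el$max == 1L) "?"
             else if (el$min == el$max) sprintf("{%d}", el$min)
             else sprintf("{%d,%d}", el$min, el$max)
    paste0(base, quant)
  }, character(1))
  paste0(paste(parts, collapse = ""), if (p$anchored) "$" else "")
}

#' @export
print.motif_pattern <- function(x, ...) {
  w <- motif_width_range(x)
  cat("Motif '", x$name, "': ", x$normalized, " (width ", w[1],
      if (w[2] > w[1]) paste0("-", w[2]), ", expected side: ",
      x$expected_side, ")\n", sep = "")
  invisible(x)
}

#' Width bounds of a compiled motif
#' @param pattern A `motif_pattern`.
#' @return Integer vector `c(min_width, max_width)`.
#' @export
motif_width_range <- function(pattern) {
  c(sum(vapply(pattern$elements, `[[`, integer(1), "min")),
    sum(vapply(pattern$elements, `[[`, integer(1), "max")))
}

#' Scan a sequence for a degenerate motif
#'
#' Reports matches leftmost-first with 1-based inclusive coordinates. With
#' `overlapping = TRUE` (the default for library scans, since motif spacing
#' varies across families) every admissible match span is reported, including
#' all repeat widths at a common start. With `overlapping = FALSE` the scan is
#' greedy left-to-right, keeping the shortest match at each accepted start and
#' skipping overlapped starts.
#'
#' Wildcards range over the 20-letter alphabet only, so an `X` in the
#' sequence never matches.
#'
#' @param sequence Residue string (1-based positions).
#' @param pattern A `motif_pattern` (or grammar string, compiled on the fly).
#' @param overlapping Logical (default TRUE).
#' @return Data frame with columns `name`, `start`, `end`, `match`, and
#'   placeholder `loop`/`side` columns filled by [assign_loops()].
#' @export
scan_motif <- function(sequence, pattern, overlapping = TRUE) {
  if (is.character(pattern)) pattern <- compile_motif(pattern)
  stopifnot(inherits(pattern, "motif_pattern"))
  widths <- lapply(pattern$elements, function(el) el$min:el$max)
  n_combo <- prod(vapply(widths, length, numeric(1)))
  if (n_combo > 1e5) {
    stop("pattern expands to too many repeat-width combinations", call. = FALSE)
  }
  grid <- expand.grid(widths, KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(g) {
    ws <- as.integer(grid[g, ])
    rx <- paste(vapply(seq_along(ws), function(e) {
      if (ws[e] == 0L) return("")
      cls <- paste0("[", paste(pattern$elements[[e]]$residues, collapse = ""),
                    "]")
      if (ws[e] == 1L) cls else sprintf("%s{%d}", cls, ws[e])
    }, character(1)), collapse = "")
    if (rx == "") return(NULL)
    if (pattern$anchored) rx <- paste0(rx, "$")
    m <- gregexpr(paste0("(?=(", rx, "))"), sequence, perl = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    data.frame(start = as.integer(m), width = sum(ws))
  })
  res <- do.call(rbind, res)
  if (is.null(res) || nrow(res) == 0L) {
    return(.empty_hits())
  }
  res <- unique(res)
  res <- res[order(res$start, res$width), , drop = FALSE]
  if (!overlapping) {
    keep <- logical(nrow(res))
    last_end <- 0L
    for (i in seq_len(nrow(res))) {
      if (res$start[i] > last_end) {
        keep[i] <- TRUE
        last_end <- res$start[i] + res$width[i] - 1L
      }
    }
    res <- res[keep, , drop = FALSE]
  }
  data.frame(name = pattern$name, start = res$start,
             end = res$start + res$width - 1L,
             match = substring(sequence, res$start,
                               res$start + res$width - 1L),
             loop = NA_character_, side = NA_character_,
             row.names = NULL)
}

.empty_hits <- function() {
  data.frame(name = character(0), start = integer(0), end = integer(0),
             match = character(0), loop = character(0), side = character(0))
}

#' Assign motif hits to topology loops
#'
#' A hit is placed in the inter-segment loop (or terminus) containing its
#' start; hits overlapping any TMD are labelled `TMD-embedded` (some conserved
#' residues sit inside a membrane-spanning segment). Coordinates are never
#' altered; every hit receives exactly one label.
#'
#' @param hits Data frame from [scan_motif()].
#' @param model A `topology_model` covering the scanned sequence.
#' @return `hits` with `loop` and `side` filled (side `NA` for embedded hits).
#' @export
assign_loops <- function(hits, model) {
  if (nrow(hits) == 0L) return(hits)
  if (max(hits$end) > model$length) {
    stop("hit coordinates exceed the model length", call. = FALSE)
  }
  seg <- model$segments
  loops <- model$loops
  for (i in seq_len(nrow(hits))) {
    hs <- hits$start[i]; he <- hits$end[i]
    ov <- which(seg$start <= he & seg$end >= hs)
    if (length(ov)) {
      hits$loop[i] <- paste0("TMD-embedded:TMD", seg$index[ov[1]])
      hits$side[i] <- NA_character_
    } else {
      lp <- which(loops$start <= hs & loops$end >= hs)
      hits$loop[i] <- loops$label[lp[1]]
      hits$side[i] <- loops$side[lp[1]]
    }
  }
  hits
}

#' Detect a C-terminal dilysine ER-retrieval signal
#'
#' Lysines at positions -3/-4 (`KKxx$`) or -3/-5 (`KxKxx$`) from the
#' C-terminus.
#'
#' @param sequence Residue string.
#' @return Logical scalar.
#' @export
has_dilysine <- function(sequence) {
  L <- nchar(sequence)
  kk <- L >= 4L && substr(sequence, L - 3L, L - 2L) == "KK"
  kxk <- L >= 5L && substr(sequence, L - 4L, L - 4L) == "K" &&
    substr(sequence, L - 2L, L - 2L) == "K"
  kk || kxk
}

#' The GT-C luminal motif library
#'
#' Curated degenerate patterns observed across GT-C glycosyltransferase
#' families: the EL1 acidic pair (`[DE]x?[DE]`, e.g. ExD in STT3 / ExE in
#' DPY19), the EL2 variants (`Rx{6}[DL][NR]E` for STT3/DPY19 and `Rx{4}D`
#' elsewhere), the conserved basic/amide single position of EL3 (a residue
#' class, applied through [call_conserved()] rather than string matching), the
#' `Rx{4,14}P` motif of the C-terminal helix cluster's luminal loop, and the
#' cytoplasmic C-terminal dilysine forms. Editable: supply your own TSV with
#' columns `name`, `pattern`, `expected_side`, `type`, `families`.
#'
#' @param path Optional path to a library TSV; defaults to the file shipped
#'   in `inst/extdata/motif_library.tsv`.
#' @return List of library entries; entries of type `"pattern"` carry a
#'   compiled `motif_pattern` in `$compiled`.
#' @export
gtc_motif_library <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "motif_library.tsv", package = "gtctopo",
                        mustWork = TRUE)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  lapply(seq_len(nrow(df)), function(i) {
    entry <- as.list(df[i, ])
    if (entry$type == "pattern") {
      entry$compiled <- compile_motif(entry$pattern, name = entry$name,
                                      expected_side = entry$expected_side)
    }
    entry
  })
}

#' The GT-C family registry
#'
#' Maps each GT-C family to its expected transmembrane-helix count,
#' topology-organization class, whether a C-terminal dilysine signal is
#' expected (even helix counts, cytoplasmic C-terminus) and which library
#' motifs are known to be absent (ALG9 lacks the EL2 and EL3 motifs).
#'
#' @param path Optional path to a registry TSV; defaults to the shipped file.
#' @return Data frame with columns `family`, `n_tmds`, `organization`,
#'   `dilysine`, `motifs_absent`.
#' @export
gtc_family_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "family_registry.tsv", package = "gtctopo",
                        mustWork = TRUE)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  df$dilysine <- as.logical(df$dilysine)
  df
}

#' Scan a sequence with every pattern in a library
#'
#' @param sequence Residue string.
#' @param library Library from [gtc_motif_library()].
#' @param overlapping Passed to [scan_motif()].
#' @param family Optional registry family name; entries whose `families`
#'   column names other families only are skipped.
#' @return Combined hit data frame.
#' @export
scan_library <- function(sequence, library = gtc_motif_library(),
                         overlapping = TRUE, family = NULL) {
  hits <- lapply(library, function(entry) {
    if (entry$type != "pattern") return(NULL)
    if (!is.null(family) && entry$families != "all" &&
        !family %in% strsplit(entry$families, ",")[[1]]) {
      return(NULL)
    }
    scan_motif(sequence, entry$compiled, overlapping = overlapping)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits)) .empty_hits() else hits
}

#' Export motif hits as TSV
#' @param hits Hit data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hits_tsv <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
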