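test_that("the degenerate grammar compiles, normalizes and rejects bad syntax", {
  p <- compile_motif("[DE]x?[DE]")
  expect_equal(motif_width_range(p), c(2L, 3L))
  ## matches exactly the 8 acid-pair variants
  for (s in c("DD", "DE", "ED", "EE")) {
    expect_equal(nrow(scan_motif(s, p)), 1L, label = s)
  }
  for (s in c("DAD", "EAE", "DAE", "EAD")) {
    expect_true(any(scan_motif(s, p)$end - scan_motif(s, p)$start == 2),
                label = s)
  }
  expect_equal(nrow(scan_motif("DAAD", p)), 0L)

  p2 <- compile_motif("Rx{6}LRE")
  expect_equal(motif_width_range(p2), c(10L, 10L))

  expect_error(compile_motif("Rx{4,2}P"), "m > n")
  expect_error(compile_motif("R[DE"), "unterminated")
  expect_error(compile_motif("R$E"), "end")
  expect_error(compile_motif("Rx{a}"), "repeat")
  expect_error(compile_motif("[]E"), "empty")

  ## compile . normalize is idempotent
  for (pat in c("[DE]x?[DE]", "Rx{6}[DL][NR]E", "Rx{4,14}P", "KKxx$",
                "[ED][ED]x{2,3}W?")) {
    n1 <- compile_motif(pat)$normalized
    expect_identical(compile_motif(n1)$normalized, n1, label = pat)
  }
})

test_that("scanning reports 1-based inclusive spans, leftmost-first", {
  ## an Rx6-LRE site placed so the arginine sits at position 211
  seq <- paste0(strrep("A", 210), "R", "GSTWYH", "LRE", strrep("A", 30))
  hits <- scan_motif(seq, compile_motif("Rx{6}LRE"))
  expect_equal(hits$start, 211L)
  expect_equal(hits$end, 220L)
  expect_equal(hits$match, "RGSTWYHLRE")

  ## poly-A never matches any library pattern
  polyA <- strrep("A", 300)
  for (entry in gtc_motif_library()) {
    if (entry$type != "pattern") next
    expect_equal(nrow(scan_motif(polyA, entry$compiled)), 0L,
                 label = entry$name)
  }

  ## bounded repeats: all admissible widths at one start when overlapping
  s <- "RAAAAPAAAAAAAAPA"
  h <- scan_motif(s, compile_motif("Rx{4,14}P"), overlapping = TRUE)
  expect_equal(nrow(h), 2L)
  expect_equal(sort(h$end), c(6L, 15L))
  h1 <- scan_motif(s, compile_motif("Rx{4,14}P"), overlapping = FALSE)
  expect_equal(nrow(h1), 1L)
  expect_equal(h1$end, 6L)   # shortest match only

  ## anchored patterns match only at the C-terminus
  expect_equal(scan_motif("KKAAKKAA", compile_motif("KKxx$"))$start, 5L)
  expect_equal(nrow(scan_motif("KKAAKKA", compile_motif("KKxx$"))), 0L)
})

test_that("the scanner agrees with the exhaustive enumeration oracle", {
  set.seed(13)
  pats <- list(compile_motif("[DE]x?[DE]"),
               compile_motif("Rx{4,14}P"),
               compile_motif("Rx{6}[DL][NR]E"),
               compile_motif("KKxx$"))
  for (rep in 1:30) {
    s <- random_protein(300)
    for (p in pats) {
      got <- scan_motif(s, p, overlapping = TRUE)[, c("start", "end")]
      want <- oracle_scan_one(s, p)
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got, want, label = p$name)
    }
  }
})

test_that("hits are assigned to loops; TMD overlaps are embedded", {
  seg <- data.frame(index = 1:4, start = c(50L, 120L, 180L, 240L),
                    end = c(70L, 140L, 204L, 260L))
  model <- topology_model(seg, "cytoplasmic", 300L)
  ## loop between TMD3 and TMD4 (205..239) is luminal (loop index 3)
  hits <- data.frame(name = "m", start = 211L, end = 220L, match = "x",
                     loop = NA_character_, side = NA_character_)
  out <- assign_loops(hits, model)
  expect_equal(out$loop, "EL2")
  expect_equal(out$side, "luminal")

  ## spanning a TMD boundary: embedded
  emb <- assign_loops(data.frame(name = "m", start = 68L, end = 75L,
                                 match = "x", loop = NA, side = NA), model)
  expect_match(emb$loop, "TMD-embedded")
  expect_true(is.na(emb$side))

  ## C-terminal hit: with a cytoplasmic N-terminus and 4 TMDs the C-tail
  ## (loop 4) is cytoplasmic, where a dilysine signal can act
  cterm <- assign_loops(data.frame(name = "dilysine_kkxx", start = 295L,
                                   end = 298L, match = "KKAA",
                                   loop = NA, side = NA), model)
  expect_equal(cterm$side, "cytoplasmic")

  expect_error(assign_loops(data.frame(name = "m", start = 290L, end = 310L,
                                       match = "x", loop = NA, side = NA),
                            model), "exceed")
  ## coordinates never altered
  expect_equal(out[, c("start", "end")], hits[, c("start", "end")])
})

test_that("dilysine detection covers KKxx and KxKxx spacings only", {
  expect_true(has_dilysine("AAAKKAA"))    # K at -4,-3
  expect_true(has_dilysine("AAKAKAA"))    # K at -5,-3
  expect_false(has_dilysine("AAAAKKA"))   # K at -3,-2
  expect_false(has_dilysine("KKAAAAA"))
  expect_false(has_dilysine("AAA"))
})

test_that("the shipped library and registry carry the GT-C expectations", {
  lib <- gtc_motif_library()
  names(lib) <- vapply(lib, `[[`, character(1), "name")
  expect_true(all(c("el1_acidic", "el56_rp", "dilysine_kkxx") %in% names(lib)))
  expect_equal(lib$el56_rp$expected_side, "luminal")
  expect_equal(lib$el3_basic$type, "conserved_class")

  reg <- gtc_family_registry()
  expect_equal(reg$n_tmds[reg$family == "STT3"], 13L)
  expect_equal(reg$organization[reg$family == "STT3"], "1-8-4")
  expect_equal(reg$n_tmds[reg$family == "ALG6"], 14L)
  expect_true(reg$dilysine[reg$family == "ALG6"])
  expect_match(reg$motifs_absent[reg$family == "ALG9"], "el2")
  expect_false(any(reg$dilysine[reg$n_tmds %% 2 == 1]))

  ## library scans respect family applicability
  s <- paste0("AAARGSTWYHLREAAA")
  all_hits <- scan_library(s, family = "STT3")
  pomt_hits <- scan_library(s, family = "POMT")
  expect_true("el2_stt3_dpy19" %in% all_hits$name)
  expect_false("el2_stt3_dpy19" %in% pomt_hits$name)
})
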