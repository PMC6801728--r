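test_that("information content matches closed forms", {
  ## invariant column: H = 0, ic = log2(20)
  fam <- profile_family(rep("E", 10), sprintf("e%d", 1:10))
  p <- conservation_profile(fam)
  expect_equal(p$ic, log2(20), tolerance = 1e-10)
  expect_equal(round(p$ic, 4), 4.3219)

  ## uniform column over all 20 residues: ic = 0
  fam20 <- profile_family(AA20, sprintf("u%02d", 1:20))
  expect_equal(conservation_profile(fam20)$ic, 0, tolerance = 1e-12)

  ## 50/50 two-residue column: H = 1 bit
  fam2 <- profile_family(c("D", "D", "E", "E"), sprintf("d%d", 1:4))
  expect_equal(conservation_profile(fam2)$ic, log2(20) - 1, tolerance = 1e-12)
  expect_equal(round(conservation_profile(fam2)$ic, 4), 3.3219)

  ## gaps and X excluded from the denominator
  famg <- profile_family(c("D", "D", "-", "X"), sprintf("g%d", 1:4))
  pg <- conservation_profile(famg)
  expect_equal(pg$n_eff, 2L)
  expect_equal(pg$ic, log2(20))

  ## single-record family: warning, maximal ic
  expect_warning(p1 <- conservation_profile(profile_family("ADE")), "single")
  expect_equal(p1$ic, rep(log2(20), 3))
})

test_that("conservation is invariant to row order, within-column shuffles and residue relabelling", {
  set.seed(5)
  seqs <- replicate(12, random_protein(30))
  fam <- profile_family(seqs)
  p <- conservation_profile(fam)

  ## shuffle rows
  perm <- sample(12)
  p2 <- conservation_profile(profile_family(seqs[perm],
                                            sprintf("s%02d", 1:12)))
  expect_equal(p2$ic, p$ic)

  ## shuffle residues within one column
  mat <- do.call(rbind, strsplit(seqs, ""))
  mat[, 7] <- sample(mat[, 7])
  p3 <- conservation_profile(profile_family(apply(mat, 1, paste,
                                                  collapse = "")))
  expect_equal(p3$ic, p$ic)

  ## bijective alphabet relabelling leaves ic untouched
  relabel <- setNames(sample(AA20), AA20)
  seqs_r <- vapply(seqs, function(s) {
    paste(relabel[strsplit(s, "")[[1]]], collapse = "")
  }, character(1), USE.NAMES = FALSE)
  p4 <- conservation_profile(profile_family(seqs_r))
  expect_equal(p4$ic, p$ic)
})

test_that("conserved-position calling matches brute-force recomputation", {
  fam <- profile_family(c("DAK", "DAK", "DAR", "EAR", "DCK", "DAX",
                          "DAK", "EAK", "DAR", "DAK"),
                        sprintf("c%02d", 1:10))
  p <- conservation_profile(fam)

  ## class mode: D/E merged reaches 1.0 at position 1; K/R at position 3
  called <- call_conserved(p, "class_freq", cutoff = 0.8)
  expect_setequal(called$position, c(1L, 2L, 3L))
  expect_equal(called$class[called$position == 1L], "DE")
  expect_equal(called$class[called$position == 3L], "KR")

  ## ic mode equals direct thresholding
  ic_called <- call_conserved(p, "ic", cutoff = 3)
  expect_equal(ic_called$position, which(p$ic >= 3))

  expect_error(call_conserved(p, "class_freq", cutoff = 1.4), "cutoff")
  expect_error(call_conserved(p, "ic", cutoff = -1), "cutoff")

  ## random fixture: calls equal brute-force recomputation from freq vectors
  set.seed(9)
  famr <- profile_family(replicate(15, random_protein(25)))
  pr <- conservation_profile(famr)
  got <- call_conserved(pr, "class_freq", cutoff = 0.5)$position
  classes <- default_residue_classes()
  want <- which(vapply(seq_along(pr$positions), function(j) {
    any(vapply(classes, function(cl) sum(pr$freq[cl, j]) >= 0.5, logical(1)))
  }, logical(1)))
  expect_equal(got, want)
})

test_that("logo letter heights stack to the column information content", {
  fam <- profile_family(c("ED", "ED", "EE", "ED"), sprintf("l%d", 1:4))
  p <- conservation_profile(fam)
  m <- logo_matrix(p)
  expect_equal(colSums(m), p$ic)
  expect_equal(unname(m["E", 1]), log2(20))          # invariant column
  fam5050 <- profile_family(c("D", "D", "E", "E"), sprintf("h%d", 1:4))
  m2 <- logo_matrix(conservation_profile(fam5050))
  expect_equal(unname(round(m2["D", 1], 4)), 1.6610) # 0.5 x 3.3219
  expect_equal(unname(round(m2["E", 1], 4)), 1.6610)
  ## uniform column: all heights zero
  m3 <- logo_matrix(conservation_profile(profile_family(AA20,
                                                        sprintf("u%d", 1:20))))
  expect_equal(max(abs(m3[, 1])), 0, tolerance = 1e-12)
})

test_that("small-sample correction lowers ic and TSV exports are readable", {
  fam <- profile_family(c("DAK", "DAK", "DAR", "EAR"), sprintf("c%d", 1:4))
  p0 <- conservation_profile(fam)
  p1 <- conservation_profile(fam, correct = TRUE)
  expect_true(all(p1$ic <= p0$ic))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_logo_tsv(p0, path)
  back <- read.delim(path)
  expect_true(all(c("position", "residue", "height") %in% names(back)))
  expect_equal(consensus_sequence(p0), "DAK")
})
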