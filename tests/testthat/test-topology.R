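test_that("consensus hydropathy matches per-column means of present residues", {
  p1 <- hydropathy_profile(profile_family("IIIII"), window = 5)
  expect_equal(p1$raw, rep(4.5, 5))
  expect_equal(p1$smoothed, rep(4.5, 5))

  p2 <- hydropathy_profile(profile_family("SSSSS"), window = 5)
  expect_equal(p2$raw, rep(-0.8, 5))

  ## two sequences, one gap: column means over present residues only
  fam <- profile_family(c("SIIII", "I-III"), c("ref", "oth"))
  p3 <- hydropathy_profile(fam, window = 5)
  expect_equal(p3$raw, c(mean(c(-0.8, 4.5)), 4.5, 4.5, 4.5, 4.5))
  expect_equal(p3$coverage, c(1, 0.5, 1, 1, 1))
  expect_true(p3$low_coverage[2] == FALSE && all(!p3$imputed))

  ## smoothing oracle: direct mean over the truncated window
  vals <- p3$raw
  expect_equal(p3$smoothed[1], mean(vals[1:3]))
  expect_equal(p3$smoothed[3], mean(vals[1:5]))

  expect_error(hydropathy_profile(fam, window = 4), "odd")
})

test_that("threshold segmentation finds, filters and splits runs", {
  flat <- manual_profile(rep(-2, 80))
  expect_equal(nrow(segment_tmds(flat)), 0L)

  one <- rep(-2, 80); one[30:50] <- 3       # 21-wide run
  seg <- segment_tmds(manual_profile(one), threshold = 1.5,
                      min_tm = 15, max_tm = 28)
  expect_equal(seg[, c("start", "end")],
               data.frame(start = 30L, end = 50L))

  short <- rep(-2, 80); short[30:40] <- 3   # 11 < min_tm: discarded
  expect_equal(nrow(segment_tmds(manual_profile(short))), 0L)

  ## 35-wide run with an interior dip inside the split margins
  vals <- rep(-2, 100); vals[20:54] <- 3; vals[37] <- 1.8
  seg2 <- segment_tmds(manual_profile(vals), threshold = 1.5,
                       min_tm = 15, max_tm = 28)
  expect_equal(nrow(seg2), 2L)
  expect_equal(seg2$end[1], 36L)   # boundary at the dip
  expect_equal(seg2$start[2], 37L)

  ## randomized runs against the independent re-segmentation oracle
  set.seed(11)
  for (rep in 1:25) {
    vals <- rep(-3, 300)
    pos <- 1
    while (pos < 260) {
      len <- sample(10:60, 1)
      gap <- sample(5:25, 1)
      hi <- pmin(pos + len - 1, 300)
      vals[pos:hi] <- 2 + runif(hi - pos + 1)
      pos <- hi + gap
    }
    got <- segment_tmds(manual_profile(vals), 1.5, 15, 28)
    want <- oracle_segment(vals, 1.5, 15, 28)
    expect_equal(got[, c("start", "end")], want)
    if (nrow(got)) {
      lens <- got$end - got$start + 1
      splittable <- !(got$start %in% attr(got, "unsplittable"))
      expect_true(all(lens[splittable] >= 15 & lens[splittable] <= 28))
    }
  }
})

test_that("segmentation is translation-equivariant under hydrophilic padding", {
  vals <- rep(-2, 60); vals[20:40] <- 3
  base <- segment_tmds(manual_profile(vals))
  padded <- segment_tmds(manual_profile(c(rep(-4, 25), vals)))
  expect_equal(padded$start, base$start + 25L)
  expect_equal(padded$end, base$end + 25L)
})

test_that("DP refinement recovers exact boundaries on separable profiles", {
  ## two helices separated by a 6-residue loop: one merged run for the
  ## 19-window smoother, but raw decoding must split and localize exactly
  raw <- c(rep(-2.5, 12), rep(3.5, 20), rep(-2.5, 6), rep(3.5, 22),
           rep(-2.5, 15))
  prof <- manual_profile(raw)
  prof$smoothed <- gtctopo:::.shrinking_mean(raw, 19L)
  coarse <- segment_tmds(prof)
  expect_equal(nrow(coarse), 2L)    # split rule resolves the merged run
  fine <- refine_tmds(prof)
  expect_equal(fine$start, c(13L, 39L))
  expect_equal(fine$end, c(32L, 60L))
})

test_that("orientation follows positive-inside with a dilysine override", {
  ## one TMD; K-rich N-tail
  fam <- profile_family(paste0("KKKK", strrep("I", 18), "SSSS"))
  seg <- data.frame(index = 1L, start = 5L, end = 22L)
  m <- orient(seg, fam)
  expect_equal(m$n_term_side, "cytoplasmic")
  expect_equal(m$decided_by, "positive-inside")

  ## exact K/R tie, no dilysine: documented default
  fam2 <- profile_family(paste0("KSSS", strrep("I", 18), "KSSS"))
  m2 <- orient(data.frame(index = 1L, start = 5L, end = 22L), fam2)
  expect_equal(m2$n_term_side, "cytoplasmic")
  expect_equal(m2$decided_by, "tie-default")

  ## dilysine forces the C-terminus cytoplasmic against the K/R tally
  fam3 <- profile_family(paste0("KKKKKK", strrep("I", 18), "SKKSS"))
  m3 <- orient(data.frame(index = 1L, start = 7L, end = 24L), fam3)
  expect_equal(m3$decided_by, "dilysine")
  expect_equal(m3$loops$side[m3$loops$loop_index == 1L], "cytoplasmic")

  expect_error(orient(data.frame(index = integer(0), start = integer(0),
                                 end = integer(0)), fam), "zero segments")
})

test_that("loop sides alternate and are labelled EL/CL from the N-terminus", {
  seg <- data.frame(index = 1:3, start = c(10L, 40L, 70L),
                    end = c(29L, 59L, 89L))
  m <- topology_model(seg, "cytoplasmic", 100L)
  expect_equal(m$loops$side,
               c("cytoplasmic", "luminal", "cytoplasmic", "luminal"))
  expect_equal(m$loops$label, c("CL1", "EL1", "CL2", "EL2"))
  ## strict alternation for arbitrary segment counts
  for (k in 3:7) {
    sg <- data.frame(index = 1:k, start = seq(10, by = 40, length.out = k),
                     end = seq(29, by = 40, length.out = k))
    mm <- topology_model(sg, "luminal", max(sg$end) + 10)
    expect_true(all(abs(diff(mm$loops$side == "luminal")) == 1))
  }
})

test_that("forced-loop intervals drop or trim segments and report conflicts", {
  seg <- data.frame(index = 1:2, start = c(10L, 60L), end = c(30L, 80L))
  fl <- force_loops(seg, data.frame(start = 55L, end = 85L))
  expect_equal(nrow(fl$segments), 1L)
  expect_equal(nrow(fl$conflicts), 1L)
  ## partial overlap trims
  fl2 <- force_loops(seg, data.frame(start = 26L, end = 35L))
  expect_equal(fl2$segments$end[1], 25L)
})
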