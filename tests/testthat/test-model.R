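## helper: a model with n helices, given large luminal loops after chosen
## helix indices (loops are otherwise short)
arch_model <- function(n, large_after, tm = 20L, short = 8L, large = 60L) {
  starts <- integer(n); ends <- integer(n)
  pos <- short + 1L
  for (i in seq_len(n)) {
    starts[i] <- pos
    ends[i] <- pos + tm - 1L
    gap <- if (i %in% large_after) large else short
    pos <- ends[i] + gap + 1L
  }
  topology_model(data.frame(index = seq_len(n), start = starts, end = ends),
                 "cytoplasmic", ends[n] + short)
}

test_that("organization strings partition helices at large luminal loops", {
  expect_equal(organization_string(arch_model(13, c(1, 9))), "1-8-4")
  expect_equal(organization_string(arch_model(11, c(1, 7))), "1-6-4")
  expect_equal(organization_string(arch_model(12, c(1, 7))), "1-6-5")
  expect_equal(organization_string(arch_model(14, c(1, 7))), "1-6-7")

  ## large loops on the cytoplasmic side are not landmarks
  m <- arch_model(5, integer(0))
  m$loops$length[m$loops$loop_index == 2] <- 80L   # cytoplasmic loop
  expect_equal(organization_string(m), "5")

  ## organization parts always sum to the helix count
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(3:15, 1)
    la <- sort(sample(seq(1, n - 1, by = 2), sample(0:2, 1)))
    org <- organization_string(arch_model(n, la))
    expect_equal(sum(as.integer(strsplit(org, "-")[[1]])), n)
  }

  two <- topology_model(data.frame(index = 1:2, start = c(10L, 50L),
                                   end = c(30L, 70L)), "cytoplasmic", 90L)
  expect_true(is.na(organization_string(two)))
})

test_that("the asymmetry statistic is zero and non-significant under flat ic", {
  m <- arch_model(9, c(1, 5))
  prof <- list(positions = seq_len(m$length), ic = rep(2, m$length))
  class(prof) <- "conservation_profile"
  res <- asymmetry_test(m, prof, n_perm = 200, seed = 3)
  expect_equal(res$statistic, 0)
  expect_gt(res$p_value, 0.9)
  expect_gte(res$p_value, 1 / 201)
})

test_that("the permutation test is deterministic and respects its p floor", {
  sim <- generate_family(family_spec(seed = 7))
  prof <- conservation_profile(sim$family)
  model <- topology_model(sim$truth$segments, "cytoplasmic",
                          nchar(sim$truth$template))
  r1 <- asymmetry_test(model, prof, n_perm = 500, seed = 11)
  r2 <- asymmetry_test(model, prof, n_perm = 500, seed = 11)
  expect_identical(r1$statistic, r2$statistic)
  expect_identical(r1$p_value, r2$p_value)
  expect_gte(r1$p_value, 1 / 501)
  expect_lte(abs(r1$statistic), log2(20))

  ## too few loops on one side (2 TMDs: a single luminal loop)
  one <- topology_model(data.frame(index = 1:2, start = c(10L, 40L),
                                   end = c(29L, 59L)), "cytoplasmic", 70L)
  prof70 <- structure(list(positions = 1:70, ic = rep(1, 70)),
                      class = "conservation_profile")
  expect_error(asymmetry_test(one, prof70), "insufficient")
})

test_that("family reports cross-check topology, motifs and dilysine placement", {
  sim <- generate_family(family_spec(seed = 5))
  fam <- sim$family
  topo <- recover_topology(fam)
  prof <- conservation_profile(fam)
  hits <- scan_library(reference_sequence(fam), family = "STT3")
  reg <- gtc_family_registry()

  rep13 <- build_report("STT3", fam, topo$model, prof, hits,
                        registry_entry = reg[reg$family == "STT3", ],
                        n_perm = 200, seed = 5)
  expect_s3_class(rep13, "family_report")
  expect_equal(rep13$n_tmds, 13L)
  expect_equal(rep13$organization, "1-8-4")
  expect_length(rep13$flags, 0L)
  expect_true(all(c("EL1", "EL2") %in% rep13$model$loops$label))

  ## expected 11 vs observed 13: count mismatch flag
  rep_mis <- build_report("POMT", fam, topo$model, prof, hits,
                          registry_entry = reg[reg$family == "POMT", ],
                          n_perm = 200, seed = 5)
  expect_true("count_mismatch" %in% rep_mis$flags)

  ## a dilysine hit on a luminal C-terminus raises the consistency flag
  seg <- data.frame(index = 1:4, start = c(10L, 40L, 70L, 100L),
                    end = c(29L, 59L, 89L, 119L))
  lum_c <- topology_model(seg, "luminal", 130L)   # loop 4 luminal
  fake_fam <- profile_family(random_protein(130))
  fake_prof <- conservation_profile(
    profile_family(c(random_protein(130), random_protein(130))))
  dily_hit <- data.frame(name = "dilysine_kkxx", start = 125L, end = 128L,
                         match = "KKAA", loop = NA, side = NA)
  rep_bad <- build_report("ALG3", fake_fam, lum_c, fake_prof, dily_hit,
                          n_perm = 0, seed = 1)
  expect_true("dilysine_not_cytoplasmic" %in% rep_bad$flags)
})

test_that("report JSON serialization is stable under re-serialization", {
  sim <- generate_family(family_spec(n_tmds = 11, seed = 9))
  topo <- recover_topology(sim$family)
  prof <- conservation_profile(sim$family)
  repx <- build_report("POMT", sim$family, topo$model, prof,
                       scan_library(reference_sequence(sim$family),
                                    family = "POMT"),
                       n_perm = 200, seed = 9)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_report_json(repx, p1)
  write_report_json(repx, p2)
  expect_identical(readLines(p1), readLines(p2))
  parsed <- jsonlite::read_json(p1)
  expect_equal(parsed$organization, "1-6-4")
  expect_equal(parsed$parameters$seed, 9)
})
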