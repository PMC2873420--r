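test_that("profile columns follow the smoothed log-odds closed form", {
  bg <- rfxcilia:::aa_background()
  inst <- rep("ACDE", 3) # three identical instances, n = 3
  p <- build_profile(inst, bg, pseudocount = 1, name = "t")
  expect_equal(p$length, 4L)
  # consensus residue at column 1 is 'A': count 3 of n 3
  expect_equal(unname(p$columns[1, "A"]),
               log((3 + 1 * bg[["A"]]) / ((3 + 1) * bg[["A"]])))
  # unseen residue: count 0
  expect_equal(unname(p$columns[1, "W"]),
               log((0 + bg[["W"]]) / (4 * bg[["W"]])))
  expect_equal(unname(p$columns[1, "W"]), log(1 / 4))
  # consensus has the maximum score in every column
  cons <- strsplit("ACDE", "")[[1]]
  for (k in 1:4) {
    expect_equal(names(which.max(p$columns[k, ])), cons[k])
  }
  expect_error(build_profile(c("ACDE", "ACD"), bg), "equal length")
  expect_error(build_profile("ACDE", bg), "at least 2")
})

test_that("count proportions, not instance multiplicity, define the profile", {
  bg <- rfxcilia:::aa_background()
  p2 <- build_profile(c("ACDE", "ACDE"), bg)
  p4 <- build_profile(rep("ACDE", 4), bg)
  # doubling n changes the smoothing weight, per the closed form
  expect_equal(unname(p2$columns[1, "A"]),
               log((2 + bg[["A"]]) / (3 * bg[["A"]])))
  expect_equal(unname(p4$columns[1, "A"]),
               log((4 + bg[["A"]]) / (5 * bg[["A"]])))
  expect_gt(unname(p4$columns[1, "A"]), unname(p2$columns[1, "A"]))
})

test_that("expected column score under the background is never positive", {
  bg <- rfxcilia:::aa_background()
  seeds <- synthetic_profile_seeds()
  for (nm in names(seeds)) {
    p <- build_profile(seeds[[nm]], bg, name = nm)
    exp_scores <- as.numeric(p$columns %*% bg)
    expect_true(all(exp_scores <= 1e-12))
  }
})

test_that("window scores are exact column sums", {
  bg <- rfxcilia:::aa_background()
  p <- build_profile(c("ACDE", "ACDE"), bg)
  s <- "WACDEW"
  scores <- rfxcilia:::profile_window_scores(s, p)
  expect_length(scores, 3)
  manual <- sum(vapply(1:4, function(k) {
    p$columns[k, substr(s, k + 1, k + 1)]
  }, numeric(1)))
  expect_equal(unname(scores[2]), unname(manual), tolerance = 1e-9)
})

test_that("threshold calibration is a null quantile, monotone in q", {
  bg <- rfxcilia:::aa_background()
  seeds <- synthetic_profile_seeds()
  p <- build_profile(seeds$DD, bg, name = "DD")
  p99 <- calibrate_threshold(p, bg, n_null = 1000, quantile = 0.99,
                             rng_seed = 7)
  p100 <- calibrate_threshold(p, bg, n_null = 1000, quantile = 1.0,
                              rng_seed = 7)
  p50 <- calibrate_threshold(p, bg, n_null = 1000, quantile = 0.5,
                             rng_seed = 7)
  expect_lte(p50$score_threshold, p99$score_threshold)
  expect_lte(p99$score_threshold, p100$score_threshold)
  # at quantile 1.0 the threshold equals the best null score: none may pass
  nulls <- rfxcilia:::with_seed(7, vapply(1:1000, function(i) {
    max(rfxcilia:::profile_window_scores(
      rfxcilia:::random_peptide(300L, bg), p))
  }, numeric(1)))
  expect_equal(p100$score_threshold, max(nulls))
  expect_error(calibrate_threshold(p, bg, n_null = 100), "at least 1000")
})

test_that("scanning finds training instances and rejects background", {
  bg <- rfxcilia:::aa_background()
  seeds <- synthetic_profile_seeds()
  p <- calibrate_threshold(build_profile(seeds$AD, bg, name = "AD"), bg,
                           rng_seed = 11)
  inst <- seeds$AD[1]
  host <- paste0(rfxcilia:::with_seed(12, rfxcilia:::random_peptide(100L, bg)),
                 inst,
                 rfxcilia:::with_seed(13, rfxcilia:::random_peptide(80L, bg)))
  ann <- scan_profile(host, p)
  expect_equal(nrow(ann), 1)
  expect_equal(ann$start, 100L)
  expect_equal(ann$end, 100L + p$length)
  # verbatim consensus-identical instance scores the window maximum
  self_ann <- scan_profile(inst, p)
  expect_equal(self_ann$score,
               max(rfxcilia:::profile_window_scores(inst, p)))
  # seeded background protein: no annotation at the 0.99 null quantile
  noise <- rfxcilia:::with_seed(14, rfxcilia:::random_peptide(300L, bg))
  expect_equal(nrow(scan_profile(noise, p)), 0)
  # protein shorter than the profile: empty result
  expect_equal(nrow(scan_profile("ACD", p)), 0)
})

test_that("two disjoint implanted instances give two non-overlapping hits", {
  bg <- rfxcilia:::aa_background()
  seeds <- synthetic_profile_seeds()
  p <- calibrate_threshold(build_profile(seeds$B, bg, name = "B"), bg,
                           rng_seed = 21)
  inst <- seeds$B[1]
  host <- paste0(inst,
                 rfxcilia:::with_seed(22, rfxcilia:::random_peptide(60L, bg)),
                 inst)
  ann <- scan_profile(host, p)
  expect_equal(nrow(ann), 2)
  expect_lte(ann$end[1], ann$start[2])
})

test_that("diverged instances are still recovered at the default threshold", {
  bg <- rfxcilia:::aa_background()
  seeds <- synthetic_profile_seeds()
  p <- calibrate_threshold(build_profile(seeds$DD, bg, name = "DD"), bg,
                           rng_seed = 31)
  q <- query_domain("DD0", seeds$DD[1])
  hits <- vapply(1:100, function(s) {
    ev <- evolve_domain(q, 0.2, FALSE, rng_seed = 4000 + s)
    max(rfxcilia:::profile_window_scores(ev, p)) >= p$score_threshold
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("architecture strings order domains by position and resolve overlaps", {
  bg <- rfxcilia:::aa_background()
  seeds <- synthetic_profile_seeds()
  profs <- lapply(names(seeds), function(nm) {
    calibrate_threshold(build_profile(seeds[[nm]], bg, name = nm), bg,
                        rng_seed = 41)
  })
  names(profs) <- names(seeds)
  dbd <- seed_queries()[[1]]$sequence
  spacer <- function(seed) rfxcilia:::with_seed(seed,
                                                rfxcilia:::random_peptide(40L, bg))
  host <- paste0(seeds$AD[1], spacer(51), dbd, spacer(52), seeds$DD[1])
  dbd_call <- list(start = nchar(seeds$AD[1]) + 40, end = nchar(seeds$AD[1]) + 40 + 76,
                   score = 400)
  arch <- architecture(host, profs, dbd_call = dbd_call)
  expect_equal(as.character(arch), "AD-DBD-DD")
  # supply order of profiles must not matter
  arch2 <- architecture(host, rev(profs), dbd_call = dbd_call)
  expect_equal(as.character(arch2), "AD-DBD-DD")
  # a bare DBD (the RFX5/RFX7-like shape) and the empty case
  host2 <- paste0(spacer(53), dbd, spacer(54))
  expect_equal(as.character(architecture(host2, profs,
                                         dbd_call = list(start = 40,
                                                         end = 116,
                                                         score = 400))),
               "DBD")
  expect_equal(as.character(architecture(spacer(55), profs)), "")
})
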