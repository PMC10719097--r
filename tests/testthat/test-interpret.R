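# Haplarithm interpretation: d-values, copy-state templates, segregational
# origin, mosaic fraction and contamination.

test_that("d-values match the allele-count enumeration oracle", {
  # non-mosaic maternal trisomy: (d_pat, d_mat) = (2/3, 1/3)
  qt <- simulate_quartet(
    aberration_spec("trisomy", "2", parent = "maternal",
                    seg_origin = "mitotic"),
    probe_map = pm_six, noise = noise_free, seed = 11)
  h <- build_haplarithm(qt, "CV")
  dv <- compute_d_values(h, "2")
  expect_equal(dv$d_pat, 2 / 3, tolerance = 1e-9)
  expect_equal(dv$d_mat, 1 / 3, tolerance = 1e-9)
  expect_equal(dv$mean_logr, log2(3 / 2), tolerance = 1e-9)

  # disomy: (0.5, 0.5)
  dv <- compute_d_values(h, "3")
  expect_equal(dv$d_pat, 0.5, tolerance = 1e-9)
  expect_equal(dv$d_mat, 0.5, tolerance = 1e-9)

  # EM-confined maternal isodisomy, CV euploid seed: the paternal series
  # splits to (0, 1) while the maternal series collapses -> (1, 0)
  qt <- simulate_quartet(
    aberration_spec("upd_iso", "5", parent = "maternal",
                    mosaic_fraction_cv = 0, mosaic_fraction_em = 1),
    probe_map = pm_six, noise = noise_free, seed = 12)
  dv <- compute_d_values(build_haplarithm(qt, "EM"), "5")
  expect_equal(dv$d_pat, 1, tolerance = 1e-9)
  expect_equal(dv$d_mat, 0, tolerance = 1e-9)

  # EM-confined monosomy losing the maternal homolog, CV euploid seed:
  # the paternal series collapses, the maternal splits -> (0, 1)
  qt <- simulate_quartet(
    aberration_spec("monosomy", "4", parent = "maternal",
                    mosaic_fraction_cv = 0, mosaic_fraction_em = 1),
    probe_map = pm_six, noise = noise_free, seed = 13)
  dv <- compute_d_values(build_haplarithm(qt, "EM"), "4")
  expect_equal(dv$d_pat, 0, tolerance = 1e-9)
  expect_equal(dv$d_mat, 1, tolerance = 1e-9)
})

test_that("copy-state classification matches the expected templates", {
  cls <- classify_copy_state(list(d_pat = 0.67, d_mat = 0.33,
                                  mean_logr = 0.58))
  expect_equal(cls$copy_state, "gain")
  expect_equal(cls$parental_origin, "maternal")
  expect_equal(cls$copy_number, 3)

  cls <- classify_copy_state(list(d_pat = 0.5, d_mat = 0.5, mean_logr = 0))
  expect_equal(cls$copy_state, "disomy")

  # maternal isodisomy under a euploid seed phase: (1, 0, 0)
  cls <- classify_copy_state(list(d_pat = 1, d_mat = 0, mean_logr = 0))
  expect_equal(cls$copy_state, "neutral_UPD")
  expect_equal(cls$parental_origin, "maternal")

  # paternal isodisomy: the mirrored pattern (0, 1, 0)
  cls <- classify_copy_state(list(d_pat = 0, d_mat = 1, mean_logr = 0))
  expect_equal(cls$copy_state, "neutral_UPD")
  expect_equal(cls$parental_origin, "paternal")

  # conflicting d and logR evidence: not determined
  cls <- classify_copy_state(list(d_pat = 0.67, d_mat = 0.33,
                                  mean_logr = -0.9))
  expect_equal(cls$copy_state, "ND")
})

test_that("mosaic-fraction closed forms invert the simulator's bands", {
  # trisomy: band (1+f)/(2+f); monosomy: (1-f)/(2-f); UPD: (1+f)/2
  for (f in seq(0.05, 1, 0.05)) {
    expect_equal(estimate_mosaic_fraction((1 + f) / (2 + f) - 0.5, "gain"),
                 f, tolerance = 1e-9)
    expect_equal(estimate_mosaic_fraction(0.5 - (1 - f) / (2 - f), "loss"),
                 f, tolerance = 1e-9)
    expect_equal(estimate_mosaic_fraction(f / 2, "neutral_UPD"),
                 f, tolerance = 1e-9)
  }
  expect_equal(estimate_mosaic_fraction(1 / 6, "trisomy"), 1)
  expect_equal(estimate_mosaic_fraction(0.0625, "trisomy"), 2 / 7,
               tolerance = 1e-9)
  expect_equal(estimate_mosaic_fraction(0, "monosomy"), 0)
  expect_error(estimate_mosaic_fraction(0.6, "gain"), "0.5")
  expect_error(estimate_mosaic_fraction(0.5, "gain"), "impossible")
  # the UPD band reaches 0.5 exactly at f = 1; beyond is out of domain
  expect_equal(estimate_mosaic_fraction(0.5, "neutral_UPD"), 1)
  expect_error(estimate_mosaic_fraction(0.51, "neutral_UPD"), "0.5")
})

test_that("segregational origin follows the centromeric homolog composition", {
  for (seed in c(2, 7)) {
    for (so in c("MI", "MII", "mitotic")) {
      qt <- simulate_quartet(
        aberration_spec("trisomy", "2", parent = "maternal",
                        seg_origin = so),
        probe_map = pm_six, noise = noise_free, seed = seed)
      fit <- haplarith(qt)
      expect_true(all(fit$calls$segregational_origin == so),
                  info = paste(so, seed))
    }
  }
})

test_that("maternal contamination is recovered by grid search", {
  for (cc in c(0, 0.2)) {
    qt <- simulate_quartet(
      aberration_spec("none"), probe_map = pm_six,
      noise = noise_model(baf_sd = 0.03, maternal_contamination = cc),
      seed = 31 + round(10 * cc))
    est <- estimate_maternal_contamination(qt, "CV")
    expect_lt(abs(est$c_hat - cc), 0.03)
    expect_false(est$complete_flag)
  }
  # a target that IS the maternal array: complete contamination, excluded
  qt <- simulate_quartet(aberration_spec("none"), probe_map = pm_six,
                         noise = noise_model(baf_sd = 0.03), seed = 41)
  qt$cv <- qt$mother
  est <- estimate_maternal_contamination(qt, "CV")
  expect_true(est$complete_flag)
  calls <- call_aberrations(qt)
  expect_identical(attr(calls, "excluded"), "CV")
  expect_equal(sum(calls$tissue == "CV"), 0)
})

test_that("a euploid quartet yields no calls in either tissue", {
  qt <- simulate_quartet(aberration_spec("none"), probe_map = pm_six,
                         noise = noise_model(baf_sd = 0.03), seed = 51)
  expect_equal(nrow(haplarith(qt)$calls), 0)
})

test_that("tissue-specific mosaicism is called in the right tissue only", {
  # modelled after an EM-confined mosaic monosomy with a euploid CV
  qt <- simulate_quartet(
    aberration_spec("monosomy", "1", parent = "paternal",
                    mosaic_fraction_cv = 0, mosaic_fraction_em = 0.5),
    probe_map = pm_three, noise = noise_model(baf_sd = 0.03), seed = 21)
  calls <- haplarith(qt)$calls
  expect_equal(nrow(calls), 1)
  expect_equal(calls$tissue, "EM")
  expect_equal(calls$copy_state, "loss")
  expect_equal(calls$parental_origin, "paternal")
  expect_lt(abs(calls$mosaic_fraction - 0.5), 0.05)
})

test_that("triploidy is flagged genome-wide with per-chromosome MII origin", {
  pm8 <- default_probe_map(700, chromosomes = as.character(1:8), seed = 5)
  qt <- simulate_quartet(
    aberration_spec("triploidy", parent = "maternal", seg_origin = "MII"),
    probe_map = pm8, noise = noise_free, seed = 9)
  calls <- haplarith(qt)$calls
  cv <- calls[calls$tissue == "CV", ]
  expect_equal(nrow(cv), 8)
  expect_true(all(cv$size_class == "genome_wide"))
  expect_true(all(cv$copy_state == "gain"))
  expect_true(all(cv$parental_origin == "maternal"))
  expect_true(all(cv$segregational_origin == "MII"))
})

test_that("non-mosaic tetrasomy is assigned copy number 4", {
  qt <- simulate_quartet(
    aberration_spec("tetrasomy", "2", parent = "maternal"),
    probe_map = pm_three, noise = noise_model(baf_sd = 0.02), seed = 13)
  calls <- haplarith(qt)$calls
  expect_true(all(calls$copy_state == "gain"))
  expect_true(all(calls$copy_number == 4))
  expect_true(all(abs(calls$mean_logr - 1) < 0.1))
})

test_that("X-chromosome gains are classified from the maternal series alone", {
  pmx <- default_probe_map(1000, chromosomes = c("1", "2", "X"), seed = 4)
  qt <- simulate_quartet(
    aberration_spec("trisomy", "X", parent = "maternal",
                    seg_origin = "mitotic"),
    probe_map = pmx, noise = noise_model(baf_sd = 0.02), seed = 8)
  calls <- haplarith(qt)$calls
  expect_equal(nrow(calls), 2)
  expect_true(all(calls$chromosome == "X"))
  expect_true(all(calls$copy_state == "gain"))
  expect_true(all(calls$parental_origin == "maternal"))
  expect_true(all(abs(calls$mosaic_fraction - 1) <= 0.05))
})
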