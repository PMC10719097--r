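# The quartet simulator: parental haplotypes, meiosis models, conceptus
# assembly and array rendering.

test_that("parental haplotypes follow the population allele frequency and are seeded", {
  pm <- probe_map(sprintf("s%05d", 1:10000), rep("1", 10000),
                  seq(1e5, by = 2e4, length.out = 10000),
                  rep(0.5, 10000))
  g1 <- simulate_parent_haplotypes(pm, seed = 42)
  g2 <- simulate_parent_haplotypes(pm, seed = 42)
  expect_identical(g1, g2)
  # mean B share within the binomial confidence bound around 0.5
  expect_lt(abs(mean(g1$mother[["1"]]) - 0.5), 0.02)
  expect_lt(abs(mean(g1$father[["1"]]) - 0.5), 0.02)

  pm0 <- probe_map(paste0("s", 1:50), rep("1", 50),
                   seq(1e5, by = 1e5, length.out = 50), rep(0, 50))
  g0 <- simulate_parent_haplotypes(pm0, seed = 1)
  expect_true(all(g0$mother[["1"]] == 0))
  expect_true(all(g0$father[["1"]] == 0))
  expect_error(simulate_parent_haplotypes(data.frame()), "empty")
})

test_that("meiosis produces the demanded homolog structure at the centromere", {
  pm <- pm_six
  parent <- hom_marked_parent(pm)
  cen <- centromere_positions("2")
  pos <- pm$position[pm$chromosome == "2"]
  near_cen <- which.min(abs(pos - cen))
  xo <- c(cen - 3e7, cen + 4e7)

  for (seed in 1:20) {
    mi <- simulate_meiosis(parent, "2", xo, error = "MI", seed = seed)
    # centromeric segments derive from different homologs
    expect_length(mi, 2)
    expect_false(mi[[1]][near_cen] == mi[[2]][near_cen])

    mii <- simulate_meiosis(parent, "2", xo, error = "MII", seed = seed)
    expect_true(mii[[1]][near_cen] == mii[[2]][near_cen])
    expect_gt(sum(mii[[1]] != mii[[2]]), 0)   # differ distal to a crossover

    one <- simulate_meiosis(parent, "2", xo, error = "none", seed = seed)
    expect_length(one, 1)
  }
  # no crossovers: the gamete is one unmodified parental homolog
  g <- simulate_meiosis(parent, "2", numeric(0), error = "none", seed = 3)
  expect_true(all(g[[1]] == 0) || all(g[[1]] == 1))
  # MII without a crossover is indistinguishable from mitotic duplication
  expect_error(simulate_meiosis(parent, "2", numeric(0), error = "MII"),
               "crossover")
})

test_that("conceptus assembly realizes the aberration spec", {
  pm <- pm_six
  parents <- simulate_parent_haplotypes(pm, seed = 7)
  gam <- function(genome) {
    g <- lapply(names(genome), function(ch)
      simulate_meiosis(genome, ch, numeric(0), error = "none", seed = 1))
    names(g) <- names(genome)
    g
  }
  mg <- gam(parents$mother); pg <- gam(parents$father)

  lines <- assemble_conceptus(mg, pg, aberration_spec("none"), pm)
  expect_null(lines$aberrant)
  expect_true(all(vapply(lines$euploid, function(tr)
    nrow(tr$alleles) == 2, logical(1))))

  # maternal mitotic trisomy: the same maternal homolog twice
  ab <- assemble_conceptus(mg, pg,
    aberration_spec("trisomy", "2", parent = "maternal",
                    seg_origin = "mitotic"), pm)$aberrant
  tr <- ab[["2"]]
  expect_identical(tr$parent, c("mat", "mat", "pat"))
  expect_identical(tr$alleles[1, ], tr$alleles[2, ])

  # maternal isodisomic UPD: two identical maternal homologs, zero paternal,
  # total copy number 2 (allele-count enumeration oracle)
  ab <- assemble_conceptus(mg, pg,
    aberration_spec("upd_iso", "1", parent = "maternal"), pm)$aberrant
  tr <- ab[["1"]]
  expect_identical(tr$parent, c("mat", "mat"))
  expect_identical(tr$alleles[1, ], tr$alleles[2, ])
  bands <- enumerate_bands(list(ab), 1, pm)
  expect_true(all(bands$total[pm$chromosome == "1"] == 2))

  # a trisomy never carries an interval; a short segment is rejected
  expect_error(aberration_spec("trisomy", "2", start = 1, end = 2e6,
                               parent = "maternal"), "interval")
  expect_error(aberration_spec("segmental_gain", "2", start = 1e6,
                               end = 1e6 + 5e4, parent = "maternal"),
               "100 kb")
})

test_that("rendered BAF values lie on the enumerated mixture bands", {
  pm <- pm_six
  # mosaic monosomy at f = 0.5: a het SNP losing its B homolog reads 1/3
  for (seed in c(2, 9)) {
    qt <- simulate_quartet(
      aberration_spec("monosomy", "4", parent = "paternal",
                      mosaic_fraction_cv = 0.5, mosaic_fraction_em = 0.25),
      probe_map = pm, noise = noise_free, seed = seed)
    tr <- qt$truth
    expected_cv <- enumerate_bands(tr$cell_lines, c(0.5, 0.5), pm)
    expected_em <- enumerate_bands(tr$cell_lines, c(0.75, 0.25), pm)
    expect_equal(qt$cv$baf, expected_cv$baf, tolerance = 1e-12)
    expect_equal(qt$em$baf, expected_em$baf, tolerance = 1e-12)
    i4 <- pm$chromosome == "4"
    expect_true(any(abs(expected_cv$baf[i4] - 1/3) < 1e-12))
  }
  # pure trisomy: het SNP with 2 B of 3 copies reads 2/3; logR log2(3/2)
  qt <- simulate_quartet(
    aberration_spec("trisomy", "2", parent = "maternal",
                    seg_origin = "mitotic"),
    probe_map = pm, noise = noise_free, seed = 4)
  i2 <- pm$chromosome == "2"
  expect_true(all(abs(qt$cv$logr[i2] - log2(3 / 2)) < 1e-12))
  expect_true(all(qt$cv$baf[i2] %in% c(0, 1) |
                  abs(qt$cv$baf[i2] - 1/3) < 1e-12 |
                  abs(qt$cv$baf[i2] - 2/3) < 1e-12))
})

test_that("rendering is reproducible and respects the noise model", {
  pm <- pm_six
  q1 <- simulate_quartet(aberration_spec("none"), probe_map = pm,
                         noise = noise_model(baf_sd = 0.03), seed = 12)
  q2 <- simulate_quartet(aberration_spec("none"), probe_map = pm,
                         noise = noise_model(baf_sd = 0.03), seed = 12)
  expect_identical(q1$cv$baf, q2$cv$baf)
  expect_identical(q1$em$logr, q2$em$logr)
  expect_true(all(q1$cv$baf >= 0 & q1$cv$baf <= 1))
  # mean logR over a constant-copy region approaches log2(CN/2)
  expect_lt(abs(mean(q1$cv$logr)), 0.01)
  expect_error(render_array(list(), c(0.7, 0.7), NULL,
                            noise_model(), pm), "sum to 1")
})

test_that("genotype thresholds emulate cluster calling", {
  expect_identical(call_genotype(c(0, 0.10, 1/3, 0.5, 2/3, 0.90, 1, 0.2)),
                   c("AA", "AA", "AB", "AB", "AB", "BB", "BB", "NC"))
})
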