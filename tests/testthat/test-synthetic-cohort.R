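test_that("expected_ratio follows clonal-mixture arithmetic", {
  expect_equal(expected_ratio(-1, 1.0), 0.5)
  expect_equal(expected_ratio(-1, 0.5), 0.75)
  expect_equal(expected_ratio(+1, 1.0), 1.5)
  expect_equal(expected_ratio(-2, 1.0), 0.0)  # homozygous loss, full clonality
  expect_equal(expected_ratio(c(-1, 2), c(0.5, 0.25)), c(0.75, 1.25))
  expect_error(expected_ratio(0, 0.5), "copy_change")
  expect_error(expected_ratio(-1, 0), "clonal_fraction")
  expect_error(expected_ratio(-1, 1.2), "clonal_fraction")
})

test_that("a null cohort centres at ratio 1", {
  cfg <- simulation_config(genome_spec = c(chr1 = 50e6), n_probes = 2000,
                           class_counts = c(CP = 6, control = 4),
                           noise_sd_range = c(0.09, 0.09),
                           signature_regions = NULL, cnv_loci = NULL, seed = 11)
  co <- simulate_cohort(cfg)
  mu <- colMeans(co$fr)
  expect_true(all(abs(mu - 1) < 3 * 0.09 / sqrt(2000)))
  expect_equal(nrow(co$truth$events), 0L)
})

test_that("a planted deletion attenuates the mean ratio by copy_change * clonal_fraction / 2", {
  sig <- data.frame(name = "DEL", chrom = "chr1", start = 10e6, end = 12e6,
                    role = "primary", copy_change = -1L, cf_low = 1, cf_high = 1)
  cfg <- simulation_config(genome_spec = c(chr1 = 50e6), n_probes = 1000,
                           class_counts = c(BCL = 1, control = 5),
                           noise_sd_range = c(0.09, 0.09),
                           signature_regions = sig, cnv_loci = NULL, seed = 3)
  co <- simulate_cohort(cfg)
  idx <- with(co$grid, which(chrom == "chr1" & start < 12e6 & end > 10e6))
  bcl <- co$samples$sample_id[co$samples$class == "BCL"]
  m <- mean(co$fr[idx, bcl])
  expect_true(abs(m - 0.5) < 4 * 0.09 / sqrt(length(idx)))
  # control samples unaffected
  ctl <- co$samples$sample_id[co$samples$class == "control"]
  expect_true(all(abs(colMeans(co$fr[idx, ctl]) - 1) < 4 * 0.09 / sqrt(length(idx))))
})

test_that("simulation is reproducible byte-for-byte and seeds matter", {
  cfg <- demo_simulation_config(n_probes = 800,
                                class_counts = c(CP = 5, BCL = 3, control = 4),
                                n_concomitant = 2, seed = 9)
  a <- simulate_cohort(cfg); b <- simulate_cohort(cfg)
  expect_identical(a$fr, b$fr)
  expect_identical(a$truth$events, b$truth$events)
  expect_identical(a$samples, b$samples)
  f1 <- tempfile(); f2 <- tempfile()
  write_fr_matrix(a$fr, f1); write_fr_matrix(b$fr, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  cfg2 <- demo_simulation_config(n_probes = 800,
                                 class_counts = c(CP = 5, BCL = 3, control = 4),
                                 n_concomitant = 2, seed = 10)
  expect_false(identical(simulate_cohort(cfg2)$fr, a$fr))
})

test_that("signature events are confined to lymphoid samples; CNVs are class-agnostic", {
  for (seed in c(1, 2, 3)) {
    cfg <- demo_simulation_config(n_probes = 500, seed = seed)
    co <- simulate_cohort(cfg)
    ev <- co$truth$events
    cls <- co$samples$class[match(ev$sample_id, co$samples$sample_id)]
    expect_true(all(cls[ev$type == "signature"] %in% c("BCL", "BCmix")))
    # every signature carrier at the configured clonal fraction range
    expect_true(all(ev$clonal_fraction[ev$type == "signature"] >= 0.8))
  }
  # a frequent CNV locus appears across classes at ~ its population frequency
  cnv <- data.frame(name = "CNVHOT", chrom = "chr1", start = 1e6, end = 1.3e6,
                    freq = 0.5, copy_change = -1L)
  cfg <- simulation_config(genome_spec = c(chr1 = 50e6), n_probes = 300,
                           class_counts = c(CP = 60, control = 40),
                           signature_regions = NULL, cnv_loci = cnv, seed = 21)
  co <- simulate_cohort(cfg)
  carriers <- co$truth$events$sample_id
  cls <- co$samples$class[match(carriers, co$samples$sample_id)]
  n <- nrow(co$samples)
  expect_true(abs(length(carriers) / n - 0.5) < 4 * sqrt(0.25 / n))
  expect_true(all(c("CP", "control") %in% cls))
})

test_that("per-sample robust noise estimates recover the planted SD range", {
  cfg <- demo_simulation_config(n_probes = 4000, seed = 5)
  co <- simulate_cohort(cfg)
  auto <- drop_sex_chromosomes(co$fr, co$grid)
  qc <- sample_qc(auto$fr)
  truth_sd <- co$truth$noise_sd[qc$sample_id]
  expect_true(all(qc$sd > 0.057 * 0.9 & qc$sd < 0.187 * 1.1))
  expect_gt(cor(qc$sd, truth_sd), 0.95)
})

test_that("planted events satisfy the signal-calibration bound", {
  cfg <- demo_simulation_config(n_probes = 6000, seed = 13)
  co <- simulate_cohort(cfg)
  ev <- co$truth$events
  ok <- logical(0)
  for (i in seq_len(nrow(ev))) {
    idx <- with(co$grid, which(chrom == ev$chrom[i] & start < ev$end[i] & end > ev$start[i]))
    if (length(idx) < 2) next
    expect_shift <- ev$copy_change[i] * ev$clonal_fraction[i] / 2
    target <- max(1 + expect_shift, 0)  # expected ratios clip at 0
    sdn <- co$truth$noise_sd[ev$sample_id[i]]
    m <- mean(co$fr[idx, ev$sample_id[i]])
    # clipping of the noise at 0 biases deep-deletion means slightly upwards
    tol <- 4 * sdn / sqrt(length(idx)) + if (target < 2 * sdn) 0.5 * sdn else 0
    ok <- c(ok, abs(m - target) <= tol)
  }
  expect_gte(mean(ok), 0.95)
})
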