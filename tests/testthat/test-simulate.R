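test_that("identical config and seed reproduce identical outputs", {
  cfg <- sim_config()
  b1 <- simulate_peak_tables(cfg, seed = 42)
  b2 <- simulate_peak_tables(cfg, seed = 42)
  expect_identical(b1, b2)
  e1 <- simulate_experiment(cfg, seed = 42)
  e2 <- simulate_experiment(cfg, seed = 42)
  expect_identical(e1, e2)
  b3 <- simulate_peak_tables(cfg, seed = 43)
  expect_false(identical(b1$peaks$area, b3$peaks$area))
})

test_that("noiseless standards are exactly linear after background removal", {
  cfg <- noiseless_config(crosstalk = FALSE)
  batch <- simulate_peak_tables(cfg, seed = 1)
  pk <- read_peak_table(batch$peaks, cfg$panel)
  curves <- calibrate_batch(pk, cfg$panel)
  for (a in names(curves)) {
    expect_equal(curves[[a]]$r_squared, 1, tolerance = 1e-9)
    expect_equal(curves[[a]]$sigma, 0, tolerance = 1e-9)
    # true response factor: area ratio slope = rf / (rf * istd_nM) per nM
    expect_equal(curves[[a]]$slope, 1 / cfg$istd_nM, tolerance = 1e-9)
  }
})

test_that("crosstalk injection conserves signal exactly at zero noise", {
  cfg <- noiseless_config(crosstalk = TRUE)
  batch <- simulate_peak_tables(cfg, seed = 1)
  blk <- batch$peaks[batch$peaks$role == "blank", ]
  naad <- blk$area[blk$channel_id == "NAAD|12C"]
  nad <- blk$area[blk$channel_id == "NAD+|12C"]
  frac <- isotope_ratio("C21H27N7O14P2", 1)
  # true NAAD is zero: its channel carries exactly the NAD+ M+1 fraction
  expect_true(all(naad > 0))
  expect_equal(naad, nad * frac, tolerance = 1e-12)

  off <- simulate_peak_tables(noiseless_config(crosstalk = FALSE), seed = 1)
  blk_off <- off$peaks[off$peaks$role == "blank", ]
  expect_true(all(blk_off$area[blk_off$channel_id == "NAAD|12C"] == 0))
})

test_that("matrix blanks carry endogenous signal only", {
  cfg <- noiseless_config(crosstalk = FALSE)
  batch <- simulate_peak_tables(cfg, seed = 2)
  blk <- batch$peaks[batch$peaks$role == "blank" &
                       batch$peaks$sample_id == "BLK01", ]
  for (a in c("NAD+", "NADH", "NMN")) {
    area <- blk$area[blk$channel_id == paste0(a, "|12C")]
    expect_equal(area,
                 cfg$response_factor[[a]] * cfg$matrix_endogenous[[a]],
                 tolerance = 1e-12)
  }
  # endogenous NAD+ and NADH exceed the low QC level, triggering the
  # bias skip rule there
  expect_true(cfg$matrix_endogenous[["NAD+"]] > 250)
  expect_true(cfg$matrix_endogenous[["NADH"]] > 250)
})

test_that("planted effects shape the experiment's ground truth", {
  cfg <- noiseless_config()
  ex <- simulate_experiment(cfg, seed = 1)
  tr <- ex$truth$samples
  pool <- function(a, tp) unique(tr$true_pool[tr$analyte == a &
                                                tr$timepoint == tp])
  expect_equal(pool("NADPH", "T5"), 0.5 * pool("NADPH", "T1"))
  expect_equal(pool("NADP+", "T2"), 0.5 * pool("NADP+", "T1"))
  expect_equal(pool("NCA", "T3"), 3 * pool("NCA", "T1"))
  expect_equal(pool("ADPR", "T2"), pool("ADPR", "T1"))
  expect_equal(pool("ADPR", "T3"), 2 * pool("ADPR", "T1"))
  expect_equal(pool("NAD+", "T5"), pool("NAD+", "T1"))

  # with all multipliers 1 and no noise, every downstream log2FC is 0
  cfg1 <- noiseless_config(effects = list())
  batch <- simulate_peak_tables(cfg1, seed = 1)
  curves <- calibrate_batch(read_peak_table(batch$peaks, cfg1$panel),
                            cfg1$panel)
  ex1 <- simulate_experiment(cfg1, seed = 1)
  quant <- quantify_samples(read_peak_table(ex1$peaks, cfg1$panel),
                            read_sample_meta(ex1$meta), curves, cfg1$panel)
  fc <- log2_fold_changes(quant, reference = "T1")
  expect_equal(fc$log2fc, rep(0, nrow(fc)), tolerance = 1e-6)
})

test_that("experiment peak areas encode the pools through the meta chain", {
  cfg <- noiseless_config(crosstalk = FALSE)
  ex <- simulate_experiment(cfg, seed = 3)
  tr <- ex$truth$samples
  row <- tr[tr$analyte == "NAD+" & tr$sample_id == "T2_b1_t1", ]
  meta <- ex$meta[ex$meta$sample_id == "T2_b1_t1", ]
  # extract nM is the exact inverse of normalize_to_cdw
  expect_equal(normalize_to_cdw(row$true_extract_nM, meta$dilution_factor,
                                meta$extract_volume_L, meta$broth_volume_L,
                                meta$cdw_g_L),
               row$true_pool, tolerance = 1e-12)
  area <- ex$peaks$area[ex$peaks$sample_id == "T2_b1_t1" &
                          ex$peaks$channel_id == "NAD+|12C"]
  expect_equal(area, cfg$response_factor[["NAD+"]] * row$true_extract_nM,
               tolerance = 1e-12)
})

test_that("simulated physiology is internally consistent", {
  cfg <- sim_config()
  ts <- simulate_physiology(cfg)
  expect_true(all(diff(ts$time_h) > 0))
  expect_true(all(ts$glucose_g_L >= 0))
  expect_true(all(diff(ts$glucose_g_L) <= 1e-12))
  expect_true(all(diff(ts$biomass_g_L) > 0))
  for (p in names(cfg$q_p)) expect_true(all(diff(ts[[p]]) >= -1e-12))
  # anaerobic phase: no oxygen uptake
  anae <- ts[ts$time_h > cfg$t_samples[["T2"]], ]
  expect_true(all(anae$o2_in == anae$o2_out))
})
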