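# Synthetic-data generators: determinism, distributional structure, and the
# ground-truth bookkeeping every downstream test relies on.

test_that("PSSM libraries are seeded-deterministic and row-normalized", {
  a <- make_library(3, sharpness = 2, seed = 7)
  b <- make_library(3, sharpness = 2, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, make_library(3, sharpness = 2, seed = 8)))
  for (p in a$pssms) {
    expect_equal(unname(rowSums(p)), rep(1, 10), tolerance = 1e-12)
    expect_true(all(p > 0))
    expect_identical(dim(p), c(10L, 20L))
  }
})

test_that("large sharpness concentrates each position on one residue", {
  lib <- make_library(2, sharpness = 1e6, seed = 3)
  for (p in lib$pssms)
    expect_true(all(apply(p, 1, max) > 0.99))
})

test_that("make_library rejects nonpositive arguments", {
  expect_error(make_library(0), "positive")
  expect_error(make_library(3, sharpness = 0), "positive")
})

test_that("motif_fraction controls generating-kinase labels", {
  lib <- make_library(4, seed = 1)
  s0 <- make_sites(200, lib, motif_fraction = 0, seed = 2)
  expect_true(all(is.na(s0$generating_kinase)))
  lib1 <- make_library(1, seed = 1)
  s1 <- make_sites(200, lib1, motif_fraction = 1, seed = 2)
  expect_true(all(s1$generating_kinase == "KIN001"))
  expect_error(make_sites(10, list(), motif_fraction = 0.5), "library")
  # binomial(1000, 0.5): P(|X - 500| > 100) < 1e-9, so [400, 600] is safe
  s <- make_sites(1000, lib, motif_fraction = 0.5, seed = 5)
  n_motif <- sum(!is.na(s$generating_kinase))
  expect_gte(n_motif, 400)
  expect_lte(n_motif, 600)
})

test_that("site flanks are valid 11-mers with S/T centers", {
  lib <- make_library(3, seed = 1)
  s <- make_sites(500, lib, motif_fraction = 0.5, seed = 4)
  expect_true(all(nchar(s$flank) == 11))
  expect_true(all(substr(s$flank, 6, 6) %in% c("S", "T")))
  expect_identical(substr(s$flank, 6, 6), s$center)
  expect_false(anyDuplicated(s$site) > 0)
})

test_that("simulate_quant applies the spiked effect exactly where stated", {
  lib <- make_library(5, seed = 1)
  sites <- make_sites(300, lib, motif_fraction = 1, seed = 2)

  cfg0 <- sim_config(n_sites = 300, target_kinase = "KIN002",
                     effect_log2 = 0, noise_sd = 0.1, seed = 3)
  sq0 <- simulate_quant(sites, cfg0)
  expect_length(sq0$truth$affected_sites, 0)
  expect_true(all(sq0$truth$effects == 0))

  cfg <- sim_config(n_sites = 300, target_kinase = "KIN002",
                    effect_log2 = -2, noise_sd = 0, seed = 3)
  sq <- simulate_quant(sites, cfg)
  expect_setequal(sq$truth$affected_sites,
                  sites$site[sites$generating_kinase == "KIN002"])
  lm <- log2(sq$quant)
  ko <- sq$truth$affected_channels
  wt <- setdiff(colnames(sq$quant), ko)
  fc <- rowMeans(lm[, ko]) - rowMeans(lm[, wt])
  expect_equal(unname(fc[sq$truth$affected_sites]),
               rep(-2, length(sq$truth$affected_sites)), tolerance = 1e-12)
  expect_equal(unname(fc[setdiff(sites$site, sq$truth$affected_sites)]),
               rep(0, 300 - length(sq$truth$affected_sites)),
               tolerance = 1e-12)
  expect_true(all(sq$quant > 0))
})

test_that("mean estimated log2FC over affected sites is near the true effect", {
  # sd of a per-site 4v4 mean difference = 0.25 * sqrt(1/4 + 1/4) ~ 0.177;
  # averaging over >= 200 affected sites leaves a standard error ~ 0.0125,
  # so +/- 0.1 is an ~8-sigma band.
  lib <- make_library(1, seed = 9)
  sites <- make_sites(400, lib, motif_fraction = 1, seed = 9)
  cfg <- sim_config(n_sites = 400, target_kinase = "KIN001",
                    effect_log2 = -2, noise_sd = 0.25, seed = 9)
  sq <- simulate_quant(sites, cfg)
  lm <- log2(sq$quant)
  fc <- rowMeans(lm[, sprintf("ch%02d", 9:12)]) -
    rowMeans(lm[, sprintf("ch%02d", 1:4)])
  expect_lt(abs(mean(fc[sq$truth$affected_sites]) - (-2)), 0.1)
})

test_that("sim_config validates its invariants", {
  expect_error(sim_config(motif_fraction = 1.5), "motif_fraction")
  expect_error(sim_config(groups = list(A = 1:8, B = 10:16)), "partition")
  expect_error(sim_config(affected_groups = "nope"), "affected group")
})

test_that("simulate_psm_table reproduces quant exactly in the clean limit", {
  lib <- make_library(2, seed = 1)
  sites <- make_sites(50, lib, motif_fraction = 0.5, seed = 1)
  cfg <- sim_config(n_sites = 50, seed = 1)
  sq <- simulate_quant(sites, cfg)
  rec <- simulate_psm_table(sq$quant, diag(16), seed = 1, sites = sites)
  ch <- sprintf("ch%02d", 1:16)
  expect_equal(unname(as.matrix(rec[, ch])), unname(sq$quant))
  flt <- filter_records(rec, filter_policy("phospho"))
  expect_identical(nrow(flt$kept), 50L)
  expect_identical(nrow(flt$rejected), 0L)
})

test_that("artifact rates drive filter failures as injected", {
  lib <- make_library(2, seed = 1)
  sites <- make_sites(1000, lib, motif_fraction = 0, seed = 2)
  cfg <- sim_config(n_sites = 1000, seed = 2)
  sq <- simulate_quant(sites, cfg)

  rec_all <- simulate_psm_table(sq$quant, diag(16),
                                artifact_rates = list(low_isolation = 1),
                                seed = 3, sites = sites)
  flt <- filter_records(rec_all, filter_policy("phospho"))
  expect_identical(nrow(flt$kept), 0L)
  expect_true(all(flt$rejected$reason == "isolation_specificity"))

  # binomial(1000, 0.1): P(X outside [70, 130]) < 1e-3 for one fixed seed
  rec_p <- simulate_psm_table(sq$quant, diag(16),
                              artifact_rates = list(low_localization = 0.1),
                              seed = 4, sites = sites)
  n_fail <- attr(rec_p, "defect_counts")[["low_localization"]]
  expect_gte(n_fail, 70)
  expect_lte(n_fail, 130)
  flt_p <- filter_records(rec_p, filter_policy("phospho"))
  expect_identical(sum(flt_p$rejected$reason == "localization"),
                   as.integer(n_fail))
})

test_that("simulate_psm_table rejects bad impurity matrices", {
  q <- matrix(1, 2, 3, dimnames = list(c("a_S1", "b_S2"), c("ch01", "ch02", "ch03")))
  expect_error(simulate_psm_table(q, diag(2)), "square")
  bad <- diag(3); bad[1, 1] <- 0
  expect_error(simulate_psm_table(q, bad), "diagonal")
})

test_that("identical configs give byte-identical simulations", {
  run <- function() {
    lib <- make_library(5, seed = 42)
    sites <- make_sites(100, lib, 0.5, seed = 42)
    cfg <- sim_config(n_sites = 100, target_kinase = "KIN003", seed = 42)
    sq <- simulate_quant(sites, cfg)
    rec <- simulate_psm_table(sq$quant, default_impurity(16),
                              list(low_sn = 0.05), seed = 42, sites = sites)
    list(lib, sites, sq, rec)
  }
  expect_identical(run(), run())
})
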