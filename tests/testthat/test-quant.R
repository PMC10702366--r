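# Reporter-quantification cascade: impurity correction, quality filters,
# protein collapse, and the three normalization steps.

test_that("impurity correction solves the stated mixing model", {
  expect_equal(correct_impurities(c(100, 50), diag(2)), c(100, 50))
  # column 1 = c(0.9, 0.1): 10% of reagent 1 leaks into channel 2
  m <- matrix(c(0.9, 0.1, 0, 1), 2, 2)
  expect_equal(correct_impurities(c(90, 60), m), c(100, 50), tolerance = 1e-12)
  expect_equal(correct_impurities(c(0, 0), m), c(0, 0))
  expect_error(correct_impurities(c(1, 2, 3), m), "does not match")
  expect_error(correct_impurities(c(1, 2), matrix(c(1, 1, 1, 1), 2, 2)),
               "singular")
})

test_that("impurity correction round-trips random mixing matrices", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(2:16, 1)
    m <- random_impurity(n)
    x <- stats::runif(n, 0, 1000)
    expect_equal(correct_impurities(as.vector(m %*% x), m), x,
                 tolerance = 1e-9)
  }
})

make_records <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, as.data.frame))
}

base_record <- function(ch01 = 100, ch02 = 100, iso = 0.9, sn = NULL,
                        miss = 0, loc = 20, protein = "P1", n_phospho = 1L) {
  data.frame(record = "r", site = "P1_S10", protein = protein,
             ch01 = ch01, ch02 = ch02,
             isolation_specificity = iso,
             summed_sn = sn %||% sum(c(ch01, ch02), na.rm = TRUE),
             n_missing_channels = miss, localization_score = loc,
             n_phospho = n_phospho, stringsAsFactors = FALSE)
}

test_that("filters follow the printed thresholds strictly", {
  pol <- filter_policy("phospho")
  r_iso <- base_record(iso = 0.79)
  flt <- filter_records(r_iso, pol)
  expect_identical(flt$rejected$reason, "isolation_specificity")

  r_sn <- base_record(ch01 = 80, ch02 = 80)  # summed_sn exactly 160
  expect_identical(nrow(filter_records(r_sn, pol)$rejected), 0L)
  r_sn159 <- base_record(ch01 = 80, ch02 = 79.9)
  expect_identical(filter_records(r_sn159, pol)$rejected$reason, "summed_sn")

  r_loc <- base_record(loc = 12.9)
  expect_identical(filter_records(r_loc, pol)$rejected$reason, "localization")
  r_loc13 <- base_record(loc = 13)
  expect_identical(nrow(filter_records(r_loc13, pol)$rejected), 0L)

  r_miss <- base_record(miss = 12)
  expect_identical(filter_records(r_miss, pol)$rejected$reason,
                   "missing_channels")
  expect_identical(nrow(filter_records(base_record(miss = 11), pol)$rejected), 0L)
})

test_that("first failing reason follows the fixed order", {
  pol <- filter_policy("phospho")
  r <- base_record(iso = 0.5, ch01 = 10, ch02 = 10, miss = 13, loc = 1)
  expect_identical(filter_records(r, pol)$rejected$reason, "missing_channels")
  r2 <- base_record(iso = 0.5, ch01 = 10, ch02 = 10, loc = 1)
  expect_identical(filter_records(r2, pol)$rejected$reason,
                   "isolation_specificity")
})

test_that("proteome policy relaxes isolation and missing-channel rules", {
  pol <- filter_policy("proteome")
  expect_identical(nrow(filter_records(base_record(iso = 0.75), pol)$rejected), 0L)
  expect_identical(filter_records(base_record(iso = 0.69), pol)$rejected$reason,
                   "isolation_specificity")
  expect_identical(filter_records(base_record(miss = 8), pol)$rejected$reason,
                   "missing_channels")
  expect_identical(nrow(filter_records(base_record(loc = 1), pol)$rejected), 0L)
})

test_that("filtering partitions the input and is idempotent", {
  set.seed(7)
  recs <- do.call(rbind, lapply(1:200, function(i)
    base_record(ch01 = stats::runif(1, 0, 200), ch02 = stats::runif(1, 0, 200),
                iso = stats::runif(1), loc = stats::runif(1, 0, 30),
                miss = sample(0:14, 1))))
  flt <- filter_records(recs, filter_policy("phospho"))
  expect_identical(nrow(flt$kept) + nrow(flt$rejected), nrow(recs))
  again <- filter_records(flt$kept, filter_policy("phospho"))
  expect_identical(nrow(again$rejected), 0L)
  expect_true(all(flt$rejected$reason %in%
                    c("missing_channels", "isolation_specificity",
                      "summed_sn", "localization", "no_quant")))
})

test_that("protein collapse sums records and conserves intensity", {
  recs <- rbind(base_record(1, 2), base_record(3, 4))
  tab <- collapse_to_protein(recs)
  expect_equal(unname(tab["P1", ]), c(4, 6))
  single <- collapse_to_protein(base_record(5, 7))
  expect_equal(unname(single["P1", ]), c(5, 7))
  recs2 <- rbind(base_record(1, 2, protein = "A"),
                 base_record(3, 4, protein = "B"),
                 base_record(10, 20, protein = "A"))
  tab2 <- collapse_to_protein(recs2)
  expect_equal(colSums(tab2), colSums(recs2[, c("ch01", "ch02")]),
               ignore_attr = TRUE)
  expect_warning(collapse_to_protein(rbind(base_record(1, 2),
                                           base_record(3, 4, protein = NA))),
                 "skipped")
})

test_that("equal-loading normalization equalizes and preserves the total", {
  m <- matrix(c(2, 2, 6, 2), 2, 2, dimnames = list(c("a", "b"), c("ch01", "ch02")))
  out <- normalize_equal_loading(m)
  expect_equal(unname(out), matrix(c(3, 3, 4.5, 1.5), 2, 2),
               ignore_attr = TRUE)
  expect_equal(sum(out), sum(m), tolerance = 1e-9)
  cs <- colSums(out)
  expect_lt(diff(range(cs)) / mean(cs), 1e-9)
  expect_equal(normalize_equal_loading(out), out, ignore_attr = TRUE,
               tolerance = 1e-12)
  eq <- matrix(c(1, 3, 2, 2), 2, 2, dimnames = dimnames(m))
  expect_equal(normalize_equal_loading(eq), eq, ignore_attr = TRUE)
  bad <- m; bad[, 2] <- 0
  expect_error(normalize_equal_loading(bad), "ch02")
})

test_that("phospho-to-protein normalization divides by the relative profile", {
  ph <- matrix(c(8, 8), 1, 2, dimnames = list("P1_S10", c("ch01", "ch02")))
  pr_flat <- matrix(c(4, 4), 1, 2, dimnames = list("P1", c("ch01", "ch02")))
  expect_equal(normalize_phospho_to_protein(ph, pr_flat), ph,
               ignore_attr = TRUE)
  pr <- matrix(c(2, 6), 1, 2, dimnames = list("P1", c("ch01", "ch02")))
  out <- normalize_phospho_to_protein(ph, pr)
  expect_equal(unname(out[1, ]), c(16, 16 / 3), tolerance = 1e-12)
  ph2 <- matrix(c(8, 8), 1, 2, dimnames = list("QX_S5", c("ch01", "ch02")))
  out2 <- normalize_phospho_to_protein(ph2, pr)
  expect_equal(out2, ph2, ignore_attr = TRUE)
  expect_identical(attr(out2, "unmatched"), "QX_S5")
  expect_error(normalize_phospho_to_protein(ph, pr[, 2:1, drop = FALSE]),
               "channel set")
})

test_that("median centering zeroes every column median", {
  m <- matrix(c(0, 0, 0, 1, 3, 5), 3, 2,
              dimnames = list(NULL, c("ch01", "ch02")))
  out <- median_center(m)
  expect_equal(unname(out[, 1]), c(0, 0, 0))
  expect_equal(unname(out[, 2]), c(-2, 0, 2))
  expect_equal(unname(apply(out, 2, stats::median)), c(0, 0))
  set.seed(3)
  big <- matrix(stats::rnorm(200), 50, 4,
                dimnames = list(NULL, sprintf("ch%02d", 1:4)))
  expect_equal(unname(apply(median_center(big), 2, stats::median)),
               rep(0, 4))
  bad <- m; bad[, 1] <- NA
  expect_error(median_center(bad), "no observed values")
})
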