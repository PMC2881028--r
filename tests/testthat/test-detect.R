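test_that("threshold matches the inverse-normal cutoff on standard draws", {
  withr::with_seed(71, {
    x <- rnorm(1e5)
  })
  nm <- fit_noise(x)
  # qnorm(0.999) = 3.090232
  expect_equal(nm$threshold, qnorm(0.999), tolerance = 0.05 / 3.09)
  expect_equal(nm$threshold, nm$location + qnorm(0.999) * nm$scale)

  withr::with_seed(72, {
    y <- rnorm(1e5, 7, 0.5)
  })
  nm2 <- fit_noise(y)
  expect_equal(nm2$threshold, 7 + qnorm(0.999) * 0.5, tolerance = 0.03 / 8.5)

  nm3 <- fit_noise(y, estimator = "mad")
  expect_equal(nm3$threshold, 7 + qnorm(0.999) * 0.5, tolerance = 0.03 / 8.5)
})

test_that("left-half scale shrugs off an expressed upper tail", {
  withr::with_seed(73, {
    clean <- rnorm(2e4)
    dirty <- clean
    dirty[sample.int(2e4, 1e3)] <- 6  # 5% contamination at +6 sigma
  })
  t_clean <- fit_noise(clean)$threshold
  t_dirty <- fit_noise(dirty)$threshold
  # mixture quantile algebra: median shifts to qnorm(0.5/0.95) = 0.066,
  # the 15.87th percentile to qnorm(0.1587/0.95) = -0.966, so the
  # contaminated threshold is at most ~6% above the clean one
  expect_gt(t_dirty, t_clean)
  expect_lt(t_dirty / t_clean, 1.07)
  # a naive mean + z*sd cutoff inflates far more
  t_naive <- mean(dirty) + qnorm(0.999) * sd(dirty)
  expect_gt(t_naive / t_clean, 1.25)
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_noise(rnorm(10)), "at least 20")
  expect_error(fit_noise(rep(1, 100)), "zero")
})

test_that("threshold is monotone in percentile and location-equivariant", {
  withr::with_seed(74, {
    x <- rnorm(5000)
  })
  p <- c(0.5, 0.9, 0.99, 0.999)
  thr <- vapply(p, function(pp) fit_noise(x, percentile = pp)$threshold,
                numeric(1))
  expect_true(all(diff(thr) > 0))
  # percentile 0.5 puts the threshold at the location
  expect_equal(thr[1], fit_noise(x)$location)
  # adding a constant shifts the threshold by that constant
  nm <- fit_noise(x)
  nm_shift <- fit_noise(x + 3)
  expect_equal(nm_shift$threshold, nm$threshold + 3, tolerance = 1e-12)
})

test_that("per-condition null call rate matches 1 - percentile", {
  withr::with_seed(75, {
    x <- rnorm(1e5)
  })
  nm <- fit_noise(x)
  rate <- mean(x > nm$threshold)
  # binomial 95% CI around p = 0.001 at n = 1e5: +-1.96*sqrt(p(1-p)/n)
  expect_lt(abs(rate - 0.001), 1.96 * sqrt(0.001 * 0.999 / 1e5) + 2e-4)
})

test_that("expression flags follow the any-condition rule", {
  summaries <- rbind(low = c(0, 0, 0, 0, 0),
                     one = c(0, 0, 5, 0, 0),
                     all = c(5, 5, 5, 5, 5))
  colnames(summaries) <- sprintf("c%d", 1:5)
  models <- lapply(1:5, function(i) {
    structure(list(threshold = 1), class = "noise_model")
  })
  calls <- call_expressed(summaries, models)
  expect_equal(unname(calls$expressed), c(FALSE, TRUE, TRUE))
  expect_equal(unname(calls$expressed_in["one", ]),
               c(FALSE, FALSE, TRUE, FALSE, FALSE))
})

test_that("profile standard deviations use the n-1 denominator", {
  withr::with_seed(76, {
    null_prof <- matrix(rnorm(500 * 5, 7, 0.1), 500, 5)
  })
  summaries <- rbind(null_prof,
                     konst = rep(3, 5),
                     spike = c(0, 0, 0, 0, 5))
  rownames(summaries) <- c(sprintf("n%03d", 1:500), "konst", "spike")
  colnames(summaries) <- sprintf("c%d", 1:5)
  dd <- call_differential(summaries)
  expect_equal(unname(dd$sd["konst"]), 0)
  expect_equal(unname(dd$sd["spike"]), sqrt(5))
  expect_false(dd$differential[["konst"]])
  expect_true(dd$differential[["spike"]])
})

test_that("differential null rate matches the sd-distribution oracle", {
  # With 5 Gaussian conditions the profile sd is chi-distributed (4 df),
  # not Gaussian, so the normal-quantile cutoff on a robust location/scale
  # fit exceeds its nominal 0.1%. The expected rate is derived here
  # independently from chi-squared quantiles: threshold ~= median +
  # qnorm(0.999) * (median - q15.87) of the sd distribution.
  med <- sqrt(qchisq(0.5, 4) / 4)
  q16 <- sqrt(qchisq(pnorm(-1), 4) / 4)
  thr_theory <- med + qnorm(0.999) * (med - q16)
  rate_theory <- pchisq(4 * thr_theory^2, 4, lower.tail = FALSE)
  withr::with_seed(77, {
    summaries <- matrix(rnorm(20000 * 5), 20000, 5)
  })
  rownames(summaries) <- sprintf("r%05d", seq_len(nrow(summaries)))
  colnames(summaries) <- sprintf("c%d", 1:5)
  dd <- call_differential(summaries)
  rate <- mean(dd$differential)
  expect_equal(rate, rate_theory,
               tolerance = 3 * sqrt(rate_theory / 20000) / rate_theory)
})

test_that("detect_regions wires expression and differential calls together", {
  withr::with_seed(78, {
    base <- matrix(rnorm(300 * 5, 7, 0.2), 300, 5)
  })
  rownames(base) <- sprintf("r%03d", 1:300)
  colnames(base) <- sprintf("c%d", 1:5)
  base["r001", 3] <- base["r001", 3] + 3  # expressed in c3 only
  det <- detect_regions(base)
  expect_s3_class(det, "region_expression")
  r1 <- det[det$region_id == "r001", ]
  expect_true(r1$expressed)
  expect_true(r1$expressed_c3)
  expect_false(r1$expressed_c1)
  expect_true(r1$differential)
  # flags unchanged when a constant is added to one condition
  shifted <- base
  shifted[, 2] <- shifted[, 2] + 5
  det2 <- detect_regions(shifted)
  expect_equal(det2$expressed, det$expressed)
})

test_that("detection report writes thresholds as header metadata", {
  withr::with_seed(79, {
    m <- matrix(rnorm(200 * 5, 7, 0.2), 200, 5,
                dimnames = list(sprintf("r%03d", 1:200),
                                sprintf("c%d", 1:5)))
  })
  det <- detect_regions(m)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_detection(det, path)
  hdr <- grep("^#", readLines(path), value = TRUE)
  expect_true(any(grepl("threshold c1=", hdr)))
  expect_true(any(grepl("sd_threshold=", hdr)))
  body <- read.table(path, sep = "\t", header = TRUE, comment.char = "#")
  expect_equal(nrow(body), 200)
})
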