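test_that("artificial reference is the per-probe median across arrays", {
  m <- rbind(c(1, 2, 10), c(3, 3, 3), c(0, 5, 4))
  rownames(m) <- paste0("p", 1:3)
  expect_equal(unname(build_reference(m)), c(2, 3, 4))
  # single array: reference equals that array
  m1 <- m[, 1, drop = FALSE]
  expect_equal(unname(build_reference(m1)), unname(m1[, 1]))
})

test_that("normalization leaves a bias-free array essentially unchanged", {
  withr::with_seed(61, {
    ref <- rnorm(2000, 8, 1)
  })
  m <- cbind(a = ref)
  rownames(m) <- sprintf("p%04d", seq_along(ref))
  norm <- loess_normalize(m, reference = setNames(ref, rownames(m)))
  expect_lt(max(abs(norm - m)), 1e-9)
})

test_that("a constant per-array offset is removed exactly", {
  withr::with_seed(62, {
    ref <- rnorm(3000, 8, 1)
  })
  m <- cbind(a = ref + 0.5, b = ref - 0.3, c = ref)
  rownames(m) <- sprintf("p%04d", seq_along(ref))
  names(ref) <- rownames(m)
  norm <- loess_normalize(m, reference = ref)
  expect_lt(max(abs(norm[, "a"] - ref)), 1e-6)
  expect_lt(max(abs(norm[, "b"] - ref)), 1e-6)
  # the reference itself is never altered
  expect_lt(max(abs(norm[, "c"] - ref)), 1e-9)
})

test_that("smooth quadratic intensity bias is flattened", {
  withr::with_seed(63, {
    n <- 10000
    A <- rnorm(n, 8, 1)
    bias <- 0.3 * (A - mean(A))^2
    m <- cbind(arr = A + bias)
    rownames(m) <- sprintf("p%05d", 1:n)
    ref <- setNames(A, rownames(m))
    norm <- loess_normalize(m, reference = ref)
    resid <- norm[, 1] - A
    # residual trend: smooth of the residual against A
    trend <- lowess(A, resid, f = 0.25)$y
    expect_lt(sqrt(mean(trend^2)), 0.02)
  })
})

test_that("normalization is idempotent", {
  # the local-linear fit reproduces any array whose log-ratio against the
  # reference is linear in A, so a second pass changes nothing there
  withr::with_seed(64, {
    ref <- rnorm(2000, 8, 1)
  })
  m <- cbind(a = ref + 0.4, b = ref - 0.25 + 0.1 * (ref - 8))
  rownames(m) <- sprintf("p%04d", seq_len(nrow(m)))
  names(ref) <- rownames(m)
  once <- loess_normalize(m, reference = ref)
  twice <- loess_normalize(once, reference = ref)
  expect_lt(max(abs(twice - once)), 1e-6)
  # with noise and curvature the smoother is only approximately
  # idempotent: the second pass must move the data far less than the first
  withr::with_seed(65, {
    m2 <- cbind(a = ref + 0.2 + 0.1 * (ref - 8)^2 + rnorm(2000, 0, 0.05))
  })
  rownames(m2) <- rownames(m)
  once2 <- loess_normalize(m2, reference = ref)
  twice2 <- loess_normalize(once2, reference = ref)
  first_move <- sqrt(mean((once2 - m2)^2))
  second_move <- sqrt(mean((twice2 - once2)^2))
  expect_lt(second_move, 0.05 * first_move)
})

test_that("too-small spans are rejected", {
  m <- cbind(a = rnorm(20))
  rownames(m) <- sprintf("p%02d", 1:20)
  expect_error(loess_normalize(m, span = 0.05), "fewer than 3")
})

test_that("median polish recovers an exactly additive decomposition", {
  r <- c(-1, 0, 1, 2, -2)   # median 0
  cc <- c(-0.5, 0, 0.5, 1, -1)
  x <- outer(r, cc, `+`) + 2
  mp <- median_polish(x, tol = 1e-10, max_iter = 50)
  expect_equal(mp$overall + mp$col, 2 + cc, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unname(mp$row), r, tolerance = 1e-12)
  expect_lt(max(abs(mp$residuals)), 1e-12)
})

test_that("median polish agrees with the reference implementation", {
  withr::with_seed(65, {
    for (i in 1:30) {
      x <- matrix(rnorm(25), 5, 5)
      mine <- median_polish(x, tol = 1e-10, max_iter = 100)
      ref <- stats::medpolish(x, eps = 1e-12, maxiter = 200, trace.iter = FALSE)
      expect_equal(mine$overall + mine$col, ref$overall + ref$col,
                   tolerance = 1e-6, ignore_attr = TRUE)
    }
  })
})

test_that("one gross outlier barely moves the summaries", {
  r <- c(-1, 0, 1, 0.5, -0.5)
  cc <- c(-2, 0, 2, 1, -1)
  x <- outer(r, cc, `+`) + 5
  clean <- median_polish(x, tol = 1e-10, max_iter = 100)
  x_out <- x
  x_out[2, 3] <- x_out[2, 3] + 10
  dirty <- median_polish(x_out, tol = 1e-10, max_iter = 100)
  expect_lt(max(abs((dirty$overall + dirty$col) -
                      (clean$overall + clean$col))), 0.01)
})

test_that("converged residuals have near-zero row and column medians", {
  withr::with_seed(66, {
    x <- matrix(rnorm(63), 9, 7)
  })
  mp <- median_polish(x, tol = 1e-8, max_iter = 100)
  expect_lt(max(abs(apply(mp$residuals, 1, median))), 1e-8)
  expect_lt(max(abs(apply(mp$residuals, 2, median))), 1e-8)
})

test_that("region summaries are invariant to probe order; singles pass through", {
  withr::with_seed(67, {
    m <- matrix(rnorm(40), 8, 5,
                dimnames = list(sprintf("p%d", 1:8), sprintf("c%d", 1:5)))
  })
  asg <- list(regA = c("p1", "p3", "p5", "p7"), regB = "p2")
  su1 <- summarize_regions(m, asg)
  asg_shuffled <- list(regA = c("p7", "p1", "p5", "p3"), regB = "p2")
  su2 <- summarize_regions(m, asg_shuffled)
  expect_equal(su1$summaries, su2$summaries)
  expect_equal(unname(su1$summaries["regB", ]), unname(m["p2", ]))
  # constant region summarizes to the constant
  m5 <- matrix(5, 4, 5, dimnames = list(sprintf("q%d", 1:4), colnames(m)))
  su3 <- summarize_regions(rbind(m, m5), list(konst = rownames(m5)))
  expect_equal(unname(su3$summaries["konst", ]), rep(5, 5))
})

test_that("zero-probe regions are flagged and excluded, not an error", {
  m <- matrix(rnorm(10), 2, 5,
              dimnames = list(c("p1", "p2"), sprintf("c%d", 1:5)))
  su <- summarize_regions(m, list(ok = c("p1", "p2"), empty = character(0)))
  expect_equal(su$excluded, "empty")
  expect_equal(rownames(su$summaries), "ok")
  expect_equal(unname(su$n_probes["empty"]), 0L)
})

test_that("intensity TSV round-trips through the raw/log2 readers", {
  withr::with_seed(68, {
    m <- matrix(abs(rnorm(20, 500, 100)), 4, 5,
                dimnames = list(sprintf("p%d", 1:4), sprintf("c%d", 1:5)))
  })
  attr(m, "scale") <- "raw"
  path <- withr::local_tempfile(fileext = ".tsv")
  write_intensities(m, path)
  back <- read_intensities(path)
  expect_equal(back, m, tolerance = 1e-12)
  lg <- log2_transform(back)
  expect_equal(attr(lg, "scale"), "log2")
  expect_error(log2_transform(matrix(c(-1, 2), 1, 2)), "positive")
})
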