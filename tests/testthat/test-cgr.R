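test_that("trajectory follows the midpoint rule from the centre", {
  t1 <- cgr_trajectory("ACGT")
  expect_equal(unname(t1),
               cbind(c(0.25, 0.125, 0.5625, 0.78125),
                     c(0.25, 0.625, 0.8125, 0.40625)),
               tolerance = 1e-15)
  # non-standard symbols step toward the centre, a fixed point from there
  tn <- cgr_trajectory("NNN")
  expect_true(all(tn == 0.5))
  # repeated halving toward the A corner has a closed form
  ta <- cgr_trajectory(strrep("A", 10))
  expect_equal(unname(ta[10, ]), rep(0.5 * 2^-10, 2), tolerance = 1e-15)
  expect_error(cgr_trajectory(""), "empty")
})

test_that("trajectory agrees with a literal loop oracle, stays in the square", {
  withr::local_seed(41)
  alphabet <- c("A", "C", "G", "T", "N", "R", "Y")
  for (rep in 1:20) {
    s <- paste0(sample(alphabet, sample(1:80, 1), replace = TRUE),
                collapse = "")
    tr <- cgr_trajectory(s)
    expect_equal(unname(tr), cgr_trajectory_loop(s), tolerance = 1e-12)
    expect_true(all(tr >= 0 & tr <= 1))
  }
})

test_that("counts are conserved and oriented with C/G at the top", {
  m <- cgr_matrix("AAAA", 2)
  expect_identical(sum(m), 4L)
  expect_identical(m[2, 1], 4L)    # bottom-left pixel: the A corner
  expect_identical(cgr_matrix(strrep("G", 5), 2)[1, 2], 5L)  # top-right
  withr::local_seed(42)
  for (rep in 1:25) {
    s <- random_acgt(sample(1:300, 1))
    for (R in c(1, 2, 4, 8, 224)) {
      expect_identical(sum(cgr_matrix(s, R)), nchar(s))
    }
  }
  expect_error(cgr_accumulate(cbind(0.5, 0.5), 0), "invalid resolution")
})

test_that("pixels at dyadic resolution are determined by the last k bases", {
  withr::local_seed(7)
  for (k in 1:4) {
    R <- 2^k
    for (rep in 1:5) {
      s <- random_acgt(100)
      traj <- cgr_trajectory(s)
      chars <- strsplit(s, "")[[1]]
      for (i in k:nchar(s)) {
        actual <- pixel_of(traj[i, 1], traj[i, 2], R)
        suffix <- paste0(chars[(i - k + 1):i], collapse = "")
        st <- cgr_trajectory(suffix)
        oracle <- pixel_of(st[k, 1], st[k, 2], R)
        expect_identical(actual, oracle)
      }
    }
  }
})

test_that("counts at R = 2^k aggregate by 2x2 blocks to R = 2^(k-1)", {
  withr::local_seed(8)
  for (rep in 1:10) {
    s <- random_acgt(400)
    strip <- function(m) matrix(as.integer(m), nrow(m))
    hi <- strip(cgr_matrix(s, 16))
    lo <- strip(cgr_matrix(s, 8))
    agg <- matrix(0L, 8, 8)
    for (i in 1:8) {
      for (j in 1:8) {
        agg[i, j] <- sum(hi[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
      }
    }
    expect_identical(agg, lo)
  }
})

test_that("normalization methods match hand-computed values", {
  m <- matrix(c(0, 2, 1, 9), 2)
  expect_equal(as.vector(cgr_normalize(m, "log")),
               (log1p(c(0, 2, 1, 9))) / log1p(9), tolerance = 1e-12)
  lin <- cgr_normalize(m, "linear")
  expect_equal(as.vector(lin), c(0, 2, 1, 9) / 9)
  # constant matrix: degenerate range collapses to zeros
  expect_true(all(cgr_normalize(matrix(3, 2, 2), "linear") == 0))
  # single hot pixel
  hot <- matrix(c(0, 0, 0, 10), 2)
  expect_equal(as.vector(cgr_normalize(hot, "linear")), c(0, 0, 0, 1))
  expect_equal(as.vector(cgr_normalize(hot, "none")), c(0, 0, 0, 1))
  expect_true(all(cgr_normalize(matrix(0, 2, 2), "none") == 0))
  expect_error(cgr_normalize(m, "fancy"))
})

test_that("robust scaling centres by median/IQR and falls back on zero IQR", {
  withr::local_seed(9)
  m <- matrix(rpois(64, 5), 8)
  q <- quantile(m, c(0.25, 0.75), names = FALSE)
  expect_gt(q[2] - q[1], 0)
  r <- cgr_normalize(m, "robust")
  z <- (m - median(m)) / (q[2] - q[1])
  expect_equal(unclass(r), (z - min(z)) / (max(z) - min(z)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(r >= 0 & r <= 1))
  expect_warning(rf <- cgr_normalize(matrix(c(rep(0, 15), 9), 4), "robust"),
                 "zero IQR")
  expect_identical(attr(rf, "method_used"), "linear")
})

test_that("PNG export writes round(255 v) bytes and round-trips", {
  withr::local_seed(10)
  path <- withr::local_tempfile(fileext = ".png")
  img <- matrix(runif(64), 8)
  write_cgr_png(img, path)
  back <- png::readPNG(path)
  expect_equal(back * 255, round(img * 255), tolerance = 1e-9)
  write_cgr_png(matrix(0, 4, 4), path)
  expect_true(all(png::readPNG(path) == 0))
  write_cgr_png(matrix(1, 4, 4), path)
  expect_true(all(png::readPNG(path) * 255 == 255))
  expect_error(write_cgr_png(matrix(2, 2, 2), path), "normalize")
})
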