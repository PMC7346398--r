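test_that("discard_initial trims volumes and guards the empty series", {
  run <- make_test_run(dims = c(3, 3, 3), nt = 217)
  expect_equal(dim(discard_initial(run, 5)$data)[4], 212)
  expect_identical(discard_initial(run, 0), run)
  expect_error(discard_initial(run, 217), "n_discard")
  expect_equal(discard_initial(run, 2)$data[, , , 1], run$data[, , , 3])
})

test_that("friston24 matches its definition and a brute-force builder", {
  z <- matrix(0, 10, 6)
  expect_equal(friston24(z), matrix(0, 10, 24), ignore_attr = TRUE)

  m <- matrix(0, 10, 6)
  m[3, 1] <- 2
  f <- friston24(m)
  expect_equal(unname(f[3, 7]), 4)    # R^2 block, same row
  expect_equal(unname(f[4, 13]), 2)   # one-volume lag block, next row
  expect_equal(unname(f[4, 19]), 4)   # squared lag
  expect_equal(unname(f[1, 13:24]), rep(0, 12))

  set.seed(11)
  m <- matrix(rnorm(60), 10, 6)
  # independent elementwise loop construction
  expect_24 <- matrix(0, 10, 24)
  for (t in 1:10) for (j in 1:6) {
    expect_24[t, j] <- m[t, j]
    expect_24[t, j + 6] <- m[t, j]^2
    lag <- if (t == 1) 0 else m[t - 1, j]
    expect_24[t, j + 12] <- lag
    expect_24[t, j + 18] <- lag^2
  }
  expect_equal(unname(friston24(m)), expect_24)

  m[2, 3] <- NA
  expect_error(friston24(m), "non-finite")
})

test_that("nuisance signals are mask means, centered, with named errors", {
  dims <- c(4, 4, 3)
  run <- make_test_run(dims = dims, nt = 12)
  wm <- array(FALSE, dims); wm[1, 1, 1] <- TRUE
  csf <- array(FALSE, dims); csf[4, 4, 3] <- TRUE

  # constant image -> all three signals identically zero after centering
  crun <- run; crun$data[] <- 7
  sig <- extract_nuisance_signals(crun, wm, csf)
  expect_equal(sig$wm, rep(0, 12))
  expect_equal(sig$csf, rep(0, 12))
  expect_equal(sig$global, rep(0, 12))

  # one-voxel wm mask equals that voxel's centered series
  sig <- extract_nuisance_signals(run, wm, csf)
  v <- run$data[1, 1, 1, ]
  expect_equal(sig$wm, v - mean(v))

  # two-voxel toy: series (1,2,3) and (3,2,1) -> centered mean is zero
  toy <- bold_run(array(0, dim = c(2, 1, 2, 3)), tr_seconds = 2)
  toy$data[1, 1, 1, ] <- c(1, 2, 3)
  toy$data[2, 1, 1, ] <- c(3, 2, 1)
  wm2 <- array(FALSE, c(2, 1, 2)); wm2[, 1, 1] <- TRUE
  csf2 <- array(FALSE, c(2, 1, 2)); csf2[1, 1, 2] <- TRUE
  expect_equal(extract_nuisance_signals(toy, wm2, csf2)$wm, c(0, 0, 0))

  empty <- array(FALSE, dims)
  expect_error(extract_nuisance_signals(run, empty, csf), "wm_mask")
  expect_error(extract_nuisance_signals(run, wm, empty), "csf_mask")
})

test_that("regress_out produces orthogonal residuals and is idempotent", {
  run <- make_test_run(dims = c(3, 3, 2), nt = 20)
  X <- cbind(intercept = 1, a = rnorm(20), b = rnorm(20))

  res <- regress_out(run, X)
  Y <- matrix(res$data, ncol = 20)
  expect_lt(max(abs(Y %*% X)), 1e-8)   # residual orthogonal to each column

  # intercept only -> mean-centered series
  res0 <- regress_out(run, matrix(1, 20, 1))
  v <- run$data[2, 2, 1, ]
  expect_equal(res0$data[2, 2, 1, ], v - mean(v))

  # a voxel equal to a regressor residualizes to zero
  run2 <- run; run2$data[1, 1, 1, ] <- X[, 2]
  expect_equal(max(abs(regress_out(run2, X)$data[1, 1, 1, ])), 0,
               tolerance = 1e-12)

  # idempotence
  expect_equal(regress_out(res, X)$data, res$data, tolerance = 1e-10)

  # collinear column dropped with warning, not an error
  Xc <- cbind(X, dup = X[, 2])
  expect_warning(rc <- regress_out(run, Xc), "collinear")
  expect_equal(rc$data, res$data, tolerance = 1e-10)
})

test_that("nuisance_design has 28 columns with a single intercept", {
  m <- matrix(rnorm(60), 10, 6)
  sig <- list(wm = rnorm(10), csf = rnorm(10), global = rnorm(10))
  X <- nuisance_design(friston24(m), sig)
  expect_equal(ncol(X), 28)
  expect_equal(sum(colnames(X) == "intercept"), 1)
  expect_equal(X[, "intercept"], rep(1, 10))
  expect_equal(ncol(nuisance_design(friston24(m),
                                    sig[c("wm", "csf")])), 27)
})

test_that("band-pass annihilates DC and has the declared passband", {
  nt <- 212; tr <- 2.4
  run <- bold_run(array(5, dim = c(1, 1, 1, nt)), tr_seconds = tr)
  expect_equal(max(abs(bandpass(run)$data)), 0, tolerance = 1e-10)

  tt <- (seq_len(nt) - 1) * tr
  inband <- sin(2 * pi * 0.05 * tt)
  run$data[1, 1, 1, ] <- inband
  out <- bandpass(run)$data[1, 1, 1, ]
  expect_gte(sum(out^2) / sum(inband^2), 0.9)

  outband <- sin(2 * pi * 0.18 * tt)
  run$data[1, 1, 1, ] <- outband
  out <- bandpass(run)$data[1, 1, 1, ]
  expect_lte(sum(out^2) / sum(outband^2), 0.1)

  expect_error(bandpass(run, 0.01, 0.3), "Nyquist")
  expect_error(bandpass(run, 0.1, 0.05), "low_hz")
})

test_that("filtering acts per voxel: no cross-voxel leakage", {
  run <- make_test_run(dims = c(2, 1, 1), nt = 40)
  both <- bandpass(run)
  for (i in 1:2) {
    single <- bold_run(run$data[i, 1, 1, , drop = FALSE],
                       tr_seconds = run$tr_seconds)
    expect_equal(both$data[i, 1, 1, ], bandpass(single)$data[1, 1, 1, ])
  }
})

test_that("preprocess_bold applies discard, regression and filter in order", {
  dims <- c(4, 4, 3)
  run <- make_test_run(dims = dims, nt = 40)
  wm <- array(FALSE, dims); wm[1, 1, ] <- TRUE
  csf <- array(FALSE, dims); csf[4, 4, ] <- TRUE
  motion <- generate_motion(40, 0.05, seed = 3)
  out <- preprocess_bold(run, motion, wm, csf, n_discard = 4)
  expect_equal(dim(out$data)[4], 36)
  # manual replication of the fixed stage order
  r2 <- discard_initial(run, 4)
  m2 <- motion$params[-(1:4), ]
  sig <- extract_nuisance_signals(r2, wm, csf)
  man <- bandpass(regress_out(r2, nuisance_design(friston24(m2), sig)))
  expect_equal(out$data, man$data, tolerance = 1e-12)
  expect_error(preprocess_bold(run, motion$params[1:30, ], wm, csf),
               "motion")
})
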