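test_that("voxel-wise group statistics match textbook ANOVA arithmetic", {
  dims <- c(2, 2, 1)
  vals <- c(0.1, 0.2, 0.5, 0.6, 0.9, 1.0)
  g <- rep(c("AA", "AG", "GG"), each = 2)
  maps <- lapply(vals, function(v) make_fcs_map(array(v, dims)))
  sm <- voxelwise_group_stat(maps, g, model = "additive")
  expect_equal(sm$stat_kind, "F")
  expect_equal(sm$df, c(2, 3))
  expect_equal(as.vector(sm$data), rep(64, 4), tolerance = 1e-10)

  # identical maps across subjects -> F = 0 everywhere
  same <- lapply(1:6, function(i) make_fcs_map(array(1:4, dims)))
  expect_equal(as.vector(voxelwise_group_stat(same, g)$data), rep(0, 4))

  # groups each holding {1,2,3} at a voxel -> F = 0
  rep3 <- lapply(rep(1:3, 3), function(v) make_fcs_map(array(v, dims)))
  # each group holds the same values {1,2,3}
  g9 <- rep(c("AA", "AG", "GG"), each = 3)
  expect_equal(as.vector(voxelwise_group_stat(rep3, g9)$data), rep(0, 4))

  expect_error(voxelwise_group_stat(maps, rep("XX", 6)), "unknown")
  expect_error(voxelwise_group_stat(maps[1:4], c("AA", "AA", "AG", "AG")),
               "model")
})

test_that("dominant/recessive t maps square to the two-group F", {
  dims <- c(3, 2, 1)
  set.seed(9)
  vals <- rnorm(12)
  g <- rep(c("AA", "AG", "GG"), each = 4)
  maps <- lapply(vals, function(v)
    make_fcs_map(array(v + rnorm(prod(dims), sd = 0.2), dims)))
  for (model in c("dominant", "recessive")) {
    sm <- voxelwise_group_stat(maps, g, model = model)
    expect_equal(sm$stat_kind, "t")
    grp <- if (model == "dominant") ifelse(g == "GG", "GG", "carrier") else
      ifelse(g == "AA", "AA", "carrier")
    Y <- sapply(maps, function(m) m$data[2, 2, 1])
    f2 <- oneway_anova(Y, grp)
    expect_equal(sm$data[2, 2, 1]^2, f2$F, tolerance = 1e-10)
    expect_equal(sm$df, f2$df2)
  }
})

test_that("covariate adjustment residualizes and spends degrees of freedom", {
  dims <- c(2, 1, 1)
  set.seed(10)
  n <- 18
  g <- rep(c("AA", "AG", "GG"), each = 6)
  cov <- data.frame(sex = sample(c("male", "female"), n, TRUE),
                    age = rnorm(n, 21, 1))
  vals <- rnorm(n) + 0.5 * cov$age
  maps <- lapply(vals, function(v) make_fcs_map(array(v, dims)))
  sm <- voxelwise_group_stat(maps, g, covariates = cov)
  expect_equal(sm$df, c(2, n - 3 - 2))
  # oracle: residualize on the covariate model, then one-way ANOVA with
  # the reduced error df
  r <- resid(lm(vals ~ sex + age, data = cov))
  gm <- tapply(r, g, mean)
  ssb <- sum(6 * (gm - mean(r))^2)
  ssw <- sum((r - gm[g])^2)
  expect_equal(sm$data[1, 1, 1], (ssb / 2) / (ssw / (n - 5)),
               tolerance = 1e-10)
})

test_that("smoothness estimator hits its analytic white-noise floor", {
  set.seed(12)
  dims <- c(14, 14, 10)
  mask <- array(TRUE, dims)
  maps <- lapply(1:40, function(i) array(rnorm(prod(dims)), dims))
  est <- estimate_smoothness(maps, mask)
  expect_equal(est$fwhm_vox, rep(sqrt(2 * log(2)), 3), tolerance = 0.03)
  expect_equal(est$search_volume_vox, prod(dims))
  expect_equal(est$resel_count, prod(dims) / prod(est$fwhm_vox))
})

test_that("smoothness estimator recovers a known applied FWHM", {
  set.seed(13)
  dims <- c(26, 26, 18)
  mask <- array(FALSE, dims); mask[5:22, 5:22, 5:14] <- TRUE
  maps <- lapply(1:12, function(i) smooth_noise_field(dims, fwhm_vox = 3))
  est <- estimate_smoothness(maps, mask)
  expect_equal(est$fwhm_vox, rep(3, 3), tolerance = 0.1 * 3)

  # resel extensivity: doubling the mask doubles the resel count
  mask2 <- array(FALSE, c(26, 52, 18)); mask2[5:22, 5:40, 5:14] <- TRUE
  maps2 <- lapply(1:12, function(i)
    smooth_noise_field(c(26, 52, 18), fwhm_vox = 3))
  est2 <- estimate_smoothness(maps2, mask2)
  expect_equal(est2$resel_count / est$resel_count, 2, tolerance = 0.1)
})

test_that("connected components respect connectivity and partition the set", {
  d <- c(5, 5, 3)
  fg <- array(FALSE, d)
  fg[1, 1, 1] <- TRUE; fg[2, 2, 1] <- TRUE   # diagonal neighbors
  fg[5, 5, 3] <- TRUE
  l26 <- fcstrength:::label_components(fg, 26L)
  l6 <- fcstrength:::label_components(fg, 6L)
  expect_equal(max(l26), 2)   # diagonal pair joined under 26
  expect_equal(max(l6), 3)    # separated under 6
  expect_setequal(which(l26 > 0), which(fg))
  # labels partition the foreground
  set.seed(14)
  fg2 <- array(runif(prod(d)) < 0.4, d)
  lab <- fcstrength:::label_components(fg2, 18L)
  expect_true(all((lab > 0) == fg2))
})

test_that("GRF pieces match independent closed forms", {
  # expected cluster count at u = 3.09 vs directly coded EC density
  u <- qnorm(0.001, lower.tail = FALSE)
  R <- 123.4
  expected <- R * (4 * log(2))^(3 / 2) * (2 * pi)^(-2) * (u^2 - 1) *
    exp(-u^2 / 2)
  expect_equal(fcstrength:::grf_expected_clusters(u, R), expected,
               tolerance = 1e-12)

  # infinite forming threshold -> empty table, not an error
  dims <- c(6, 6, 4)
  mask <- array(TRUE, dims)
  maps <- lapply(1:9, function(i) make_fcs_map(array(rnorm(prod(dims)), dims)))
  g <- rep(c("AA", "AG", "GG"), each = 3)
  sm <- voxelwise_group_stat(maps, g)
  smo <- estimate_smoothness(sm$residuals, mask)
  tab <- grf_cluster_inference(sm, smo, voxel_forming_p = 1e-14)
  expect_s3_class(tab, "cluster_table")
  expect_equal(nrow(tab), 0)
  expect_error(grf_cluster_inference(sm, NULL), "smoothness")
})

test_that("corrected cluster p decreases with extent at fixed smoothness", {
  dims <- c(12, 12, 6)
  mask <- array(TRUE, dims)
  stat <- array(0, dims)
  stat[2:3, 2, 2] <- 40          # 2-voxel cluster
  stat[7:10, 7:9, 3:4] <- 40     # 24-voxel cluster
  sm <- structure(list(data = stat, stat_kind = "F", df = c(2, 57),
                       mask = mask, residuals = NULL, groups = NULL),
                  class = "stat_map")
  smo <- structure(list(fwhm_vox = c(2, 2, 2), resel_count = prod(dims) / 8,
                        search_volume_vox = prod(dims)),
                   class = "smoothness_estimate")
  tab <- attr(grf_cluster_inference(sm, smo, cluster_alpha = 0.5),
              "all_clusters")
  expect_equal(nrow(tab), 2)
  big <- tab[tab$size_vox == 24, ]; small <- tab[tab$size_vox == 2, ]
  expect_lt(big$cluster_p_corrected, small$cluster_p_corrected)
  # peak index is 0-based
  expect_true(all(tab$peak_x >= 0 & tab$peak_x < dims[1]))
})

test_that("LSD post hoc uses the pooled error and orders p by |mean diff|", {
  vals <- c(1, 2, 1, 2, 5, 6)
  g <- rep(c("A", "B", "C"), each = 2)
  got <- posthoc_lsd(vals, g)
  # hand arithmetic: MSE = 1.5/3 = 0.5, se = sqrt(0.5 * 1) for n=2 pairs
  se <- sqrt(0.5 * (1 / 2 + 1 / 2))
  expect_equal(got$t[got$group1 == "A" & got$group2 == "B"], 0)
  expect_equal(got$p[got$group1 == "A" & got$group2 == "B"], 1)
  expect_equal(got$t[got$group1 == "A" & got$group2 == "C"], -4 / se,
               tolerance = 1e-12)
  expect_equal(got$p[got$group1 == "A" & got$group2 == "C"],
               2 * pt(-abs(4 / se), 3), tolerance = 1e-12)
  # largest |mean difference| gets the smallest p under the shared SE
  set.seed(15)
  vals2 <- c(rnorm(5, 0), rnorm(5, 1), rnorm(5, 3))
  g2 <- rep(c("A", "B", "C"), each = 5)
  got2 <- posthoc_lsd(vals2, g2)
  expect_equal(order(abs(got2$mean_diff)), order(-got2$p))
  expect_error(posthoc_lsd(c(1, 2, 3), c("a", "a", "b")), "genotypes")
})
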