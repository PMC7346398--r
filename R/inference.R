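#' Voxel-wise genotype-group statistic maps
#'
#' Tests each in-mask voxel's FCS across genotype groups under one of
#' three genetic models: `additive` contrasts the three genotypes
#' (one-way ANOVA F), `dominant` contrasts A-allele carriers (AA + AG)
#' against GG, and `recessive` contrasts AA against G-allele carriers
#' (AG + GG), both by pooled-variance two-sample t. When a covariate table
#' (e.g. sex, age) is supplied, covariates are regressed out of the FCS
#' values first and the error degrees of freedom reduced accordingly.
#' Standardized residual maps (unit voxel-wise variance under the group
#' model) are returned for smoothness estimation.
#'
#' @param fcs_maps List of `fcs_map`s sharing grid and mask (one per
#'   subject).
#' @param genotypes Character/factor vector of "AA"/"AG"/"GG" per subject.
#' @param model `"additive"`, `"dominant"` or `"recessive"`.
#' @param covariates Optional data frame of per-subject covariates.
#' @return A `stat_map`: list with 3D `data` (F or t), `stat_kind`, `df`
#'   (c(df1, df2) for F, scalar for t), `mask`, `residuals` (subjects x
#'   in-mask-voxel matrix), `groups` (the model's group factor).
#' @export
voxelwise_group_stat <- function(fcs_maps, genotypes,
                                 model = c("additive", "dominant",
                                           "recessive"),
                                 covariates = NULL) {
  model <- match.arg(model)
  genotypes <- as.character(genotypes)
  bad <- setdiff(unique(genotypes), c("AA", "AG", "GG"))
  if (length(bad))
    stop_field("genotypes", paste("unknown label(s):",
                                  paste(bad, collapse = ", ")))
  n <- length(fcs_maps)
  if (n != length(genotypes))
    stop_field("genotypes", "length does not match number of maps")
  mask <- fcs_maps[[1]]$mask
  sp <- dim(fcs_maps[[1]]$data)
  for (m in fcs_maps)
    if (!identical(dim(m$data), sp) || !identical(m$mask, mask))
      stop_field("fcs_maps", "maps do not share grid and mask")
  g <- switch(model,
    additive = factor(genotypes, levels = c("AA", "AG", "GG")),
    dominant = factor(ifelse(genotypes %in% c("AA", "AG"),
                             "carrier", "GG"),
                      levels = c("carrier", "GG")),
    recessive = factor(ifelse(genotypes == "AA", "AA", "carrier"),
                       levels = c("AA", "carrier")))
  if (any(table(g) < 2L))
    stop_field("genotypes", sprintf(
      "model '%s' needs >= 2 subjects in every group", model))
  inm <- which(as.vector(mask))
  Y <- t(vapply(fcs_maps, function(m) as.vector(m$data)[inm],
                numeric(length(inm))))          # subjects x V
  p_cov <- 0L
  if (!is.null(covariates)) {
    X <- stats::model.matrix(~ ., data = as.data.frame(covariates))
    p_cov <- ncol(X) - 1L
    Y <- qr.resid(qr(X), Y)
  }
  k <- nlevels(g)
  ng <- as.integer(table(g))
  gm <- colMeans(Y)
  G <- rowsum(Y, g) / ng                         # k x V group means
  ssb <- colSums(ng * (t(t(G) - gm))^2)
  sst <- colSums(t(t(Y) - gm)^2)
  ssw <- pmax(sst - ssb, 0)
  df2 <- n - k - p_cov
  if (df2 < 1L) stop_field("covariates", "no residual degrees of freedom")
  if (k == 2L) {
    mse <- ssw / df2
    se <- sqrt(mse * (1 / ng[1] + 1 / ng[2]))
    stat <- (G[1, ] - G[2, ]) / se
    stat[!is.finite(stat)] <- 0
    kind <- "t"; df <- df2
  } else {
    stat <- (ssb / (k - 1)) / (ssw / df2)
    stat[ssb == 0] <- 0                          # 0/0 when flat everywhere
    kind <- "F"; df <- c(k - 1, df2)
  }
  resid <- Y - G[as.integer(g), , drop = FALSE]
  s <- sqrt(ssw / df2)
  ok <- s > 0
  resid[, ok] <- sweep(resid[, ok, drop = FALSE], 2, s[ok], "/")
  resid[, !ok] <- 0
  out <- numeric(prod(sp)); out[inm] <- stat
  structure(list(data = array(out, dim = sp), stat_kind = kind, df = df,
                 mask = mask, residuals = resid, groups = g),
            class = "stat_map")
}

#' Estimate field smoothness from standardized residuals
#'
#' Per-axis smoothness (FWHM in voxel units) from the variance of first
#' spatial differences of the standardized residual maps:
#' `FWHM_axis = sqrt(4 ln 2 / var_axis)`, pooled over maps, where the
#' residual field is first scaled to unit variance voxel-wise. The RESEL
#' count is the resels-per-voxel sum `sum_mask prod_axis(1 / FWHM_axis)`.
#' For an unsmoothed i.i.d. Gaussian field the difference variance is 2,
#' so the estimator returns `sqrt(2 ln 2) ~ 1.1774` voxels per axis (its
#' white-noise floor).
#'
#' @param residual_maps Subjects x in-mask-voxels matrix (as returned by
#'   [voxelwise_group_stat()]) or a list of 3D arrays.
#' @param mask Logical 3D array.
#' @return A `smoothness_estimate`: list with `fwhm_vox` (length 3),
#'   `resel_count`, `search_volume_vox`.
#' @export
estimate_smoothness <- function(residual_maps, mask) {
  d <- dim(mask)
  if (is.list(residual_maps)) {
    inm <- which(as.vector(mask))
    residual_maps <- t(vapply(residual_maps,
                              function(a) as.vector(a)[inm],
                              numeric(length(inm))))
  }
  if (nrow(residual_maps) < 2L)
    stop_field("residual_maps", "need at least 2 maps")
  # voxel-wise standardization across maps
  s <- sqrt(colMeans(residual_maps^2))
  if (all(s == 0)) stop_field("residual_maps", "residuals have zero variance")
  ok <- s > 0
  R <- residual_maps
  R[, ok] <- sweep(R[, ok, drop = FALSE], 2, s[ok], "/")
  inm_idx <- which(as.vector(mask))
  vol <- array(NA_real_, dim = d)
  fwhm <- numeric(3)
  for (ax in 1:3) {
    nbr <- shift_array(mask, -1L, ax) & mask     # voxel and its +1 neighbor
    pairs <- which(as.vector(nbr))
    if (length(pairs) == 0L) { fwhm[ax] <- Inf; next }
    step <- c(1L, d[1], d[1] * d[2])[ax]
    pos <- match(pairs, inm_idx); pos2 <- match(pairs + step, inm_idx)
    dif <- R[, pos2, drop = FALSE] - R[, pos, drop = FALSE]
    v <- mean(dif^2)
    if (v <= 0) stop_field("residual_maps", "zero-variance differences")
    fwhm[ax] <- sqrt(4 * log(2) / v)
  }
  if (any(!is.finite(fwhm)))
    fwhm[!is.finite(fwhm)] <- max(fwhm[is.finite(fwhm)], 1)
  nvox <- length(inm_idx)
  structure(list(fwhm_vox = fwhm,
                 resel_count = nvox / prod(fwhm),
                 search_volume_vox = nvox),
            class = "smoothness_estimate")
}

# 3D connected-component labelling under 6/18/26 connectivity.
# Returns an integer array, 0 outside the foreground.
label_components <- function(fg, connectivity = 26L) {
  d <- dim(fg)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  offs <- switch(as.character(connectivity),
                 "6"  = offs[rowSums(abs(offs)) == 1, , drop = FALSE],
                 "18" = offs[rowSums(abs(offs)) <= 2, , drop = FALSE],
                 "26" = offs,
                 stop_field("connectivity", "must be 6, 18 or 26"))
  lab <- array(0L, dim = d)
  idx <- which(fg)
  if (length(idx) == 0L) return(lab)
  co <- arrayInd(idx, d)
  key <- function(m) (m[, 3] - 1L) * d[1] * d[2] + (m[, 2] - 1L) * d[1] + m[, 1]
  cur <- 0L
  for (s in idx) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s; lab[s] <- cur
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      vc <- arrayInd(v, d)[1, ]
      nb <- sweep(offs, 2, vc, "+")
      okb <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[okb, , drop = FALSE]
      if (!nrow(nb)) next
      ni <- key(nb)
      ni <- ni[fg[ni] & lab[ni] == 0L]
      if (length(ni)) { lab[ni] <- cur; queue <- c(queue, ni) }
    }
  }
  lab
}

# Expected number of clusters (maxima) of a unit Gaussian field above
# threshold u over R resels: 3-D Euler-characteristic density.
grf_expected_clusters <- function(u, resels) {
  resels * (4 * log(2))^1.5 * (2 * pi)^-2 * (u^2 - 1) * exp(-u^2 / 2)
}

#' Gaussian-random-field cluster-level inference
#'
#' Converts the statistic map to equivalent Z scores by p-value matching
#' under the statistic's null distribution, thresholds at the
#' cluster-forming level, labels connected components, and assigns each
#' cluster a GRF-corrected p-value using the three-dimensional
#' expected-Euler-characteristic and cluster-extent forms: with `E_m` the
#' expected cluster count above the forming threshold over the estimated
#' RESEL count and `E_n` the expected cluster size in voxels, cluster
#' extent is modelled as `P(n >= k) = exp(-beta k^(2/3))` with `beta`
#' fixed by `E_n`, and the corrected p is `1 - exp(-E_m P(n >= k))`.
#'
#' F maps are thresholded one-sidedly; t maps two-sidedly as two
#' one-sided passes at `voxel_forming_p / 2`, with cluster peaks keeping
#' their sign.
#'
#' @param stat_map A `stat_map` from [voxelwise_group_stat()].
#' @param smoothness A `smoothness_estimate` from [estimate_smoothness()].
#' @param voxel_forming_p Voxel-level cluster-forming p (default 0.001).
#' @param cluster_alpha Cluster-level corrected significance (default
#'   0.05).
#' @param connectivity Neighborhood for component labelling: 6, 18 or 26
#'   (default 26).
#' @return A `cluster_table` data frame with columns `cluster_id`,
#'   `size_vox`, `peak_x`, `peak_y`, `peak_z` (0-based voxel indices),
#'   `peak_stat`, `cluster_p_corrected`, holding the clusters with
#'   corrected p <= `cluster_alpha`; the unfiltered table is attached as
#'   `attr(, "all_clusters")` and the labelled cluster mask of the
#'   significant clusters as `attr(, "cluster_labels")`.
#' @export
grf_cluster_inference <- function(stat_map, smoothness,
                                  voxel_forming_p = 0.001,
                                  cluster_alpha = 0.05,
                                  connectivity = 26L) {
  stopifnot(inherits(stat_map, "stat_map"))
  if (is.null(smoothness) || !inherits(smoothness, "smoothness_estimate"))
    stop_field("smoothness", "a smoothness_estimate is required")
  if (voxel_forming_p <= 0 || voxel_forming_p >= 1)
    stop_field("voxel_forming_p", "must lie in (0, 1)")
  if (cluster_alpha <= 0 || cluster_alpha >= 1)
    stop_field("cluster_alpha", "must lie in (0, 1)")
  d <- dim(stat_map$data)
  if (stat_map$stat_kind == "F") {
    pvox <- stats::pf(stat_map$data, stat_map$df[1], stat_map$df[2],
                      lower.tail = FALSE)
    passes <- list(list(sign = 1,
                        supra = stat_map$mask & pvox < voxel_forming_p,
                        u = stats::qnorm(voxel_forming_p, lower.tail = FALSE),
                        p_tail = voxel_forming_p))
  } else {
    ptail <- voxel_forming_p / 2
    u <- stats::qnorm(ptail, lower.tail = FALSE)
    pu <- stats::pt(stat_map$data, stat_map$df, lower.tail = FALSE)
    pl <- stats::pt(stat_map$data, stat_map$df, lower.tail = TRUE)
    passes <- list(
      list(sign = 1, supra = stat_map$mask & pu < ptail, u = u,
           p_tail = ptail),
      list(sign = -1, supra = stat_map$mask & pl < ptail, u = u,
           p_tail = ptail))
  }
  rows <- list()
  labels_sig <- array(0L, dim = d)
  n_sig <- 0L
  for (pass in passes) {
    if (!any(pass$supra)) next
    lab <- label_components(pass$supra, connectivity)
    Em <- grf_expected_clusters(pass$u, smoothness$resel_count)
    Em <- max(Em, .Machine$double.eps)
    En <- smoothness$search_volume_vox * pass$p_tail / Em
    beta <- (gamma(2.5) / En)^(2 / 3)
    for (cid in seq_len(max(lab))) {
      vox <- which(lab == cid)
      k <- length(vox)
      pk <- vox[which.max(abs(stat_map$data[vox]))]
      pnk <- exp(-beta * k^(2 / 3))
      pcor <- 1 - exp(-Em * pnk)
      co <- arrayInd(pk, d)[1, ]
      rows[[length(rows) + 1L]] <- data.frame(
        size_vox = k, peak_x = co[1] - 1L, peak_y = co[2] - 1L,
        peak_z = co[3] - 1L,
        peak_stat = stat_map$data[pk],
        cluster_p_corrected = pcor, .vox = I(list(vox)))
    }
  }
  if (length(rows) == 0L) {
    tab <- empty_cluster_table()
  } else {
    all_tab <- do.call(rbind, rows)
    all_tab <- all_tab[order(all_tab$cluster_p_corrected,
                             -all_tab$size_vox), , drop = FALSE]
    all_tab$cluster_id <- seq_len(nrow(all_tab))
    sig <- all_tab$cluster_p_corrected <= cluster_alpha
    for (i in which(sig)) {
      n_sig <- n_sig + 1L
      labels_sig[all_tab$.vox[[i]]] <- n_sig
    }
    keep <- c("cluster_id", "size_vox", "peak_x", "peak_y", "peak_z",
              "peak_stat", "cluster_p_corrected")
    tab <- all_tab[sig, keep, drop = FALSE]
    tab$cluster_id <- seq_len(nrow(tab))
    rownames(tab) <- NULL
    attr(tab, "all_clusters") <- all_tab[, keep, drop = FALSE]
  }
  attr(tab, "cluster_labels") <- labels_sig
  attr(tab, "voxel_forming_p") <- voxel_forming_p
  attr(tab, "cluster_alpha") <- cluster_alpha
  class(tab) <- c("cluster_table", class(tab))
  tab
}

empty_cluster_table <- function() {
  tab <- data.frame(cluster_id = integer(), size_vox = integer(),
                    peak_x = integer(), peak_y = integer(),
                    peak_z = integer(), peak_stat = numeric(),
                    cluster_p_corrected = numeric())
  attr(tab, "all_clusters") <- tab
  tab
}

#' Fisher LSD post hoc pairwise comparisons
#'
#' Pairwise two-sample t-tests among groups using the pooled one-way ANOVA
#' mean-square error and its degrees of freedom, with unadjusted p-values
#' (the least-significant-difference convention).
#'
#' @param values Numeric vector of per-subject values.
#' @param genotypes Group labels (>= 2 per group).
#' @return Data frame with one row per group pair: `group1`, `group2`,
#'   `mean_diff`, `t`, `df`, `p`.
#' @export
posthoc_lsd <- function(values, genotypes) {
  g <- factor(genotypes)
  if (nlevels(g) < 2L) stop_field("genotypes", "need at least 2 groups")
  ng <- table(g)
  if (any(ng < 2L)) stop_field("genotypes", "every group needs >= 2 subjects")
  n <- length(values)
  k <- nlevels(g)
  means <- tapply(values, g, mean)
  ssw <- sum(tapply(values, g, function(v) sum((v - mean(v))^2)))
  df <- n - k
  mse <- ssw / df
  pairs <- utils::combn(levels(g), 2)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    mean_diff = NA_real_, t = NA_real_, df = df,
                    p = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    dd <- means[[a]] - means[[b]]
    se <- sqrt(mse * (1 / ng[[a]] + 1 / ng[[b]]))
    tv <- if (se > 0) dd / se else 0
    out$mean_diff[i] <- dd
    out$t[i] <- tv
    out$p[i] <- 2 * stats::pt(-abs(tv), df)
  }
  out
}
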