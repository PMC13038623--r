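test_that("pointwise t matches the closed-form two-sample t", {
  # single grid point, A = {1,2,3}, B = {4,5,6}: pooled SD 1, SE 0.8165
  A <- matrix(c(1, 2, 3), 3, 1); B <- matrix(c(4, 5, 6), 3, 1)
  g <- pointwise_t(A, B, "between")
  expect_equal(g$tmap[1, 1], -3/sqrt(2/3), tolerance = 1e-4)  # -3.674
  expect_equal(g$df, 4)
  # identical groups: t = 0 everywhere
  X <- matrix(rnorm(12), 4, 3)
  g0 <- pointwise_t(X[1:2, , drop = FALSE], X[1:2, , drop = FALSE], "between")
  expect_equal(max(abs(g0$tmap)), 0)
  # antisymmetry under group swap
  set.seed(20)
  A2 <- array(rnorm(3 * 4 * 5), c(3, 4, 5)); B2 <- array(rnorm(3 * 4 * 5), c(3, 4, 5))
  expect_equal(pointwise_t(A2, B2)$tmap, -pointwise_t(B2, A2)$tmap)
  # paired design df and value
  gp <- pointwise_t(A2, B2, "within")
  expect_equal(gp$df, 2)
  expect_equal(gp$tmap[2, 3],
               unname(t.test(A2[, 2, 3], B2[, 2, 3], paired = TRUE)$statistic),
               tolerance = 1e-10)
  expect_error(pointwise_t(A2, B2[, 1:2, ]), "mismatched")
})

test_that("pointwise t agrees with t.test across the grid", {
  set.seed(21)
  A <- array(rnorm(5 * 3 * 4), c(5, 3, 4)); B <- array(rnorm(6 * 3 * 4, 0.5), c(6, 3, 4))
  g <- pointwise_t(A, B, "between")
  gw <- pointwise_t(A, B, "between", welch = TRUE)
  for (i in 1:3) for (j in 1:4) {
    expect_equal(g$tmap[i, j],
                 unname(t.test(A[, i, j], B[, i, j], var.equal = TRUE)$statistic),
                 tolerance = 1e-10)
    expect_equal(gw$tmap[i, j],
                 unname(t.test(A[, i, j], B[, i, j])$statistic),
                 tolerance = 1e-10)
  }
})

test_that("cluster formation respects threshold, sign and 4-adjacency", {
  mk_grid <- function(tmap, df = 28) {
    structure(list(tmap = tmap, df = df, design = "between",
                   freqs = seq_len(nrow(tmap)), times = seq_len(ncol(tmap))),
              class = "verge_tfgrid")
  }
  cfg <- perm_config(n_perm = 100)
  # one suprathreshold point
  tm <- matrix(0, 4, 4); tm[2, 2] <- 3
  cl <- form_clusters(mk_grid(tm), cfg)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$mass, 3)
  expect_equal(cl[[1]]$sign, "+")
  # 2x2 block all 2.5: one cluster, mass 10
  tm2 <- matrix(0, 5, 5); tm2[2:3, 2:3] <- 2.5
  cl2 <- form_clusters(mk_grid(tm2), cfg)
  expect_length(cl2, 1)
  expect_equal(cl2[[1]]$mass, 10)
  # checkerboard of +3/-3: every point its own cluster
  tm3 <- matrix(ifelse((outer(1:6, 1:6, "+") %% 2) == 0, 3, -3), 6, 6)
  cl3 <- form_clusters(mk_grid(tm3), cfg)
  expect_length(cl3, 36)
  expect_true(all(abs(vapply(cl3, `[[`, 0, "mass")) == 3))
  # subthreshold grid: empty list
  expect_length(form_clusters(mk_grid(matrix(1, 3, 3)), cfg), 0)
})

test_that("component labelling matches a brute-force oracle on random masks", {
  set.seed(22)
  for (rep in 1:20) {
    tm <- matrix(rnorm(15 * 12, sd = 2), 15, 12)
    cl <- form_clusters(structure(list(tmap = tm, df = 28, design = "between",
                                       freqs = 1:15, times = 1:12),
                                  class = "verge_tfgrid"),
                        perm_config(n_perm = 100))
    t_crit <- qt(0.975, 28)
    # oracle masses per sign
    masses <- c()
    for (sgn in c(1, -1)) {
      mask <- (sgn * tm) > t_crit
      if (!any(mask)) next
      lab <- oracle_label(mask)
      masses <- c(masses, sapply(seq_len(max(lab)), function(k) sum(tm[lab == k])))
    }
    expect_equal(sort(vapply(cl, `[[`, 0, "mass")), sort(as.numeric(masses)))
  }
})

test_that("Monte-Carlo permutation null is seeded and exhaustive mode is exact", {
  set.seed(23)
  A <- array(rnorm(4 * 5 * 6), c(4, 5, 6)); B <- array(rnorm(4 * 5 * 6, 0.1), c(4, 5, 6))
  cfg <- perm_config(n_perm = 150, seed = 99)
  n1 <- permutation_null(A, B, cfg, "between")
  n2 <- permutation_null(A, B, cfg, "between")
  expect_identical(n1, n2)
  expect_length(n1, 150)
  # exhaustive enumeration equals the independent oracle's multiset
  ex <- permutation_null(A, B, cfg, "between", exhaustive = TRUE)
  expect_length(ex, choose(8, 4))
  X <- rbind(vergelab:::flatten_stack(A), vergelab:::flatten_stack(B))
  t_crit <- qt(0.975, 6)
  oracle <- apply(combn(8, 4), 2, function(idxA) {
    XA <- X[idxA, , drop = FALSE]; XB <- X[setdiff(1:8, idxA), , drop = FALSE]
    tv <- sapply(seq_len(ncol(X)), function(j) {
      unname(t.test(XA[, j], XB[, j], var.equal = TRUE)$statistic)
    })
    oracle_max_mass(matrix(tv, 5, 6), t_crit)
  })
  expect_equal(sort(ex), sort(oracle), tolerance = 1e-10)
  expect_error(perm_config(n_perm = 50), "n_perm")
})

test_that("cluster p-values follow the +1-corrected Monte-Carlo formula", {
  cl <- list(list(mass = 100, sign = "+"), list(mass = 0, sign = "+"),
             list(mass = 10, sign = "-"))
  null <- c(rep(5, 4999))
  out <- cluster_p(cl, null, perm_config(n_perm = 4999))
  expect_equal(out[[1]]$p_value, 1 / 5000)
  expect_equal(out[[2]]$p_value, 1)          # mass 0: all null >= 0
  # p monotone non-increasing in |mass|
  ps <- vapply(out, `[[`, 0, "p_value")
  ms <- abs(vapply(out, `[[`, 0, "mass"))
  expect_true(all(diff(ps[order(ms)]) <= 0))
  expect_error(cluster_p(cl, numeric(0)), "empty null")
})

test_that("observed clusters are invariant to relabeling subjects within groups", {
  co <- tiny_cohort(seed = 31, n_per_group = 4,
                    effects = list(frontal_theta_effect(3)))
  ep <- epoch_cohort(co, "bo_break")
  st <- cohort_tf_stack(ep, roi_channels("frontal"), reduced_cwt_config(),
                        time_decim = 10)
  # permute subjects inside each group; the t-map must be identical
  perm <- c(sample(1:4), sample(5:8))
  st2 <- st; st2$data <- st$data[perm, , ]; st2$groups <- st$groups[perm]
  g1 <- pointwise_t(st$data[st$groups == "control", , ],
                    st$data[st$groups == "nsbvd", , ])
  g2 <- pointwise_t(st2$data[st2$groups == "control", , ],
                    st2$data[st2$groups == "nsbvd", , ])
  expect_equal(g1$tmap, g2$tmap, tolerance = 1e-12)
})

test_that("the full test recovers an injected effect and reports extents", {
  co <- generate_cohort(synth_config(n_per_group = 10, seed = 6),
                        list(frontal_theta_effect(4)), conditions = "bo_break")
  ep <- epoch_cohort(co, "bo_break")
  st <- cohort_tf_stack(ep, roi_channels("frontal"), reduced_cwt_config(),
                        time_decim = 10, measure = "ratio")
  res <- run_cluster_test(st, design = "between",
                          bands = list(theta = c(4, 8)),
                          cfg = perm_config(n_perm = 200, seed = 5))
  sig <- res$table[res$table$significant, ]
  expect_gt(nrow(sig), 0)
  # patients have higher theta: control - nsbvd mass is negative
  expect_true(any(sig$cluster_mass < 0))
  # extent overlaps the injected window
  ov <- pmin(sig$window_end_ms, -302) - pmax(sig$window_start_ms, -548)
  expect_gt(max(ov) / 246, 0.5)
  # empty result on a flat grid
  stn <- st
  stn$data[] <- 1
  stn$data <- stn$data + array(rnorm(length(stn$data), sd = 1e-3), dim(stn$data))
  res0 <- run_cluster_test(stn, design = "between",
                           bands = list(theta = c(4, 8)),
                           cfg = perm_config(n_perm = 100, seed = 2))
  expect_true(all(!res0$table$significant) || nrow(res0$table) == 0)
})
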