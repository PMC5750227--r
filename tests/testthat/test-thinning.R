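test_that("group contrast matches the closed-form two-sample t", {
  set.seed(4)
  n <- 30; V <- 12
  delta <- matrix(rnorm(n * V, 0.02, 0.01), n, V)
  grp <- rep(c("PD", "HC"), each = n / 2)
  panel <- panel_from_delta(delta, grp)
  tmap <- longitudinal_contrast(panel, covariates = character())
  # textbook pooled two-sample t per vertex
  oracle <- vapply(seq_len(V), function(v) {
    x <- delta[grp == "PD", v]; y <- delta[grp == "HC", v]
    sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
      (length(x) + length(y) - 2)
    (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  }, numeric(1))
  expect_equal(tmap$t, oracle, tolerance = 1e-10)
  expect_equal(attr(tmap, "df"), n - 2)
})

test_that("contrast is zero for identical groups and shift-invariant", {
  delta <- matrix(rep(0.02, 20 * 5), 20, 5)
  panel <- panel_from_delta(delta, rep(c("PD", "HC"), each = 10))
  tmap <- longitudinal_contrast(panel, covariates = character())
  expect_equal(tmap$t, rep(0, 5))

  set.seed(5)
  delta2 <- matrix(rnorm(20 * 5), 20, 5)
  p1 <- panel_from_delta(delta2, rep(c("PD", "HC"), each = 10))
  p2 <- p1; p2$t1 <- p1$t1 + 0.7; p2$t2 <- p1$t2 + 0.7
  expect_equal(longitudinal_contrast(p1, character())$t,
               longitudinal_contrast(p2, character())$t)
})

test_that("site covariate absorbs a constant site offset", {
  set.seed(6)
  n <- 40
  delta <- matrix(rnorm(n * 6, 0.02, 0.01), n, 6)
  site <- rep(1:2, times = n / 2)
  grp <- rep(c("PD", "HC"), each = n / 2)
  p0 <- panel_from_delta(delta, grp, site = site)
  t0 <- longitudinal_contrast(p0, "site")$t
  offset <- delta; offset[site == 2, ] <- offset[site == 2, ] + 0.5
  p1 <- panel_from_delta(offset, grp, site = site)
  expect_equal(longitudinal_contrast(p1, "site")$t, t0, tolerance = 1e-9)
})

test_that("rank-deficient designs are rejected naming the column", {
  delta <- matrix(rnorm(20 * 3), 20, 3)
  panel <- panel_from_delta(delta, rep(c("PD", "HC"), each = 10),
                            age = rep(60, 20))  # constant age column
  expect_error(longitudinal_contrast(panel, "age"), "collinear.*age")
})

test_that("cluster extraction equals an independent components oracle", {
  surf <- chain_surface(30)
  # planted contiguous patch
  t <- rep(0, 30); t[6:15] <- 5
  map <- structure(data.frame(vertex_id = 1:30, t = t, effect = t),
                   class = c("thinning_map", "data.frame"))
  cl <- find_clusters(map, surf, 3)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$nverts, 10)
  expect_equal(sort(attr(cl, "members")[[1]]), 6:15)

  # empty table when nothing is supra-threshold
  expect_equal(nrow(find_clusters(map, surf, 10)), 0)

  # arbitrary field vs igraph connected components
  skip_if_not_installed("igraph")
  set.seed(8)
  cfg <- small_config(seed = 8)
  d <- gen_dataset(cfg)
  tmap <- longitudinal_contrast(d$panel)
  thr <- stats::quantile(tmap$t, 0.8)
  cl2 <- find_clusters(tmap, d$surface, thr)
  keep <- tmap$vertex_id[tmap$t >= thr]
  g <- igraph::graph_from_data_frame(
    d$surface$edges[d$surface$edges$v1 %in% keep &
                      d$surface$edges$v2 %in% keep, ],
    directed = FALSE,
    vertices = data.frame(name = keep))
  comp <- igraph::components(g)
  oracle_sizes <- sort(as.vector(comp$csize), decreasing = TRUE)
  expect_equal(sort(cl2$nverts, decreasing = TRUE), oracle_sizes)
  oracle_members <- split(as.integer(names(comp$membership)),
                          comp$membership)
  got <- lapply(attr(cl2, "members"), sort)
  expect_setequal(vapply(got, paste, collapse = ",", ""),
                  vapply(lapply(oracle_members, sort), paste,
                         collapse = ",", ""))
})

test_that("permutation cluster correction behaves at the extremes", {
  set.seed(9)
  n <- 24; V <- 30
  delta <- matrix(rnorm(n * V, 0, 0.01), n, V)
  grp <- rep(c("PD", "HC"), each = n / 2)
  delta[grp == "PD", 10:20] <- delta[grp == "PD", 10:20] + 0.2  # huge effect
  panel <- panel_from_delta(delta, grp)
  surf <- chain_surface(V)
  cl <- cluster_correction_permutation(panel, surf,
                                       covariates = character(),
                                       t_threshold = 3, n_perm = 99,
                                       seed = 1)
  expect_gte(nrow(cl), 1)
  # p values equal the add-one count against the stored null maxima
  null_max <- attr(cl, "null_max")
  expect_length(null_max, 99)
  expect_equal(cl$p, vapply(cl$nverts, function(sz)
    (1 + sum(null_max >= sz)) / 100, numeric(1)))
  # a planted effect of this size is familywise significant
  expect_lt(min(cl$p), 0.05)
  expect_gte(min(cl$p), 1 / (99 + 1))
  # p is monotone non-increasing in cluster size for the same null
  if (nrow(cl) > 1)
    expect_true(all(diff(cl$p[order(cl$nverts)]) <= 0))

  expect_error(cluster_correction_permutation(panel, surf, character(),
                                              3, n_perm = 0), "n_perm")
})

test_that("single-group site strata are excluded with a warning", {
  set.seed(10)
  delta <- matrix(rnorm(20 * 10, 0.02, 0.01), 20, 10)
  grp <- rep(c("PD", "HC"), each = 10)
  site <- c(rep(1, 10), rep(2, 10))  # site 1 all PD, site 2 all HC
  panel <- panel_from_delta(delta, grp, site = site)
  expect_warning(
    cluster_correction_permutation(panel, chain_surface(10),
                                   covariates = character(),
                                   t_threshold = 3, n_perm = 19, seed = 1),
    "single group")
})

test_that("whole-brain change matches the paired-t oracle", {
  set.seed(11)
  d <- gen_dataset(small_config(seed = 11))
  wb <- whole_brain_change(d$panel, "PD")
  idx <- d$panel$subjects$group == "PD"
  m1 <- rowMeans(d$panel$t1[idx, ]); m2 <- rowMeans(d$panel$t2[idx, ])
  oracle <- t.test(m1, m2, paired = TRUE)
  expect_equal(wb$t, unname(oracle$statistic), tolerance = 1e-10)
  expect_equal(wb$p, oracle$p.value, tolerance = 1e-10)
  expect_equal(wb$mean_t1, mean(m1))

  # no change at all: t = 0; constant nonzero change: degenerate flag
  pe <- d$panel; pe$t2 <- pe$t1
  expect_equal(whole_brain_change(pe, "PD")$t, 0)
  pc <- d$panel; pc$t2 <- pc$t1 - 0.02
  res <- whole_brain_change(pc, "PD")
  expect_true(res$degenerate)
  expect_true(is.na(res$t))
  ps <- d$panel; ps$subjects$group[ps$subjects$group == "HC"] <- "XX"
  expect_error(whole_brain_change(ps, "HC"), "fewer than 2")
})

test_that("network summaries equal group means with calibrated permutation p", {
  set.seed(12)
  d <- gen_dataset(small_config(seed = 12))
  tmap <- longitudinal_contrast(d$panel)
  ns <- network_summary(tmap, d$atlas, d$map, n_perm = 199, n_boot = 199,
                        seed = 2)
  # mu equals an independent group-by mean oracle
  pid <- d$map$parcel_id[match(tmap$vertex_id, d$map$vertex_id)]
  lab <- d$atlas$network[match(pid, d$atlas$parcel_id)]
  for (nw in unique(stats::na.omit(lab))) {
    expect_equal(ns$mu[ns$network == nw], mean(tmap$t[lab %in% nw]),
                 tolerance = 1e-12)
  }
  expect_true(all(ns$ci_low <= ns$mu & ns$mu <= ns$ci_high, na.rm = TRUE))

  # uniform field: every network's permutation p is ~1 (exchangeable ties)
  tmap_c <- tmap; tmap_c$t <- rep(1, nrow(tmap_c))
  ns_c <- network_summary(tmap_c, d$atlas, d$map, n_perm = 49, n_boot = 9,
                          seed = 3)
  expect_true(all(ns_c$p_perm == 1, na.rm = TRUE))

  # one network carrying all signal gets the minimal p
  lab_first <- d$atlas$network[d$atlas$tissue == "cortical"][1]
  tmap_s <- tmap
  tmap_s$t <- ifelse(lab == lab_first & !is.na(lab), 10, rnorm(length(lab)))
  ns_s <- network_summary(tmap_s, d$atlas, d$map, n_perm = 199, n_boot = 9,
                          seed = 4)
  expect_equal(ns_s$p_perm[ns_s$network == lab_first], 1 / 200)
})
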