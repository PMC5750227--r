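test_that("disease exposure is the connectivity-weighted atrophy sum", {
  # hand-arithmetic instance: Conn rows [[1,0],[0.5,0.5]], atrophy (2,0)
  atlas <- tiny_atlas(nc = 1, ns = 1)  # cortical 1,2 (L,R); subcortical 3,4
  W <- matrix(0, 4, 4)
  W[1, 3] <- 1; W[1, 4] <- 0
  W[2, 3] <- 0.5; W[2, 4] <- 0.5
  W <- W + t(W); diag(W) <- 0
  conn <- connectome(W, "structural", atlas$parcel_id)
  atr <- uniform_atrophy(atlas)
  atr$z[atr$parcel_id == 3] <- 2
  atr$z[atr$parcel_id == 4] <- 0
  ex <- disease_exposure(conn, atr, reservoir = 3:4, atlas = atlas)
  expect_equal(ex$exposure, c(2, 1))

  # all-zero atrophy gives all-zero exposure
  atr0 <- atr; atr0$z[] <- 0
  ex0 <- disease_exposure(conn, atr0, reservoir = 3:4, atlas = atlas)
  expect_equal(ex0$exposure, c(0, 0))

  expect_error(disease_exposure(distance_connectome(atlas), atr,
                                atlas = atlas), "distance")
})

test_that("exposure matches the double-loop oracle and is linear in atrophy", {
  set.seed(13)
  cfg <- synth_config(n_cortical = 30, n_subcortical = 15,
                      vertices_per_parcel = 1, seed = 13)
  atlas <- gen_atlas(cfg)$atlas
  conn <- gen_connectomes(atlas, cfg)$functional
  a1 <- gen_atrophy(atlas, cfg)
  ex <- disease_exposure(conn, a1, atlas = atlas)
  # explicit double loop over (cortical i, reservoir j)
  res <- a1$parcel_id[a1$z != 0]
  ctx <- atlas$parcel_id[atlas$tissue == "cortical"]
  oracle <- numeric(length(ctx))
  for (ii in seq_along(ctx)) for (j in res)
    oracle[ii] <- oracle[ii] +
      conn$weights[match(ctx[ii], conn$parcel_ids),
                   match(j, conn$parcel_ids)] *
      a1$z[a1$parcel_id == j]
  expect_equal(ex$exposure, oracle, tolerance = 1e-12)

  # linearity: exposure(a1 + a2) = exposure(a1) + exposure(a2), and scaling
  a2 <- a1; a2$z[a2$z != 0] <- runif(sum(a2$z != 0), 0.5, 2)
  asum <- a1; asum$z <- a1$z + a2$z
  expect_equal(disease_exposure(conn, asum, atlas = atlas)$exposure,
               ex$exposure + disease_exposure(conn, a2,
                                              atlas = atlas)$exposure,
               tolerance = 1e-12)
  ascal <- a1; ascal$z <- 3 * a1$z
  expect_equal(disease_exposure(conn, ascal, atlas = atlas)$exposure,
               3 * ex$exposure, tolerance = 1e-12)
})

test_that("association recovers perfect monotone relations", {
  x <- as_exposure(sort(runif(20)))
  res <- associate(x, seq_len(20) + 0.0, n_perm = 99, n_boot = 99, seed = 1)
  expect_equal(res$rho, 1)
  expect_equal(res$p_perm, 1 / 100)
  res_neg <- associate(x, -seq_len(20) + 0.0, n_perm = 99, n_boot = 99,
                       seed = 1)
  expect_equal(res_neg$rho, -1)
  expect_error(associate(x, rep(1, 20), n_perm = 9, n_boot = 9),
               "zero-variance")
})

test_that("rho equals rank-then-Pearson and is monotone-invariant", {
  set.seed(14)
  for (k in 1:10) {
    x <- as_exposure(rnorm(20))
    y <- rnorm(20)
    res <- associate(x, y, n_perm = 9, n_boot = 9, seed = k)
    expect_equal(res$rho, cor(rank(x$exposure), rank(y)),
                 tolerance = 1e-12)
    # strictly monotone transforms leave rho unchanged
    res2 <- associate(as_exposure(exp(x$exposure)), y^3 + 2 * y,
                      n_perm = 9, n_boot = 9, seed = k)
    expect_equal(res2$rho, res$rho, tolerance = 1e-12)
  }
})

test_that("scope restricts cortical parcels and keeps a bilateral reservoir", {
  set.seed(15)
  cfg <- small_config(seed = 15)
  d <- gen_dataset(cfg)
  ex <- disease_exposure(d$connectomes$functional, d$atrophy,
                         atlas = d$atlas)
  thin <- rnorm(nrow(ex))
  names(thin) <- ex$parcel_id
  left <- associate(ex, thin, scope = "left", n_perm = 19, n_boot = 19)
  expect_equal(left$n, sum(ex$hemisphere == "L"))
  # the reservoir spans both hemispheres even for hemispheric scope
  res_h <- d$atlas$hemisphere[match(attr(ex, "reservoir"),
                                    d$atlas$parcel_id)]
  expect_setequal(unique(res_h), c("L", "R"))
  # scope rho equals direct Spearman on that hemisphere's parcels
  keep <- ex$hemisphere == "L"
  expect_equal(left$rho, cor(ex$exposure[keep], thin[keep],
                             method = "spearman"), tolerance = 1e-12)
})

test_that("distance comparator is antitone by construction", {
  atlas <- tiny_atlas(nc = 5, ns = 1)
  atr <- uniform_atrophy(atlas)
  dist <- distance_connectome(atlas)
  dex <- distance_exposure(dist, atr, atlas = atlas)
  thin <- -dex$exposure  # thinning strictly decreasing in distance-exposure
  names(thin) <- dex$parcel_id
  res <- associate_distance(dist, atr, thin, n_perm = 19, n_boot = 19,
                            atlas = atlas)
  expect_equal(res$rho, -1)
  # all-zero atrophy means constant exposure: zero-variance error
  atr0 <- atr; atr0$z[] <- 0
  expect_error(associate_distance(dist, atr0, thin, n_perm = 9, n_boot = 9,
                                  atlas = atlas),
               "zero-variance")
})

test_that("multivariate fit recovers exact constructions", {
  set.seed(16)
  ef <- as_exposure(runif(60))
  es <- as_exposure(runif(60), modality = "structural")
  thin <- 2 * ef$exposure
  fit <- suppressWarnings(multivariate_fit(thin, ef, es))
  b <- fit$coefficients$beta[match(c("functional", "structural"),
                                   fit$coefficients$term)]
  expect_equal(b[1], 2, tolerance = 1e-10)
  expect_equal(b[2], 0, tolerance = 1e-10)
  expect_equal(fit$df, 60 - 3)

  # coefficients match the normal-equations oracle on a noisy instance
  y <- 1 + 0.5 * ef$exposure - 0.3 * es$exposure + rnorm(60, 0, 0.1)
  fit2 <- multivariate_fit(y, ef, es)
  X <- cbind(1, ef$exposure, es$exposure)
  beta_oracle <- solve(crossprod(X), crossprod(X, y))
  expect_equal(fit2$coefficients$beta, as.vector(beta_oracle),
               tolerance = 1e-10)

  # collinear predictors are refused
  es_c <- ef; attr(es_c, "modality") <- "structural"
  expect_error(multivariate_fit(y, ef, es_c), "collinear")
})

test_that("reservoir subsetting zeroes atrophy outside the subset", {
  set.seed(17)
  cfg <- synth_config(n_cortical = 30, n_subcortical = 15,
                      vertices_per_parcel = 1, seed = 17)
  atlas <- gen_atlas(cfg)$atlas
  atr <- gen_atrophy(atlas, cfg)
  expect_identical(subset_reservoir(atr, "all"), atr)
  bg <- subset_reservoir(atr, "basal_ganglia")
  bg_ids <- atlas$parcel_id[!is.na(atlas$structure) &
                              atlas$structure %in% BASAL_GANGLIA]
  expect_length(bg_ids, 8)  # caudate, putamen, pallidum, accumbens x2
  expect_setequal(bg$parcel_id[bg$z != 0], bg_ids)

  # basal-ganglia exposure equals the manual sum over the 8 parcels
  conn <- gen_connectomes(atlas, cfg)$functional
  ex_bg <- disease_exposure(conn, bg, atlas = atlas)
  ctx <- atlas$parcel_id[atlas$tissue == "cortical"]
  manual <- vapply(ctx, function(i) {
    s <- 0
    for (j in bg_ids)
      s <- s + conn$weights[match(i, conn$parcel_ids),
                            match(j, conn$parcel_ids)] *
        atr$z[atr$parcel_id == j]
    s
  }, numeric(1))
  expect_equal(ex_bg$exposure, manual, tolerance = 1e-12)

  # excluding every nonzero parcel is an error
  expect_error(subset_reservoir(atr, subset = ctx[1]), "no parcel")
})

test_that("hemispheric structural associations survive when interhemispheric
           weights are attenuated but whole-brain mixing degrades", {
  # thinning driven by the functional connectome (bilateral, symmetric
  # reservoir); structural exposure measured with near-zero interhemispheric
  # weights plus a hemisphere-dependent sensitivity artifact (right-
  # hemisphere weights scaled up), emulating tractography's hemisphere-scale
  # biases. Spearman is scale-invariant within each hemisphere, so the
  # per-hemisphere associations are untouched, but pooled ranks are
  # scrambled because the attenuated matrix carries no cross-hemisphere
  # information to compensate the scale difference.
  res <- vapply(1:15, function(s) {
    cfg <- small_config(seed = s, interhemi_attenuation = 0.01, b = 0.05,
                        n_pd = 40, n_hc = 40)
    d <- gen_dataset(cfg)
    tmap <- longitudinal_contrast(d$panel)
    pt <- aggregate_to_parcels(d$map, tmap$t)
    sc <- ifelse(d$atlas$hemisphere == "R", 2, 1)
    Ws <- d$connectomes$structural$weights * outer(sc, sc)
    es <- disease_exposure(connectome(Ws, "structural", d$atlas$parcel_id),
                           d$atrophy, atlas = d$atlas)
    rho <- function(scp) associate(es, pt, scope = scp, n_perm = 1,
                                   n_boot = 1, seed = 1)$rho
    c(hemi = mean(c(rho("left"), rho("right"))), whole = rho("whole"))
  }, numeric(2))
  # per-hemisphere associations remain clearly positive
  expect_gt(mean(res["hemi", ]), 0.3)
  # whole-brain association is degraded relative to the hemispheric ones
  expect_gt(mean(res["hemi", ] - res["whole", ]), 0)
  expect_gt(mean(res["hemi", ] > res["whole", ]), 0.7)
})
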