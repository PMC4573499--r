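test_that("quantile normalization maps ranks onto normal quantiles", {
  # n = 2: quantiles at (0.25, 0.75)
  out <- normalize_editing_levels(c(0.1, 0.9))
  expect_equal(out, stats::qnorm(c(0.25, 0.75)), tolerance = 1e-10)
  expect_equal(out[2], 0.6744898, tolerance = 1e-6)

  set.seed(51)
  x <- runif(101)
  z <- normalize_editing_levels(x)
  expect_lt(abs(mean(z)), 1e-10)          # symmetric grid: exact zero mean
  expect_lt(abs(sd(z) - 1), 0.05)
  expect_equal(order(z), order(x))        # monotone in the input
  # ties share the average rank
  z2 <- normalize_editing_levels(c(0.2, 0.2, 0.8))
  expect_equal(z2[1], z2[2])
  # missing propagates, zero variance warns
  expect_true(is.na(normalize_editing_levels(c(0.1, NA, 0.9))[2]))
  expect_warning(normalize_editing_levels(rep(0.3, 5)), "variance")
})

test_that("association scan matches the closed-form and lm oracles", {
  # worked example with df = 4
  g <- c(0, 0, 0, 1, 1, 1)
  y <- c(-0.2, 0.1, -0.1, 0.9, 1.1, 1.0)
  calls <- matrix(as.integer(g), nrow = 1, ncol = 6)
  gm <- gm_from_calls(calls)
  res <- cis_association_scan(stats::setNames(y, gm$strains), gm,
                              gene = "g001", min_minor = 3, min_obs = 6)
  fit <- stats::lm(y ~ g)
  sm <- summary(fit)$coefficients
  expect_equal(res$beta, unname(sm["g", "Estimate"]), tolerance = 1e-12)
  expect_equal(res$p, unname(sm["g", "Pr(>|t|)"]), tolerance = 1e-12)
  expect_equal(res$n, 6L)

  # random instances, including missing data
  set.seed(52)
  for (k in 1:200) {
    n <- sample(10:60, 1)
    g <- stats::rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(g)) == 1) next
    y <- stats::rnorm(n) + g * stats::rnorm(1)
    if (k %% 3 == 0) g[sample(n, 2)] <- NA
    calls <- matrix(as.integer(g), nrow = 1)
    gm <- gm_from_calls(calls)
    res <- cis_association_scan(stats::setNames(y, gm$strains), gm,
                                gene = "g001", min_minor = 1, min_obs = 8)
    if (!nrow(res)) next
    sm <- summary(stats::lm(y ~ g))$coefficients
    expect_equal(res$p, unname(sm["g", "Pr(>|t|)"]), tolerance = 1e-10)
    expect_equal(res$beta, unname(sm["g", "Estimate"]), tolerance = 1e-10)
  }
})

test_that("null p-values are uniform", {
  set.seed(53)
  ps <- numeric(0)
  for (k in 1:1000) {
    g <- stats::rbinom(40, 1, 0.4)
    if (min(sum(g), 40 - sum(g)) < 4) next
    y <- stats::rnorm(40)
    calls <- matrix(as.integer(g), nrow = 1)
    gm <- gm_from_calls(calls)
    res <- cis_association_scan(stats::setNames(y, gm$strains), gm,
                                gene = "g001")
    ps <- c(ps, res$p)
  }
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("permutation empirical p uses the add-one rank estimator", {
  set.seed(54)
  n <- 60
  g <- stats::rbinom(n, 1, 0.5)
  y <- stats::setNames(g * 3 + stats::rnorm(n, 0, 0.1), sprintf("st%03d", 1:n))
  y <- normalize_editing_levels(y)
  gm <- gm_from_calls(matrix(as.integer(g), nrow = 1))
  perm <- permutation_empirical_p(y, gm, gene = "g001", n_perm = 1000,
                                  seed = 7, site_id = "sX")
  # overwhelming effect: observed min-p beats every permutation
  expect_equal(perm$p_empirical, 1 / 1001)
  expect_equal(perm$best_variant, "v01")
  # reproducible for the same (seed, site)
  perm2 <- permutation_empirical_p(y, gm, gene = "g001", n_perm = 1000,
                                   seed = 7, site_id = "sX")
  expect_identical(perm$null_min_p, perm2$null_min_p)
  perm3 <- permutation_empirical_p(y, gm, gene = "g001", n_perm = 1000,
                                   seed = 8, site_id = "sX")
  expect_false(identical(perm$null_min_p, perm3$null_min_p))

  # a null phenotype lands mid-distribution
  y0 <- normalize_editing_levels(stats::setNames(stats::rnorm(n),
                                                 names(y)))
  perm0 <- permutation_empirical_p(y0, gm, gene = "g001", n_perm = 1000,
                                   seed = 7, site_id = "sY")
  expect_gt(perm0$p_empirical, 0.01)
})

test_that("q-values reduce to Benjamini-Hochberg when pi0 is 1", {
  expect_equal(qvalue_fdr(c(0.01, 0.02, 0.03, 0.04), pi0 = 1),
               rep(0.04, 4))
  expect_equal(qvalue_fdr(rep(1, 5)), rep(1, 5))
  set.seed(55)
  for (k in 1:20) {
    p <- runif(sample(5:200, 1))
    expect_equal(qvalue_fdr(p, pi0 = 1), stats::p.adjust(p, "BH"),
                 tolerance = 1e-12)
  }
  # uniform nulls: almost nothing passes q < 0.05
  p <- runif(10000)
  expect_lt(sum(qvalue_fdr(p) < 0.05), 5)
  expect_error(qvalue_fdr(c(0.5, 0)), "0, 1")
})

test_that("effect size is half the homozygote mean difference", {
  g <- c(0, 0, 1, 1)
  expect_equal(effect_size(c(0.30, 0.30, 0.40, 0.40), g), 0.05)
  expect_equal(effect_size(c(0.4, 0.4, 0.4, 0.4), g), 0)
  expect_true(is.na(effect_size(c(0.4, 0.4, NA, NA), g)))
  expect_true(is.na(effect_size(c(0.1, 0.2, 0.3, 0.4), c(0, 0, 0, 0))))
})

test_that("secondary scan residualizes exactly and finds a second signal", {
  set.seed(56)
  n <- 100
  g1 <- stats::rbinom(n, 1, 0.5)
  y <- stats::setNames(2 * g1 + stats::rnorm(n, 0, 0.5),
                       sprintf("st%03d", 1:n))
  r <- edscape:::regress_out(y, g1)
  expect_lt(abs(stats::cor(r, g1)), 1e-12)
  # a phenotype exactly linear in the primary leaves no residual signal
  y_exact <- stats::setNames(as.numeric(g1), names(y))
  r0 <- edscape:::regress_out(y_exact, g1)
  expect_lt(max(abs(r0)), 1e-12)

  # two independent planted variants: primary catches one, secondary the other
  found_both <- 0
  for (s in 1:20) {
    set.seed(600 + s)
    g1 <- stats::rbinom(n, 1, 0.4)
    g2 <- stats::rbinom(n, 1, 0.4)
    lv <- pmin(1, pmax(0, 0.4 + 0.2 * g1 + 0.2 * g2 +
                         stats::rnorm(n, 0, 0.05)))
    calls <- rbind(as.integer(g1), as.integer(g2),
                   matrix(stats::rbinom(3 * n, 1, 0.3), nrow = 3))
    gm <- gm_from_calls(calls)
    em <- em_from_levels(matrix(lv, nrow = 1,
                                dimnames = list("s01", gm$strains)))
    fit <- edqtl_map(em, gm, n_perm = 200, seed = s, secondary = TRUE)
    tab <- fit$table
    prim <- tab$variant_id[tab$rank == "primary"]
    sec <- tab$variant_id[tab$rank == "secondary" & tab$p_empirical < 0.05]
    if (length(prim) && length(sec) &&
        setequal(c(prim, sec), c("v01", "v02"))) found_both <- found_both + 1
  }
  expect_gte(found_both, 18)
})

test_that("edQTL mapping recovers planted effects with correct metadata", {
  cfg <- sim_config(n_strains = 80, n_sites = 8, effect_sizes = c(0.12, 0),
                    seed = 61)
  sim <- simulate_dataset(cfg)
  fit <- edqtl_map(sim$levels, sim$genotypes, n_perm = 300, seed = 2)
  tab <- fit$table[fit$table$rank == "primary", ]
  truth <- sim$truth$qtl_assignments
  called <- tab$site_id[tab$sig_fdr10]
  expect_setequal(intersect(called, truth$site_id), truth$site_id)
  hit <- merge(tab, truth, by = "site_id")
  expect_true(all(hit$variant_id.x == hit$variant_id.y))
  expect_true(all(abs(hit$effect_size - abs(hit$effect)) < 0.05))
  # distances signed by transcript orientation on the + strand
  vp <- sim$genotypes$variants$pos[match(tab$variant_id,
                                         sim$genotypes$variants$variant_id)]
  sp <- sim$sites$pos[match(tab$site_id, sim$sites$site_id)]
  expect_equal(tab$distance, vp - sp)
  # S3 surface
  expect_output(print(fit), "edQTL scan")
  expect_silent(cf <- coef(fit))
  expect_equal(length(cf), nrow(fit$table))
})

test_that("edQTLs propagate to co-regulated sites in the same gene", {
  set.seed(57)
  n <- 80
  g <- stats::rbinom(n, 1, 0.5)
  lv1 <- pmin(1, pmax(0, 0.3 + 0.2 * g + stats::rnorm(n, 0, 0.05)))
  lv2 <- pmin(1, pmax(0, 0.5 + 0.2 * g + stats::rnorm(n, 0, 0.05)))
  lv3 <- pmin(1, pmax(0, 0.5 + stats::rnorm(n, 0, 0.05)))
  lev <- rbind(s1 = lv1, s2 = lv2, s3 = lv3)
  em <- em_from_levels(lev, pos = c(1000L, 1500L, 40000L))
  gm <- gm_from_calls(matrix(as.integer(g), nrow = 1), pos = 1200L)
  fit <- edqtl_map(em, gm, n_perm = 200, seed = 3, secondary = FALSE)
  shared <- shared_site_association(fit, em, gm)
  drv <- shared[shared$site_id == "s01" & shared$other_site == "s02", ]
  expect_lt(drv$p, 1e-4)
  expect_equal(drv$distance_bin, "<1 kb")
  far <- shared[shared$site_id == "s01" & shared$other_site == "s03", ]
  expect_equal(far$distance_bin, "10-50 kb")

  # sites in another gene are not tested
  em2 <- em
  em2$sites$gene_id <- c("g001", "g001", "gZZZ")
  shared2 <- shared_site_association(fit, em2, gm)
  expect_false("s03" %in% shared2$other_site)
})
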