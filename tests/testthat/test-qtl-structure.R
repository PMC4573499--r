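test_that("variants are classified against the predicted duplex", {
  pred <- mock_prediction("gX", site_pos = 150L, ecs_interval = c(200L, 225L),
                          edit_interval = c(140L, 165L))
  expect_equal(classify_variant_location(list(chrom = "gX", pos = 210L), pred),
               "within_duplex")
  expect_equal(classify_variant_location(list(chrom = "gX", pos = 150L), pred),
               "within_duplex")
  expect_equal(classify_variant_location(list(chrom = "gX", pos = 3000L), pred),
               "distal")
  expect_equal(classify_variant_location(list(chrom = "gX", pos = 210L), NULL),
               "unresolved")
})

test_that("LD r-squared equals the squared Pearson correlation", {
  expect_equal(ld_r2(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(ld_r2(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  expect_true(is.na(ld_r2(c(1, 1, 1, 1), c(0, 1, 0, 1))))
  set.seed(91)
  for (k in 1:200) {
    n <- sample(10:60, 1)
    a <- stats::rbinom(n, 1, 0.5); b <- stats::rbinom(n, 1, 0.5)
    if (k %% 4 == 0) { a[1:2] <- NA; b[3] <- NA }
    ok <- !is.na(a) & !is.na(b)
    if (stats::var(a[ok]) == 0 || stats::var(b[ok]) == 0) next
    # brute-force covariance formula
    am <- a[ok] - mean(a[ok]); bm <- b[ok] - mean(b[ok])
    want <- sum(am * bm)^2 / (sum(am^2) * sum(bm^2))
    expect_equal(ld_r2(a, b), want, tolerance = 1e-12)
  }
})

test_that("control selection excludes edQTLs and linked variants", {
  set.seed(92)
  n <- 60
  g_qtl <- stats::rbinom(n, 1, 0.5)
  g_linked <- g_qtl                         # r2 = 1
  g_free <- stats::rbinom(n, 1, 0.5)        # independent
  while (ld_r2(g_free, g_qtl) > 0.05) g_free <- stats::rbinom(n, 1, 0.5)
  calls <- rbind(g_qtl, g_linked, g_free, stats::rbinom(n, 1, 0.5))
  gm <- gm_from_calls(matrix(as.integer(calls), nrow = 4),
                      pos = c(150L, 210L, 212L, 3000L))
  pred <- mock_prediction("g001", site_pos = 150L,
                          ecs_interval = c(200L, 225L),
                          edit_interval = c(140L, 165L))
  ctrl <- select_control_variants(gm, edqtl_variants = "v01",
                                  predictions = list(s1 = pred),
                                  mode = "duplex")
  expect_equal(ctrl, "v03") # in-duplex, unlinked, not an edQTL
  # the r2 boundary is inclusive
  r2 <- ld_r2(gm$calls["v03", ], gm$calls["v01", ])
  expect_equal(select_control_variants(gm, "v01", list(s1 = pred),
                                       mode = "duplex", max_r2 = r2), "v03")
  expect_warning(
    none <- select_control_variants(gm, "v01", list(s1 = pred),
                                    mode = "duplex",
                                    max_r2 = max(0, r2 - 1e-6)),
    "no control")
  expect_equal(length(none), 0)

  # distal-matched mode excludes in-duplex variants and samples with seed
  ctrl_d <- select_control_variants(gm, "v01", list(s1 = pred),
                                    mode = "distal-matched",
                                    distal_genes = "g001")
  expect_true("v04" %in% ctrl_d)
  expect_false(any(c("v02", "v03") %in% ctrl_d))
})

test_that("allelic comparison reports stability loss of the disrupted allele", {
  hits <- 0; paired_high <- 0
  for (s in 1:20) {
    loc <- generate_duplex_locus(list(stem_len = 25, ecs_offset = 40),
                                 seed = 400 + s)
    site <- list(chrom = "gX", pos = loc$site_pos, strand = "+",
                 site_id = "sX")
    pred <- predict_proximal_ecs(site, c(gX = loc$sequence))
    if (is.null(pred)) next
    # pick a paired edit-side stem position away from the site and break it
    cand <- setdiff(seq(loc$stem5[1], loc$stem5[2]), loc$site_pos)
    set.seed(s)
    vpos <- sample(cand, 1)
    ref <- substring(loc$sequence, vpos, vpos)
    partner_base <- substring(loc$sequence, loc$ecs[1] +
                                (loc$ecs[2] - loc$ecs[1]) -
                                (vpos - loc$stem5[1]), loc$ecs[1] +
                                (loc$ecs[2] - loc$ecs[1]) -
                                (vpos - loc$stem5[1]))
    alt <- setdiff(c("A", "C", "G", "T"), c(ref, partner_base))[1]
    variant <- data.frame(variant_id = "vD", chrom = "gX", pos = vpos,
                          ref = ref, alt = alt, stringsAsFactors = FALSE)
    # intact (reference) homozygotes edit more
    n <- 40
    g <- stats::setNames(rep(c(0L, 1L), each = n / 2),
                         sprintf("st%03d", 1:n))
    lv <- stats::setNames(c(rep(0.6, n / 2), rep(0.4, n / 2)), names(g))
    cmp <- compare_alleles(variant, pred, c(gX = loc$sequence), lv, g)
    expect_equal(cmp$allele_high, ref)
    expect_equal(cmp$effect_size, 0.1)
    expect_true(cmp$gated)
    if (cmp$delta_g < 0) hits <- hits + 1
    if (cmp$is_base_paired) paired_high <- paired_high + 1
  }
  expect_gte(hits, 18)      # the higher-editing (intact) allele is more stable
  expect_gte(paired_high, 18)
})

test_that("allelic comparison degenerate and gating cases", {
  loc <- generate_duplex_locus(list(stem_len = 25, ecs_offset = 40),
                               seed = 421)
  site <- list(chrom = "gX", pos = loc$site_pos, strand = "+",
               site_id = "sX")
  pred <- predict_proximal_ecs(site, c(gX = loc$sequence))
  vpos <- loc$stem5[1] + 3L
  ref <- substring(loc$sequence, vpos, vpos)
  variant <- data.frame(variant_id = "vE", chrom = "gX", pos = vpos,
                        ref = ref, alt = ref, stringsAsFactors = FALSE)
  n <- 20
  g <- stats::setNames(rep(c(0L, 1L), each = n / 2), sprintf("st%03d", 1:n))
  lv <- stats::setNames(c(rep(0.52, n / 2), rep(0.48, n / 2)), names(g))
  cmp <- compare_alleles(variant, pred, c(gX = loc$sequence), lv, g)
  expect_equal(cmp$delta_g, 0)           # identical alleles
  expect_equal(cmp$effect_size, 0.02)
  expect_false(cmp$gated)                # below the 0.025 gate
  # distal variants are refused
  vd <- data.frame(variant_id = "vF", chrom = "gX", pos = 5L,
                   ref = "A", alt = "G", stringsAsFactors = FALSE)
  expect_error(compare_alleles(vd, pred, c(gX = loc$sequence), lv, g),
               "not within")
})

test_that("signed stem positions follow the 3'-positive convention", {
  # perfect 21-pair hairpin with the site at stem centre
  stem_len <- 21L
  loc <- generate_duplex_locus(list(stem_len = stem_len, ecs_offset = 40),
                               seed = 431)
  site <- list(chrom = "gX", pos = loc$site_pos, strand = "+",
               site_id = "sX")
  pred <- predict_proximal_ecs(site, c(gX = loc$sequence), min_pairs = 15)
  expect_false(is.null(pred))
  expect_equal(signed_position(list(chrom = "gX", pos = loc$site_pos), pred),
               0)
  expect_equal(signed_position(list(chrom = "gX", pos = loc$site_pos + 7L),
                               pred), 7)
  expect_equal(signed_position(list(chrom = "gX", pos = loc$site_pos - 3L),
                               pred), -3)
  # an ECS position inherits the sign of its paired edit-side position:
  # the base paired to edit-side position (site - 5)
  ecs_pos <- fold_mfe(loc$sequence)$pairs[loc$site_pos - 5L]
  expect_equal(signed_position(list(chrom = "gX", pos = ecs_pos), pred), -5)
})

test_that("Fisher pairing test matches hypergeometric enumeration", {
  tab_cases <- list(rbind(c(3, 1), c(1, 3)), rbind(c(9, 1), c(3, 7)),
                    rbind(c(5, 5), c(5, 5)), rbind(c(0, 4), c(4, 0)),
                    rbind(c(2, 8), c(6, 4)))
  for (tab in tab_cases) {
    res <- pairing_enrichment_test(rep(c(TRUE, FALSE), tab[1, ]),
                                   rep(c(TRUE, FALSE), tab[2, ]))
    expect_equal(res$p, orc_fisher_p(tab), tolerance = 1e-12)
  }
  sym <- pairing_enrichment_test(rep(c(TRUE, FALSE), c(5, 5)),
                                 rep(c(TRUE, FALSE), c(5, 5)))
  expect_equal(sym$p, 1)
  # planted pairing difference is detected
  set.seed(93)
  sig <- 0
  for (k in 1:40) {
    q <- stats::runif(30) < 0.9
    ctl <- stats::runif(100) < 0.3
    if (pairing_enrichment_test(q, ctl)$p < 0.01) sig <- sig + 1
  }
  expect_gte(sig, 38)
})

test_that("Mann-Whitney delta-G test matches exact enumeration", {
  # closed case: complete separation at n = 3 vs 3
  res <- delta_g_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p, 0.05)
  expect_equal(unname(res$U), 0)
  expect_equal(res$p, orc_mw_p_less(c(1, 2, 3), c(4, 5, 6)))
  # identical samples: no evidence of a shift
  expect_gte(delta_g_test(c(1, 2, 3), c(1, 2, 3))$p, 0.5)
  expect_equal(delta_g_test(c(2, 2), c(2, 2))$p, 1)
  # random small samples without ties: exact equality
  set.seed(94)
  for (k in 1:25) {
    nx <- sample(3:10, 1); ny <- sample(3:10, 1)
    x <- stats::rnorm(nx); y <- stats::rnorm(ny)
    expect_equal(delta_g_test(x, y)$p, orc_mw_p_less(x, y),
                 tolerance = 1e-12)
  }
  # tied data falls back to the corrected normal approximation
  x <- c(1, 1, 2, 3, 3, 4, 5, 5, 6, 7)
  y <- c(3, 3, 4, 5, 6, 6, 7, 8, 8, 9)
  approx_p <- delta_g_test(x, y)$p
  exact_p <- orc_mw_p_less(x, y)
  expect_lt(abs(approx_p - exact_p) / exact_p, 0.1)
})

test_that("secondary stems are found around structured variants only", {
  found <- 0
  for (s in 1:10) {
    loc <- generate_duplex_locus(list(stem_len = 24, ecs_offset = 40),
                                 seed = 500 + s)
    vpos <- loc$stem5[1] + 5L
    variant <- data.frame(variant_id = "vS", chrom = "gX", pos = vpos,
                          stringsAsFactors = FALSE)
    stems <- find_distal_stems(variant, c(gX = loc$sequence),
                               site_pos = 9999L)
    if (length(stems) == 1 && stems[[1]]$stem$n_pairs >= 24) found <- found + 1
  }
  expect_gte(found, 9)

  # 19-pair planted stems never qualify
  none19 <- TRUE
  for (s in 1:10) {
    loc <- generate_duplex_locus(list(stem_len = 19, ecs_offset = 40),
                                 seed = 520 + s)
    variant <- data.frame(variant_id = "vS", chrom = "gX",
                          pos = loc$stem5[1] + 5L, stringsAsFactors = FALSE)
    if (length(find_distal_stems(variant, c(gX = loc$sequence))) > 0)
      none19 <- FALSE
  }
  expect_true(none19)

  # unstructured loci rarely contain qualifying stems
  set.seed(95)
  spurious <- 0
  for (s in 1:20) {
    seqs <- rand_dna(500)
    variant <- data.frame(variant_id = "vS", chrom = "gX", pos = 250L,
                          stringsAsFactors = FALSE)
    if (length(find_distal_stems(variant, c(gX = seqs))) > 0)
      spurious <- spurious + 1
  }
  expect_lte(spurious, 2)
})

test_that("editing-site window counts are monotone in window size", {
  variants <- data.frame(variant_id = c("v1", "v2"), chrom = "c1",
                         pos = c(1000L, 5000L), stringsAsFactors = FALSE)
  sites <- data.frame(chrom = "c1", pos = c(950L, 1050L, 1500L, 9000L))
  counts <- editing_site_window_frequency(variants, sites,
                                          windows = c(200L, 1200L, 20000L))
  expect_equal(unname(counts["v1", ]), c(2, 3, 4))
  expect_equal(unname(counts["v2", "w200"]), 0)
  expect_true(all(diff(counts["v1", ]) >= 0))
  expect_error(editing_site_window_frequency(variants, sites, windows = 201L),
               "even")
})
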