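test_that("proximal ECS prediction recovers planted duplexes and rejects short stems", {
  hits <- 0
  for (s in 1:15) {
    loc <- generate_duplex_locus(list(stem_len = 25, ecs_offset = 40),
                                 seed = 100 + s)
    site <- list(chrom = "gX", pos = loc$site_pos, strand = "+",
                 site_id = "sX")
    p <- predict_proximal_ecs(site, c(gX = loc$sequence))
    if (!is.null(p) && p$accepted &&
        all(abs(p$ecs_interval - loc$ecs) <= 2)) hits <- hits + 1
  }
  expect_gte(hits, 14)

  rejected <- 0
  for (s in 1:15) {
    loc <- generate_duplex_locus(list(stem_len = 19, ecs_offset = 40),
                                 seed = 200 + s)
    site <- list(chrom = "gX", pos = loc$site_pos, strand = "+",
                 site_id = "sX")
    if (is.null(predict_proximal_ecs(site, c(gX = loc$sequence))))
      rejected <- rejected + 1
  }
  expect_equal(rejected, 15)
})

test_that("predictions are strand-consistent under reverse complement", {
  loc <- generate_duplex_locus(list(stem_len = 25, ecs_offset = 40),
                               seed = 301)
  n <- nchar(loc$sequence)
  site_f <- list(chrom = "gX", pos = loc$site_pos, strand = "+",
                 site_id = "sX")
  pf <- predict_proximal_ecs(site_f, c(gX = loc$sequence))
  # mirrored genome: same transcript read off the minus strand
  site_r <- list(chrom = "gX", pos = n - loc$site_pos + 1L, strand = "-",
                 site_id = "sX")
  pr <- predict_proximal_ecs(site_r, c(gX = reverse_complement(loc$sequence)))
  expect_false(is.null(pf))
  expect_false(is.null(pr))
  expect_equal(sort(n - pr$ecs_interval + 1L), pf$ecs_interval)
  expect_equal(pr$stem$n_pairs, pf$stem$n_pairs)
  expect_equal(pr$distance, pf$distance)
})

test_that("conservation smoothing is a truncated centered moving average", {
  expect_equal(smooth_conservation(rep(1, 200)), rep(1, 200))
  x <- numeric(201); x[101] <- 1
  sm <- smooth_conservation(x, 51)
  expect_equal(sm[101], 1 / 51)
  expect_equal(sm[75], 0)
  # step track: smoothed crosses 0.5 at the step midpoint
  step <- c(numeric(100), rep(1, 100))
  sms <- smooth_conservation(step, 51)
  expect_lt(sms[100], 0.5)
  expect_gte(sms[101], 0.5)
  # truncated ends still average over the in-range window
  expect_equal(smooth_conservation(rep(0.8, 60), 51)[1], 0.8)
  expect_error(smooth_conservation(rep(1, 10), 50), "odd")
})

test_that("conserved candidate regions honor length, score and distance", {
  track <- numeric(6000)
  track[1001:1019] <- 1     # 19 bases: too short
  track[2001:2040] <- 1     # qualifies
  track[5601:5640] <- 1     # 40 bases but > 2500 bp from the site
  smoothed <- ifelse(track >= 1, 1, 0) # already-binary "smoothed" scores
  cand <- candidate_conserved_regions(smoothed, site_pos = 3000)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$start, 2001)
  expect_equal(cand$end, 2040)

  # smoothed score below 0.90 is rejected
  sm2 <- numeric(6000); sm2[2001:2040] <- 0.89
  expect_equal(nrow(candidate_conserved_regions(sm2, 3000)), 0)

  # intron restriction
  cand2 <- candidate_conserved_regions(
    smoothed, 3000, introns = data.frame(start = 1900, end = 2100))
  expect_equal(nrow(cand2), 1)
  cand3 <- candidate_conserved_regions(
    smoothed, 3000, introns = data.frame(start = 2010, end = 2100))
  expect_equal(nrow(cand3), 0)
})

test_that("distal ECS prediction pairs the site flank to the candidate", {
  rec <- 0
  for (s in 1:8) {
    pl <- plant_distal_locus(stem_len = 25, gap = 1500, seed = s)
    smoothed <- smooth_conservation(pl$track, 51)
    cand <- candidate_conserved_regions(smoothed, pl$site_pos)
    expect_gte(nrow(cand), 1)
    site <- list(chrom = "gX", pos = pl$site_pos, strand = "+",
                 site_id = "sX")
    p <- predict_distal_ecs(site, cand[1, ], c(gX = pl$sequence))
    if (!is.null(p)) {
      expect_equal(p$approach, "distal")
      expect_true(p$ecs_interval[1] >= cand$start[1] - 30 &&
                    p$ecs_interval[2] <= cand$end[1] + 30)
      rec <- rec + 1
    }
  }
  expect_equal(rec, 8)

  # a stem pairing the site flank only to itself is rejected: give the
  # site a local hairpin and an unrelated candidate
  loc <- generate_duplex_locus(list(stem_len = 25, ecs_offset = 40),
                               seed = 77)
  filler <- strrep("A", 2000)
  seqs <- paste0(loc$sequence, filler)
  site <- list(chrom = "gX", pos = loc$site_pos, strand = "+",
               site_id = "sX")
  cand <- data.frame(start = nchar(loc$sequence) + 1000,
                     end = nchar(loc$sequence) + 1040)
  expect_null(predict_distal_ecs(site, cand, c(gX = seqs)))

  # overlapping windows fall back to the proximal approach
  cand_close <- data.frame(start = loc$site_pos + 70, end = loc$site_pos + 120)
  expect_warning(p <- predict_distal_ecs(site, cand_close, c(gX = seqs)),
                 "proximal")
})

test_that("enrichment score is the ECS/flank site-density ratio", {
  # 5 loci; per locus 10 ECS sites and 2 per flank side -> 50 vs 20
  preds <- list(); sites <- list()
  for (i in 1:5) {
    chrom <- paste0("c", i)
    preds[[i]] <- mock_prediction(chrom, site_pos = 10L,
                                  ecs_interval = c(1001L, 1100L),
                                  edit_interval = c(5L, 15L))
    sites[[i]] <- data.frame(
      chrom = chrom,
      pos = c(seq(1005L, 1095L, by = 10L),          # 10 in the ECS
              951L, 961L, 1105L, 1115L),            # 2 per flank
      stringsAsFactors = FALSE)
  }
  all_sites <- do.call(rbind, sites)
  sc <- enrichment_score(preds, all_sites)
  expect_equal(sc$ecs_count, 50)
  expect_equal(sc$flank_count, 20)
  expect_equal(sc$score, 5)

  # no flank sites: score missing, counts still reported
  sc0 <- enrichment_score(preds, all_sites[all_sites$pos > 1000 &
                                             all_sites$pos <= 1100, ])
  expect_true(is.na(sc0$score))
  expect_equal(sc0$ecs_count, 50)

  # the anchoring editing site itself is not tallied
  one <- mock_prediction("c9", site_pos = 1050L,
                         ecs_interval = c(1001L, 1100L))
  sc1 <- enrichment_score(list(one),
                          data.frame(chrom = "c9", pos = c(1050L, 1060L, 951L)))
  expect_equal(sc1$ecs_count, 1)
})

test_that("uniformly placed sites give enrichment near one", {
  set.seed(71)
  preds <- list(); sites <- list()
  for (i in 1:200) {
    chrom <- paste0("u", i)
    preds[[i]] <- mock_prediction(chrom, site_pos = 5L,
                                  ecs_interval = c(501L, 560L),
                                  edit_interval = c(2L, 8L))
    pos <- sample(441:620, 12) # uniform across ECS and both flanks
    sites[[i]] <- data.frame(chrom = chrom, pos = pos,
                             stringsAsFactors = FALSE)
  }
  sc <- enrichment_score(preds, do.call(rbind, sites))
  expect_gt(sc$score, 0.8)
  expect_lt(sc$score, 1.2)
})

test_that("substrate property profiles summarize the predictions", {
  loc <- generate_duplex_locus(list(stem_len = 25, ecs_offset = 40),
                               seed = 81)
  site <- list(chrom = "gX", pos = loc$site_pos, strand = "+",
               site_id = "sX")
  p <- predict_proximal_ecs(site, c(gX = loc$sequence))
  props <- substrate_properties(list(p))
  expect_equal(length(props$distances), 1)
  expect_equal(props$stem_lengths, p$stem$n_pairs)
  expect_equal(names(props$pairing_fraction), as.character(-10:10))
  # a perfect helix through the site is fully paired at position 0
  expect_equal(unname(props$pairing_fraction["0"]), 1)
  expect_true(all(props$pairing_fraction >= 0 & props$pairing_fraction <= 1))
  expect_equal(props$distances, p$distance)
})
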