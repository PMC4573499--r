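# oriented window on a contig: returns the 5'->3' transcript-strand
# sequence plus closures mapping local <-> genomic coordinates
oriented_window <- function(contig_seq, start, end, strand) {
  len <- nchar(contig_seq)
  start <- max(1L, as.integer(start))
  end <- min(len, as.integer(end))
  if (start > end) stop("empty window")
  raw <- substring(contig_seq, start, end)
  if (strand == "-") {
    list(seq = reverse_complement(raw),
         to_genomic = function(i) end - i + 1L,
         to_local = function(g) end - g + 1L,
         start = start, end = end)
  } else {
    list(seq = raw,
         to_genomic = function(i) start + i - 1L,
         to_local = function(g) g - start + 1L,
         start = start, end = end)
  }
}

new_ecs_prediction <- function(site, approach, stem, struct, window,
                               ecs_interval, edit_interval, distance,
                               accepted, cutoffs) {
  structure(list(site = site, approach = approach, stem = stem,
                 structure = struct, window = window,
                 ecs_interval = ecs_interval, edit_interval = edit_interval,
                 distance = distance, accepted = accepted,
                 cutoffs = cutoffs),
            class = "ecs_prediction")
}

#' @export
print.ecs_prediction <- function(x, ...) {
  cat(sprintf(
    "ECS prediction (%s) for %s: %s; stem %d bp, max bulge %d, ECS %s:%d-%d, distance %d bp\n",
    x$approach, x$site$site_id,
    if (x$accepted) "accepted" else "rejected",
    x$stem$n_pairs, x$stem$max_bulge, x$site$chrom,
    x$ecs_interval[1], x$ecs_interval[2], x$distance))
  invisible(x)
}

# distance between the editing site and its (closest) paired base, in nt
site_pair_distance <- function(pairs, anchor, stem) {
  if (pairs[anchor] > 0L) return(abs(pairs[anchor] - anchor))
  side <- if (stem$anchor_side == "left") stem$left_positions else stem$right_positions
  nearest <- side[which.min(abs(side - anchor))]
  abs(pairs[nearest] - anchor)
}

#' Predict a proximal ECS by folding the editing-site window
#'
#' Folds the transcript-strand sequence within `window` nt up- and
#' downstream of the editing site (truncated at contig ends), anchors stem
#' extraction on the editing site, and accepts the prediction when the
#' stem reaches `min_pairs` base pairs with every interruption at most
#' `max_bulge` nt. The ECS is the strand of the stem opposite the editing
#' site, bounded by its first and last paired bases, reported in genomic
#' coordinates.
#'
#' @param site One-row data frame or list with chrom, pos (1-based),
#'   strand, site_id.
#' @param genome Named character vector of contig sequences.
#' @param window Half-window in bp (default 200, i.e. a 401-nt fold).
#' @param min_pairs,max_bulge Stem cutoffs (defaults 20 bp / 8 nt).
#' @param fold_fun Folding engine: a function(sequence) returning an
#'   `rna_structure` (defaults to the built-in [fold_mfe()]; pass a
#'   wrapper to plug in an external folder).
#' @return An `ecs_prediction` with `accepted = TRUE`, or `NULL` when no
#'   qualifying stem contains the site.
#' @export
predict_proximal_ecs <- function(site, genome, window = 200L,
                                 min_pairs = 20L, max_bulge = 8L,
                                 fold_fun = fold_mfe) {
  contig <- genome[[site$chrom]]
  if (is.null(contig)) stop("contig not found: ", site$chrom)
  w <- oriented_window(contig, site$pos - window, site$pos + window,
                       site$strand)
  anchor <- w$to_local(site$pos)
  struct <- fold_fun(w$seq)
  stem <- extract_stem_at(struct, anchor, min_pairs = min_pairs,
                          max_bulge = max_bulge)
  if (is.null(stem)) return(NULL)
  ecs_local <- if (stem$anchor_side == "left") stem$right else stem$left
  edit_local <- if (stem$anchor_side == "left") stem$left else stem$right
  new_ecs_prediction(
    site = site, approach = "proximal", stem = stem, struct = struct,
    window = sort(c(w$to_genomic(1L), w$to_genomic(nchar(w$seq)))),
    ecs_interval = sort(vapply(ecs_local, w$to_genomic, integer(1))),
    edit_interval = sort(vapply(edit_local, w$to_genomic, integer(1))),
    distance = site_pair_distance(struct$pairs, anchor, stem),
    accepted = TRUE,
    cutoffs = c(min_pairs = min_pairs, max_bulge = max_bulge))
}

#' Smooth a conservation track with a centered sliding window
#'
#' Centered moving average; the window is truncated at the track ends.
#'
#' @param track Numeric per-base scores in \[0, 1\].
#' @param window Odd window width in nt (default 51).
#' @return Numeric vector of smoothed scores, same length.
#' @export
smooth_conservation <- function(track, window = 51L) {
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("smoothing window must be odd")
  n <- length(track)
  h <- window %/% 2L
  cs <- cumsum(c(0, track))
  lo <- pmax(1L, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Candidate conserved regions for distal ECS prediction
#'
#' Maximal runs of positions whose smoothed conservation score is at least
#' `min_score`, at least `min_len` bases long, and within `max_dist` bp of
#' the editing site; optionally restricted to introns.
#'
#' @param smoothed Numeric per-base smoothed scores covering the contig.
#' @param site_pos 1-based editing-site position on the same contig.
#' @param max_dist Maximum distance from the site (default 2500 bp).
#' @param min_len Minimum region length (default 20 nt).
#' @param min_score Minimum smoothed score (default 0.90).
#' @param introns Optional data frame (start, end, 1-based inclusive);
#'   when given, regions must fall entirely inside an intron.
#' @return Data frame (start, end, length, mean_score, distance).
#' @export
candidate_conserved_regions <- function(smoothed, site_pos, max_dist = 2500L,
                                        min_len = 20L, min_score = 0.90,
                                        introns = NULL) {
  qual <- !is.na(smoothed) & smoothed >= min_score
  r <- rle(qual)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- data.frame(start = starts[keep], end = ends[keep])
  if (nrow(out)) {
    out$length <- out$end - out$start + 1L
    out$distance <- pmax(0L, pmax(out$start - site_pos, site_pos - out$end))
    out$mean_score <- vapply(seq_len(nrow(out)), function(i)
      mean(smoothed[out$start[i]:out$end[i]]), numeric(1))
    out <- out[out$length >= min_len & out$distance <= max_dist, , drop = FALSE]
    if (!is.null(introns) && nrow(out)) {
      inside <- vapply(seq_len(nrow(out)), function(i)
        any(introns$start <= out$start[i] & introns$end >= out$end[i]),
        logical(1))
      out <- out[inside, , drop = FALSE]
    }
  } else {
    out <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0), distance = integer(0),
                      mean_score = numeric(0))
  }
  rownames(out) <- NULL
  out[, c("start", "end", "length", "mean_score", "distance")]
}

#' Predict a distal ECS against a conserved candidate region
#'
#' Assembles the editing-site flank (site +/- `site_flank` nt), an
#' unpairable adenosine linker, and the buffered candidate region
#' (candidate +/- `buffer` nt), all in transcript orientation; folds the
#' construct; and anchors stem extraction on the editing site. The
#' prediction is accepted only when the stem pairs the editing-site flank
#' to the candidate segment (not flank-to-flank) and meets the usual stem
#' cutoffs. When the site flank and the buffered candidate overlap, the
#' proximal approach is used instead, with a warning.
#'
#' @inheritParams predict_proximal_ecs
#' @param candidate One-row data frame with `start`, `end` (1-based
#'   inclusive genomic interval of the conserved region).
#' @param buffer Buffer around the candidate region (default 30 nt).
#' @param site_flank Half-window around the editing site (default 60 nt).
#' @param linker Adenosine linker length (default 100 nt).
#' @return An accepted `ecs_prediction` (approach "distal"), or `NULL`.
#' @export
predict_distal_ecs <- function(site, candidate, genome, buffer = 30L,
                               site_flank = 60L, linker = 100L,
                               min_pairs = 20L, max_bulge = 8L,
                               fold_fun = NULL) {
  contig <- genome[[site$chrom]]
  if (is.null(contig)) stop("contig not found: ", site$chrom)
  s1 <- site$pos - site_flank; e1 <- site$pos + site_flank
  s2 <- candidate$start - buffer; e2 <- candidate$end + buffer
  if (s2 <= e1 + 1L && e2 >= s1 - 1L) {
    warning("candidate overlaps the editing-site flank; falling back to the proximal approach")
    return(predict_proximal_ecs(site, genome, window = 200L,
                                min_pairs = min_pairs,
                                max_bulge = max_bulge))
  }
  w1 <- oriented_window(contig, s1, e1, site$strand)
  w2 <- oriented_window(contig, s2, e2, site$strand)
  n1 <- nchar(w1$seq)
  construct <- paste0(w1$seq, strrep("A", linker), w2$seq)
  mask <- seq2(n1 + 1L, n1 + linker)
  struct <- if (is.null(fold_fun)) fold_mfe(construct, constraint_mask = mask)
            else fold_fun(construct, mask)
  anchor <- w1$to_local(site$pos)
  stem <- extract_stem_at(struct, anchor, min_pairs = min_pairs,
                          max_bulge = max_bulge)
  if (is.null(stem)) return(NULL)
  cand_range <- c(n1 + linker + 1L, nchar(construct))
  partner_local <- if (stem$anchor_side == "left") stem$right else stem$left
  if (partner_local[1] < cand_range[1] || partner_local[2] > cand_range[2])
    return(NULL) # stem must pair the site flank to the candidate segment
  to_g2 <- function(i) w2$to_genomic(i - (n1 + linker))
  edit_local <- if (stem$anchor_side == "left") stem$left else stem$right
  site_paired <- site_pair_distance(struct$pairs, anchor, stem)
  # genomic distance between the site and its paired candidate base
  partner_pos <- if (struct$pairs[anchor] > 0L) struct$pairs[anchor] else {
    side <- if (stem$anchor_side == "left") stem$left_positions else stem$right_positions
    struct$pairs[side[which.min(abs(side - anchor))]]
  }
  dist_genomic <- abs(to_g2(partner_pos) - site$pos)
  new_ecs_prediction(
    site = site, approach = "distal", stem = stem, struct = struct,
    window = sort(c(w2$to_genomic(1L), w2$to_genomic(nchar(w2$seq)))),
    ecs_interval = sort(vapply(partner_local, to_g2, integer(1))),
    edit_interval = sort(vapply(edit_local, w1$to_genomic, integer(1))),
    distance = dist_genomic,
    accepted = TRUE,
    cutoffs = c(min_pairs = min_pairs, max_bulge = max_bulge))
}

# merge overlapping 1-based inclusive intervals within one chromosome
merge_intervals <- function(df) {
  if (!nrow(df)) return(df)
  df <- df[order(df$start), , drop = FALSE]
  out <- df[1, , drop = FALSE]
  for (i in seq_len(nrow(df))[-1]) {
    j <- nrow(out)
    if (df$start[i] <= out$end[j] + 1L) {
      out$end[j] <- max(out$end[j], df$end[i])
    } else out <- rbind(out, df[i, , drop = FALSE])
  }
  out
}

#' Editing-site enrichment in predicted ECS regions
#'
#' Compares the density of known editing sites inside predicted ECS
#' intervals with flanking control regions: each (merged) ECS interval
#' gets one control region immediately upstream and one immediately
#' downstream, each of the ECS's own length (truncated at contig ends,
#' with densities length-normalized). The score is the ratio of the
#' per-base site density in ECSs to that in flanks; with untruncated
#' flanks it equals sites-in-ECS divided by half the flank total. The
#' editing site anchoring each prediction is excluded from the tallies.
#'
#' @param predictions List of accepted `ecs_prediction` objects.
#' @param all_sites Data frame of editing sites (chrom, pos, site_id).
#' @param contig_lengths Named integer vector of contig lengths (for flank
#'   truncation); `Inf` assumed when absent.
#' @return List with `score` (NA when no flank site), `ecs_count`,
#'   `flank_count`, `ecs_length`, `flank_length` and a per-region data
#'   frame `regions`.
#' @export
enrichment_score <- function(predictions, all_sites, contig_lengths = NULL) {
  stopifnot(length(predictions) > 0L)
  anchors <- vapply(predictions, function(p) paste0(p$site$chrom, ":", p$site$pos),
                    character(1))
  ivs <- do.call(rbind, lapply(predictions, function(p)
    data.frame(chrom = p$site$chrom, start = p$ecs_interval[1],
               end = p$ecs_interval[2], stringsAsFactors = FALSE)))
  site_key <- paste0(all_sites$chrom, ":", all_sites$pos)
  counted <- all_sites[!site_key %in% anchors, , drop = FALSE]
  ecs_count <- 0L; flank_count <- 0L
  ecs_len <- 0; flank_len <- 0
  regions <- list()
  for (chrom in unique(ivs$chrom)) {
    merged <- merge_intervals(ivs[ivs$chrom == chrom, , drop = FALSE])
    clen <- if (!is.null(contig_lengths) && chrom %in% names(contig_lengths))
      contig_lengths[[chrom]] else Inf
    pos <- counted$pos[counted$chrom == chrom]
    for (i in seq_len(nrow(merged))) {
      a <- merged$start[i]; b <- merged$end[i]; L <- b - a + 1L
      fl <- c(max(1L, a - L), a - 1L)
      fr <- c(b + 1L, min(clen, b + L))
      n_ecs <- sum(pos >= a & pos <= b)
      n_fl <- if (fl[1] <= fl[2]) sum(pos >= fl[1] & pos <= fl[2]) else 0L
      n_fr <- if (fr[1] <= fr[2]) sum(pos >= fr[1] & pos <= fr[2]) else 0L
      len_fl <- max(0L, fl[2] - fl[1] + 1L)
      len_fr <- max(0L, fr[2] - fr[1] + 1L)
      ecs_count <- ecs_count + n_ecs; ecs_len <- ecs_len + L
      flank_count <- flank_count + n_fl + n_fr
      flank_len <- flank_len + len_fl + len_fr
      regions[[length(regions) + 1L]] <- data.frame(
        chrom = chrom, start = a, end = b, ecs_sites = n_ecs,
        flank_sites = n_fl + n_fr, stringsAsFactors = FALSE)
    }
  }
  score <- if (flank_count > 0L && flank_len > 0L)
    (ecs_count / ecs_len) / (flank_count / flank_len) else NA_real_
  list(score = score, ecs_count = ecs_count, flank_count = flank_count,
       ecs_length = ecs_len, flank_length = flank_len,
       regions = do.call(rbind, regions))
}

#' Structural properties of predicted editing substrates
#'
#' Distributions over accepted predictions: site-to-ECS distance, stem
#' length, max bulge (overall and on the editing-site side), and the
#' fraction of substrates base-paired at each position from -10 to +10
#' relative to the editing site (position 0 = the edited A, positive =
#' downstream in transcript orientation).
#'
#' @param predictions List of accepted `ecs_prediction` objects.
#' @return List with `distances`, `stem_lengths`, `max_bulges`,
#'   `max_bulges_edit_side` (vectors, one entry per prediction) and
#'   `pairing_fraction` (named vector over relative positions -10..10).
#' @export
substrate_properties <- function(predictions) {
  stopifnot(length(predictions) > 0L)
  rel <- -10:10
  paired <- matrix(NA, nrow = length(predictions), ncol = length(rel))
  for (i in seq_along(predictions)) {
    p <- predictions[[i]]
    anchor <- p$stem$anchor
    pairs <- p$structure$pairs
    idx <- anchor + rel
    ok <- idx >= 1L & idx <= length(pairs)
    paired[i, ok] <- pairs[idx[ok]] > 0L
  }
  list(
    distances = vapply(predictions, `[[`, numeric(1), "distance"),
    stem_lengths = vapply(predictions, function(p) p$stem$n_pairs, numeric(1)),
    max_bulges = vapply(predictions, function(p) p$stem$max_bulge, numeric(1)),
    max_bulges_edit_side = vapply(predictions, function(p)
      if (p$stem$anchor_side == "left") p$stem$max_bulge_left
      else p$stem$max_bulge_right, numeric(1)),
    pairing_fraction = stats::setNames(colMeans(paired, na.rm = TRUE),
                                       as.character(rel)))
}
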