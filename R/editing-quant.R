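#' Construct an editing matrix
#'
#' Sites x strains matrix of editing levels (fraction of reads carrying G
#' at the edited A), with per-site counts of measured strains.
#'
#' @param sites Data frame with columns chrom, pos, strand, gene_id,
#'   site_id (one row per editing site; `pos` is 1-based).
#' @param strains Character vector of strain IDs.
#' @param level Numeric matrix (sites x strains) in \[0, 1\] or NA.
#' @return An object of class `editing_matrix`: list with `sites`,
#'   `strains`, `level`, `n_measured`.
#' @export
editing_matrix <- function(sites, strains, level) {
  stopifnot(is.matrix(level), nrow(level) == nrow(sites),
            ncol(level) == length(strains))
  if (any(level < 0 | level > 1, na.rm = TRUE))
    stop("editing levels must lie in [0, 1]")
  if (any(sites$pos < 1)) stop("site positions are 1-based and must be >= 1")
  rownames(level) <- sites$site_id
  colnames(level) <- strains
  structure(list(sites = sites, strains = strains, level = level,
                 n_measured = rowSums(!is.na(level))),
            class = "editing_matrix")
}

#' @export
print.editing_matrix <- function(x, ...) {
  cat(sprintf("Editing matrix: %d sites x %d strains; median strains measured per site: %d\n",
              nrow(x$level), ncol(x$level), as.integer(stats::median(x$n_measured))))
  invisible(x)
}

#' Editing level from allele counts
#'
#' The editing level is the fraction of reads carrying G at the site.
#' Sites below the coverage floor (50 reads by default) are reported as
#' missing rather than as noisy fractions.
#'
#' @param g_count Reads carrying G (vectorized).
#' @param total Total reads covering the site.
#' @param min_coverage Coverage floor (default 50 reads).
#' @return Numeric vector of fractions, NA below the floor.
#' @export
compute_editing_level <- function(g_count, total, min_coverage = 50L) {
  if (any(g_count > total, na.rm = TRUE))
    stop("g_count exceeds total read count")
  if (any(g_count < 0 | total < 0, na.rm = TRUE))
    stop("negative read counts")
  ifelse(!is.na(total) & total >= min_coverage, g_count / total, NA_real_)
}

#' Combine replicate editing levels with a concordance filter
#'
#' Replicates differing by more than `max_diff` (20 percentage points by
#' default) are treated as unreliable for that strain/site and dropped;
#' concordant replicates are combined by a coverage-weighted mean, the
#' maximum-likelihood estimate under binomial read sampling. A difference
#' of exactly `max_diff` is retained (the exclusion rule is strictly
#' greater-than).
#'
#' @param rep1,rep2 Editing levels of the two replicates (vectorized).
#' @param cov1,cov2 Read coverages used as weights; equal by default.
#' @param max_diff Maximum tolerated replicate difference (default 0.20).
#' @return Numeric vector: weighted mean, or NA where discordant or
#'   either replicate missing.
#' @export
filter_replicates <- function(rep1, rep2, cov1 = 1, cov2 = 1,
                              max_diff = 0.20) {
  ok <- !is.na(rep1) & !is.na(rep2) & abs(rep1 - rep2) <= max_diff
  out <- rep(NA_real_, length(ok))
  w1 <- rep_len(cov1, length(ok))[ok]
  w2 <- rep_len(cov2, length(ok))[ok]
  out[ok] <- (rep1[ok] * w1 + rep2[ok] * w2) / (w1 + w2)
  out
}

#' Build a filtered editing matrix from a replicate count table
#'
#' Applies the full quantification cascade: per-replicate levels with the
#' coverage floor, replicate-concordance filtering per strain/site, and
#' removal of sites measured in fewer than `min_strains` strains.
#'
#' @param counts Data frame with columns site_id, strain, replicate,
#'   g_count, total_count; at most one row per (site, strain, replicate).
#' @param sites Optional site annotation data frame (chrom, pos, strand,
#'   gene_id, site_id); a minimal one is synthesized when absent.
#' @param min_strains Minimum strains with a retained measurement
#'   (default 35).
#' @param min_coverage Coverage floor per replicate (default 50 reads).
#' @param max_rep_diff Replicate concordance threshold (default 0.20).
#' @return An `editing_matrix` containing only retained sites.
#' @export
build_editing_matrix <- function(counts, sites = NULL, min_strains = 35L,
                                 min_coverage = 50L, max_rep_diff = 0.20) {
  need <- c("site_id", "strain", "replicate", "g_count", "total_count")
  if (!all(need %in% names(counts)))
    stop("counts table must have columns: ", paste(need, collapse = ", "))
  key <- paste(counts$site_id, counts$strain, counts$replicate)
  if (anyDuplicated(key)) stop("duplicate (site, strain, replicate) rows")
  site_ids <- sort(unique(counts$site_id))
  strains <- sort(unique(counts$strain))
  if (!length(site_ids)) {
    return(editing_matrix(
      data.frame(chrom = character(0), pos = integer(0), strand = character(0),
                 gene_id = character(0), site_id = character(0)),
      character(0), matrix(numeric(0), 0, 0)))
  }
  counts$level <- compute_editing_level(counts$g_count, counts$total_count,
                                        min_coverage = min_coverage)
  lev <- matrix(NA_real_, nrow = length(site_ids), ncol = length(strains),
                dimnames = list(site_ids, strains))
  split_key <- paste(counts$site_id, counts$strain, sep = "\r")
  for (chunk in split(seq_len(nrow(counts)), split_key)) {
    rows <- counts[chunk, , drop = FALSE]
    lv <- rows$level[order(rows$replicate)]
    cv <- rows$total_count[order(rows$replicate)]
    val <- if (length(lv) == 1L) {
      lv
    } else if (length(lv) == 2L) {
      filter_replicates(lv[1], lv[2], cv[1], cv[2], max_diff = max_rep_diff)
    } else { # >2 replicates: require full concordance of the present ones
      pres <- !is.na(lv)
      if (!any(pres) || diff(range(lv[pres])) > max_rep_diff) NA_real_
      else sum(lv[pres] * cv[pres]) / sum(cv[pres])
    }
    lev[rows$site_id[1], rows$strain[1]] <- val
  }
  keep <- rowSums(!is.na(lev)) >= min_strains
  lev <- lev[keep, , drop = FALSE]
  kept_ids <- site_ids[keep]
  if (is.null(sites)) {
    sites <- data.frame(chrom = rep("chrU", length(kept_ids)),
                        pos = seq_along(kept_ids),
                        strand = rep("+", length(kept_ids)),
                        gene_id = kept_ids, site_id = kept_ids,
                        stringsAsFactors = FALSE)
  } else {
    sites <- sites[match(kept_ids, sites$site_id), , drop = FALSE]
    if (anyNA(sites$site_id)) stop("sites annotation is missing some site_ids")
  }
  editing_matrix(sites, strains, lev)
}

#' Pairwise strain differences in editing
#'
#' For every pair of strains, the fraction of co-measured sites whose
#' editing levels differ by at least `threshold` (10 percentage points by
#' default).
#'
#' @param matrix An `editing_matrix`.
#' @param threshold Editing-level difference counted as differing
#'   (default 0.10).
#' @return Symmetric strains x strains matrix of fractions (NA diagonal
#'   and NA for pairs with no co-measured site).
#' @export
pairwise_strain_difference <- function(matrix, threshold = 0.10) {
  stopifnot(inherits(matrix, "editing_matrix"))
  lv <- matrix$level
  n <- ncol(lv)
  out <- base::matrix(NA_real_, n, n, dimnames = list(colnames(lv), colnames(lv)))
  for (a in seq_len(n - 1L)) {
    for (b in seq((a + 1L), n)) {
      both <- !is.na(lv[, a]) & !is.na(lv[, b])
      if (!any(both)) next
      frac <- mean(abs(lv[both, a] - lv[both, b]) >= threshold)
      out[a, b] <- frac
      out[b, a] <- frac
    }
  }
  out
}

#' Per-site editing variability
#'
#' Two variability scores per site: the sample variance of editing levels
#' across strains, and a binomial-scaled variant -- the sample variance
#' divided by `p * (1 - p)` with `p` the site's mean level -- which puts
#' sites with different mean levels on a comparable scale. The scaled
#' score is missing when the mean is 0 or 1.
#'
#' @param matrix An `editing_matrix`.
#' @return Data frame (site_id, n, mean, variance, binomial_scaled) with
#'   rank columns on both scores.
#' @export
site_variability <- function(matrix) {
  stopifnot(inherits(matrix, "editing_matrix"))
  lv <- matrix$level
  n <- rowSums(!is.na(lv))
  m <- rowMeans(lv, na.rm = TRUE)
  v <- apply(lv, 1L, stats::var, na.rm = TRUE)
  v[n < 2L] <- NA_real_
  denom <- m * (1 - m)
  bs <- ifelse(denom > 0, v / denom, NA_real_)
  out <- data.frame(site_id = rownames(lv), n = n, mean = m, variance = v,
                    binomial_scaled = bs, row.names = NULL,
                    stringsAsFactors = FALSE)
  out$rank_variance <- rank(-out$variance, na.last = "keep")
  out$rank_binomial <- rank(-out$binomial_scaled, na.last = "keep")
  out
}

#' Screen a candidate site's pileup through the discovery filter cascade
#'
#' Accepts an A-to-G (sense-strand) candidate editing site only if it
#' passes every filter: at least `min_reads` supporting reads after
#' discarding reads whose mismatch falls in the first `trim_bases` read
#' positions or has base/mapping quality below `min_qual`; variant
#' frequency at least `min_freq`; no homopolymer or simple-repeat context;
#' not within `splice_dist` nt of a splice junction; no bidirectional
#' transcription; resolvable strand; and zero altered reads in an
#' ADAR-null pileup when one is supplied. All failed filters are reported
#' as reason codes.
#'
#' @param site List describing one candidate: `ref`/`alt` bases on the
#'   sense strand, `strand` ("+", "-" or NA), `reads` data frame with
#'   columns base, base_qual, map_qual, read_pos, `depth` total reads, and
#'   logical context flags `homopolymer`, `simple_repeat`,
#'   `bidirectional`, plus `splice_junction_dist` (nt, Inf when far).
#' @param adar_null Optional list with `altered_reads`: count of
#'   mismatched reads at this position in an ADAR-null sample.
#' @param min_reads,min_freq,min_qual,trim_bases,splice_dist Filter
#'   parameters (defaults 2 reads, 3 percent, quality 20, 6 bases, 4 nt).
#' @return List with `accept` (logical) and `reasons` (character vector of
#'   reason codes, empty when accepted).
#' @export
discover_sites_from_pileup <- function(site, adar_null = NULL,
                                       min_reads = 2L, min_freq = 0.03,
                                       min_qual = 20L, trim_bases = 6L,
                                       splice_dist = 4L) {
  reasons <- character(0)
  if (is.null(site$strand) || is.na(site$strand)) {
    return(list(accept = FALSE, reasons = "no strand"))
  }
  if (!identical(site$ref, "A") || !identical(site$alt, "G"))
    reasons <- c(reasons, "not A-to-G")
  reads <- site$reads
  supporting <- reads[reads$base == site$alt &
                        reads$base_qual >= min_qual &
                        reads$map_qual >= min_qual &
                        reads$read_pos > trim_bases, , drop = FALSE]
  if (nrow(supporting) < min_reads) reasons <- c(reasons, "min reads")
  freq <- nrow(supporting) / max(site$depth, 1L)
  if (freq < min_freq) reasons <- c(reasons, "min frequency")
  if (isTRUE(site$homopolymer)) reasons <- c(reasons, "homopolymer")
  if (isTRUE(site$simple_repeat)) reasons <- c(reasons, "simple repeat")
  sj <- site$splice_junction_dist
  if (!is.null(sj) && is.finite(sj) && sj <= splice_dist)
    reasons <- c(reasons, "splice junction")
  if (isTRUE(site$bidirectional)) reasons <- c(reasons, "bidirectional transcription")
  if (!is.null(adar_null) && isTRUE(adar_null$altered_reads > 0L))
    reasons <- c(reasons, "present in ADAR-null")
  list(accept = length(reasons) == 0L, reasons = reasons)
}
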