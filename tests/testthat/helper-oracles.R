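# Independent oracle implementations used to cross-check the package.
# They re-state the energy model and definitions from first principles in
# plain R, sharing no code with the implementation under test.

ORC_PAIR <- matrix(Inf, 4, 4, dimnames = rep(list(c("A", "C", "G", "U")), 2))
ORC_PAIR["G", "C"] <- ORC_PAIR["C", "G"] <- -3
ORC_PAIR["A", "U"] <- ORC_PAIR["U", "A"] <- -2
ORC_PAIR["G", "U"] <- ORC_PAIR["U", "G"] <- -1
ORC_STACK <- -1
ORC_INIT <- 4
ORC_LOOPBASE <- 0.5
ORC_MINHP <- 3

orc_chars <- function(seq) {
  x <- strsplit(toupper(seq), "")[[1]]
  x[x == "T"] <- "U"
  x
}

orc_pair_ok <- function(ch, i, j) {
  if (j - i <= ORC_MINHP) return(FALSE)
  if (!ch[i] %in% rownames(ORC_PAIR) || !ch[j] %in% rownames(ORC_PAIR))
    return(FALSE)
  is.finite(ORC_PAIR[ch[i], ch[j]])
}

# energy of a fixed structure, re-derived from the model statement
orc_structure_energy <- function(seq, pairs) {
  ch <- orc_chars(seq)
  n <- length(ch)
  e <- 0
  for (i in seq_len(n)) {
    j <- pairs[i]
    if (j <= i) next
    e <- e + ORC_PAIR[ch[i], ch[j]]
    if (i + 1 <= n && pairs[i + 1] == j - 1 && j - 1 > i + 1)
      e <- e + ORC_STACK
    opens <- i == 1 || j == n || pairs[i - 1] != j + 1
    if (opens) e <- e + ORC_INIT
  }
  # unpaired bases inside a non-hairpin loop
  for (x in seq_len(n)) {
    if (pairs[x] != 0) next
    enclosing <- NULL
    for (i in seq_len(x)) {
      j <- pairs[i]
      if (j > x && i < x && (is.null(enclosing) || i > enclosing[1]))
        enclosing <- c(i, j)
    }
    if (is.null(enclosing)) next
    interior <- (enclosing[1] + 1):(enclosing[2] - 1)
    if (any(pairs[interior] != 0)) e <- e + ORC_LOOPBASE
  }
  e
}

# bottom-up MFE recurrence in plain R (same model, independent code path)
orc_mfe_energy <- function(seq) {
  ch <- orc_chars(seq)
  n <- length(ch)
  if (n <= ORC_MINHP + 1) return(0)
  canp <- matrix(FALSE, n, n)
  pe <- matrix(Inf, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (orc_pair_ok(ch, i, j)) {
      canp[i, j] <- TRUE
      pe[i, j] <- ORC_PAIR[ch[i], ch[j]]
    }
  }
  V <- matrix(Inf, n, n)
  W <- matrix(0, n, n)
  M <- matrix(0, n, n)
  diag(M) <- ORC_LOOPBASE
  for (span in 1:(n - 1)) {
    for (i in 1:(n - span)) {
      j <- i + span
      if (canp[i, j]) {
        best <- 0
        if (canp[i + 1, j - 1]) best <- min(best, V[i + 1, j - 1] + ORC_STACK)
        if (j - 1 >= i + 1) best <- min(best, M[i + 1, j - 1])
        V[i, j] <- pe[i, j] + best
      }
      ks <- seq_len(max(0, j - ORC_MINHP - 1 - i + 1)) + i - 1
      ks <- ks[canp[ks, j]]
      mleft <- function(k) if (k - 1 < i) 0 else M[i, k - 1]
      wleft <- function(k) if (k - 1 < i) 0 else W[i, k - 1]
      bm <- (if (j - 1 >= i) M[i, j - 1] else 0) + ORC_LOOPBASE
      bw <- if (j - 1 >= i) W[i, j - 1] else 0
      for (k in ks) {
        bm <- min(bm, mleft(k) + V[k, j] + ORC_INIT)
        bw <- min(bw, wleft(k) + V[k, j] + ORC_INIT)
      }
      M[i, j] <- bm
      W[i, j] <- bw
    }
  }
  W[1, n]
}

# exhaustive enumeration of every nested structure (tiny n only)
orc_all_structures <- function(seq) {
  ch <- orc_chars(seq)
  n <- length(ch)
  memo <- new.env()
  rec <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (j - i <= ORC_MINHP) {
      out <- list(matrix(integer(0), ncol = 2))
      memo[[key]] <- out
      return(out)
    }
    out <- lapply(rec(i, j - 1), identity) # j unpaired
    for (k in i:(j - ORC_MINHP - 1)) {
      if (!orc_pair_ok(ch, k, j)) next
      lefts <- if (k - 1 >= i) rec(i, k - 1) else list(matrix(integer(0), ncol = 2))
      inners <- rec(k + 1, j - 1)
      for (L in lefts) for (In in inners)
        out[[length(out) + 1]] <- rbind(L, In, c(k, j))
    }
    memo[[key]] <- out
    out
  }
  base <- rec(1, n)
  lapply(base, function(m) {
    pairs <- integer(n)
    if (nrow(m)) {
      pairs[m[, 1]] <- m[, 2]
      pairs[m[, 2]] <- m[, 1]
    }
    pairs
  })
}

orc_exhaustive_min_energy <- function(seq) {
  structs <- orc_all_structures(seq)
  min(vapply(structs, function(p) orc_structure_energy(seq, p), numeric(1)))
}

# exhaustive stem finder: all maximal chains of pairs whose inter-pair
# gaps are <= max_bulge on both strands; returns the chain containing
# (or, failing that, enclosing) the anchor if it has >= min_pairs pairs
orc_stem_at <- function(pairs, anchor, min_pairs = 20, max_bulge = 8) {
  op <- which(pairs > seq_along(pairs))
  if (!length(op)) return(NULL)
  prs <- cbind(i = op, j = pairs[op])
  prs <- prs[order(prs[, "i"]), , drop = FALSE]
  gap_unpaired <- function(a, b) { # positions strictly between, all unpaired?
    if (b - a <= 1) return(TRUE)
    all(pairs[(a + 1):(b - 1)] == 0)
  }
  follows <- function(a, b) { # pair b directly continues pair a inward
    prs[b, "i"] > prs[a, "i"] && prs[b, "j"] < prs[a, "j"] &&
      gap_unpaired(prs[a, "i"], prs[b, "i"]) &&
      gap_unpaired(prs[b, "j"], prs[a, "j"]) &&
      (prs[b, "i"] - prs[a, "i"] - 1) <= max_bulge &&
      (prs[a, "j"] - prs[b, "j"] - 1) <= max_bulge
  }
  np <- nrow(prs)
  nxt <- rep(NA_integer_, np)
  prev <- rep(NA_integer_, np)
  for (a in seq_len(np)) {
    b <- which(prs[, "i"] > prs[a, "i"])
    if (!length(b)) next
    b <- b[which.min(prs[b, "i"])] # the immediately next pair inward
    if (follows(a, b)) { nxt[a] <- b; prev[b] <- a }
  }
  chains <- list()
  for (a in which(is.na(prev))) {
    chain <- a
    while (!is.na(nxt[chain[length(chain)]]))
      chain <- c(chain, nxt[chain[length(chain)]])
    chains[[length(chains) + 1]] <- chain
  }
  # chain whose strand spans contain the anchor; otherwise the chain of
  # the innermost pair enclosing the anchor
  pick <- NULL
  for (chain in chains) {
    ii <- prs[chain, "i"]; jj <- prs[chain, "j"]
    if ((anchor >= min(ii) && anchor <= max(ii)) ||
        (anchor >= min(jj) && anchor <= max(jj))) { pick <- chain; break }
  }
  if (is.null(pick)) {
    innermost <- -Inf
    for (chain in chains) {
      ii <- prs[chain, "i"]; jj <- prs[chain, "j"]
      enc <- which(ii < anchor & jj > anchor)
      if (length(enc) && max(ii[enc]) > innermost) {
        innermost <- max(ii[enc])
        pick <- chain
      }
    }
  }
  if (is.null(pick) || length(pick) < min_pairs) return(NULL)
  ii <- prs[pick, "i"]; jj <- prs[pick, "j"]
  list(n_pairs = length(pick),
       left = c(min(ii), max(ii)), right = c(min(jj), max(jj)))
}

# exact two-sided Fisher p by hypergeometric enumeration
orc_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m <- a + c_; n <- b + d; k <- a + b
  kk <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(kk, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact one-sided (x stochastically smaller) Mann-Whitney p by
# enumeration of all assignments of the pooled values
orc_mw_p_less <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)])
  idx <- utils::combn(length(pooled), nx)
  ws <- colSums(matrix(r[idx], nrow = nx))
  mean(ws <= w_obs)
}
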