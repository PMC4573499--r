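#' @useDynLib edscape, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# integer encoding shared with the C++ folder: A=0 C=1 G=2 U/T=3 other=4
encode_rna <- function(sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  code <- match(chars, c("A", "C", "G", "U")) - 1L
  code[chars == "T"] <- 3L
  code[is.na(code)] <- 4L
  code
}

#' Fold an RNA sequence to its minimum-free-energy secondary structure
#'
#' Deterministic single-strand folding under the package's built-in
#' nearest-neighbour energy model: Watson-Crick (G-C, A-U) and wobble (G-U)
#' pairs with pair energies of -3, -2 and -1 kcal/mol, a -1 kcal/mol bonus
#' for each stacked pair, hairpin loops of at least 3 nt, and strictly
#' nested structures (no pseudoknots). `N` bases and positions listed in
#' `constraint_mask` never pair. The energies are model-relative: they rank
#' structures of the same sequence and are comparable between alleles of
#' the same locus, but are not calibrated to experimental folding energies.
#'
#' Externally computed structures (e.g. from a thermodynamic folding
#' program, exported as dot-bracket) can be injected into every downstream
#' operation through [parse_dotbracket()] and [rna_structure()], so the
#' built-in folder is a default, not a hard dependency of the analyses.
#'
#' @param sequence Character scalar over A/C/G/U/T/N (T is treated as U).
#' @param constraint_mask Integer vector of 1-based positions forbidden
#'   from pairing (e.g. a linker), or `NULL`.
#' @return An object of class `rna_structure`: a list with `sequence`,
#'   `pairs` (integer partner table, 1-based, 0 = unpaired), `energy`
#'   (kcal/mol, <= 0) and `constraint_mask`.
#' @examples
#' fold_mfe("GGGGAAAACCCC")
#' @export
fold_mfe <- function(sequence, constraint_mask = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) stop("empty sequence")
  code <- encode_rna(sequence)
  mask <- rep(FALSE, length(code))
  if (!is.null(constraint_mask)) {
    constraint_mask <- as.integer(constraint_mask)
    if (any(constraint_mask < 1L | constraint_mask > length(code)))
      stop("constraint_mask positions out of range")
    mask[constraint_mask] <- TRUE
  }
  res <- .fold_mfe_cpp(code, mask)
  rna_structure(sequence, res$pairs, energy = res$energy,
                constraint_mask = constraint_mask)
}

#' Construct an RNA secondary-structure object
#'
#' Container shared by the built-in folder and externally supplied
#' structures. The pair table must be an involution (the partner of a
#' partner is the position itself) with no self-pairs.
#'
#' @param sequence Character scalar.
#' @param pairs Integer partner table (1-based positions, 0 = unpaired).
#' @param energy Free energy in kcal/mol; computed from the built-in model
#'   via [structure_energy()] when `NULL`.
#' @param constraint_mask Positions forbidden from pairing, or `NULL`.
#' @return An `rna_structure` object.
#' @export
rna_structure <- function(sequence, pairs, energy = NULL,
                          constraint_mask = NULL) {
  pairs <- as.integer(pairs)
  n <- nchar(sequence)
  if (length(pairs) != n) stop("pair table length does not match sequence")
  paired <- which(pairs > 0L)
  if (any(pairs[paired] == paired)) stop("a position cannot pair with itself")
  if (any(pairs[pairs[paired]] != paired))
    stop("pair table is not an involution")
  if (!is.null(constraint_mask) && any(pairs[constraint_mask] > 0L))
    stop("constrained position is paired")
  if (is.null(energy)) energy <- structure_energy(sequence, pairs)
  structure(list(sequence = sequence, pairs = pairs, energy = energy,
                 constraint_mask = constraint_mask),
            class = "rna_structure")
}

#' Evaluate the energy of a fixed structure under the built-in model
#'
#' @param sequence Character scalar.
#' @param pairs Integer partner table (1-based, 0 = unpaired).
#' @return Energy in kcal/mol.
#' @export
structure_energy <- function(sequence, pairs) {
  .structure_energy_cpp(encode_rna(sequence), as.integer(pairs))
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(sprintf("RNA structure: %d nt, %d pairs, energy %.1f kcal/mol\n",
              nchar(x$sequence), sum(x$pairs > 0) / 2, x$energy))
  if (nchar(x$sequence) <= 120) {
    cat(x$sequence, "\n", sep = "")
    cat(to_dotbracket(x$pairs), "\n", sep = "")
  }
  invisible(x)
}

#' Parse a dot-bracket string into a pair table
#'
#' @param x Character scalar of `.`, `(` and `)`.
#' @return Integer partner table (1-based, 0 = unpaired).
#' @export
parse_dotbracket <- function(x) {
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c(".", "(", ")"))
  if (length(bad)) stop("invalid dot-bracket character at position ", bad[1])
  pairs <- integer(length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (!length(stack)) stop("unbalanced ')' at position ", i)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pairs[i] <- j
      pairs[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced '(' at position ", stack[length(stack)])
  pairs
}

#' Render a pair table as a dot-bracket string
#'
#' @param pairs Integer partner table (1-based, 0 = unpaired, nested).
#' @return Character scalar.
#' @export
to_dotbracket <- function(pairs) {
  out <- rep(".", length(pairs))
  out[pairs > seq_along(pairs)] <- "("
  out[pairs > 0 & pairs < seq_along(pairs)] <- ")"
  paste(out, collapse = "")
}

# innermost pair (i,j) with i <= anchor <= j, or NULL
enclosing_pair <- function(pairs, anchor) {
  if (pairs[anchor] > 0L) {
    return(sort(c(anchor, pairs[anchor])))
  }
  # innermost enclosing pair = largest i < anchor with partner > anchor
  cand <- which(pairs > anchor & seq_along(pairs) < anchor)
  if (!length(cand)) return(NULL)
  i <- max(cand)
  c(i, pairs[i])
}

# one accretion step away from pair (i,j); dir = "out" or "in"
step_pair <- function(pairs, i, j, max_bulge, dir) {
  if (dir == "out") {
    lo <- if (i > 1L) max(c(0L, which(pairs[seq_len(i - 1L)] > 0L))) else 0L
    if (lo == 0L) return(NULL)
    j2 <- pairs[lo]
    if (j2 <= j) return(NULL)
    if (any(pairs[seq2(lo + 1L, i - 1L)] > 0L)) return(NULL)
    if (any(pairs[seq2(j + 1L, j2 - 1L)] > 0L)) return(NULL)
    gl <- i - lo - 1L; gr <- j2 - j - 1L
  } else {
    inner <- which(pairs > 0L)
    inner <- inner[inner > i & inner < j]
    if (!length(inner)) return(NULL)
    lo <- min(inner)
    j2 <- pairs[lo]
    if (j2 >= j || j2 <= lo) return(NULL)
    if (any(pairs[seq2(i + 1L, lo - 1L)] > 0L)) return(NULL)
    if (any(pairs[seq2(j2 + 1L, j - 1L)] > 0L)) return(NULL)
    gl <- lo - i - 1L; gr <- j - j2 - 1L
  }
  if (max(gl, gr) > max_bulge) return(NULL)
  list(i = lo, j = j2, gap_left = gl, gap_right = gr)
}

seq2 <- function(from, to) if (from > to) integer(0) else seq.int(from, to)

#' Extract the stem containing a position from a folded structure
#'
#' Starting from the pair at (or the innermost pair enclosing) `anchor`,
#' consecutive pairs are accreted in both directions along the helix while
#' every interruption -- the unpaired run on either strand between
#' consecutive stem pairs -- is at most `max_bulge` nt. The stem is
#' reported only if it reaches `min_pairs` base pairs; the defaults are the
#' 20 bp / 8 nt cutoffs used for ECS prediction. The strand interval not
#' containing the anchor is the predicted complementary (ECS) side, bounded
#' by its first and last paired bases.
#'
#' @param struct An `rna_structure`.
#' @param anchor 1-based position the stem must contain (the editing site).
#' @param min_pairs Minimum number of base pairs (default 20).
#' @param max_bulge Maximum interruption size in nt (default 8).
#' @return An object of class `rna_stem`, or `NULL` if no qualifying stem
#'   contains the anchor. The stem records the 1-based inclusive intervals
#'   of both strands, `n_pairs`, `max_bulge` (overall and per strand) and
#'   the anchor side.
#' @export
extract_stem_at <- function(struct, anchor, min_pairs = 20L, max_bulge = 8L) {
  stopifnot(inherits(struct, "rna_structure"))
  pairs <- struct$pairs
  anchor <- as.integer(anchor)
  if (anchor < 1L || anchor > length(pairs)) stop("anchor out of range")
  start <- enclosing_pair(pairs, anchor)
  if (is.null(start)) return(NULL)
  lefts <- start[1]; rights <- start[2]
  gaps_l <- integer(0); gaps_r <- integer(0)
  i <- start[1]; j <- start[2]
  repeat { # outward (towards the helix base)
    st <- step_pair(pairs, i, j, max_bulge, "out")
    if (is.null(st)) break
    lefts <- c(st$i, lefts); rights <- c(st$j, rights)
    gaps_l <- c(st$gap_left, gaps_l); gaps_r <- c(st$gap_right, gaps_r)
    i <- st$i; j <- st$j
  }
  i <- start[1]; j <- start[2]
  repeat { # inward (towards the loop)
    st <- step_pair(pairs, i, j, max_bulge, "in")
    if (is.null(st)) break
    lefts <- c(lefts, st$i); rights <- c(rights, st$j)
    gaps_l <- c(gaps_l, st$gap_left); gaps_r <- c(gaps_r, st$gap_right)
    i <- st$i; j <- st$j
  }
  n_pairs <- length(lefts)
  if (n_pairs < min_pairs) return(NULL)
  anchor_side <- if (anchor <= max(lefts)) "left" else "right"
  structure(list(
    left = c(min(lefts), max(lefts)),
    right = c(min(rights), max(rights)),
    left_positions = lefts,
    right_positions = sort(rights),
    n_pairs = n_pairs,
    max_bulge = if (n_pairs > 1L) max(c(0L, pmax(gaps_l, gaps_r))) else 0L,
    max_bulge_left = if (n_pairs > 1L) max(c(0L, gaps_l)) else 0L,
    max_bulge_right = if (n_pairs > 1L) max(c(0L, gaps_r)) else 0L,
    anchor = anchor,
    anchor_side = anchor_side
  ), class = "rna_stem")
}

#' @export
print.rna_stem <- function(x, ...) {
  cat(sprintf(
    "RNA stem: %d pairs, max bulge %d nt; 5' strand [%d, %d], 3' strand [%d, %d], anchor %d (%s)\n",
    x$n_pairs, x$max_bulge, x$left[1], x$left[2], x$right[1], x$right[2],
    x$anchor, x$anchor_side))
  invisible(x)
}

#' Maximum bulge size of a stem
#'
#' The interruption between two consecutive stem pairs may be asymmetric
#' (an internal loop); its size is the longer of the two strands' unpaired
#' runs. `side` selects the overall maximum or a per-strand maximum (the
#' editing-site side of the stem is reported separately in substrate
#' summaries).
#'
#' @param stem An `rna_stem`.
#' @param side One of "both", "left", "right".
#' @return Integer bulge size in nt.
#' @export
max_bulge <- function(stem, side = c("both", "left", "right")) {
  stopifnot(inherits(stem, "rna_stem"))
  side <- match.arg(side)
  switch(side, both = stem$max_bulge, left = stem$max_bulge_left,
         right = stem$max_bulge_right)
}

#' Enumerate all maximal stems in a structure
#'
#' Partitions the pair table into maximal runs of consecutive pairs whose
#' interruptions are all `<= max_bulge` and keeps runs with at least
#' `min_pairs` pairs.
#'
#' @inheritParams extract_stem_at
#' @return List of `rna_stem` objects, ordered by 5' start.
#' @export
enumerate_stems <- function(struct, min_pairs = 20L, max_bulge = 8L) {
  pairs <- struct$pairs
  visited <- rep(FALSE, length(pairs))
  stems <- list()
  for (p in seq_along(pairs)) {
    if (visited[p] || pairs[p] <= p) next
    stem <- extract_stem_at(struct, p, min_pairs = 1L, max_bulge = max_bulge)
    visited[stem$left_positions] <- TRUE
    visited[stem$right_positions] <- TRUE
    if (stem$n_pairs >= min_pairs) stems[[length(stems) + 1L]] <- stem
  }
  stems
}

#' Fold a two-segment duplex through an unpairable adenosine linker
#'
#' Joins the editing-side sequence and the candidate complementary (ECS)
#' sequence with a linker of adenosines whose positions are forbidden from
#' pairing, then folds the concatenation with the built-in MFE folder. Used
#' for allelic free-energy comparison and distal ECS prediction.
#'
#' @param edit_side Character scalar, editing-side sequence.
#' @param ecs Character scalar, complementary-side sequence.
#' @param linker Linker length in nt (default 100).
#' @return An `rna_structure` for the full construct; attribute
#'   `segments` gives the 1-based intervals of the two segments.
#' @export
duplex_fold <- function(edit_side, ecs, linker = 100L) {
  stopifnot(nchar(edit_side) > 0L, nchar(ecs) > 0L)
  n1 <- nchar(edit_side)
  seqs <- paste0(edit_side, strrep("A", linker), ecs)
  mask <- seq2(n1 + 1L, n1 + linker)
  st <- fold_mfe(seqs, constraint_mask = mask)
  attr(st, "segments") <- list(edit_side = c(1L, n1),
                               linker = c(n1 + 1L, n1 + linker),
                               ecs = c(n1 + linker + 1L, nchar(seqs)))
  st
}

#' Free energy of a linked two-segment duplex
#'
#' @inheritParams duplex_fold
#' @return Energy in kcal/mol of the MFE fold of the linked construct.
#' @export
duplex_free_energy <- function(edit_side, ecs, linker = 100L) {
  duplex_fold(edit_side, ecs, linker = linker)$energy
}

#' Read and write Vienna dot-bracket files
#'
#' The file holds records of a `>name` line, a sequence line and a
#' structure line (an optional trailing ` (energy)` on the structure line
#' is parsed when present).
#'
#' @param path File path.
#' @return `read_dotbracket()` returns a named list of `rna_structure`
#'   objects.
#' @export
read_dotbracket <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  out <- list()
  for (h in heads) {
    name <- sub("^>\\s*", "", lines[h])
    seqs <- lines[h + 1L]
    strct <- lines[h + 2L]
    energy <- NULL
    m <- regmatches(strct, regexec("^([().]+)\\s*\\((\\s*-?[0-9.]+)\\)\\s*$", strct))[[1]]
    if (length(m)) {
      strct <- m[2]
      energy <- as.numeric(m[3])
    }
    out[[name]] <- rna_structure(seqs, parse_dotbracket(strct), energy = energy)
  }
  out
}

#' @rdname read_dotbracket
#' @param structures Named list of `rna_structure` objects.
#' @export
write_dotbracket <- function(structures, path) {
  if (inherits(structures, "rna_structure")) structures <- list(structure1 = structures)
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(structures)) {
    s <- structures[[nm]]
    writeLines(c(paste0(">", nm), s$sequence,
                 sprintf("%s (%.2f)", to_dotbracket(s$pairs), s$energy)), con)
  }
  invisible(path)
}

#' Read and write CT (connectivity table) structure files
#'
#' @param path File path.
#' @return `read_ct()` returns an `rna_structure`.
#' @export
read_ct <- function(path) {
  lines <- readLines(path)
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- as.integer(header[1])
  energy <- suppressWarnings(as.numeric(header[grep("^-?[0-9.]+$", header)][2]))
  body <- do.call(rbind, strsplit(trimws(lines[1 + seq_len(n)]), "\\s+"))
  seqs <- paste(body[, 2], collapse = "")
  pairs <- as.integer(body[, 5])
  rna_structure(seqs, pairs, energy = if (is.na(energy)) NULL else energy)
}

#' @rdname read_ct
#' @param struct An `rna_structure`.
#' @export
write_ct <- function(struct, path) {
  n <- nchar(struct$sequence)
  bases <- strsplit(struct$sequence, "", fixed = TRUE)[[1]]
  lines <- c(sprintf("%d  ENERGY = %.2f  structure", n, struct$energy),
             sprintf("%d %s %d %d %d %d", seq_len(n), bases,
                     seq_len(n) - 1L, c(seq_len(n - 1L) + 1L, 0L),
                     struct$pairs, seq_len(n)))
  writeLines(lines, path)
  invisible(path)
}
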