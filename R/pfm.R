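# Position frequency matrices: construction from seed occurrence sets,
# information weights, and the normalized information-weighted similarity
# score used for promoter scanning.
#
# Score of a width-W subsequence s against matrix f with per-position
# information weights w[i] = 2 + sum_b f[i,b] log2 f[i,b]:
#
#   similarity(s) = sum_i w[i] f[i, s_i] / sum_i w[i] max_b f[i,b]
#
# which is 1 exactly on the per-position argmax (consensus) string. An N at
# position i contributes the minimum base frequency at that position.

#' Construct a position frequency matrix from aligned sequences
#'
#' Base counts per column are regularized with a pseudocount of
#' `pseudocount` (default 0.25) per base, i.e. frequencies
#' `(count + 0.25) / (n + 1)`, which keeps all log terms finite and vanishes
#' with seed depth.
#'
#' @param seqs character vector of equal-length A/C/G/T sequences.
#' @param pseudocount per-base pseudocount added to each column's counts.
#' @param id matrix identifier.
#' @return object of class `pfm`: list with `f` (4 x W frequency matrix, rows
#'   A/C/G/T, columns summing to 1), `w` (information weights in bits, in
#'   `[0, 2]`), `n_seqs`, `width`, `id`.
#' @export
pfm_from_alignment <- function(seqs, pseudocount = 0.25, id = "pfm") {
  seqs <- toupper(seqs)
  if (length(seqs) < 1L) stop("need at least one sequence")
  if (grepl("[^ACGT]", paste(seqs, collapse = "")))
    stop("aligned seed sequences must be over A/C/G/T")
  chars <- seq_char_matrix(seqs)
  n <- nrow(chars)
  counts <- vapply(seq_len(ncol(chars)),
                   function(j) tabulate(factor(chars[, j], DNA_BASES), 4L),
                   integer(4L))
  f <- (counts + pseudocount) / (n + 4 * pseudocount)
  dimnames(f) <- list(DNA_BASES, NULL)
  new_pfm(f, n_seqs = n, id = id)
}

new_pfm <- function(f, n_seqs, id = "pfm") {
  stopifnot(is.matrix(f), nrow(f) == 4L, all(f > 0), all(f < 1),
            all(abs(colSums(f) - 1) < 1e-9))
  rownames(f) <- DNA_BASES
  w <- 2 + colSums(f * log2(f))
  structure(list(f = f, w = w, n_seqs = n_seqs, width = ncol(f), id = id),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("PFM '%s': width %d, built from %d sequence(s)\n",
              x$id, x$width, x$n_seqs))
  cat("consensus:", pfm_consensus(x), "\n")
  cat("information weights (bits):",
      paste(sprintf("%.2f", x$w), collapse = " "), "\n")
  invisible(x)
}

#' Consensus string of a PFM
#'
#' Per-position argmax base; ties broken in A < C < G < T order.
#'
#' @param pfm a [pfm_from_alignment()] object.
#' @return character consensus string of length `pfm$width`.
#' @export
pfm_consensus <- function(pfm) {
  paste(DNA_BASES[apply(pfm$f, 2L, which.max)], collapse = "")
}

#' Matrix similarity of a subsequence to a PFM
#'
#' The information-weighted frequency ratio normalized by the consensus
#' score (see the package vignette for the formula). Scores lie in (0, 1]
#' and reach 1 exactly on the consensus string. `N` contributes the minimum
#' base frequency at its position.
#'
#' @param pfm a `pfm` object.
#' @param subseq character string over A/C/G/T/N with `nchar == pfm$width`.
#' @return similarity score in (0, 1].
#' @export
matrix_similarity <- function(pfm, subseq) {
  subseq <- toupper(subseq)
  if (nchar(subseq) != pfm$width)
    stop("subsequence length ", nchar(subseq),
         " does not match matrix width ", pfm$width)
  if (all(pfm$w < 1e-12))
    stop("zero-information matrix: all positions are uninformative")
  b <- match(strsplit(subseq, "")[[1]], DNA_BASES)
  fi <- numeric(pfm$width)
  for (i in seq_len(pfm$width)) {
    fi[i] <- if (is.na(b[i])) min(pfm$f[, i]) else pfm$f[b[i], i]
  }
  sum(pfm$w * fi) / sum(pfm$w * apply(pfm$f, 2L, max))
}

# per-sequence k-mer inventory of the forward strand
kmers_of <- function(s, k) {
  L <- nchar(s)
  if (L < k) return(character(0))
  substring(s, 1:(L - k + 1L), k:L)
}

#' Build a position frequency matrix from a seed occurrence set
#'
#' A matrix-definition procedure in the classic conserved-tuple style:
#' \enumerate{
#'   \item find the `tuple_size`-mer present (exact forward-strand match) in
#'     at least `min_tuple_frac` of the seed sequences; ties are broken by
#'     highest total occurrence count, then lexicographic order;
#'   \item anchor-align all sequences containing it at their first tuple
#'     occurrence; the matrix spans the columns covered by every anchored
#'     sequence;
#'   \item build a provisional frequency matrix with pseudocounts;
#'   \item rescan every input sequence (both strands, best window) and retain
#'     those whose best matrix similarity reaches `include_threshold`;
#'     rebuild the matrix from the retained best windows.
#' }
#' Seed occurrence sets produced by a site scanner arrive strand-oriented,
#' so the tuple census uses the forward strand; the inclusion rescan is
#' strand-blind.
#'
#' @param seqs character vector (or `DNAStringSet`) of seed occurrences.
#' @param tuple_size anchor tuple length (default 8).
#' @param min_tuple_frac minimum fraction of sequences containing the tuple
#'   (default 0.6).
#' @param include_threshold matrix similarity required for a sequence to be
#'   retained in the final matrix (default 0.9).
#' @param pseudocount per-base pseudocount, see [pfm_from_alignment()].
#' @param id matrix identifier.
#' @return a `pfm` with extra fields `tuple` (the anchor tuple) and
#'   `n_input` (number of seed sequences offered).
#' @export
build_matrix_from_seeds <- function(seqs, tuple_size = 8,
                                    min_tuple_frac = 0.6,
                                    include_threshold = 0.9,
                                    pseudocount = 0.25, id = "pfm") {
  seqs <- toupper(as.character(seqs))
  n <- length(seqs)
  if (n < 2L) stop("need >= 2 seed sequences")
  if (min(nchar(seqs)) < tuple_size)
    stop("tuple_size exceeds the shortest seed sequence")

  km_per_seq <- lapply(seqs, kmers_of, k = tuple_size)
  presence <- table(unlist(lapply(km_per_seq, unique)))
  occurrences <- table(unlist(km_per_seq))
  frac <- as.numeric(presence) / n
  ok <- frac >= min_tuple_frac
  if (!any(ok))
    stop(sprintf(
      "no %d-mer is present in >= %.0f%% of the seed sequences (best: %.1f%%)",
      tuple_size, 100 * min_tuple_frac, 100 * max(frac)))
  cand <- names(presence)[ok]
  occ <- as.numeric(occurrences[cand])
  ord <- order(-as.numeric(presence[cand]), -occ, cand)
  tuple <- cand[ord[1]]

  has <- vapply(km_per_seq, function(k) tuple %in% k, logical(1))
  anchor <- vapply(seqs[has], function(s)
    as.integer(regexpr(tuple, s, fixed = TRUE)), integer(1))
  len <- nchar(seqs[has])
  left <- min(anchor - 1L)
  right <- min(len - anchor - tuple_size + 1L)
  aligned <- substr(seqs[has], anchor - left,
                    anchor + tuple_size - 1L + right)
  provisional <- pfm_from_alignment(aligned, pseudocount, id = id)

  best <- best_window(seqs, provisional)
  keep <- best$score >= include_threshold - 1e-12
  if (!any(keep)) stop("no seed sequence reaches the inclusion threshold")
  final <- pfm_from_alignment(best$window[keep], pseudocount, id = id)
  final$tuple <- tuple
  final$n_input <- n
  final
}

# best-scoring window (both strands) of each sequence against a pfm;
# ties resolved leftmost, forward strand first
best_window <- function(seqs, pfm) {
  W <- pfm$width
  score <- numeric(length(seqs))
  window <- character(length(seqs))
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    wins <- kmers_of(s, W)
    wins <- c(wins, revcomp(wins))
    sc <- vapply(wins, function(x) matrix_similarity(pfm, x), numeric(1))
    j <- which.max(sc)
    score[i] <- sc[j]
    window[i] <- wins[j]
  }
  list(score = score, window = window)
}

# matrix TSV I/O -------------------------------------------------------------

#' Write a PFM to a tab-separated file
#'
#' One row per position with columns A, C, G, T holding relative frequencies.
#'
#' @param pfm a `pfm`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pfm_tsv <- function(pfm, path) {
  tab <- as.data.frame(t(pfm$f))
  write.table(format(tab, digits = 10), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a PFM from a tab-separated file
#'
#' Accepts per-position rows with columns A, C, G, T containing either
#' relative frequencies or (JASPAR-style) integer counts; counts are
#' normalized with the standard pseudocount.
#'
#' @param path input path.
#' @param id matrix identifier.
#' @param pseudocount per-base pseudocount applied when the file holds counts.
#' @return a `pfm`.
#' @export
read_pfm_tsv <- function(path, id = basename(path), pseudocount = 0.25) {
  tab <- read.delim(path, check.names = FALSE)
  stopifnot(all(DNA_BASES %in% names(tab)))
  m <- t(as.matrix(tab[, DNA_BASES]))
  if (max(m) > 1 + 1e-9) {            # count matrix
    f <- sweep(m + pseudocount, 2L, colSums(m) + 4 * pseudocount, "/")
    n_seqs <- max(colSums(m))
  } else {
    f <- sweep(m, 2L, colSums(m), "/")
    # re-regularize exact zeros so information weights stay finite
    if (any(f == 0)) f <- sweep(f + 1e-6, 2L, colSums(f) + 4e-6, "/")
    n_seqs <- NA_integer_
  }
  new_pfm(f, n_seqs = n_seqs, id = id)
}
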