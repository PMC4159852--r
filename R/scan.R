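# Promoter scanning: exhaustive sliding-window evaluation of the matrix
# similarity score on both strands of a TSS-relative window.

#' Scan promoters for matrix matches
#'
#' Slides each matrix over every position of the TSS-relative window
#' `[-upstream, +downstream)` on both strands (the minus-strand score of a
#' window is the similarity of its reverse complement) and reports every
#' placement scoring at least `threshold`. Overlapping calls are all kept.
#' Coordinates are 0-based, half-open, and reported relative to the TSS
#' (negative = upstream); a minus-strand call is reported at the forward
#' coordinates of the window it occupies.
#'
#' @param promoters a [promoter_set()].
#' @param pfms a single `pfm` or a (optionally named) list of them.
#' @param threshold minimum matrix similarity for a call (inclusive;
#'   default 0.8).
#' @param upstream,downstream extent of the scanned window around the TSS in
#'   bp (defaults 950 and 50). The window is clipped to the available
#'   sequence; an error is raised if the clipped window is shorter than the
#'   matrix.
#' @return data.frame of site calls: gene, matrix, start, end (TSS-relative,
#'   half-open), strand (`+`/`-`), score.
#' @export
scan_promoters <- function(promoters, pfms, threshold = 0.8,
                           upstream = 950, downstream = 50) {
  stopifnot(inherits(promoters, "promoter_set"))
  if (inherits(pfms, "pfm")) pfms <- list(pfms)
  ids <- vapply(seq_along(pfms), function(i)
    names(pfms)[i] %||% pfms[[i]]$id, character(1))
  if (!is.null(names(pfms)) )
    ids <- ifelse(nzchar(names(pfms)), names(pfms), ids)

  widths <- integer(length(pfms))
  mats <- vector("list", length(pfms))
  for (k in seq_along(pfms)) {
    pfm <- pfms[[k]]
    stopifnot(inherits(pfm, "pfm"))
    if (all(pfm$w < 1e-12))
      stop("zero-information matrix '", ids[k],
           "': all positions are uninformative")
    W <- pfm$width
    widths[k] <- W
    contrib <- sweep(pfm$f, 2L, pfm$w, "*")              # 4 x W, rows ACGT
    n_fwd <- apply(pfm$f, 2L, min) * pfm$w               # N contribution
    # minus-strand table: reverse positions, complement bases
    fwd <- rbind(contrib, n_fwd)
    rev_ <- rbind(contrib[4:1, W:1, drop = FALSE], rev(n_fwd))
    max_raw <- sum(pfm$w * apply(pfm$f, 2L, max))
    mats[[k]] <- list(fwd = fwd, rev = rev_,
                      min_raw = threshold * max_raw - 1e-12,
                      max_raw = max_raw)
  }

  # absolute, 0-based inclusive range of window starts per promoter
  lo <- pmax(promoters$tss - as.integer(upstream), 0L)
  hi <- pmin(promoters$tss + as.integer(downstream), nchar(promoters$seq))
  short <- hi - lo < max(widths)
  if (any(short))
    stop("scanning window shorter than the matrix width for promoter(s) ",
         paste(utils::head(promoters$gene[short], 3L), collapse = ", "))

  hits <- scan_sequences_cpp(promoters$seq, mats, lo, hi)
  W <- widths[hits$mat]
  res <- data.frame(gene = promoters$gene[hits$seq],
                    matrix = ids[hits$mat],
                    start = hits$start - promoters$tss[hits$seq],
                    end = hits$start + W - promoters$tss[hits$seq],
                    strand = c("+", "-")[hits$strand],
                    score = hits$score, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Write site calls to TSV
#'
#' @param sites site-call data.frame from [scan_promoters()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sites_tsv <- function(sites, path) {
  write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
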