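# Over-representation statistics.
#
# Site/module enrichment of a gene set against the promoter background uses
# the exact hypergeometric null of drawing n promoters from the N-promoter
# universe of which K carry the feature:
#   E  = n K / N
#   sd = sqrt( n K (N - K) (N - n) / (N^2 (N - 1)) )
#   z  = (x - E) / sd        (no continuity correction)
# |z| > 2 is the conventional significance boundary, corresponding to
# p ~ 0.05 under the normal approximation.
#
# GO term enrichment uses the upper-tail hypergeometric p with
# Benjamini-Yekutieli adjustment (valid under arbitrary dependence between
# the nested GO terms).

#' Hypergeometric z-score over-representation of promoter features
#'
#' For each logical feature column of `flags`, counts how many genes of
#' `set_genes` carry the feature and standardizes the count against the
#' hypergeometric null of drawing `length(set_genes)` promoters from the
#' universe. Features carried by no promoter or by all promoters have an
#' undefined z (sd = 0) and are reported with status `"degenerate"`.
#'
#' @param set_genes character vector of gene ids; must be a subset of the
#'   universe and neither empty nor the whole universe.
#' @param flags flag table from [build_flag_table()] (column `gene` plus
#'   logical feature columns) covering the promoter universe.
#' @return data.frame of class `enrichment_result`: feature, x, n, N, K,
#'   expected, sd, z, status.
#' @export
feature_zscore <- function(set_genes, flags) {
  set_genes <- unique(as.character(set_genes))
  stopifnot(is.data.frame(flags), "gene" %in% names(flags))
  universe <- flags$gene
  if (!all(set_genes %in% universe))
    stop("set_genes must be a subset of the flag-table universe")
  N <- length(universe)
  n <- length(set_genes)
  if (n == 0L || n == N)
    stop("the gene set must be a strict, non-empty subset of the universe")
  N <- as.numeric(N)
  n <- as.numeric(n)
  in_set <- universe %in% set_genes
  feats <- setdiff(names(flags), "gene")
  res <- lapply(feats, function(ft) {
    carrier <- as.logical(flags[[ft]])
    K <- sum(carrier)
    x <- sum(carrier & in_set)
    E <- n * K / N
    sd <- sqrt(n * K * (N - K) * (N - n) / (N^2 * (N - 1)))
    if (K == 0L || K == N) {
      data.frame(feature = ft, x = x, n = n, N = N, K = K, expected = E,
                 sd = 0, z = NA_real_, status = "degenerate",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(feature = ft, x = x, n = n, N = N, K = K, expected = E,
                 sd = sd, z = (x - E) / sd, status = "ok",
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, res)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' GO term enrichment with Benjamini-Yekutieli control
#'
#' Upper-tail hypergeometric test per term (`P(X >= x)` for `x` set genes
#' annotated to a term with `K` universe genes annotated), adjusted across
#' all tested terms with the Benjamini-Yekutieli procedure. The annotation
#' must already include the ancestor closure (a gene annotated to a term is
#' annotated to all its ancestors); see [expand_annotation()]. Terms
#' annotated to no universe gene are skipped.
#'
#' @param set_genes non-empty character vector, subset of `universe_genes`.
#' @param universe_genes character vector of background genes.
#' @param annotation data.frame with columns `gene`, `term` and optionally
#'   `name` (term description).
#' @param p_cut report terms with BY-adjusted p below this (default 0.01).
#' @param top_k keep at most this many terms, most significant first
#'   (default 20).
#' @return data.frame: term, name, x, K, n, N, p, p_by, log10_p (log10 of
#'   the adjusted p), sorted by ascending p.
#' @export
go_enrichment <- function(set_genes, universe_genes, annotation,
                          p_cut = 0.01, top_k = 20) {
  set_genes <- unique(as.character(set_genes))
  universe_genes <- unique(as.character(universe_genes))
  if (length(set_genes) == 0L) stop("empty gene set")
  if (!all(set_genes %in% universe_genes))
    stop("set_genes must be a subset of universe_genes")
  stopifnot(all(c("gene", "term") %in% names(annotation)))

  ann <- unique(annotation[annotation$gene %in% universe_genes,
                           c("gene", "term")])
  if (nrow(ann) == 0L) stop("annotation covers no universe gene")
  N <- length(universe_genes)
  n <- length(set_genes)
  K <- table(ann$term)
  x <- table(factor(ann$term[ann$gene %in% set_genes], names(K)))
  terms <- names(K)
  Kv <- as.integer(K)
  xv <- as.integer(x)
  p <- phyper(xv - 1L, Kv, N - Kv, n, lower.tail = FALSE)
  p_by <- p.adjust(p, method = "BY")

  nm <- rep(NA_character_, length(terms))
  if ("name" %in% names(annotation)) {
    lut <- unique(annotation[, c("term", "name")])
    nm <- lut$name[match(terms, lut$term)]
  }
  res <- data.frame(term = terms, name = nm, x = xv, K = Kv, n = n, N = N,
                    p = p, p_by = p_by, log10_p = log10(p_by),
                    stringsAsFactors = FALSE)
  res <- res[res$p_by < p_cut, , drop = FALSE]
  res <- res[order(res$p, res$term), , drop = FALSE]
  rownames(res) <- NULL
  utils::head(res, top_k)
}

# GO closure helpers ---------------------------------------------------------

#' Extract `is_a` edges from a minimal OBO file
#'
#' A convenience parser reading only `[Term]` stanzas with their `id:`,
#' `name:` and `is_a:` lines; sufficient to build an ancestor closure for
#' enrichment. Obsolete terms are skipped.
#'
#' @param path OBO file path.
#' @return list with `terms` (data.frame: term, name) and `edges`
#'   (data.frame: term, parent).
#' @export
read_obo_isa <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- which(lines == "[Term]")
  terms <- character(0); names_ <- character(0)
  e_child <- character(0); e_parent <- character(0)
  bounds <- c(starts, length(lines) + 1L)
  for (i in seq_along(starts)) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    if (any(block == "is_obsolete: true")) next
    id <- sub("^id: ", "", grep("^id: ", block, value = TRUE)[1])
    nm <- sub("^name: ", "", grep("^name: ", block, value = TRUE)[1])
    parents <- sub("^is_a: ([^ !]+).*$", "\\1",
                   grep("^is_a: ", block, value = TRUE))
    terms <- c(terms, id); names_ <- c(names_, nm)
    if (length(parents) > 0L) {
      e_child <- c(e_child, rep(id, length(parents)))
      e_parent <- c(e_parent, parents)
    }
  }
  list(terms = data.frame(term = terms, name = names_,
                          stringsAsFactors = FALSE),
       edges = data.frame(term = e_child, parent = e_parent,
                          stringsAsFactors = FALSE))
}

#' Reflexive-transitive ancestor closure of an `is_a` graph
#'
#' @param edges data.frame with columns `term` and `parent`.
#' @return data.frame with columns `term`, `ancestor`; every term is its own
#'   ancestor.
#' @export
term_closure <- function(edges) {
  terms <- unique(c(edges$term, edges$parent))
  up <- split(edges$parent, edges$term)
  anc <- lapply(terms, function(t) {
    seen <- character(0)
    frontier <- t
    while (length(frontier) > 0L) {
      nxt <- setdiff(unique(unlist(up[frontier], use.names = FALSE)), seen)
      seen <- c(seen, frontier[!frontier %in% seen])
      frontier <- nxt
    }
    seen
  })
  data.frame(term = rep(terms, lengths(anc)),
             ancestor = unlist(anc, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Expand a gene-to-term annotation with an ancestor closure
#'
#' @param gene2term data.frame with columns `gene` and `term` (direct
#'   annotations).
#' @param closure closure table from [term_closure()] (columns `term`,
#'   `ancestor`).
#' @return data.frame with columns `gene`, `term` containing direct and
#'   inherited annotations, deduplicated.
#' @export
expand_annotation <- function(gene2term, closure) {
  merged <- merge(gene2term[, c("gene", "term")], closure, by = "term")
  out <- unique(data.frame(gene = merged$gene, term = merged$ancestor,
                           stringsAsFactors = FALSE))
  out[order(out$gene, out$term), , drop = FALSE]
}
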