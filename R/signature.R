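# Cross-cohort gene signature: intersection of up-regulated gene lists,
# localization / prior-knowledge annotation, and a links-file export usable
# by external circular-plot tools.

normalize_symbols <- function(x) unique(toupper(trimws(as.character(x))))

#' Intersect up-regulated gene lists across datasets
#'
#' Returns the gene symbols present in every list (exact symbol match after
#' upper-casing and deduplication), sorted. Intersection is commutative and
#' associative in the input order.
#'
#' @param lists a list of two or more character vectors of gene symbols.
#' @return sorted character vector: the signature members.
#' @export
intersect_signatures <- function(lists) {
  if (!is.list(lists) || length(lists) < 2L)
    stop("need at least two gene lists")
  sets <- lapply(lists, normalize_symbols)
  sort(Reduce(intersect, sets))
}

#' Annotate a gene signature
#'
#' Fills localization, known-STAT1-regulation and atherosclerosis-link fields
#' from user-supplied tables keyed by gene symbol (case-insensitive); genes
#' absent from a table get `"unknown"` / `FALSE`. Annotation never alters
#' membership. Per-localization counts are attached as attribute `counts`.
#'
#' @param genes character vector of signature members (see
#'   [intersect_signatures()]).
#' @param localization optional data.frame with columns `gene` and
#'   `localization` (values such as secreted / membrane / intracellular).
#' @param stat1 optional data.frame with columns `gene`,
#'   `known_stat1_regulation` (logical or yes/no) and optionally `citation`.
#' @param athero optional data.frame with columns `gene` and `athero_link`
#'   (logical or yes/no).
#' @param flags optional flag table from [build_flag_table()]; its feature
#'   columns are joined onto the signature.
#' @return data.frame of class `gene_signature`: gene, localization,
#'   known_stat1_regulation, citation, athero_link, plus any flag columns.
#' @export
annotate_signature <- function(genes, localization = NULL, stat1 = NULL,
                               athero = NULL, flags = NULL) {
  genes <- sort(normalize_symbols(genes))
  k <- length(genes)
  sig <- data.frame(gene = genes, localization = rep("unknown", k),
                    known_stat1_regulation = rep(FALSE, k),
                    citation = rep(NA_character_, k),
                    athero_link = rep(FALSE, k), stringsAsFactors = FALSE)
  as_flag <- function(v) {
    if (is.logical(v)) return(v)
    tolower(as.character(v)) %in% c("true", "yes", "+", "1")
  }
  if (!is.null(localization)) {
    i <- match(sig$gene, toupper(localization$gene))
    sig$localization <- ifelse(is.na(i), "unknown",
                               as.character(localization$localization)[i])
  }
  if (!is.null(stat1)) {
    i <- match(sig$gene, toupper(stat1$gene))
    sig$known_stat1_regulation <-
      !is.na(i) & as_flag(stat1$known_stat1_regulation)[ifelse(is.na(i), 1L, i)]
    if ("citation" %in% names(stat1))
      sig$citation <- ifelse(is.na(i), NA_character_,
                             as.character(stat1$citation)[i])
  }
  if (!is.null(athero)) {
    i <- match(sig$gene, toupper(athero$gene))
    sig$athero_link <-
      !is.na(i) & as_flag(athero$athero_link)[ifelse(is.na(i), 1L, i)]
  }
  if (!is.null(flags)) {
    i <- match(sig$gene, toupper(flags$gene))
    for (j in setdiff(names(flags), "gene"))
      sig[[j]] <- ifelse(is.na(i), FALSE, flags[[j]][i])
  }
  attr(sig, "counts") <- table(sig$localization)
  class(sig) <- c("gene_signature", "data.frame")
  sig
}

#' Export a signature links file
#'
#' One row per gene with symbol, localization and a ribbon weight (`wide`
#' for genes with a literature-supported atherosclerosis link, `narrow`
#' otherwise) — a tabular stand-in renderable by external circular-plot
#' tools. An empty signature produces a header-only file.
#'
#' @param signature an [annotate_signature()] result.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
export_links <- function(signature, path) {
  stopifnot(inherits(signature, "gene_signature"))
  links <- data.frame(gene = signature$gene,
                      localization = signature$localization,
                      weight = ifelse(signature$athero_link, "wide",
                                      "narrow"),
                      stringsAsFactors = FALSE)
  write.table(links, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("Gene signature: %d member(s)\n", nrow(x)))
  cnt <- attr(x, "counts")
  if (!is.null(cnt) && length(cnt) > 0)
    cat("localization:",
        paste(sprintf("%s=%d", names(cnt), as.integer(cnt)),
              collapse = ", "), "\n")
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more rows\n")
  invisible(x)
}
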