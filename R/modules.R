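# Composite cis-regulatory modules: pairs of site calls of two disjoint
# classes within a bounded edge-to-edge distance on the same promoter.

#' Specification of a composite module
#'
#' @param stat1 matrix ids accepted as the STAT1 element (default both GAS
#'   and ISRE, which STAT1-containing complexes can bind; set to `"GAS"` for
#'   a GAS-only definition).
#' @param partner matrix ids accepted as the partner element (NFKB or IRF).
#' @param max_gap maximum inter-site gap in bp, measured between the nearest
#'   edges of the two site intervals (default 50; overlapping sites have
#'   gap 0).
#' @param name module label used in flag tables.
#' @return a `module_spec` list.
#' @export
module_spec <- function(stat1 = c("GAS", "ISRE"), partner, max_gap = 50,
                        name = paste0("STAT1-", partner[1])) {
  stopifnot(max_gap >= 0, length(partner) >= 1)
  if (length(intersect(stat1, partner)) > 0)
    stop("STAT1 and partner matrix classes must be disjoint")
  structure(list(stat1 = stat1, partner = partner,
                 max_gap = as.integer(max_gap), name = name),
            class = "module_spec")
}

#' Detect composite modules from site calls
#'
#' Emits every pair of an A-class (STAT1) and a B-class (partner) site on the
#' same promoter whose edge-to-edge gap `max(0, nearest-edge distance)` does
#' not exceed `spec$max_gap`. Order (which element lies upstream) and strands
#' are ignored; the gap rule is symmetric in the two classes.
#'
#' @param sites site-call data.frame from [scan_promoters()].
#' @param spec a [module_spec()].
#' @return data.frame of module calls: gene, module, stat1_matrix,
#'   stat1_start, stat1_end, partner_matrix, partner_start, partner_end, gap.
#' @export
detect_modules <- function(sites, spec) {
  stopifnot(inherits(spec, "module_spec"))
  a <- sites[sites$matrix %in% spec$stat1, , drop = FALSE]
  b <- sites[sites$matrix %in% spec$partner, , drop = FALSE]
  empty <- data.frame(gene = character(0), module = character(0),
                      stat1_matrix = character(0), stat1_start = integer(0),
                      stat1_end = integer(0), partner_matrix = character(0),
                      partner_start = integer(0), partner_end = integer(0),
                      gap = integer(0), stringsAsFactors = FALSE)
  if (nrow(a) == 0L || nrow(b) == 0L) return(empty)
  names(a) <- paste0("a_", names(a))
  names(b) <- paste0("b_", names(b))
  pairs <- merge(a, b, by.x = "a_gene", by.y = "b_gene")
  if (nrow(pairs) == 0L) return(empty)
  gap <- pmax(0L, pmax(pairs$b_start - pairs$a_end,
                       pairs$a_start - pairs$b_end))
  keep <- gap <= spec$max_gap
  res <- data.frame(gene = pairs$a_gene[keep],
                    module = rep(spec$name, sum(keep)),
                    stat1_matrix = pairs$a_matrix[keep],
                    stat1_start = pairs$a_start[keep],
                    stat1_end = pairs$a_end[keep],
                    partner_matrix = pairs$b_matrix[keep],
                    partner_start = pairs$b_start[keep],
                    partner_end = pairs$b_end[keep],
                    gap = gap[keep], stringsAsFactors = FALSE)
  res[order(res$gene, res$stat1_start, res$partner_start), , drop = FALSE]
}

#' Per-gene presence flags for sites and modules
#'
#' One row per gene with a logical column per matrix id and per module name;
#' a flag is TRUE iff at least one corresponding site or module call exists.
#' Rows are ordered lexicographically by gene id. Genes from the universe
#' that have no site call at all are flagged all-FALSE; their count is
#' reported in a single consolidated warning.
#'
#' @param sites site-call data.frame covering all scanned matrices.
#' @param modules a module-call data.frame from [detect_modules()], or a
#'   list of them.
#' @param genes character vector: the promoter universe (row set of the
#'   table). Defaults to the genes present in `sites`.
#' @return data.frame: `gene` plus one logical column per feature.
#' @export
build_flag_table <- function(sites, modules = list(),
                             genes = sort(unique(sites$gene))) {
  if (is.data.frame(modules)) modules <- list(modules)
  genes <- sort(unique(as.character(genes)))
  tab <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (m in sort(unique(sites$matrix)))
    tab[[m]] <- genes %in% sites$gene[sites$matrix == m]
  for (i in seq_along(modules)) {
    mod <- modules[[i]]
    nm <- names(modules)[i]
    if (is.null(nm) || !nzchar(nm))
      nm <- if (nrow(mod) > 0L) mod$module[1] else paste0("module", i)
    tab[[nm]] <- genes %in% mod$gene
  }
  missing <- setdiff(genes, unique(sites$gene))
  if (length(missing) > 0L)
    warning(length(missing),
            " gene(s) in the universe have no site call; flagged all-FALSE")
  rownames(tab) <- NULL
  tab
}

#' Format a flag table with +/- cells
#'
#' Converts the logical columns of a [build_flag_table()] result to the
#' `+`/`-` notation used in published module-presence tables.
#'
#' @param flags flag table.
#' @return data.frame with `+`/`-` character cells.
#' @export
format_flag_table <- function(flags) {
  out <- flags
  for (j in setdiff(names(out), "gene"))
    out[[j]] <- ifelse(out[[j]], "+", "-")
  out
}
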