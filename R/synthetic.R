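# Synthetic data with planted ground truth.
#
# Two generators: expression matrices with planted fold changes and additive
# batch shifts, and promoter universes with planted GAS/ISRE/NFkB/IRF site
# instances and composite modules at controlled rates and spacings. Every
# planted feature is recorded in a truth manifest so downstream stages can be
# validated without external data.

#' Configuration for the expression-matrix simulator
#'
#' Defaults emulate a two-group (lesion vs control tissue) microarray design
#' on the log2 scale: 1000 genes, 10 samples per group in 2 balanced batches,
#' 10% of genes up-regulated four-fold (log2 fold change 2) with Gaussian
#' log-scale noise of SD 0.5.
#'
#' @param n_genes number of genes.
#' @param n_samples_per_group samples in each of the two condition groups.
#' @param n_batches number of batches; samples are assigned round-robin
#'   within each group so batches stay balanced across conditions.
#' @param de_fraction fraction of genes that are differentially expressed
#'   (up-regulated in the case group).
#' @param de_log2fc planted log2 fold change of DE genes (case minus control).
#' @param noise_sd SD of i.i.d. Gaussian noise on the log2 scale.
#' @param batch_shift_sd SD of the additive per-gene, per-batch shift.
#' @param baseline_mean,baseline_sd mean/SD of per-gene baseline log2 levels.
#' @param seed integer seed; identical seeds give identical output.
#' @return an `expression_sim_config` list.
#' @export
expression_sim_config <- function(n_genes = 1000, n_samples_per_group = 10,
                                  n_batches = 2, de_fraction = 0.1,
                                  de_log2fc = 2, noise_sd = 0.5,
                                  batch_shift_sd = 0.3, baseline_mean = 8,
                                  baseline_sd = 1.5, seed = 1) {
  stopifnot(n_genes >= 1, n_samples_per_group >= 1, n_batches >= 1,
            de_fraction >= 0, de_fraction <= 1, noise_sd > 0,
            batch_shift_sd >= 0)
  structure(list(n_genes = as.integer(n_genes),
                 n_samples_per_group = as.integer(n_samples_per_group),
                 n_batches = as.integer(n_batches),
                 de_fraction = de_fraction, de_log2fc = de_log2fc,
                 noise_sd = noise_sd, batch_shift_sd = batch_shift_sd,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 seed = as.integer(seed)),
            class = "expression_sim_config")
}

#' Simulate a two-group expression matrix with planted fold changes
#'
#' Per gene g and sample s the simulated log2 intensity is
#' `baseline_g + de_g * I(s in case) + shift_{g, batch(s)} + noise`.
#' DE genes are a random subset of size `round(de_fraction * n_genes)`; their
#' case-group mean exceeds the control mean by `de_log2fc` in expectation.
#' Batch shifts are additive per gene x batch and balanced across groups, so
#' they cancel from the group contrast when group sizes divide the batch
#' count evenly.
#'
#' @param config an [expression_sim_config()].
#' @return list with `values` (genes x samples log2 matrix), `samples`
#'   (data.frame: sample, group, batch), and `truth` (data.frame: gene, de,
#'   log2fc).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "expression_sim_config"))
  set.seed(config$seed)
  ng <- config$n_genes
  np <- config$n_samples_per_group
  genes <- sprintf("gene%05d", seq_len(ng))
  samples <- data.frame(
    sample = c(sprintf("ctrl%02d", seq_len(np)), sprintf("case%02d", seq_len(np))),
    group = rep(c("control", "case"), each = np),
    batch = rep(rep_len(seq_len(config$n_batches), np), 2L),
    stringsAsFactors = FALSE)

  n_de <- round(config$de_fraction * ng)
  de_idx <- if (n_de > 0) sort(sample.int(ng, n_de)) else integer(0)
  de <- logical(ng); de[de_idx] <- TRUE

  baseline <- rnorm(ng, config$baseline_mean, config$baseline_sd)
  shift <- matrix(rnorm(ng * config$n_batches, 0, config$batch_shift_sd),
                  nrow = ng)
  if (config$n_batches == 1L) shift[] <- 0

  values <- matrix(rnorm(ng * 2L * np, 0, config$noise_sd), nrow = ng,
                   dimnames = list(genes, samples$sample))
  values <- values + baseline
  values <- values + shift[, samples$batch, drop = FALSE]
  case_cols <- samples$group == "case"
  values[de, case_cols] <- values[de, case_cols] + config$de_log2fc

  truth <- data.frame(gene = genes, de = de,
                      log2fc = ifelse(de, config$de_log2fc, 0),
                      stringsAsFactors = FALSE)
  list(values = values, samples = samples, truth = truth)
}

#' Default motif consensus strings
#'
#' Reads the editable consensus fixture shipped with the package: one row per
#' motif class (GAS, ISRE, NFKB, IRF) with a concrete consensus string used
#' for exact-instance planting.
#'
#' @param path optional path to an alternative two-column TSV
#'   (`class`, `consensus`).
#' @return named character vector of consensus strings.
#' @export
default_motif_consensus <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "motifs", "consensus.tsv",
                        package = "stat1mod", mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(toupper(tab$consensus), tab$class)
}

#' Configuration for the promoter-universe simulator
#'
#' Defaults emulate the study design used throughout the package's validation:
#' 5000 promoters of 2 kb (TSS at offset 1500, i.e. 1.5 kb upstream and 0.5 kb
#' downstream retrieved), i.i.d. background bases at 45% GC, per-class single
#' sites planted at 5% per promoter, and a composite STAT1-partner module
#' planted in 40% of a designated 100-promoter target set versus 5% of the
#' background. All planting happens inside the scanning window so planted
#' structure is recoverable.
#'
#' @param n_promoters number of promoters in the universe.
#' @param length promoter length in bp.
#' @param tss_offset 0-based index of the TSS within each sequence.
#' @param gc_content background GC proportion (i.i.d. base model).
#' @param site_rates named per-class planting probability for single sites.
#' @param module_fraction_target_set,module_fraction_background probability of
#'   planting one composite module in target-set / background promoters.
#' @param module_gap_range integer interval (bp) the planted inter-site gap is
#'   drawn from, edge to edge.
#' @param target_set_size number of promoters (the first ones) in the
#'   designated target set.
#' @param module_stat1_class,module_partner_class motif classes used for the
#'   planted module's STAT1 element and partner element.
#' @param plant_window TSS-relative half-open interval `c(from, to)` inside
#'   which sites are planted; defaults to the scanning window −950..+50.
#' @param consensus named consensus strings, see [default_motif_consensus()].
#' @param site_mutations number of random point mutations applied to each
#'   planted instance (0 = exact consensus).
#' @param seed integer seed.
#' @return a `promoter_sim_config` list.
#' @export
promoter_sim_config <- function(n_promoters = 5000, length = 2000,
                                tss_offset = 1500, gc_content = 0.45,
                                site_rates = c(GAS = 0.05, ISRE = 0.05,
                                               NFKB = 0.05, IRF = 0.05),
                                module_fraction_target_set = 0.4,
                                module_fraction_background = 0.05,
                                module_gap_range = c(5L, 50L),
                                target_set_size = 100,
                                module_stat1_class = "GAS",
                                module_partner_class = "NFKB",
                                plant_window = c(-950L, 50L),
                                consensus = default_motif_consensus(),
                                site_mutations = 0L, seed = 1) {
  stopifnot(n_promoters >= 1, length >= 1,
            tss_offset >= 0, tss_offset < length,
            gc_content >= 0, gc_content <= 1,
            all(site_rates >= 0), all(site_rates <= 1),
            module_fraction_target_set >= 0, module_fraction_target_set <= 1,
            module_fraction_background >= 0, module_fraction_background <= 1,
            length(module_gap_range) == 2L, module_gap_range[1] >= 0,
            module_gap_range[2] >= module_gap_range[1],
            target_set_size >= 0, target_set_size <= n_promoters,
            site_mutations >= 0)
  stopifnot(all(names(site_rates) %in% names(consensus)),
            module_stat1_class %in% names(consensus),
            module_partner_class %in% names(consensus))
  win <- tss_offset + plant_window
  if (win[1] < 0 || win[2] > length)
    stop("plant_window does not fit inside the promoter sequence")
  structure(list(n_promoters = as.integer(n_promoters),
                 length = as.integer(length),
                 tss_offset = as.integer(tss_offset),
                 gc_content = gc_content, site_rates = site_rates,
                 module_fraction_target_set = module_fraction_target_set,
                 module_fraction_background = module_fraction_background,
                 module_gap_range = as.integer(module_gap_range),
                 target_set_size = as.integer(target_set_size),
                 module_stat1_class = module_stat1_class,
                 module_partner_class = module_partner_class,
                 plant_window = as.integer(plant_window),
                 consensus = consensus,
                 site_mutations = as.integer(site_mutations),
                 seed = as.integer(seed)),
            class = "promoter_sim_config")
}

#' A set of promoter sequences with TSS offsets
#'
#' @param gene character gene/promoter identifiers (unique).
#' @param seq DNA sequences over A/C/G/T/N (upper-cased on input).
#' @param tss 0-based index of the TSS within each sequence.
#' @return data.frame of class `promoter_set` with columns gene, seq, tss.
#' @export
promoter_set <- function(gene, seq, tss) {
  seq <- toupper(seq)
  stopifnot(length(gene) == length(seq), length(tss) == length(seq),
            !anyDuplicated(gene),
            !grepl("[^ACGTN]", paste(seq, collapse = "")),
            all(tss >= 0), all(tss < nchar(seq)))
  new_promoter_set(as.character(gene), seq, as.integer(tss))
}

# internal constructor without validation (inputs known well-formed)
new_promoter_set <- function(gene, seq, tss) {
  structure(data.frame(gene = unname(gene), seq = unname(seq),
                       tss = unname(tss), row.names = NULL,
                       stringsAsFactors = FALSE),
            class = c("promoter_set", "data.frame"))
}

# draw a random DNA string of total length n at the given GC content
random_dna <- function(n, gc_content) {
  prob <- c((1 - gc_content) / 2, gc_content / 2, gc_content / 2,
            (1 - gc_content) / 2)
  intToUtf8(c(65L, 67L, 71L, 84L)[sample.int(4L, n, replace = TRUE,
                                             prob = prob)])
}

mutate_string <- function(s, k) {
  if (k <= 0) return(s)
  ch <- strsplit(s, "")[[1]]
  pos <- sample.int(length(ch), min(k, length(ch)))
  for (p in pos) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
  paste(ch, collapse = "")
}

# sample a 1-based start for an interval of width w inside [lo, hi] (1-based,
# inclusive) that does not overlap any interval in `taken` (2-column matrix);
# returns NA when no placement is found
place_interval <- function(w, lo, hi, taken, tries = 200L) {
  if (hi - w + 1L < lo) return(NA_integer_)
  cand <- lo:(hi - w + 1L)
  for (i in seq_len(tries)) {
    st <- cand[sample.int(length(cand), 1L)]
    en <- st + w - 1L
    if (nrow(taken) == 0L || all(en < taken[, 1] | st > taken[, 2]))
      return(st)
  }
  NA_integer_
}

#' Simulate a promoter universe with planted sites and modules
#'
#' Background bases are i.i.d. at the configured GC content. Planted single
#' sites and composite modules are exact consensus strings (optionally
#' mutated), placed on a random strand inside the plant window by rejection
#' sampling so planted features never overlap. Composite modules consist of a
#' STAT1-class element and a partner element separated edge-to-edge by a gap
#' drawn uniformly from `module_gap_range`, in random order.
#'
#' @param config a [promoter_sim_config()].
#' @return list with `promoters` (a [promoter_set()]) and `truth`, itself a
#'   list of `promoters` (promoter, target_set, module), `sites` (one row per
#'   planted instance: promoter, class, start, end, rel_start, strand, seq,
#'   in_module), and `modules` (promoter, stat1_class, partner_class, gap).
#'   Coordinates are 0-based half-open; `rel_start` is TSS-relative.
#' @export
simulate_promoters <- function(config) {
  stopifnot(inherits(config, "promoter_sim_config"))
  set.seed(config$seed)
  n <- config$n_promoters
  len <- config$length
  tss <- config$tss_offset
  ids <- sprintf("g%05d", seq_len(n))

  all_bases <- random_dna(n * len, config$gc_content)
  starts <- (seq_len(n) - 1L) * len + 1L
  seqs <- substring(all_bases, starts, starts + len - 1L)

  is_target <- seq_len(n) <= config$target_set_size
  p_mod <- ifelse(is_target, config$module_fraction_target_set,
                  config$module_fraction_background)
  has_module <- runif(n) < p_mod
  classes <- names(config$site_rates)
  single <- vapply(classes, function(cl) runif(n) < config$site_rates[[cl]],
                   logical(n))
  if (n == 1L) single <- matrix(single, nrow = 1L,
                                dimnames = list(NULL, classes))

  # 1-based inclusive planting bounds
  lo <- tss + config$plant_window[1] + 1L
  hi <- tss + config$plant_window[2]

  # flat accumulators for planted sites (1-based starts) and modules
  sp_prom <- integer(0); sp_class <- character(0)
  sp_start1 <- integer(0); sp_width <- integer(0); sp_inmod <- logical(0)
  md_prom <- integer(0); md_gap <- integer(0)
  ca <- config$module_stat1_class
  cb <- config$module_partner_class
  wa <- nchar(config$consensus[[ca]])
  wb <- nchar(config$consensus[[cb]])
  gaps <- config$module_gap_range[1]:config$module_gap_range[2]
  widths <- vapply(config$consensus, nchar, integer(1))

  need <- which(has_module | rowSums(single) > 0)
  for (i in need) {
    taken <- matrix(integer(0), ncol = 2L)
    if (has_module[i]) {
      gap <- gaps[sample.int(length(gaps), 1L)]
      span <- wa + gap + wb
      if (hi - lo + 1L < span)
        stop("planted module span (", span,
             " bp) exceeds the available plant window")
      st <- place_interval(span, lo, hi, taken)
      first_a <- runif(1) < 0.5
      sa <- if (first_a) st else st + wb + gap
      sb <- if (first_a) st + wa + gap else st
      taken <- rbind(taken, c(st, st + span - 1L))
      sp_prom <- c(sp_prom, i, i); sp_class <- c(sp_class, ca, cb)
      sp_start1 <- c(sp_start1, sa, sb); sp_width <- c(sp_width, wa, wb)
      sp_inmod <- c(sp_inmod, TRUE, TRUE)
      md_prom <- c(md_prom, i); md_gap <- c(md_gap, gap)
    }
    for (cl in classes[single[i, ]]) {
      wc <- widths[[cl]]
      st <- place_interval(wc, lo, hi, taken)
      if (is.na(st)) next  # window saturated; skip this single site
      taken <- rbind(taken, c(st, st + wc - 1L))
      sp_prom <- c(sp_prom, i); sp_class <- c(sp_class, cl)
      sp_start1 <- c(sp_start1, st); sp_width <- c(sp_width, wc)
      sp_inmod <- c(sp_inmod, FALSE)
    }
  }

  sites <- if (length(sp_prom) > 0L)
    data.frame(promoter = ids[sp_prom], class = sp_class,
               start1 = sp_start1, width = sp_width, in_module = sp_inmod,
               stringsAsFactors = FALSE) else NULL
  if (is.null(sites)) {
    sites <- data.frame(promoter = character(0), class = character(0),
                        start = integer(0), end = integer(0),
                        rel_start = integer(0), strand = character(0),
                        seq = character(0), in_module = logical(0),
                        stringsAsFactors = FALSE)
  } else {
    ns <- nrow(sites)
    strand <- ifelse(runif(ns) < 0.5, "+", "-")
    planted <- unname(config$consensus[sites$class])
    if (config$site_mutations > 0L)
      planted <- vapply(planted, mutate_string, character(1),
                        k = config$site_mutations)
    minus <- strand == "-"
    if (any(minus)) planted[minus] <- revcomp(planted[minus])
    idx <- match(sites$promoter, ids)
    for (k in seq_len(ns)) {
      i <- idx[k]
      substr(seqs[i], sites$start1[k], sites$start1[k] + sites$width[k] - 1L) <-
        planted[k]
    }
    sites <- data.frame(promoter = sites$promoter, class = sites$class,
                        start = sites$start1 - 1L,
                        end = sites$start1 - 1L + sites$width,
                        rel_start = sites$start1 - 1L - tss,
                        strand = strand, seq = planted,
                        in_module = sites$in_module, stringsAsFactors = FALSE)
  }
  modules <- data.frame(promoter = ids[md_prom],
                        stat1_class = rep(ca, length(md_prom)),
                        partner_class = rep(cb, length(md_prom)),
                        gap = md_gap, stringsAsFactors = FALSE)

  truth <- list(
    promoters = data.frame(promoter = ids, target_set = is_target,
                           module = has_module, stringsAsFactors = FALSE),
    sites = sites, modules = modules)
  list(promoters = new_promoter_set(ids, seqs, rep(tss, n)), truth = truth)
}

# I/O ------------------------------------------------------------------------

#' Write promoters to FASTA with TSS offsets in the headers
#'
#' Headers have the form `>geneID tss=<offset>`; output is deterministic for
#' a fixed promoter set.
#'
#' @param promoters a [promoter_set()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_promoters_fasta <- function(promoters, path) {
  stopifnot(inherits(promoters, "promoter_set"))
  x <- Biostrings::DNAStringSet(promoters$seq)
  names(x) <- sprintf("%s tss=%d", promoters$gene, promoters$tss)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Read promoters from FASTA with `tss=` headers
#'
#' @param path FASTA path; record headers must be `>geneID tss=<offset>`.
#' @return a [promoter_set()].
#' @export
read_promoters_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  hdr <- names(x)
  gene <- sub("\\s.*$", "", hdr)
  m <- regmatches(hdr, regexpr("tss=\\d+", hdr))
  if (length(m) != length(hdr))
    stop("every FASTA header must carry a 'tss=<offset>' field")
  promoter_set(gene, as.character(x), as.integer(sub("tss=", "", m)))
}

#' Write a simulated expression experiment as TSV files
#'
#' Emits `matrix.tsv` (first column `feature`, one column per sample),
#' `samples.tsv` (sample, group, batch), and `truth.tsv` in `dir`.
#'
#' @param sim result of [simulate_expression()].
#' @param dir output directory (created if missing).
#' @return character vector of the three paths, invisibly.
#' @export
write_expression_tsv <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("matrix.tsv", "samples.tsv", "truth.tsv"))
  mat <- data.frame(feature = rownames(sim$values), sim$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(mat, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$samples, paths[2], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$truth, paths[3], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

#' Read an expression matrix TSV
#'
#' First column is the feature id, remaining columns are samples.
#'
#' @param path TSV path.
#' @return numeric matrix with feature rownames.
#' @export
read_expression_tsv <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  m
}
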