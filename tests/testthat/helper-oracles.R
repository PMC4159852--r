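# Shared fixtures and independent oracles for the test suite.

# The four shipped seed-derived matrices, built once per test run.
seed_pfms <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      classes <- c("GAS", "ISRE", "NFKB", "IRF")
      cache <<- lapply(classes, function(cl) {
        fa <- system.file("extdata", "motifs", paste0(cl, "_seeds.fa"),
                          package = "stat1mod", mustWork = TRUE)
        build_matrix_from_seeds(Biostrings::readDNAStringSet(fa), id = cl)
      })
      names(cache) <<- classes
    }
    cache
  }
})

# Exhaustive-enumeration oracle for the hypergeometric z moments: mean and
# population SD of the carrier count over every C(N, n) equally likely draw.
enum_count_moments <- function(carrier, n) {
  sets <- utils::combn(length(carrier), n)
  xs <- colSums(matrix(carrier[sets], nrow = n))
  m <- mean(xs)
  c(mean = m, sd = sqrt(mean((xs - m)^2)))
}

# A random PFM built the way users build them: from a handful of random
# equal-length sequences (guaranteeing valid frequencies and positive
# information content almost surely).
random_pfm <- function(width = sample(6:12, 1), n_seqs = 8, id = "rnd") {
  seqs <- vapply(seq_len(n_seqs), function(i)
    paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
          collapse = ""), character(1))
  pfm_from_alignment(seqs, id = id)
}

random_dna_string <- function(width) {
  paste(sample(c("A", "C", "G", "T"), width, replace = TRUE), collapse = "")
}

# Reference (pure R) scan: score every window of every promoter on both
# strands with matrix_similarity; independent of the compiled kernel.
reference_scan <- function(promoters, pfm, threshold, upstream = 950,
                           downstream = 50) {
  out <- list()
  for (i in seq_len(nrow(promoters))) {
    s <- promoters$seq[i]
    tss <- promoters$tss[i]
    a <- max(tss - upstream, 0L)
    b <- min(tss + downstream, nchar(s))
    for (p in a:(b - pfm$width)) {
      win <- substr(s, p + 1L, p + pfm$width)
      for (st in c("+", "-")) {
        sc <- matrix_similarity(pfm, if (st == "+") win else revcomp(win))
        if (sc >= threshold - 1e-12)
          out[[length(out) + 1L]] <- data.frame(
            gene = promoters$gene[i], start = p - tss,
            end = p + pfm$width - tss, strand = st, score = sc,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(gene = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      score = numeric(0)))
  do.call(rbind, out)
}

# Toy GO world: `n_terms` terms over a universe, term k annotating a random
# gene subset; returns the annotation table (already closed: flat ontology).
toy_go_annotation <- function(universe, n_terms = 10, k_per_term = 50) {
  do.call(rbind, lapply(seq_len(n_terms), function(t)
    data.frame(gene = sample(universe, k_per_term),
               term = sprintf("GO:%07d", t),
               name = sprintf("process %d", t), stringsAsFactors = FALSE)))
}

expect_sorted_desc <- function(x) expect_true(all(diff(x) <= 0))
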