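# Small in-code builders and independent oracles shared across test files.

make_genes <- function(gene_id, scaffold, start, end, strand = "+",
                       category = "Unknown") {
  tibble::tibble(gene_id = gene_id, scaffold = scaffold, start = start,
                 end = end, strand = strand, category = category)
}

make_peaks <- function(scaffold, start, end, e_value = 1e-10, read_count = 10,
                       condition = "P7", peak_id = NULL) {
  n <- length(start)
  tibble::tibble(
    peak_id = peak_id %||% sprintf("pk_%02d", seq_len(n)),
    scaffold = scaffold, start = start, end = end,
    e_value = rep_len(e_value, n), read_count = rep_len(read_count, n),
    condition = condition)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_dna <- function(n, at = 0.5) {
  paste(sample(c("A", "T", "C", "G"), n, replace = TRUE,
               prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)),
        collapse = "")
}

# Brute-force tandem-repeat oracle: O(n^2 k) enumeration, independent of the
# run-length implementation. A hit starts at s (0-based) if the period-k
# relation fails just before s (or s is at the sequence start), the unit is
# primitive and unambiguous, and at least min_copies complete units follow.
naive_find_repeats <- function(seq, k_min = 2, k_max = 5,
                               min_copies = h4map::default_min_copies()) {
  seq <- toupper(seq)
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  hits <- list()
  for (k in k_min:k_max) {
    mc <- unname(min_copies[as.character(k)])
    if (is.na(mc) || n < k * mc) next
    for (s in 0:(n - k * mc)) {
      if (s > 0 && chars[s] == chars[s + k]) next  # not a run start
      unit <- substr(seq, s + 1, s + k)
      if (grepl("[^ACGT]", unit)) next
      primitive <- TRUE
      for (d in seq_len(k - 1)) {
        if (k %% d == 0 && strrep(substr(unit, 1, d), k / d) == unit) {
          primitive <- FALSE
        }
      }
      if (!primitive) next
      # extend the periodicity as far as it holds
      len <- k
      while (s + len < n && chars[s + len - k + 1] == chars[s + len + 1]) {
        len <- len + 1
      }
      copies <- len %/% k
      if (copies < mc) next
      hits[[length(hits) + 1]] <- data.frame(
        unit = unit, start = s, copies = copies,
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0) {
    return(data.frame(unit = character(), start = integer(),
                      copies = integer()))
  }
  out <- do.call(rbind, hits)
  out[order(out$start, nchar(out$unit)), , drop = FALSE]
}

# Textbook Pearson chi-square on a contingency table.
naive_chisq_stat <- function(tab) {
  tab <- as.matrix(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - expected)^2 / expected)
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "h4map", mustWork = TRUE)
}

# Naive interval logic for locality: overlap -> GB, else side vs strand.
naive_locality <- function(ps, pe, gs, ge, strand) {
  if (ps < ge && gs < pe) return("GB")
  left <- pe <= gs
  if (strand == "+") {
    if (left) "UP" else "DOWN"
  } else {
    if (left) "DOWN" else "UP"
  }
}

small_sim_config <- function(seed, ...) {
  base <- list(
    seed = seed,
    n_scaffolds = 6L, n_characterized_lgs = 4L,
    scaffold_length = 80000L, n_genes_per_scaffold = 12L,
    n_specific_peaks = 12L, n_shared_peaks = 4L, n_core_targets = 5L,
    n_transcripts = 400L, zero_fpkm_fraction = 0.25,
    n_deg_parasitism = 40L, n_deg_viral = 30L, n_deg_common = 10L,
    fpkm_noise_cv = 0)
  do.call(h4map::sim_config, utils::modifyList(base, list(...)))
}
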