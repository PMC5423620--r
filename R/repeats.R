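# Joining-site sequence characterization: AT content, maximal short tandem
# repeat detection (unit lengths 2-5), rotation-canonical motif classes, and
# the repeat-class by regulation-direction cross-tabulation.

#' AT content of a nucleotide sequence
#'
#' `(A + T) / (A + C + G + T)`, case-insensitive. Ambiguity codes (N, Y, ...)
#' are excluded from both numerator and denominator; a sequence with no
#' unambiguous base has no defined AT content and raises an error.
#'
#' @param seq A nucleotide string.
#' @return A value in `[0, 1]`; `at_content(s) + gc_content(s) == 1` for
#'   unambiguous `s`.
#' @examples
#' at_content("ATAT") # 1
#' at_content("ACGT") # 0.5
#' @export
at_content <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n_at <- sum(chars %in% c("A", "T"))
  n_acgt <- sum(chars %in% c("A", "C", "G", "T"))
  if (n_acgt == 0) {
    abort("AT content undefined: no unambiguous bases",
          class = "h4map_domain_error")
  }
  n_at / n_acgt
}

#' @rdname at_content
#' @export
gc_content <- function(seq) 1 - at_content(seq)

#' Default minimum copy numbers per unit length
#'
#' Dinucleotide runs must reach 5 copies, trinucleotide 4, tetra- and
#' pentanucleotide 3. These floors keep chance hits in random AT-rich
#' sequence rare while admitting the motif run lengths seen in joining-site
#' alignments; they are configuration, not biology, and are echoed in output
#' headers.
#'
#' @return A named integer vector keyed by unit length `"2"`..`"5"`.
#' @export
default_min_copies <- function() c(`2` = 5L, `3` = 4L, `4` = 3L, `5` = 3L)

# TRUE when the unit is not a power of a shorter unit ("AGAG" -> FALSE).
is_primitive_unit <- function(unit) {
  k <- nchar(unit)
  for (d in seq_len(k - 1)) {
    if (k %% d == 0 &&
        strrep(substr(unit, 1, d), k / d) == unit) {
      return(FALSE)
    }
  }
  TRUE
}

#' Canonical rotation class of a repeat unit
#'
#' The lexicographically smallest cyclic rotation: runs starting `TG...`
#' classify as class `GT`. Reverse complements are deliberately NOT collapsed
#' (`GT` and `AC` are distinct classes, as are `CT` and `AG`), since the two
#' strands' repeat tallies are reported separately.
#'
#' @param unit A repeat unit string.
#' @return The canonical representative.
#' @examples
#' unit_class("TG") # "GT"
#' @export
unit_class <- function(unit) {
  vapply(unit, function(u) {
    k <- nchar(u)
    rots <- vapply(seq_len(k), function(i) {
      paste0(substr(u, i, k), substr(u, 1, i - 1))
    }, character(1))
    min(rots)
  }, character(1), USE.NAMES = FALSE)
}

#' Find maximal short tandem repeats
#'
#' Scans a sequence for tandem runs of primitive units of length `k_min` to
#' `k_max`. A hit is a maximal run: it cannot be extended left or right while
#' keeping the periodicity, and a run expressible under several unit lengths
#' is reported once, under its primitive (shortest) unit. `copies` counts
#' complete units only; a trailing partial unit is recorded by the
#' `partial_tail` flag and, when `allow_partial_tail` is set, included in
#' `span`. Homopolymer runs (unit length 1) are never reported.
#'
#' @param seq A nucleotide string.
#' @param k_min,k_max Unit length bounds (defaults 2 and 5).
#' @param min_copies Named vector of minimum complete copies per unit length;
#'   see [default_min_copies()].
#' @param allow_partial_tail Include the partial tail in `span`.
#' @return A tibble of hits sorted by `start` (0-based offset within `seq`):
#'   `unit`, `unit_class`, `start`, `copies`, `span`, `partial_tail`.
#' @examples
#' find_tandem_repeats("AAGTGTGTGTCC", min_copies = c(`2` = 4))
#' @export
find_tandem_repeats <- function(seq, k_min = 2, k_max = 5,
                                min_copies = default_min_copies(),
                                allow_partial_tail = TRUE) {
  stopifnot(k_min >= 2, k_min <= k_max)
  if (any(min_copies < 2)) {
    abort("min_copies must be >= 2 for every unit length",
          class = "h4map_config_error")
  }
  seq <- toupper(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  hits <- list()
  for (k in k_min:k_max) {
    mc <- unname(min_copies[as.character(k)])
    if (is.na(mc)) next
    if (n < k * mc) next
    # ok[i]: position i continues a period-k run (chars[i] == chars[i + k])
    ok <- chars[seq_len(n - k)] == chars[(k + 1):n]
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (j in which(r$values)) {
      i <- starts[j]                       # 1-based run start
      run_len <- r$lengths[j] + k          # repeated segment length in bases
      copies <- run_len %/% k
      tail_len <- run_len %% k
      if (copies < mc) next
      unit <- substr(seq, i, i + k - 1)
      if (grepl("[^ACGT]", unit)) next     # ambiguity codes never seed a unit
      if (!is_primitive_unit(unit)) next   # reported under the shorter unit
      hits[[length(hits) + 1]] <- tibble(
        unit = unit,
        unit_class = unit_class(unit),
        start = i - 1,
        copies = copies,
        span = copies * k + if (allow_partial_tail) tail_len else 0L,
        partial_tail = tail_len > 0)
    }
  }
  if (length(hits) == 0) {
    return(tibble(unit = character(), unit_class = character(),
                  start = integer(), copies = integer(), span = integer(),
                  partial_tail = logical()))
  }
  bind_rows(hits) |> arrange(.data$start, nchar(.data$unit))
}

#' Repeat classes present in one joining-site sequence
#'
#' Runs [find_tandem_repeats()] and returns the set of rotation-canonical
#' unit classes present. A site may carry several classes (e.g. both a GT-
#' and a CT-run).
#'
#' @inheritParams find_tandem_repeats
#' @return A character vector of distinct classes (possibly empty).
#' @export
classify_site_repeats <- function(seq, k_min = 2, k_max = 5,
                                  min_copies = default_min_copies()) {
  unique(find_tandem_repeats(seq, k_min, k_max, min_copies)$unit_class)
}

#' Per-site sequence features for a target table
#'
#' Extracts each target's plus-strand sequence from the genome and computes
#' its AT content and repeat classes.
#'
#' @param targets A target tibble with `scaffold`, `start`, `end` (internal
#'   coordinates).
#' @param genome A [Biostrings::DNAStringSet].
#' @inheritParams find_tandem_repeats
#' @return `targets` with added columns `at_content` and `repeat_classes`
#'   (list column of class vectors).
#' @export
characterize_targets <- function(targets, genome, k_min = 2, k_max = 5,
                                 min_copies = default_min_copies()) {
  seqs <- purrr::pmap_chr(
    list(targets$scaffold, targets$start, targets$end),
    function(s, a, b) extract_interval_sequence(genome, s, a, b))
  targets$at_content <- purrr::map_dbl(seqs, at_content)
  targets$repeat_classes <- purrr::map(
    seqs, classify_site_repeats, k_min = k_min, k_max = k_max,
    min_copies = min_copies)
  targets
}

#' Cross-tabulate repeat classes against nearest-gene regulation
#'
#' For every repeat class, counts target sites whose nearest gene is
#' up-regulated, down-regulated, or not regulated (`none`) in the supplied
#' DEG list. Sites with no repeat class contribute to no row; a site carrying
#' several classes contributes to each of its rows.
#'
#' @param sites A characterized target tibble ([characterize_targets()]) with
#'   `nearest_gene` and `repeat_classes`.
#' @param degs A DEG tibble ([call_degs()]).
#' @return A tibble with columns `unit_class`, `up`, `down`, `none`.
#' @export
repeat_deg_crosstab <- function(sites, degs) {
  reg <- tibble(transcript_id = degs$transcript_id,
                regulation = degs$direction)
  long <- sites |>
    select("nearest_gene", "repeat_classes") |>
    tidyr::unnest_longer("repeat_classes", values_to = "unit_class") |>
    filter(!is.na(.data$unit_class))
  if (nrow(long) == 0) {
    return(tibble(unit_class = character(), up = integer(),
                  down = integer(), none = integer()))
  }
  long |>
    left_join(reg, by = c(nearest_gene = "transcript_id")) |>
    mutate(regulation = tidyr::replace_na(.data$regulation, "none")) |>
    count(.data$unit_class, .data$regulation) |>
    tidyr::pivot_wider(names_from = "regulation", values_from = "n",
                       values_fill = 0L) |>
    (\(d) {
      for (col in c("up", "down", "none")) {
        if (!col %in% names(d)) d[[col]] <- 0L
      }
      select(d, "unit_class", "up", "down", "none")
    })() |>
    arrange(.data$unit_class)
}
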