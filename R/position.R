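# Locality of ChIP signal around target genes: UP / GB / DOWN classification,
# seven-gene neighborhood read profiles, main-peak position calls, and the
# positional-effect chi-square.

#' Classify a peak's locality relative to one gene
#'
#' `GB` when the intervals overlap by at least 1 bp; otherwise `UP` when the
#' peak lies on the gene's strand-aware 5' side and `DOWN` on the 3' side.
#' Both intervals are internal 0-based half-open and must share a scaffold.
#'
#' @param peak_start,peak_end Peak interval.
#' @param gene One-row gene annotation (fields `scaffold`, `start`, `end`,
#'   `strand`).
#' @param peak_scaffold Scaffold of the peak (checked against the gene's).
#' @return `"UP"`, `"GB"`, or `"DOWN"`.
#' @export
classify_locality <- function(peak_start, peak_end, gene,
                              peak_scaffold = gene$scaffold) {
  if (!identical(peak_scaffold, gene$scaffold)) {
    abort("peak and gene are on different scaffolds",
          class = "h4map_domain_error")
  }
  geo <- peak_gene_geometry(peak_start, peak_end, gene$start, gene$end,
                            gene$strand)
  if (geo$overlap) "GB" else if (geo$upstream) "UP" else "DOWN"
}

#' Build the ChIP read profile of a gene neighborhood
#'
#' Takes the focal gene plus up to `flank` annotated genes on each side
#' (seven genes at the default flank of 3) and tiles the neighborhood into
#' alternating gene-body and intergenic regions, including the two outer
#' intergenic segments bounding the neighborhood (up to 8 intergenic regions).
#' Every peak whose midpoint falls in a region contributes its full
#' `read_count` to that region, so region counts conserve the total read
#' count of assigned peaks. Truncated neighborhoods at scaffold ends are kept
#' and flagged.
#'
#' @param focal A `gene_id` present in `genes`.
#' @param genes Gene annotation tibble.
#' @param peaks Condition-tagged peak tibble.
#' @param flank Genes per side (default 3).
#' @param fc_table Optional tibble `transcript_id` -> `signed_fc` used to
#'   attach per-gene fold changes.
#' @return An `h4_profile` object: `focal_gene`, `flank`, `truncated`, and a
#'   `regions` tibble (`region_id`, `type`, `gene_id`, `start`, `end`,
#'   `chip_count`, `signed_fc`).
#' @export
build_neighborhood_profile <- function(focal, genes, peaks, flank = 3,
                                       fc_table = NULL) {
  if (!focal %in% genes$gene_id) {
    abort(paste0("unknown focal gene: ", focal), class = "h4map_lookup_error")
  }
  g0 <- genes[genes$gene_id == focal, , drop = FALSE]
  scaf <- g0$scaffold[1]
  neigh <- genes |>
    filter(.data$scaffold == scaf) |>
    arrange(.data$start, .data$end, .data$gene_id)
  idx <- which(neigh$gene_id == focal)
  lo <- max(1, idx - flank)
  hi <- min(nrow(neigh), idx + flank)
  truncated <- (idx - lo < flank) || (hi - idx < flank)
  sel <- neigh[lo:hi, , drop = FALSE]

  # outer bounds: previous / next gene outside the window, else scaffold edge
  left_bound <- if (lo > 1) neigh$end[lo - 1] else 0
  right_bound <- if (hi < nrow(neigh)) neigh$start[hi + 1] else Inf

  regions <- list()
  push <- function(type, gene_id, start, end) {
    regions[[length(regions) + 1]] <<- tibble(
      type = type, gene_id = gene_id, start = start, end = end)
  }
  push("intergenic", NA_character_, left_bound, sel$start[1])
  for (i in seq_len(nrow(sel))) {
    push("gene", sel$gene_id[i], sel$start[i], sel$end[i])
    next_start <- if (i < nrow(sel)) sel$start[i + 1] else right_bound
    push("intergenic", NA_character_, sel$end[i], next_start)
  }
  regions <- bind_rows(regions) |>
    filter(.data$end > .data$start) |>
    mutate(region_id = row_number()) |>
    relocate("region_id")

  p <- peaks[peaks$scaffold == scaf, , drop = FALSE]
  counts <- numeric(nrow(regions))
  if (nrow(p) > 0) {
    mid <- floor((p$start + p$end) / 2)
    for (i in seq_len(nrow(p))) {
      hit <- which(regions$start <= mid[i] & mid[i] < regions$end)
      if (length(hit) == 1) counts[hit] <- counts[hit] + p$read_count[i]
    }
  }
  regions$chip_count <- counts
  regions$signed_fc <- if (!is.null(fc_table)) {
    fc_table$signed_fc[match(regions$gene_id, fc_table$transcript_id)]
  } else {
    NA_real_
  }
  structure(list(focal_gene = focal, flank = flank, truncated = truncated,
                 strand = g0$strand[1], regions = regions),
            class = "h4_profile")
}

#' @export
print.h4_profile <- function(x, ...) {
  cat(sprintf("Neighborhood profile of %s (flank %d%s): %d regions, %g reads\n",
              x$focal_gene, x$flank,
              if (x$truncated) ", truncated" else "",
              nrow(x$regions), sum(x$regions$chip_count)))
  invisible(x)
}

#' @export
tidy.h4_profile <- function(x, ...) x$regions

#' Call the main ChIP position of a profiled gene
#'
#' Aggregates region read counts into the three localities relative to the
#' focal gene — `GB` is the focal gene body, `UP` and `DOWN` are the two
#' intergenic segments immediately adjacent to it on its strand-aware 5' and
#' 3' sides (not the whole neighborhood span). The main locality is the
#' argmax; ties are broken by the fixed precedence UP > GB > DOWN. A profile
#' with no reads in the three regions yields `main_locality = NA` and is
#' flagged. Regulation (`up`/`down`/`none`) is looked up from `degs` when
#' supplied.
#'
#' @param profile An `h4_profile`.
#' @param degs Optional DEG tibble used to attach the focal gene's regulation.
#' @return A one-row tibble: `gene_id`, `main_locality`, `regulation`,
#'   `up_count`, `gb_count`, `down_count`.
#' @export
call_main_position <- function(profile, degs = NULL) {
  r <- profile$regions
  focal_row <- which(r$type == "gene" & r$gene_id == profile$focal_gene)
  gb <- r$chip_count[focal_row]
  ig <- function(row) if (length(row) == 1 && !is.na(row) &&
                          row >= 1 && row <= nrow(r) &&
                          r$type[row] == "intergenic") r$chip_count[row] else 0
  left <- ig(focal_row - 1)
  right <- ig(focal_row + 1)
  if (identical(profile$strand, "-")) {
    up <- right; down <- left
  } else {
    up <- left; down <- right
  }
  counts <- c(UP = up, GB = gb, DOWN = down)
  main <- if (sum(counts) == 0) NA_character_ else
    names(counts)[which.max(counts)]  # which.max takes the first maximum:
                                      # order UP, GB, DOWN is the precedence
  regulation <- "none"
  if (!is.null(degs) && profile$focal_gene %in% degs$transcript_id) {
    regulation <- degs$direction[match(profile$focal_gene,
                                       degs$transcript_id)]
  }
  tibble(gene_id = profile$focal_gene, main_locality = main,
         regulation = regulation,
         up_count = up, gb_count = gb, down_count = down)
}

#' Positional-effect chi-square
#'
#' Tests whether the main ChIP locality (UP / GB / DOWN) is associated with
#' the direction of regulation of the focal gene. Pearson chi-square on the
#' 3 x 2 contingency table of locality by direction; calls with
#' `regulation == "none"` or an undefined locality are excluded first, and a
#' locality row or direction column with zero total is dropped (with a
#' warning) before testing, reducing the degrees of freedom accordingly.
#'
#' @param calls A tibble of position calls ([call_main_position()] rows).
#' @return An `h4_chisq` object (df = 2 for the full 3 x 2 layout).
#' @export
positional_effect_test <- function(calls) {
  use <- calls |>
    filter(.data$regulation %in% c("up", "down"),
           !is.na(.data$main_locality))
  tab <- table(factor(use$main_locality, levels = c("UP", "GB", "DOWN")),
               factor(use$regulation, levels = c("up", "down")))
  keep_r <- rowSums(tab) > 0
  keep_c <- colSums(tab) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warn("dropping empty locality/direction levels; degrees of freedom reduced")
  }
  tab <- tab[keep_r, keep_c, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    abort("positional_effect_test needs >= 2 non-empty localities and both directions",
          class = "h4map_test_error")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  new_h4_chisq(ht, unclass(tab))
}
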