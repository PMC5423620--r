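# Differential ChIP-target screening: significance filtering, nearest-gene
# annotation with signed distances, control subtraction by gene identity, and
# intersection of the two screens into core targets.

#' Filter peaks by E-value
#'
#' Retains peaks whose `e_value` is less than or equal to `threshold`
#' (inclusive, configurable only through the threshold itself). The two
#' screens use different defaults: 1e-8 for the parasitism screen (P7 vs NP5)
#' and 1e-13 for the viral-expression screen (vH4 vs vH4T), reflecting their
#' different mapping ratios.
#'
#' @param peaks A peak tibble.
#' @param threshold Positive significance cut-off.
#' @return The retained subset, order preserved. Idempotent at a fixed
#'   threshold.
#' @export
filter_peaks_by_evalue <- function(peaks, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0) {
    abort("threshold must be a single positive number",
          class = "h4map_config_error")
  }
  peaks[peaks$e_value <= threshold, , drop = FALSE]
}

# Geometry between a peak and a gene, strand-aware; intervals are 0-based
# half-open. `gap` is the unsigned edge-to-edge distance (0 on overlap OR
# adjacency); `overlap` requires >= 1 shared bp; `upstream` is the gene's 5'
# side. Locality is GB only on true overlap — an exactly adjacent peak (gap
# 0, no shared base) keeps its side label.
peak_gene_geometry <- function(p_start, p_end, g_start, g_end, g_strand) {
  overlap <- p_start < g_end & g_start < p_end
  gap <- pmax(g_start - p_end, p_start - g_end, 0)
  left_of_gene <- p_end <= g_start  # peak entirely at lower coordinates
  upstream <- if_else(g_strand == "+", left_of_gene, !left_of_gene)
  list(gap = gap, overlap = overlap, upstream = upstream,
       signed = if_else(overlap, 0, if_else(upstream, gap, -gap)))
}

signed_gap <- function(p_start, p_end, g_start, g_end, g_strand) {
  peak_gene_geometry(p_start, p_end, g_start, g_end, g_strand)$signed
}

#' Annotate peaks with their nearest gene
#'
#' For every peak the nearest gene on its scaffold minimizes the edge-to-edge
#' gap between the two intervals (0 when they overlap). The signed distance is
#' positive when the peak lies on the gene's strand-aware 5' (upstream) side,
#' negative on the 3' (downstream) side, and 0 on overlap; the locality label
#' follows: overlap -> `GB`, 5' -> `UP`, 3' -> `DOWN`. Equidistant ties are
#' broken by the lexicographically smallest `gene_id`. With
#' `ignore_strand = TRUE` lower coordinates always count as upstream.
#'
#' Peaks on scaffolds with no annotated gene get `nearest_gene = NA` and are
#' flagged (`annotated = FALSE`) for downstream exclusion.
#'
#' @param peaks A peak tibble (internal coordinates).
#' @param genes A gene annotation tibble.
#' @param screen Screen label stamped on the output (`"parasitism"` or
#'   `"viral"`), or `NA` to omit.
#' @param ignore_strand Treat lower coordinates as upstream regardless of gene
#'   strand (the unstranded presentation used by printed target tables).
#' @return A target-site tibble: the peak columns plus `nearest_gene`,
#'   `signed_distance`, `locality`, `screen`, `annotated`.
#' @export
annotate_nearest_cds <- function(peaks, genes, screen = NA_character_,
                                 ignore_strand = FALSE) {
  if (!is.na(screen)) screen <- match.arg(screen, c("parasitism", "viral"))
  if (nrow(peaks) == 0) {
    return(mutate(peaks, nearest_gene = character(0),
                  signed_distance = numeric(0), locality = character(0),
                  screen = character(0), annotated = logical(0)))
  }
  ann <- purrr::pmap(
    list(peaks$scaffold, peaks$start, peaks$end),
    function(scaf, ps, pe) {
      g <- genes[genes$scaffold == scaf, , drop = FALSE]
      if (nrow(g) == 0) {
        return(list(gene = NA_character_, dist = NA_real_,
                    loc = NA_character_))
      }
      strand <- if (ignore_strand) rep("+", nrow(g)) else g$strand
      geo <- peak_gene_geometry(ps, pe, g$start, g$end, strand)
      best <- which(geo$gap == min(geo$gap))
      if (length(best) > 1) best <- best[order(g$gene_id[best])[1]]
      loc <- if (geo$overlap[best]) "GB"
             else if (geo$upstream[best]) "UP" else "DOWN"
      list(gene = g$gene_id[best], dist = geo$signed[best], loc = loc)
    })
  out <- peaks
  out$nearest_gene <- purrr::map_chr(ann, "gene")
  out$signed_distance <- purrr::map_dbl(ann, "dist")
  out$locality <- purrr::map_chr(ann, "loc")
  out$screen <- screen
  out$annotated <- !is.na(out$nearest_gene)
  if (any(!out$annotated)) {
    warn(sprintf("%d peak(s) on gene-less scaffolds left unannotated",
                 sum(!out$annotated)))
  }
  out
}

#' Treatment-specific target sites
#'
#' Subtracts, from the treatment screen, every site whose nearest gene also
#' appears as the nearest gene of any control site. The subtraction is by
#' gene identity, not coordinate overlap: a treatment peak 2 kb away from a
#' control peak is still removed if both resolve to the same gene.
#' Unannotated sites are dropped first.
#'
#' @param treatment,control Annotated target tibbles over the same gene set.
#' @return The treatment-specific subset.
#' @export
specific_targets <- function(treatment, control) {
  if ("annotated" %in% names(treatment)) {
    treatment <- treatment[treatment$annotated, , drop = FALSE]
  }
  control_genes <- unique(control$nearest_gene[!is.na(control$nearest_gene)])
  filter(treatment, !(.data$nearest_gene %in% control_genes))
}

#' Core targets shared by the two screens
#'
#' A gene is a core target when it is the nearest gene of a treatment-specific
#' site in both screens. When several sites within one screen share a gene,
#' the site with the smallest `|signed_distance|` represents it (ties broken
#' by `peak_id`).
#'
#' @param spec_a,spec_b Specific-target tibbles from [specific_targets()]
#'   (conventionally the parasitism and viral screens).
#' @return A tibble with one row per shared gene: `gene_id` plus the
#'   representative site columns suffixed `_a` and `_b`.
#' @export
core_targets <- function(spec_a, spec_b) {
  reduce <- function(d) {
    d |>
      filter(!is.na(.data$nearest_gene)) |>
      group_by(.data$nearest_gene) |>
      arrange(abs(.data$signed_distance), .data$peak_id, .by_group = TRUE) |>
      dplyr::slice(1) |>
      ungroup()
  }
  a <- reduce(spec_a)
  b <- reduce(spec_b)
  shared <- intersect(a$nearest_gene, b$nearest_gene)
  a <- a[match(shared, a$nearest_gene), , drop = FALSE]
  b <- b[match(shared, b$nearest_gene), , drop = FALSE]
  keep <- c("peak_id", "scaffold", "start", "end", "e_value", "read_count",
            "signed_distance", "locality")
  out <- tibble(gene_id = shared)
  for (col in keep) {
    out[[paste0(col, "_a")]] <- a[[col]]
    out[[paste0(col, "_b")]] <- b[[col]]
  }
  out
}

#' Run one differential ChIP screen end to end
#'
#' Convenience wrapper: E-value filtering of treatment and control peak sets,
#' nearest-gene annotation of both against the same gene table, and control
#' subtraction by gene identity.
#'
#' @param treatment,control Peak tibbles.
#' @param genes Gene annotation tibble.
#' @param e_threshold Significance cut-off applied to both sets.
#' @param screen Screen label (`"parasitism"` or `"viral"`).
#' @param ignore_strand Passed to [annotate_nearest_cds()].
#' @return A specific-target tibble.
#' @export
chip_screen <- function(treatment, control, genes, e_threshold,
                        screen = c("parasitism", "viral"),
                        ignore_strand = FALSE) {
  screen <- match.arg(screen)
  t_ann <- annotate_nearest_cds(filter_peaks_by_evalue(treatment, e_threshold),
                                genes, screen = screen,
                                ignore_strand = ignore_strand)
  c_ann <- annotate_nearest_cds(filter_peaks_by_evalue(control, e_threshold),
                                genes, screen = screen,
                                ignore_strand = ignore_strand)
  specific_targets(t_ann, c_ann)
}
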