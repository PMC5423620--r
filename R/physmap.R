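# Physical mapping of core targets onto linkage groups, with DEG overlay.

#' @importFrom ggplot2 autoplot
NULL

#' Map target sites onto linkage groups
#'
#' Buckets every target by the linkage group of its scaffold (from the
#' scaffold table; scaffolds without an assignment are the uncharacterized
#' bucket `"LGUN"`). Positions within a linkage group are cumulative
#' scaffold-offset coordinates for plotting, with scaffolds ordered as in the
#' scaffold table.
#'
#' @param targets A target tibble with `scaffold`, `start`, `end`.
#' @param scaffolds A scaffold tibble ([read_scaffold_table()]).
#' @return An `h4_chromosome_map`: `targets` (with `linkage_group` and
#'   `lg_position`), `scaffolds`, and `summary` (a one-row tibble with
#'   `n_targets`, `n_targets_characterized`, `n_distinct_characterized_lgs`,
#'   `n_targets_un`).
#' @export
map_targets_to_lgs <- function(targets, scaffolds) {
  unknown <- setdiff(unique(targets$scaffold), scaffolds$name)
  if (length(unknown) > 0) {
    abort(paste0("target scaffold(s) missing from scaffold table: ",
                 paste(unknown, collapse = ", ")),
          class = "h4map_lookup_error")
  }
  scaffolds <- scaffolds |>
    group_by(.data$linkage_group) |>
    mutate(lg_offset = cumsum(.data$length) - .data$length) |>
    ungroup()
  t2 <- targets |>
    left_join(select(scaffolds, scaffold = "name", "linkage_group",
                     "lg_offset"),
              by = "scaffold") |>
    mutate(lg_position = .data$lg_offset + (.data$start + .data$end) / 2)
  char <- t2$linkage_group != "LGUN"
  summary <- tibble(
    n_targets = nrow(t2),
    n_targets_characterized = sum(char),
    n_distinct_characterized_lgs = dplyr::n_distinct(t2$linkage_group[char]),
    n_targets_un = sum(!char))
  structure(list(targets = t2, scaffolds = scaffolds, summary = summary,
                 degs = NULL, deg_window = NULL),
            class = "h4_chromosome_map")
}

#' @export
print.h4_chromosome_map <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Physical map: %d targets; %d on %d characterized LGs, %d on LGUN\n",
    s$n_targets, s$n_targets_characterized,
    s$n_distinct_characterized_lgs, s$n_targets_un))
  if (!is.null(x$degs)) {
    cat(sprintf("  DEG overlay: %d placed; %d within %d bp of a target; %d on LGs without targets\n",
                nrow(x$degs), sum(x$targets$n_degs_within_window > 0),
                x$deg_window, x$n_degs_on_targetless_lgs))
  }
  invisible(x)
}

#' @export
glance.h4_chromosome_map <- function(x, ...) x$summary

#' @export
tidy.h4_chromosome_map <- function(x, ...) x$targets

#' Overlay DEG positions on a physical map
#'
#' Resolves each DEG to its gene's position, buckets it by linkage group, and
#' reports (a) per target, the number of DEGs whose gene lies within `window`
#' bp of the target interval (edge-to-edge), and (b) the count of DEGs that
#' fall on linkage groups carrying no target at all. Target bucketing is
#' never altered by the overlay. Unresolvable DEG ids produce a warning, not
#' an error.
#'
#' @param map An `h4_chromosome_map`.
#' @param degs A DEG tibble ([call_degs()]).
#' @param genes Gene annotation tibble used to position DEGs.
#' @param window Distance window in bp (default 1000).
#' @return The map with a `degs` tibble, per-target `n_degs_within_window`,
#'   and `n_degs_on_targetless_lgs`.
#' @export
overlay_degs <- function(map, degs, genes, window = 1000) {
  pos <- degs |>
    inner_join(select(genes, transcript_id = "gene_id", "scaffold",
                      gene_start = "start", gene_end = "end"),
               by = "transcript_id")
  lost <- setdiff(degs$transcript_id, pos$transcript_id)
  if (length(lost) > 0) {
    warn(sprintf("%d DEG id(s) not resolvable to gene positions (e.g. %s)",
                 length(lost), lost[1]))
  }
  pos <- pos |>
    left_join(select(map$scaffolds, scaffold = "name", "linkage_group",
                     "lg_offset"),
              by = "scaffold") |>
    filter(!is.na(.data$linkage_group)) |>
    mutate(lg_position = .data$lg_offset +
             (.data$gene_start + .data$gene_end) / 2)

  t <- map$targets
  t$n_degs_within_window <- vapply(seq_len(nrow(t)), function(i) {
    same <- pos[pos$scaffold == t$scaffold[i], , drop = FALSE]
    if (nrow(same) == 0) return(0L)
    gap <- pmax(same$gene_start - t$end[i], t$start[i] - same$gene_end, 0)
    sum(gap <= window)
  }, integer(1))

  target_lgs <- unique(t$linkage_group)
  map$targets <- t
  map$degs <- pos
  map$deg_window <- window
  map$n_degs_on_targetless_lgs <- sum(!pos$linkage_group %in% target_lgs)
  map
}

#' Plot a physical map
#'
#' One facet per linkage group: the LG axis in cumulative coordinates,
#' targets as downward-pointing triangles, and (when overlaid) DEGs as
#' direction-colored ticks.
#'
#' @param map An `h4_chromosome_map`.
#' @return A ggplot object.
#' @export
plot_physical_map <- function(map) {
  lg_len <- map$scaffolds |>
    group_by(.data$linkage_group) |>
    summarise(lg_length = sum(.data$length), .groups = "drop")
  p <- ggplot2::ggplot(lg_len) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$lg_length,
                                       y = 0, yend = 0),
                          linewidth = 2, colour = "grey70") +
    ggplot2::geom_point(data = map$targets,
                        ggplot2::aes(x = .data$lg_position, y = 0.08),
                        shape = 25, fill = "black", size = 2) +
    ggplot2::facet_wrap(~linkage_group, ncol = 4) +
    ggplot2::labs(x = "position (bp, cumulative over scaffolds)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
  if (!is.null(map$degs) && nrow(map$degs) > 0) {
    p <- p + ggplot2::geom_segment(
      data = map$degs,
      ggplot2::aes(x = .data$lg_position, xend = .data$lg_position,
                   y = -0.12, yend = -0.02, colour = .data$direction)) +
      ggplot2::scale_colour_manual(values = c(up = "red3", down = "green4"))
  }
  p
}

#' @export
autoplot.h4_chromosome_map <- function(object, ...) plot_physical_map(object)

#' Plot a neighborhood read profile
#'
#' Region-level ChIP read counts across the seven-gene neighborhood, gene
#' bodies shaded, the focal gene highlighted.
#'
#' @param profile An `h4_profile`.
#' @return A ggplot object.
#' @export
plot_neighborhood_profile <- function(profile) {
  r <- profile$regions |>
    mutate(role = dplyr::case_when(
      .data$gene_id == profile$focal_gene ~ "focal gene",
      .data$type == "gene" ~ "gene body",
      TRUE ~ "intergenic"))
  ggplot2::ggplot(r) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                    ymin = 0, ymax = .data$chip_count,
                                    fill = .data$role)) +
    ggplot2::scale_fill_manual(values = c(`focal gene` = "red3",
                                          `gene body` = "grey40",
                                          intergenic = "grey75")) +
    ggplot2::labs(x = "position (bp)", y = "ChIP reads",
                  title = paste("Neighborhood of", profile$focal_gene)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.h4_profile <- function(object, ...) plot_neighborhood_profile(object)
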