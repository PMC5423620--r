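# Orchestration: one parameter object, the staged pipeline, and a
# machine-readable summary of every headline count.

#' Pipeline parameters
#'
#' Stage parameters with their standard defaults: DEG fold-change threshold
#' 2; screening E-value thresholds 1e-8 (parasitism) and 1e-13 (viral
#' expression); repeat-finder minimum copies per unit length from
#' [default_min_copies()]; neighborhood flank of 3 genes per side; DEG
#' overlay window 1 kb; strand-aware locality.
#'
#' @param fc_threshold DEG |fold change| cut-off; must be > 1.
#' @param e_threshold_parasitism,e_threshold_viral Screening E-value
#'   thresholds.
#' @param min_copies Named vector for the repeat finder.
#' @param flank Neighborhood genes per side.
#' @param deg_window Overlay window (bp).
#' @param ignore_strand Treat lower coordinates as upstream.
#' @return A validated list of class `h4_params`.
#' @export
h4_params <- function(fc_threshold = 2,
                      e_threshold_parasitism = 1e-8,
                      e_threshold_viral = 1e-13,
                      min_copies = default_min_copies(),
                      flank = 3,
                      deg_window = 1000,
                      ignore_strand = FALSE) {
  if (!is.numeric(fc_threshold) || fc_threshold <= 1) {
    abort("fc_threshold must be > 1", class = "h4map_config_error")
  }
  if (e_threshold_parasitism <= 0 || e_threshold_viral <= 0) {
    abort("E-value thresholds must be positive", class = "h4map_config_error")
  }
  if (flank < 1 || deg_window < 0) {
    abort("flank must be >= 1 and deg_window >= 0",
          class = "h4map_config_error")
  }
  structure(list(fc_threshold = fc_threshold,
                 e_threshold_parasitism = e_threshold_parasitism,
                 e_threshold_viral = e_threshold_viral,
                 min_copies = min_copies, flank = flank,
                 deg_window = deg_window, ignore_strand = ignore_strand),
            class = "h4_params")
}

#' Run the full analysis pipeline on in-memory tables
#'
#' Stages, in order: zero-FPKM filtering; DEG calling for the parasitism
#' (P7/NP5) and viral (vH4/vH4T) contrasts; direction-concordant DEG overlap
#' with contribution percentage; the two differential ChIP screens
#' (E-value filter, nearest-gene annotation, control subtraction);
#' intersection into core targets; sequence characterization of core sites
#' (AT content, repeat classes) with the repeat-by-regulation cross-tab;
#' neighborhood position calls and the positional-effect chi-square; and
#' physical mapping with DEG overlay. No stage mutates another stage's
#' outputs.
#'
#' @param expression Expression tibble.
#' @param peaks Named list of peak tibbles (`NP5`, `P7`, `vH4`, `vH4T`).
#' @param genes Gene annotation tibble.
#' @param scaffolds Scaffold tibble.
#' @param genome A [Biostrings::DNAStringSet].
#' @param params An [h4_params()] object.
#' @return An `h4_report`: every stage output plus a `summary` list of
#'   headline counts.
#' @export
h4_pipeline <- function(expression, peaks, genes, scaffolds, genome,
                        params = h4_params()) {
  stopifnot(inherits(params, "h4_params"))
  missing_conds <- setdiff(h4_conditions(), names(peaks))
  if (length(missing_conds) > 0) {
    abort(paste0("peaks must name all four conditions; missing: ",
                 paste(missing_conds, collapse = ", ")),
          class = "h4map_config_error")
  }
  categories <- tibble(transcript_id = genes$gene_id,
                       category = genes$category)

  expressed <- filter_expressed(expression)
  filter_counts <- attr(expressed, "filter_counts")

  deg_par <- call_degs(expressed, "P7/NP5", params$fc_threshold, categories)
  deg_vir <- call_degs(expressed, "vH4/vH4T", params$fc_threshold, categories)
  overlap <- overlap_degs(deg_par, deg_vir)

  spec_par <- chip_screen(peaks$P7, peaks$NP5, genes,
                          params$e_threshold_parasitism, "parasitism",
                          params$ignore_strand)
  spec_vir <- chip_screen(peaks$vH4, peaks$vH4T, genes,
                          params$e_threshold_viral, "viral",
                          params$ignore_strand)
  core <- core_targets(spec_par, spec_vir)

  core_sites <- core |>
    select(nearest_gene = "gene_id", peak_id = "peak_id_a",
           scaffold = "scaffold_a", start = "start_a", end = "end_a",
           read_count = "read_count_a",
           signed_distance = "signed_distance_a", locality = "locality_a")
  features <- characterize_targets(core_sites, genome,
                                   min_copies = params$min_copies)
  crosstab <- repeat_deg_crosstab(features, deg_vir)

  fc_table <- tibble(
    transcript_id = expressed$transcript_id,
    signed_fc = signed_fold_change(expressed$vH4, expressed$vH4T))
  all_treatment_peaks <- bind_rows(peaks$P7, peaks$vH4)
  profiles <- purrr::map(core$gene_id, function(g) {
    build_neighborhood_profile(g, genes, all_treatment_peaks,
                               flank = params$flank, fc_table = fc_table)
  })
  calls <- bind_rows(purrr::map(profiles, call_main_position, degs = deg_vir))
  position_test <- tryCatch(positional_effect_test(calls),
                            error = function(e) NULL)

  map <- map_targets_to_lgs(features, scaffolds)
  map <- overlay_degs(map, deg_vir, genes, window = params$deg_window)

  has_di <- purrr::map_lgl(features$repeat_classes,
                           function(cl) any(nchar(cl) == 2))
  summary <- list(
    transcripts = as.list(filter_counts),
    degs = list(
      parasitism = list(n = nrow(deg_par),
                        up = sum(deg_par$direction == "up"),
                        down = sum(deg_par$direction == "down")),
      viral = list(n = nrow(deg_vir),
                   up = sum(deg_vir$direction == "up"),
                   down = sum(deg_vir$direction == "down"))),
    overlap = list(n_common = overlap$n_common,
                   up = length(overlap$common_up),
                   down = length(overlap$common_down),
                   n_reference = overlap$n_reference,
                   contribution_pct =
                     round_half_up(overlap$contribution_pct, 1)),
    screens = list(parasitism_specific = nrow(spec_par),
                   viral_specific = nrow(spec_vir),
                   core = nrow(core)),
    sequence = list(
      mean_at_pct = round_half_up(100 * mean(features$at_content), 1),
      pct_sites_with_dinucleotide_repeat =
        round_half_up(100 * mean(has_di), 1),
      repeat_class_tally = as.list(table(unlist(features$repeat_classes)))),
    localities = as.list(table(factor(features$locality,
                                      levels = c("UP", "GB", "DOWN")))),
    position_test = if (is.null(position_test)) NULL else
      list(statistic = position_test$statistic, df = position_test$df,
           p_value = position_test$p_value),
    physical_map = as.list(map$summary),
    degs_on_targetless_lgs = map$n_degs_on_targetless_lgs)

  structure(list(expressed = expressed, deg_parasitism = deg_par,
                 deg_viral = deg_vir, overlap = overlap,
                 specific_parasitism = spec_par, specific_viral = spec_vir,
                 core = core, features = features, crosstab = crosstab,
                 profiles = profiles, position_calls = calls,
                 position_test = position_test, map = map,
                 params = params, summary = summary),
            class = "h4_report")
}

#' @export
print.h4_report <- function(x, ...) {
  s <- x$summary
  cat("h4map pipeline report\n")
  cat(sprintf("  transcripts: %d total, %d removed, %d retained\n",
              s$transcripts$total, s$transcripts$removed,
              s$transcripts$retained))
  cat(sprintf("  DEGs: parasitism %d (%d up / %d down); viral %d (%d up / %d down)\n",
              s$degs$parasitism$n, s$degs$parasitism$up,
              s$degs$parasitism$down, s$degs$viral$n, s$degs$viral$up,
              s$degs$viral$down))
  cat(sprintf("  overlap: %d common (%d up / %d down); contribution %.1f%%\n",
              s$overlap$n_common, s$overlap$up, s$overlap$down,
              s$overlap$contribution_pct))
  cat(sprintf("  screens: %d / %d specific sites; %d core targets\n",
              s$screens$parasitism_specific, s$screens$viral_specific,
              s$screens$core))
  cat(sprintf("  core sites: mean AT %.1f%%; %.1f%% with dinucleotide repeat\n",
              s$sequence$mean_at_pct,
              s$sequence$pct_sites_with_dinucleotide_repeat))
  cat(sprintf("  physical map: %d on %d characterized LGs, %d on LGUN\n",
              s$physical_map$n_targets_characterized,
              s$physical_map$n_distinct_characterized_lgs,
              s$physical_map$n_targets_un))
  invisible(x)
}

#' Run the pipeline from a file-based configuration
#'
#' `config` is a list (or path to a YAML file) with input paths
#' (`expression`, `peaks` — named per condition —, `genes`, `scaffolds`,
#' `genome`), optional stage parameters (merged into [h4_params()]), and an
#' optional `out_dir`. When `out_dir` is set, the report bundle is written:
#' per-stage TSVs, `summary.json`, and the effective parameters; the summary
#' also embeds a hash of the configuration for provenance. Alternatively
#' `config$simulate` may hold an [sim_config()] object (or its fields), in
#' which case inputs are generated rather than read.
#'
#' @param config A list or YAML path.
#' @return An `h4_report` (invisibly when writing a bundle).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  par_fields <- intersect(names(formals(h4_params)), names(config))
  params <- do.call(h4_params, config[par_fields])

  if (!is.null(config$simulate)) {
    sim_cfg <- if (inherits(config$simulate, "h4_sim_config")) {
      config$simulate
    } else if (isTRUE(config$simulate)) {
      do.call(sim_config, config[intersect(names(formals(sim_config)),
                                           names(config))])
    } else {
      do.call(sim_config, config$simulate)
    }
    sim <- simulate_h4_dataset(sim_cfg)
    inputs <- sim[c("expression", "peaks", "genes", "scaffolds", "genome")]
  } else {
    inputs <- list(
      expression = read_expression_table(config$expression),
      peaks = purrr::imap(config$peaks,
                          function(p, cond) read_peak_table(p, cond)),
      genes = read_gene_annotation(config$genes),
      scaffolds = read_scaffold_table(config$scaffolds),
      genome = read_genome_fasta(config$genome))
  }
  report <- h4_pipeline(inputs$expression, inputs$peaks, inputs$genes,
                        inputs$scaffolds, inputs$genome, params)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_target_table(report$specific_parasitism |> select(-"annotated"),
                       file.path(config$out_dir, "specific_parasitism.tsv"))
    write_target_table(report$specific_viral |> select(-"annotated"),
                       file.path(config$out_dir, "specific_viral.tsv"))
    feat <- report$features |>
      mutate(repeat_classes = purrr::map_chr(
        .data$repeat_classes, paste, collapse = ","))
    write_target_table(feat, file.path(config$out_dir, "core_targets.tsv"))
    readr::write_tsv(report$deg_parasitism,
                     file.path(config$out_dir, "deg_parasitism.tsv"))
    readr::write_tsv(report$deg_viral,
                     file.path(config$out_dir, "deg_viral.tsv"))
    summary <- report$summary
    summary$config_hash <- rlang::hash(config[setdiff(names(config),
                                                      "out_dir")])
    summary$seed <- config$seed %||% config$simulate$seed %||% NA
    jsonlite::write_json(summary,
                         file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    return(invisible(report))
  }
  report
}
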