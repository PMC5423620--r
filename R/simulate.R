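# Synthetic data with ground truth: a multi-scaffold genome with annotated
# genes and linkage groups, four ChIP peak tables with planted specific and
# shared peaks, and four-condition FPKM tables with planted DEGs. Every
# generator is deterministic for a fixed seed, and every planted feature is
# recorded in a truth object so downstream inferences can be scored exactly.

stage_seed <- function(config, offset) {
  set.seed((config$seed + offset) %% .Machine$integer.max)
}

#' Simulation configuration
#'
#' Builds and validates the configuration of the synthetic-data generators.
#' The defaults encode the study conditions of the analysis the package
#' implements: 18,073 transcripts of which 5,128 carry a zero FPKM in at
#' least one condition; 1,858 parasitism DEGs (877 up / 981 down), 1,190
#' viral-expression DEGs (431 up / 759 down) and 302 common DEGs (81 up /
#' 221 down); joining-site footprints 133-155 bp wide with AT fraction
#' 0.602 against a 0.55 background; 40% of specific sites carrying a planted
#' short tandem repeat with dinucleotide classes GT and AC weighted above CT
#' and AG; and peak significance values straddling the screening thresholds
#' 1e-8 / 1e-13. Genome scale (scaffold number and length, genes per
#' scaffold) is reduced relative to a real assembly so that the full
#' pipeline runs in seconds; domain lengths around genes keep the realistic
#' means (gene body about 1.5 kb, upstream about 2.5 kb, downstream about
#' 3 kb).
#'
#' @param seed Integer seed; the single source of randomness.
#' @param n_scaffolds,n_characterized_lgs,scaffold_length,n_genes_per_scaffold
#'   Genome scale. The first `n_characterized_lgs` scaffolds are assigned
#'   linkage groups `LG1`, `LG2`, ...; the rest fall in the `LGUN` bucket.
#' @param gb_length_mean,up_length_mean,down_length_mean Mean gene-body and
#'   intergenic domain lengths (bp).
#' @param at_fraction_sites,at_background Per-base AT probability inside
#'   planted peak footprints and elsewhere.
#' @param n_specific_peaks,n_shared_peaks Per screen: treatment-specific peaks
#'   and peaks shared with the control.
#' @param n_core_targets Nearest genes shared by the two screens' specific
#'   sets (planted core targets); must not exceed `n_specific_peaks`.
#' @param e_value_specific,e_value_nonspecific Significance values planted on
#'   specific and shared peaks.
#' @param peak_width_range Inclusive bp range of peak widths.
#' @param repeat_site_fraction Fraction of specific peaks carrying a planted
#'   tandem repeat.
#' @param repeat_unit_weights Named sampling weights over repeat units.
#' @param repeat_copies_range Inclusive range of planted complete copies.
#' @param n_transcripts,zero_fpkm_fraction Expression-table size and the
#'   fraction of transcripts planted with at least one zero FPKM cell.
#' @param n_deg_parasitism,n_deg_viral,n_deg_common Planted DEG counts;
#'   `n_deg_common <= min()` of the other two.
#' @param up_fraction_parasitism,up_fraction_viral,up_fraction_common
#'   Up-regulated fraction within each planted DEG set.
#' @param fc_range Range of planted |fold change|; the lower bound must be
#'   >= 2 or the planted truth would blur into the calling threshold.
#' @param fpkm_noise_cv Coefficient of variation of multiplicative FPKM
#'   noise (0 = noiseless).
#' @param mixed_strands Draw gene strands at random instead of all `+`.
#' @return A validated list of class `h4_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_scaffolds = 20L,
                       n_characterized_lgs = 12L,
                       scaffold_length = 150000L,
                       n_genes_per_scaffold = 18L,
                       gb_length_mean = 1500,
                       up_length_mean = 2500,
                       down_length_mean = 3000,
                       at_fraction_sites = 0.602,
                       at_background = 0.55,
                       n_specific_peaks = 40L,
                       n_shared_peaks = 10L,
                       n_core_targets = 12L,
                       e_value_specific = 1e-16,
                       e_value_nonspecific = 1e-5,
                       peak_width_range = c(133L, 155L),
                       repeat_site_fraction = 0.40,
                       repeat_unit_weights = c(
                         GT = 14.9, AC = 12.4, CT = 6.3, AG = 4.6,
                         CAT = 1, TGA = 1, TACA = 1, TCAC = 1, TGAG = 1,
                         TCTG = 1, GTCT = 1, TAGA = 1,
                         TTCTG = 1, CAATA = 1, ATTCT = 1),
                       repeat_copies_range = c(6L, 10L),
                       n_transcripts = 18073L,
                       zero_fpkm_fraction = 5128 / 18073,
                       n_deg_parasitism = 1858L,
                       n_deg_viral = 1190L,
                       n_deg_common = 302L,
                       up_fraction_parasitism = 877 / 1858,
                       up_fraction_viral = 431 / 1190,
                       up_fraction_common = 81 / 302,
                       fc_range = c(4, 64),
                       fpkm_noise_cv = 0.1,
                       mixed_strands = FALSE) {
  cfg <- as.list(environment())
  counts <- c("n_scaffolds", "n_characterized_lgs", "scaffold_length",
              "n_genes_per_scaffold", "n_specific_peaks", "n_shared_peaks",
              "n_core_targets", "n_transcripts", "n_deg_parasitism",
              "n_deg_viral", "n_deg_common")
  for (nm in counts) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] < 0 ||
        cfg[[nm]] != round(cfg[[nm]])) {
      abort(paste0(nm, " must be a non-negative integer"),
            class = "h4map_config_error")
    }
  }
  if (cfg$n_deg_common > min(cfg$n_deg_parasitism, cfg$n_deg_viral)) {
    abort("n_deg_common must not exceed either per-contrast DEG count",
          class = "h4map_config_error")
  }
  if (cfg$n_core_targets > cfg$n_specific_peaks) {
    abort("n_core_targets must not exceed n_specific_peaks",
          class = "h4map_config_error")
  }
  if (cfg$fc_range[1] < 2) {
    abort("fc_range lower bound must be >= 2 (planted DEGs must clear the calling threshold)",
          class = "h4map_config_error")
  }
  if (!(cfg$e_value_specific < cfg$e_value_nonspecific)) {
    abort("e_value_specific must be smaller than e_value_nonspecific",
          class = "h4map_config_error")
  }
  for (nm in c("at_fraction_sites", "at_background", "repeat_site_fraction",
               "zero_fpkm_fraction")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) {
      abort(paste0(nm, " must lie in [0, 1]"), class = "h4map_config_error")
    }
  }
  structure(cfg, class = "h4_sim_config")
}

# uniform integer in [lo, hi]; safe when lo == hi (unlike sample())
rint <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L

random_sequence <- function(n, at_fraction) {
  probs <- c(A = at_fraction / 2, T = at_fraction / 2,
             C = (1 - at_fraction) / 2, G = (1 - at_fraction) / 2)
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

#' Generate a synthetic genome with gene annotation
#'
#' Scaffolds carry background sequence at the configured AT fraction; genes
#' tile each scaffold left to right with gene-body lengths and intergenic
#' gaps drawn around the configured means (truncated normal, 15% CV).
#' Deterministic for a fixed seed.
#'
#' @param config An [sim_config()] object.
#' @return A list: `genome` ([Biostrings::DNAStringSet]), `scaffolds`
#'   (tibble `name`, `length`, `linkage_group`), `genes` (annotation tibble
#'   in internal coordinates).
#' @export
generate_genome <- function(config) {
  stage_seed(config, 101L)
  n_sc <- config$n_scaffolds
  sc_names <- sprintf("SC_%02d", seq_len(n_sc))
  lgs <- c(paste0("LG", seq_len(min(config$n_characterized_lgs, n_sc))),
           rep("LGUN", max(0, n_sc - config$n_characterized_lgs)))
  scaffolds <- tibble(name = sc_names, length = config$scaffold_length,
                      linkage_group = lgs)

  draw_len <- function(n, mean) {
    pmax(round(stats::rnorm(n, mean, 0.15 * mean)), round(mean / 4))
  }
  genes <- list()
  gid <- 0L
  for (s in seq_len(n_sc)) {
    ng <- config$n_genes_per_scaffold
    if (ng == 0) next
    gaps <- draw_len(ng, ifelse(seq_len(ng) %% 2 == 1,
                                config$up_length_mean,
                                config$down_length_mean))
    lens <- draw_len(ng, config$gb_length_mean)
    starts <- cumsum(gaps + dplyr::lag(lens, default = 0))
    ends <- starts + lens
    if (ends[ng] + 200 > config$scaffold_length) {
      abort("infeasible packing: genes exceed scaffold length",
            class = "h4map_config_error")
    }
    strand <- if (config$mixed_strands) {
      sample(c("+", "-"), ng, replace = TRUE)
    } else {
      rep("+", ng)
    }
    genes[[s]] <- tibble(
      gene_id = sprintf("Px%06d", gid + seq_len(ng)),
      scaffold = sc_names[s],
      start = starts, end = ends, strand = strand,
      category = sample(h4_categories(), ng, replace = TRUE))
    gid <- gid + ng
  }
  genes <- if (length(genes) > 0) bind_rows(genes) else {
    tibble(gene_id = character(), scaffold = character(), start = numeric(),
           end = numeric(), strand = character(), category = character())
  }
  seqs <- vapply(seq_len(n_sc), function(i) {
    random_sequence(config$scaffold_length, config$at_background)
  }, character(1))
  genome <- Biostrings::DNAStringSet(stats::setNames(seqs, sc_names))
  list(genome = genome, scaffolds = scaffolds, genes = genes)
}

sample_repeat_unit <- function(config) {
  units <- names(config$repeat_unit_weights)
  units[sample.int(length(units), 1, prob = config$repeat_unit_weights)]
}

# Place one peak next to (or inside) a gene so that the gene is provably the
# peak's nearest gene and, for UP/DOWN placements, no other planted peak in
# the same intergenic gap can collide with it.
place_peak <- function(gene, neigh_prev_end, neigh_next_start, width,
                       locality) {
  gs <- gene$start; ge <- gene$end
  if (locality == "GB" || ge - gs <= width) {
    off <- sample.int(max(1, ge - gs - width), 1) - 1
    return(list(start = gs + off, end = gs + off + width, locality = "GB",
                distance = 0))
  }
  if (locality == "UP") {
    gap_avail <- floor((gs - neigh_prev_end) / 2) - width - 1
    if (gap_avail < 10) {
      return(place_peak(gene, neigh_prev_end, neigh_next_start, width, "GB"))
    }
    d <- rint(10, min(950, gap_avail))
    return(list(start = gs - d - width, end = gs - d, locality = "UP",
                distance = d))
  }
  gap_avail <- floor((neigh_next_start - ge) / 2) - width - 1
  if (gap_avail < 10) {
    return(place_peak(gene, neigh_prev_end, neigh_next_start, width, "GB"))
  }
  d <- rint(10, min(950, gap_avail))
  list(start = ge + d, end = ge + d + width, locality = "DOWN", distance = d)
}

#' Generate the four ChIP peak tables with planted truth
#'
#' Each of the two screens (parasitism: treatment `P7` vs control `NP5`;
#' viral: `vH4` vs `vH4T`) receives `n_specific_peaks` treatment-specific
#' peaks at `e_value_specific` and `n_shared_peaks` nonspecific peaks planted
#' in treatment AND control next to the same nearest gene at
#' `e_value_nonspecific` (the subtraction step removes targets by nearest
#' gene, not coordinate overlap, so shared peaks need not coincide).
#' `n_core_targets` nearest genes are common to both screens' specific sets.
#' Peak footprints are rewritten in the genome at the configured site AT
#' fraction, and `repeat_site_fraction` of specific footprints receive a
#' tandem repeat written at a recorded offset. Specific peaks are placed
#' upstream, inside, or downstream of their target gene (probabilities
#' 0.45 / 0.20 / 0.35) with an edge-to-edge gap below 1 kb.
#'
#' @param config An [sim_config()] object.
#' @param annotation Gene annotation tibble from [generate_genome()].
#' @param genome The matching [Biostrings::DNAStringSet].
#' @return A list: `peaks` (named list of four peak tibbles), `genome` (with
#'   footprints written in), and `truth` (an `h4_truth` object).
#' @export
generate_peak_sets <- function(config, annotation, genome) {
  stage_seed(config, 202L)
  n_spec <- config$n_specific_peaks
  n_shared <- config$n_shared_peaks
  n_core <- config$n_core_targets
  need <- n_core + 2 * (n_spec - n_core) + 2 * n_shared
  if (need > nrow(annotation)) {
    abort("more peaks requested than available gene slots",
          class = "h4map_config_error")
  }
  pool <- sample(annotation$gene_id, need)
  core_genes <- pool[seq_len(n_core)]
  rest <- pool[-seq_len(n_core)]
  only_a <- rest[seq_len(n_spec - n_core)]
  rest <- rest[-seq_len(n_spec - n_core)]
  only_b <- rest[seq_len(n_spec - n_core)]
  rest <- rest[-seq_len(n_spec - n_core)]
  shared_a <- if (n_shared > 0) rest[seq_len(n_shared)] else character()
  rest <- if (n_shared > 0) rest[-seq_len(n_shared)] else rest
  shared_b <- if (n_shared > 0) rest[seq_len(n_shared)] else character()

  seqs <- as.character(genome)
  ann <- annotation |> arrange(.data$scaffold, .data$start)
  neighbors <- ann |>
    group_by(.data$scaffold) |>
    mutate(prev_end = dplyr::lag(.data$end, default = 0),
           next_start = dplyr::lead(.data$start,
                                    default = config$scaffold_length)) |>
    ungroup()

  peak_rows <- list()
  truth_rows <- list()
  counter <- stats::setNames(rep(0L, 4), h4_conditions())

  occupied <- list()  # per-scaffold footprint intervals already written

  plant_peak <- function(gene_id, condition, screen, role, e_value,
                         with_repeat) {
    g <- neighbors[neighbors$gene_id == gene_id, , drop = FALSE]
    width <- rint(config$peak_width_range[1], config$peak_width_range[2])
    loc <- sample(c("UP", "GB", "DOWN"), 1, prob = c(0.45, 0.20, 0.35))
    # the two screens both plant next to core genes: redraw on footprint
    # collision so one screen's peak never overwrites the other's sequence
    for (try in 1:50) {
      p <- place_peak(g, g$prev_end, g$next_start, width, loc)
      used <- occupied[[g$scaffold]]
      clash <- !is.null(used) &&
        any(p$start < used[, 2] & used[, 1] < p$end)
      if (!clash) break
      if (try == 50) {
        abort("could not place peaks without footprint collisions; lower peak counts",
              class = "h4map_config_error")
      }
    }
    occupied[[g$scaffold]] <<- rbind(occupied[[g$scaffold]],
                                     c(p$start, p$end))
    footprint <- random_sequence(width, config$at_fraction_sites)
    unit <- NA_character_; copies <- NA_integer_; offset <- NA_integer_
    if (with_repeat) {
      unit <- sample_repeat_unit(config)
      k <- nchar(unit)
      copies <- rint(config$repeat_copies_range[1], config$repeat_copies_range[2])
      copies <- min(copies, (width - 2) %/% k)
      span <- copies * k
      offset <- sample.int(width - span - 1, 1)
      substr(footprint, offset + 1, offset + span) <- strrep(unit, copies)
      # guard the run from accidental extension by its flanking bases
      flank_char <- setdiff(c("C", "G", "A", "T"),
                            c(substr(unit, 1, 1), substr(unit, k, k)))[1]
      if (offset >= 1) substr(footprint, offset, offset) <- flank_char
      if (offset + span + 1 <= width) {
        substr(footprint, offset + span + 1, offset + span + 1) <- flank_char
      }
    }
    substr(seqs[[g$scaffold]], p$start + 1, p$end) <<- footprint
    counter[condition] <<- counter[condition] + 1L
    pid <- sprintf("%s_peak_%03d", condition, counter[condition])
    read_count <- if (role == "specific") rint(40, 80) else rint(8, 25)
    peak_rows[[length(peak_rows) + 1]] <<- tibble(
      peak_id = pid, scaffold = g$scaffold, start = p$start, end = p$end,
      e_value = e_value, read_count = read_count, condition = condition)
    truth_rows[[length(truth_rows) + 1]] <<- tibble(
      peak_id = pid, condition = condition, screen = screen, role = role,
      scaffold = g$scaffold, start = p$start, end = p$end,
      target_gene = gene_id, locality = p$locality, distance = p$distance,
      planted_unit = unit,
      planted_unit_class = if (is.na(unit)) NA_character_ else unit_class(unit),
      planted_copies = copies,
      planted_offset = if (is.na(offset)) NA_real_ else p$start + offset)
    invisible(NULL)
  }

  screens <- list(
    parasitism = list(treatment = "P7", control = "NP5",
                      spec = c(core_genes, only_a), shared = shared_a),
    viral = list(treatment = "vH4", control = "vH4T",
                 spec = c(core_genes, only_b), shared = shared_b))
  for (scr in names(screens)) {
    sc <- screens[[scr]]
    n <- length(sc$spec)
    n_rep <- round(config$repeat_site_fraction * n)
    with_rep <- seq_len(n) %in% sample.int(n, n_rep)
    for (i in seq_len(n)) {
      plant_peak(sc$spec[i], sc$treatment, scr, "specific",
                 config$e_value_specific, with_rep[i])
    }
    for (gid in sc$shared) {
      plant_peak(gid, sc$treatment, scr, "shared",
                 config$e_value_nonspecific, FALSE)
      plant_peak(gid, sc$control, scr, "shared",
                 config$e_value_nonspecific, FALSE)
    }
  }

  peaks_all <- bind_rows(peak_rows)
  peaks <- lapply(stats::setNames(h4_conditions(), h4_conditions()),
                  function(cond) {
    peaks_all |>
      filter(.data$condition == cond) |>
      arrange(.data$scaffold, .data$start, .data$end, .data$peak_id)
  })
  truth <- structure(
    list(peaks = bind_rows(truth_rows), core_genes = core_genes,
         transcripts = NULL),
    class = "h4_truth")
  list(peaks = peaks, genome = Biostrings::DNAStringSet(seqs), truth = truth)
}

#' Generate a four-condition FPKM table with planted DEGs
#'
#' Baseline abundances are log-normal; planted DEGs multiply the treatment
#' condition of their contrast by a fold change drawn from `fc_range` (up) or
#' its reciprocal (down); every cell then receives multiplicative log-normal
#' noise with coefficient of variation `fpkm_noise_cv`. Common DEGs are
#' planted in both contrasts with the same direction. An exact count
#' `round(zero_fpkm_fraction * n_transcripts)` of non-DEG transcripts is
#' planted with zeros in a random non-empty subset of conditions.
#'
#' @param config An [sim_config()] object.
#' @param annotation Optional gene annotation; its `gene_id`s head the
#'   transcript universe so DEGs can be tied to genomic positions.
#' @return A list: `table` (expression tibble) and `truth` (tibble of
#'   per-transcript planted flags).
#' @export
generate_expression <- function(config, annotation = NULL) {
  stage_seed(config, 303L)
  n <- config$n_transcripts
  ids <- character(n)
  n_genes <- if (is.null(annotation)) 0L else min(nrow(annotation), n)
  if (n_genes > 0) ids[seq_len(n_genes)] <- annotation$gene_id[seq_len(n_genes)]
  if (n > n_genes) {
    ids[(n_genes + 1):n] <- sprintf("Tx%06d", seq_len(n - n_genes))
  }

  n_zero <- round(config$zero_fpkm_fraction * n)
  n_par <- config$n_deg_parasitism
  n_vir <- config$n_deg_viral
  n_com <- config$n_deg_common
  n_deg_total <- n_par + n_vir - n_com
  if (n_deg_total + n_zero > n) {
    abort("n_transcripts too small for requested DEG and zero counts",
          class = "h4map_config_error")
  }
  ord <- sample.int(n)
  common_idx <- ord[seq_len(n_com)]
  par_only <- ord[n_com + seq_len(n_par - n_com)]
  vir_only <- ord[(n_par) + seq_len(n_vir - n_com)]
  zero_idx <- ord[(n_deg_total) + seq_len(n_zero)]

  dir_split <- function(idx, n_up) {
    up <- rep(FALSE, length(idx))
    if (length(idx) > 0 && n_up > 0) up[seq_len(min(n_up, length(idx)))] <- TRUE
    up
  }
  com_up <- dir_split(common_idx, round(config$up_fraction_common * n_com))
  par_up_total <- round(config$up_fraction_parasitism * n_par)
  vir_up_total <- round(config$up_fraction_viral * n_vir)
  paronly_up <- dir_split(par_only, par_up_total - sum(com_up))
  vironly_up <- dir_split(vir_only, vir_up_total - sum(com_up))

  deg_par <- logical(n); deg_par[c(common_idx, par_only)] <- TRUE
  deg_vir <- logical(n); deg_vir[c(common_idx, vir_only)] <- TRUE
  up_par <- logical(n); up_par[common_idx] <- com_up; up_par[par_only] <- paronly_up
  up_vir <- logical(n); up_vir[common_idx] <- com_up; up_vir[vir_only] <- vironly_up

  draw_fc <- function(m) stats::runif(m, config$fc_range[1], config$fc_range[2])
  fc_par <- rep(NA_real_, n)
  fc_par[deg_par] <- ifelse(up_par[deg_par], 1, -1) * draw_fc(sum(deg_par))
  fc_vir <- rep(NA_real_, n)
  fc_vir[deg_vir] <- ifelse(up_vir[deg_vir], 1, -1) * draw_fc(sum(deg_vir))

  baseline <- stats::rlnorm(n, meanlog = 3, sdlog = 1.2)
  cv <- config$fpkm_noise_cv
  noise <- function() {
    if (cv <= 0) return(rep(1, n))
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  effect <- function(fc, is_deg) {
    e <- rep(1, n)
    e[is_deg & fc > 0] <- fc[is_deg & fc > 0]
    e[is_deg & fc < 0] <- 1 / abs(fc[is_deg & fc < 0])
    e
  }
  tab <- tibble(
    transcript_id = ids,
    NP5 = baseline * noise(),
    P7 = baseline * effect(fc_par, deg_par) * noise(),
    vH4T = baseline * noise(),
    vH4 = baseline * effect(fc_vir, deg_vir) * noise())
  tab <- tab[, c("transcript_id", h4_conditions())]

  zero_planted <- logical(n); zero_planted[zero_idx] <- TRUE
  for (i in zero_idx) {
    k <- sample.int(4, 1)
    conds <- sample(h4_conditions(), k)
    for (cond in conds) tab[[cond]][i] <- 0
  }

  truth <- tibble(
    transcript_id = ids, zero_planted = zero_planted,
    deg_parasitism = deg_par, deg_viral = deg_vir,
    deg_common = deg_par & deg_vir,
    fc_parasitism = fc_par, fc_viral = fc_vir)
  list(table = tab, truth = truth)
}

#' Generate a complete synthetic dataset
#'
#' Runs [generate_genome()], [generate_peak_sets()] and
#' [generate_expression()] under one configuration and merges their truth
#' records.
#'
#' @param config An [sim_config()] object.
#' @return A list with `genome`, `scaffolds`, `genes`, `peaks` (named list of
#'   four tibbles), `expression`, `truth` (class `h4_truth`), and `config`.
#' @export
simulate_h4_dataset <- function(config = sim_config()) {
  gen <- generate_genome(config)
  pk <- generate_peak_sets(config, gen$genes, gen$genome)
  ex <- generate_expression(config, gen$genes)
  truth <- pk$truth
  truth$transcripts <- ex$truth
  list(genome = pk$genome, scaffolds = gen$scaffolds, genes = gen$genes,
       peaks = pk$peaks, expression = ex$table, truth = truth,
       config = config)
}

#' @export
print.h4_truth <- function(x, ...) {
  cat(sprintf("Planted truth: %d peaks (%d specific), %d core genes%s\n",
              nrow(x$peaks), sum(x$peaks$role == "specific"),
              length(x$core_genes),
              if (!is.null(x$transcripts)) {
                sprintf(", %d planted DEGs", sum(x$transcripts$deg_parasitism |
                                                   x$transcripts$deg_viral))
              } else ""))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits exactly the formats the package readers consume: genome FASTA,
#' annotation / scaffold / peak / expression TSVs, the configuration as YAML,
#' and the truth record as JSON.
#'
#' @param sim Output of [simulate_h4_dataset()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome_fasta(sim$genome, file.path(dir, "genome.fasta"))
  write_gene_annotation(sim$genes, file.path(dir, "genes.tsv"))
  write_scaffold_table(sim$scaffolds, file.path(dir, "scaffolds.tsv"))
  for (cond in names(sim$peaks)) {
    write_peak_table(sim$peaks[[cond]],
                     file.path(dir, paste0("peaks_", cond, ".tsv")))
  }
  write_expression_table(sim$expression, file.path(dir, "expression.tsv"))
  cfg <- unclass(sim$config)
  cfg$repeat_unit_weights <- as.list(cfg$repeat_unit_weights)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  truth <- list(peaks = sim$truth$peaks, core_genes = sim$truth$core_genes,
                transcripts = sim$truth$transcripts)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", na = "null", auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
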