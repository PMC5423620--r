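#' @importFrom rlang .data abort warn inform %||%
#' @importFrom dplyr arrange mutate filter select left_join anti_join semi_join
#'   inner_join group_by summarise ungroup bind_rows distinct n row_number
#'   rename relocate across if_else pull count slice_min first
#' @importFrom tibble tibble as_tibble
NULL

# Closed label sets used across the pipeline ---------------------------------

#' Experimental conditions and functional categories
#'
#' The four RNA-Seq / ChIP-Seq conditions: nonparasitized larvae (`NP5`),
#' parasitized larvae (`P7`), larvae transiently expressing the full-length
#' viral histone H4 (`vH4`), and larvae expressing the tail-truncated control
#' construct (`vH4T`). Functional categories are the closed annotation label
#' set used by the gene tables; labels outside the set are mapped to
#' `"Unknown"` on read.
#'
#' @return A character vector of labels.
#' @export
h4_conditions <- function() c("NP5", "P7", "vH4", "vH4T")

#' @rdname h4_conditions
#' @export
h4_categories <- function() {
  c("Development", "Metabolism", "Immune", "Signaling", "Gene expression",
    "Unknown")
}

# Coordinate conventions ------------------------------------------------------
#
# On disk every interval is 1-based inclusive (the dialect of the host genome
# database tables); internally every interval is 0-based half-open so that
# widths are end - start and adjacency is equality. The two helpers below are
# inverses of one another.

#' Convert genomic interval coordinates between disk and internal conventions
#'
#' On-disk coordinates are 1-based inclusive; the internal representation is
#' 0-based half-open. `coords_to_internal()` and `coords_to_disk()` are exact
#' inverses (an involution when composed).
#'
#' @param start,end Integer vectors of interval bounds.
#' @return A list with components `start` and `end` in the target convention.
#' @examples
#' coords_to_internal(267416, 267973) # list(start = 267415, end = 267973)
#' @export
coords_to_internal <- function(start, end) {
  list(start = as.numeric(start) - 1, end = as.numeric(end))
}

#' @rdname coords_to_internal
#' @export
coords_to_disk <- function(start, end) {
  list(start = as.numeric(start) + 1, end = as.numeric(end))
}

# Commented-header TSV dialect ------------------------------------------------
# All tabular writers emit a first line "# col1<TAB>col2..." followed by
# header-less rows; readers also accept a plain readr-style header.

read_commented_tsv <- function(path, required = character()) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "h4map_io_error")
  }
  first <- readLines(path, n = 1L)
  if (length(first) == 1L && startsWith(first, "#")) {
    nms <- strsplit(sub("^#\\s*", "", first), "\t", fixed = TRUE)[[1]]
    df <- readr::read_tsv(path, skip = 1L, col_names = nms,
                          col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE, comment = "")
  } else {
    df <- readr::read_tsv(path,
                          col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE, comment = "")
  }
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0("missing column(s) in ", path, ": ",
                 paste(missing, collapse = ", ")),
          class = "h4map_parse_error")
  }
  df
}

write_commented_tsv <- function(df, path) {
  header <- paste0("# ", paste(names(df), collapse = "\t"))
  body <- do.call(paste, c(lapply(df, as.character), sep = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

# column coercion with line-numbered errors; data row i is file line i + 1
# because of the single header line
parse_numeric_col <- function(x, col, path, positive = FALSE,
                              nonneg = FALSE, integerish = FALSE) {
  suppressWarnings(v <- as.numeric(x))
  bad <- which(is.na(v) & !is.na(x) | is.na(x))
  if (length(bad) > 0) {
    abort(paste0("malformed value in column '", col, "' of ", path,
                 " at line ", bad[1] + 1L),
          class = "h4map_parse_error")
  }
  if (positive && any(v <= 0)) {
    abort(paste0("non-positive value in column '", col, "' of ", path,
                 " at line ", which(v <= 0)[1] + 1L),
          class = "h4map_parse_error")
  }
  if (nonneg && any(v < 0)) {
    abort(paste0("negative value in column '", col, "' of ", path,
                 " at line ", which(v < 0)[1] + 1L),
          class = "h4map_parse_error")
  }
  if (integerish && any(v != round(v))) {
    abort(paste0("non-integer value in column '", col, "' of ", path),
          class = "h4map_parse_error")
  }
  v
}

# Gene annotation -------------------------------------------------------------

#' Read a gene annotation table
#'
#' Accepts either GFF3 (`.gff`/`.gff3`, read through \pkg{rtracklayer}) or the
#' package's 6-column TSV dialect (`gene_id`, `scaffold`, `start`, `end`,
#' `strand`, `category`). On-disk coordinates are 1-based inclusive and are
#' converted to the internal 0-based half-open convention. Category labels
#' outside [h4_categories()] are mapped to `"Unknown"` (optionally after
#' translation through `category_map`, a two-column table `label` ->
#' `category`).
#'
#' @param path Path to the annotation file.
#' @param category_map Optional data frame with columns `label` and
#'   `category` used to translate free-text labels before validation.
#' @return A tibble with columns `gene_id`, `scaffold`, `start`, `end`,
#'   `strand`, `category`, ordered by (`scaffold`, `start`); coordinates are
#'   0-based half-open.
#' @export
read_gene_annotation <- function(path, category_map = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3")) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      abort("reading GFF3 requires the rtracklayer package")
    }
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[gr$type == "gene"]
    ids <- gr$ID %||% gr$Name
    cat <- if (!is.null(gr$category)) as.character(gr$category) else NA_character_
    df <- tibble(
      gene_id = as.character(ids),
      scaffold = as.character(GenomicRanges::seqnames(gr)),
      start = as.character(GenomicRanges::start(gr)),
      end = as.character(GenomicRanges::end(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      category = cat
    )
  } else {
    df <- read_commented_tsv(path, required = c("gene_id", "scaffold", "start",
                                                "end", "strand", "category"))
  }
  start <- parse_numeric_col(df$start, "start", path, positive = TRUE,
                             integerish = TRUE)
  end <- parse_numeric_col(df$end, "end", path, positive = TRUE,
                           integerish = TRUE)
  if (any(start > end)) {
    abort(paste0("start > end in ", path), class = "h4map_parse_error")
  }
  if (anyDuplicated(df$gene_id)) {
    dup <- unique(df$gene_id[duplicated(df$gene_id)])
    abort(paste0("duplicate gene_id in ", path, ": ",
                 paste(dup, collapse = ", ")),
          class = "h4map_integrity_error")
  }
  strand <- ifelse(df$strand %in% c("+", "-"), df$strand, "+")
  category <- as.character(df$category)
  if (!is.null(category_map)) {
    idx <- match(category, category_map$label)
    category <- if_else(is.na(idx), category, category_map$category[idx])
  }
  category[is.na(category) | !(category %in% h4_categories())] <- "Unknown"
  int <- coords_to_internal(start, end)
  tibble(gene_id = df$gene_id, scaffold = df$scaffold,
         start = int$start, end = int$end,
         strand = strand, category = category) |>
    arrange(.data$scaffold, .data$start, .data$end, .data$gene_id)
}

#' @rdname read_gene_annotation
#' @param genes A gene annotation tibble (internal coordinates).
#' @export
write_gene_annotation <- function(genes, path) {
  disk <- coords_to_disk(genes$start, genes$end)
  out <- tibble(gene_id = genes$gene_id, scaffold = genes$scaffold,
                start = format(disk$start, scientific = FALSE, trim = TRUE),
                end = format(disk$end, scientific = FALSE, trim = TRUE),
                strand = genes$strand, category = genes$category)
  write_commented_tsv(out, path)
}

# Peak tables ------------------------------------------------------------------

#' Read or write a ChIP peak table
#'
#' Peak tables carry `peak_id`, `scaffold`, `start`, `end`, `e_value`
#' (significance of the called peak, consumed as an input column) and
#' `read_count`. `condition` stamps every record with one of
#' [h4_conditions()]. Output rows are totally ordered by
#' (`scaffold`, `start`, `end`, `peak_id`).
#'
#' @param path File path.
#' @param condition One of `"NP5"`, `"P7"`, `"vH4"`, `"vH4T"`.
#' @return A tibble of peaks in internal (0-based half-open) coordinates.
#' @export
read_peak_table <- function(path, condition) {
  condition <- match.arg(condition, h4_conditions())
  df <- read_commented_tsv(path, required = c("peak_id", "scaffold", "start",
                                              "end", "e_value", "read_count"))
  if (nrow(df) == 0) {
    return(tibble(peak_id = character(), scaffold = character(),
                  start = numeric(), end = numeric(), e_value = numeric(),
                  read_count = numeric(), condition = character()))
  }
  start <- parse_numeric_col(df$start, "start", path, positive = TRUE,
                             integerish = TRUE)
  end <- parse_numeric_col(df$end, "end", path, positive = TRUE,
                           integerish = TRUE)
  e_value <- parse_numeric_col(df$e_value, "e_value", path, nonneg = TRUE)
  read_count <- parse_numeric_col(df$read_count, "read_count", path,
                                  nonneg = TRUE, integerish = TRUE)
  if (any(start > end)) {
    abort(paste0("start > end in ", path), class = "h4map_parse_error")
  }
  int <- coords_to_internal(start, end)
  tibble(peak_id = df$peak_id, scaffold = df$scaffold,
         start = int$start, end = int$end,
         e_value = e_value, read_count = read_count,
         condition = condition) |>
    arrange(.data$scaffold, .data$start, .data$end, .data$peak_id)
}

#' @rdname read_peak_table
#' @param peaks A peak tibble (internal coordinates).
#' @export
write_peak_table <- function(peaks, path) {
  disk <- coords_to_disk(peaks$start, peaks$end)
  out <- tibble(peak_id = peaks$peak_id, scaffold = peaks$scaffold,
                start = format(disk$start, scientific = FALSE, trim = TRUE),
                end = format(disk$end, scientific = FALSE, trim = TRUE),
                e_value = format(peaks$e_value, trim = TRUE),
                read_count = format(peaks$read_count, scientific = FALSE,
                                    trim = TRUE))
  write_commented_tsv(out, path)
}

# Expression tables ------------------------------------------------------------

#' Read or write an FPKM expression table
#'
#' The table must name all four conditions ([h4_conditions()]) in its header;
#' every transcript must carry a value for every condition (blank cells are an
#' error, never imputed) and FPKM values must be non-negative.
#'
#' @param path File path.
#' @return A tibble with columns `transcript_id`, `NP5`, `P7`, `vH4`, `vH4T`.
#' @export
read_expression_table <- function(path) {
  df <- read_commented_tsv(path, required = c("transcript_id", h4_conditions()))
  for (cond in h4_conditions()) {
    df[[cond]] <- parse_numeric_col(df[[cond]], cond, path, nonneg = TRUE)
  }
  as_tibble(df[, c("transcript_id", h4_conditions())])
}

#' @rdname read_expression_table
#' @param table An expression tibble.
#' @export
write_expression_table <- function(table, path) {
  out <- table
  for (cond in h4_conditions()) {
    out[[cond]] <- format(table[[cond]], digits = 17, scientific = FALSE,
                          trim = TRUE)
  }
  write_commented_tsv(out, path)
}

# Scaffold table ---------------------------------------------------------------

#' Read or write the scaffold / linkage-group table
#'
#' Columns: `name`, `length` (bp), `linkage_group` (a characterized label such
#' as `"LG5"`, or the sentinel `"LGUN"` for scaffolds not assigned to a
#' characterized chromosome). Rows with a missing label default to `"LGUN"`.
#'
#' @param path File path.
#' @return A tibble with columns `name`, `length`, `linkage_group`.
#' @export
read_scaffold_table <- function(path) {
  df <- read_commented_tsv(path, required = c("name", "length",
                                              "linkage_group"))
  len <- parse_numeric_col(df$length, "length", path, positive = TRUE,
                           integerish = TRUE)
  lg <- df$linkage_group
  lg[is.na(lg) | lg == ""] <- "LGUN"
  tibble(name = df$name, length = len, linkage_group = lg)
}

#' @rdname read_scaffold_table
#' @param scaffolds A scaffold tibble.
#' @export
write_scaffold_table <- function(scaffolds, path) {
  out <- tibble(name = scaffolds$name,
                length = format(scaffolds$length, scientific = FALSE,
                                trim = TRUE),
                linkage_group = scaffolds$linkage_group)
  write_commented_tsv(out, path)
}

# Target tables ----------------------------------------------------------------

#' Read or write a screened target-site table
#'
#' The generic reader for the package's target exports (and for transcribed
#' target tables shipped as fixtures). Coordinate columns `start`/`end` are
#' converted from the 1-based inclusive disk dialect to internal 0-based
#' half-open; all other columns pass through, with `signed_distance`, `fc`
#' parsed numerically when present.
#'
#' @param path File path.
#' @return A tibble in internal coordinates.
#' @export
read_target_table <- function(path) {
  df <- read_commented_tsv(path, required = c("scaffold", "start", "end"))
  start <- parse_numeric_col(df$start, "start", path, positive = TRUE,
                             integerish = TRUE)
  end <- parse_numeric_col(df$end, "end", path, positive = TRUE,
                           integerish = TRUE)
  int <- coords_to_internal(start, end)
  df$start <- int$start
  df$end <- int$end
  for (col in intersect(c("signed_distance", "fc", "e_value", "read_count"),
                        names(df))) {
    df[[col]] <- parse_numeric_col(df[[col]], col, path)
  }
  as_tibble(df)
}

#' @rdname read_target_table
#' @param targets A target tibble (internal coordinates).
#' @export
write_target_table <- function(targets, path) {
  out <- targets
  disk <- coords_to_disk(targets$start, targets$end)
  out$start <- format(disk$start, scientific = FALSE, trim = TRUE)
  out$end <- format(disk$end, scientific = FALSE, trim = TRUE)
  write_commented_tsv(out, path)
}

#' Export target sites as BED6
#'
#' BED is natively 0-based half-open, matching the internal convention, so
#' coordinates are written unchanged. The name field carries the target id
#' (falling back to the peak id), the score field the ChIP read count when
#' available.
#'
#' @param targets A target tibble with `scaffold`, `start`, `end`.
#' @param path Output path.
#' @export
write_targets_bed <- function(targets, path) {
  name <- targets$target_id %||% targets$peak_id %||%
    paste0("target_", seq_len(nrow(targets)))
  score <- targets$read_count %||% rep(0, nrow(targets))
  strand <- targets$strand %||% rep(".", nrow(targets))
  body <- paste(targets$scaffold,
                format(targets$start, scientific = FALSE, trim = TRUE),
                format(targets$end, scientific = FALSE, trim = TRUE),
                name, score, strand, sep = "\t")
  writeLines(body, path)
  invisible(path)
}

# Genome sequence --------------------------------------------------------------

#' Extract a genomic interval sequence
#'
#' Returns the plus-strand sequence of `[start, end)` (internal 0-based
#' half-open) on `scaffold`, uppercased. Ambiguity codes are preserved.
#' Strand enters the analysis only through gene orientation, never through
#' sequence extraction.
#'
#' @param genome A [Biostrings::DNAStringSet] keyed by scaffold name.
#' @param scaffold Scaffold name.
#' @param start,end Internal 0-based half-open bounds.
#' @return A character scalar of length `end - start`.
#' @examples
#' genome <- Biostrings::DNAStringSet(c(s1 = "AAACGT"))
#' extract_interval_sequence(genome, "s1", 0, 3) # "AAA"
#' @export
extract_interval_sequence <- function(genome, scaffold, start, end) {
  if (!scaffold %in% names(genome)) {
    abort(paste0("unknown scaffold: ", scaffold), class = "h4map_lookup_error")
  }
  len <- length(genome[[scaffold]])
  if (start < 0 || end > len || start > end) {
    abort(paste0("interval [", start, ",", end, ") out of bounds for ",
                 scaffold, " (length ", len, ")"),
          class = "h4map_range_error")
  }
  if (start == end) return("")
  toupper(as.character(Biostrings::subseq(genome[[scaffold]],
                                          start = start + 1, end = end)))
}

#' @rdname extract_interval_sequence
#' @param path FASTA path.
#' @export
read_genome_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' @rdname extract_interval_sequence
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}
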