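# Differential expression from FPKM tables: zero filtering, signed fold
# change, threshold calling, two-contrast overlap, and the category test.

#' Drop transcripts with any zero FPKM
#'
#' A transcript is retained only if its FPKM is strictly positive in all four
#' conditions; downstream fold changes are then always finite. The counts
#' (total, removed, retained) are reported via [message()] and attached as the
#' `"filter_counts"` attribute.
#'
#' @param table An expression tibble from [read_expression_table()] or
#'   [generate_expression()].
#' @return The filtered tibble (possibly empty).
#' @export
filter_expressed <- function(table) {
  conds <- h4_conditions()
  keep <- rowSums(as.matrix(table[, conds]) > 0) == length(conds)
  out <- table[keep, , drop = FALSE]
  counts <- c(total = nrow(table), removed = sum(!keep), retained = sum(keep))
  inform(sprintf(
    "filter_expressed: %d transcripts in, %d removed (zero FPKM in >=1 condition), %d retained",
    counts[["total"]], counts[["removed"]], counts[["retained"]]))
  attr(out, "filter_counts") <- counts
  out
}

#' Signed fold change between two FPKM values
#'
#' The ratio `t/c` when expression does not decrease, and the negative
#' reciprocal `-c/t` when it does, so `|signed_fc| >= 1` always and a negative
#' value reads directly as "x-fold down". Equal inputs give `+1` (the sign at
#' the measure-zero boundary is fixed as positive). Vectorized; both inputs
#' must be strictly positive — a non-positive value signals that the zero
#' filter was skipped.
#'
#' @param fpkm_t,fpkm_c Treatment and control FPKM (strictly positive).
#' @return A numeric vector, `signed_fold_change(a, b) == -signed_fold_change(b, a)`
#'   whenever `a != b`.
#' @examples
#' signed_fold_change(10, 5)  # +2
#' signed_fold_change(5, 10)  # -2
#' @export
signed_fold_change <- function(fpkm_t, fpkm_c) {
  if (any(fpkm_t <= 0) || any(fpkm_c <= 0)) {
    abort("signed_fold_change requires strictly positive FPKM (run filter_expressed first)",
          class = "h4map_domain_error")
  }
  if_else(fpkm_t >= fpkm_c, fpkm_t / fpkm_c, -fpkm_c / fpkm_t)
}

#' Call differentially expressed genes in one contrast
#'
#' Computes the signed fold change for the chosen contrast (`"P7/NP5"`,
#' parasitism; or `"vH4/vH4T"`, viral-gene expression) and retains transcripts
#' with `|signed_fc| >= threshold` (inclusive: printed DEG lists carry
#' boundary values such as -2.0). Direction is `up` for positive and `down`
#' for negative fold changes.
#'
#' @param table A filtered expression tibble (all FPKM > 0).
#' @param contrast `"P7/NP5"` or `"vH4/vH4T"`.
#' @param threshold Fold-change cut-off, default 2; must be >= 1.
#' @param categories Optional data frame `transcript_id` -> `category`.
#' @return A tibble with columns `transcript_id`, `contrast`, `signed_fc`,
#'   `direction`, `category`.
#' @export
call_degs <- function(table, contrast = c("P7/NP5", "vH4/vH4T"),
                      threshold = 2, categories = NULL) {
  contrast <- match.arg(contrast)
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 1) {
    abort("threshold must be a single number >= 1", class = "h4map_config_error")
  }
  parts <- strsplit(contrast, "/", fixed = TRUE)[[1]]
  if (nrow(table) == 0) {
    return(tibble(transcript_id = character(), contrast = character(),
                  signed_fc = numeric(), direction = character(),
                  category = character()))
  }
  fc <- signed_fold_change(table[[parts[1]]], table[[parts[2]]])
  out <- tibble(transcript_id = table$transcript_id,
                contrast = contrast,
                signed_fc = fc,
                direction = if_else(fc >= 0, "up", "down")) |>
    filter(abs(.data$signed_fc) >= threshold)
  if (!is.null(categories)) {
    out$category <- categories$category[match(out$transcript_id,
                                              categories$transcript_id)]
    out$category[is.na(out$category)] <- "Unknown"
  } else {
    out$category <- "Unknown"
  }
  out
}

#' Overlap two DEG sets and quantify the contribution
#'
#' Membership is direction-concordant: a transcript counts as common only if
#' it is up-regulated in both lists or down-regulated in both lists;
#' discordant genes belong to neither overlap. The contribution percentage is
#' reference-relative, `100 * n_common / nrow(deg_ref)` — swapping the
#' arguments leaves `n_common` unchanged but not `contribution_pct`.
#'
#' @param deg_ref Reference DEG tibble (e.g. the parasitism contrast).
#' @param deg_test Test DEG tibble (e.g. the viral-gene contrast).
#' @return An object of class `h4_overlap` with fields `common_up`,
#'   `common_down` (id vectors), `n_common`, `n_reference`,
#'   `contribution_pct` (unrounded; rounding is a reporting concern).
#' @export
overlap_degs <- function(deg_ref, deg_test) {
  ids_dir <- function(d, dir) d$transcript_id[d$direction == dir]
  common_up <- intersect(ids_dir(deg_ref, "up"), ids_dir(deg_test, "up"))
  common_down <- intersect(ids_dir(deg_ref, "down"), ids_dir(deg_test, "down"))
  n_common <- length(common_up) + length(common_down)
  n_reference <- nrow(deg_ref)
  structure(
    list(common_up = common_up, common_down = common_down,
         n_common = n_common, n_reference = n_reference,
         contribution_pct = if (n_reference > 0) 100 * n_common / n_reference
                            else NA_real_),
    class = "h4_overlap")
}

#' @export
print.h4_overlap <- function(x, ...) {
  cat(sprintf(
    "DEG overlap: %d common (%d up, %d down) of %d reference DEGs; contribution %.1f%%\n",
    x$n_common, length(x$common_up), length(x$common_down), x$n_reference,
    round_half_up(x$contribution_pct, 1)))
  invisible(x)
}

#' @importFrom generics tidy glance
#' @export
tidy.h4_overlap <- function(x, ...) {
  tibble(transcript_id = c(x$common_up, x$common_down),
         direction = rep(c("up", "down"),
                         c(length(x$common_up), length(x$common_down))))
}

#' @export
glance.h4_overlap <- function(x, ...) {
  tibble(n_common = x$n_common, n_up = length(x$common_up),
         n_down = length(x$common_down), n_reference = x$n_reference,
         contribution_pct = x$contribution_pct)
}

# half-up rounding, used only at the reporting layer (base round() is
# half-to-even, which would print 16.25 -> 16.2)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Chi-square homogeneity test across functional categories
#'
#' Pearson chi-square on the 2 x k contingency table formed by two category
#' count vectors (e.g. DEGs regulated by parasitism vs by the viral gene).
#' Categories with a zero total in both groups are dropped before testing;
#' the degrees of freedom are `k - 1` for k retained categories.
#'
#' @param counts_a,counts_b Named numeric vectors of per-category counts;
#'   names are matched (missing categories count 0).
#' @return An `h4_chisq` object with `statistic`, `df`, `p_value`, and the
#'   tested `table`.
#' @export
category_chisq <- function(counts_a, counts_b) {
  cats <- union(names(counts_a), names(counts_b))
  a <- counts_a[cats]; a[is.na(a)] <- 0
  b <- counts_b[cats]; b[is.na(b)] <- 0
  keep <- (a + b) > 0
  a <- a[keep]; b <- b[keep]
  if (sum(keep) < 2) {
    abort("category_chisq needs >= 2 non-empty categories",
          class = "h4map_test_error")
  }
  tab <- rbind(a = as.numeric(a), b = as.numeric(b))
  colnames(tab) <- cats[keep]
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  new_h4_chisq(ht, tab)
}

new_h4_chisq <- function(ht, tab) {
  structure(
    list(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value, table = tab),
    class = "h4_chisq")
}

#' @export
print.h4_chisq <- function(x, ...) {
  cat(sprintf("Chi-square: X2 = %.4f, df = %d, P = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' @export
tidy.h4_chisq <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value)
}

#' @export
glance.h4_chisq <- function(x, ...) tidy(x)
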