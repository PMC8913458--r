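#' Read a sample-metadata table
#'
#' CSV with columns `sample_id`, `patient_id`, `date` (ISO 8601),
#' `material`, `response`, `serology`, `involved_chain`.
#'
#' @param path CSV path.
#' @return Tibble with standardized columns (`collection_date` as Date,
#'   `response_raw`).
#' @export
read_sample_meta <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "patient_id", "date", "material", "response",
            "serology", "involved_chain")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0L) {
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    sample_id = as.character(raw$sample_id),
    patient_id = as.character(raw$patient_id),
    collection_date = parse_meta_date(raw$date),
    material = as.character(raw$material),
    response_raw = as.character(raw$response),
    serology = as.character(raw$serology),
    involved_chain = as.character(raw$involved_chain)
  )
}

parse_meta_date <- function(x) {
  d <- as.Date(x, format = "%Y-%m-%d")
  if (anyNA(d)) {
    stop("unparseable collection date(s): ",
         paste(utils::head(x[is.na(d)], 3L), collapse = ", "), call. = FALSE)
  }
  d
}

#' Exclude repetitive samples
#'
#' Within each patient and material stream (cfDNA and whole blood are
#' deduplicated separately), samples are ordered by collection date and
#' a sample is dropped when it was taken less than `min_days` days after
#' the most recent *retained* sample. Deterministic and idempotent.
#'
#' @param meta Metadata tibble (see [read_sample_meta()]).
#' @param min_days Minimum spacing in days (default 16; a gap of exactly
#'   16 days is kept).
#' @return The retained rows of `meta`, original order preserved.
#' @export
dedup_samples <- function(meta, min_days = 16L) {
  if (!inherits(meta$collection_date, "Date")) {
    meta$collection_date <- parse_meta_date(meta$collection_date)
  }
  keep_ids <- meta |>
    dplyr::arrange(.data$collection_date, .data$sample_id) |>
    dplyr::group_by(.data$patient_id, .data$material) |>
    dplyr::group_map(function(g, key) {
      kept <- character(0)
      anchor <- as.Date(NA)
      for (i in seq_len(nrow(g))) {
        d <- g$collection_date[i]
        if (is.na(anchor) || as.numeric(d - anchor) >= min_days) {
          kept <- c(kept, g$sample_id[i])
          anchor <- d
        }
      }
      kept
    }) |>
    unlist()
  meta[meta$sample_id %in% keep_ids, , drop = FALSE]
}

#' Collapse raw response labels into reporting groups
#'
#' Stringent complete response is not separated from complete response
#' (`sCR -> CR`) and minor responses are classified as stable disease
#' (`MR -> SD`). For group statistics, initial diagnosis and relapse are
#' pooled (`ID/RD`), as are stable and progressive disease (`SD/PD`);
#' partial remissions before/after transplant (`PRb`, `PRa`) report
#' under `PR` (the sublabel is available via [response_sublabel()]).
#'
#' @param response Character vector of raw labels: ID, RD, PD, SD, MR,
#'   PR, PRa, PRb, VGPR, CR, sCR.
#' @return Character vector over `ID/RD`, `SD/PD`, `PR`, `VGPR`, `CR`.
#' @export
map_response_group <- function(response) {
  lut <- c(ID = "ID/RD", RD = "ID/RD", PD = "SD/PD", SD = "SD/PD",
           MR = "SD/PD", PR = "PR", PRa = "PR", PRb = "PR",
           VGPR = "VGPR", CR = "CR", sCR = "CR")
  bad <- setdiff(unique(response), names(lut))
  if (length(bad) > 0L) {
    stop("unknown response label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(lut[response])
}

#' @rdname map_response_group
#' @return For `response_sublabel()`: `"PRa"`/`"PRb"` where applicable,
#'   otherwise `NA`.
#' @export
response_sublabel <- function(response) {
  ifelse(response %in% c("PRa", "PRb"), response, NA_character_)
}

#' @rdname map_response_group
#' @details `response_groups()` returns the group display order.
#' @export
response_groups <- function() c("ID/RD", "SD/PD", "PR", "VGPR", "CR")

#' Binarize an NGS result category
#'
#' Samples in which the myeloma clone was detected — irrespective of
#' frequency — are NGS positive; samples without the clone are negative;
#' samples without a defined clone are `NA` (excluded from concordance).
#'
#' @param category Character vector over [ngs_categories()].
#' @return Logical vector (with `NA` for `NO_CLONE_DEFINED`).
#' @export
binarize_ngs <- function(category) {
  stopifnot(all(category %in% ngs_categories()))
  dplyr::case_when(
    category %in% c("MM_TOP", "MM_DETECTED") ~ TRUE,
    category == "MM_NOT_DETECTED" ~ FALSE,
    .default = NA
  )
}

#' Binarize a flow-cytometry category
#'
#' Samples containing aberrant plasma cells only, or both aberrant and
#' normal plasma cells, are MFC positive; only-normal-plasma-cell and
#' no-plasma-cell samples are negative.
#'
#' @param category Character vector over [flow_categories()].
#' @return Logical vector.
#' @export
binarize_flow <- function(category) {
  stopifnot(all(category %in% flow_categories()))
  category %in% c("MM_PC", "MM_AND_N_PC")
}

#' Inter-method concordance (percent agreement and Cohen's kappa)
#'
#' Cross-classifies paired binary calls from the two assays into a 2x2
#' table (a: both positive, b: first-only, c: second-only, d: both
#' negative). Percent agreement is `100 (a + d) / n`; Cohen's kappa is
#' `(p_o - p_e) / (1 - p_e)` with observed agreement `p_o = (a + d)/n`
#' and chance agreement
#' `p_e = ((a+b)(a+c) + (c+d)(b+d)) / n^2`. When `p_e == 1`, kappa is 1
#' if agreement is also perfect and undefined (error) otherwise.
#'
#' @param pairs Tibble (or data frame) with logical columns `ngs` and
#'   `mfc`; rows with `NA` in either must be excluded beforehand.
#' @return Object of class `concordance_result` with [generics::tidy()]
#'   and [generics::glance()] methods.
#' @export
concordance <- function(pairs) {
  stopifnot(all(c("ngs", "mfc") %in% names(pairs)))
  if (anyNA(pairs$ngs) || anyNA(pairs$mfc)) {
    stop("undefined (NA) results must be excluded before concordance",
         call. = FALSE)
  }
  n <- nrow(pairs)
  if (n == 0L) stop("no pairs to compare", call. = FALSE)
  a <- sum(pairs$ngs & pairs$mfc)
  b <- sum(pairs$ngs & !pairs$mfc)
  c_ <- sum(!pairs$ngs & pairs$mfc)
  d <- sum(!pairs$ngs & !pairs$mfc)
  p_o <- (a + d) / n
  p_e <- ((a + b) * (a + c_) + (c_ + d) * (b + d)) / n^2
  kappa <- if (p_e == 1) {
    if (p_o == 1) 1 else stop("kappa undefined: chance agreement is 1",
                              call. = FALSE)
  } else {
    (p_o - p_e) / (1 - p_e)
  }
  structure(list(table = matrix(c(a, c_, b, d), nrow = 2,
                                dimnames = list(ngs = c("pos", "neg"),
                                                mfc = c("pos", "neg"))),
                 n = n, percent_agreement = 100 * p_o, kappa = kappa),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat("<concordance_result> n =", x$n, "\n")
  print(x$table)
  cat(sprintf("agreement %.1f%%, Cohen's kappa %.3f\n",
              x$percent_agreement, x$kappa))
  invisible(x)
}

#' @export
tidy.concordance_result <- function(x, ...) {
  tibble::tibble(
    ngs = c(TRUE, TRUE, FALSE, FALSE),
    mfc = c(TRUE, FALSE, TRUE, FALSE),
    count = c(x$table["pos", "pos"], x$table["pos", "neg"],
              x$table["neg", "pos"], x$table["neg", "neg"])
  )
}

#' @export
glance.concordance_result <- function(x, ...) {
  tibble::tibble(n = x$n, percent_agreement = x$percent_agreement,
                 kappa = x$kappa)
}

#' Spearman correlation of clone frequencies across compartments
#'
#' Rank correlation (average ranks for ties) of, e.g., myeloma-clone
#' frequencies in paired cfDNA and genomic-DNA samples. The p-value uses
#' the t-distribution approximation (`stats::cor.test`, `exact = FALSE`).
#'
#' @param pairs Tibble with numeric columns `freq_a` and `freq_b`;
#'   at least 3 complete pairs.
#' @return One-row tibble: `rho`, `p.value`, `n`.
#' @export
spearman_clone_correlation <- function(pairs) {
  stopifnot(all(c("freq_a", "freq_b") %in% names(pairs)))
  ok <- stats::complete.cases(pairs[, c("freq_a", "freq_b")])
  x <- pairs$freq_a[ok]
  y <- pairs$freq_b[ok]
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  tibble::tibble(rho = unname(ct$estimate), p.value = ct$p.value,
                 n = length(x))
}

#' Cohort summary of categorical results
#'
#' Counts and within-group percentages of per-sample result categories
#' (NGS or flow) per response group or serology stratum, mirroring the
#' stacked-bar cohort panels.
#'
#' @param results Tibble with a grouping column and a `category` column.
#' @param group Name of the grouping column (default `"group"`).
#' @return Tidy tibble: group, `category`, `count`, `percent` (within
#'   group; sums to 100 per group). Empty groups are omitted.
#' @export
summarize_cohort <- function(results, group = "group") {
  stopifnot(group %in% names(results), "category" %in% names(results))
  results |>
    dplyr::count(.data[[group]], .data$category, name = "count") |>
    dplyr::group_by(.data[[group]]) |>
    dplyr::mutate(percent = 100 * .data$count / sum(.data$count)) |>
    dplyr::ungroup()
}
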