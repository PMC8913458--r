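#' Identify a patient's myeloma clonotype
#'
#' Combines two lines of evidence across all of one patient's
#' quality-passing repertoires on the involved light chain:
#'
#' * **Overrepresentation** — a clonotype comprising more than
#'   `overrep_threshold` (default 1/3, strictly) of the light-chain
#'   spectrum in a sample taken at a diagnostic disease phase (initial
#'   diagnosis, relapse, or progression).
#' * **Cross-compartment overlap** — a clonotype exceeding
#'   `overlap_threshold` (default 5%, strictly) in both a cfDNA sample
#'   and a genomic-DNA/FFPE sample (bone marrow, pleural effusion, or
#'   tissue), since confident identification is not possible from cfDNA
#'   alone.
#'
#' A candidate is *confirmed* when supported by at least two samples or
#' by a cross-compartment pair. When several candidates arise, the one
#' with the highest maximal frequency across samples wins (ties broken
#' by clonotype key for determinism).
#'
#' @param reps List of [repertoire()] objects for one patient.
#' @param meta Tibble of sample metadata (see [read_sample_meta()]) with
#'   one row per element of `reps`, matched by `sample_id`.
#' @param overrep_threshold Strict spectrum-fraction threshold for the
#'   overrepresentation rule (default `1/3`).
#' @param overlap_threshold Strict frequency threshold for the
#'   cross-compartment rule (default `0.05`).
#' @return An object of class `mm_clone` (fields `patient_id`, `chain`,
#'   `cdr3_nt`, `v_segment`, `j_segment`, `evidence` — one of
#'   `"OVERREPRESENTED"`, `"CROSS_COMPARTMENT"`, `"BOTH"` —
#'   `confirmed`, `support_samples`, `max_freq`), or `NULL` when no
#'   candidate emerges.
#' @export
identify_mm_clone <- function(reps, meta,
                              overrep_threshold = 1 / 3,
                              overlap_threshold = 0.05) {
  stopifnot(is.list(reps), is.data.frame(meta))
  ids <- vapply(reps, rep_sample_id, character(1))
  meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) {
    stop("every repertoire needs a metadata row (matched by sample_id)",
         call. = FALSE)
  }
  patient_id <- unique(meta$patient_id)
  stopifnot(length(patient_id) == 1L)
  chain <- setdiff(unique(meta$involved_chain), "UNKNOWN")
  if (length(chain) != 1L) {
    stop("patient ", patient_id,
         ": involved chain is not uniquely defined", call. = FALSE)
  }
  on_chain <- vapply(reps, function(r) identical(rep_chain(r), chain),
                     logical(1))
  usable <- on_chain & vapply(reps, qc_pass, logical(1))
  if (!any(on_chain)) {
    stop("patient ", patient_id, ": no samples on involved chain ", chain,
         call. = FALSE)
  }
  if (!any(usable)) return(NULL)
  reps <- reps[usable]
  meta <- meta[usable, , drop = FALSE]

  gdna_materials <- c("GDNA_BM", "GDNA_PLEURAL", "FFPE")
  diag_phase <- meta$response_raw %in% c("ID", "RD", "PD")

  # long table of (sample, key, freq) across the patient's repertoires
  long <- purrr::map2_dfr(reps, meta$sample_id, function(r, sid) {
    tibble::tibble(sample_id = sid,
                   key = clone_key(r),
                   cdr3_nt = r$cdr3_nt, v_segment = r$v_segment,
                   j_segment = r$j_segment, freq = r$freq)
  })

  over_keys <- unique(long$key[long$freq > overrep_threshold &
                                 long$sample_id %in% meta$sample_id[diag_phase]])

  cf_ids <- meta$sample_id[meta$material == "CFDNA_PB"]
  gd_ids <- meta$sample_id[meta$material %in% gdna_materials]
  hi <- long[long$freq > overlap_threshold, ]
  cross_keys <- intersect(unique(hi$key[hi$sample_id %in% cf_ids]),
                          unique(hi$key[hi$sample_id %in% gd_ids]))

  cand_keys <- union(over_keys, cross_keys)
  if (length(cand_keys) == 0L) return(NULL)

  cand <- long |>
    dplyr::filter(.data$key %in% cand_keys, .data$freq > 0) |>
    dplyr::group_by(.data$key, .data$cdr3_nt, .data$v_segment,
                    .data$j_segment) |>
    dplyr::summarise(max_freq = max(.data$freq),
                     support = list(unique(.data$sample_id)),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$max_freq), .data$key)
  best <- cand[1L, ]
  evidence <- if (best$key %in% over_keys && best$key %in% cross_keys) {
    "BOTH"
  } else if (best$key %in% cross_keys) {
    "CROSS_COMPARTMENT"
  } else {
    "OVERREPRESENTED"
  }
  support <- best$support[[1L]]
  structure(
    list(patient_id = patient_id, chain = chain,
         cdr3_nt = best$cdr3_nt, v_segment = best$v_segment,
         j_segment = best$j_segment,
         evidence = evidence,
         confirmed = length(support) >= 2L ||
           evidence %in% c("CROSS_COMPARTMENT", "BOTH"),
         support_samples = support,
         max_freq = best$max_freq),
    class = "mm_clone"
  )
}

#' @export
print.mm_clone <- function(x, ...) {
  cat("<mm_clone> patient", x$patient_id, "chain", x$chain, "\n")
  cat("  key:", x$cdr3_nt, x$v_segment, x$j_segment, "\n")
  cat("  evidence:", x$evidence,
      if (x$confirmed) "(confirmed)" else "(unconfirmed)", "\n")
  cat("  max freq:", format(x$max_freq, digits = 4),
      " support:", paste(x$support_samples, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.mm_clone <- function(x, ...) {
  tibble::tibble(
    patient_id = x$patient_id, chain = x$chain,
    cdr3_nt = x$cdr3_nt, v_segment = x$v_segment, j_segment = x$j_segment,
    evidence = x$evidence, confirmed = x$confirmed,
    n_support = length(x$support_samples), max_freq = x$max_freq
  )
}

#' NGS result categories
#'
#' @return Character vector of the four per-sample NGS result categories.
#' @export
ngs_categories <- function() {
  c("MM_TOP", "MM_DETECTED", "MM_NOT_DETECTED", "NO_CLONE_DEFINED")
}

#' Classify one sample's NGS result against the patient's myeloma clone
#'
#' `NO_CLONE_DEFINED` when no clone is known for the patient (positivity
#' undefined, excluded from concordance); `MM_TOP` when the clone is the
#' sample's most abundant clonotype; `MM_DETECTED` when present at any
#' read count — irrespective of frequency — but not top;
#' `MM_NOT_DETECTED` otherwise. Samples with a detected clone, at
#' whatever frequency, count as NGS positive.
#'
#' @param rep An [repertoire()] passing [qc_pass()].
#' @param clone An `mm_clone` or `NULL`.
#' @return One-row tibble with columns `category` and `positive`
#'   (logical, `NA` when no clone is defined).
#' @export
classify_ngs <- function(rep, clone) {
  if (is.null(clone)) {
    return(tibble::tibble(category = "NO_CLONE_DEFINED", positive = NA))
  }
  f <- clone_freq(rep, clone)
  category <- if (f <= 0) {
    "MM_NOT_DETECTED"
  } else {
    top <- top_clonotype(rep)
    if (identical(clone_key(top), clone_key(clone))) "MM_TOP" else "MM_DETECTED"
  }
  tibble::tibble(category = category,
                 positive = category %in% c("MM_TOP", "MM_DETECTED"))
}
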