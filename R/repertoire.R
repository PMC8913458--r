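#' Construct a light-chain clonotype repertoire
#'
#' A repertoire is a tibble of clonotypes — one row per unique
#' (CDR3 nucleotide, V segment, J segment) key — carrying the sample
#' identifier, chain (IGK or IGL) and total read count as attributes.
#' Rows are ordered by descending read count (ties broken by CDR3
#' nucleotide sequence so the ordering is deterministic). Frequencies
#' are always recomputed from counts, never trusted from the caller.
#'
#' @param clonotypes Data frame with columns `cdr3_nt`, `cdr3_aa`,
#'   `v_segment`, `j_segment`, `count`. A `freq` column, if present,
#'   is ignored and recomputed. Duplicate keys are merged by summing
#'   counts; zero-count rows are dropped.
#' @param sample_id Sample identifier string.
#' @param chain `"IGK"` or `"IGL"`.
#' @return A tibble of class `lc_repertoire` with columns `cdr3_nt`,
#'   `cdr3_aa`, `v_segment`, `j_segment`, `count`, `freq` and attributes
#'   `sample_id`, `chain`, `total_reads`.
#' @examples
#' df <- tibble::tibble(
#'   cdr3_nt = c("TGCCAA", "TGCGGG"), cdr3_aa = c("CQ", "CG"),
#'   v_segment = "IGKV1-5", j_segment = "IGKJ1", count = c(70, 30)
#' )
#' rep <- repertoire(df, "S1", "IGK")
#' total_reads(rep)
#' @export
repertoire <- function(clonotypes, sample_id, chain = c("IGK", "IGL")) {
  chain <- match.arg(chain)
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  needed <- c("cdr3_nt", "v_segment", "j_segment", "count")
  missing_cols <- setdiff(needed, names(clonotypes))
  if (length(missing_cols) > 0L) {
    stop("clonotype table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tab <- tibble::as_tibble(clonotypes)
  if (!"cdr3_aa" %in% names(tab)) tab$cdr3_aa <- ""
  tab <- dplyr::filter(tab, .data$count > 0)
  if (nrow(tab) == 0L) {
    stop("empty repertoire: no clonotypes with positive count", call. = FALSE)
  }
  if (any(!grepl("^[ACGT]+$", tab$cdr3_nt))) {
    stop("cdr3_nt must be nonempty uppercase ACGT strings", call. = FALSE)
  }
  # merge duplicate (cdr3_nt, V, J) keys; counts are additive
  tab <- tab |>
    dplyr::group_by(.data$cdr3_nt, .data$v_segment, .data$j_segment) |>
    dplyr::summarise(
      cdr3_aa = dplyr::first(.data$cdr3_aa),
      count = sum(.data$count),
      .groups = "drop"
    )
  total <- sum(tab$count)
  tab <- tab |>
    dplyr::mutate(freq = .data$count / total) |>
    dplyr::select("cdr3_nt", "cdr3_aa", "v_segment", "j_segment",
                  "count", "freq") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$cdr3_nt)
  structure(tab,
            sample_id = sample_id, chain = chain, total_reads = total,
            class = c("lc_repertoire", class(tab)))
}

#' @rdname repertoire
#' @param x An `lc_repertoire`.
#' @export
total_reads <- function(x) attr(x, "total_reads")

#' @rdname repertoire
#' @export
rep_chain <- function(x) attr(x, "chain")

#' @rdname repertoire
#' @export
rep_sample_id <- function(x) attr(x, "sample_id")

#' Read a clonotype table exported by a repertoire pipeline
#'
#' Reads the tab-separated clonotype export dialect produced by standard
#' repertoire tools (header row; columns `count`, `freq`, `cdr3nt`, `v`,
#' `j`, optionally `cdr3aa` and `d`; common aliases such as `cloneCount`
#' or `allVHitsWithScore` are recognized). Zero-count rows are dropped,
#' duplicate (CDR3nt, V, J) rows merged, and frequencies recomputed from
#' counts.
#'
#' @param path Path to a TSV file.
#' @param sample_id Sample identifier to attach.
#' @param chain `"IGK"`, `"IGL"`, or `NULL` to infer from the V-segment
#'   prefix (IGKV/IGLV) of the most abundant clonotype.
#' @return An [repertoire()] object.
#' @export
read_clonotype_table <- function(path, sample_id, chain = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(raw) == 0L) stop("empty clonotype table: ", path, call. = FALSE)
  nm <- tolower(names(raw))
  pick <- function(aliases, required = TRUE, label = aliases[[1]]) {
    hit <- which(nm %in% aliases)
    if (length(hit) == 0L) {
      if (required) {
        stop("clonotype table ", path, " is missing the '", label,
             "' column", call. = FALSE)
      }
      return(NA_integer_)
    }
    hit[[1]]
  }
  i_count <- pick(c("count", "clonecount", "#count", "reads"), label = "count")
  i_nt <- pick(c("cdr3nt", "cdr3_nt", "nseqcdr3"), label = "cdr3nt")
  i_v <- pick(c("v", "v_segment", "allvhitswithscore", "bestvhit"), label = "v")
  i_j <- pick(c("j", "j_segment", "alljhitswithscore", "bestjhit"), label = "j")
  i_aa <- pick(c("cdr3aa", "cdr3_aa", "aaseqcdr3"), required = FALSE)
  tab <- tibble::tibble(
    cdr3_nt = toupper(as.character(raw[[i_nt]])),
    cdr3_aa = if (is.na(i_aa)) "" else as.character(raw[[i_aa]]),
    v_segment = as.character(raw[[i_v]]),
    j_segment = as.character(raw[[i_j]]),
    count = as.integer(raw[[i_count]])
  )
  if (is.null(chain)) {
    top_v <- tab$v_segment[which.max(tab$count)]
    chain <- if (startsWith(top_v, "IGLV")) "IGL" else "IGK"
  }
  repertoire(tab, sample_id = sample_id, chain = chain)
}

#' Write a repertoire back to the tab-separated clonotype dialect
#'
#' @param rep An [repertoire()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_clonotype_table <- function(rep, path) {
  out <- tibble::tibble(
    count = rep$count, freq = rep$freq, cdr3nt = rep$cdr3_nt,
    cdr3aa = rep$cdr3_aa, v = rep$v_segment, j = rep$j_segment
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read-depth quality control
#'
#' A repertoire is analyzable when it incorporates at least `min_reads`
#' reads aligned to the involved light chain (boundary inclusive).
#'
#' @param rep An [repertoire()].
#' @param min_reads Minimum total read count (default 20000).
#' @return Logical scalar.
#' @export
qc_pass <- function(rep, min_reads = 20000L) {
  total_reads(rep) >= min_reads
}

#' Bias-corrected Chao1 diversity estimator
#'
#' Estimates clonotype richness as
#' \deqn{S_{obs} + \frac{f_1 (f_1 - 1)}{2 (f_2 + 1)}}
#' where \eqn{S_{obs}} is the number of observed clonotypes and
#' \eqn{f_1}, \eqn{f_2} the numbers of clonotypes seen exactly once and
#' twice. Always at least \eqn{S_{obs}}.
#'
#' @param rep An [repertoire()].
#' @return Numeric richness estimate.
#' @export
chao1_bc <- function(rep) {
  if (nrow(rep) == 0L) stop("empty repertoire", call. = FALSE)
  s_obs <- nrow(rep)
  f1 <- sum(rep$count == 1L)
  f2 <- sum(rep$count == 2L)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Most abundant clonotype
#'
#' Returns the clonotype with maximal read count; ties are broken by
#' lexicographic CDR3 nucleotide sequence so the answer is deterministic.
#'
#' @param rep An [repertoire()].
#' @return One-row tibble.
#' @export
top_clonotype <- function(rep) {
  if (nrow(rep) == 0L) stop("empty repertoire", call. = FALSE)
  tibble::as_tibble(rep)[1L, ]  # rows are sorted (count desc, cdr3_nt)
}

clone_key <- function(df) {
  paste(df$cdr3_nt, df$v_segment, df$j_segment, sep = "|")
}

#' Clonotypes shared above a frequency threshold
#'
#' Keys present at frequency strictly greater than `min_freq` in both
#' repertoires, sorted by combined frequency, descending. Symmetric in
#' its two arguments.
#'
#' @param rep_a,rep_b Repertoires on the same chain.
#' @param min_freq Strict frequency threshold (default 0.05, i.e. > 5%).
#' @return Tibble with columns `cdr3_nt`, `v_segment`, `j_segment`,
#'   `freq_a`, `freq_b`.
#' @export
shared_clonotypes <- function(rep_a, rep_b, min_freq = 0.05) {
  if (!identical(rep_chain(rep_a), rep_chain(rep_b))) {
    stop("repertoires are on different chains (",
         rep_chain(rep_a), " vs ", rep_chain(rep_b), ")", call. = FALSE)
  }
  a <- dplyr::filter(tibble::as_tibble(rep_a), .data$freq > min_freq)
  b <- dplyr::filter(tibble::as_tibble(rep_b), .data$freq > min_freq)
  dplyr::inner_join(
    dplyr::select(a, "cdr3_nt", "v_segment", "j_segment", freq_a = "freq"),
    dplyr::select(b, "cdr3_nt", "v_segment", "j_segment", freq_b = "freq"),
    by = c("cdr3_nt", "v_segment", "j_segment")
  ) |>
    dplyr::arrange(dplyr::desc(.data$freq_a + .data$freq_b), .data$cdr3_nt)
}

#' Frequency of one clonotype key in a repertoire
#'
#' @param rep An [repertoire()].
#' @param key One-row data frame (or list) with `cdr3_nt`, `v_segment`,
#'   `j_segment`.
#' @return Frequency in `[0, 1]`; 0 when absent.
#' @export
clone_freq <- function(rep, key) {
  hit <- rep$cdr3_nt == key$cdr3_nt &
    rep$v_segment == key$v_segment & rep$j_segment == key$j_segment
  if (any(hit)) rep$freq[which(hit)[1L]] else 0
}

#' Track a myeloma clone across time-ordered samples
#'
#' @param reps List of repertoires (all on the clone's chain).
#' @param dates Vector of collection dates, same length as `reps`.
#' @param clone An `mm_clone` (see [identify_mm_clone()]) or any object
#'   with `cdr3_nt`, `v_segment`, `j_segment`.
#' @return Tibble with columns `date`, `sample_id`, `freq` (0 where the
#'   clone is absent), in the order supplied.
#' @export
track_clone <- function(reps, dates, clone) {
  stopifnot(length(reps) == length(dates))
  if (length(reps) == 0L) {
    return(tibble::tibble(date = as.Date(character()),
                          sample_id = character(), freq = numeric()))
  }
  ok <- vapply(reps, function(r) identical(rep_chain(r), clone$chain), logical(1))
  if (!is.null(clone$chain) && !all(ok)) {
    stop("all repertoires must be on the clone's chain", call. = FALSE)
  }
  tibble::tibble(
    date = dates,
    sample_id = vapply(reps, rep_sample_id, character(1)),
    freq = vapply(reps, clone_freq, numeric(1), key = clone)
  )
}
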