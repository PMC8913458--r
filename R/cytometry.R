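#' The nine-marker plasma-cell panel
#'
#' Marker order is fixed: CD81, CD45, CD38, CD138, CD27, CD19, CD117,
#' CD56, CD200. Plasma cells are gated on CD138 with CD38 and/or CD27;
#' the remaining markers carry the seven aberrancy criteria
#' (low-to-negative CD45, CD19, CD81, CD27; aberrant-positive CD117,
#' CD56, CD200).
#'
#' @return Character vector of the nine marker labels, in panel order.
#' @export
marker_panel <- function() {
  c("CD81", "CD45", "CD38", "CD138", "CD27", "CD19", "CD117", "CD56", "CD200")
}

aberrancy_low_markers <- function() c("CD45", "CD19", "CD81", "CD27")
aberrancy_pos_markers <- function() c("CD117", "CD56", "CD200")

check_event_table <- function(events) {
  miss <- setdiff(marker_panel(), names(events))
  if (length(miss) > 0L) {
    stop("event table is missing marker column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  invisible(events)
}

#' Read an event-level cytometry table
#'
#' CSV with a header of marker labels and one row per event (raw
#' fluorescence units, post-cleanup: scatter gating, doublet exclusion
#' and compensation are assumed done upstream).
#'
#' @param path CSV path.
#' @param sample_id Optional sample identifier stored as an attribute.
#' @return Tibble with the nine marker columns.
#' @export
read_event_table <- function(path, sample_id = NULL) {
  ev <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_event_table(ev)
  if (!is.null(sample_id)) attr(ev, "sample_id") <- sample_id
  ev
}

#' Gate thresholds for plasma-cell analysis
#'
#' Per-marker cutoffs in transformed (asinh) units: `positive_cutoff`
#' (at or above which a marker is positive) and `lowneg_cutoff` (below
#' which expression is low-to-negative), plus the asinh transform
#' cofactor and the minimum event count for a conclusive population.
#' Instruments and panels differ, so no universal numeric cutoffs
#' exist; [default_gate_thresholds()] places both cutoffs midway
#' between the low and high population means the synthetic generator is
#' calibrated to, and every value can be overridden (see
#' [read_gate_thresholds()] for YAML configuration).
#'
#' @param positive_cutoff,lowneg_cutoff Named numeric vectors (one value
#'   per panel marker) or scalars recycled across the panel.
#' @param cofactor asinh cofactor in raw fluorescence units.
#' @param min_events Minimum event count; a population is conclusive
#'   only when strictly more than `min_events` events support it.
#' @return List of class `gate_thresholds`.
#' @export
gate_thresholds <- function(positive_cutoff, lowneg_cutoff,
                            cofactor = 150, min_events = 10L) {
  expand <- function(x) {
    if (length(x) == 1L) x <- stats::setNames(rep(x, 9L), marker_panel())
    stopifnot(all(marker_panel() %in% names(x)))
    x[marker_panel()]
  }
  pos <- expand(positive_cutoff)
  low <- expand(lowneg_cutoff)
  if (any(low > pos)) {
    stop("lowneg_cutoff must not exceed positive_cutoff", call. = FALSE)
  }
  stopifnot(cofactor > 0)
  structure(list(positive_cutoff = pos, lowneg_cutoff = low,
                 cofactor = cofactor, min_events = as.integer(min_events)),
            class = "gate_thresholds")
}

#' @rdname gate_thresholds
#' @param lo_mean,hi_mean Transformed-unit means of the low and high
#'   expression populations the cutoffs separate (defaults 1 and 6,
#'   matching [make_flow_sample()]).
#' @export
default_gate_thresholds <- function(lo_mean = 1, hi_mean = 6,
                                    cofactor = 150, min_events = 10L) {
  mid <- (lo_mean + hi_mean) / 2
  gate_thresholds(positive_cutoff = mid, lowneg_cutoff = mid,
                  cofactor = cofactor, min_events = min_events)
}

#' Read gate thresholds from a YAML configuration
#'
#' Expected keys: `transform_cofactor`, `min_events`, and a `markers`
#' map of per-marker `positive_cutoff` / `lowneg_cutoff`; markers not
#' listed fall back to `default` entries.
#'
#' @param path YAML file path.
#' @return A [gate_thresholds()] object.
#' @export
read_gate_thresholds <- function(path) {
  cfg <- yaml::read_yaml(path)
  def_pos <- cfg$default$positive_cutoff %||% 3.5
  def_low <- cfg$default$lowneg_cutoff %||% def_pos
  pos <- low <- stats::setNames(rep(NA_real_, 9L), marker_panel())
  for (m in marker_panel()) {
    pos[m] <- cfg$markers[[m]]$positive_cutoff %||% def_pos
    low[m] <- cfg$markers[[m]]$lowneg_cutoff %||% def_low
  }
  gate_thresholds(pos, low,
                  cofactor = cfg$transform_cofactor %||% 150,
                  min_events = cfg$min_events %||% 10L)
}

#' asinh-transform raw fluorescence intensities
#'
#' Standard cytometry variance stabilization: each intensity `x` maps to
#' `asinh(x / cofactor)`. Monotone and order-preserving; 0 maps to 0.
#'
#' @param events Event table (raw units).
#' @param cofactor Positive cofactor (default 150).
#' @return Event table in transformed units.
#' @export
transform_intensities <- function(events, cofactor = 150) {
  stopifnot(cofactor > 0)
  check_event_table(events)
  dplyr::mutate(tibble::as_tibble(events),
                dplyr::across(dplyr::all_of(marker_panel()),
                              ~ asinh(.x / cofactor)))
}

#' Gate plasma-cell events
#'
#' An event is a plasma cell when CD138 is positive and CD38 and/or
#' CD27 is positive (all against `positive_cutoff`, in transformed
#' units).
#'
#' @param events Transformed event table.
#' @param thr A [gate_thresholds()].
#' @return Integer vector of plasma-cell row indices.
#' @export
gate_pc <- function(events, thr) {
  check_event_table(events)
  pos <- thr$positive_cutoff
  which(events$CD138 >= pos["CD138"] &
          (events$CD38 >= pos["CD38"] | events$CD27 >= pos["CD27"]))
}

event_aberrancy_flags <- function(events, idx, thr) {
  lo <- vapply(aberrancy_low_markers(),
               function(m) events[[m]][idx] < thr$lowneg_cutoff[m],
               logical(length(idx)))
  hi <- vapply(aberrancy_pos_markers(),
               function(m) events[[m]][idx] >= thr$positive_cutoff[m],
               logical(length(idx)))
  flags <- cbind(matrix(lo, nrow = length(idx)), matrix(hi, nrow = length(idx)))
  colnames(flags) <- c(aberrancy_low_markers(), aberrancy_pos_markers())
  flags
}

new_pc_population <- function(events, idx, label, thr) {
  med <- vapply(marker_panel(), function(m) stats::median(events[[m]][idx]),
                numeric(1))
  score <- sum(med[aberrancy_low_markers()] <
                 thr$lowneg_cutoff[aberrancy_low_markers()]) +
    sum(med[aberrancy_pos_markers()] >=
          thr$positive_cutoff[aberrancy_pos_markers()])
  structure(list(event_indices = idx, label = label,
                 aberrancy_score = as.integer(score),
                 mfi = vapply(marker_panel(),
                              function(m) mean(events[[m]][idx]), numeric(1))),
            class = "pc_population")
}

#' @export
print.pc_population <- function(x, ...) {
  cat("<pc_population>", x$label, "-", length(x$event_indices),
      "events, aberrancy score", x$aberrancy_score, "/7\n")
  invisible(x)
}

#' Split gated plasma cells into normal and aberrant subsets
#'
#' Each plasma-cell event receives seven aberrancy flags
#' (low-to-negative CD45, CD19, CD81, CD27; aberrant-positive CD117,
#' CD56, CD200). Events carrying at least two flags form the ABERRANT
#' (myeloma-phenotype) subset, the rest the NORMAL subset; empty subsets
#' are omitted. Each population's `aberrancy_score` counts the criteria
#' met by its per-marker median — phenotype aberrancy is a population
#' property, while per-event flags only drive the split.
#'
#' @param events Transformed event table.
#' @param pc_idx Plasma-cell indices from [gate_pc()].
#' @param thr A [gate_thresholds()].
#' @return List of `pc_population` objects (NORMAL first when present).
#' @export
split_pc_subsets <- function(events, pc_idx, thr) {
  check_event_table(events)
  if (length(pc_idx) == 0L) return(list())
  stopifnot(all(pc_idx >= 1L), all(pc_idx <= nrow(events)))
  n_flags <- rowSums(event_aberrancy_flags(events, pc_idx, thr))
  out <- list()
  normal_idx <- pc_idx[n_flags < 2]
  aberrant_idx <- pc_idx[n_flags >= 2]
  if (length(normal_idx) > 0L) {
    out <- c(out, list(new_pc_population(events, normal_idx, "NORMAL", thr)))
  }
  if (length(aberrant_idx) > 0L) {
    out <- c(out, list(new_pc_population(events, aberrant_idx, "ABERRANT", thr)))
  }
  out
}

#' Flow-cytometry sample categories
#'
#' @return Character vector of the four sample-level categories.
#' @export
flow_categories <- function() c("NO_PC", "N_PC", "MM_PC", "MM_AND_N_PC")

#' Categorize a sample by circulating-plasma-cell content
#'
#' More than `min_events` gated plasma-cell events count as a
#' significant number of circulating plasma cells; at or below that the
#' sample is `NO_PC` (the conservative reading of the at-exactly-ten
#' boundary). Otherwise the gated events are split into normal and
#' aberrant subsets: both conclusive (each > `min_events`) gives
#' `MM_AND_N_PC`, only the aberrant subset `MM_PC`, only the normal
#' subset `N_PC`, neither `NO_PC`.
#'
#' @param events Transformed event table.
#' @param thr A [gate_thresholds()].
#' @param min_events Conclusive-population threshold (default from `thr`).
#' @return Length-one character, one of [flow_categories()].
#' @export
classify_flow <- function(events, thr, min_events = thr$min_events) {
  pc_idx <- gate_pc(events, thr)
  if (length(pc_idx) <= min_events) return("NO_PC")
  pops <- split_pc_subsets(events, pc_idx, thr)
  n_of <- function(label) {
    hit <- purrr::keep(pops, ~ .x$label == label)
    if (length(hit) == 0L) 0L else length(hit[[1L]]$event_indices)
  }
  n_ab <- n_of("ABERRANT")
  n_no <- n_of("NORMAL")
  if (n_ab > min_events && n_no > min_events) return("MM_AND_N_PC")
  if (n_ab > min_events) return("MM_PC")
  if (n_no > min_events) return("N_PC")
  "NO_PC"
}

#' Mean fluorescence intensity of a marker over an event subset
#'
#' Arithmetic mean of the raw (untransformed) intensities.
#'
#' @param events Event table in raw units.
#' @param idx Nonempty event indices.
#' @param marker Panel marker label.
#' @return Numeric scalar.
#' @export
mfi <- function(events, idx, marker) {
  check_event_table(events)
  if (length(idx) == 0L) stop("empty event index set", call. = FALSE)
  stopifnot(marker %in% marker_panel())
  mean(events[[marker]][idx])
}

#' Holm-Sidak step-down adjustment
#'
#' Sorts the raw p-values ascending and takes
#' `adj_i = max_{j <= i} (1 - (1 - p_j)^(m - j + 1))`, clipped to 1,
#' returned in the original order. Uniformly at least as large as the
#' raw p-values and monotone along the sorted order.
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values, same order as `p`.
#' @export
holm_sidak <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  m <- length(p)
  ord <- order(p)
  step <- 1 - (1 - p[ord])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(step), 1)
  adj[order(ord)]
}

#' Paired marker-intensity comparison between compartments
#'
#' Per-marker paired t-tests of, e.g., peripheral-blood versus
#' bone-marrow MFI in the same patients, with Holm-Sidak step-down
#' adjustment across the nine panel markers.
#'
#' @param pairs Tibble with columns `marker`, `mfi_a`, `mfi_b` (one row
#'   per patient and marker; at least 2 complete pairs per marker) and
#'   optionally `patient_id`.
#' @return Tibble with one row per marker: `marker`, `n`, `estimate`
#'   (mean of `mfi_a - mfi_b`), `statistic`, `p.value`, `p.adjusted`.
#' @export
compare_mfi_paired <- function(pairs) {
  stopifnot(all(c("marker", "mfi_a", "mfi_b") %in% names(pairs)))
  res <- pairs |>
    dplyr::filter(!is.na(.data$mfi_a), !is.na(.data$mfi_b)) |>
    dplyr::group_by(.data$marker) |>
    dplyr::summarise(
      n = dplyr::n(),
      estimate = mean(.data$mfi_a - .data$mfi_b),
      statistic = {
        if (dplyr::n() < 2L) {
          stop("marker ", dplyr::cur_group()$marker,
               ": need at least 2 complete pairs", call. = FALSE)
        }
        d <- .data$mfi_a - .data$mfi_b
        if (stats::sd(d) == 0) 0 else unname(stats::t.test(d)$statistic)
      },
      p.value = {
        d <- .data$mfi_a - .data$mfi_b
        if (stats::sd(d) == 0) 1 else stats::t.test(d)$p.value
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(p.adjusted = holm_sidak(.data$p.value))
  res
}
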