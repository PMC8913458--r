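#' @importFrom rlang %||% .data
NULL

v_segment_labels <- function(chain) {
  switch(chain,
    IGK = c("IGKV1-5", "IGKV1-39", "IGKV2-28", "IGKV3-11", "IGKV3-20",
            "IGKV4-1"),
    IGL = c("IGLV1-40", "IGLV1-44", "IGLV2-8", "IGLV2-14", "IGLV3-1",
            "IGLV3-19")
  )
}

j_segment_labels <- function(chain) {
  switch(chain,
    IGK = paste0("IGKJ", 1:5),
    IGL = paste0("IGLJ", 1:3)
  )
}

# random in-frame CDR3 nucleotide sequences (length 30-60, multiple of 3)
random_cdr3 <- function(n) {
  lens <- sample(seq(30L, 60L, by = 3L), n, replace = TRUE)
  vapply(lens, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
}

random_keys <- function(n, chain) {
  tibble::tibble(
    cdr3_nt = random_cdr3(n),
    v_segment = sample(v_segment_labels(chain), n, replace = TRUE),
    j_segment = sample(j_segment_labels(chain), n, replace = TRUE)
  )
}

zipf_freqs <- function(n, shape) {
  w <- seq_len(n)^(-shape)
  w / sum(w)
}

# multinomial read sampling over explicit (key, freq) targets
sample_repertoire <- function(keys, freqs, total_reads, sample_id, chain) {
  stopifnot(nrow(keys) == length(freqs), abs(sum(freqs) - 1) < 1e-9)
  counts <- as.integer(stats::rmultinom(1L, total_reads, freqs))
  repertoire(
    tibble::tibble(
      cdr3_nt = keys$cdr3_nt,
      cdr3_aa = "",
      v_segment = keys$v_segment, j_segment = keys$j_segment,
      count = counts
    ),
    sample_id = sample_id, chain = chain
  )
}

#' Simulate a light-chain clonotype repertoire
#'
#' Clone-rank base frequencies follow a power law (Zipf) with exponent
#' `shape`, renormalized to `1 - mm_clone_freq`; an optional myeloma
#' clonotype is inserted at `mm_clone_freq` with a reserved key. Read
#' counts are drawn multinomially at `total_reads`. CDR3s are random
#' in-frame ACGT strings of length 30-60 with V/J labels from fixed
#' IGKV/IGKJ (or IGLV/IGLJ) lists. Pure function of its arguments and
#' `seed` (byte-identical reruns).
#'
#' The default exponent 1.2 yields several clonotypes above 5% of the
#' spectrum, emulating the oligoclonality of cell-free-DNA light-chain
#' repertoires at any disease stage.
#'
#' @param n_clonotypes Number of background clonotypes.
#' @param total_reads Total read count to distribute.
#' @param shape Power-law exponent for clone-rank frequencies.
#' @param mm_clone_freq Target frequency of the myeloma clone, or `NULL`
#'   for none.
#' @param mm_clone Optional key (list/row with `cdr3_nt`, `v_segment`,
#'   `j_segment`) to reuse for the myeloma clone, e.g. across samples of
#'   one patient; generated when `NULL`.
#' @param chain `"IGK"` or `"IGL"`.
#' @param sample_id Sample identifier.
#' @param seed Integer seed.
#' @return A [repertoire()]; when a myeloma clone was inserted its key
#'   is available as `attr(x, "mm_clone")`.
#' @export
make_repertoire <- function(n_clonotypes = 150L, total_reads = 30000L,
                            shape = 1.2, mm_clone_freq = NULL,
                            mm_clone = NULL, chain = c("IGK", "IGL"),
                            sample_id = "SIM", seed = 1L) {
  chain <- match.arg(chain)
  stopifnot(n_clonotypes >= 1L, total_reads >= 1L, shape > 0)
  if (!is.null(mm_clone_freq) &&
      (mm_clone_freq < 0 || mm_clone_freq >= 1)) {
    stop("mm_clone_freq must be in [0, 1)", call. = FALSE)
  }
  withr::with_seed(seed, {
    keys <- random_keys(n_clonotypes, chain)
    mmf <- mm_clone_freq %||% 0
    freqs <- zipf_freqs(n_clonotypes, shape) * (1 - mmf)
    if (!is.null(mm_clone_freq)) {
      mm_key <- if (is.null(mm_clone)) random_keys(1L, chain) else
        tibble::tibble(cdr3_nt = mm_clone$cdr3_nt,
                       v_segment = mm_clone$v_segment,
                       j_segment = mm_clone$j_segment)
      keys <- dplyr::bind_rows(mm_key, keys)
      freqs <- c(mmf, freqs)
    }
    out <- sample_repertoire(keys, freqs, total_reads, sample_id, chain)
    if (!is.null(mm_clone_freq)) {
      attr(out, "mm_clone") <- as.list(keys[1L, ])
    }
    out
  })
}

#' Simulate paired cfDNA and genomic-DNA repertoires
#'
#' The myeloma clone is shared by construction (`mm_clone_freq` in the
#' cfDNA sample, `gdna_mm_freq` in the genomic-DNA sample). A
#' `shared_fraction` of background clonotypes — taken from the
#' low-frequency tail of the rank spectrum — reuse identical keys in
#' both compartments; `n_shared_high` additional clonotypes are planted
#' at high frequency (9%, 7%, 6%, ...) in both, to emulate pairs with
#' more than one prominent shared rearrangement. All other keys are
#' disjoint.
#'
#' @inheritParams make_repertoire
#' @param shared_fraction Fraction in `[0, 1]` of background clonotype
#'   ranks whose keys are reused across compartments.
#' @param gdna_mm_freq Myeloma-clone frequency in the genomic-DNA
#'   sample.
#' @param n_shared_high Number of extra shared high-frequency
#'   clonotypes.
#' @param sample_id_cf,sample_id_gd Sample identifiers.
#' @return List with elements `cfdna` and `gdna` ([repertoire()]s
#'   sharing `attr(, "mm_clone")`).
#' @export
make_paired_compartments <- function(n_clonotypes = 150L,
                                     total_reads = 30000L, shape = 1.2,
                                     mm_clone_freq = 0.35,
                                     gdna_mm_freq = 0.5,
                                     shared_fraction = 0.3,
                                     n_shared_high = 0L,
                                     chain = c("IGK", "IGL"),
                                     sample_id_cf = "SIM_CF",
                                     sample_id_gd = "SIM_GD",
                                     seed = 1L) {
  chain <- match.arg(chain)
  stopifnot(shared_fraction >= 0, shared_fraction <= 1, n_shared_high >= 0L)
  high_freqs <- c(0.09, 0.07, 0.06, 0.055)[seq_len(n_shared_high)]
  withr::with_seed(seed, {
    mm_key <- random_keys(1L, chain)
    high_keys <- if (n_shared_high > 0L) random_keys(n_shared_high, chain)
    bg_cf <- random_keys(n_clonotypes, chain)
    n_shared <- round(shared_fraction * n_clonotypes)
    bg_gd <- dplyr::bind_rows(
      random_keys(n_clonotypes - n_shared, chain),
      utils::tail(bg_cf, n_shared)  # low-frequency tail reused
    )
    build <- function(bg, mmf, sid) {
      mass <- 1 - mmf - sum(high_freqs)
      stopifnot(mass > 0)
      keys <- dplyr::bind_rows(mm_key, high_keys, bg)
      freqs <- c(mmf, high_freqs, zipf_freqs(n_clonotypes, shape) * mass)
      sample_repertoire(keys, freqs, total_reads, sid, chain)
    }
    cf <- build(bg_cf, mm_clone_freq, sample_id_cf)
    gd <- build(bg_gd, gdna_mm_freq, sample_id_gd)
    attr(cf, "mm_clone") <- attr(gd, "mm_clone") <- as.list(mm_key)
    list(cfdna = cf, gdna = gd)
  })
}

#' Reference expression profiles for simulated event populations
#'
#' `"background"` — non-plasma-cell leukocytes (CD45 high, all else
#' low). `"normal_pc"` — normal plasma cells (CD38/CD138/CD27 high,
#' lineage markers CD45/CD19/CD81 high, no aberrant markers).
#' `"mm_pc"` — aberrant plasma cells carrying two phenotypic
#' aberrancies (CD45 low-to-negative, CD56 aberrant-positive).
#'
#' @param name Profile name.
#' @return Named character vector over the panel markers, values
#'   `"LO"`/`"HI"`.
#' @export
flow_profile <- function(name = c("background", "normal_pc", "mm_pc")) {
  name <- match.arg(name)
  base <- stats::setNames(rep("LO", 9L), marker_panel())
  switch(name,
    background = replace(base, "CD45", "HI"),
    normal_pc = replace(base, c("CD81", "CD45", "CD38", "CD138", "CD27",
                                "CD19"), "HI"),
    mm_pc = replace(base, c("CD81", "CD38", "CD138", "CD27", "CD19",
                            "CD56"), "HI")
  )
}

#' Simulate an event-level cytometry sample
#'
#' Each event is drawn from its population's profile: the marker's
#' transformed (asinh) intensity is Gaussian with mean `lo_mean` or
#' `hi_mean` and standard deviation `sigma`, then mapped back to raw
#' fluorescence units through the inverse transform (negative raw
#' values are clamped to 0). Rows are shuffled; the generating
#' population of each row is retained in `attr(, "truth")`.
#'
#' @param n_background Number of background (non-plasma-cell) events.
#' @param populations List of `list(profile = , n_events = )`
#'   entries; `profile` is a named `"LO"`/`"HI"` vector (see
#'   [flow_profile()]) or a profile name.
#' @param lo_mean,hi_mean Transformed-unit population means (defaults 1
#'   and 6: five transformed units of separation).
#' @param sigma Transformed-unit standard deviation (default 0.35).
#' @param cofactor asinh cofactor used for the inverse mapping.
#' @param sample_id Sample identifier (stored as attribute).
#' @param seed Integer seed.
#' @return Tibble of raw intensities (nine marker columns) with
#'   attributes `sample_id` and `truth`.
#' @export
make_flow_sample <- function(n_background = 9950L,
                             populations = list(),
                             lo_mean = 1, hi_mean = 6, sigma = 0.35,
                             cofactor = 150, sample_id = "SIM",
                             seed = 1L) {
  stopifnot(n_background >= 0L, sigma > 0, lo_mean < hi_mean)
  specs <- c(list(list(profile = "background", n_events = n_background)),
             populations)
  withr::with_seed(seed, {
    blocks <- purrr::imap(specs, function(sp, i) {
      prof <- sp$profile
      if (is.character(prof) && length(prof) == 1L) prof <- flow_profile(prof)
      stopifnot(all(marker_panel() %in% names(prof)))
      n <- sp$n_events
      if (n == 0L) return(NULL)
      cols <- lapply(marker_panel(), function(m) {
        mu <- if (prof[[m]] == "HI") hi_mean else lo_mean
        pmax(0, sinh(stats::rnorm(n, mu, sigma)) * cofactor)
      })
      names(cols) <- marker_panel()
      tb <- tibble::as_tibble(cols)
      tb$.pop <- if (i == 1L) "background" else
        sp$label %||% paste0("pop", i - 1L)
      tb
    })
    ev <- dplyr::bind_rows(blocks)
    ev <- ev[sample.int(nrow(ev)), , drop = FALSE]
    truth <- ev$.pop
    ev$.pop <- NULL
    attr(ev, "sample_id") <- sample_id
    attr(ev, "truth") <- truth
    ev
  })
}
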