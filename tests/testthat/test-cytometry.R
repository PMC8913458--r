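# transformed-unit event rows: everything LO (1) except the named markers HI
hi_event <- function(hi = character(), hi_val = 6, lo_val = 1) {
  v <- stats::setNames(rep(lo_val, 9L), marker_panel())
  v[hi] <- hi_val
  v
}

thr <- default_gate_thresholds()  # cutoffs at 3.5 transformed units

test_that("asinh transform is anchored at zero and order-preserving", {
  ev <- events_from_matrix(matrix(0, nrow = 1, ncol = 9))
  expect_equal(as.numeric(transform_intensities(ev)[1, ]), rep(0, 9))
  ev2 <- events_from_matrix(matrix(150, nrow = 1, ncol = 9))
  expect_equal(transform_intensities(ev2, 150)$CD38, asinh(1),
               tolerance = 1e-12)
  x <- sort(stats::runif(50, 0, 1e4))
  tx <- asinh(x / 150)
  expect_true(all(diff(tx) > 0))
})

test_that("plasma-cell gate requires CD138 with CD38 and/or CD27", {
  expect_length(gate_pc(events_from_matrix(matrix(numeric(0), ncol = 9)),
                        thr), 0L)
  rows <- rbind(
    hi_event(c("CD138", "CD38")),          # in
    hi_event(c("CD138", "CD27")),          # in: and/or rule
    hi_event(c("CD138", "CD38", "CD27")),  # in
    hi_event("CD138"),                     # out: no CD38/CD27
    hi_event(c("CD38", "CD27")),           # out: no CD138
    hi_event()                             # out
  )
  expect_equal(gate_pc(events_from_matrix(rows), thr), 1:3)
})

test_that("well-separated spiked plasma cells are gated exactly", {
  ev <- make_flow_sample(
    n_background = 1000L,
    populations = list(list(profile = "normal_pc", n_events = 50L,
                            label = "pc")),
    seed = 11L)
  tev <- transform_intensities(ev, thr$cofactor)
  idx <- gate_pc(tev, thr)
  expect_setequal(idx, which(attr(ev, "truth") == "pc"))
})

test_that("gate matches a row-by-row predicate oracle", {
  set.seed(21)
  ev <- events_from_matrix(matrix(stats::runif(900 * 9, 0, 7), ncol = 9))
  oracle <- which(vapply(seq_len(nrow(ev)), function(i) {
    ev$CD138[i] >= thr$positive_cutoff["CD138"] &&
      (ev$CD38[i] >= thr$positive_cutoff["CD38"] ||
         ev$CD27[i] >= thr$positive_cutoff["CD27"])
  }, logical(1)))
  expect_identical(gate_pc(ev, thr), oracle)
})

test_that("subset split needs at least two per-event aberrancy flags", {
  normal <- hi_event(c("CD81", "CD45", "CD38", "CD138", "CD27", "CD19"))
  aberr <- hi_event(c("CD81", "CD38", "CD138", "CD27", "CD19", "CD56"))
  one_flag <- hi_event(c("CD81", "CD45", "CD38", "CD138", "CD27", "CD19",
                         "CD117"))  # only CD117 aberrant-positive

  all_norm <- events_from_matrix(do.call(rbind, replicate(5, list(normal))))
  pops <- split_pc_subsets(all_norm, 1:5, thr)
  expect_length(pops, 1L)
  expect_equal(pops[[1]]$label, "NORMAL")

  mix <- events_from_matrix(rbind(normal, normal, aberr, aberr, aberr))
  pops <- split_pc_subsets(mix, 1:5, thr)
  expect_setequal(vapply(pops, `[[`, character(1), "label"),
                  c("NORMAL", "ABERRANT"))
  ab <- pops[[which(vapply(pops, `[[`, character(1), "label") == "ABERRANT")]]
  expect_gte(ab$aberrancy_score, 2L)
  expect_equal(ab$event_indices, 3:5)

  single <- events_from_matrix(rbind(one_flag, one_flag))
  pops <- split_pc_subsets(single, 1:2, thr)
  expect_length(pops, 1L)
  expect_equal(pops[[1]]$label, "NORMAL")
})

test_that("subset split partitions the gated indices", {
  set.seed(31)
  ev <- events_from_matrix(matrix(stats::runif(600 * 9, 0, 7), ncol = 9))
  idx <- gate_pc(ev, thr)
  pops <- split_pc_subsets(ev, idx, thr)
  got <- sort(unlist(lapply(pops, `[[`, "event_indices")))
  expect_identical(got, sort(idx))
  if (length(pops) == 2L) {
    expect_length(intersect(pops[[1]]$event_indices,
                            pops[[2]]$event_indices), 0L)
  }
})

test_that("sample categories follow the conclusive-event rules", {
  empty <- events_from_matrix(matrix(numeric(0), ncol = 9))
  expect_equal(classify_flow(empty, thr), "NO_PC")

  aberr <- hi_event(c("CD81", "CD38", "CD138", "CD27", "CD19", "CD56"))
  normal <- hi_event(c("CD81", "CD45", "CD38", "CD138", "CD27", "CD19"))
  bg <- hi_event("CD45")

  mm30 <- events_from_matrix(do.call(rbind, c(replicate(30, list(aberr)),
                                              replicate(100, list(bg)))))
  expect_equal(classify_flow(mm30, thr), "MM_PC")

  both <- events_from_matrix(do.call(rbind, c(replicate(15, list(aberr)),
                                              replicate(15, list(normal)))))
  expect_equal(classify_flow(both, thr), "MM_AND_N_PC")

  n30 <- events_from_matrix(do.call(rbind, replicate(30, list(normal))))
  expect_equal(classify_flow(n30, thr), "N_PC")

  # exactly ten gated events are not conclusive (conservative boundary)
  ten <- events_from_matrix(do.call(rbind, replicate(10, list(aberr))))
  expect_equal(classify_flow(ten, thr), "NO_PC")
  eleven <- events_from_matrix(do.call(rbind, replicate(11, list(aberr))))
  expect_equal(classify_flow(eleven, thr), "MM_PC")
})

test_that("appending aberrant events never demotes an MM_PC call", {
  aberr <- hi_event(c("CD81", "CD38", "CD138", "CD27", "CD19", "CD56"))
  base <- do.call(rbind, replicate(12, list(aberr)))
  for (extra in c(0, 10, 100)) {
    ev <- events_from_matrix(
      do.call(rbind, c(list(base), replicate(extra, list(aberr)))))
    expect_equal(classify_flow(ev, thr), "MM_PC")
  }
})

test_that("MFI is the arithmetic mean of raw intensities", {
  ev <- events_from_matrix(matrix(rep(c(100, 10, 30), each = 9),
                                  ncol = 9, byrow = TRUE))
  expect_equal(mfi(ev, 1L, "CD38"), 100)
  expect_equal(mfi(ev, 2:3, "CD38"), 20)
  expect_equal(mfi(ev, c(3L, 2L), "CD38"), 20)  # order-invariant
  expect_error(mfi(ev, integer(0), "CD38"), "empty")
  expect_error(mfi(ev, 1L, "CD3"))
})

test_that("Holm-Sidak step-down matches its closed form", {
  expect_equal(holm_sidak(c(0.01, 0.04)), c(1 - 0.99^2, 0.04),
               tolerance = 1e-12)
  set.seed(41)
  for (i in 1:20) {
    p <- stats::runif(9)
    adj <- holm_sidak(p)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))  # monotone when sorted
  }
})

test_that("paired MFI comparison handles identical and shifted markers", {
  pairs <- dplyr::bind_rows(
    tibble::tibble(marker = "CD38", mfi_a = c(10, 20, 30),
                   mfi_b = c(10, 20, 30)),
    tibble::tibble(marker = "CD138", mfi_a = c(10, 20, 30),
                   mfi_b = c(15, 26, 34))
  )
  res <- compare_mfi_paired(pairs)
  same <- res[res$marker == "CD38", ]
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  shift <- res[res$marker == "CD138", ]
  expect_lt(shift$estimate, 0)
  expect_gte(shift$p.adjusted, shift$p.value)
  expect_error(compare_mfi_paired(
    tibble::tibble(marker = "CD56", mfi_a = 1, mfi_b = 2)), "2 complete")
})

test_that("YAML threshold configuration round-trips", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "transform_cofactor: 120",
    "min_events: 15",
    "default:",
    "  positive_cutoff: 3.0",
    "  lowneg_cutoff: 2.5",
    "markers:",
    "  CD56:",
    "    positive_cutoff: 4.0"
  ), path)
  cfg <- read_gate_thresholds(path)
  expect_equal(cfg$cofactor, 120)
  expect_equal(cfg$min_events, 15L)
  expect_equal(unname(cfg$positive_cutoff["CD56"]), 4.0)
  expect_equal(unname(cfg$positive_cutoff["CD38"]), 3.0)
  expect_equal(unname(cfg$lowneg_cutoff["CD45"]), 2.5)
  expect_error(gate_thresholds(1, 2), "lowneg")
})
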