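# deterministic ACGT string for clonotype i (base-4 encoding, length 9)
int2nt <- function(i, width = 9L) {
  digits <- integer(width)
  for (k in seq_len(width)) {
    digits[k] <- i %% 4L
    i <- i %/% 4L
  }
  paste(c("A", "C", "G", "T")[digits + 1L], collapse = "")
}

# minimal repertoire with the given counts and deterministic unique keys
mini_rep <- function(counts, sample_id = "T1", chain = "IGK",
                     cdr3 = NULL, v = "IGKV1-5", j = "IGKJ1") {
  n <- length(counts)
  repertoire(
    tibble::tibble(
      cdr3_nt = cdr3 %||% vapply(seq_len(n), int2nt, character(1)),
      cdr3_aa = "",
      v_segment = rep_len(v, n),
      j_segment = rep_len(j, n),
      count = counts
    ),
    sample_id = sample_id, chain = chain
  )
}

# metadata row builder
meta_row <- function(sample_id, patient_id = "P1", date = "2017-01-01",
                     material = "CFDNA_PB", response = "ID",
                     serology = "UNKNOWN", chain = "IGK") {
  tibble::tibble(sample_id = sample_id, patient_id = patient_id,
                 collection_date = as.Date(date), material = material,
                 response_raw = response, serology = serology,
                 involved_chain = chain)
}

# event table with explicit transformed values for a few events
events_from_matrix <- function(m) {
  colnames(m) <- marker_panel()
  tibble::as_tibble(m)
}
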