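# Small fixture builders used across test files. Everything is generated
# in code; no binary fixtures.

quant_row <- function(run = "r1", study = "s1", matrix = "EDTA",
                      platform = "p1", sample = "smp1", group = "pool",
                      protein = "P1", seq = "SPELQAEAK", charge = 2L,
                      channel = "L", intensity = 100, rt = NA_real_) {
  data.frame(run_id = run, study_id = study, matrix = matrix,
             platform_id = platform, sample_id = sample, group = group,
             protein_group = protein, stripped_seq = seq,
             modified_seq = seq, charge = charge, channel = channel,
             intensity = intensity, rt = rt, stringsAsFactors = FALSE)
}

# one-study quant table from a precursor-by-run intensity matrix (NA = not
# detected)
pool_table <- function(mat, study = "s1", matrix = "EDTA",
                       seqs = NULL, proteins = NULL) {
  if (is.null(seqs)) {
    # unique letter-only sequences: two index letters + tryptic core
    aa <- c("A", "D", "E", "F", "G", "I", "L", "N", "S", "T", "V", "W", "Y")
    seqs <- vapply(seq_len(nrow(mat)), function(i) {
      paste0(aa[((i - 1) %/% length(aa)) + 1], aa[((i - 1) %% length(aa)) + 1],
             "ELVDGTSK")
    }, character(1))
  }
  if (is.null(proteins)) proteins <- paste0("PR", seq_len(nrow(mat)))
  rows <- list()
  for (i in seq_len(nrow(mat))) {
    for (j in seq_len(ncol(mat))) {
      rows[[length(rows) + 1L]] <- quant_row(
        run = sprintf("%s_run%d", study, j), study = study,
        matrix = matrix, sample = sprintf("%s_run%d", study, j),
        protein = proteins[i], seq = seqs[i],
        intensity = mat[i, j])
    }
  }
  df <- do.call(rbind, rows)
  # absence is simply no record
  df <- df[!is.na(df$intensity), , drop = FALSE]
  as_quant_table(df)
}

# simple tryptic-looking sequences valid under canonical-residue checks
toy_seq <- function(i) {
  pool <- c("ALVEDTGK", "SSLVGDLAK", "TTEAVFDGR", "NLEGISDAR",
            "AVLDEGTSK", "GGDFLATVK", "EEVSNDLAR", "TLDSAGVEK",
            "VVDNESGLR", "ADTLSGFEK", "SLEGDTAVR", "FFDNATGLK")
  pool[((i - 1) %% length(pool)) + 1]
}
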