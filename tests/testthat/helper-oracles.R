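# Independent oracles used to cross-check the implementation.
# These deliberately re-derive results from first principles (exhaustive
# enumeration, per-pixel loops) rather than reusing package internals.

# Brute-force digestion: enumerate every substring of the protein and keep
# those whose boundaries coincide with protease cut points and whose
# internal missed-cleavage count, length and mass satisfy the parameters.
brute_force_digest <- function(sequence, protease, max_missed = 4L,
                               min_length = 6L, max_mass = 6000) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  cut_after <- vapply(seq_len(max(n - 1L, 0L)), function(i) {
    switch(protease,
      trypsin = chars[i] %in% c("K", "R") && chars[i + 1L] != "P",
      lysc    = chars[i] == "K",
      aspn    = chars[i + 1L] == "D")
  }, logical(1L))
  rows <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      ok_start <- i == 1L || cut_after[i - 1L]
      ok_end <- j == n || cut_after[j]
      if (!ok_start || !ok_end) next
      internal <- if (j > i) sum(cut_after[i:(j - 1L)]) else 0L
      if (internal > max_missed) next
      if (j - i + 1L < min_length) next
      pep <- paste(chars[i:j], collapse = "")
      if (pexphos::peptide_mass(pep) > max_mass) next
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = pep, start = i, end = j, missed = internal,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(sequence = character(0L), start = integer(0L),
                      end = integer(0L), missed = integer(0L)))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$end - out$start), , drop = FALSE]
}

random_protein <- function(n) {
  paste(sample(c("G", "A", "S", "P", "V", "T", "C", "L", "I", "N", "D", "Q",
                 "K", "E", "M", "H", "F", "R", "Y", "W"), n, replace = TRUE),
        collapse = "")
}

# Per-pixel loop oracle for the maximum-intensity projection.
loop_max_projection <- function(stack) {
  d <- dim(stack)
  out <- matrix(-Inf, d[1L], d[2L])
  for (r in seq_len(d[1L])) {
    for (c in seq_len(d[2L])) {
      for (p in seq_len(d[3L])) {
        if (stack[r, c, p] > out[r, c]) out[r, c] <- stack[r, c, p]
      }
    }
  }
  out
}

# Small, fast simulation configuration shared by imaging tests.
small_sim_config <- function(seed, n_cells = 6L, gfp_level = 40, ...) {
  image_sim_config(rows = 360L, cols = 360L, n_planes = 3L,
                   n_cells = n_cells, gfp_level = gfp_level, seed = seed, ...)
}

table1_evidence <- function() {
  read_evidence(system.file("extdata", "pex14_phosphosite_evidence.tsv",
                            package = "pexphos"))
}
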