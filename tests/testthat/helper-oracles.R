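# Shared fixtures and independent brute-force oracles used by several
# test files. Oracles are deliberately naive (per-residue masks, all-pairs
# loops, direct formula evaluation) and never call the code paths they
# check.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

rand_seq <- function(n, letters = AA) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

rand_intervals <- function(k, L) {
  s <- sample.int(L, k, replace = TRUE)
  e <- pmin(L, s + sample(0:14, k, replace = TRUE))
  data.frame(start = s, end = e)
}

# residue-mask oracle: coverage set of a list of intervals
mask_of <- function(iv, L) {
  m <- logical(L)
  for (i in seq_len(nrow(iv))) m[iv$start[i]:iv$end[i]] <- TRUE
  m
}

# direct per-letter entropy tally (independent of window_entropy)
entropy_oracle <- function(s) {
  ch <- strsplit(s, "")[[1]]
  n <- as.numeric(table(ch))
  p <- n / length(ch)
  -sum(p * log2(p))
}

# Abeta42 worked example used across files
abeta_record <- function() {
  protein_records("Abeta42",
                  "DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVVIA")
}

fixture_pssm <- function() {
  pssm_from_motifs(c("KLVFFA", "GGVVIA", "EGVLYV", "KVQIIN"))
}

extdata <- function(name) {
  system.file("extdata", name, package = "idrscape", mustWork = TRUE)
}
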