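#' SEG-style segmentation parameters
#'
#' The canonical low-complexity triple: window of 12 residues, trigger
#' ("locut") entropy 2.2 bits to seed a region, extension ("hicut") entropy
#' 2.5 bits to grow it. Entropies are Shannon entropies in bits over the
#' residue counts of a window.
#'
#' @param window window width in residues.
#' @param trigger_entropy seed threshold in bits; windows at or below it
#'   can start a low-complexity stretch.
#' @param extension_entropy growth threshold in bits
#'   (`>= trigger_entropy`); windows at or below it extend a stretch.
#' @param refine logical; apply the minimal-composition-probability
#'   refinement of each raw stretch (see [detect_lcr()]).
#' @return A list of class `seg_params`.
#' @export
seg_params <- function(window = 12L, trigger_entropy = 2.2,
                       extension_entropy = 2.5, refine = TRUE) {
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1")
  if (trigger_entropy > extension_entropy)
    stop("trigger_entropy must be <= extension_entropy")
  structure(list(window = window, trigger_entropy = trigger_entropy,
                 extension_entropy = extension_entropy,
                 refine = isTRUE(refine)),
            class = "seg_params")
}

#' Shannon entropy of a residue window
#'
#' `H = -sum_i (n_i/W) log2(n_i/W)` over the residue counts `n_i` of the
#' window of size `W`; 0 for a homopolymer, `log2(min(W, 20))` at most.
#'
#' @param window_seq a non-empty string over the 20-letter alphabet.
#' @return Entropy in bits.
#' @examples
#' window_entropy("AAAAAAAAAAAA")  # 0
#' window_entropy("ACDEFGHIKLMN")  # log2(12)
#' @export
window_entropy <- function(window_seq) {
  if (!nzchar(window_seq)) stop("empty window")
  counts <- table(strsplit(window_seq, "")[[1]])
  p <- as.numeric(counts) / sum(counts)
  -sum(p * log2(p))
}

# Integer-coded sliding-window entropies, NA where a window contains an
# ambiguity letter. Rolling count update: one residue leaves, one enters.
sliding_entropies <- function(sequence, window) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  n_win <- L - window + 1L
  if (n_win < 1L) return(numeric(0))
  code <- match(chars, AA20)              # NA for ambiguity letters
  counts <- integer(20)
  n_ambig <- 0L
  for (i in seq_len(window)) {
    if (is.na(code[i])) n_ambig <- n_ambig + 1L
    else counts[code[i]] <- counts[code[i]] + 1L
  }
  ent_from_counts <- function(counts) {
    n <- counts[counts > 0L]
    p <- n / sum(n)
    -sum(p * log2(p))
  }
  H <- rep(NA_real_, n_win)
  if (n_ambig == 0L) H[1] <- ent_from_counts(counts)
  if (n_win > 1L) for (s in 2:n_win) {
    out <- code[s - 1L]; inc <- code[s + window - 1L]
    if (is.na(out)) n_ambig <- n_ambig - 1L else
      counts[out] <- counts[out] - 1L
    if (is.na(inc)) n_ambig <- n_ambig + 1L else
      counts[inc] <- counts[inc] + 1L
    if (n_ambig == 0L) H[s] <- ent_from_counts(counts)
  }
  H
}

#' Windowed compositional-complexity profile
#'
#' Sliding-window Shannon entropies at every start position (step 1);
#' windows containing ambiguity letters get `NA` and can neither seed nor
#' extend a low-complexity region.
#'
#' @param record one row of a protein record table (or any list with `id`
#'   and `sequence`).
#' @param params a [seg_params()] object.
#' @return A `data.frame` with columns `protein_id`, `position` (window
#'   start, 1-based) and `entropy` (bits); zero rows (with a warning) when
#'   the protein is shorter than the window.
#' @export
complexity_profile <- function(record, params = seg_params()) {
  H <- sliding_entropies(record$sequence, params$window)
  if (length(H) == 0L) {
    warning("protein ", record$id, " is shorter than the window (",
            params$window, "): empty complexity profile")
    return(data.frame(protein_id = character(), position = integer(),
                      entropy = numeric(), stringsAsFactors = FALSE))
  }
  data.frame(protein_id = record$id, position = seq_along(H), entropy = H,
             stringsAsFactors = FALSE)
}

# log multinomial composition probability of a residue-count vector under
# a uniform 20-letter alphabet: log[ W!/(prod n_i!) * 20^-W ].
log_composition_prob <- function(counts) {
  W <- sum(counts)
  lfactorial(W) - sum(lfactorial(counts)) - W * log(20)
}

# Refine one raw stretch to the contiguous sub-window (length >= window)
# minimizing the per-residue multinomial composition probability (the
# whole-window probability normalized by window length; the unnormalized
# probability almost always decreases when duplicated flank residues are
# absorbed, which would systematically inflate the boundaries). Ties are
# broken by longest, then leftmost.
refine_stretch <- function(code, from, to, window) {
  m <- to - from + 1L
  if (m <= window) return(c(from, to))
  best <- c(from, to); best_rate <- Inf; best_len <- -1L
  for (i in from:(to - window + 1L)) {
    counts <- integer(20)
    for (j in i:(i + window - 2L)) counts[code[j]] <- counts[code[j]] + 1L
    for (j in (i + window - 1L):to) {
      counts[code[j]] <- counts[code[j]] + 1L
      len <- j - i + 1L
      rate <- log_composition_prob(counts) / len
      if (rate < best_rate - 1e-9 ||
          (abs(rate - best_rate) <= 1e-9 && len > best_len)) {
        best_rate <- rate; best_len <- len; best <- c(i, j)
      }
    }
  }
  best
}

#' Detect low-complexity regions by windowed entropy
#'
#' SEG-style segmentation: windows at entropy `<= trigger_entropy` seed a
#' stretch; each seed grows through contiguous windows at entropy
#' `<= extension_entropy`; spans of qualifying windows are unioned into
#' residue stretches; overlapping or contiguous stretches merge; each
#' merged stretch is finally reduced to the contiguous sub-window (length
#' `>= window`) with minimal per-residue multinomial composition
#' probability, i.e. minimal `log(P)/W` with
#' `P = W!/(prod n_i!) * 20^-W` (ties: longest, then leftmost). The
#' refinement is a single-pass reduction, not the original recursive
#' optimal-segment search; disable with `refine = FALSE` in [seg_params()].
#'
#' @inheritParams complexity_profile
#' @return A region table of kind LCR (possibly zero rows).
#' @export
detect_lcr <- function(record, params = seg_params()) {
  empty <- region_table(character(), character(), integer(), integer())
  W <- params$window
  H <- sliding_entropies(record$sequence, W)
  if (length(H) == 0L) {
    warning("protein ", record$id, " shorter than window: no LCR scan")
    return(empty)
  }
  ext_ok <- !is.na(H) & H <= params$extension_entropy
  seed <- !is.na(H) & H <= params$trigger_entropy
  if (!any(seed)) return(empty)
  # runs of extension-qualifying windows that contain at least one seed
  r <- rle(ext_ok)
  run_end <- cumsum(r$lengths); run_start <- run_end - r$lengths + 1L
  qualify <- logical(length(H))
  for (k in which(r$values)) {
    if (any(seed[run_start[k]:run_end[k]]))
      qualify[run_start[k]:run_end[k]] <- TRUE
  }
  # union of residue spans of qualifying windows
  mask <- logical(nchar(record$sequence))
  for (s in which(qualify)) mask[s:(s + W - 1L)] <- TRUE
  mr <- rle(mask)
  me <- cumsum(mr$lengths); ms <- me - mr$lengths + 1L
  starts <- ms[mr$values]; ends <- me[mr$values]
  if (params$refine) {
    code <- match(strsplit(record$sequence, "")[[1]], AA20)
    for (i in seq_along(starts)) {
      # stretches can cover ambiguity-free windows only, but guard anyway
      if (anyNA(code[starts[i]:ends[i]])) next
      b <- refine_stretch(code, starts[i], ends[i], W)
      starts[i] <- b[1]; ends[i] <- b[2]
    }
  }
  rt <- region_table(rep(record$id, length(starts)), "LCR", starts, ends)
  rt$subsequence <- substring(record$sequence, rt$start, rt$end)
  rt
}
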