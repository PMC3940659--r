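#' Interval length in residues
#'
#' Intervals are 1-based and inclusive at both ends, so the interval
#' (97, 112) spans 16 residues.
#'
#' @param start,end integer vectors of interval bounds, `start <= end`.
#' @return Integer vector of lengths `end - start + 1`.
#' @export
interval_length <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start > end)) stop("interval with start > end")
  end - start + 1L
}

#' Intersection of two intervals
#'
#' @param a,b length-2 integer vectors `c(start, end)`.
#' @return `c(start, end)` of the intersection, or `NULL` when the
#'   intervals are disjoint (adjacent intervals do not intersect).
#' @examples
#' interval_intersect(c(101, 116), c(97, 112)) # (101, 112): 12 residues
#' @export
interval_intersect <- function(a, b) {
  s <- max(a[1], b[1]); e <- min(a[2], b[2])
  if (s > e) return(NULL)
  c(as.integer(s), as.integer(e))
}

#' Merge overlapping same-kind intervals
#'
#' Produces the minimal set of non-overlapping intervals covering the same
#' residues. Abutting intervals (end + 1 == next start) are kept distinct:
#' they share no residue and remain separate regions for counting purposes.
#'
#' @param rt a region table (single protein and kind expected for region
#'   semantics; arbitrary tables are merged within `protein_id` x `kind`).
#' @return A region table with pairwise non-overlapping intervals, sorted
#'   by protein, kind and start. Subsequences are dropped (no longer
#'   well-defined after merging) unless nothing was merged.
#' @export
merge_regions <- function(rt) {
  if (nrow(rt) == 0L) return(rt)
  pieces <- split(rt, list(rt$protein_id, rt$kind), drop = TRUE)
  merged <- lapply(pieces, function(g) {
    g <- g[order(g$start, g$end), , drop = FALSE]
    ns <- g$start[1]; ne <- g$end[1]
    out_s <- integer(0); out_e <- integer(0)
    if (nrow(g) > 1L) for (i in 2:nrow(g)) {
      if (g$start[i] <= ne) {            # true overlap (not mere abutment)
        ne <- max(ne, g$end[i])
      } else {
        out_s <- c(out_s, ns); out_e <- c(out_e, ne)
        ns <- g$start[i]; ne <- g$end[i]
      }
    }
    out_s <- c(out_s, ns); out_e <- c(out_e, ne)
    data.frame(protein_id = g$protein_id[1], kind = g$kind[1],
               start = out_s, end = out_e, length = out_e - out_s + 1L,
               subsequence = NA_character_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$protein_id, out$kind, out$start), , drop = FALSE]
  rownames(out) <- NULL
  # keep subsequences when merging was a no-op
  if (nrow(out) == nrow(rt) && "subsequence" %in% names(rt)) {
    key <- paste(rt$protein_id, rt$kind, rt$start, rt$end)
    out$subsequence <- rt$subsequence[match(
      paste(out$protein_id, out$kind, out$start, out$end), key)]
  }
  out
}

#' Region content of a protein, in percent
#'
#' The percentage of a protein's residues covered by its regions of one
#' kind: 100 x (residues covered after merging) / protein length. Returned
#' at full precision; use [format_pct()] for table-style rounding.
#'
#' @param rt region table for a single protein and kind (overlapping
#'   intervals are merged internally so no residue is double-counted).
#' @param protein_length protein length in residues (> 0).
#' @return A numeric percentage in \[0, 100\].
#' @examples
#' ars <- region_table("Abeta42", "AR", c(16, 37), c(21, 42))
#' content_percent(ars, 42)          # 28.571...
#' format_pct(content_percent(ars, 42), 0)   # "29"
#' @export
content_percent <- function(rt, protein_length) {
  protein_length <- as.integer(protein_length)
  if (is.na(protein_length) || protein_length <= 0L)
    stop("protein_length must be a positive integer")
  if (nrow(rt) == 0L) return(0)
  if (any(rt$end > protein_length))
    stop("region extends beyond protein length")
  m <- merge_regions(rt)
  100 * sum(m$end - m$start + 1L) / protein_length
}

#' Half-up presentation rounding of percentages
#'
#' Core computations never round; printed tables use half-up rounding
#' (0 decimals for whole-protein summaries, 2 decimals elsewhere).
#' R's `round()` rounds half to even, hence this explicit formatter.
#'
#' @param x numeric vector of percentages.
#' @param digits decimal places (default 0).
#' @return Character vector of formatted values.
#' @export
format_pct <- function(x, digits = 0) {
  scaled <- x * 10^digits
  out <- floor(scaled + 0.5 + 1e-9) / 10^digits   # half-up, guard fp dust
  formatC(out, format = "f", digits = digits)
}

#' Count regions near the protein termini
#'
#' A region counts for the N-terminal tally when it intersects positions
#' `[1, margin]` and for the C-terminal tally when it intersects
#' `[protein_length - margin + 1, protein_length]` (any region residue
#' inside the terminal window counts).
#'
#' @param rt region table for a single protein.
#' @param protein_length protein length in residues.
#' @param margin terminal window width in residues (default 15).
#' @return `c(n_count = ..., c_count = ...)`.
#' @export
terminal_counts <- function(rt, protein_length, margin = 15L) {
  protein_length <- as.integer(protein_length)
  margin <- as.integer(margin)
  if (margin >= protein_length)
    warning("margin >= protein length: both terminal windows cover the ",
            "whole protein")
  if (nrow(rt) == 0L) return(c(n_count = 0L, c_count = 0L))
  n_win_end <- min(margin, protein_length)
  c_win_start <- max(protein_length - margin + 1L, 1L)
  c(n_count = sum(rt$start <= n_win_end),
    c_count = sum(rt$end >= c_win_start))
}

#' Catalog of AR x LCR overlaps on one protein
#'
#' One record per (AR, LCR) pair with a non-empty intersection; a protein
#' "has overlap" iff the catalog is non-empty.
#'
#' @param ars,lcrs region tables of kinds AR and LCR for the same protein.
#' @return A `data.frame` with columns `protein_id`, `ar_start`, `ar_end`,
#'   `lcr_start`, `lcr_end`, `overlap_start`, `overlap_end`,
#'   `overlap_length` (zero rows when nothing overlaps).
#' @export
overlap_catalog <- function(ars, lcrs) {
  empty <- data.frame(protein_id = character(), ar_start = integer(),
                      ar_end = integer(), lcr_start = integer(),
                      lcr_end = integer(), overlap_start = integer(),
                      overlap_end = integer(), overlap_length = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(ars) == 0L || nrow(lcrs) == 0L) return(empty)
  pid <- unique(c(ars$protein_id, lcrs$protein_id))
  if (length(pid) != 1L)
    stop("overlap_catalog expects AR and LCR sets of a single protein")
  rows <- list()
  for (i in seq_len(nrow(ars))) for (j in seq_len(nrow(lcrs))) {
    ov <- interval_intersect(c(ars$start[i], ars$end[i]),
                             c(lcrs$start[j], lcrs$end[j]))
    if (!is.null(ov))
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = pid, ar_start = ars$start[i], ar_end = ars$end[i],
        lcr_start = lcrs$start[j], lcr_end = lcrs$end[j],
        overlap_start = ov[1], overlap_end = ov[2],
        overlap_length = ov[2] - ov[1] + 1L, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
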