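#' Specification of a synthetic disordered-protein cohort
#'
#' Describes a cohort with the statistical structure the analysis assumes:
#' lognormal protein lengths peaking around 400 residues, a PDP/MDP/LDP
#' class mix echoing curated disorder databases, planted low-complexity
#' stretches with heavy-tailed (stable-law) lengths and a
#' Ser/Pro/Gly/Ala-biased composition, planted amyloidogenic hexapeptide
#' motifs detectable by the indicator fixture PSSM, and disorder intervals
#' sized so each protein's realized disorder fraction lands in its
#' requested class.
#'
#' @param n_proteins cohort size.
#' @param length_meanlog,length_sdlog lognormal length law (defaults:
#'   median 400 aa, sdlog 0.55); lengths are clamped to
#'   `[length_min, length_max]`.
#' @param length_min,length_max hard length bounds in residues.
#' @param class_mix named proportions over PDP/MDP/LDP (normalized).
#' @param lcr_mean,ar_mean Poisson means of planted region counts per
#'   protein.
#' @param lcr_count_fixed,ar_count_fixed optional fixed per-protein region
#'   counts overriding the Poisson laws.
#' @param lcr_length_law a [stable_params()] for planted LCR lengths,
#'   truncated to `[lcr_min_len, floor(length/2)]` and rounded to
#'   integers.
#' @param lcr_min_len minimum planted LCR length.
#' @param lcr_composition `"biased"` (Ser/Pro/Gly/Ala-enriched) or
#'   `"homopolymer"` (single repeated residue per region).
#' @param ar_motifs hexapeptide motifs copied verbatim into the sequence;
#'   the fixture PSSM is the indicator matrix of this list.
#' @param background_weights optional named residue weights of the
#'   background composition (default uniform over the 20 residues, the
#'   composition most distinguishable from the planted stretches).
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_proteins = 200L,
                           length_meanlog = log(400),
                           length_sdlog = 0.55,
                           length_min = 120L, length_max = 2500L,
                           class_mix = c(PDP = 0.48, MDP = 0.26,
                                         LDP = 0.26),
                           lcr_mean = 2.9, ar_mean = 4.0,
                           lcr_count_fixed = NULL,
                           ar_count_fixed = NULL,
                           lcr_length_law = stable_params(0.92, 0.99,
                                                          14.99, 4.67),
                           lcr_min_len = 6L,
                           lcr_composition = c("biased", "homopolymer"),
                           ar_motifs = c("KLVFFA", "GGVVIA",
                                         "EGVLYV", "KVQIIN"),
                           background_weights = NULL) {
  lcr_composition <- match.arg(lcr_composition)
  if (!setequal(names(class_mix), c("PDP", "MDP", "LDP")))
    stop("class_mix must be named over PDP, MDP, LDP")
  if (any(class_mix < 0) || sum(class_mix) <= 0)
    stop("class_mix proportions must be non-negative and sum > 0")
  if (any(nchar(ar_motifs) != 6L)) stop("AR motifs must be hexapeptides")
  if (is.null(background_weights))
    background_weights <- setNames(rep(1, 20), AA20)
  structure(list(
    n_proteins = as.integer(n_proteins),
    length_meanlog = length_meanlog, length_sdlog = length_sdlog,
    length_min = as.integer(length_min),
    length_max = as.integer(length_max),
    class_mix = class_mix / sum(class_mix),
    lcr_mean = lcr_mean, ar_mean = ar_mean,
    lcr_count_fixed = if (is.null(lcr_count_fixed)) NULL
                      else as.integer(lcr_count_fixed),
    ar_count_fixed = if (is.null(ar_count_fixed)) NULL
                     else as.integer(ar_count_fixed),
    lcr_length_law = lcr_length_law,
    lcr_min_len = as.integer(lcr_min_len),
    lcr_composition = lcr_composition,
    ar_motifs = toupper(ar_motifs),
    background_weights = background_weights[AA20]
  ), class = "synthetic_spec")
}

# Ser/Pro/Gly/Ala-enriched sampling weights for planted LCR stretches.
lcr_bias_weights <- function() {
  w <- setNames(rep(0.41 / 16, 20), AA20)
  w["S"] <- 0.18; w["P"] <- 0.16; w["G"] <- 0.13; w["A"] <- 0.12
  w
}

# Place a region of `len` residues disjoint (with `gap` residues of
# clearance) from already-placed regions; NULL when no slot is found.
place_region <- function(L, len, placed, gap = 12L, tries = 60L) {
  if (len > L) return(NULL)
  for (k in seq_len(tries)) {
    s <- sample.int(L - len + 1L, 1L)
    e <- s + len - 1L
    ok <- TRUE
    if (nrow(placed))
      ok <- all(placed$start > e + gap | placed$end < s - gap)
    if (ok) return(c(s, e))
  }
  NULL
}

# Disorder-residue budget whose realized percentage classifies into the
# requested class (class boundaries: PDP <= 30 < MDP <= 70 < LDP).
disorder_budget <- function(L, class) {
  p30 <- floor(0.30 * L); p70 <- floor(0.70 * L)
  rng <- switch(class,
                PDP = c(0L, p30),
                MDP = c(p30 + 1L, p70),
                LDP = c(p70 + 1L, L))
  if (rng[1] > rng[2]) rng[1] <- rng[2]
  rng[1] + sample.int(rng[2] - rng[1] + 1L, 1L) - 1L
}

# Split a residue budget into up to 3 disjoint intervals on [1, L].
place_disorder <- function(L, budget) {
  if (budget == 0L)
    return(data.frame(start = integer(), end = integer()))
  k <- sample.int(min(3L, budget), 1L)
  cuts <- sort(sample.int(budget - 1L, k - 1L))
  lens <- diff(c(0L, cuts, budget))
  placed <- data.frame(start = integer(), end = integer())
  for (len in lens) {
    slot <- place_region(L, len, placed, gap = 2L, tries = 40L)
    if (is.null(slot)) next
    placed <- rbind(placed, data.frame(start = slot[1], end = slot[2]))
  }
  got <- sum(placed$end - placed$start + 1L)
  if (got < budget) {     # fall back to one contiguous stretch
    s <- sample.int(L - budget + 1L, 1L)
    placed <- data.frame(start = s, end = s + budget - 1L)
  }
  placed[order(placed$start), , drop = FALSE]
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Deterministic for a fixed seed; each protein draws from its own
#' reproducible stream derived from the global seed, so a cohort is
#' stable under `n_proteins` changes up to the shared prefix. Background
#' residues are drawn from the spec's background composition, planted
#' LCRs from the biased composition (or as homopolymers), planted AR
#' motifs are copied verbatim at recorded positions, and disorder
#' intervals are sized so the realized disorder fraction lands in the
#' requested class.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer global seed.
#' @return A list of class `synthetic_cohort`: `proteins` (record table),
#'   `ar_truth`, `lcr_truth`, `disorder` (region tables), `truth`
#'   (per-protein class labels and targets), `pssm` (fixture matrix),
#'   `spec`, `seed`.
#' @export
generate_cohort <- function(spec = synthetic_spec(), seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  lcr_w <- lcr_bias_weights()
  classes <- names(spec$class_mix)
  recs <- vector("list", spec$n_proteins)
  ar_l <- vector("list", spec$n_proteins)
  lcr_l <- vector("list", spec$n_proteins)
  dis_l <- vector("list", spec$n_proteins)
  truth_l <- vector("list", spec$n_proteins)
  for (i in seq_len(spec$n_proteins)) {
    set.seed((as.integer(seed) %% 65011L) * 33013L + i)
    pid <- sprintf("SYN%05d", i)
    L <- round(rlnorm(1, spec$length_meanlog, spec$length_sdlog))
    L <- as.integer(min(max(L, spec$length_min), spec$length_max))
    target_class <- sample(classes, 1L, prob = spec$class_mix)
    chars <- sample(AA20, L, replace = TRUE,
                    prob = spec$background_weights)
    placed <- data.frame(start = integer(), end = integer())
    # planted LCRs: heavy-tailed lengths, biased composition
    n_lcr <- if (is.null(spec$lcr_count_fixed))
      stats::rpois(1, spec$lcr_mean) else spec$lcr_count_fixed
    lmax <- max(spec$lcr_min_len, floor(L / 2))
    lcr_iv <- data.frame(start = integer(), end = integer())
    for (j in seq_len(n_lcr)) {
      len <- NA
      for (k in 1:100) {
        cand <- round(rstable(1, spec$lcr_length_law))
        if (!is.na(cand) && cand >= spec$lcr_min_len && cand <= lmax) {
          len <- as.integer(cand); break
        }
      }
      if (is.na(len)) len <- spec$lcr_min_len
      slot <- place_region(L, len, placed)
      if (is.null(slot) && !is.null(spec$lcr_count_fixed))
        slot <- place_region(L, len, placed, gap = 4L, tries = 300L)
      if (is.null(slot)) {
        if (!is.null(spec$lcr_count_fixed))
          stop("cannot place the requested LCR plants on protein ", i,
               " (length ", L, "): demanded residues exceed capacity")
        next
      }
      stretch <- if (spec$lcr_composition == "homopolymer") {
        rep(sample(AA20, 1L, prob = lcr_w), len)
      } else {
        sample(AA20, len, replace = TRUE, prob = lcr_w)
      }
      chars[slot[1]:slot[2]] <- stretch
      placed <- rbind(placed, data.frame(start = slot[1], end = slot[2]))
      lcr_iv <- rbind(lcr_iv, data.frame(start = slot[1], end = slot[2]))
    }
    # planted AR motifs, disjoint from the LCR plants
    n_ar <- if (is.null(spec$ar_count_fixed))
      stats::rpois(1, spec$ar_mean) else spec$ar_count_fixed
    ar_iv <- data.frame(start = integer(), end = integer())
    for (j in seq_len(n_ar)) {
      motif <- sample(spec$ar_motifs, 1L)
      slot <- place_region(L, 6L, placed)
      if (is.null(slot) && !is.null(spec$ar_count_fixed))
        slot <- place_region(L, 6L, placed, gap = 4L, tries = 300L)
      if (is.null(slot)) {
        if (!is.null(spec$ar_count_fixed))
          stop("cannot place the requested AR plants on protein ", i,
               " (length ", L, "): demanded residues exceed capacity")
        next
      }
      chars[slot[1]:slot[2]] <- strsplit(motif, "")[[1]]
      placed <- rbind(placed, data.frame(start = slot[1], end = slot[2]))
      ar_iv <- rbind(ar_iv, data.frame(start = slot[1], end = slot[2]))
    }
    dis_iv <- place_disorder(L, disorder_budget(L, target_class))
    recs[[i]] <- data.frame(id = pid,
                            sequence = paste(chars, collapse = ""),
                            stringsAsFactors = FALSE)
    if (nrow(ar_iv))
      ar_l[[i]] <- data.frame(protein_id = pid, kind = "AR",
                              start = ar_iv$start, end = ar_iv$end,
                              stringsAsFactors = FALSE)
    if (nrow(lcr_iv))
      lcr_l[[i]] <- data.frame(protein_id = pid, kind = "LCR",
                               start = lcr_iv$start, end = lcr_iv$end,
                               stringsAsFactors = FALSE)
    if (nrow(dis_iv))
      dis_l[[i]] <- data.frame(protein_id = pid, kind = "DISORDER",
                               start = dis_iv$start, end = dis_iv$end,
                               stringsAsFactors = FALSE)
    truth_l[[i]] <- data.frame(protein_id = pid, length = L,
                               target_class = target_class,
                               n_ar = nrow(ar_iv), n_lcr = nrow(lcr_iv),
                               stringsAsFactors = FALSE)
  }
  rdf <- do.call(rbind, recs)
  proteins <- protein_records(rdf$id, rdf$sequence, source = "synthetic")
  bind_regions <- function(lst) {
    lst <- Filter(Negate(is.null), lst)
    if (length(lst) == 0L)
      return(region_table(character(), character(), integer(), integer()))
    df <- do.call(rbind, lst)
    region_table(df$protein_id, df$kind, df$start, df$end,
                 proteins = proteins)
  }
  structure(list(
    proteins = proteins,
    ar_truth = bind_regions(ar_l),
    lcr_truth = bind_regions(lcr_l),
    disorder = bind_regions(dis_l),
    truth = do.call(rbind, truth_l),
    pssm = pssm_from_motifs(spec$ar_motifs),
    spec = spec, seed = as.integer(seed)
  ), class = "synthetic_cohort")
}

#' Disorder class realized by a ground-truth entry
#'
#' Closes the loop between generator and classifier:
#' `classify_protein(disorder_fraction(...))` on the planted disorder
#' intervals of one protein.
#'
#' @param cohort a [generate_cohort()] result.
#' @param protein_id one protein id of the cohort.
#' @return `"PDP"`, `"MDP"` or `"LDP"`.
#' @export
class_of_truth <- function(cohort, protein_id) {
  L <- cohort$truth$length[cohort$truth$protein_id == protein_id]
  if (length(L) != 1L) stop("unknown protein id: ", protein_id)
  d <- cohort$disorder[cohort$disorder$protein_id == protein_id, ,
                       drop = FALSE]
  classify_protein(disorder_fraction(d, L))
}

#' Write a synthetic cohort to disk
#'
#' Emits `cohort.fa`, `ar_truth.tsv`, `lcr_truth.tsv`, `disorder.tsv`,
#' `pssm_fixture.tsv` and `truth.json` into `dir`; re-reading these files
#' through the package's readers reproduces the ground truth exactly.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(cohort$proteins, file.path(dir, "cohort.fa"))
  write_region_table(cohort$ar_truth, file.path(dir, "ar_truth.tsv"))
  write_region_table(cohort$lcr_truth, file.path(dir, "lcr_truth.tsv"))
  write_region_table(cohort$disorder, file.path(dir, "disorder.tsv"))
  write_pssm(cohort$pssm, file.path(dir, "pssm_fixture.tsv"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(dir)
}
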