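test_that("interval length counts both inclusive endpoints", {
  expect_equal(interval_length(97, 112), 16L)  # a printed 16-mer LCR
  expect_equal(interval_length(5, 5), 1L)
  expect_equal(interval_length(2, 24), 23L)
  expect_error(interval_length(9, 3), "start > end")
})

test_that("interval intersection matches the worked overlap examples", {
  expect_equal(interval_intersect(c(101, 116), c(97, 112)), c(101L, 112L))
  expect_equal(interval_length(101, 112), 12L)  # 12-residue overlap
  expect_equal(interval_intersect(c(10, 20), c(2, 33)), c(10L, 20L))
  expect_null(interval_intersect(c(1, 5), c(6, 9)))  # adjacent, disjoint
})

test_that("intersection is commutative and idempotent on its output", {
  set.seed(5)
  for (rep in 1:50) {
    a <- sort(sample.int(80, 2)); b <- sort(sample.int(80, 2))
    ab <- interval_intersect(a, b)
    expect_identical(ab, interval_intersect(b, a))
    if (!is.null(ab)) {
      expect_identical(interval_intersect(ab, ab), ab)
      expect_identical(interval_intersect(a, ab), ab)
    }
  }
})

test_that("merging keeps abutting intervals distinct but unions overlaps", {
  rt <- region_table(c("p", "p"), "LCR", c(5, 8), c(10, 14))
  m <- merge_regions(rt)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(5L, 14L))
  ab <- region_table(c("p", "p"), "LCR", c(1, 4), c(3, 6))
  expect_equal(nrow(merge_regions(ab)), 2L)
})

test_that("merged coverage equals the brute-force residue-mask union", {
  set.seed(13)
  for (rep in 1:200) {
    L <- sample(30:120, 1)
    iv <- rand_intervals(sample(1:8, 1), L)
    rt <- region_table(rep("p", nrow(iv)), "AR", iv$start, iv$end)
    m <- merge_regions(rt)
    expect_identical(mask_of(m, L), mask_of(iv, L))
    # pairwise non-overlapping after merge
    if (nrow(m) > 1)
      expect_true(all(m$start[-1] > m$end[-nrow(m)]))
  }
})

test_that("content percentages reproduce printed worked examples", {
  ab <- region_table(c("Abeta42", "Abeta42"), "AR", c(16, 37), c(21, 42))
  expect_equal(content_percent(ab, 42), 100 * 12 / 42)
  expect_equal(format_pct(content_percent(ab, 42), 0), "29")
  cy <- region_table("P01034", "LCR", 2, 33)
  expect_equal(format_pct(content_percent(cy, 146), 2), "21.92")
  none <- region_table(character(), character(), integer(), integer())
  expect_equal(content_percent(none, 100), 0)
  expect_error(content_percent(none, 0), "positive")
})

test_that("content is invariant under splitting intervals and bounded", {
  set.seed(17)
  for (rep in 1:50) {
    L <- sample(50:200, 1)
    iv <- rand_intervals(sample(1:5, 1), L)
    rt <- region_table(rep("p", nrow(iv)), "LCR", iv$start, iv$end)
    p <- content_percent(rt, L)
    expect_gte(p, 0); expect_lte(p, 100)
    # split the longest interval into two abutting pieces
    k <- which.max(rt$end - rt$start)
    if (rt$end[k] > rt$start[k]) {
      cut <- rt$start[k] + sample.int(rt$end[k] - rt$start[k], 1) - 1L
      sp <- rbind(rt[-k, ],
                  region_table(c("p", "p"), "LCR",
                               c(rt$start[k], cut + 1L),
                               c(cut, rt$end[k])))
      expect_equal(content_percent(sp, L), p)
    }
  }
  full <- region_table("p", "LCR", 1, 77)
  expect_equal(content_percent(full, 77), 100)
})

test_that("half-up formatting differs from banker's rounding", {
  expect_equal(format_pct(2.5, 0), "3")
  expect_equal(format_pct(28.571, 0), "29")
  expect_equal(format_pct(21.915, 2), "21.92")
  expect_equal(format_pct(38.4956, 0), "38")
})

test_that("terminal counts follow the window-intersection reading", {
  ar <- region_table("DP00069", "AR", 101, 116)
  expect_equal(terminal_counts(ar, 116),
               c(n_count = 0L, c_count = 1L))
  interior <- region_table("Abeta42", "AR", 16, 21)
  expect_equal(terminal_counts(interior, 42),
               c(n_count = 0L, c_count = 0L))
  expect_warning(terminal_counts(interior, 14), "margin")
})

test_that("terminal counts equal a per-region membership oracle", {
  set.seed(19)
  for (rep in 1:200) {
    L <- sample(40:150, 1)
    iv <- rand_intervals(sample(1:6, 1), L)
    rt <- region_table(rep("p", nrow(iv)), "AR", iv$start, iv$end)
    tc <- terminal_counts(rt, L, 15)
    n_o <- sum(vapply(seq_len(nrow(iv)), function(i)
      any(iv$start[i]:iv$end[i] <= 15), logical(1)))
    c_o <- sum(vapply(seq_len(nrow(iv)), function(i)
      any(iv$start[i]:iv$end[i] >= L - 15 + 1), logical(1)))
    expect_equal(unname(tc), c(n_o, c_o))
  }
})

test_that("overlap catalog reproduces the printed AR/LCR overlap pairs", {
  ars <- region_table("DP00332", "AR", 310, 317)
  lcrs <- region_table(rep("DP00332", 2), "LCR", c(62, 302),
                       c(106, 314))
  cat <- overlap_catalog(ars, lcrs)
  expect_equal(nrow(cat), 1L)
  expect_equal(cat$overlap_start, 310L)
  expect_equal(cat$overlap_end, 314L)
  expect_equal(cat$overlap_length, 5L)
  disjoint <- overlap_catalog(region_table("p", "AR", 1, 6),
                              region_table("p", "LCR", 20, 30))
  expect_equal(nrow(disjoint), 0L)
})

test_that("overlap catalog equals the all-pairs quadratic oracle", {
  set.seed(23)
  for (rep in 1:200) {
    L <- 100
    a <- rand_intervals(sample(0:4, 1) + 1L, L)
    b <- rand_intervals(sample(0:4, 1) + 1L, L)
    ars <- region_table(rep("p", nrow(a)), "AR", a$start, a$end)
    lcrs <- region_table(rep("p", nrow(b)), "LCR", b$start, b$end)
    cat <- overlap_catalog(ars, lcrs)
    n_oracle <- 0L
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b)))
      if (max(a$start[i], b$start[j]) <= min(a$end[i], b$end[j]))
        n_oracle <- n_oracle + 1L
    expect_equal(nrow(cat), n_oracle)
    if (nrow(cat))
      expect_true(all(
        cat$overlap_length <=
          pmin(cat$ar_end - cat$ar_start + 1L,
               cat$lcr_end - cat$lcr_start + 1L)))
  }
})
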