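test_that("disorder fraction equals the residue-mask oracle", {
  full <- region_table("p", "DISORDER", 1, 50)
  expect_equal(disorder_fraction(full, 50), 100)
  none <- region_table(character(), character(), integer(), integer())
  expect_equal(disorder_fraction(none, 50), 0)
  set.seed(79)
  for (rep in 1:50) {
    L <- sample(40:150, 1)
    iv <- rand_intervals(sample(1:5, 1), L)
    rt <- region_table(rep("p", nrow(iv)), "DISORDER", iv$start, iv$end)
    expect_equal(disorder_fraction(rt, L), 100 * sum(mask_of(iv, L)) / L)
  }
})

test_that("disorder classes partition [0, 100] with closed right bounds", {
  expect_equal(classify_protein(c(0, 30, 30.5, 50, 70, 70.1, 100)),
               c("PDP", "PDP", "MDP", "MDP", "MDP", "LDP", "LDP"))
  expect_error(classify_protein(101), "0, 100")
  expect_error(classify_protein(-1), "0, 100")
  set.seed(83)
  x <- runif(500, 0, 100)
  cl <- classify_protein(x)
  expect_true(all(cl %in% c("PDP", "MDP", "LDP")))
  expect_equal(cl == "PDP", x <= 30)
  expect_equal(cl == "LDP", x > 70)
})

test_that("class aggregation reproduces printed percentage arithmetic", {
  mk <- function(n, n_amy, cl) data.frame(
    protein_id = sprintf("%s%03d", cl, 1:n), length = 100,
    disorder_pct = switch(cl, PDP = 10, MDP = 50, LDP = 90),
    class_label = cl, ar_count = rep(c(1L, 0L), c(n_amy, n - n_amy)),
    ar_pct = 5, lcr_count = 1L, lcr_pct = 10, overlap_count = 0L,
    n_terminal_ars = 0L, c_terminal_ars = 0L,
    amyloidogenic = rep(c(TRUE, FALSE), c(n_amy, n - n_amy)),
    stringsAsFactors = FALSE)
  s <- rbind(mk(107, 99, "PDP"), mk(8, 8, "LDP"))
  cs <- summarize_class(s)
  expect_equal(format_pct(
    cs$amyloidogenic_pct[cs$class_label == "PDP"], 2), "92.52")
  expect_equal(cs$amyloidogenic_pct[cs$class_label == "LDP"], 100)
  tot <- cs[cs$class_label == "Total", ]
  body <- cs[cs$class_label != "Total", ]
  expect_equal(tot$total_proteins, sum(body$total_proteins))
  expect_equal(tot$amyloidogenic_count, sum(body$amyloidogenic_count))
  expect_equal(tot$ar_count, sum(body$ar_count))
  one <- mk(1, 0, "MDP")
  expect_equal(summarize_class(one)$amyloidogenic_pct, c(0, 0))
  expect_equal(nrow(summarize_class(s[0, ])), 0L)
})

test_that("composition profiles count residues in the right context", {
  rec <- protein_records("p", "KLVFFA")
  prof <- composition_profile(rec)
  expect_equal(unname(prof["F"]), 100 * 2 / 6)
  expect_equal(unname(prof[c("K", "L", "V", "A")]),
               rep(100 / 6, 4))
  expect_equal(sum(prof), 100)
  reg <- region_table("p2", "LCR", 3, 7, proteins =
                        protein_records("p2", "CCAAAAACC"))
  prof2 <- composition_profile(protein_records("p2", "CCAAAAACC"), reg)
  expect_equal(unname(prof2["A"]), 100)
  # ambiguity letters excluded from numerator and denominator
  recx <- protein_records("p3", "AAXBB")  # B is an ambiguity letter too
  expect_equal(unname(composition_profile(recx)["A"]), 100)
  expect_error(composition_profile(protein_records("p4", "XXXX")),
               "no standard residues")
})

test_that("composition is invariant to protein and region order", {
  set.seed(89)
  recs <- protein_records(c("a", "b", "c"),
                          c(rand_seq(50), rand_seq(70), rand_seq(30)))
  expect_equal(composition_profile(recs),
               composition_profile(recs[c(3, 1, 2), ]))
  rt <- region_table(c("a", "b", "c"), "AR", c(5, 10, 2),
                     c(20, 30, 12), proteins = recs)
  expect_equal(composition_profile(recs, rt),
               composition_profile(recs, rt[c(2, 3, 1), ]))
})

test_that("secondary-structure preferences tally labels per residue", {
  ss <- c(p = "HHHEEECCC")
  expect_equal(unname(ss_preference(c(p = strrep("H", 9)))),
               c(100, 0, 0))
  reg <- region_table("p", "AR", 4, 6)
  expect_equal(unname(ss_preference(ss, reg)), c(0, 100, 0))
  expect_equal(sum(ss_preference(ss)), 100)
  expect_error(ss_preference(c(p = "HHQ")), "unknown")
  expect_error(ss_preference(ss, region_table("zz", "AR", 1, 2)),
               "no annotation")
  set.seed(97)
  for (rep in 1:50) {
    L <- sample(20:80, 1)
    lab <- sample(c("H", "E", "C"), L, replace = TRUE)
    ann <- setNames(paste(lab, collapse = ""), "p")
    iv <- rand_intervals(2, L)
    rt <- region_table(c("p", "p"), "AR", iv$start, iv$end)
    got <- ss_preference(ann, rt)
    inreg <- unlist(lapply(1:2, function(i) lab[iv$start[i]:iv$end[i]]))
    expect_equal(unname(got), 100 * c(mean(inreg == "H"),
                                      mean(inreg == "E"),
                                      mean(inreg == "C")))
  }
})

test_that("region-majority mode reports per-region preferences", {
  ss <- c(p = "HHHHEEEECC")
  rt <- region_table(c("p", "p"), "AR", c(1, 5), c(4, 10))
  got <- ss_preference(ss, rt, mode = "region")
  expect_equal(unname(got), c(50, 50, 0))  # one H region, one E region
  expect_error(ss_preference(ss, mode = "region"), "region table")
})

test_that("the propensity baseline labels known formers correctly", {
  expect_equal(chou_fasman_baseline(protein_records("a", "AAAAA")),
               "HHHHH")
  expect_equal(chou_fasman_baseline(protein_records("g", "GGGG")),
               "CCCC")
  expect_equal(chou_fasman_baseline(protein_records("v", "VVV")), "EEE")
  set.seed(101)
  s <- rand_seq(60)
  out <- chou_fasman_baseline(protein_records("p", s))
  expect_equal(nchar(out), 60L)
  expect_false(grepl("[^HEC]", out))
})

test_that("planted AR regions are hydrophobic-enriched in composition", {
  co <- generate_cohort(synthetic_spec(n_proteins = 40), seed = 9)
  ar_prof <- composition_profile(co$proteins, co$ar_truth)
  whole_prof <- composition_profile(co$proteins)
  # motif residues (V, I, F, L) must be enriched over background
  expect_true(all(ar_prof[c("V", "I", "F", "L")] >
                    whole_prof[c("V", "I", "F", "L")]))
  lcr_prof <- composition_profile(co$proteins, co$lcr_truth)
  top5 <- names(sort(lcr_prof, decreasing = TRUE))[1:5]
  expect_true(all(c("S", "P", "G") %in% top5))
})
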