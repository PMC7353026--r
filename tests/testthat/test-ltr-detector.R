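# Structural detector: candidate search, TSD/termini validation, lineage
# labelling, and recovery of planted elements.

test_that("random background yields no candidates (brute-force concordance)", {
  cfg <- simulation_config(seed = 31, genome_length = 1e5, n_elements = 0,
                           n_fragments = 0, n_genes = 0, n_reads = 0)
  sim <- simulate_genome(cfg)
  cand <- find_ltr_candidates(as.character(sim$genome[[1]]))
  expect_equal(nrow(cand), 0)
  # independent diagonal-sweep oracle certifies the absence of any
  # qualifying repeat pair on a 20 kb slice
  slice <- substr(as.character(sim$genome[[1]]), 1, 20000)
  expect_false(brute_has_repeat_pair(slice))
})

test_that("an age-zero element is recovered with exact LTR intervals", {
  cfg <- simulation_config(seed = 13, genome_length = 3e4, n_elements = 1,
                           age_range_my = c(0, 0), n_fragments = 0,
                           n_genes = 0, n_reads = 0,
                           tsd_mismatch_probs = c(1, 0, 0))
  sim <- simulate_genome(cfg)
  tt <- sim$te_truth
  cand <- find_ltr_candidates(as.character(sim$genome[[1]]))
  expect_equal(nrow(cand), 1)
  expect_equal(cand$left_start, tt$ltr5_start)
  expect_equal(cand$left_end, tt$ltr5_end)
  expect_equal(cand$right_start, tt$ltr3_start)
  expect_equal(cand$right_end, tt$ltr3_end)
  expect_equal(cand$ltr_pair_identity, 1)
})

test_that("pairs below the identity floor are not reported", {
  # age chosen so the expected pair identity is ~0.5, far below 0.80
  cfg <- simulation_config(seed = 19, genome_length = 3e4, n_elements = 1,
                           age_range_my = c(106, 106), n_fragments = 0,
                           n_genes = 0, n_reads = 0)
  sim <- simulate_genome(cfg)
  det <- detect_full_length_ltrs(sim$genome)
  expect_equal(nrow(det), 0)
})

test_that("validate_structure enforces termini and TSD evidence", {
  el <- plant_element(tsd = "ACGTC")
  ok <- validate_structure(el$cand, el$seq)
  expect_false(is_rejected(ok))
  expect_equal(ok$tsd_mismatches, 0)
  expect_identical(ok$tsd_left, "ACGTC")
  expect_identical(ok$tsd_right, "ACGTC")
  expect_true(all(ok$tg_ca_ok))

  # three TSD mismatches exceed the cap
  el3 <- plant_element(tsd = "ACGTC", tsd_right = "TTTTC")
  rej <- validate_structure(el3$cand, el3$seq)
  expect_true(is_rejected(rej))
  expect_match(rej$reason, "tsd_mismatches>2")

  # two mismatches stay within the cap
  el2 <- plant_element(tsd = "ACGTC", tsd_right = "TTGTC")
  ok2 <- validate_structure(el2$cand, el2$seq)
  expect_false(is_rejected(ok2))
  expect_equal(ok2$tsd_mismatches, 2)

  # a 5'LTR starting AG fails the termini check
  broken <- el$seq
  substr(broken, el$cand$left_start, el$cand$left_start) <- "A"
  rej2 <- validate_structure(el$cand, broken)
  expect_true(is_rejected(rej2))
  expect_identical(rej2$reason, "termini")

  # but passes when termini are not required
  ok3 <- validate_structure(el$cand, broken,
                            detector_params(require_tg_ca = FALSE))
  expect_false(is_rejected(ok3))
  expect_false(ok3$tg_ca_ok[["ltr5"]])

  # out-of-bounds candidate errors
  bad <- el$cand
  bad$right_end <- nchar(el$seq) + 50
  expect_error(validate_structure(bad, el$seq), "out of bounds")
})

test_that("lineage classification matches signatures with table-order ties", {
  lt <- default_lineage_table()
  sig <- lt$signature[lt$lineage == "Del/Tekay"]
  set.seed(1)
  internal <- paste0(rand_seq(200), sig, rand_seq(200))
  fake_el <- structure(list(internal = c(start = 1, end = nchar(internal))),
                       class = "ltr_element")
  cls <- classify_lineage(fake_el, internal, lt)
  expect_identical(cls$lineage, "Del/Tekay")
  expect_identical(cls$superfamily, "Ty3/gypsy")

  bg_el <- structure(list(internal = c(start = 1, end = 400)),
                     class = "ltr_element")
  cls_bg <- classify_lineage(bg_el, rand_seq(400), lt)
  expect_identical(cls_bg$lineage, "RLX")
  expect_identical(cls_bg$superfamily, "unknown")

  # identical signatures under two names: first table entry wins
  twin <- data.frame(lineage = c("first", "second"),
                     superfamily = c("Ty1/copia", "Ty3/gypsy"),
                     signature = c(sig, sig), stringsAsFactors = FALSE)
  cls_twin <- classify_lineage(fake_el, internal, twin)
  expect_identical(cls_twin$lineage, "first")

  # empty table stays unclassified
  expect_identical(classify_lineage(fake_el, internal,
                                    twin[0, ])$lineage, "RLX")
})

test_that("planted elements are recovered; fragments are not", {
  cfg <- simulation_config(seed = 23, genome_length = 3e5, n_elements = 20,
                           ltr_length_range = c(300, 900),
                           internal_length_range = c(1000, 2500),
                           age_range_my = c(0, 5), n_fragments = 5,
                           n_genes = 5, n_reads = 0)
  sim <- simulate_genome(cfg)
  det <- detect_full_length_ltrs(sim$genome)
  full <- sim$te_truth[sim$te_truth$is_full_length, ]
  frags <- sim$te_truth[!sim$te_truth$is_full_length, ]
  matched <- vapply(seq_len(nrow(full)), function(i) {
    any(abs(det$ltr5_start - full$ltr5_start[i]) <= 5 &
          abs(det$ltr3_end - full$ltr3_end[i]) <= 5)
  }, logical(1))
  expect_gte(mean(matched), 0.95)
  # no detected element centred on a fragment-only copy
  in_frag <- vapply(seq_len(nrow(det)), function(i) {
    any(det$start[i] >= frags$start & det$end[i] <= frags$end)
  }, logical(1))
  expect_false(any(in_frag))
  # lineages of exactly matched elements agree with truth
  hit <- match(det$ltr5_start, full$ltr5_start)
  exact <- !is.na(hit)
  expect_gt(mean(det$lineage[exact] == full$lineage[hit[exact]]), 0.9)
})

test_that("reported elements do not overlap and re-validate idempotently", {
  cfg <- simulation_config(seed = 29, genome_length = 2e5, n_elements = 10,
                           ltr_length_range = c(300, 800),
                           internal_length_range = c(900, 2000),
                           age_range_my = c(0, 8), n_fragments = 3,
                           n_genes = 3, n_reads = 0)
  sim <- simulate_genome(cfg)
  det <- detect_full_length_ltrs(sim$genome)
  expect_gt(nrow(det), 0)
  ir <- IRanges::IRanges(det$start, det$end)
  expect_equal(sum(IRanges::width(IRanges::reduce(ir))),
               sum(IRanges::width(ir)))
  g <- as.character(sim$genome[[1]])
  for (i in seq_len(nrow(det))) {
    cand <- data.frame(left_start = det$ltr5_start[i],
                       left_end = det$ltr5_end[i],
                       right_start = det$ltr3_start[i],
                       right_end = det$ltr3_end[i],
                       ltr_pair_identity = det$ltr_pair_identity[i])
    again <- validate_structure(cand, g)
    expect_false(is_rejected(again))
    expect_equal(again$tsd_mismatches, det$tsd_mismatches[i])
  }
})

test_that("pure background of 1 Mb yields no elements across 5 seeds", {
  for (seed in 1:5) {
    cfg <- simulation_config(seed = seed, genome_length = 1e6,
                             n_elements = 0, n_fragments = 0, n_genes = 0,
                             n_reads = 0)
    sim <- simulate_genome(cfg)
    det <- detect_full_length_ltrs(sim$genome)
    expect_equal(nrow(det), 0)
  }
})

test_that("sequences are split at N runs longer than 11 nt", {
  el <- plant_element()
  withN <- paste0(el$seq, paste(rep("N", 50), collapse = ""), el$seq)
  cand <- find_ltr_candidates(withN)
  # each copy of the planted element is found in its own chunk; the N run
  # never participates in a candidate
  expect_equal(nrow(cand), 2)
  expect_equal(cand$left_start[2] - cand$left_start[1],
               nchar(el$seq) + 50)
})
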