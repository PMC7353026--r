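# Read collapsing, miRNA exclusion, best-hit mapping, TE intersection and
# quantification.

test_that("collapsing merges duplicates and normalises U to T", {
  a21 <- strrep("A", 21)
  c24 <- strrep("C", 24)
  col <- collapse_reads(c(a21, a21, c24))
  expect_equal(nrow(col), 2)
  expect_equal(col$count, c(2L, 1L))
  expect_equal(col$length_nt, c(21L, 24L))
  expect_identical(col$sequence[1], a21)

  # U-form merges with its T-form duplicate
  u <- collapse_reads(c("ACGU", "ACGT"))
  expect_equal(nrow(u), 1)
  expect_equal(u$count, 2L)
  expect_identical(u$sequence, "ACGT")

  expect_equal(nrow(collapse_reads(character(0))), 0)
  expect_error(collapse_reads(c("ACGT", "")), "empty")
  expect_error(collapse_reads("ACGX"), "A/C/G/T/U")
})

test_that("miRNA exclusion drops exact matches only", {
  col <- collapse_reads(c(strrep("A", 21), strrep("C", 21),
                          strrep("G", 21)))
  res <- exclude_mirnas(col, strrep("C", 21))
  expect_equal(nrow(res$kept), 2)
  expect_equal(res$dropped, 1)
  expect_equal(exclude_mirnas(col, character(0))$kept, col)
  all_bl <- exclude_mirnas(col, col$sequence)
  expect_equal(nrow(all_bl$kept), 0)
  expect_equal(all_bl$dropped, 3)
  # blacklist in RNA alphabet still matches
  rna <- exclude_mirnas(col, gsub("T", "U", strrep("A", 21)))
  expect_equal(rna$dropped, 1)
})

test_that("best-hit mapping resolves unique, ambiguous and unmapped reads", {
  set.seed(42)
  unique_read <- rand_seq(21)
  twice_read <- rand_seq(22)
  minus_read <- rand_seq(24)
  absent_read <- rand_seq(21)
  g <- paste0(rand_seq(300), unique_read, rand_seq(100), twice_read,
              rand_seq(100), twice_read, rand_seq(100),
              rc_chr(minus_read), rand_seq(300))
  genome <- c(chr1 = g)
  col <- collapse_reads(c(unique_read, twice_read, minus_read,
                          absent_read))
  loci <- map_best_hit(col, genome)

  u <- loci[loci$sequence == unique_read, ]
  expect_identical(u$status, "unique")
  expect_equal(u$start, 301)
  expect_equal(u$end, 321)
  expect_identical(u$strand, "+")
  expect_equal(u$score, 21L)

  tw <- loci[loci$sequence == twice_read, ]
  expect_identical(tw$status, "ambiguous")
  expect_equal(tw$n_hits, 2L)
  expect_equal(tw$start, 422)  # leftmost of the two hits

  mi <- loci[loci$sequence == minus_read, ]
  expect_identical(mi$status, "unique")
  expect_identical(mi$strand, "-")
  expect_equal(mi$start, 666)

  ab <- loci[loci$sequence == absent_read, ]
  expect_identical(ab$status, "unmapped")
  expect_true(is.na(ab$start))

  # every locus has exactly one status
  expect_true(all(loci$status %in% c("unique", "ambiguous", "unmapped")))
})

test_that("TE intersection assigns by largest overlap with leftmost ties", {
  loci <- data.frame(
    sequence = c(strrep("A", 21), strrep("C", 21), strrep("G", 21),
                 strrep("T", 21)),
    count = c(1L, 2L, 1L, 1L), length_nt = 21L, chrom = "chr1",
    start = c(150, 395, 700, 120), end = c(170, 415, 720, 140),
    strand = "+", score = 21L,
    status = c("unique", "unique", "unique", "ambiguous"),
    n_hits = c(1L, 1L, 1L, 2L), te_assignment = NA_character_,
    stringsAsFactors = FALSE)
  tes <- data.frame(te_id = c("TE1", "TE2", "TE3"), chrom = "chr1",
                    start = c(100, 400, 410), end = c(200, 500, 510),
                    stringsAsFactors = FALSE)
  res <- intersect_te(loci, tes)
  expect_identical(res$te_assignment[1], "TE1")   # wholly inside
  # 395-415 overlaps TE2 by 16 bp and TE3 by 6 bp: largest overlap wins
  expect_identical(res$te_assignment[2], "TE2")
  expect_true(is.na(res$te_assignment[3]))        # no TE overlap
  expect_true(is.na(res$te_assignment[4]))        # ambiguous never assigned

  # exactly 1 bp of overlap qualifies at min_overlap_bp = 1
  edge <- loci[1, ]
  edge$start <- 200; edge$end <- 220
  expect_identical(intersect_te(edge, tes)$te_assignment, "TE1")
  edge$start <- 201; edge$end <- 221
  expect_true(is.na(intersect_te(edge, tes)$te_assignment))

  # equal overlap: leftmost TE wins
  twin <- loci[1, ]
  twin$start <- 405; twin$end <- 425
  # both TEs overlap the 405-425 locus by exactly 16 bp
  tes_eq <- data.frame(te_id = c("R", "L"), chrom = "chr1",
                       start = c(410, 300), end = c(600, 420),
                       stringsAsFactors = FALSE)
  expect_identical(intersect_te(twin, tes_eq)$te_assignment, "L")
})

test_that("TE intersection agrees with the all-pairs oracle", {
  set.seed(99)
  for (rep in 1:5) {
    n_te <- 40
    te_start <- sort(sample(1:5000, n_te))
    tes <- data.frame(te_id = sprintf("T%02d", 1:n_te), chrom = "chr1",
                      start = te_start,
                      end = te_start + sample(20:200, n_te, replace = TRUE),
                      stringsAsFactors = FALSE)
    n_loc <- 60
    ls <- sample(1:5200, n_loc)
    loci <- data.frame(sequence = vapply(1:n_loc, function(i) rand_seq(21),
                                         character(1)),
                       count = 1L, length_nt = 21L, chrom = "chr1",
                       start = ls, end = ls + 20, strand = "+",
                       score = 21L, status = "unique", n_hits = 1L,
                       te_assignment = NA_character_,
                       stringsAsFactors = FALSE)
    res <- intersect_te(loci, tes)
    for (i in seq_len(n_loc)) {
      expect_identical(res$te_assignment[i],
                       brute_te_assignment(loci[i, ], tes, 1))
    }
  }
})

test_that("size distribution fractions honour the chosen weighting", {
  loci <- data.frame(sequence = c(vapply(1:10, function(i) rand_seq(24),
                                         character(1)),
                                  vapply(1:10, function(i) rand_seq(21),
                                         character(1))),
                     count = 1L, length_nt = rep(c(24L, 21L), each = 10),
                     chrom = "chr1", start = 1, end = 24, strand = "+",
                     score = 1L, status = "unique", n_hits = 1L,
                     te_assignment = "TE1", stringsAsFactors = FALSE)
  sd <- size_distribution(loci)
  expect_equal(sd$fraction[sd$length_nt == 24], 0.5)
  expect_equal(sd$fraction[sd$length_nt == 21], 0.5)
  expect_equal(sum(sd$fraction), 1, tolerance = 1e-9)

  # read-count weighting vs unique-sequence weighting diverge
  loci$count[1] <- 11L  # one 24-nt sequence with many reads
  by_reads <- size_distribution(loci, "by_read_count")
  by_seq <- size_distribution(loci, "by_unique_sequence")
  expect_equal(by_reads$fraction[by_reads$length_nt == 24], 20 / 30)
  expect_equal(by_seq$fraction[by_seq$length_nt == 24], 0.5)

  empty <- size_distribution(loci[0, ])
  expect_equal(sum(empty$fraction), 0)
  expect_equal(attr(empty, "n"), 0)
})

test_that("per-superfamily production percentages sum to 100", {
  tes <- data.frame(te_id = c("g", "i", "c", "d"), chrom = "chr1",
                    start = c(1, 1000, 2000, 3000),
                    end = c(500, 1500, 2500, 3500),
                    wicker_code = c("RLG-comp", "RIX-incomp", "RLC-comp",
                                    "DTX-incomp"),
                    stringsAsFactors = FALSE)
  mk <- function(te, count) {
    data.frame(sequence = rand_seq(24), count = count, length_nt = 24L,
               chrom = "chr1", start = 1, end = 24, strand = "+",
               score = 24L, status = "unique", n_hits = 1L,
               te_assignment = te, stringsAsFactors = FALSE)
  }
  set.seed(3)
  loci <- rbind(mk("g", 33L), mk("i", 18L), mk("c", 16L), mk("d", 33L))
  prod <- production_by_superfamily(loci, tes)
  expect_equal(sum(prod$percent), 100, tolerance = 1e-9)
  expect_equal(prod$percent[prod$code == "RLG"], 33)
  expect_equal(prod$percent[prod$code == "RIX"], 18)
  expect_equal(prod$percent[prod$code == "RLC"], 16)
  expect_equal(prod$percent[prod$code == "DTX"], 33)

  only_g <- production_by_superfamily(mk("g", 5L), tes)
  expect_equal(only_g$percent, 100)

  none <- production_by_superfamily(mk("g", 5L), tes, length_nt = 22)
  expect_equal(nrow(none), 0)
  expect_equal(attr(none, "n"), 0L)
})

test_that("the pipeline conserves reads and recovers true origins", {
  cfg <- simulation_config(seed = 55, genome_length = 1.2e5, n_elements = 4,
                           ltr_length_range = c(300, 600),
                           internal_length_range = c(800, 1500),
                           age_range_my = c(3, 8), n_fragments = 0,
                           n_genes = 4, n_reads = 2000, frac_te_reads = 0.6)
  sim <- simulate_genome(cfg)
  rr <- simulate_small_rna_reads(sim$genome, sim$te_truth, sim$gene_truth,
                                 cfg)
  col <- collapse_reads(as.character(rr$reads))
  expect_equal(sum(col$count), 2000)
  bl <- col$sequence[seq_len(5)]
  ex <- exclude_mirnas(col, bl)
  expect_equal(nrow(ex$kept) + ex$dropped, nrow(col))
  loci <- map_best_hit(ex$kept, sim$genome)
  expect_true(all(table(loci$status) >= 0))
  # uniquely mapped sequences sit at the locus their reads came from
  uni <- loci[loci$status == "unique", ]
  truth_by_seq <- split(rr$truth, as.character(rr$reads))
  ok <- vapply(seq_len(nrow(uni)), function(i) {
    tr <- truth_by_seq[[uni$sequence[i]]]
    any(tr$start == uni$start[i] & tr$end == uni$end[i])
  }, logical(1))
  expect_gte(mean(ok), 0.99)
})
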