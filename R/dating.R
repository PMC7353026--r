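# Molecular-clock dating of LTR retrotransposon insertions. The age of a
# full-length element is T = d / (2 r): the two LTR copies are identical at
# insertion and diverge independently afterwards, so their pairwise
# divergence d accumulates at twice the per-site substitution rate r. The
# rate itself is calibrated from cross-species synonymous divergence
# (r_coding = dKs / (2 T_speciation)) and doubled for non-coding sequence.

#' Calibrate the substitution rate from cross-species divergence
#'
#' `coding_rate = delta_ks / (2 * t_spec_my * 1e6)` and `working_rate =
#' coding_rate * noncoding_multiplier`, both computed at full precision;
#' rounding to 3 significant figures happens only in the display methods.
#' With the synonymous divergence between cassava and rubber tree (dKs =
#' 0.37 - 0.23 = 0.14) and a 36 My speciation time, the coding rate is
#' 1.94e-9 subs/site/year and the doubled non-coding working rate 3.89e-9.
#'
#' @param delta_ks Synonymous substitutions per site accumulated between
#'   the two species since speciation.
#' @param t_spec_my Speciation time in million years.
#' @param noncoding_multiplier Factor applied for non-coding sequence
#'   (default 2: non-coding sites evolve roughly twice as fast).
#' @return A list of class `rate_calibration` with fields `delta_ks`,
#'   `t_spec_my`, `coding_rate`, `noncoding_multiplier`, `working_rate`
#'   and `non_dating` (TRUE when the rate is zero and dating is refused).
#' @export
calibrate_rate <- function(delta_ks, t_spec_my, noncoding_multiplier = 2.0) {
  if (!is.numeric(delta_ks) || delta_ks < 0) {
    stop("delta_ks must be non-negative")
  }
  if (!is.numeric(t_spec_my) || t_spec_my <= 0) {
    stop("t_spec_my must be positive")
  }
  if (noncoding_multiplier <= 0) {
    stop("noncoding_multiplier must be positive")
  }
  coding <- delta_ks / (2 * t_spec_my * 1e6)
  structure(list(delta_ks = delta_ks, t_spec_my = t_spec_my,
                 coding_rate = coding,
                 noncoding_multiplier = noncoding_multiplier,
                 working_rate = coding * noncoding_multiplier,
                 non_dating = coding == 0),
            class = "rate_calibration")
}

#' @rdname calibrate_rate
#' @param ks_species_a,ks_species_b Per-species Ks values against a common
#'   reference; their difference is the `delta_ks` used for calibration.
#' @export
calibrate_rate_from_ks <- function(ks_species_a, ks_species_b, t_spec_my,
                                   noncoding_multiplier = 2.0) {
  calibrate_rate(abs(ks_species_a - ks_species_b), t_spec_my,
                 noncoding_multiplier)
}

#' Format a substitution rate at 3 significant figures
#' @param x Numeric rate.
#' @return Character like `"1.94e-09"`.
#' @export
format_rate <- function(x) formatC(x, format = "e", digits = 2)

#' @export
print.rate_calibration <- function(x, ...) {
  cat("Substitution-rate calibration\n")
  cat(sprintf("  delta Ks:            %g subs/site\n", x$delta_ks))
  cat(sprintf("  speciation time:     %g My\n", x$t_spec_my))
  cat(sprintf("  coding rate:         %s subs/site/year\n",
              format_rate(x$coding_rate)))
  cat(sprintf("  non-coding multiplier: %g\n", x$noncoding_multiplier))
  cat(sprintf("  working rate:        %s subs/site/year\n",
              format_rate(x$working_rate)))
  if (x$non_dating) cat("  [non-dating calibration: rate is zero]\n")
  invisible(x)
}

#' Align the two LTR copies of an element
#'
#' Global (Needleman-Wunsch) alignment with affine gaps using the fixed
#' scoring defaults match +2, mismatch -2, gap open -6, gap extend -1.
#' Gap columns are excluded from the p-distance denominator.
#'
#' @param ltr5,ltr3 The two LTR sequences (character or
#'   [Biostrings::DNAString]).
#' @return A list of class `ltr_alignment_stats` with `aligned_columns`,
#'   `match_columns`, `mismatch_columns`, `gap_columns` and `p_distance`.
#' @export
align_ltr_pair <- function(ltr5, ltr3) {
  ltr5 <- toupper(as.character(ltr5))
  ltr3 <- toupper(as.character(ltr3))
  if (nchar(ltr5) == 0 || nchar(ltr3) == 0) {
    stop("both LTR sequences must be non-empty")
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -2,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(ltr5), Biostrings::DNAString(ltr3),
    type = "global", substitutionMatrix = mat,
    gapOpening = 6, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  gap <- pa == "-" | sa == "-"
  match_cols <- sum(!gap & pa == sa)
  mism_cols <- sum(!gap & pa != sa)
  structure(list(aligned_columns = length(pa),
                 match_columns = match_cols,
                 mismatch_columns = mism_cols,
                 gap_columns = sum(gap),
                 p_distance = if (match_cols + mism_cols > 0) {
                   mism_cols / (match_cols + mism_cols)
                 } else 0,
                 scoring = c(match = 2, mismatch = -2, gap_open = -6,
                             gap_extend = -1)),
            class = "ltr_alignment_stats")
}

#' Divergence from alignment statistics
#'
#' `raw` returns the p-distance unchanged; `jc` applies the Jukes-Cantor
#' multiple-hit correction `d = -(3/4) log(1 - 4p/3)`, which inverts the
#' Jukes-Cantor substitution process in expectation.
#'
#' @param stats An `ltr_alignment_stats` object or a numeric p-distance.
#' @param model "jc" (default) or "raw".
#' @return Divergence d in substitutions per site.
#' @export
divergence <- function(stats, model = c("jc", "raw")) {
  model <- match.arg(model)
  p <- if (inherits(stats, "ltr_alignment_stats")) stats$p_distance
       else as.numeric(stats)
  if (any(p < 0 | p >= 1)) stop("p-distance must lie in [0, 1)")
  if (model == "raw") return(p)
  if (any(p >= 0.75)) {
    stop("Jukes-Cantor correction saturates at p >= 0.75")
  }
  -0.75 * log(1 - 4 * p / 3)
}

#' Insertion age from divergence
#'
#' `age_years = d / (2 * working_rate)`.
#'
#' @param d Divergence between the two LTR copies (subs/site).
#' @param calibration A [calibrate_rate()] result.
#' @return A list with `age_years` and `age_my`.
#' @export
estimate_insertion_time <- function(d, calibration) {
  if (!inherits(calibration, "rate_calibration")) {
    stop("calibration must be a rate_calibration")
  }
  if (calibration$working_rate <= 0 || calibration$non_dating) {
    stop("non-dating calibration: working rate is zero")
  }
  if (any(d < 0)) stop("divergence must be non-negative")
  age_years <- d / (2 * calibration$working_rate)
  list(age_years = age_years, age_my = age_years / 1e6)
}

#' Date a set of full-length elements
#'
#' Extracts both LTR copies of each element from the genome, aligns them,
#' converts the p-distance to divergence under the chosen model and to an
#' insertion age under the calibration. Also tallies the fraction of
#' elements with 0, 1 and 2 TSD mismatches (elements with more were
#' rejected upstream by the structural validator).
#'
#' @param elements Data frame from [detect_full_length_ltrs()].
#' @param genome The genome the elements were detected on.
#' @param calibration A [calibrate_rate()] result.
#' @param model Divergence model, "jc" or "raw".
#' @return A list with `dates` (element_id, d, model, age_years, age_my,
#'   plus lineage/superfamily when present) and `tsd_tally` (fractions for
#'   0/1/2 mismatches and `n`).
#' @export
date_elements <- function(elements, genome, calibration,
                          model = c("jc", "raw")) {
  model <- match.arg(model)
  gchars <- as_genome_chars(genome)
  n <- nrow(elements)
  if (n == 0) {
    tally <- c("0" = 0, "1" = 0, "2" = 0)
    return(list(dates = data.frame(element_id = character(0), d = numeric(0),
                                   model = character(0),
                                   age_years = numeric(0),
                                   age_my = numeric(0),
                                   stringsAsFactors = FALSE),
                tsd_tally = list(fractions = tally, n = 0L)))
  }
  d <- numeric(n)
  for (i in seq_len(n)) {
    s <- gchars[[elements$chrom[i]]]
    l5 <- substr(s, elements$ltr5_start[i], elements$ltr5_end[i])
    l3 <- substr(s, elements$ltr3_start[i], elements$ltr3_end[i])
    d[i] <- divergence(align_ltr_pair(l5, l3), model)
  }
  age <- estimate_insertion_time(d, calibration)
  dates <- data.frame(element_id = elements$element_id, d = d,
                      model = model, age_years = age$age_years,
                      age_my = age$age_my, stringsAsFactors = FALSE)
  for (cc in c("lineage", "superfamily")) {
    if (cc %in% names(elements)) dates[[cc]] <- elements[[cc]]
  }
  mm <- elements$tsd_mismatches
  tally <- c("0" = mean(mm == 0), "1" = mean(mm == 1), "2" = mean(mm == 2))
  list(dates = dates, tsd_tally = list(fractions = tally, n = n))
}

#' Histogram of insertion ages
#'
#' Bins ages into half-open intervals `[k w, (k+1) w)` per group
#' (superfamily or lineage). All bins from 0 up to the oldest observed age
#' are reported per group, including empty ones, so counts sum to n.
#'
#' @param dates The `dates` data.frame from [date_elements()].
#' @param bin_width_my Bin width in million years (default 0.5).
#' @param group_key Grouping column: "superfamily" or "lineage".
#' @return Data frame with `group`, `bin_start_my`, `bin_end_my`, `count`.
#' @export
bin_ages <- function(dates, bin_width_my = 0.5,
                     group_key = c("superfamily", "lineage")) {
  group_key <- match.arg(group_key)
  if (bin_width_my <= 0) stop("bin_width_my must be positive")
  empty <- data.frame(group = character(0), bin_start_my = numeric(0),
                      bin_end_my = numeric(0), count = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(dates) == 0) return(empty)
  grp <- if (group_key %in% names(dates)) dates[[group_key]] else
    rep("all", nrow(dates))
  bin <- floor(dates$age_my / bin_width_my)
  out <- list()
  for (g in sort(unique(grp))) {
    b <- bin[grp == g]
    levels <- 0:max(b)
    counts <- vapply(levels, function(k) sum(b == k), integer(1))
    out[[g]] <- data.frame(group = g, bin_start_my = levels * bin_width_my,
                           bin_end_my = (levels + 1) * bin_width_my,
                           count = counts, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
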