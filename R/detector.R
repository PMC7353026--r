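# Structural detection of full-length LTR retrotransposons. The search is a
# transparent seed-and-extend scan for long direct repeats: exact seed-word
# matches are hashed, clustered per diagonal, extended ungapped with an
# X-drop rule, snapped to TG..CA termini, and finally validated against the
# canonical structural evidence (terminal dinucleotides and a near-intact
# target-site duplication on both flanks).

#' Detector parameters
#'
#' @param seed_word Exact seed-word length in bp used for the initial
#'   direct-repeat scan.
#' @param ltr_length_range Acceptable LTR length in bp.
#' @param element_span_range Acceptable full element span (5'LTR start to
#'   3'LTR end) in bp.
#' @param min_ltr_pair_identity Minimum identity between the two LTR copies.
#' @param require_tg_ca Require TG..CA terminal dinucleotides on both LTRs.
#' @param tsd_length_range Target-site duplication length searched, in bp.
#' @param max_tsd_mismatches Maximum mismatches tolerated between the two
#'   TSD copies; elements above the cap are rejected.
#' @return A validated list of class `detector_params`.
#' @export
detector_params <- function(seed_word = 15,
                            ltr_length_range = c(100, 3000),
                            element_span_range = c(1000, 15000),
                            min_ltr_pair_identity = 0.80,
                            require_tg_ca = TRUE,
                            tsd_length_range = c(4, 6),
                            max_tsd_mismatches = 2) {
  check_range_pair(ltr_length_range, "ltr_length_range")
  check_range_pair(element_span_range, "element_span_range")
  check_range_pair(tsd_length_range, "tsd_length_range")
  if (min_ltr_pair_identity <= 0 || min_ltr_pair_identity > 1) {
    stop("min_ltr_pair_identity must be in (0, 1]")
  }
  if (max_tsd_mismatches < 0 || max_tsd_mismatches > 2) {
    stop("max_tsd_mismatches must be in [0, 2]")
  }
  structure(list(seed_word = as.integer(seed_word),
                 ltr_length_range = ltr_length_range,
                 element_span_range = element_span_range,
                 min_ltr_pair_identity = min_ltr_pair_identity,
                 require_tg_ca = isTRUE(require_tg_ca),
                 tsd_length_range = tsd_length_range,
                 max_tsd_mismatches = as.integer(max_tsd_mismatches)),
            class = "detector_params")
}

# Rolling exact hash of every k-mer (A=0..T=3); windows containing an
# ambiguous base hash to NA. k <= 15 keeps 4^k exactly representable.
kmer_hashes <- function(code, k) {
  n <- length(code) - k + 1
  if (n < 1) return(numeric(0))
  h <- numeric(n)
  for (t in 0:(k - 1)) {
    h <- h + code[(1 + t):(n + t)] * 4^(k - 1 - t)
  }
  h
}

base_codes <- function(chars) {
  code <- match(chars, BASES) - 1
  code  # NA for N and anything non-ACGT
}

# Split a sequence into chunks at runs of N longer than 11 nt, returning
# per-chunk character vectors and their 1-based offsets.
split_on_n_runs <- function(seq_chr) {
  m <- gregexpr("N{12,}", seq_chr)[[1]]
  n <- nchar(seq_chr)
  if (m[1] == -1) {
    return(list(list(offset = 0L, chars = strsplit(seq_chr, "")[[1]])))
  }
  runs <- data.frame(start = as.integer(m),
                     end = as.integer(m) + attr(m, "match.length") - 1L)
  keep_start <- c(1L, runs$end + 1L)
  keep_end <- c(runs$start - 1L, n)
  out <- list()
  for (i in seq_along(keep_start)) {
    if (keep_start[i] > keep_end[i]) next
    out[[length(out) + 1]] <- list(
      offset = keep_start[i] - 1L,
      chars = strsplit(substr(seq_chr, keep_start[i], keep_end[i]), "")[[1]])
  }
  out
}

# Ungapped X-drop extension along one direction; returns the number of
# steps to the maximal-score column.
xdrop_extend <- function(ch, a0, b0, dir, max_steps, xdrop = 15) {
  best <- 0; best_t <- 0L; sc <- 0; t <- 0L
  n <- length(ch)
  while (t < max_steps) {
    t <- t + 1L
    pa <- a0 + dir * t
    pb <- b0 + dir * t
    if (pa < 1L || pb < 1L || pa > n || pb > n) break
    sc <- sc + (if (ch[pa] == ch[pb]) 1 else -2)
    if (sc > best) { best <- sc; best_t <- t }
    if (best - sc > xdrop) break
  }
  best_t
}

# Best-matching TSD pair flanking a putative element (left_start = 5'LTR
# start, right_end = 3'LTR end): compares the L bases immediately left of
# the element with the L bases immediately right of it, for each L in the
# allowed range; minimal mismatch count wins, ties go to the longer TSD.
best_tsd <- function(ch, left_start, right_end, tsd_range) {
  best <- list(len = NA_integer_, mismatches = Inf,
               left = NA_character_, right = NA_character_)
  n <- length(ch)
  for (L in seq(tsd_range[2], tsd_range[1])) {
    if (left_start - L < 1 || right_end + L > n) next
    lf <- ch[(left_start - L):(left_start - 1)]
    rf <- ch[(right_end + 1):(right_end + L)]
    mm <- sum(lf != rf)
    if (mm < best$mismatches) {
      best <- list(len = L, mismatches = mm,
                   left = paste(lf, collapse = ""),
                   right = paste(rf, collapse = ""))
    }
  }
  best
}

# Snap candidate LTR boundaries to TG..CA termini shared by both copies
# (same diagonal offset d), preferring boundaries that produce the
# cleanest TSD, then the smallest move.  Returns c(start, end) or NULL.
snap_tg_ca <- function(ch, ls, le, d, params, window = 12L) {
  n <- length(ch)
  s_cand <- ls + (-window:window)
  s_cand <- s_cand[s_cand >= 1 & (s_cand + d + 1) <= n]
  s_ok <- s_cand[ch[s_cand] == "T" & ch[s_cand + 1] == "G" &
                 ch[s_cand + d] == "T" & ch[s_cand + d + 1] == "G"]
  e_cand <- le + (-window:window)
  e_cand <- e_cand[e_cand >= 2 & (e_cand + d) <= n]
  e_ok <- e_cand[ch[e_cand - 1] == "C" & ch[e_cand] == "A" &
                 ch[e_cand + d - 1] == "C" & ch[e_cand + d] == "A"]
  if (length(s_ok) == 0 || length(e_ok) == 0) return(NULL)
  combos <- expand.grid(s = s_ok, e = e_ok)
  len <- combos$e - combos$s + 1
  keep <- len >= params$ltr_length_range[1] &
    len <= min(params$ltr_length_range[2], d)
  combos <- combos[keep, , drop = FALSE]
  if (nrow(combos) == 0) return(NULL)
  mm <- mapply(function(s, e) {
    best_tsd(ch, s, e + d, params$tsd_length_range)$mismatches
  }, combos$s, combos$e)
  move <- abs(combos$s - ls) + abs(combos$e - le)
  o <- order(mm, move)
  c(combos$s[o[1]], combos$e[o[1]])
}

#' Find candidate LTR pairs in one sequence
#'
#' Scans a single DNA sequence for long direct-repeat pairs: exact
#' seed-word matches are clustered per diagonal, extended ungapped with an
#' X-drop rule, and (when `require_tg_ca`) snapped to shared TG..CA
#' termini. Candidates must satisfy the length, span and pair-identity
#' constraints in `params`; overlapping candidates are resolved by highest
#' pair identity, then longest span, then leftmost start.
#'
#' @param sequence A DNA string (character or [Biostrings::DNAString]),
#'   uppercase A/C/G/T/N.
#' @param params A [detector_params()].
#' @return A data.frame of candidates (`left_start`, `left_end`,
#'   `right_start`, `right_end`, `ltr_pair_identity`), sorted by
#'   `left_start`; zero rows when nothing is found.
#' @export
find_ltr_candidates <- function(sequence, params = detector_params()) {
  seq_chr <- toupper(as.character(sequence))
  stopifnot(length(seq_chr) == 1)
  k <- params$seed_word
  d_min <- max(params$ltr_length_range[1], k)
  d_max <- params$element_span_range[2] - params$ltr_length_range[1]
  cands <- list()
  for (chunk in split_on_n_runs(seq_chr)) {
    ch <- chunk$chars
    if (length(ch) < 2 * k) next
    h <- kmer_hashes(base_codes(ch), k)
    dt <- data.table::data.table(h = h, pos = seq_along(h))
    dt <- dt[!is.na(h)]
    dt[, n_occ := .N, by = h]
    dt <- dt[n_occ >= 2 & n_occ <= 64]
    if (nrow(dt) == 0) next
    data.table::setorder(dt, h, pos)
    pairs <- dt[, {
      p <- pos
      m <- length(p)
      ii <- rep(seq_len(m - 1), times = (m - 1):1)
      jj <- sequence((m - 1):1) + ii
      list(i = p[ii], j = p[jj])
    }, by = h]
    pairs[, d := j - i]
    pairs <- pairs[d >= d_min & d <= d_max]
    if (nrow(pairs) == 0) next
    data.table::setorder(pairs, d, i)
    pairs[, grp := cumsum(c(1L, diff(i) > 500L)), by = d]
    clusters <- pairs[, list(i0 = min(i), i1 = max(i), nseed = .N),
                      by = list(d, grp)]
    for (r in seq_len(nrow(clusters))) {
      d <- clusters$d[r]
      ls <- clusters$i0[r]
      le <- clusters$i1[r] + k - 1L
      # extend left and right, capped so the copies never overlap
      max_left <- min(ls - 1L, params$ltr_length_range[2] - (le - ls + 1L))
      tl <- if (max_left > 0) xdrop_extend(ch, ls, ls + d, -1L, max_left)
            else 0L
      ls <- ls - tl
      max_right <- min(length(ch) - (le + d),
                       params$ltr_length_range[2] - (le - ls + 1L),
                       ls + d - 1L - le)
      tr <- if (max_right > 0) xdrop_extend(ch, le, le + d, 1L, max_right)
            else 0L
      le <- le + tr
      if (params$require_tg_ca) {
        snapped <- snap_tg_ca(ch, ls, le, d, params)
        if (!is.null(snapped)) { ls <- snapped[1]; le <- snapped[2] }
      }
      len <- le - ls + 1L
      if (len < params$ltr_length_range[1] ||
          len > params$ltr_length_range[2] || len > d) next
      span <- d + len
      if (span < params$element_span_range[1] ||
          span > params$element_span_range[2]) next
      ident <- mean(ch[ls:le] == ch[(ls:le) + d])
      if (ident < params$min_ltr_pair_identity) next
      cands[[length(cands) + 1]] <- data.frame(
        left_start = ls + chunk$offset, left_end = le + chunk$offset,
        right_start = ls + d + chunk$offset,
        right_end = le + d + chunk$offset,
        ltr_pair_identity = ident)
    }
  }
  if (length(cands) == 0) return(empty_candidates())
  cand <- unique(do.call(rbind, cands))
  # resolve overlapping candidates: best identity, then longest span,
  # then leftmost
  span <- cand$right_end - cand$left_start + 1
  o <- order(-cand$ltr_pair_identity, -span, cand$left_start)
  cand <- cand[o, , drop = FALSE]
  kept <- logical(nrow(cand))
  occ_s <- numeric(0); occ_e <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    s <- cand$left_start[i]; e <- cand$right_end[i]
    if (!any(s <= occ_e & e >= occ_s)) {
      kept[i] <- TRUE
      occ_s <- c(occ_s, s); occ_e <- c(occ_e, e)
    }
  }
  cand <- cand[kept, , drop = FALSE]
  cand <- cand[order(cand$left_start), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

empty_candidates <- function() {
  data.frame(left_start = integer(0), left_end = integer(0),
             right_start = integer(0), right_end = integer(0),
             ltr_pair_identity = numeric(0))
}

#' Validate the structure of one candidate
#'
#' Checks the TG prefix / CA suffix of each LTR copy (when
#' `require_tg_ca`), finds the best-matching target-site duplication pair
#' in the flanking windows, and rejects candidates whose TSD copies differ
#' at more than `max_tsd_mismatches` positions.
#'
#' @param candidate A one-row data.frame (or list) with `left_start`,
#'   `left_end`, `right_start`, `right_end` (1-based inclusive).
#' @param sequence The DNA sequence the candidate lives on.
#' @param params A [detector_params()].
#' @return On acceptance, a list of class `ltr_element` with the populated
#'   structural evidence; on rejection, a list of class `ltr_rejection`
#'   with a `reason` string.
#' @export
validate_structure <- function(candidate, sequence,
                               params = detector_params()) {
  seq_chr <- toupper(as.character(sequence))
  n <- nchar(seq_chr)
  ls <- as.integer(candidate$left_start)
  le <- as.integer(candidate$left_end)
  rs <- as.integer(candidate$right_start)
  re <- as.integer(candidate$right_end)
  if (any(is.na(c(ls, le, rs, re))) || ls < 1 || re > n || le >= rs) {
    stop("candidate intervals out of bounds or malformed")
  }
  ch <- strsplit(substr(seq_chr, max(1, ls - params$tsd_length_range[2]),
                        min(n, re + params$tsd_length_range[2])), "")[[1]]
  off <- max(1, ls - params$tsd_length_range[2]) - 1L
  at <- function(i) ch[i - off]
  tg5 <- at(ls) == "T" && at(ls + 1) == "G"
  ca5 <- at(le - 1) == "C" && at(le) == "A"
  tg3 <- at(rs) == "T" && at(rs + 1) == "G"
  ca3 <- at(re - 1) == "C" && at(re) == "A"
  ok5 <- tg5 && ca5
  ok3 <- tg3 && ca3
  if (params$require_tg_ca && !(ok5 && ok3)) {
    return(structure(list(reason = "termini", candidate = candidate),
                     class = "ltr_rejection"))
  }
  tsd <- best_tsd(ch, ls - off, re - off, params$tsd_length_range)
  if (!is.finite(tsd$mismatches)) {
    return(structure(list(reason = "tsd_out_of_bounds",
                          candidate = candidate), class = "ltr_rejection"))
  }
  if (tsd$mismatches > params$max_tsd_mismatches) {
    return(structure(list(reason = sprintf("tsd_mismatches>%d",
                                           params$max_tsd_mismatches),
                          candidate = candidate), class = "ltr_rejection"))
  }
  ident <- candidate$ltr_pair_identity
  if (is.null(ident) || is.na(ident)) {
    l5 <- substr(seq_chr, ls, le)
    l3 <- substr(seq_chr, rs, re)
    ident <- align_ltr_pair(l5, l3)$p_distance
    ident <- 1 - ident
  }
  structure(list(
    ltr5 = c(start = ls, end = le),
    ltr3 = c(start = rs, end = re),
    internal = c(start = le + 1L, end = rs - 1L),
    ltr_pair_identity = as.numeric(ident),
    tg_ca_ok = c(ltr5 = ok5, ltr3 = ok3),
    tsd_left = tsd$left, tsd_right = tsd$right,
    tsd_mismatches = as.integer(tsd$mismatches)),
    class = "ltr_element")
}

#' Test whether a validation result is a rejection
#' @param x Result of [validate_structure()].
#' @return Logical.
#' @export
is_rejected <- function(x) inherits(x, "ltr_rejection")

#' Label an element with its lineage by signature match
#'
#' Scans the internal region for the lineage signature with the
#' highest-identity local alignment covering at least half of the
#' signature at >= 0.7 identity; elements without such a match stay
#' unclassified (`RLX` / `unknown`). Ties are broken by table order.
#'
#' @param element An `ltr_element` from [validate_structure()].
#' @param sequence The DNA sequence the element lives on.
#' @param lineage_table Data frame with `lineage`, `superfamily`,
#'   `signature` columns (see [default_lineage_table()]).
#' @return A list with `lineage` and `superfamily`.
#' @export
classify_lineage <- function(element, sequence,
                             lineage_table = default_lineage_table()) {
  unknown <- list(lineage = "RLX", superfamily = "unknown")
  if (is.null(lineage_table) || nrow(lineage_table) == 0) return(unknown)
  seq_chr <- toupper(as.character(sequence))
  int <- substr(seq_chr, element$internal["start"], element$internal["end"])
  if (nchar(int) < 1) return(unknown)
  subj <- Biostrings::DNAString(int)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -2,
                                                  baseOnly = TRUE)
  best_i <- 0L
  best_ident <- -Inf
  for (i in seq_len(nrow(lineage_table))) {
    sig <- lineage_table$signature[i]
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(sig), subj, type = "local",
      substitutionMatrix = mat, gapOpening = 6, gapExtension = 1)
    pat <- as.character(Biostrings::alignedPattern(aln))
    cols <- nchar(pat)
    if (cols == 0) next
    ident <- Biostrings::nmatch(aln) / cols
    pat_letters <- cols - sum(strsplit(pat, "")[[1]] == "-")
    coverage <- pat_letters / nchar(sig)
    if (coverage >= 0.5 && ident >= 0.7 && ident > best_ident) {
      best_ident <- ident
      best_i <- i
    }
  }
  if (best_i == 0L) return(unknown)
  list(lineage = lineage_table$lineage[best_i],
       superfamily = lineage_table$superfamily[best_i])
}

#' Detect full-length LTR retrotransposons across a genome
#'
#' Composes [find_ltr_candidates()], [validate_structure()] and
#' [classify_lineage()] over every sequence of a genome. The scan is
#' forward-strand and fully deterministic.
#'
#' @param genome Named [Biostrings::DNAStringSet] or character vector.
#' @param params A [detector_params()].
#' @param lineage_table Signature table for lineage labelling (see
#'   [default_lineage_table()]); `NULL` skips classification.
#' @return A data.frame with one row per accepted element: coordinates of
#'   both LTRs and the internal region, pair identity, terminal and TSD
#'   evidence, lineage and superfamily.
#' @export
detect_full_length_ltrs <- function(genome, params = detector_params(),
                                    lineage_table = default_lineage_table()) {
  gchars <- as_genome_chars(genome)
  rows <- list()
  for (chrom in names(gchars)) {
    cand <- find_ltr_candidates(gchars[[chrom]], params)
    for (i in seq_len(nrow(cand))) {
      el <- validate_structure(cand[i, ], gchars[[chrom]], params)
      if (is_rejected(el)) next
      cls <- if (is.null(lineage_table)) {
        list(lineage = "RLX", superfamily = "unknown")
      } else {
        classify_lineage(el, gchars[[chrom]], lineage_table)
      }
      rows[[length(rows) + 1]] <- data.frame(
        element_id = NA_character_, chrom = chrom,
        start = el$ltr5["start"], end = el$ltr3["end"],
        ltr5_start = el$ltr5["start"], ltr5_end = el$ltr5["end"],
        ltr3_start = el$ltr3["start"], ltr3_end = el$ltr3["end"],
        internal_start = el$internal["start"],
        internal_end = el$internal["end"],
        ltr_pair_identity = el$ltr_pair_identity,
        tg_ca_ok_5 = el$tg_ca_ok[["ltr5"]],
        tg_ca_ok_3 = el$tg_ca_ok[["ltr3"]],
        tsd_left = el$tsd_left, tsd_right = el$tsd_right,
        tsd_mismatches = el$tsd_mismatches,
        lineage = cls$lineage, superfamily = cls$superfamily,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty_elements())
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$element_id <- sprintf("FLE%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

empty_elements <- function() {
  data.frame(element_id = character(0), chrom = character(0),
             start = integer(0), end = integer(0), ltr5_start = integer(0),
             ltr5_end = integer(0), ltr3_start = integer(0),
             ltr3_end = integer(0), internal_start = integer(0),
             internal_end = integer(0), ltr_pair_identity = numeric(0),
             tg_ca_ok_5 = logical(0), tg_ca_ok_3 = logical(0),
             tsd_left = character(0), tsd_right = character(0),
             tsd_mismatches = integer(0), lineage = character(0),
             superfamily = character(0), stringsAsFactors = FALSE)
}
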