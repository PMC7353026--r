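# Brute-force oracles and small fixture builders, independent of the
# package's GenomicRanges/data.table-backed implementations.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

rc_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# O(n*m) all-pairs nearest distance (1-based inclusive intervals,
# overlap/adjacency = 0).
brute_min_distance <- function(gene, tes) {
  if (nrow(tes) == 0) return(Inf)
  d <- Inf
  for (i in seq_len(nrow(tes))) {
    if (!is.na(gene$chrom) && tes$chrom[i] != gene$chrom) next
    gap <- max(gene$start, tes$start[i]) - min(gene$end, tes$end[i]) - 1
    d <- min(d, max(0, gap))
  }
  d
}

# O(n*m) all-pairs largest-overlap TE assignment for one locus.
brute_te_assignment <- function(locus, tes, min_overlap) {
  best_id <- NA_character_
  best_w <- 0
  best_start <- Inf
  for (i in seq_len(nrow(tes))) {
    if (tes$chrom[i] != locus$chrom) next
    w <- min(locus$end, tes$end[i]) - max(locus$start, tes$start[i]) + 1
    if (w < min_overlap) next
    if (w > best_w || (w == best_w && tes$start[i] < best_start)) {
      best_w <- w
      best_id <- tes$te_id[i]
      best_start <- tes$start[i]
    }
  }
  best_id
}

# All-pairs word comparison dot-plot oracle.
brute_dotplot <- function(a, b, w) {
  na <- nchar(a) - w + 1
  nb <- nchar(b) - w + 1
  out <- list()
  if (na < 1 || nb < 1) {
    return(data.frame(i = integer(0), j = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  wa <- substring(a, 1:na, w:(na + w - 1))
  wb <- substring(b, 1:nb, w:(nb + w - 1))
  wb_rc <- vapply(wb, rc_chr, character(1), USE.NAMES = FALSE)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      if (wa[i] == wb[j]) {
        out[[length(out) + 1]] <- data.frame(i = i, j = j, strand = "+",
                                             stringsAsFactors = FALSE)
      }
      if (wa[i] == wb_rc[j]) {
        out[[length(out) + 1]] <- data.frame(i = i, j = j, strand = "-",
                                             stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(i = integer(0), j = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$i, res$j, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Diagonal-sweep scan for any direct-repeat pair of length >= min_len with
# identity >= min_ident at separation d in [d_lo, d_hi]; O(n) per diagonal
# via a rolling match count. Used to certify absence on background.
brute_has_repeat_pair <- function(seq_chr, min_len = 100, min_ident = 0.8,
                                  d_lo = 100, d_hi = 15000) {
  ch <- strsplit(seq_chr, "")[[1]]
  n <- length(ch)
  need <- ceiling(min_len * min_ident)
  for (d in d_lo:min(d_hi, n - min_len)) {
    eq <- ch[1:(n - d)] == ch[(1 + d):n]
    if (length(eq) < min_len) next
    cs <- cumsum(eq)
    wins <- cs[min_len:length(cs)] - c(0, cs[seq_len(length(cs) - min_len)])
    if (any(wins >= need)) return(TRUE)
  }
  FALSE
}

# Hand-built full-length element planted into background; returns the
# sequence and the truth coordinates (1-based inclusive).
plant_element <- function(background_left = 500, background_right = 500,
                          ltr_len = 300, internal_len = 800, tsd = "ACGTC",
                          tsd_right = tsd, seed = 99) {
  set.seed(seed)
  ltr <- c("T", "G", sample(c("A", "C", "G", "T"), ltr_len - 4,
                            replace = TRUE), "C", "A")
  internal <- sample(c("A", "C", "G", "T"), internal_len, replace = TRUE)
  left_bg <- sample(c("A", "C", "G", "T"), background_left, replace = TRUE)
  right_bg <- sample(c("A", "C", "G", "T"), background_right,
                     replace = TRUE)
  tsd_l <- strsplit(tsd, "")[[1]]
  tsd_r <- strsplit(tsd_right, "")[[1]]
  seq_chr <- paste(c(left_bg, tsd_l, ltr, internal, ltr, tsd_r, right_bg),
                   collapse = "")
  ltr5_start <- background_left + length(tsd_l) + 1
  ltr5_end <- ltr5_start + ltr_len - 1
  ltr3_start <- ltr5_end + internal_len + 1
  ltr3_end <- ltr3_start + ltr_len - 1
  list(seq = seq_chr,
       cand = data.frame(left_start = ltr5_start, left_end = ltr5_end,
                         right_start = ltr3_start, right_end = ltr3_end,
                         ltr_pair_identity = 1))
}
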