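# Attribution of small RNA reads to transposable elements: collapse reads,
# exclude known miRNAs, place each distinct sequence at its best genomic
# hit, intersect the loci with the TE annotation and quantify size classes
# and per-superfamily production.
#
# Reads of 20-25 nt are short enough that exact matching on both strands is
# the appropriate "best hit" notion: every full-length exact hit scores the
# read length, a single best locus makes the read `unique`, several make it
# `ambiguous` (recorded at the leftmost locus and excluded from
# quantification), and no hit at or above `min_score` leaves it `unmapped`.

#' Mapping parameters for small RNA loci
#'
#' @param min_score Minimum matching bases for a mapped locus (default 10).
#' @param max_mismatches Mismatches allowed per hit; only exact matching
#'   (0) is supported.
#' @param min_overlap_bp Minimum overlap with a TE span for a locus to be
#'   TE-derived (default 1).
#' @return A list of class `mapping_params`.
#' @export
mapping_params <- function(min_score = 10, max_mismatches = 0,
                           min_overlap_bp = 1) {
  if (min_score < 0 || max_mismatches < 0 || min_overlap_bp < 0) {
    stop("mapping parameters must be non-negative")
  }
  if (max_mismatches != 0) {
    stop("only exact matching (max_mismatches = 0) is supported")
  }
  structure(list(min_score = as.integer(min_score),
                 max_mismatches = as.integer(max_mismatches),
                 min_overlap_bp = as.integer(min_overlap_bp)),
            class = "mapping_params")
}

#' Collapse raw reads into distinct sequences
#'
#' Uppercases, maps U to T, and returns one record per distinct sequence
#' with its multiplicity, in lexicographic order.
#'
#' @param raw Character vector or [Biostrings::XStringSet] of read
#'   sequences (A/C/G/T/U).
#' @return Data frame with `sequence`, `count`, `length_nt`.
#' @export
collapse_reads <- function(raw) {
  if (!is.character(raw)) raw <- as.character(raw)
  if (length(raw) == 0) {
    return(data.frame(sequence = character(0), count = integer(0),
                      length_nt = integer(0), stringsAsFactors = FALSE))
  }
  raw <- toupper(raw)
  if (any(nchar(raw) == 0)) stop("empty read sequence")
  raw <- gsub("U", "T", raw, fixed = TRUE)
  bad <- grepl("[^ACGT]", raw)
  if (any(bad)) {
    stop(sprintf("read sequences must be over A/C/G/T/U (offending: %s)",
                 raw[which(bad)[1]]))
  }
  tab <- table(raw)
  seqs <- sort(names(tab))
  data.frame(sequence = seqs, count = as.integer(tab[seqs]),
             length_nt = nchar(seqs), stringsAsFactors = FALSE)
}

#' Remove blacklisted miRNA sequences
#'
#' Drops collapsed reads whose sequence exactly matches an entry of the
#' miRNA blacklist (normalised the same way as the reads).
#'
#' @param collapsed Output of [collapse_reads()].
#' @param mirna_blacklist Character vector or
#'   [Biostrings::XStringSet] of miRNA sequences.
#' @return List with `kept` (data frame) and `dropped` (count).
#' @export
exclude_mirnas <- function(collapsed, mirna_blacklist) {
  bl <- toupper(as.character(mirna_blacklist))
  bl <- gsub("U", "T", bl, fixed = TRUE)
  keep <- !collapsed$sequence %in% bl
  kept <- collapsed[keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, dropped = sum(!keep))
}

#' Map collapsed reads to their best genomic hit
#'
#' Exact-match search on both strands. A read with exactly one hit is
#' `unique` there; with several, `ambiguous` and recorded at the leftmost
#' locus (chromosome lexicographic, then coordinate, plus strand before
#' minus at the same position); with none (or shorter than `min_score`),
#' `unmapped`.
#'
#' @param collapsed Output of [collapse_reads()] / [exclude_mirnas()].
#' @param genome Named [Biostrings::DNAStringSet] or character vector.
#' @param params A [mapping_params()].
#' @return Data frame: the collapsed columns plus `chrom`, `start`, `end`,
#'   `strand`, `score`, `status`, `n_hits`, `te_assignment`.
#' @export
map_best_hit <- function(collapsed, genome, params = mapping_params()) {
  gset <- as_dna_string_set(genome)
  n <- nrow(collapsed)
  out <- collapsed
  out$chrom <- NA_character_
  out$start <- NA_integer_
  out$end <- NA_integer_
  out$strand <- NA_character_
  out$score <- NA_integer_
  out$status <- "unmapped"
  out$n_hits <- 0L
  out$te_assignment <- NA_character_
  if (n == 0) return(out)
  searchable <- which(collapsed$length_nt >= params$min_score)
  if (length(searchable) == 0) return(out)
  hits <- list()
  chrom_names <- sort(names(gset))
  for (len in sort(unique(collapsed$length_nt[searchable]))) {
    idx <- searchable[collapsed$length_nt[searchable] == len]
    fwd <- Biostrings::DNAStringSet(collapsed$sequence[idx])
    pd_fwd <- Biostrings::PDict(fwd)
    pd_rev <- Biostrings::PDict(Biostrings::reverseComplement(fwd))
    for (chrom in chrom_names) {
      subj <- gset[[chrom]]
      for (strand in c("+", "-")) {
        pd <- if (strand == "+") pd_fwd else pd_rev
        m <- Biostrings::matchPDict(pd, subj)
        starts <- Biostrings::startIndex(m)
        for (q in seq_along(idx)) {
          ss <- starts[[q]]
          if (is.null(ss) || length(ss) == 0) next
          hits[[length(hits) + 1]] <- data.frame(
            read = idx[q], chrom = chrom, start = ss, strand = strand,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(hits) > 0) {
    ht <- data.table::as.data.table(do.call(rbind, hits))
    data.table::setorder(ht, read, chrom, start, strand)
    first <- ht[, list(chrom = chrom[1], start = start[1],
                       strand = strand[1], n_hits = .N), by = read]
    i <- first$read
    out$chrom[i] <- first$chrom
    out$start[i] <- first$start
    out$end[i] <- first$start + out$length_nt[i] - 1L
    out$strand[i] <- first$strand
    out$score[i] <- out$length_nt[i]
    out$n_hits[i] <- first$n_hits
    out$status[i] <- ifelse(first$n_hits == 1L, "unique", "ambiguous")
  }
  out
}

#' Intersect small RNA loci with TE annotations
#'
#' A locus is TE-derived iff its span overlaps a TE span by at least
#' `min_overlap_bp`; it is assigned to the TE with the largest overlap
#' (ties: leftmost TE). Only uniquely mapped loci receive an assignment;
#' ambiguous loci are excluded from downstream quantification.
#'
#' @param loci Output of [map_best_hit()].
#' @param te_annotations Data frame with `chrom`, `start`, `end` and
#'   optionally `te_id` (synthesised when absent).
#' @param params A [mapping_params()].
#' @param gff3_out Optional path: writes the TE-derived loci as GFF3
#'   (`siRNA` records with `te_id` and `count` attributes).
#' @return `loci` with `te_assignment` filled in.
#' @export
intersect_te <- function(loci, te_annotations, params = mapping_params(),
                         gff3_out = NULL) {
  te <- te_annotations
  if (!"te_id" %in% names(te)) {
    te$te_id <- sprintf("TEA%05d", seq_len(nrow(te)))
  }
  loci$te_assignment <- NA_character_
  cand <- which(loci$status == "unique")
  if (length(cand) > 0 && nrow(te) > 0) {
    q <- GenomicRanges::GRanges(loci$chrom[cand],
                                IRanges::IRanges(loci$start[cand],
                                                 loci$end[cand]))
    s <- GenomicRanges::GRanges(te$chrom,
                                IRanges::IRanges(te$start, te$end))
    ov <- GenomicRanges::findOverlaps(q, s, ignore.strand = TRUE,
                                      minoverlap = params$min_overlap_bp)
    if (length(ov) > 0) {
      qh <- S4Vectors::queryHits(ov)
      sh <- S4Vectors::subjectHits(ov)
      w <- GenomicRanges::width(IRanges::pintersect(
        GenomicRanges::ranges(q)[qh], GenomicRanges::ranges(s)[sh]))
      dt <- data.table::data.table(q = qh, s = sh, w = w,
                                   te_chrom = te$chrom[sh],
                                   te_start = te$start[sh])
      data.table::setorder(dt, q, -w, te_chrom, te_start, s)
      best <- dt[, list(s = s[1]), by = q]
      loci$te_assignment[cand[best$q]] <- te$te_id[best$s]
    }
  }
  if (!is.null(gff3_out)) {
    sel <- !is.na(loci$te_assignment)
    gr <- GenomicRanges::GRanges(
      loci$chrom[sel], IRanges::IRanges(loci$start[sel], loci$end[sel]),
      strand = loci$strand[sel])
    S4Vectors::mcols(gr)$type <- rep("siRNA", sum(sel))
    S4Vectors::mcols(gr)$ID <- sprintf("sirna%05d", seq_len(sum(sel)))
    S4Vectors::mcols(gr)$te_id <- loci$te_assignment[sel]
    S4Vectors::mcols(gr)$count <- loci$count[sel]
    export_gff3_safe(gr, gff3_out)
  }
  loci
}

#' Size distribution of TE-derived small RNA loci
#'
#' Fractions over read lengths 20-25 nt among TE-assigned loci, either
#' weighting each distinct sequence by its read count (`by_read_count`) or
#' counting each distinct sequence once (`by_unique_sequence`).
#'
#' @param te_loci Output of [intersect_te()].
#' @param weighting "by_read_count" (default) or "by_unique_sequence".
#' @return Data frame `length_nt`, `fraction` (all-zero with attribute
#'   `n = 0` when no loci qualify).
#' @export
size_distribution <- function(te_loci,
                              weighting = c("by_read_count",
                                            "by_unique_sequence")) {
  weighting <- match.arg(weighting)
  sel <- !is.na(te_loci$te_assignment)
  lens <- te_loci$length_nt[sel]
  w <- if (weighting == "by_read_count") te_loci$count[sel] else
    rep(1L, sum(sel))
  total <- sum(w)
  out <- data.frame(length_nt = 20:25, fraction = 0)
  if (total > 0) {
    for (i in seq_len(nrow(out))) {
      out$fraction[i] <- sum(w[lens == out$length_nt[i]]) / total
    }
  }
  attr(out, "n") <- total
  attr(out, "weighting") <- weighting
  out
}

#' Small RNA production by TE superfamily code
#'
#' Percent of reads of the stated length produced per Wicker superfamily
#' code, over uniquely mapped TE-assigned loci, weighted by read count.
#'
#' @param te_loci Output of [intersect_te()].
#' @param te_annotations TE annotation table with `te_id` and either a
#'   `wicker_code` column or the class/order/superfamily/completeness
#'   columns it can be derived from.
#' @param length_nt Read length to quantify (default 24).
#' @return Data frame `code`, `reads`, `percent` (attribute `n` = total
#'   reads); percentages sum to 100 up to rounding.
#' @export
production_by_superfamily <- function(te_loci, te_annotations,
                                      length_nt = 24) {
  te <- te_annotations
  if (!"te_id" %in% names(te)) {
    te$te_id <- sprintf("TEA%05d", seq_len(nrow(te)))
  }
  code <- if ("wicker_code" %in% names(te)) te$wicker_code else
    assign_wicker_code(te$te_class, te$order, te$superfamily,
                       te$completeness)
  # quantify by the three-letter code without the completeness suffix
  code <- sub("-(comp|incomp)$", "", code)
  sel <- !is.na(te_loci$te_assignment) & te_loci$length_nt == length_nt &
    te_loci$status == "unique"
  empty <- data.frame(code = character(0), reads = integer(0),
                      percent = numeric(0), stringsAsFactors = FALSE)
  if (!any(sel)) {
    attr(empty, "n") <- 0L
    return(empty)
  }
  cnt <- te_loci$count[sel]
  te_code <- code[match(te_loci$te_assignment[sel], te$te_id)]
  agg <- tapply(cnt, te_code, sum)
  out <- data.frame(code = names(agg), reads = as.integer(agg),
                    stringsAsFactors = FALSE)
  out$percent <- 100 * out$reads / sum(out$reads)
  out <- out[order(-out$reads, out$code), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n") <- sum(out$reads)
  out
}
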