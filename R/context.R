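# Genomic-context utilities: gene-TE proximity, promoter extraction from
# the start codon, IUPAC cis-element scanning, and a word-match dot-plot
# for locus comparison. Coordinates are 1-based inclusive throughout, as
# in GFF3 and the Bioconductor ranges stack.

as_interval <- function(x, what) {
  if (is.data.frame(x)) {
    if (nrow(x) != 1) stop(sprintf("'%s' must be a single interval", what))
    return(list(chrom = if ("chrom" %in% names(x)) x$chrom else NA,
                start = x$start, end = x$end))
  }
  if (is.numeric(x) && length(x) == 2) {
    return(list(chrom = NA, start = x[1], end = x[2]))
  }
  stop(sprintf("'%s' must be c(start, end) or a one-row data.frame", what))
}

#' Distance between two genomic intervals
#'
#' Zero when the intervals overlap or are adjacent, otherwise the number
#' of bases strictly between them. Intervals on different chromosomes have
#' no defined distance and raise an error.
#'
#' @param a,b Intervals as `c(start, end)` (1-based inclusive) or one-row
#'   data.frames with `chrom`, `start`, `end`.
#' @return Non-negative integer gap length in bp.
#' @export
interval_distance <- function(a, b) {
  ia <- as_interval(a, "a")
  ib <- as_interval(b, "b")
  if (!is.na(ia$chrom) && !is.na(ib$chrom) && ia$chrom != ib$chrom) {
    stop("intervals lie on different chromosomes; distance undefined")
  }
  if (ia$start > ia$end || ib$start > ib$end) stop("malformed interval")
  gap <- max(ia$start, ib$start) - min(ia$end, ib$end) - 1
  max(0L, as.integer(gap))
}

#' Fraction of genes with a TE within a distance threshold
#'
#' A gene counts for threshold t iff the minimum distance from its
#' annotated span to any TE is at most t bp; a TE overlapping the gene
#' (including one inside an intron) gives distance 0 and counts at every
#' threshold. The fraction is monotone non-decreasing in t.
#'
#' @param genes Data frame with `chrom`, `start`, `end`.
#' @param tes Data frame with `chrom`, `start`, `end`.
#' @param thresholds Positive distance thresholds in bp.
#' @return Data frame with one row per threshold: `threshold_bp`,
#'   `n_genes`, `n_genes_with_te`, `fraction`.
#' @export
gene_te_proximity <- function(genes, tes, thresholds = c(500, 1000)) {
  if (any(thresholds <= 0)) stop("thresholds must be positive")
  n_genes <- nrow(genes)
  dmin <- rep(Inf, n_genes)
  if (n_genes > 0 && nrow(tes) > 0) {
    q <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(genes$start, genes$end))
    s <- GenomicRanges::GRanges(tes$chrom,
                                IRanges::IRanges(tes$start, tes$end))
    hit <- GenomicRanges::distanceToNearest(q, s, ignore.strand = TRUE)
    dmin[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance
  }
  out <- lapply(sort(thresholds), function(t) {
    hits <- sum(dmin <= t)
    data.frame(threshold_bp = t, n_genes = n_genes,
               n_genes_with_te = hits,
               fraction = if (n_genes > 0) hits / n_genes else 0)
  })
  do.call(rbind, out)
}

#' Extract promoter sequences upstream of the start codon
#'
#' For a plus-strand gene the promoter is the `length_bp` bases
#' immediately upstream of `cds_start` (the genomic coordinate of the
#' first base of the start codon in transcript orientation); for a
#' minus-strand gene, the reverse complement of the `length_bp` bases
#' immediately downstream. Promoters are truncated at contig edges, so the
#' returned width may be shorter than requested.
#'
#' @param genes Data frame with `gene_id`, `chrom`, `strand`, `cds_start`.
#' @param genome Named [Biostrings::DNAStringSet] or character vector.
#' @param length_bp Requested promoter length in bp (default 2000).
#' @return A [Biostrings::DNAStringSet] named by gene id; widths report
#'   the actual extracted lengths.
#' @export
extract_promoters <- function(genes, genome, length_bp = 2000) {
  gchars <- as_genome_chars(genome)
  out <- character(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    chrom <- genes$chrom[i]
    if (!chrom %in% names(gchars)) {
      stop(sprintf("chromosome '%s' absent from genome", chrom))
    }
    clen <- nchar(gchars[[chrom]])
    cds <- genes$cds_start[i]
    if (identical(genes$strand[i], "-")) {
      from <- cds + 1
      to <- min(clen, cds + length_bp)
      s <- if (from > to) "" else substr(gchars[[chrom]], from, to)
      if (nchar(s) > 0) s <- revcomp_chr(s)
    } else {
      from <- max(1, cds - length_bp)
      to <- cds - 1
      s <- if (from > to) "" else substr(gchars[[chrom]], from, to)
    }
    out[i] <- s
  }
  Biostrings::DNAStringSet(stats::setNames(out, genes$gene_id))
}

#' Default cis-element catalog
#'
#' Ships the names and categories of commonly scanned plant promoter
#' cis-elements (CAAT-box, G-Box, ARE, ABRE, ...) together with synthetic
#' placeholder IUPAC patterns. The patterns are NOT the proprietary
#' PlantCARE matrices -- they are plausible stand-ins so the scanning
#' machinery can be exercised; counts obtained with them are not
#' comparable to PlantCARE output.
#'
#' @return Data frame with `name`, `category`, `iupac`.
#' @export
default_motif_catalog <- function() {
  data.frame(
    name = c("CAAT-box", "G-Box", "ACE", "Box 4", "GT1-motif", "ARE",
             "ABRE", "AuxRR-core", "TGA-element", "CGTCA-motif", "MBS",
             "TC-rich repeats"),
    category = c("Enhancer", "light", "light", "light", "light",
                 "Anaerobic", "Hormone", "Hormone", "Hormone", "Hormone",
                 "Abiotic stress", "Abiotic stress"),
    iupac = c("CAAT", "CACGTG", "GACACGTAGA", "ATTAAT", "GGTTAA",
              "AAACCA", "ACGTGKC", "GGTCCAT", "AACGAC", "CGTCA",
              "CAACTG", "ATTYTCTYCC"),
    stringsAsFactors = FALSE)
}

#' Scan promoters for IUPAC cis-element patterns
#'
#' Counts occurrences of each pattern on both strands, including
#' overlapping occurrences. A palindromic pattern matches the same sites
#' on both strands and is therefore counted twice by default
#' (`palindrome_both_strands = FALSE` counts such sites once).
#'
#' @param promoters [Biostrings::DNAStringSet] or named character vector.
#' @param catalog Data frame with `name`, `category`, `iupac` (see
#'   [default_motif_catalog()]).
#' @param palindrome_both_strands Count palindromic-pattern sites on both
#'   strands (default TRUE).
#' @return List with `counts` (promoter x motif integer matrix with a
#'   `Total` column), `categories` (per-motif category vector) and
#'   `category_totals` (promoter x category matrix).
#' @export
scan_motifs <- function(promoters, catalog = default_motif_catalog(),
                        palindrome_both_strands = TRUE) {
  proms <- as_dna_string_set(promoters)
  iupac_ok <- names(Biostrings::IUPAC_CODE_MAP)
  n_mot <- nrow(catalog)
  if (n_mot > 0) {
    for (i in seq_len(n_mot)) {
      pat <- toupper(catalog$iupac[i])
      if (nchar(pat) == 0 ||
          !all(strsplit(pat, "")[[1]] %in% iupac_ok)) {
        stop(sprintf("catalog entry '%s' has an invalid IUPAC pattern '%s'",
                     catalog$name[i], catalog$iupac[i]))
      }
    }
  }
  counts <- matrix(0L, nrow = length(proms), ncol = n_mot,
                   dimnames = list(names(proms), catalog$name))
  for (i in seq_len(n_mot)) {
    pat <- Biostrings::DNAString(toupper(catalog$iupac[i]))
    rc <- Biostrings::reverseComplement(pat)
    fwd <- Biostrings::vcountPattern(pat, proms, fixed = FALSE)
    if (as.character(rc) == as.character(pat) &&
        !palindrome_both_strands) {
      counts[, i] <- fwd
    } else {
      counts[, i] <- fwd + Biostrings::vcountPattern(rc, proms,
                                                     fixed = FALSE)
    }
  }
  total <- rowSums(counts)
  cats <- unique(catalog$category)
  cat_tot <- matrix(0L, nrow = length(proms), ncol = length(cats),
                    dimnames = list(names(proms), cats))
  for (cc in cats) {
    cat_tot[, cc] <- rowSums(counts[, catalog$category == cc,
                                    drop = FALSE])
  }
  list(counts = cbind(counts, Total = total),
       categories = stats::setNames(catalog$category, catalog$name),
       category_totals = cat_tot)
}

#' Word-match dot-plot between two sequences
#'
#' Reports every pair of positions (i in `seq_a`, j in `seq_b`, 1-based)
#' where the `word_size`-mer of `seq_a` at i equals the `word_size`-mer of
#' `seq_b` at j (`+`) or its reverse complement (`-`).
#'
#' @param seq_a,seq_b DNA sequences (character or
#'   [Biostrings::DNAString]).
#' @param word_size Word length in bp, at least 4 (default 10).
#' @return Data frame `i`, `j`, `strand`, sorted by `i`, `j`; zero rows
#'   when either sequence is shorter than `word_size`.
#' @export
dotplot_matrix <- function(seq_a, seq_b, word_size = 10) {
  if (word_size < 4) stop("word_size must be at least 4")
  a <- toupper(as.character(seq_a))
  b <- toupper(as.character(seq_b))
  empty <- data.frame(i = integer(0), j = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
  na <- nchar(a) - word_size + 1
  nb <- nchar(b) - word_size + 1
  if (na < 1 || nb < 1) return(empty)
  words_a <- substring(a, 1:na, word_size:(na + word_size - 1))
  words_b <- substring(b, 1:nb, word_size:(nb + word_size - 1))
  da <- data.table::data.table(word = words_a, i = 1:na)
  db <- data.table::data.table(word = words_b, j = 1:nb)
  plus <- merge(da, db, by = "word", allow.cartesian = TRUE)
  b_rc <- revcomp_chr(b)
  words_b_rc <- substring(b_rc, 1:nb, word_size:(nb + word_size - 1))
  dbr <- data.table::data.table(word = words_b_rc, jr = 1:nb)
  minus <- merge(da, dbr, by = "word", allow.cartesian = TRUE)
  res <- rbind(
    if (nrow(plus)) data.frame(i = plus$i, j = plus$j, strand = "+",
                               stringsAsFactors = FALSE) else empty,
    # position jr on the reverse complement corresponds to the original
    # window starting at nb_total - (jr + w - 1) + 1
    if (nrow(minus)) data.frame(
      i = minus$i, j = nchar(b) - (minus$jr + word_size - 1) + 1,
      strand = "-", stringsAsFactors = FALSE) else empty)
  res <- res[order(res$i, res$j, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}
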