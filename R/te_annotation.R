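# Wicker-code bookkeeping, the >=80 bp / >=80 % identity filter, and
# genome-level summary tables for TE annotation sets.
#
# A TE annotation set is a plain data.frame with (at least) the columns
# chrom, start, end, strand, te_class ("I"/"II"/"unknown"), order ("LTR",
# "LINE", "SINE", "TIR", "Helitron", "LARD", "TRIM", "unknown"),
# superfamily, completeness ("comp"/"incomp"), identity_to_consensus
# (percent) and length_bp.  identity_to_consensus is carried as an input
# attribute (e.g. from a GFF3 `identity=` tag); consensus building is the
# job of an upstream annotation pipeline, not of this package.

WICKER_ORDER_LETTER <- c(LTR = "L", LINE = "I", SINE = "S", TIR = "T",
                         unknown = "X")
WICKER_SUPERFAMILY_LETTER <- c("Ty3/gypsy" = "G", "Gypsy" = "G",
                               "Ty1/copia" = "C", "Copia" = "C")

#' Assign a Wicker classification code
#'
#' Builds the three-letter hierarchical code (class / order / superfamily,
#' `X` for unknown) with a `-comp`/`-incomp` completeness suffix. The
#' non-autonomous LARD and TRIM derivatives map to `RXX-LARD` /
#' `RXX-TRIM` without a suffix, and Helitrons are coded `HX` as
#' conventionally printed.
#'
#' @param te_class "I", "II" or "unknown".
#' @param order One of LTR, LINE, SINE, TIR, Helitron, LARD, TRIM, unknown.
#' @param superfamily Superfamily name; anything unrecognised codes as `X`.
#' @param completeness "comp" or "incomp".
#' @return Character vector of codes (vectorised over the inputs).
#' @export
assign_wicker_code <- function(te_class, order, superfamily = "unknown",
                               completeness = "incomp") {
  n <- max(length(te_class), length(order), length(superfamily),
           length(completeness))
  te_class <- rep_len(te_class, n)
  order <- rep_len(order, n)
  superfamily <- rep_len(superfamily, n)
  completeness <- rep_len(completeness, n)
  bad <- !te_class %in% c("I", "II", "unknown")
  if (any(bad)) stop(sprintf("unknown te_class value: %s",
                             paste(unique(te_class[bad]), collapse = ", ")))
  bad <- !order %in% c("LTR", "LINE", "SINE", "TIR", "Helitron", "LARD",
                       "TRIM", "unknown")
  if (any(bad)) stop(sprintf("unknown order value: %s",
                             paste(unique(order[bad]), collapse = ", ")))
  out <- character(n)
  for (i in seq_len(n)) {
    if (order[i] == "LARD") { out[i] <- "RXX-LARD"; next }
    if (order[i] == "TRIM") { out[i] <- "RXX-TRIM"; next }
    if (!completeness[i] %in% c("comp", "incomp")) {
      stop(sprintf("unknown completeness value: %s", completeness[i]))
    }
    base <- if (order[i] == "Helitron") {
      "HX"
    } else {
      cls <- switch(te_class[i], I = "R", II = "D", unknown = "X")
      sf <- WICKER_SUPERFAMILY_LETTER[superfamily[i]]
      if (is.na(sf)) sf <- "X"
      paste0(cls, WICKER_ORDER_LETTER[[order[i]]], sf)
    }
    out[i] <- paste0(base, "-", completeness[i])
  }
  out
}

#' Filter thresholds for TE annotations
#'
#' Threshold semantics are "at least": records are kept when both
#' `length_bp >= min_length_bp` and
#' `identity_to_consensus >= min_identity_pct`.
#'
#' @param min_length_bp Minimum TE length in bp (default 80).
#' @param min_identity_pct Minimum identity to consensus in percent
#'   (default 80).
#' @return A list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_length_bp = 80, min_identity_pct = 80.0) {
  if (min_length_bp < 0 || min_identity_pct < 0) {
    stop("thresholds must be non-negative")
  }
  structure(list(min_length_bp = min_length_bp,
                 min_identity_pct = min_identity_pct),
            class = "filter_thresholds")
}

#' Apply the length/identity filter to a TE annotation set
#'
#' Keeps annotations at least `min_length_bp` long with at least
#' `min_identity_pct` identity to their consensus; order-preserving.
#' Dropped records are partitioned by reason (too short, low identity, or
#' both).
#'
#' @param annotations TE annotation data.frame with `length_bp` and
#'   `identity_to_consensus` columns (`length_bp` is derived from
#'   `start`/`end` when absent).
#' @param thresholds A [filter_thresholds()].
#' @return A list with `kept`, `dropped` (both data.frames) and `summary`
#'   (named counts: short, low_identity, both).
#' @export
filter_80_80 <- function(annotations, thresholds = filter_thresholds()) {
  if (!"length_bp" %in% names(annotations)) {
    annotations$length_bp <- annotations$end - annotations$start + 1
  }
  short <- annotations$length_bp < thresholds$min_length_bp
  lowid <- annotations$identity_to_consensus < thresholds$min_identity_pct
  keep <- !short & !lowid
  kept <- annotations[keep, , drop = FALSE]
  dropped <- annotations[!keep, , drop = FALSE]
  summary <- c(short = sum(short & !lowid),
               low_identity = sum(lowid & !short),
               both = sum(short & lowid))
  list(kept = kept, dropped = dropped, summary = summary)
}

#' Summarise a TE annotation set by Wicker code
#'
#' One row per Wicker code with copy number and percentage of the total TE
#' count, plus footer quantities: total TE length in bp (overlapping spans
#' merged per chromosome before summing, so each base is counted once) and
#' the percentage of the genome covered.
#'
#' @param annotations TE annotation data.frame; a `wicker_code` column is
#'   used if present, otherwise codes are derived with
#'   [assign_wicker_code()].
#' @param genome_length_bp Total genome length in bp.
#' @return A list with `table` (code, n, pct_of_te), `n_te`,
#'   `total_te_bp` and `pct_genome`.
#' @export
summarize_by_code <- function(annotations, genome_length_bp) {
  stopifnot(genome_length_bp > 0)
  n_te <- nrow(annotations)
  code <- if ("wicker_code" %in% names(annotations)) {
    annotations$wicker_code
  } else if (n_te > 0) {
    assign_wicker_code(annotations$te_class, annotations$order,
                       annotations$superfamily, annotations$completeness)
  } else {
    character(0)
  }
  tab <- as.data.frame(table(code = code), stringsAsFactors = FALSE)
  names(tab) <- c("code", "n")
  tab$pct_of_te <- if (n_te > 0) 100 * tab$n / n_te else numeric(0)
  tab <- tab[order(tab$code), , drop = FALSE]
  rownames(tab) <- NULL
  total_bp <- 0
  if (n_te > 0) {
    gr <- GenomicRanges::GRanges(annotations$chrom,
                                 IRanges::IRanges(annotations$start,
                                                  annotations$end))
    total_bp <- sum(GenomicRanges::width(GenomicRanges::reduce(
      gr, ignore.strand = TRUE)))
  }
  list(table = tab, n_te = n_te, total_te_bp = total_bp,
       pct_genome = 100 * total_bp / genome_length_bp)
}

#' Read / write TE annotations as GFF3
#'
#' The `wicker_code` and `identity` attributes round-trip through the GFF3
#' attribute column; coordinates are 1-based inclusive as the format
#' requires.
#'
#' @param path GFF3 file path.
#' @return For `read_te_gff3`, a TE annotation data.frame.
#' @export
read_te_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  mc <- S4Vectors::mcols(gr)
  if ("ID" %in% names(mc)) df$te_id <- as.character(mc$ID)
  if ("wicker_code" %in% names(mc)) {
    df$wicker_code <- as.character(mc$wicker_code)
  }
  if ("identity" %in% names(mc)) {
    df$identity_to_consensus <- as.numeric(mc$identity)
  }
  df$length_bp <- df$end - df$start + 1
  df
}

#' @rdname read_te_gff3
#' @param annotations TE annotation data.frame.
#' @export
write_te_gff3 <- function(annotations, path) {
  id <- if ("te_id" %in% names(annotations)) annotations$te_id else
    sprintf("TEA%05d", seq_len(nrow(annotations)))
  gr <- GenomicRanges::GRanges(
    annotations$chrom,
    IRanges::IRanges(annotations$start, annotations$end),
    strand = if ("strand" %in% names(annotations)) annotations$strand
             else "*")
  S4Vectors::mcols(gr)$type <- rep("transposable_element",
                                   nrow(annotations))
  S4Vectors::mcols(gr)$ID <- id
  if (!"wicker_code" %in% names(annotations) &&
      all(c("te_class", "order") %in% names(annotations))) {
    annotations$wicker_code <- assign_wicker_code(
      annotations$te_class, annotations$order, annotations$superfamily,
      annotations$completeness)
  }
  if ("wicker_code" %in% names(annotations)) {
    S4Vectors::mcols(gr)$wicker_code <- annotations$wicker_code
  }
  if ("identity_to_consensus" %in% names(annotations)) {
    S4Vectors::mcols(gr)$identity <- annotations$identity_to_consensus
  }
  export_gff3_safe(gr, path)
  invisible(path)
}
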