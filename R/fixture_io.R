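# Plain-text fixture I/O. Genomes and reads travel as FASTA, features as
# GFF3 (1-based inclusive, as the format requires), and the full-fidelity
# truth tables as TSV with doubles serialised at 17 significant digits so a
# write/read cycle is lossless.

fmt_exact <- function(x) {
  if (is.numeric(x)) {
    out <- vapply(x, function(v) {
      if (is.na(v)) NA_character_ else sprintf("%.17g", v)
    }, character(1))
    out
  } else if (is.logical(x)) {
    ifelse(is.na(x), NA_character_, ifelse(x, "TRUE", "FALSE"))
  } else {
    as.character(x)
  }
}

write_tsv_exact <- function(df, path) {
  out <- as.data.frame(lapply(df, fmt_exact), stringsAsFactors = FALSE,
                       optional = TRUE)
  names(out) <- names(df)
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop(sprintf("failed writing '%s': %s", path,
                                conditionMessage(ok)))
  invisible(path)
}

read_tsv_typed <- function(path, schema) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = "NA")
  for (nm in names(schema)) {
    df[[nm]] <- switch(schema[[nm]],
                       integer = as.integer(df[[nm]]),
                       numeric = as.numeric(df[[nm]]),
                       logical = as.logical(df[[nm]]),
                       df[[nm]])
  }
  df
}

te_truth_schema <- c(element_id = "character", chrom = "character",
                     start = "integer", end = "integer",
                     ltr5_start = "integer", ltr5_end = "integer",
                     ltr3_start = "integer", ltr3_end = "integer",
                     true_age_my = "numeric", lineage = "character",
                     superfamily = "character", tsd_seq = "character",
                     tsd_mismatches_planted = "integer",
                     is_full_length = "logical")

gene_truth_schema <- c(gene_id = "character", chrom = "character",
                       start = "integer", end = "integer",
                       strand = "character", cds_start = "integer")

read_truth_schema <- c(read_id = "character", origin_feature = "character",
                       chrom = "character", start = "integer",
                       end = "integer", strand = "character",
                       length_nt = "integer")

# rtracklayer refuses to export a zero-length GRanges carrying metadata
# columns; fall back to writing the bare GFF3 header ourselves.
export_gff3_safe <- function(gr, path) {
  if (length(gr) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

features_to_granges <- function(df, id_col, type, extra_cols = character(0),
                                seqlens = NULL) {
  strand <- if ("strand" %in% names(df)) df$strand else
    rep("*", nrow(df))
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = strand)
  S4Vectors::mcols(gr)$type <- rep(type, nrow(df))
  S4Vectors::mcols(gr)$ID <- df[[id_col]]
  for (cc in extra_cols) S4Vectors::mcols(gr)[[cc]] <- df[[cc]]
  if (!is.null(seqlens)) {
    GenomeInfoDb_ok <- requireNamespace("GenomeInfoDb", quietly = TRUE)
    if (GenomeInfoDb_ok) {
      lv <- union(names(seqlens), as.character(unique(df$chrom)))
      GenomeInfoDb::seqlevels(gr) <- lv
      GenomeInfoDb::seqlengths(gr) <- seqlens[lv]
    }
  }
  gr
}

#' Write a simulation fixture to plain-text files
#'
#' Writes the genome (FASTA), TE and gene truth (GFF3 with Sequence
#' Ontology types `LTR_retrotransposon` and `gene`, plus lossless TSV
#' tables), and optionally the simulated reads (FASTA) and read truth
#' (TSV). Re-reading with [read_fixture()] reproduces the inputs exactly.
#'
#' @param genome Named [Biostrings::DNAStringSet] or character vector.
#' @param te_truth,gene_truth Truth tables from [simulate_genome()].
#' @param reads Optional reads ([Biostrings::DNAStringSet]).
#' @param read_truth Optional read truth table.
#' @param out_dir Output directory (created if missing).
#' @return Named character vector of the files written (the manifest).
#' @export
write_fixture <- function(genome, te_truth, gene_truth, reads = NULL,
                          read_truth = NULL, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create output directory '%s'", out_dir))
  }
  genome <- as_dna_string_set(genome)
  manifest <- c()
  p <- file.path(out_dir, "genome.fa")
  Biostrings::writeXStringSet(genome, p)
  manifest["genome"] <- p

  seqlens <- stats::setNames(Biostrings::width(genome), names(genome))
  p <- file.path(out_dir, "te_truth.gff3")
  export_gff3_safe(
    features_to_granges(te_truth, "element_id", "LTR_retrotransposon",
                        c("lineage", "superfamily", "is_full_length"),
                        seqlens), p)
  manifest["te_gff3"] <- p
  p <- file.path(out_dir, "gene_truth.gff3")
  export_gff3_safe(
    features_to_granges(gene_truth, "gene_id", "gene", "cds_start",
                        seqlens), p)
  manifest["gene_gff3"] <- p

  p <- file.path(out_dir, "te_truth.tsv")
  write_tsv_exact(te_truth, p)
  manifest["te_truth"] <- p
  p <- file.path(out_dir, "gene_truth.tsv")
  write_tsv_exact(gene_truth, p)
  manifest["gene_truth"] <- p

  if (!is.null(reads)) {
    p <- file.path(out_dir, "reads.fa")
    Biostrings::writeXStringSet(as_dna_string_set(reads), p)
    manifest["reads"] <- p
  }
  if (!is.null(read_truth)) {
    p <- file.path(out_dir, "read_truth.tsv")
    write_tsv_exact(read_truth, p)
    manifest["read_truth"] <- p
  }
  manifest
}

#' Read a fixture written by [write_fixture()]
#'
#' @param dir Directory containing the fixture files.
#' @return A list with `genome`, `te_truth`, `gene_truth` and, when present,
#'   `reads` and `read_truth`.
#' @export
read_fixture <- function(dir) {
  need <- file.path(dir, c("genome.fa", "te_truth.tsv", "gene_truth.tsv"))
  missing <- need[!file.exists(need)]
  if (length(missing)) {
    stop(sprintf("fixture incomplete, missing: %s",
                 paste(missing, collapse = ", ")))
  }
  out <- list(
    genome = Biostrings::readDNAStringSet(file.path(dir, "genome.fa")),
    te_truth = read_tsv_typed(file.path(dir, "te_truth.tsv"),
                              te_truth_schema),
    gene_truth = read_tsv_typed(file.path(dir, "gene_truth.tsv"),
                                gene_truth_schema))
  rp <- file.path(dir, "reads.fa")
  if (file.exists(rp)) out$reads <- Biostrings::readDNAStringSet(rp)
  tp <- file.path(dir, "read_truth.tsv")
  if (file.exists(tp)) out$read_truth <- read_tsv_typed(tp,
                                                        read_truth_schema)
  out
}
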