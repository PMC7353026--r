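# Seeded synthetic genomes with planted LTR retrotransposons, degenerate TE
# fragments, genes and small RNA reads, all with full ground truth. The
# generator exists so that every downstream stage (structural detection,
# dating, read attribution, interval analysis) can be exercised against a
# known answer.

#' Default lineage table
#'
#' Nine LTR-retrotransposon lineages spanning the two major superfamilies,
#' each with a short synthetic diagnostic signature sequence. The signatures
#' are fixed arbitrary DNA strings generated from an internal deterministic
#' stream; they stand in for real lineage-diagnostic domains (which are not
#' shipped with this package) and are labelled synthetic for that reason.
#'
#' @param signature_length Length in bp of each synthetic signature.
#' @return A data.frame with columns `lineage`, `superfamily`, `signature`.
#' @export
default_lineage_table <- function(signature_length = 60) {
  lineages <- c("Del/Tekay", "Athila", "Tat", "Reina", "CRM",
                "Retrofit/Ale", "TAR/Tork", "Maximus/Sire", "Ivana/Oryco")
  superfams <- c(rep("Ty3/gypsy", 5), rep("Ty1/copia", 4))
  # Minimal LCG so signatures are stable regardless of the user's RNG state.
  state <- 20200613
  next_base <- function() {
    state <<- (1103515245 * (state %% 65536) + 12345) %% 2147483647
    BASES[(state %/% 7) %% 4 + 1]
  }
  sigs <- vapply(seq_along(lineages), function(i) {
    paste(vapply(seq_len(signature_length), function(j) next_base(),
                 character(1)), collapse = "")
  }, character(1))
  data.frame(lineage = lineages, superfamily = superfams, signature = sigs,
             stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Collects and validates every knob of the synthetic-genome generator.
#' Defaults describe a small but realistic slice of a TE-rich plant genome:
#' elements aged uniformly within the window over which the bulk of
#' full-length elements accumulated (0-10 My), an LTR-pair mutation process
#' run at the non-coding substitution rate 3.89e-9 subs/site/year, 4-6 bp
#' target-site duplications with a mismatch mix matching the observed tally
#' of intact/1-mismatch/2-mismatch TSDs, and a small RNA size profile peaked
#' at 23-24 nt.
#'
#' @param seed Integer seed; all stages derive their streams from it.
#' @param genome_length Total genome length in bp (single chromosome).
#' @param n_elements Number of planted full-length LTR retrotransposons.
#' @param ltr_length_range Integer pair, LTR length in bp.
#' @param internal_length_range Integer pair, internal-region length in bp.
#' @param tsd_length_range Integer pair within \[4, 6\], TSD length in bp.
#' @param age_range_my Non-negative real pair, insertion age in million years.
#' @param substitution_rate Substitutions/site/year used to mutate LTR copies.
#' @param lineage_table Data frame of lineage, superfamily, signature.
#' @param n_fragments Number of degenerate/truncated TE copies.
#' @param n_genes Number of non-TE gene loci.
#' @param gene_length_range Integer pair, gene length in bp.
#' @param sirna_profile Named numeric vector mapping read length (20-25 nt)
#'   to its fraction; must sum to 1.
#' @param n_reads Number of small RNA reads to simulate.
#' @param frac_te_reads Fraction of reads drawn from within TE spans.
#' @param background_gc GC content of background (and gene) sequence.
#' @param tsd_mismatch_probs Probabilities for planting 0, 1 or 2 mismatches
#'   in one TSD copy (normalised internally).
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              genome_length = 1e6,
                              n_elements = 20,
                              ltr_length_range = c(200, 1500),
                              internal_length_range = c(1000, 4000),
                              tsd_length_range = c(4, 6),
                              age_range_my = c(0, 10),
                              substitution_rate = 3.89e-9,
                              lineage_table = default_lineage_table(),
                              n_fragments = 10,
                              n_genes = 20,
                              gene_length_range = c(1000, 3000),
                              sirna_profile = c("20" = 0.02, "21" = 0.10,
                                                "22" = 0.15, "23" = 0.36,
                                                "24" = 0.35, "25" = 0.02),
                              n_reads = 10000,
                              frac_te_reads = 0.7,
                              background_gc = 0.35,
                              tsd_mismatch_probs = c(0.794, 0.190, 0.015)) {
  cfg <- list(seed = as.integer(seed), genome_length = genome_length,
              n_elements = n_elements, ltr_length_range = ltr_length_range,
              internal_length_range = internal_length_range,
              tsd_length_range = tsd_length_range,
              age_range_my = age_range_my,
              substitution_rate = substitution_rate,
              lineage_table = lineage_table, n_fragments = n_fragments,
              n_genes = n_genes, gene_length_range = gene_length_range,
              sirna_profile = sirna_profile, n_reads = n_reads,
              frac_te_reads = frac_te_reads, background_gc = background_gc,
              tsd_mismatch_probs = tsd_mismatch_probs)
  validate_simulation_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_simulation_config <- function(cfg) {
  stopifnot(length(cfg$seed) == 1, !is.na(cfg$seed))
  if (cfg$genome_length <= 0) stop("genome_length must be positive")
  for (nm in c("n_elements", "n_fragments", "n_genes", "n_reads")) {
    if (cfg[[nm]] < 0) stop(sprintf("'%s' must be non-negative", nm))
  }
  check_range_pair(cfg$ltr_length_range, "ltr_length_range")
  check_range_pair(cfg$internal_length_range, "internal_length_range")
  check_range_pair(cfg$tsd_length_range, "tsd_length_range")
  if (cfg$tsd_length_range[1] < 4 || cfg$tsd_length_range[2] > 6) {
    stop("tsd_length_range must lie within [4, 6]")
  }
  check_range_pair(cfg$age_range_my, "age_range_my", integerish = FALSE)
  if (any(cfg$age_range_my < 0)) stop("age_range_my must be non-negative")
  check_range_pair(cfg$gene_length_range, "gene_length_range")
  if (cfg$substitution_rate <= 0) stop("substitution_rate must be positive")
  if (cfg$frac_te_reads < 0 || cfg$frac_te_reads > 1) {
    stop("frac_te_reads must be a fraction in [0, 1]")
  }
  if (cfg$background_gc < 0 || cfg$background_gc > 1) {
    stop("background_gc must be a fraction in [0, 1]")
  }
  prof <- cfg$sirna_profile
  if (is.null(names(prof)) || any(is.na(as.integer(names(prof))))) {
    stop("sirna_profile must be named by read length")
  }
  lens <- as.integer(names(prof))
  if (any(lens < 20 | lens > 25)) stop("sirna_profile keys must be in [20, 25]")
  if (abs(sum(prof) - 1) > 1e-9) stop("sirna_profile fractions must sum to 1")
  lt <- cfg$lineage_table
  if (!is.data.frame(lt) ||
      !all(c("lineage", "superfamily", "signature") %in% names(lt))) {
    stop("lineage_table needs columns lineage, superfamily, signature")
  }
  if (length(cfg$tsd_mismatch_probs) != 3 || any(cfg$tsd_mismatch_probs < 0)) {
    stop("tsd_mismatch_probs must be 3 non-negative weights (0/1/2 mismatches)")
  }
  invisible(cfg)
}

# Build one ancestral element and its two independently mutated LTR copies.
# LTR termini (TG..CA) are conserved during mutation: terminal dinucleotides
# are under strong selective constraint in transposition-competent elements,
# and conserving them keeps the planted truth consistent with the
# structural definition of a full-length element.
# sample a single integer uniformly from [lo, hi]; safe when lo == hi
# (sample(x, 1) on a scalar would draw from 1:x instead)
r_int <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L

build_element <- function(cfg, id) {
  ltr_len <- r_int(cfg$ltr_length_range[1], cfg$ltr_length_range[2])
  int_len <- r_int(cfg$internal_length_range[1], cfg$internal_length_range[2])
  tsd_len <- r_int(cfg$tsd_length_range[1], cfg$tsd_length_range[2])
  age_my <- stats::runif(1, cfg$age_range_my[1], cfg$age_range_my[2])
  lineage_i <- sample(nrow(cfg$lineage_table), 1)
  lineage <- cfg$lineage_table$lineage[lineage_i]
  superfam <- cfg$lineage_table$superfamily[lineage_i]
  sig <- strsplit(cfg$lineage_table$signature[lineage_i], "")[[1]]

  anc_ltr <- random_dna(ltr_len, cfg$background_gc)
  anc_ltr[1:2] <- c("T", "G")
  anc_ltr[(ltr_len - 1):ltr_len] <- c("C", "A")

  internal <- random_dna(int_len, cfg$background_gc)
  if (int_len >= length(sig)) {
    at <- r_int(1L, int_len - length(sig) + 1L)
    internal[at:(at + length(sig) - 1)] <- sig
  }

  p1 <- jc_transition_prob(cfg$substitution_rate, age_my * 1e6)
  protect <- c(1L, 2L, ltr_len - 1L, ltr_len)
  ltr5 <- mutate_jc(anc_ltr, p1, protect)
  ltr3 <- mutate_jc(anc_ltr, p1, protect)
  internal <- mutate_jc(internal, p1)

  tsd <- random_dna(tsd_len, cfg$background_gc)
  n_mm <- sample(0:2, 1, prob = cfg$tsd_mismatch_probs)
  n_mm <- min(n_mm, tsd_len)
  tsd_right <- tsd
  if (n_mm > 0) {
    at <- sample(tsd_len, n_mm)
    for (i in at) tsd_right[i] <- sample(setdiff(BASES, tsd_right[i]), 1)
  }

  block <- c(tsd, ltr5, internal, ltr3, tsd_right)
  list(id = id, block = block, tsd_len = tsd_len, ltr_len = ltr_len,
       int_len = int_len, age_my = age_my, lineage = lineage,
       superfamily = superfam, tsd_seq = paste(tsd, collapse = ""),
       tsd_mismatches = n_mm, kind = "element")
}

# A fragment is a truncated degenerate copy: a single LTR plus part of the
# internal region, so it carries TE sequence but no LTR pair.
build_fragment <- function(cfg, id) {
  el <- build_element(cfg, id)
  keep_int <- r_int(floor(el$int_len * 0.3), floor(el$int_len * 0.7))
  from <- el$tsd_len + 1
  to <- el$tsd_len + el$ltr_len + keep_int
  list(id = id, block = el$block[from:to], age_my = el$age_my,
       lineage = el$lineage, superfamily = el$superfamily, kind = "fragment")
}

build_gene <- function(cfg, id) {
  len <- r_int(cfg$gene_length_range[1], cfg$gene_length_range[2])
  strand <- sample(c("+", "-"), 1)
  cds_off <- r_int(1L, max(1L, floor(len * 0.2)))
  list(id = id, block = random_dna(len, cfg$background_gc), strand = strand,
       cds_off = cds_off, kind = "gene")
}

#' Simulate a genome with planted TEs and genes
#'
#' Assembles a single-chromosome genome of background sequence hosting
#' non-overlapping full-length LTR retrotransposons
#' (TSD--5'LTR--internal--3'LTR--TSD, with the lineage signature embedded in
#' the internal region), truncated TE fragments, and genes. Each LTR copy is
#' mutated independently under Jukes-Cantor in proportion to the element's
#' age and the configured substitution rate, so the expected corrected
#' divergence of the pair is `2 * rate * age`.
#'
#' @param config A [simulation_config()].
#' @return A list with `genome` (a named [Biostrings::DNAStringSet]),
#'   `te_truth` and `gene_truth` data frames (1-based inclusive
#'   coordinates), and the `config` used.
#' @export
simulate_genome <- function(config) {
  validate_simulation_config(config)
  with_local_seed(stage_seed(config$seed, 1L), {
    feats <- list()
    if (config$n_elements > 0) {
      feats <- c(feats, lapply(seq_len(config$n_elements), function(i) {
        build_element(config, sprintf("TE%04d", i))
      }))
    }
    if (config$n_fragments > 0) {
      feats <- c(feats, lapply(seq_len(config$n_fragments), function(i) {
        build_fragment(config, sprintf("FRAG%04d", i))
      }))
    }
    if (config$n_genes > 0) {
      feats <- c(feats, lapply(seq_len(config$n_genes), function(i) {
        build_gene(config, sprintf("GENE%04d", i))
      }))
    }
    lens <- vapply(feats, function(f) length(f$block), integer(1))
    slack <- config$genome_length - sum(lens)
    if (slack < 0) {
      stop(sprintf(paste0("cannot place features: %d bp of features exceed ",
                          "genome_length %d"), sum(lens), config$genome_length))
    }
    n_feat <- length(feats)
    ord <- if (n_feat > 0) sample(n_feat) else integer(0)
    gaps <- if (n_feat >= 0) {
      as.vector(stats::rmultinom(1, slack, rep(1, n_feat + 1)))
    }
    segments <- character(2 * n_feat + 1)
    segments[1] <- paste(random_dna(gaps[1], config$background_gc),
                         collapse = "")
    pos <- gaps[1]
    te_rows <- list()
    gene_rows <- list()
    chrom <- "chr1"
    for (k in seq_len(n_feat)) {
      f <- feats[[ord[k]]]
      blk_start <- pos + 1
      blk_len <- length(f$block)
      segments[2 * k] <- paste(f$block, collapse = "")
      if (f$kind == "element") {
        s <- blk_start + f$tsd_len            # 5'LTR start
        e <- blk_start + blk_len - f$tsd_len - 1  # 3'LTR end
        te_rows[[length(te_rows) + 1]] <- data.frame(
          element_id = f$id, chrom = chrom, start = s, end = e,
          ltr5_start = s, ltr5_end = s + f$ltr_len - 1,
          ltr3_start = e - f$ltr_len + 1, ltr3_end = e,
          true_age_my = f$age_my, lineage = f$lineage,
          superfamily = f$superfamily, tsd_seq = f$tsd_seq,
          tsd_mismatches_planted = f$tsd_mismatches, is_full_length = TRUE,
          stringsAsFactors = FALSE)
      } else if (f$kind == "fragment") {
        te_rows[[length(te_rows) + 1]] <- data.frame(
          element_id = f$id, chrom = chrom, start = blk_start,
          end = blk_start + blk_len - 1,
          ltr5_start = NA_integer_, ltr5_end = NA_integer_,
          ltr3_start = NA_integer_, ltr3_end = NA_integer_,
          true_age_my = f$age_my, lineage = f$lineage,
          superfamily = f$superfamily, tsd_seq = NA_character_,
          tsd_mismatches_planted = NA_integer_, is_full_length = FALSE,
          stringsAsFactors = FALSE)
      } else {
        s <- blk_start
        e <- blk_start + blk_len - 1
        cds <- if (f$strand == "+") s + f$cds_off - 1 else e - f$cds_off + 1
        gene_rows[[length(gene_rows) + 1]] <- data.frame(
          gene_id = f$id, chrom = chrom, start = s, end = e,
          strand = f$strand, cds_start = cds, stringsAsFactors = FALSE)
      }
      pos <- pos + blk_len
      segments[2 * k + 1] <- paste(random_dna(gaps[k + 1],
                                              config$background_gc),
                                   collapse = "")
      pos <- pos + gaps[k + 1]
    }
    genome <- Biostrings::DNAStringSet(
      stats::setNames(paste(segments, collapse = ""), chrom))
    te_truth <- if (length(te_rows)) do.call(rbind, te_rows) else
      empty_te_truth()
    gene_truth <- if (length(gene_rows)) do.call(rbind, gene_rows) else
      empty_gene_truth()
    te_truth <- te_truth[order(te_truth$start), , drop = FALSE]
    gene_truth <- gene_truth[order(gene_truth$start), , drop = FALSE]
    rownames(te_truth) <- NULL
    rownames(gene_truth) <- NULL
    list(genome = genome, te_truth = te_truth, gene_truth = gene_truth,
         config = config)
  })
}

empty_te_truth <- function() {
  data.frame(element_id = character(0), chrom = character(0),
             start = integer(0), end = integer(0), ltr5_start = integer(0),
             ltr5_end = integer(0), ltr3_start = integer(0),
             ltr3_end = integer(0), true_age_my = numeric(0),
             lineage = character(0), superfamily = character(0),
             tsd_seq = character(0), tsd_mismatches_planted = integer(0),
             is_full_length = logical(0), stringsAsFactors = FALSE)
}

empty_gene_truth <- function() {
  data.frame(gene_id = character(0), chrom = character(0), start = integer(0),
             end = integer(0), strand = character(0), cds_start = integer(0),
             stringsAsFactors = FALSE)
}

#' Simulate small RNA reads with per-read truth
#'
#' Draws read lengths from the configured size profile and read origins from
#' planted TE spans (a fraction `frac_te_reads`) or from genes/background
#' (remaining reads, uniformly over non-TE base pairs). Strands are chosen
#' uniformly; minus-strand reads carry the reverse complement of the genomic
#' substring.
#'
#' @param genome Genome as returned by [simulate_genome()].
#' @param te_truth,gene_truth Truth tables from [simulate_genome()].
#' @param config The same [simulation_config()].
#' @return A list with `reads` (named [Biostrings::DNAStringSet]) and
#'   `truth` (data frame: read_id, origin_feature, chrom, start, end,
#'   strand, length_nt).
#' @export
simulate_small_rna_reads <- function(genome, te_truth, gene_truth, config) {
  validate_simulation_config(config)
  gchars <- as_genome_chars(genome)
  if (length(gchars) == 0 || sum(nchar(gchars)) == 0) {
    stop("genome must be non-empty")
  }
  n <- config$n_reads
  if (n == 0) {
    return(list(reads = Biostrings::DNAStringSet(),
                truth = empty_read_truth()))
  }
  with_local_seed(stage_seed(config$seed, 2L), {
    prof <- config$sirna_profile
    lens <- as.integer(sample(names(prof), n, replace = TRUE, prob = prof))
    max_len <- max(lens)

    te_iv <- te_truth[, c("chrom", "start", "end"), drop = FALSE]
    # Non-TE space: genes plus background gaps (complement of all features).
    occupied <- rbind(te_iv,
                      gene_truth[, c("chrom", "start", "end"), drop = FALSE])
    bg_iv <- complement_intervals(occupied, gchars)
    gene_iv <- gene_truth[, c("chrom", "start", "end"), drop = FALSE]
    nonte_iv <- rbind(gene_iv, bg_iv)
    nonte_feature <- c(gene_truth$gene_id,
                       rep("background", nrow(bg_iv)))

    from_te <- stats::runif(n) < config$frac_te_reads
    reads <- character(n)
    truth <- vector("list", n)
    pick_locus <- function(iv, feats, len) {
      w <- iv$end - iv$start + 1 - len + 1
      ok <- which(w > 0)
      if (length(ok) == 0) {
        stop(sprintf("requested read length %d exceeds every eligible feature",
                     len))
      }
      i <- ok[sample.int(length(ok), 1, prob = w[ok])]
      s <- iv$start[i] + sample.int(w[i], 1) - 1
      list(chrom = iv$chrom[i], start = s, end = s + len - 1,
           feature = feats[i])
    }
    for (i in seq_len(n)) {
      if (from_te[i] && nrow(te_iv) > 0) {
        loc <- pick_locus(te_iv, te_truth$element_id, lens[i])
      } else {
        loc <- pick_locus(nonte_iv, nonte_feature, lens[i])
      }
      strand <- sample(c("+", "-"), 1)
      s <- substr(gchars[[loc$chrom]], loc$start, loc$end)
      if (strand == "-") s <- revcomp_chr(s)
      reads[i] <- s
      truth[[i]] <- data.frame(
        read_id = sprintf("read%06d", i), origin_feature = loc$feature,
        chrom = loc$chrom, start = loc$start, end = loc$end, strand = strand,
        length_nt = lens[i], stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, truth)
    list(reads = Biostrings::DNAStringSet(
           stats::setNames(reads, truth$read_id)),
         truth = truth)
  })
}

empty_read_truth <- function() {
  data.frame(read_id = character(0), origin_feature = character(0),
             chrom = character(0), start = integer(0), end = integer(0),
             strand = character(0), length_nt = integer(0),
             stringsAsFactors = FALSE)
}

# Complement of a set of 1-based inclusive intervals within the genome.
complement_intervals <- function(iv, gchars) {
  out <- list()
  for (chrom in names(gchars)) {
    len <- nchar(gchars[[chrom]])
    sub <- iv[iv$chrom == chrom, , drop = FALSE]
    if (nrow(sub) == 0) {
      out[[chrom]] <- data.frame(chrom = chrom, start = 1, end = len,
                                 stringsAsFactors = FALSE)
      next
    }
    ir <- IRanges::reduce(IRanges::IRanges(sub$start, sub$end))
    gaps <- IRanges::gaps(ir, start = 1, end = len)
    if (length(gaps) > 0) {
      out[[chrom]] <- data.frame(chrom = chrom, start = IRanges::start(gaps),
                                 end = IRanges::end(gaps),
                                 stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
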