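# Internal helpers shared across the pipeline.

.datatable.aware <- TRUE

BASES <- c("A", "C", "G", "T")

#' @importFrom methods is
as_genome_chars <- function(genome) {
  if (is(genome, "DNAStringSet")) {
    x <- as.character(genome)
  } else if (is(genome, "DNAString")) {
    x <- stats::setNames(as.character(genome), "seq1")
  } else if (is.character(genome)) {
    x <- genome
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
  } else {
    stop("genome must be a DNAStringSet or a named character vector")
  }
  toupper(x)
}

as_dna_string_set <- function(genome) {
  if (is(genome, "DNAStringSet")) return(genome)
  Biostrings::DNAStringSet(as_genome_chars(genome))
}

# Derived per-stage seed so each simulation stage draws from its own
# deterministic sub-stream; kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 48271 + stage) %% 2147483647)
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return(character(0))
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  sample(BASES, n, replace = TRUE, prob = p)
}

revcomp_chr <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

# Per-site Jukes-Cantor substitution probability after rT expected
# substitutions per site (r in subs/site/year, t in years).
jc_transition_prob <- function(r, t_years) {
  0.75 * (1 - exp(-(4 / 3) * r * t_years))
}

# Mutate a character vector of bases in place under Jukes-Cantor with
# per-site substitution probability p1; positions in `protect` are left
# untouched.
mutate_jc <- function(bases, p1, protect = integer(0)) {
  n <- length(bases)
  if (n == 0 || p1 <= 0) return(bases)
  hit <- which(stats::runif(n) < p1)
  hit <- setdiff(hit, protect)
  if (length(hit) == 0) return(bases)
  for (i in hit) {
    bases[i] <- sample(setdiff(BASES, bases[i]), 1)
  }
  bases
}

check_range_pair <- function(x, name, integerish = TRUE) {
  if (!is.numeric(x) || length(x) != 2 || any(is.na(x)) || x[1] > x[2]) {
    stop(sprintf("'%s' must be a numeric pair with lo <= hi", name))
  }
  if (integerish && any(x != round(x))) {
    stop(sprintf("'%s' must contain integers", name))
  }
  invisible(x)
}
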