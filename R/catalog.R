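# SSR catalogue: greedy perfect tandem repeat detection and genome summaries.

#' Smallest repeating unit of a string
#'
#' Reduces a repeated unit to its primitive motif: the shortest string `p`
#' such that `s` is an exact concatenation of copies of `p` (e.g. `"GAGA"`
#' reduces to `"GA"`, a homopolymer run reduces to a single base).
#'
#' @param s non-empty ACGT string.
#' @return the primitive motif of `s`.
#' @examples
#' primitive_motif("GAGA")  # "GA"
#' primitive_motif("AAA")   # "A"
#' primitive_motif("GAT")   # "GAT"
#' @export
primitive_motif <- function(s) {
  s <- .check_dna(s, allow_n = FALSE, what = "motif")
  n <- nchar(s)
  if (n == 0L) stop("motif must be non-empty")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  for (p in seq_len(n)) {
    if (n %% p != 0L) next
    if (all(chars == rep_len(chars[seq_len(p)], n)))
      return(substr(s, 1L, p))
  }
  s
}

#' Find perfect simple sequence repeats in a nucleotide string
#'
#' Greedy left-to-right scan for maximal perfect tandem arrays.  At each scan
#' position all motif sizes `1..max_motif` are considered and the candidate
#' with the largest array (full units only) wins; ties go to the smaller
#' motif size, so every reported motif is primitive and nested repeats are
#' counted as their smallest unit (`"GAGAGAGA"` is one locus of 4 x `GA`).
#' Scanning resumes after each recorded locus, so reported loci never
#' overlap.  `N` breaks any repeat; soft-masked (lowercase) bases are
#' uppercased before scanning.
#'
#' @param seq single ACGTN string (lowercase allowed).
#' @param min_repeats minimum repeat number (full motif copies); default 3.
#' @param max_motif largest motif size considered, default 100.
#' @return data.frame with columns `start` (0-based inclusive), `end`
#'   (0-based exclusive), `motif` (as it occurs at `start`), `motif_size`,
#'   `repeat_number`, `array_length`.
#' @examples
#' find_ssrs("GAGAGAGA")                      # one locus: 4 repeats of GA
#' find_ssrs("AAAGAGAAAGAG", min_repeats = 2) # one locus: 2 repeats of AAAGAG
#' @export
find_ssrs <- function(seq, min_repeats = 3L, max_motif = 100L) {
  if (!is.numeric(min_repeats) || length(min_repeats) != 1L || min_repeats < 2)
    stop("min_repeats must be a single integer >= 2")
  if (!is.numeric(max_motif) || length(max_motif) != 1L || max_motif < 1)
    stop("max_motif must be a single integer >= 1")
  seq <- .check_dna(seq, allow_n = TRUE)
  out <- .scan_ssrs_cpp(seq, as.integer(min_repeats), as.integer(max_motif))
  out$array_length <- out$end - out$start
  out
}

#' Catalogue SSR loci in a genome
#'
#' Runs [find_ssrs()] on every record of a FASTA file (or `DNAStringSet`)
#' independently and summarises abundance and composition.  Motif counts are
#' orientation-resolved: each motif is recorded as it occurs on the given
#' strand, so `GA` and `AG` are distinct motifs.
#'
#' @param sequences path to a FASTA file, or a [Biostrings::DNAStringSet].
#' @inheritParams find_ssrs
#' @return list with elements `loci` (data.frame: `seq_id` plus the
#'   [find_ssrs()] columns) and `summary`, a list with
#'   `counts_by_motif_size`, `counts_by_motif` (named integer vectors),
#'   `total_loci`, `bases_covered`, `genome_size` and `fraction_covered`.
#' @export
catalog_genome <- function(sequences, min_repeats = 3L, max_motif = 100L) {
  if (is.character(sequences))
    sequences <- Biostrings::readDNAStringSet(sequences)
  stopifnot(methods::is(sequences, "DNAStringSet"))
  seq_ids <- names(sequences)
  if (is.null(seq_ids)) seq_ids <- paste0("seq_", seq_along(sequences))
  seq_ids <- sub("\\s.*$", "", seq_ids)

  per_seq <- lapply(seq_along(sequences), function(i) {
    loci <- find_ssrs(as.character(sequences[[i]]), min_repeats, max_motif)
    if (nrow(loci)) cbind(seq_id = seq_ids[i], loci, stringsAsFactors = FALSE)
    else NULL
  })
  loci <- do.call(rbind, per_seq)
  if (is.null(loci))
    loci <- data.frame(seq_id = character(), start = integer(),
                       end = integer(), motif = character(),
                       motif_size = integer(), repeat_number = integer(),
                       array_length = integer(), stringsAsFactors = FALSE)
  rownames(loci) <- NULL
  genome_size <- sum(as.numeric(Biostrings::width(sequences)))
  summary <- list(
    counts_by_motif_size = if (nrow(loci)) table(loci$motif_size) else table(integer()),
    counts_by_motif      = if (nrow(loci)) table(loci$motif) else table(character()),
    total_loci           = nrow(loci),
    bases_covered        = sum(as.numeric(loci$array_length)),
    genome_size          = genome_size,
    fraction_covered     = if (genome_size > 0)
                             sum(as.numeric(loci$array_length)) / genome_size
                           else 0
  )
  list(loci = loci, summary = summary)
}

#' Test homopolymer composition against the genomic base composition
#'
#' Compares the observed split of A/T versus G/C homopolymer loci to the
#' split expected if homopolymer identity simply followed the genomic base
#' composition.  Two-sided; an exact binomial test is used for small totals
#' (`method = "auto"`, total <= 10000) and a 1-df chi-square goodness-of-fit
#' test for genome-scale counts, where the p-value underflows to 0 for any
#' strong departure.
#'
#' @param observed_a_t,observed_g_c homopolymer locus counts.
#' @param base_comp_a_t genomic A+T fraction, in (0,1).
#' @param method `"auto"`, `"binomial"` or `"chisq"`.
#' @return list with `expected` (named length-2 vector), `statistic`
#'   (chi-square, `NA` for the exact test), `p`, and `method`.
#' @export
composition_expectation_test <- function(observed_a_t, observed_g_c,
                                         base_comp_a_t,
                                         method = c("auto", "binomial", "chisq")) {
  method <- match.arg(method)
  stopifnot(observed_a_t >= 0, observed_g_c >= 0,
            base_comp_a_t > 0, base_comp_a_t < 1)
  total <- observed_a_t + observed_g_c
  if (total == 0) stop("zero total count: composition test undefined")
  expected <- c(a_t = total * base_comp_a_t, g_c = total * (1 - base_comp_a_t))
  if (method == "auto")
    method <- if (total <= 10000) "binomial" else "chisq"
  if (method == "binomial") {
    p <- binom.test(observed_a_t, total, p = base_comp_a_t,
                    alternative = "two.sided")$p.value
    stat <- NA_real_
  } else {
    obs <- c(observed_a_t, observed_g_c)
    stat <- sum((obs - expected)^2 / expected)
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
  }
  list(expected = expected, statistic = stat, p = p, method = method)
}

#' Write a locus catalogue as BED-style TSV
#' @param loci data.frame from [catalog_genome()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(loci, path) {
  write.table(loci, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a locus catalogue written by [write_catalog()]
#' @param path TSV file.
#' @return data.frame of loci.
#' @export
read_catalog <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
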