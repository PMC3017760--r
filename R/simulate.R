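# Synthetic diploid genomes with planted SSR loci, shotgun reads and truth
# alignments.  The generator emulates the sequencing design of a single-
# genotype whole-genome shotgun project: one heterozygous diploid individual,
# ~8.7x coverage, long (mean 774 nt) reads, with per-locus unit slippage that
# rises with repeat number, motif-class rate multipliers, occasional
# multistep (>= 2 unit) changes and end-biased point interruptions (NRUPs).

#' Default planted-locus specification
#'
#' A mixture of homopolymer, dimer and trimer loci spanning the repeat
#' numbers where slippage rates change fastest (about 5-12 repeats), with
#' homopolymers the most numerous class as in real genomes.
#'
#' @return data.frame with columns `motif`, `repeat_number`, `count`.
#' @export
default_planted_loci <- function() {
  data.frame(
    motif = c("A", "A", "T", "C", "C", "G",
              "AC", "AC", "AG", "AT", "GC", "AAC", "AGG"),
    repeat_number = c(7L, 10L, 8L, 7L, 10L, 8L,
                      8L, 12L, 10L, 10L, 8L, 5L, 6L),
    count = c(300L, 300L, 200L, 250L, 250L, 150L,
              200L, 150L, 150L, 150L, 100L, 150L, 100L),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' @param seed integer seed; every stage derives its RNG stream from it, so
#'   a configuration is fully deterministic.
#' @param genome_length total reference length in nt (split over scaffolds).
#' @param n_scaffolds number of scaffolds.
#' @param base_comp_a_t genomic A+T fraction (default 0.59).
#' @param planted data.frame (`motif`, `repeat_number`, `count`) of loci to
#'   plant; see [default_planted_loci()].
#' @param het_model list: `intercept`, `slope` of a logistic increase of the
#'   per-locus unit-variant probability with repeat number, `class_mult`
#'   named multipliers per motif class (defaults order AC > AG > AT > CG and
#'   G/C homopolymers above A/T), `max_p` cap.
#' @param multistep_model list: `intercept`, `slope` (repeat number),
#'   `motif_size_coef` for the logistic probability that a variant is
#'   multistep, and `step_geom_p` for the extra-unit geometric step size
#'   (steps are `2 + rgeom`).
#' @param nrup_rate per-locus probability of planting a point interruption
#'   (on loci without a length variant).
#' @param nrup_end_bias probability that a planted NRUP falls in the first
#'   or last repeat unit.
#' @param coverage haploid-genome read coverage (default 8.7).
#' @param read_length_mean,read_length_sd,min_read_length read-length model
#'   (normal, truncated below), defaults 774 +/- 80, minimum 100.
#' @param error_rate per-base substitution sequencing error rate.
#' @param min_repeats,max_motif catalogue parameters the reference is made
#'   consistent with (background is kept free of qualifying repeats so the
#'   catalogue equals the planted truth exactly).
#' @param min_spacer minimum non-repetitive spacer between planted loci, nt.
#' @param map list: `n_intervals`, `base_cm_per_mb`, `coupling` (cM/Mb per
#'   unit of locus density in coupled mode), `noise_sd`, `gamma_shape`/
#'   `gamma_rate` for the independent mode.
#' @param paralog `NULL`, or list(`n_loci`, `coverage`, `delta_units`,
#'   `sub_offset`) describing a diverged duplicate whose reads pile onto the
#'   source loci (paralogy emulation).
#' @return validated config list of class `ssr_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 1e6,
                       n_scaffolds = 4L,
                       base_comp_a_t = 0.59,
                       planted = default_planted_loci(),
                       het_model = list(intercept = -4.8, slope = 0.3,
                                        class_mult = c(A = 1, C = 2,
                                                       AC = 1.4, AG = 1.2,
                                                       AT = 1.0, CG = 0.8),
                                        max_p = 0.95),
                       multistep_model = list(intercept = -2.5, slope = 0.08,
                                              motif_size_coef = 0.25,
                                              step_geom_p = 0.5),
                       nrup_rate = 0.05,
                       nrup_end_bias = 0.7,
                       coverage = 8.7,
                       read_length_mean = 774,
                       read_length_sd = 80,
                       min_read_length = 100L,
                       error_rate = 0.001,
                       min_repeats = 3L,
                       max_motif = 100L,
                       min_spacer = 30L,
                       map = list(n_intervals = 61L, base_cm_per_mb = 0.5,
                                  coupling = 0.005, noise_sd = 0.5,
                                  gamma_shape = 4, gamma_rate = 4 / 3),
                       paralog = NULL) {
  stopifnot(base_comp_a_t > 0, base_comp_a_t < 1,
            coverage > 0, read_length_mean > 0,
            error_rate >= 0, error_rate <= 1,
            nrup_rate >= 0, nrup_rate <= 1,
            nrup_end_bias >= 0, nrup_end_bias <= 1,
            n_scaffolds >= 1, min_repeats >= 2)
  planted <- as.data.frame(planted, stringsAsFactors = FALSE)
  stopifnot(all(c("motif", "repeat_number", "count") %in% names(planted)))
  for (m in planted$motif) {
    if (!identical(primitive_motif(m), toupper(m)))
      stop("planted motif not primitive: ", m)
  }
  if (any(planted$repeat_number < min_repeats))
    stop("planted repeat_number below min_repeats")
  if (min_spacer < 2 * max(nchar(planted$motif)))
    stop("min_spacer must be at least twice the largest planted motif size")
  cfg <- list(seed = as.integer(seed), genome_length = genome_length,
              n_scaffolds = as.integer(n_scaffolds),
              base_comp_a_t = base_comp_a_t, planted = planted,
              het_model = het_model, multistep_model = multistep_model,
              nrup_rate = nrup_rate, nrup_end_bias = nrup_end_bias,
              coverage = coverage, read_length_mean = read_length_mean,
              read_length_sd = read_length_sd,
              min_read_length = as.integer(min_read_length),
              error_rate = error_rate, min_repeats = as.integer(min_repeats),
              max_motif = as.integer(max_motif),
              min_spacer = as.integer(min_spacer), map = map,
              paralog = paralog)
  class(cfg) <- "ssr_sim_config"
  cfg
}

.base_probs <- function(at) c(A = at / 2, T = at / 2, G = (1 - at) / 2,
                              C = (1 - at) / 2)

#' Generate a reference haplotype with planted SSR loci
#'
#' Background sequence is drawn iid from the configured base composition and
#' then made free of qualifying repeats by swapping bases between positions
#' (a permutation, so the realised base composition is untouched) until the
#' catalogue of the scaffold equals the planted loci exactly.  Planted loci
#' are separated by non-repetitive spacers and their truth coordinates are
#' recorded.
#'
#' @param config an [sim_config()] object.
#' @return list of class `ssr_sim` with `reference`
#'   ([Biostrings::DNAStringSet]), `truth` (data.frame: `locus_id`,
#'   `seq_id`, `start`, `end`, `motif`, `motif_size`, `repeat_number`) and
#'   `config`.
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "ssr_sim_config"))
  set.seed(config$seed)
  inst <- config$planted[rep(seq_len(nrow(config$planted)),
                             config$planted$count), c("motif", "repeat_number")]
  inst$motif <- toupper(inst$motif)
  inst <- inst[sample.int(nrow(inst)), , drop = FALSE]
  inst$len <- nchar(inst$motif) * inst$repeat_number
  scaffold <- rep_len(seq_len(config$n_scaffolds), nrow(inst))
  L <- rep(floor(config$genome_length / config$n_scaffolds),
           config$n_scaffolds)
  L[1] <- L[1] + config$genome_length - sum(L)

  seqs <- character(config$n_scaffolds)
  truth <- vector("list", config$n_scaffolds)
  probs <- .base_probs(config$base_comp_a_t)
  for (k in seq_len(config$n_scaffolds)) {
    li <- inst[scaffold == k, , drop = FALSE]
    n <- nrow(li)
    need <- sum(li$len) + (n + 1L) * config$min_spacer
    if (need > L[k])
      stop("planted loci exceed genome_length on scaffold ", k)
    extra <- as.vector(rmultinom(1, L[k] - need, rep(1, n + 1L)))
    spacer <- config$min_spacer + extra
    chars <- character(L[k])
    starts <- integer(n)
    pos <- 0L
    bg <- sample(names(probs), sum(spacer), replace = TRUE, prob = probs)
    bgi <- 0L
    for (j in seq_len(n + 1L)) {
      sl <- spacer[j]
      chars[(pos + 1L):(pos + sl)] <- bg[(bgi + 1L):(bgi + sl)]
      bgi <- bgi + sl; pos <- pos + sl
      if (j <= n) {
        starts[j] <- pos
        arr <- strsplit(strrep(li$motif[j], li$repeat_number[j]), "")[[1L]]
        chars[(pos + 1L):(pos + li$len[j])] <- arr
        pos <- pos + li$len[j]
      }
    }
    tk <- data.frame(seq_id = sprintf("scaffold_%d", k),
                     start = starts, end = starts + li$len,
                     motif = li$motif, motif_size = nchar(li$motif),
                     repeat_number = li$repeat_number,
                     stringsAsFactors = FALSE)
    chars <- .scrub_background(chars, tk, config)
    seqs[k] <- paste(chars, collapse = "")
    truth[[k]] <- tk
  }
  truth <- do.call(rbind, truth)
  truth$array_length <- truth$end - truth$start
  truth$locus_id <- sprintf("%s:%d-%d", truth$seq_id, truth$start, truth$end)
  rownames(truth) <- NULL
  reference <- Biostrings::DNAStringSet(setNames(
    seqs, sprintf("scaffold_%d", seq_len(config$n_scaffolds))))
  structure(list(reference = reference, truth = truth, config = config),
            class = "ssr_sim")
}

# Swap bases until the only qualifying repeats on the scaffold are the
# planted loci -- on both strands, so the catalogue of the scaffold and of
# its reverse complement both equal the planted truth.  Swaps are drawn
# between a middle base of each unwanted array and a random background
# position carrying a different base.
.scrub_background <- function(chars, truth_k, config) {
  n <- length(chars)
  in_locus <- logical(n)
  for (j in seq_len(nrow(truth_k)))
    in_locus[(truth_k$start[j] + 1L):truth_k$end[j]] <- TRUE
  pad <- logical(n)
  padw <- if (nrow(truth_k)) max(3L, max(truth_k$motif_size)) else 3L
  for (j in seq_len(nrow(truth_k))) {
    lo <- max(1L, truth_k$start[j] + 1L - padw)
    hi <- min(n, truth_k$end[j] + padw)
    pad[lo:hi] <- TRUE
  }
  qpad <- logical(n)
  qbuf <- 26L  # keep swap targets clear of planted loci
  for (j in seq_len(nrow(truth_k))) {
    lo <- max(1L, truth_k$start[j] + 1L - qbuf)
    hi <- min(n, truth_k$end[j] + qbuf)
    qpad[lo:hi] <- TRUE
  }
  qpool <- which(!qpad)
  key_spans <- paste(truth_k$start, truth_k$end)
  mm_small <- min(config$max_motif, 8L)

  # spans that are not a planted locus, on either strand (reverse-scan
  # coordinates mapped back to the forward strand), deduplicated
  extra_spans <- function(chars, mm) {
    fwd <- find_ssrs(paste(chars, collapse = ""), config$min_repeats, mm)
    rev <- find_ssrs(paste(.rev_comp_chars(chars), collapse = ""),
                     config$min_repeats, mm)
    spans <- rbind(fwd[c("start", "end", "motif_size")],
                   data.frame(start = n - rev$end, end = n - rev$start,
                              motif_size = rev$motif_size))
    spans <- spans[!(paste(spans$start, spans$end) %in% key_spans), ,
                   drop = FALSE]
    unique(spans)
  }
  # would a swapped base at x sit inside a qualifying repeat?
  win <- 3L * mm_small * 3L
  in_repeat_at <- function(x) {
    lo <- max(1L, x - win); hi <- min(n, x + win)
    .repeat_at_cpp(paste(chars[lo:hi], collapse = ""), x - lo + 1L,
                   config$min_repeats, mm_small)
  }

  mm <- mm_small
  for (iter in seq_len(60L)) {
    extras <- extra_spans(chars, mm)
    if (nrow(extras) == 0L) {
      if (mm < config$max_motif) { mm <- config$max_motif; next }
      fwd <- find_ssrs(paste(chars, collapse = ""),
                       config$min_repeats, config$max_motif)
      if (length(setdiff(key_spans, paste(fwd$start, fwd$end))))
        stop("internal error: planted locus lost during background scrub")
      return(chars)
    }
    mm <- mm_small
    for (j in seq_len(nrow(extras))) {
      # break the array every third unit so no qualifying sub-run survives
      step <- 3L * extras$motif_size[j]
      span <- (extras$start[j] + 1L):extras$end[j]
      cand <- span[!in_locus[span]]
      if (!length(cand)) next  # junction artifact fully inside planted span
      picks <- cand[seq(min(ceiling(step / 2), length(cand)),
                        length(cand), by = step)]
      for (p in picks) {
        done <- FALSE
        for (try in 1:25) {
          q <- qpool[sample.int(length(qpool), 1L)]
          if (chars[q] == chars[p]) next
          tmp <- chars[p]; chars[p] <- chars[q]; chars[q] <- tmp
          if (!in_repeat_at(q) && !in_repeat_at(p)) { done <- TRUE; break }
          tmp <- chars[p]; chars[p] <- chars[q]; chars[q] <- tmp  # undo
        }
        if (!done) {  # accept the last candidate swap unconditionally
          q <- qpool[sample.int(length(qpool), 1L)]
          if (chars[q] != chars[p]) {
            tmp <- chars[p]; chars[p] <- chars[q]; chars[q] <- tmp
          }
        }
      }
    }
  }
  stop("background scrub did not converge")
}

.rev_comp_chars <- function(chars) {
  unname(rev(c(A = "T", C = "G", G = "C", T = "A")[chars]))
}

# Logistic slippage model: per-locus probability of a length variant.
.het_prob <- function(truth, model) {
  cls <- motif_class_label(truth$motif)
  mult <- model$class_mult[cls]
  mult[is.na(mult)] <- 1
  pmin(model$max_p,
       plogis(model$intercept + model$slope * truth$repeat_number) *
         unname(mult))
}

.multistep_prob <- function(truth, model) {
  plogis(model$intercept + model$slope * truth$repeat_number +
           model$motif_size_coef * (truth$motif_size - 1))
}

#' Derive the second haplotype of the simulated diploid
#'
#' Per planted locus, draws (with the configured probabilities) a repeat
#' length variant on the alternate haplotype: a single unit indel, or a
#' multistep change of two or more units (variant alleles always keep at
#' least two full perfect units).  Loci without a length variant may instead
#' receive a point interruption (NRUP substitution), placed in the first or
#' last repeat unit with probability `nrup_end_bias`.
#'
#' @param sim result of [generate_reference()].
#' @param config optional override of `sim$config`.
#' @return `sim` with added `haplotype2` ([Biostrings::DNAStringSet]),
#'   updated `truth` (columns `het`, `multistep`, `delta_hap2`, `nrup`,
#'   `nrup_offset`, `nrup_alt`, `nrup_class`, `hap2_start`, `hap2_end`) and
#'   `blocks` (per-scaffold alignment events between the haplotypes).
#' @export
diploidize <- function(sim, config = sim$config) {
  stopifnot(inherits(sim, "ssr_sim"))
  set.seed(config$seed + 1L)
  truth <- sim$truth
  n <- nrow(truth)
  p_het <- .het_prob(truth, config$het_model)
  q_ms <- .multistep_prob(truth, config$multistep_model)
  truth$het <- runif(n) < p_het
  truth$multistep <- truth$het & (runif(n) < q_ms)
  step <- ifelse(truth$multistep,
                 2L + rgeom(n, config$multistep_model$step_geom_p), 1L)
  sign <- ifelse(truth$repeat_number - step < 2L, 1L,
                 sample(c(-1L, 1L), n, replace = TRUE))
  truth$delta_hap2 <- ifelse(truth$het, sign * step, 0L)
  truth$nrup <- !truth$het & (runif(n) < config$nrup_rate)
  truth$nrup_class <- ifelse(truth$nrup,
                             ifelse(runif(n) < config$nrup_end_bias,
                                    "end", "middle"), NA_character_)
  # middle placement needs at least one interior unit
  bad_mid <- truth$nrup & truth$nrup_class == "middle" &
    truth$repeat_number < 3L
  truth$nrup_class[bad_mid] <- "end"
  m <- truth$motif_size
  arr <- truth$array_length
  off_end_pool <- function(i) c(seq_len(m[i]) - 1L,
                                (arr[i] - m[i]):(arr[i] - 1L))
  off_mid_pool <- function(i) m[i]:(arr[i] - m[i] - 1L)
  truth$nrup_offset <- NA_integer_
  truth$nrup_alt <- NA_character_
  bases <- c("A", "C", "G", "T")
  ref_chars <- lapply(as.character(sim$reference), function(s)
    strsplit(s, "")[[1L]])
  names(ref_chars) <- names(sim$reference)
  for (i in which(truth$nrup)) {
    pool <- if (truth$nrup_class[i] == "end") unique(off_end_pool(i))
            else off_mid_pool(i)
    truth$nrup_offset[i] <- pool[sample.int(length(pool), 1L)]
    refb <- ref_chars[[truth$seq_id[i]]][truth$start[i] + truth$nrup_offset[i] + 1L]
    truth$nrup_alt[i] <- sample(setdiff(bases, refb), 1L)
  }

  # assemble haplotype 2 and the hap1<->hap2 alignment events
  hap2 <- character(length(sim$reference))
  blocks <- vector("list", length(sim$reference))
  truth$hap2_start <- NA_integer_
  truth$hap2_end <- NA_integer_
  for (k in seq_along(sim$reference)) {
    sid <- names(sim$reference)[k]
    refstr <- as.character(sim$reference[[k]])
    idx <- which(truth$seq_id == sid)
    idx <- idx[order(truth$start[idx])]
    segs <- character(0)
    ev <- list()
    prev_ref <- 0L; alt_pos <- 0L
    for (i in idx) {
      gap <- truth$start[i] - prev_ref
      if (gap > 0) segs <- c(segs, substr(refstr, prev_ref + 1L, truth$start[i]))
      alt_pos <- alt_pos + gap
      new_rep <- truth$repeat_number[i] + truth$delta_hap2[i]
      allele <- strrep(truth$motif[i], new_rep)
      if (truth$nrup[i]) {
        o <- truth$nrup_offset[i]
        allele <- paste0(substr(allele, 1L, o), truth$nrup_alt[i],
                         substr(allele, o + 2L, nchar(allele)))
      }
      alt_len <- nchar(allele)
      truth$hap2_start[i] <- alt_pos
      truth$hap2_end[i] <- alt_pos + alt_len
      if (alt_len != truth$array_length[i])
        ev[[length(ev) + 1L]] <- data.frame(
          seq_id = sid, ref_start = truth$start[i],
          ref_len = truth$array_length[i], alt_len = alt_len)
      segs <- c(segs, allele)
      prev_ref <- truth$end[i]
      alt_pos <- alt_pos + alt_len
    }
    if (prev_ref < nchar(refstr))
      segs <- c(segs, substr(refstr, prev_ref + 1L, nchar(refstr)))
    hap2[k] <- paste(segs, collapse = "")
    blocks[[k]] <- if (length(ev)) do.call(rbind, ev)
                   else data.frame(seq_id = character(), ref_start = integer(),
                                   ref_len = integer(), alt_len = integer())
  }
  sim$haplotype2 <- Biostrings::DNAStringSet(setNames(hap2,
                                                      names(sim$reference)))
  sim$truth <- truth
  sim$events <- do.call(rbind, blocks)
  rownames(sim$events) <- NULL
  sim
}

# Full block table (M segments and variant-locus blocks) of an alt sequence
# against the reference scaffold.  0-based starts.
.block_table <- function(events, ref_len, ref_offset = 0L) {
  rows <- list()
  prev_ref <- 0L; prev_alt <- 0L
  if (nrow(events)) events <- events[order(events$ref_start), , drop = FALSE]
  for (j in seq_len(nrow(events))) {
    gap <- events$ref_start[j] - ref_offset - prev_ref
    if (gap > 0)
      rows[[length(rows) + 1L]] <- c(prev_ref, prev_alt, gap, gap)
    prev_ref <- prev_ref + gap; prev_alt <- prev_alt + gap
    rows[[length(rows) + 1L]] <- c(prev_ref, prev_alt,
                                   events$ref_len[j], events$alt_len[j])
    prev_ref <- prev_ref + events$ref_len[j]
    prev_alt <- prev_alt + events$alt_len[j]
  }
  if (prev_ref < ref_len)
    rows[[length(rows) + 1L]] <- c(prev_ref, prev_alt,
                                   ref_len - prev_ref, ref_len - prev_ref)
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("ref_start", "alt_start", "ref_len", "alt_len")
  out$ref_start <- out$ref_start + ref_offset
  out
}

# Alignment (POS, CIGAR) of an alt-coordinate read against the reference.
# s0 is the 0-based start in alt coordinates.  Returns NULL for reads with
# no reference-aligned base (entirely inside an insertion).
.alt_read_alignment <- function(blocks, s0, len) {
  e0 <- s0 + len
  ops <- character(0); lens <- integer(0)
  pos <- NA_integer_
  for (r in seq_len(nrow(blocks))) {
    bas <- blocks$alt_start[r]; bal <- blocks$alt_len[r]
    brs <- blocks$ref_start[r]; brl <- blocks$ref_len[r]
    b_alt_end <- bas + bal
    if (e0 <= bas) break
    if (bal > 0 && s0 < b_alt_end && e0 > bas) {
      m_alt <- min(brl, bal)
      ms <- max(s0, bas); me <- min(e0, bas + m_alt)
      if (me > ms) {
        if (is.na(pos)) pos <- brs + (ms - bas) + 1L
        ops <- c(ops, "M"); lens <- c(lens, me - ms)
      }
      is_ <- max(s0, bas + m_alt); ie <- min(e0, b_alt_end)
      if (ie > is_) { ops <- c(ops, "I"); lens <- c(lens, ie - is_) }
    }
    if (brl > bal && s0 < b_alt_end && e0 > b_alt_end) {
      ops <- c(ops, "D"); lens <- c(lens, brl - bal)
    }
  }
  if (!length(ops) || !any(ops == "M")) return(NULL)
  if (ops[1L] == "I") ops[1L] <- "S"
  if (ops[length(ops)] == "I") ops[length(ops)] <- "S"
  # drop leading/trailing deletions (no aligned base beyond them)
  while (length(ops) && ops[1L] == "D") { ops <- ops[-1L]; lens <- lens[-1L] }
  while (length(ops) && ops[length(ops)] == "D") {
    ops <- ops[-length(ops)]; lens <- lens[-length(lens)]
  }
  # merge adjacent identical ops
  keep_ops <- character(0); keep_lens <- integer(0)
  for (k in seq_along(ops)) {
    if (length(keep_ops) && keep_ops[length(keep_ops)] == ops[k])
      keep_lens[length(keep_lens)] <- keep_lens[length(keep_lens)] + lens[k]
    else { keep_ops <- c(keep_ops, ops[k]); keep_lens <- c(keep_lens, lens[k]) }
  }
  list(pos = pos, cigar = paste0(keep_lens, keep_ops, collapse = ""))
}

.apply_read_errors <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  lens <- nchar(seqs)
  nerr <- rbinom(length(seqs), lens, error_rate)
  for (i in which(nerr > 0)) {
    pos <- sample.int(lens[i], nerr[i])
    ch <- strsplit(seqs[i], "")[[1L]]
    for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Simulate shotgun reads and their truth alignments
#'
#' Samples single-end reads uniformly from both haplotypes at the configured
#' coverage and read-length model, applies substitution sequencing errors,
#' and emits each read's true alignment against the reference haplotype
#' (haplotype-2 reads acquire I/D CIGAR operations at loci carrying length
#' variants).  Optionally also simulates paralogous piles: extra reads from
#' a diverged ghost copy of selected loci, aligned onto the source locus.
#'
#' @param sim result of [diploidize()].
#' @param config optional override of `sim$config`.
#' @param fastq,sam optional output paths; when given, reads are written as
#'   FASTQ and the truth alignments as SAM.
#' @return `sim` with added `reads` (data.frame: `qname`, `seq_id`, `hap`,
#'   `alt_start`, `length`, `pos`, `cigar`, `seq`), `n_unmapped`, and file
#'   paths when written.
#' @export
simulate_reads <- function(sim, config = sim$config, fastq = NULL, sam = NULL) {
  stopifnot(inherits(sim, "ssr_sim"), !is.null(sim$haplotype2))
  if (config$coverage <= 0) stop("coverage must be positive")
  set.seed(config$seed + 2L)
  all_reads <- list()
  n_unmapped <- 0L
  for (k in seq_along(sim$reference)) {
    sid <- names(sim$reference)[k]
    ref_len <- Biostrings::width(sim$reference)[k]
    ev_k <- sim$events[sim$events$seq_id == sid, , drop = FALSE]
    haps <- list(as.character(sim$reference[[k]]),
                 as.character(sim$haplotype2[[k]]))
    btabs <- list(.block_table(ev_k[0, , drop = FALSE], ref_len),
                  .block_table(ev_k, ref_len))
    for (h in 1:2) {
      hap_seq <- haps[[h]]
      L <- nchar(hap_seq)
      n_reads <- max(1L, round(config$coverage * L /
                                 (2 * config$read_length_mean)))
      lens <- pmin(L, pmax(config$min_read_length,
                           round(rnorm(n_reads, config$read_length_mean,
                                       config$read_length_sd))))
      starts0 <- floor(runif(n_reads, 0, L - lens + 1))  # 0-based
      seqs <- substring(hap_seq, starts0 + 1L, starts0 + lens)
      seqs <- .apply_read_errors(seqs, config$error_rate)
      pos <- integer(n_reads); cig <- character(n_reads)
      if (h == 1L) {
        pos <- starts0 + 1L
        cig <- paste0(lens, "M")
      } else {
        for (i in seq_len(n_reads)) {
          a <- .alt_read_alignment(btabs[[2L]], starts0[i], lens[i])
          if (is.null(a)) { pos[i] <- NA_integer_; cig[i] <- NA_character_ }
          else { pos[i] <- a$pos; cig[i] <- a$cigar }
        }
      }
      all_reads[[length(all_reads) + 1L]] <- data.frame(
        qname = sprintf("%s_h%d_r%05d", sid, h, seq_len(n_reads)),
        seq_id = sid, hap = h, alt_start = starts0, length = lens,
        pos = pos, cigar = cig, seq = seqs, stringsAsFactors = FALSE)
    }
  }
  reads <- do.call(rbind, all_reads)

  # paralogy emulation: a diverged ghost copy of selected loci contributes
  # extra reads that a mapper would place on the source locus
  if (!is.null(config$paralog)) {
    pg <- config$paralog
    pick <- sim$truth[sample.int(nrow(sim$truth), min(pg$n_loci,
                                                      nrow(sim$truth))), ]
    margin <- as.integer(2 * config$read_length_mean)
    ghost <- list()
    for (i in seq_len(nrow(pick))) {
      tr <- pick[i, ]
      refstr <- as.character(sim$reference[[tr$seq_id]])
      seg_s <- max(0L, tr$start - margin)                     # 0-based
      seg_e <- min(nchar(refstr), tr$end + margin)
      new_rep <- max(2L, tr$repeat_number + pg$delta_units)
      allele <- strrep(tr$motif, new_rep)
      # diverge the ghost further with one substitution inside the array
      so <- min(pg$sub_offset, nchar(allele) - 1L)
      ref_b <- substr(allele, so + 1L, so + 1L)
      allele <- paste0(substr(allele, 1L, so),
                       sample(setdiff(c("A", "C", "G", "T"), ref_b), 1L),
                       substr(allele, so + 2L, nchar(allele)))
      alt_seq <- paste0(substr(refstr, seg_s + 1L, tr$start), allele,
                        substr(refstr, tr$end + 1L, seg_e))
      ev <- data.frame(seq_id = tr$seq_id, ref_start = tr$start,
                       ref_len = tr$array_length, alt_len = nchar(allele))
      bt <- .block_table(ev, seg_e - seg_s, ref_offset = seg_s)
      Lg <- nchar(alt_seq)
      n_reads <- max(1L, round(pg$coverage * Lg / config$read_length_mean))
      lens <- pmin(Lg, pmax(config$min_read_length,
                            round(rnorm(n_reads, config$read_length_mean,
                                        config$read_length_sd))))
      starts0 <- floor(runif(n_reads, 0, Lg - lens + 1))
      seqs <- .apply_read_errors(substring(alt_seq, starts0 + 1L,
                                           starts0 + lens),
                                 config$error_rate)
      pos <- integer(n_reads); cig <- character(n_reads)
      for (j in seq_len(n_reads)) {
        a <- .alt_read_alignment(bt, starts0[j], lens[j])
        if (is.null(a)) { pos[j] <- NA_integer_; cig[j] <- NA_character_ }
        else { pos[j] <- a$pos; cig[j] <- a$cigar }
      }
      ghost[[i]] <- data.frame(
        qname = sprintf("para_%s_%d_r%04d", tr$seq_id, tr$start,
                        seq_len(n_reads)),
        seq_id = tr$seq_id, hap = 3L, alt_start = starts0, length = lens,
        pos = pos, cigar = cig, seq = seqs, stringsAsFactors = FALSE)
    }
    reads <- rbind(reads, do.call(rbind, ghost))
    sim$paralog_loci <- pick$locus_id
  }

  n_unmapped <- sum(is.na(reads$pos))
  sim$reads <- reads
  sim$n_unmapped <- n_unmapped
  if (!is.null(fastq)) sim$fastq <- write_reads_fastq(reads, fastq)
  if (!is.null(sam)) sim$sam <- write_truth_sam(reads, sim$reference, sam)
  sim
}

#' Write simulated reads as FASTQ
#' @param reads read table from [simulate_reads()].
#' @param path output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  dss <- Biostrings::DNAStringSet(setNames(reads$seq, reads$qname))
  quals <- Biostrings::BStringSet(strrep("I", nchar(reads$seq)))
  Biostrings::writeXStringSet(dss, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Write truth alignments as SAM
#'
#' Emits the simulator's true read placements as a plain-text SAM file
#' (header plus one primary, forward-strand record per mapped read).
#'
#' @param reads read table from [simulate_reads()].
#' @param reference the reference `DNAStringSet` (for `@SQ` header lines).
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
write_truth_sam <- function(reads, reference, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(reference),
                   Biostrings::width(reference)))
  mapped <- reads[!is.na(reads$pos), , drop = FALSE]
  rec <- sprintf("%s\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
                 mapped$qname, mapped$seq_id, mapped$pos, mapped$cigar,
                 mapped$seq, strrep("I", nchar(mapped$seq)))
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Generate a genetic map over the simulated scaffolds
#'
#' Tiles the scaffolds into intervals and assigns centiMorgan values either
#' independently of the planted SSR density (`"independent"`, the null for
#' calibration) or linearly coupled to it (`"coupled"`, for positive-control
#' correlation tests).
#'
#' @param sim an `ssr_sim` (needs `reference` and `truth`).
#' @param config optional override of `sim$config`.
#' @param mode `"independent"` or `"coupled"`.
#' @param seed RNG seed for the map draw (default derived from the config).
#' @return data.frame with `seq_id`, `phys_start`, `phys_end` (0-based nt)
#'   and `cm`.
#' @export
generate_map <- function(sim, config = sim$config,
                         mode = c("independent", "coupled"),
                         seed = config$seed + 3L) {
  mode <- match.arg(mode)
  set.seed(seed)
  mp <- config$map
  lens <- Biostrings::width(sim$reference)
  n_int <- pmax(1L, round(mp$n_intervals * lens / sum(lens)))
  out <- list()
  for (k in seq_along(lens)) {
    bk <- round(seq(0, lens[k], length.out = n_int[k] + 1L))
    out[[k]] <- data.frame(seq_id = names(sim$reference)[k],
                           phys_start = bk[-length(bk)], phys_end = bk[-1L],
                           stringsAsFactors = FALSE)
  }
  intervals <- do.call(rbind, out)
  micro <- sim$truth[sim$truth$motif_size >= 2L, , drop = FALSE]
  count <- mapply(function(sid, s, e)
    sum(micro$seq_id == sid & micro$start >= s & micro$start < e),
    intervals$seq_id, intervals$phys_start, intervals$phys_end)
  span_mb <- (intervals$phys_end - intervals$phys_start) / 1e6
  density <- count / span_mb
  cm_per_mb <- if (mode == "coupled")
    pmax(0, mp$base_cm_per_mb + mp$coupling * density +
           rnorm(nrow(intervals), 0, mp$noise_sd))
  else rgamma(nrow(intervals), shape = mp$gamma_shape, rate = mp$gamma_rate)
  intervals$cm <- cm_per_mb * span_mb
  rownames(intervals) <- NULL
  intervals
}
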