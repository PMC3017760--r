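# Read-based SSR genotyping: repeat-unit alleles, multistep variants, NRUPs.
#
# The caller consumes standard SAM alignments (primary, mapped reads).  For
# each catalogued locus it extracts reads that fully span the locus plus a
# flank on both sides, requires the flanks to match the reference exactly
# (anchoring), and recounts repeat units inside the anchored segment, which
# is robust to how aligners place indels inside repeats.  Non-unit
# differences are resolved with a unit-cost global alignment of the segment
# against the reference array.

#' Read primary alignments from a SAM file
#'
#' Converts SAM to BAM (sorted, indexed) and loads primary, mapped
#' alignments with their query names and sequences.
#'
#' @param sam path to a SAM (or BAM) file.
#' @return a [GenomicAlignments::GAlignments] with metadata columns `qname`,
#'   `flag`, `seq`.
#' @export
read_alignments <- function(sam) {
  bam <- if (grepl("\\.bam$", sam)) sam
         else Rsamtools::asBam(sam, destination = tempfile(),
                               overwrite = TRUE, indexDestination = TRUE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "seq"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  GenomicAlignments::readGAlignments(bam, param = param)
}

# Plain-vector view of a GAlignments, with lazily cached per-read identity.
# All per-locus work happens on this structure to avoid repeated S4
# extraction inside the locus loop.
.read_store <- function(aln) {
  rd <- new.env(parent = emptyenv())
  rd$seqnames <- as.character(GenomicAlignments::seqnames(aln))
  rd$start <- GenomicAlignments::start(aln)
  rd$end <- GenomicAlignments::end(aln)
  rd$qname <- S4Vectors::mcols(aln)$qname
  rd$seq <- as.character(S4Vectors::mcols(aln)$seq)
  cig <- GenomicAlignments::cigar(aln)
  rd$ops <- GenomicAlignments::explodeCigarOps(cig)
  rd$lens <- GenomicAlignments::explodeCigarOpLengths(cig)
  rd$identity <- rep(NA_real_, length(cig))
  rd
}

# Map a 1-based reference window [wstart, wend] to query coordinates for one
# alignment (pre-exploded cigar).  Returns c(qs, qe) or NULL when the window
# edges are not covered by aligned query bases.
.ref_window_to_query <- function(ops, lens, pos, wstart, wend) {
  rpos <- pos; qpos <- 1L
  qs <- NA_integer_; qe <- NA_integer_
  for (k in seq_along(ops)) {
    op <- ops[k]; len <- lens[k]
    cr <- op == "M" || op == "D" || op == "N" || op == "=" || op == "X"
    cq <- op == "M" || op == "I" || op == "S" || op == "=" || op == "X"
    if (cr) {
      if (is.na(qs) && wstart >= rpos && wstart < rpos + len)
        qs <- if (cq) qpos + (wstart - rpos) else NA_integer_
      if (wend >= rpos && wend < rpos + len) {
        qe <- if (cq) qpos + (wend - rpos) else NA_integer_
        break
      }
      if (is.na(qs) && wstart < rpos) return(NULL)  # window start in a gap
      rpos <- rpos + len
    }
    if (cq) qpos <- qpos + len
  }
  if (is.na(qs) || is.na(qe) || qe < qs) NULL else c(qs, qe)
}

# Fraction of identical columns over the full alignment (matches divided by
# aligned columns including indel columns).
.alignment_identity <- function(qseq, ops, lens, pos, refchr) {
  rpos <- pos; qpos <- 1L
  match_n <- 0L; cols <- 0L
  for (k in seq_along(ops)) {
    op <- ops[k]; len <- lens[k]
    if (op == "M" || op == "=" || op == "X") {
      a <- charToRaw(substr(qseq, qpos, qpos + len - 1L))
      b <- charToRaw(substr(refchr, rpos, rpos + len - 1L))
      match_n <- match_n + sum(a == b)
      cols <- cols + len
      rpos <- rpos + len; qpos <- qpos + len
    } else if (op == "D" || op == "N") {
      cols <- cols + len; rpos <- rpos + len
    } else if (op == "I") {
      cols <- cols + len; qpos <- qpos + len
    } else if (op == "S") {
      qpos <- qpos + len
    }
  }
  if (cols == 0L) 0 else match_n / cols
}

# Compare the anchored read segment (flanks stripped) with the reference
# repeat array.  Unit-length indels (width a multiple of motif_size) are
# counted into delta_units; everything else is an NRUP.  Offsets are 0-based
# reference-locus coordinates; indels are reported at the leftmost subject
# position of the gap run.  Returns list(delta_units, kind, offset, alt)
# with zero-length vectors when the segment carries no NRUP.
.analyze_inner <- function(inner, motif, repeat_number) {
  m <- nchar(motif)
  none <- list(kind = character(0), offset = integer(0), alt = character(0))
  ref_arr <- strrep(motif, repeat_number)
  if (inner == ref_arr)
    return(c(list(delta_units = 0L), none))
  if (nchar(inner) %% m == 0L) {
    k <- nchar(inner) %/% m
    if (k > 0L && inner == strrep(motif, k))
      return(c(list(delta_units = k - repeat_number), none))
  }
  if (nchar(inner) == 0L)
    return(c(list(delta_units = -repeat_number), none))
  al <- .nw_align_cpp(inner, ref_arr)
  pc <- strsplit(al[1L], "")[[1L]]
  sc <- strsplit(al[2L], "")[[1L]]
  ref_at <- cumsum(sc != "-")  # subject coordinate (1-based) at each column
  delta <- 0L
  kinds <- character(0); offs <- integer(0); alts <- character(0)
  sub_cols <- which(pc != "-" & sc != "-" & pc != sc)
  if (length(sub_cols)) {
    kinds <- rep("substitution", length(sub_cols))
    offs <- ref_at[sub_cols] - 1L
    alts <- pc[sub_cols]
  }
  gap_runs <- function(is_gap) {
    r <- rle(is_gap)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cbind(starts[r$values], ends[r$values])
  }
  arr_len <- nchar(ref_arr)
  ins <- gap_runs(sc == "-")   # bases present in read, absent in reference
  if (nrow(ins)) for (k in seq_len(nrow(ins))) {
    w <- ins[k, 2L] - ins[k, 1L] + 1L
    if (w %% m == 0L) delta <- delta + w %/% m
    else {
      # left-align: slide the insert while its last base matches the
      # reference base it would cross
      o1 <- ref_at[ins[k, 1L]]   # 1-based subject position before the gap
      seq_ins <- paste(pc[ins[k, 1L]:ins[k, 2L]], collapse = "")
      while (o1 >= 1L &&
             substr(ref_arr, o1, o1) == substr(seq_ins, w, w)) {
        seq_ins <- paste0(substr(ref_arr, o1, o1), substr(seq_ins, 1L, w - 1L))
        o1 <- o1 - 1L
      }
      kinds <- c(kinds, "insertion")
      offs <- c(offs, min(o1, arr_len - 1L))
      alts <- c(alts, seq_ins)
    }
  }
  del <- gap_runs(pc == "-")   # reference bases absent from the read
  if (nrow(del)) for (k in seq_len(nrow(del))) {
    w <- del[k, 2L] - del[k, 1L] + 1L
    if (w %% m == 0L) delta <- delta - w %/% m
    else {
      o0 <- ref_at[del[k, 1L]] - 1L  # 0-based start of the deleted run
      while (o0 >= 1L &&
             substr(ref_arr, o0, o0) == substr(ref_arr, o0 + w, o0 + w))
        o0 <- o0 - 1L
      kinds <- c(kinds, "deletion")
      offs <- c(offs, o0)
      alts <- c(alts, "")
    }
  }
  list(delta_units = delta, kind = kinds, offset = offs, alt = alts)
}

# Worker: observations for one locus, over candidate read indices `ridx`
# into the read store.  Returns plain vectors.
.locus_obs_core <- function(rd, ridx, locus, refchr, flank, min_identity) {
  wstart <- locus$start - flank + 1L   # 1-based window
  wend <- locus$end + flank
  out <- list(read_id = character(0), delta_units = integer(0),
              n_nrup = integer(0),
              nr_read = character(0), nr_kind = character(0),
              nr_offset = integer(0), nr_alt = character(0),
              skipped = c(not_spanning = 0L, low_identity = 0L,
                          unanchored = 0L))
  if (wstart < 1L || wend > nchar(refchr) || !length(ridx)) return(out)
  span <- rd$start[ridx] <= wstart & rd$end[ridx] >= wend
  out$skipped["not_spanning"] <- sum(!span)
  ridx <- ridx[span]
  if (!length(ridx)) return(out)
  left_ref <- substr(refchr, wstart, wstart + flank - 1L)
  right_ref <- substr(refchr, wend - flank + 1L, wend)
  for (i in ridx) {
    ident <- rd$identity[i]
    if (is.na(ident)) {
      ident <- .alignment_identity(rd$seq[i], rd$ops[[i]], rd$lens[[i]],
                                   rd$start[i], refchr)
      rd$identity[i] <- ident
    }
    if (ident < min_identity) {
      out$skipped["low_identity"] <- out$skipped["low_identity"] + 1L
      next
    }
    q <- .ref_window_to_query(rd$ops[[i]], rd$lens[[i]], rd$start[i],
                              wstart, wend)
    if (is.null(q)) {
      out$skipped["unanchored"] <- out$skipped["unanchored"] + 1L
      next
    }
    segment <- substr(rd$seq[i], q[1L], q[2L])
    if (nchar(segment) < 2L * flank ||
        substr(segment, 1L, flank) != left_ref ||
        substr(segment, nchar(segment) - flank + 1L,
               nchar(segment)) != right_ref) {
      out$skipped["unanchored"] <- out$skipped["unanchored"] + 1L
      next
    }
    inner <- substr(segment, flank + 1L, nchar(segment) - flank)
    res <- .analyze_inner(inner, locus$motif, locus$repeat_number)
    out$read_id <- c(out$read_id, rd$qname[i])
    out$delta_units <- c(out$delta_units, res$delta_units)
    out$n_nrup <- c(out$n_nrup, length(res$kind))
    if (length(res$kind)) {
      out$nr_read <- c(out$nr_read, rep(rd$qname[i], length(res$kind)))
      out$nr_kind <- c(out$nr_kind, res$kind)
      out$nr_offset <- c(out$nr_offset, res$offset)
      out$nr_alt <- c(out$nr_alt, res$alt)
    }
  }
  out
}

#' Extract per-read allele observations at one SSR locus
#'
#' Keeps reads that fully span the locus plus `flank` bases on both sides
#' with overall alignment identity at least `min_identity`, and whose
#' flanking bases match the reference exactly (anchoring).  For each
#' anchored read, repeat units in the segment between the anchors are
#' recounted to give `delta_units` (signed difference in full units versus
#' the assembly allele), and NRUPs (base substitutions and non-unit indels)
#' are called from a unit-cost global alignment of the segment against the
#' reference array.
#'
#' @param alignments a [GenomicAlignments::GAlignments] from
#'   [read_alignments()] (metadata columns `qname`, `seq` required).
#' @param locus single-row data.frame (or list) with `seq_id`, `start`,
#'   `end`, `motif`, `motif_size`, `repeat_number` (0-based half-open
#'   coordinates as produced by [catalog_genome()]).
#' @param reference named character vector or `DNAStringSet` of assembly
#'   sequences.
#' @param flank anchor width in bp (default 5); the flank must match the
#'   reference exactly on both sides.
#' @param min_identity minimum alignment identity (default 0.90).
#' @return list with `observations` (data.frame: `read_id`, `delta_units`,
#'   `n_nrup`), `nrups` (data.frame: `read_id`, `kind`, `offset`, `alt`) and
#'   `skipped` (named counts: `not_spanning`, `low_identity`, `unanchored`;
#'   unmapped/secondary reads are already excluded by [read_alignments()]).
#' @export
extract_locus_observations <- function(alignments, locus, reference,
                                       flank = 5L, min_identity = 0.90) {
  stopifnot(flank >= 1L)
  if (methods::is(reference, "DNAStringSet"))
    reference <- setNames(as.character(reference),
                          sub("\\s.*$", "", names(reference)))
  locus <- as.list(locus)
  rd <- .read_store(alignments)
  ridx <- which(rd$seqnames == locus$seq_id)
  core <- .locus_obs_core(rd, ridx, locus, reference[[locus$seq_id]],
                          as.integer(flank), min_identity)
  list(observations = data.frame(read_id = core$read_id,
                                 delta_units = core$delta_units,
                                 n_nrup = core$n_nrup,
                                 stringsAsFactors = FALSE),
       nrups = data.frame(read_id = core$nr_read, kind = core$nr_kind,
                          offset = core$nr_offset, alt = core$nr_alt,
                          stringsAsFactors = FALSE),
       skipped = core$skipped)
}

#' Classify the position of an interruption within a repeat array
#'
#' An interruption is an "end" polymorphism when it falls within the first
#' or last full repeat unit of the locus, and a "middle" polymorphism
#' otherwise.
#'
#' @param offset 0-based position(s) within the locus,
#'   `0 <= offset < array_length`.
#' @param locus single-row data.frame or list with `motif_size` and
#'   `repeat_number` (or `array_length`).
#' @return character vector, `"end"` or `"middle"`.
#' @export
classify_nrup_position <- function(offset, locus) {
  locus <- as.list(locus)
  m <- locus$motif_size
  arr <- if (!is.null(locus$array_length)) locus$array_length
         else m * locus$repeat_number
  if (any(offset < 0 | offset >= arr))
    stop("offset out of range for this locus")
  ifelse(offset < m | offset >= arr - m, "end", "middle")
}

# Core genotyping on plain vectors.  nr_* describe per-read NRUP
# observations (possibly several per read).
.genotype_core <- function(delta_units, nr_kind, nr_offset, nr_alt,
                           locus, depth, min_depth, max_depth, min_support) {
  out <- list(
    status = "unassayable",
    allele_delta = integer(0), allele_support = integer(0),
    nrup_kind = character(0), nrup_offset = integer(0),
    nrup_alt = character(0), nrup_class = character(0),
    nrup_support = integer(0),
    depth_min = if (length(depth)) min(depth) else 0L,
    depth_max = if (length(depth)) max(depth) else 0L,
    n_obs = length(delta_units),
    n_singleton_repeat = 0L, n_singleton_snp = 0L)
  if (length(depth) == 0L || any(depth < min_depth) || any(depth > max_depth))
    return(out)
  if (length(delta_units) == 0L) return(out)

  tab <- table(delta_units)
  deltas <- as.integer(names(tab))
  support <- as.integer(tab)
  keep <- support >= min_support
  ord <- order(-support[keep], deltas[keep])
  out$allele_delta <- deltas[keep][ord]
  out$allele_support <- support[keep][ord]
  out$n_singleton_repeat <- sum(support[!keep & deltas != 0L])

  if (length(nr_kind)) {
    key <- paste(nr_kind, nr_offset, nr_alt, sep = "\r")
    ntab <- table(key)
    nsup <- as.integer(ntab)
    first <- match(names(ntab), key)
    nkeep <- nsup >= min_support
    out$n_singleton_snp <- sum(nsup[!nkeep & nr_kind[first] == "substitution"])
    if (any(nkeep)) {
      f <- first[nkeep]
      out$nrup_kind <- nr_kind[f]
      out$nrup_offset <- nr_offset[f]
      out$nrup_alt <- nr_alt[f]
      out$nrup_support <- nsup[nkeep]
      out$nrup_class <- classify_nrup_position(out$nrup_offset, locus)
    }
  }

  # two-allele caps: repeat-length alleles, and base states per site
  snp_multi <- FALSE
  subs <- out$nrup_kind == "substitution"
  if (sum(subs) >= 2L)
    snp_multi <- any(tapply(out$nrup_alt[subs], out$nrup_offset[subs],
                            function(a) length(unique(a))) >= 2L)
  n_alleles <- length(out$allele_delta)
  out$status <-
    if (n_alleles > 2L || snp_multi) "discarded_multiallelic"
    else if (n_alleles == 0L) "unassayable"
    else if (n_alleles == 1L) "homozygous"
    else if (abs(diff(out$allele_delta)) >= 2L) "het_multistep"
    else "het_unit"
  out
}

#' Genotype one SSR locus from its read observations
#'
#' Applies, in order: the per-position coverage window (every locus position
#' must have depth in `[min_depth, max_depth]`, else the locus is
#' unassayable); grouping of observations by `delta_units` with a
#' `min_support`-read consensus minimum per allele (singleton variant reads
#' are tallied as read errors, not alleles); a two-allele cap (loci with
#' more than two supported repeat alleles, or more than two supported base
#' states at one site, are discarded as putative paralogs).  A single
#' retained allele gives a homozygous call; two alleles give a heterozygous
#' call, multistep when the alleles differ by two or more repeat units.
#'
#' @param observations result of [extract_locus_observations()] (list with
#'   `observations` and `nrups`), or just its `observations` data.frame.
#' @param locus single-row data.frame or list (needs `motif_size` and
#'   `repeat_number` or `array_length`).
#' @param depth integer vector of per-position coverage across the locus.
#' @param min_depth,max_depth inclusive coverage window (defaults 4 and 16).
#' @param min_support consensus minimum per allele/NRUP (default 2 reads).
#' @return list with `status` (`"unassayable"`, `"homozygous"`,
#'   `"het_unit"`, `"het_multistep"` or `"discarded_multiallelic"`),
#'   `alleles` (data.frame `delta_units`, `support`; at most two rows
#'   retained), `nrup_calls` (data.frame `kind`, `offset`, `alt`,
#'   `position_class`, `support`), `depth_range`, `n_obs`,
#'   `n_singleton_repeat`, `n_singleton_snp`.
#' @export
genotype_locus <- function(observations, locus, depth,
                           min_depth = 4L, max_depth = 16L,
                           min_support = 2L) {
  if (is.data.frame(observations))
    observations <- list(observations = observations,
                         nrups = data.frame(read_id = character(0),
                                            kind = character(0),
                                            offset = integer(0),
                                            alt = character(0),
                                            stringsAsFactors = FALSE))
  locus <- as.list(locus)
  core <- .genotype_core(observations$observations$delta_units,
                         observations$nrups$kind,
                         observations$nrups$offset,
                         observations$nrups$alt,
                         locus, depth, min_depth, max_depth, min_support)
  list(status = core$status,
       alleles = data.frame(delta_units = core$allele_delta,
                            support = core$allele_support),
       nrup_calls = data.frame(kind = core$nrup_kind,
                               offset = core$nrup_offset,
                               alt = core$nrup_alt,
                               position_class = core$nrup_class,
                               support = core$nrup_support,
                               stringsAsFactors = FALSE),
       depth_range = c(min = core$depth_min, max = core$depth_max),
       n_obs = core$n_obs,
       n_singleton_repeat = core$n_singleton_repeat,
       n_singleton_snp = core$n_singleton_snp)
}

#' Genotype every catalogued locus from a SAM file
#'
#' Runs the per-locus observation extraction and [genotype_locus()] filters
#' over a whole catalogue, computing per-position coverage from the same
#' alignments.
#'
#' @param alignments SAM path or a [GenomicAlignments::GAlignments] from
#'   [read_alignments()].
#' @param loci catalogue data.frame from [catalog_genome()].
#' @param reference assembly FASTA path, `DNAStringSet`, or named character
#'   vector.
#' @inheritParams extract_locus_observations
#' @inheritParams genotype_locus
#' @return list with `genotypes` (one row per locus: locus columns plus
#'   `status`, `n_obs`, `depth_min`, `depth_max`, `n_alleles`, `delta_1`,
#'   `support_1`, `delta_2`, `support_2`, `n_nrup`, singleton tallies),
#'   `nrups` (supported NRUP calls with locus ids and position class) and
#'   `log` (singleton totals, skip and discard counts).
#' @export
call_variants <- function(alignments, loci, reference, flank = 5L,
                          min_identity = 0.90, min_depth = 4L,
                          max_depth = 16L, min_support = 2L) {
  if (is.character(alignments)) alignments <- read_alignments(alignments)
  if (is.character(reference))
    reference <- Biostrings::readDNAStringSet(reference)
  if (methods::is(reference, "DNAStringSet"))
    reference <- setNames(as.character(reference),
                          sub("\\s.*$", "", names(reference)))
  stopifnot(nrow(loci) > 0)
  flank <- as.integer(flank)

  rd <- .read_store(alignments)
  cov <- GenomicAlignments::coverage(alignments)
  depth_full <- lapply(names(reference), function(sid) {
    if (sid %in% names(cov)) as.integer(cov[[sid]]) else integer(0)
  })
  names(depth_full) <- names(reference)

  windows <- GenomicRanges::GRanges(
    loci$seq_id,
    IRanges::IRanges(start = pmax(1L, loci$start - flank + 1L),
                     end = loci$end + flank))
  spans <- GenomicRanges::granges(alignments)
  hits <- GenomicRanges::findOverlaps(windows, spans, type = "within")
  by_locus <- split(S4Vectors::subjectHits(hits),
                    factor(S4Vectors::queryHits(hits),
                           levels = seq_len(nrow(loci))))

  n <- nrow(loci)
  status <- character(n); n_obs <- integer(n)
  depth_min <- integer(n); depth_max <- integer(n)
  n_alleles <- integer(n)
  delta_1 <- rep(NA_integer_, n); support_1 <- rep(NA_integer_, n)
  delta_2 <- rep(NA_integer_, n); support_2 <- rep(NA_integer_, n)
  n_nrup <- integer(n)
  sing_rep <- integer(n); sing_snp <- integer(n)
  nrup_rows <- vector("list", n)
  skipped <- c(not_spanning = 0L, low_identity = 0L, unanchored = 0L)

  locus_id <- sprintf("%s:%d-%d", loci$seq_id, loci$start, loci$end)
  for (i in seq_len(n)) {
    locus <- list(seq_id = loci$seq_id[i], start = loci$start[i],
                  end = loci$end[i], motif = loci$motif[i],
                  motif_size = loci$motif_size[i],
                  repeat_number = loci$repeat_number[i],
                  array_length = loci$array_length[i])
    refchr <- reference[[locus$seq_id]]
    dfull <- depth_full[[locus$seq_id]]
    d <- if (!is.null(dfull) && locus$end <= length(dfull))
      dfull[(locus$start + 1L):locus$end]
    else if (!is.null(dfull) && locus$start < length(dfull))
      c(dfull[(locus$start + 1L):length(dfull)],
        integer(locus$end - length(dfull)))
    else integer(locus$end - locus$start)
    obs <- .locus_obs_core(rd, by_locus[[i]], locus, refchr, flank,
                           min_identity)
    skipped <- skipped + obs$skipped
    g <- .genotype_core(obs$delta_units, obs$nr_kind, obs$nr_offset,
                        obs$nr_alt, locus, d, min_depth, max_depth,
                        min_support)
    status[i] <- g$status; n_obs[i] <- g$n_obs
    depth_min[i] <- g$depth_min; depth_max[i] <- g$depth_max
    n_alleles[i] <- length(g$allele_delta)
    if (n_alleles[i] >= 1L) { delta_1[i] <- g$allele_delta[1L]
                              support_1[i] <- g$allele_support[1L] }
    if (n_alleles[i] >= 2L) { delta_2[i] <- g$allele_delta[2L]
                              support_2[i] <- g$allele_support[2L] }
    n_nrup[i] <- length(g$nrup_kind)
    sing_rep[i] <- g$n_singleton_repeat; sing_snp[i] <- g$n_singleton_snp
    if (n_nrup[i] && g$status != "unassayable")
      nrup_rows[[i]] <- data.frame(
        locus_id = locus_id[i], seq_id = locus$seq_id,
        motif = locus$motif, motif_size = locus$motif_size,
        repeat_number = locus$repeat_number,
        kind = g$nrup_kind, offset = g$nrup_offset, alt = g$nrup_alt,
        position_class = g$nrup_class, support = g$nrup_support,
        stringsAsFactors = FALSE)
  }

  genotypes <- data.frame(
    locus_id = locus_id,
    loci[c("seq_id", "start", "end", "motif", "motif_size",
           "repeat_number", "array_length")],
    status = status, n_obs = n_obs,
    depth_min = depth_min, depth_max = depth_max,
    n_alleles = n_alleles, delta_1 = delta_1, support_1 = support_1,
    delta_2 = delta_2, support_2 = support_2, n_nrup = n_nrup,
    n_singleton_repeat = sing_rep, n_singleton_snp = sing_snp,
    stringsAsFactors = FALSE)
  rownames(genotypes) <- NULL
  nrups <- do.call(rbind, nrup_rows[!vapply(nrup_rows, is.null, logical(1))])
  if (is.null(nrups))
    nrups <- data.frame(locus_id = character(0), seq_id = character(0),
                        motif = character(0), motif_size = integer(0),
                        repeat_number = integer(0), kind = character(0),
                        offset = integer(0), alt = character(0),
                        position_class = character(0), support = integer(0),
                        stringsAsFactors = FALSE)
  rownames(nrups) <- NULL
  log <- list(n_singleton_repeat = sum(sing_rep),
              n_singleton_snp = sum(sing_snp),
              skipped = skipped,
              n_discarded = sum(status == "discarded_multiallelic"))
  list(genotypes = genotypes, nrups = nrups, log = log)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarise heterozygosity, multistep and NRUP rates over genotyped loci
#'
#' @param calls result of [call_variants()], or just its `genotypes`
#'   data.frame (pass `nrups` separately for NRUP rates).
#' @param nrups optional NRUP call table (taken from `calls` when a full
#'   result is given).
#' @return list with `by_bin` (motif_size x repeat_number), `by_class`
#'   (motif class x repeat_number), `by_class_total` (motif class), and
#'   `overall` (assayed count, heterozygosity, multistep fraction and the
#'   multiallelic discard frequency).  Percentages are among genotyped
#'   (homozygous + heterozygous) loci; the multistep fraction is among
#'   heterozygous loci and `NA` where a bin has none.
#' @export
summarize_heterozygosity <- function(calls, nrups = NULL) {
  if (is.list(calls) && !is.data.frame(calls)) {
    nrups <- calls$nrups
    genotypes <- calls$genotypes
  } else genotypes <- calls
  if (is.null(nrups))
    nrups <- data.frame(locus_id = character(0))
  if (nrow(genotypes) == 0L)
    return(list(by_bin = data.frame(), by_class = data.frame(),
                by_class_total = data.frame(),
                overall = data.frame(n_loci = 0L, n_assayed = 0L)))

  g <- genotypes
  g$class <- motif_class_label(g$motif)
  nrup_by_locus <- table(nrups$locus_id)
  g$n_nrup_calls <- as.integer(nrup_by_locus[g$locus_id])
  g$n_nrup_calls[is.na(g$n_nrup_calls)] <- 0L
  g$n_nrup_calls[g$status == "unassayable"] <- 0L

  summarise_group <- function(df) {
    assayed <- df$status != "unassayable"
    geno <- df$status %in% c("homozygous", "het_unit", "het_multistep")
    het <- df$status %in% c("het_unit", "het_multistep")
    multi <- df$status == "het_multistep"
    disc <- df$status == "discarded_multiallelic"
    assayed_nt <- sum(df$array_length[assayed])
    data.frame(
      n_loci = nrow(df), n_assayed = sum(assayed),
      n_genotyped = sum(geno), n_het = sum(het),
      n_multistep = sum(multi), n_discarded = sum(disc),
      pct_het = if (sum(geno)) proportion_of(sum(het), sum(geno)) else NA_real_,
      pct_multistep_of_het = if (sum(het))
        proportion_of(sum(multi), sum(het)) else NA_real_,
      n_nrup_calls = sum(df$n_nrup_calls),
      nrup_per_nt = if (assayed_nt > 0)
        sum(df$n_nrup_calls) / assayed_nt else NA_real_)
  }
  group_summary <- function(keys) {
    groups <- split(g, keys, drop = TRUE)
    out <- do.call(rbind, lapply(groups, summarise_group))
    keycols <- do.call(rbind, strsplit(names(groups), "\r", fixed = TRUE))
    out <- cbind(as.data.frame(keycols, stringsAsFactors = FALSE), out)
    rownames(out) <- NULL
    out
  }
  by_bin <- group_summary(paste(g$motif_size, g$repeat_number, sep = "\r"))
  names(by_bin)[1:2] <- c("motif_size", "repeat_number")
  by_bin$motif_size <- as.integer(by_bin$motif_size)
  by_bin$repeat_number <- as.integer(by_bin$repeat_number)
  by_bin <- by_bin[order(by_bin$motif_size, by_bin$repeat_number), ]
  rownames(by_bin) <- NULL

  by_class <- group_summary(paste(g$class, g$repeat_number, sep = "\r"))
  names(by_class)[1:2] <- c("class", "repeat_number")
  by_class$repeat_number <- as.integer(by_class$repeat_number)
  by_class <- by_class[order(by_class$class, by_class$repeat_number), ]
  rownames(by_class) <- NULL

  by_class_total <- group_summary(g$class)
  names(by_class_total)[1] <- "class"
  rownames(by_class_total) <- NULL

  overall <- summarise_group(g)
  overall$discard_frequency <- if (overall$n_assayed > 0)
    proportion_of(overall$n_discarded, overall$n_assayed, percent = FALSE)
  else NA_real_

  list(by_bin = by_bin, by_class = by_class,
       by_class_total = by_class_total, overall = overall)
}
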