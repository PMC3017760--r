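# Statistical layer: motif classes, bias tests, curve fits, regressions.

#' Canonical motif class of a primitive motif
#'
#' SSR surveys group motifs into strand/rotation equivalence classes
#' (CA = AC = GT = TG, GA = AG = CT = TC, AT = TA, GC = CG): the members of
#' a class are all rotations of the motif plus all rotations of its reverse
#' complement, deduplicated; the class label is the lexicographically
#' smallest member.
#'
#' @param motif primitive ACGT motif.
#' @return list with `label` and `members` (sorted character vector).
#' @examples
#' motif_class_members("AC")   # AC, CA, GT, TG
#' motif_class_members("AT")   # AT, TA
#' motif_class_members("A")    # A, T
#' @export
motif_class_members <- function(motif) {
  motif <- .check_dna(motif, what = "motif")
  if (!identical(primitive_motif(motif), motif))
    stop("motif must be primitive (no smaller repeating unit)")
  members <- sort(unique(c(rotations(motif), rotations(revcomp(motif)))))
  list(label = members[1L], members = members)
}

#' Canonical class labels for a vector of motifs
#' @param motifs character vector of primitive motifs.
#' @return character vector of class labels.
#' @export
motif_class_label <- function(motifs) {
  u <- unique(motifs)
  lab <- vapply(u, function(m) motif_class_members(m)$label, character(1))
  unname(lab[match(motifs, u)])
}

#' Starting-nucleotide preference test for one motif class
#'
#' Within a motif class every member should be equally frequent if there is
#' no preference for where a perfect array starts (and which strand it is
#' read from).  Tests the observed per-member counts against a uniform split
#' of the class total with a chi-square goodness-of-fit test
#' (df = class size - 1).
#'
#' @param member_counts named numeric vector: motif -> locus count.  The
#'   names must be exactly the members of one motif class (zeros allowed).
#' @return list with `class` (label), `observed`, `expected` (per-member
#'   class mean), `expected_rounded` (half-up, as printed in report tables),
#'   `statistic`, `df`, `p`.
#' @examples
#' starting_preference_test(c(TA = 48814, AT = 35558))
#' @export
starting_preference_test <- function(member_counts) {
  stopifnot(is.numeric(member_counts), !is.null(names(member_counts)),
            all(member_counts >= 0))
  cls <- motif_class_members(names(member_counts)[1L])
  if (!setequal(names(member_counts), cls$members))
    stop(sprintf("counts must cover exactly the class {%s}",
                 paste(cls$members, collapse = ",")))
  obs <- member_counts[cls$members]
  total <- sum(obs)
  if (total == 0) stop("zero class total: preference test undefined")
  k <- length(obs)
  expected <- total / k
  stat <- sum((obs - expected)^2 / expected)
  list(class = cls$label, observed = obs,
       expected = expected, expected_rounded = round_half_up(expected),
       statistic = stat, df = k - 1L,
       p = pchisq(stat, df = k - 1L, lower.tail = FALSE))
}

#' Expected end/middle split of repeat interruptions
#'
#' Under random placement, an interruption falls within the first or last
#' full repeat unit of a locus ("end") with probability `2 / repeat_number`,
#' and in an interior unit ("middle") otherwise.
#'
#' @param repeat_number repeat number of the locus bin (>= 2).
#' @param total observed interruption count for the bin.
#' @return named numeric vector `c(end =, middle =)` (unrounded).
#' @examples
#' end_middle_expected(5, 3717)   # end 1486.8, middle 2230.2
#' @export
end_middle_expected <- function(repeat_number, total) {
  stopifnot(length(repeat_number) == 1L, length(total) == 1L, total >= 0)
  if (repeat_number < 2) stop("repeat_number must be >= 2")
  c(end = total * 2 / repeat_number,
    middle = total * (repeat_number - 2) / repeat_number)
}

#' Test observed end/middle interruption counts against random placement
#'
#' 1-df chi-square goodness of fit on the unrounded [end_middle_expected()]
#' split; falls back to the exact binomial test when any expected cell is
#' below 5 (including the degenerate `repeat_number = 2` case where the
#' middle expectation is 0).
#'
#' @param end_obs,middle_obs observed counts.
#' @param repeat_number repeat number of the bin (>= 2).
#' @return list with `expected`, `statistic` (`NA` for the exact test), `p`,
#'   `method`.
#' @export
end_middle_test <- function(end_obs, middle_obs, repeat_number) {
  stopifnot(end_obs >= 0, middle_obs >= 0)
  total <- end_obs + middle_obs
  if (total == 0) stop("zero total count: end/middle test undefined")
  expected <- end_middle_expected(repeat_number, total)
  if (any(expected < 5)) {
    p <- binom.test(end_obs, total, p = 2 / repeat_number,
                    alternative = "two.sided")$p.value
    return(list(expected = expected, statistic = NA_real_, p = p,
                method = "binomial"))
  }
  obs <- c(end_obs, middle_obs)
  stat <- sum((obs - expected)^2 / expected)
  list(expected = expected, statistic = stat,
       p = pchisq(stat, df = 1, lower.tail = FALSE), method = "chisq")
}

#' Fit a heterozygosity-versus-repeat-number curve
#'
#' Least-squares fit of per-bin heterozygosity against repeat number.  The
#' exponential model is fitted as ordinary least squares on `log(y)`
#' (positive responses only), the pattern typically seen for small motif
#' sizes; larger motifs tend to fit a linear trend.
#'
#' @param points data.frame with columns `repeat_number` and `het`
#'   (percent heterozygosity per bin); at least 3 rows.
#' @param model `"linear"` or `"exponential"`.
#' @return list with `model`, `parameters` (slope/intercept, or rate/scale
#'   for the exponential where `y = scale * exp(rate * x)`), `r2`, `p`
#'   (two-sided, slope), `n` and the underlying `fit` (lm object).
#' @export
fit_het_curve <- function(points, model = c("linear", "exponential")) {
  model <- match.arg(model)
  stopifnot(is.data.frame(points),
            all(c("repeat_number", "het") %in% names(points)))
  points <- points[complete.cases(points[c("repeat_number", "het")]), ]
  if (nrow(points) < 3) stop("need at least 3 points to fit a curve")
  x <- points$repeat_number
  if (length(unique(x)) < 2) stop("degenerate x: all repeat numbers equal")
  if (model == "exponential") {
    if (any(points$het <= 0))
      stop("exponential model requires strictly positive responses")
    y <- log(points$het)
  } else {
    y <- points$het
  }
  fit <- lm(y ~ x)
  sm <- summary(fit)
  params <- if (model == "linear")
    c(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]))
  else
    c(rate = unname(coef(fit)[2L]), scale = exp(unname(coef(fit)[1L])))
  list(model = model, parameters = params, r2 = sm$r.squared,
       p = unname(sm$coefficients[2L, 4L]), n = nrow(points), fit = fit)
}

#' Choose between linear and exponential heterozygosity curves
#'
#' Fits both models (the exponential one only when all responses are
#' positive) and returns the fit with the better r-squared.
#'
#' @inheritParams fit_het_curve
#' @return the better [fit_het_curve()] result.
#' @export
select_het_model <- function(points) {
  lin <- fit_het_curve(points, "linear")
  if (any(points$het <= 0, na.rm = TRUE)) return(lin)
  expo <- fit_het_curve(points, "exponential")
  if (expo$r2 > lin$r2) expo else lin
}

#' Correlate SSR density with recombination rate across map intervals
#'
#' For each genetic-map interval computes the density of catalogued SSR loci
#' (loci/Mb, filtered by motif size) and the recombination rate (cM/Mb), then
#' fits a linear regression of density on recombination rate with 95%
#' confidence and prediction bands.
#'
#' @param loci catalogue data.frame (needs `seq_id`, `start`, `motif_size`).
#' @param intervals data.frame with columns `seq_id`, `phys_start`,
#'   `phys_end` (0-based physical span, nt) and `cm` (centiMorgans).
#' @param min_motif_size,max_motif_size motif size filter (default: motif
#'   sizes > 1, the microsatellite convention).
#' @param seq_lengths optional named vector of assembly sequence lengths;
#'   intervals extending outside the assembly are skipped with a warning.
#' @return list with `fit` (list: `slope`, `intercept`, `r2`, `p`, `n`,
#'   `lm`) and `table` (per-interval densities, rates and bands).
#' @export
density_recombination_correlation <- function(loci, intervals,
                                              min_motif_size = 2L,
                                              max_motif_size = Inf,
                                              seq_lengths = NULL) {
  stopifnot(all(c("seq_id", "phys_start", "phys_end", "cm") %in%
                names(intervals)))
  if (any(intervals$phys_end <= intervals$phys_start))
    stop("intervals must have phys_end > phys_start")
  if (any(intervals$cm < 0)) stop("cm must be non-negative")
  if (!is.null(seq_lengths)) {
    bad <- !(intervals$seq_id %in% names(seq_lengths)) |
      intervals$phys_end > seq_lengths[intervals$seq_id] |
      intervals$phys_start < 0
    bad[is.na(bad)] <- TRUE
    if (any(bad)) {
      warning(sprintf("skipping %d interval(s) outside the assembly", sum(bad)))
      intervals <- intervals[!bad, , drop = FALSE]
    }
  }
  if (nrow(intervals) < 3) stop("need at least 3 usable intervals")
  keep <- loci$motif_size >= min_motif_size & loci$motif_size <= max_motif_size
  loci <- loci[keep, , drop = FALSE]
  count <- mapply(function(sid, s, e)
    sum(loci$seq_id == sid & loci$start >= s & loci$start < e),
    intervals$seq_id, intervals$phys_start, intervals$phys_end)
  span_mb <- (intervals$phys_end - intervals$phys_start) / 1e6
  tab <- data.frame(intervals,
                    n_loci = as.integer(count),
                    density_per_mb = count / span_mb,
                    cm_per_mb = intervals$cm / span_mb,
                    stringsAsFactors = FALSE)
  fit <- lm(density_per_mb ~ cm_per_mb, data = tab)
  sm <- summary(fit)
  conf <- predict(fit, interval = "confidence", level = 0.95)
  # bands are computed at the observed intervals by design
  pred <- suppressWarnings(predict(fit, interval = "prediction", level = 0.95))
  tab$fit_density  <- conf[, "fit"]
  tab$conf_lo <- conf[, "lwr"]; tab$conf_hi <- conf[, "upr"]
  tab$pred_lo <- pred[, "lwr"]; tab$pred_hi <- pred[, "upr"]
  list(fit = list(slope = unname(coef(fit)[2L]),
                  intercept = unname(coef(fit)[1L]),
                  r2 = sm$r.squared,
                  p = unname(sm$coefficients[2L, 4L]),
                  n = nrow(tab), lm = fit),
       table = tab)
}

#' Flag scaffolds with unusual SSR abundance
#'
#' Two-sided exact binomial test of each scaffold's locus count against the
#' genome-wide rate scaled by scaffold length, Bonferroni-corrected.  A
#' scaffold is flagged `"+"` (overabundant) or `"-"` (underabundant) when its
#' corrected p-value falls below `alpha`.
#'
#' @param loci catalogue data.frame (needs `seq_id`, `motif_size`).
#' @param scaffold_sizes named numeric vector of scaffold lengths (nt); at
#'   least 2 scaffolds, all positive.
#' @param min_motif_size,max_motif_size motif size filter.
#' @param alpha family-wise significance level (default 0.05).
#' @param n_tests Bonferroni divisor; defaults to the number of scaffolds.
#'   Pass `length(scaffold_sizes) * n_motif_size_classes` when flagging
#'   several motif-size classes side by side.
#' @return data.frame: `seq_id`, `length`, `n_loci`, `expected`, `p`, `flag`.
#' @export
scaffold_abundance_flags <- function(loci, scaffold_sizes,
                                     min_motif_size = 1L,
                                     max_motif_size = Inf,
                                     alpha = 0.05, n_tests = NULL) {
  stopifnot(is.numeric(scaffold_sizes), !is.null(names(scaffold_sizes)))
  if (length(scaffold_sizes) < 2) stop("need at least 2 scaffolds")
  if (any(scaffold_sizes <= 0)) stop("zero-length scaffold rejected")
  if (is.null(n_tests)) n_tests <- length(scaffold_sizes)
  keep <- loci$motif_size >= min_motif_size & loci$motif_size <= max_motif_size
  loci <- loci[keep, , drop = FALSE]
  total_loci <- nrow(loci)
  total_len <- sum(scaffold_sizes)
  out <- lapply(names(scaffold_sizes), function(sid) {
    n <- sum(loci$seq_id == sid)
    prob <- scaffold_sizes[[sid]] / total_len
    expected <- total_loci * prob
    p <- if (total_loci == 0) 1 else
      binom.test(n, total_loci, p = prob, alternative = "two.sided")$p.value
    flag <- if (p < alpha / n_tests) (if (n > expected) "+" else "-") else ""
    data.frame(seq_id = sid, length = scaffold_sizes[[sid]], n_loci = n,
               expected = expected, p = p, flag = flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
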