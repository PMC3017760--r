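# Brute-force SSR enumerator, independent of the scanner implementation.
# For every (start, motif_size) pair it measures the maximal perfect run by
# direct periodicity comparison, then replays the documented selection rule
# (largest full-unit array wins, ties to the smaller motif, scan resumes
# after each accepted locus).
oracle_find_ssrs <- function(seq, min_repeats = 3L, max_motif = 100L) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  n <- length(chars)
  ok <- chars != "N"
  best_arr <- integer(n); best_m <- integer(n); best_rep <- integer(n)
  for (m in seq_len(min(max_motif, n %/% min_repeats))) {
    if (n - m < 1L) break
    eq <- chars[seq_len(n - m)] == chars[(m + 1L):n] &
      ok[seq_len(n - m)] & ok[(m + 1L):n]
    r <- integer(n - m)          # consecutive matches starting at i
    rl <- rle(eq)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    for (k in which(rl$values))
      r[starts[k]:ends[k]] <- ends[k] - (starts[k]:ends[k]) + 1L
    L <- m + r
    reps <- L %/% m
    arr <- m * reps
    cand <- which(reps >= min_repeats & ok[seq_len(n - m)])
    upd <- cand[arr[cand] > best_arr[cand]]
    best_arr[upd] <- arr[upd]; best_m[upd] <- m; best_rep[upd] <- reps[upd]
  }
  out_s <- integer(0); out_m <- integer(0); out_r <- integer(0)
  i <- 1L
  while (i <= n) {
    if (i <= length(best_arr) && best_arr[i] > 0L) {
      out_s <- c(out_s, i - 1L)
      out_m <- c(out_m, best_m[i])
      out_r <- c(out_r, best_rep[i])
      i <- i + best_arr[i]
    } else i <- i + 1L
  }
  if (!length(out_s))
    return(data.frame(start = integer(0), end = integer(0),
                      motif = character(0), motif_size = integer(0),
                      repeat_number = integer(0), array_length = integer(0),
                      stringsAsFactors = FALSE))
  data.frame(start = out_s, end = out_s + out_m * out_r,
             motif = substring(toupper(seq), out_s + 1L, out_s + out_m),
             motif_size = out_m, repeat_number = out_r,
             array_length = out_m * out_r, stringsAsFactors = FALSE)
}

random_dna <- function(n, p_at = 0.59, p_n = 0) {
  at <- p_at * (1 - p_n) / 2
  gc <- (1 - p_at) * (1 - p_n) / 2
  paste(sample(c("A", "T", "G", "C", "N"), n, replace = TRUE,
               prob = c(at, at, gc, gc, p_n)), collapse = "")
}

# Two-sided exact binomial p-value by direct summation over the outcome
# space (oracle for binom.test-based paths).
exact_binom_p <- function(x, n, p) {
  d <- dbinom(0:n, n, p)
  sum(d[d <= d[x + 1L] * (1 + 1e-7)])
}
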