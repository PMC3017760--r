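# A hand-built locus: 9 bp left flank + (GA)x10 + 9 bp right flank.
left <- "ACGTTGCAA"
arr <- strrep("GA", 10)
right <- "CCATGGTTA"
refseq <- paste0(left, arr, right)          # 38 bp
ref <- Biostrings::DNAStringSet(c(chr1 = refseq))
locus <- data.frame(seq_id = "chr1", start = 9L, end = 29L, motif = "GA",
                    motif_size = 2L, repeat_number = 10L,
                    array_length = 20L, stringsAsFactors = FALSE)

read_plus1 <- paste0(left, strrep("GA", 11), right)
read_minus1 <- paste0(left, strrep("GA", 9), right)
read_snp <- paste0(left, paste0("GAG", "C", substr(arr, 5, 20)), right)

mutate_at <- function(s, pos, to) {
  substr(s, pos, pos) <- to
  s
}

test_that("locus observations recount repeat units between exact anchors", {
  low_id <- refseq
  for (p in c(1, 2, 3, 35)) low_id <- mutate_at(low_id, p, "T")  # 34/38 id
  unanch <- mutate_at(refseq, 6, "T")  # mismatch inside the left anchor
  recs <- rbind(
    sam_record("perfect", "chr1", 1, "38M", refseq),
    sam_record("ins1", "chr1", 1, "29M2I9M", read_plus1),
    sam_record("del1", "chr1", 1, "27M2D9M", read_minus1),
    sam_record("snp", "chr1", 1, "38M", read_snp),
    sam_record("short", "chr1", 1, "20M", substr(refseq, 1, 20)),
    sam_record("lowid", "chr1", 1, "38M", low_id),
    sam_record("unanch", "chr1", 1, "38M", unanch),
    sam_record("secondary", "chr1", 1, "38M", refseq, flag = 256L))
  sam <- write_mini_sam(recs, c(chr1 = 38L))
  aln <- read_alignments(sam)
  expect_equal(length(aln), 7L)  # secondary alignment dropped on load

  obs <- extract_locus_observations(aln, locus, ref)
  expect_setequal(obs$observations$read_id,
                  c("perfect", "ins1", "del1", "snp"))
  got <- setNames(obs$observations$delta_units, obs$observations$read_id)
  expect_equal(got[["perfect"]], 0L)
  expect_equal(got[["ins1"]], 1L)
  expect_equal(got[["del1"]], -1L)
  expect_equal(got[["snp"]], 0L)
  expect_equal(unname(obs$skipped),
               c(1L, 1L, 1L))  # not_spanning, low_identity, unanchored

  expect_equal(obs$nrups$read_id, "snp")
  expect_equal(obs$nrups$kind, "substitution")
  expect_equal(obs$nrups$offset, 3L)
  expect_equal(obs$nrups$alt, "C")
})

test_that("non-unit indels become NRUPs with left-aligned placement", {
  # single-base deletion inside a dimer array is a non-unit NRUP; deleting
  # the G of unit 4 leaves an unambiguous AA junction at offset 6
  del_seq <- paste0(left, substr(arr, 1, 6), substr(arr, 8, 20), right)
  ins_seq <- paste0(left, substr(arr, 1, 7), "T", substr(arr, 8, 20), right)
  recs <- rbind(
    sam_record("d1a", "chr1", 1, "15M1D22M", del_seq),
    sam_record("d1b", "chr1", 1, "15M1D22M", del_seq),
    sam_record("i1", "chr1", 1, "16M1I22M", ins_seq))
  aln <- read_alignments(write_mini_sam(recs, c(chr1 = 38L)))
  obs <- extract_locus_observations(aln, locus, ref)
  expect_equal(obs$observations$delta_units, c(0L, 0L, 0L))
  nr <- obs$nrups
  expect_equal(nr$kind[nr$read_id == "d1a"], "deletion")
  expect_equal(nr$offset[nr$read_id == "d1a"], 6L)
  expect_equal(nr$kind[nr$read_id == "i1"], "insertion")

  # in a homopolymer every placement is equivalent: the call left-aligns to
  # the array start (and any indel there is unit-length, so it goes into
  # delta_units, not the NRUP list)
  hp_ref <- Biostrings::DNAStringSet(c(chr2 = paste0(left, strrep("A", 8),
                                                     right)))
  hp_locus <- list(seq_id = "chr2", start = 9L, end = 17L, motif = "A",
                   motif_size = 1L, repeat_number = 8L, array_length = 8L)
  hp_del <- paste0(left, strrep("A", 7), right)
  aln2 <- read_alignments(write_mini_sam(
    sam_record("hd", "chr2", 1, "9M1D16M", hp_del), c(chr2 = 26L)))
  obs2 <- extract_locus_observations(aln2, hp_locus, hp_ref)
  expect_equal(obs2$observations$delta_units, -1L)
  expect_equal(nrow(obs2$nrups), 0L)
})

test_that("genotype_locus applies the documented filter cascade", {
  ok_depth <- rep(8L, 20)
  obs_df <- function(deltas) data.frame(
    read_id = sprintf("r%d", seq_along(deltas)),
    delta_units = deltas, n_nrup = rep(0L, length(deltas)),
    stringsAsFactors = FALSE)

  g <- genotype_locus(obs_df(c(rep(0L, 6), rep(1L, 4))), locus, ok_depth)
  expect_equal(g$status, "het_unit")
  expect_equal(sort(g$alleles$delta_units), c(0L, 1L))

  g <- genotype_locus(obs_df(c(rep(0L, 7), 2L)), locus, ok_depth)
  expect_equal(g$status, "homozygous")
  expect_equal(g$n_singleton_repeat, 1L)

  g <- genotype_locus(obs_df(c(rep(0L, 4), rep(1L, 3), rep(-1L, 3))),
                      locus, ok_depth)
  expect_equal(g$status, "discarded_multiallelic")

  g <- genotype_locus(obs_df(c(rep(0L, 5), rep(3L, 4))), locus, ok_depth)
  expect_equal(g$status, "het_multistep")

  # alleles at +1/-1 differ by two units: multistep by allele difference
  g <- genotype_locus(obs_df(c(rep(1L, 5), rep(-1L, 4))), locus, ok_depth)
  expect_equal(g$status, "het_multistep")

  # coverage window violations make the locus unassayable
  expect_equal(genotype_locus(obs_df(rep(0L, 6)), locus,
                              c(rep(8L, 19), 3L))$status, "unassayable")
  expect_equal(genotype_locus(obs_df(rep(0L, 6)), locus,
                              c(rep(8L, 19), 17L))$status, "unassayable")
  expect_equal(genotype_locus(obs_df(rep(0L, 6)), locus,
                              rep(4L, 20))$status, "homozygous")
  expect_equal(genotype_locus(obs_df(rep(0L, 6)), locus,
                              rep(16L, 20))$status, "homozygous")
  expect_equal(genotype_locus(obs_df(integer(0)), locus, ok_depth)$status,
               "unassayable")

  # more than two supported base states at one site: discarded
  nr <- data.frame(read_id = c("a", "b", "c", "d"),
                   kind = "substitution", offset = 3L,
                   alt = c("C", "C", "T", "T"), stringsAsFactors = FALSE)
  g <- genotype_locus(list(observations = obs_df(rep(0L, 8)), nrups = nr),
                      locus, ok_depth)
  expect_equal(g$status, "discarded_multiallelic")

  # a single supported alternative state is a clean NRUP call
  g <- genotype_locus(list(observations = obs_df(rep(0L, 8)),
                           nrups = nr[nr$alt == "C", ]), locus, ok_depth)
  expect_equal(g$status, "homozygous")
  expect_equal(g$nrup_calls$position_class, "middle")
  expect_equal(g$nrup_calls$support, 2L)
})

test_that("support filters are conservative and observations are conserved", {
  set.seed(13)
  n_het <- function(deltas, ms) {
    g <- genotype_locus(data.frame(read_id = sprintf("r%d", seq_along(deltas)),
                                   delta_units = deltas, n_nrup = 0L),
                        locus, rep(8L, 20), min_support = ms)
    as.integer(g$status %in% c("het_unit", "het_multistep"))
  }
  for (i in 1:60) {
    # two observable states: the support filter alone decides, so raising
    # the consensus minimum can only remove het calls (with three or more
    # states the two-allele cap takes over and discards instead)
    deltas <- sample(c(0L, 0L, 0L, 1L), sample(4:14, 1), replace = TRUE)
    h <- vapply(1:3, function(ms) n_het(deltas, ms), integer(1))
    expect_true(all(diff(h) <= 0))  # raising support never adds het calls

    g <- genotype_locus(data.frame(read_id = sprintf("r%d", seq_along(deltas)),
                                   delta_units = deltas, n_nrup = 0L),
                        locus, rep(8L, 20))
    unsupported_ref <- sum(deltas == 0L) *
      (sum(deltas == 0L) < 2L)
    expect_equal(sum(g$alleles$support) + g$n_singleton_repeat +
                   unsupported_ref, g$n_obs)
  }
})

test_that("interruption position classes split at the terminal repeat units", {
  hp <- list(motif_size = 1L, repeat_number = 7L)
  expect_equal(classify_nrup_position(0L, hp), "end")
  expect_equal(classify_nrup_position(3L, hp), "middle")
  expect_equal(classify_nrup_position(6L, hp), "end")
  dimer <- list(motif_size = 2L, repeat_number = 8L)
  expect_equal(classify_nrup_position(14L, dimer), "end")
  expect_equal(classify_nrup_position(13L, dimer), "middle")
  expect_equal(classify_nrup_position(c(0L, 1L, 2L), dimer),
               c("end", "end", "middle"))
  expect_error(classify_nrup_position(16L, dimer), "range")
  expect_error(classify_nrup_position(-1L, dimer), "range")
})

test_that("error-free reads from a homozygous genome yield no variant calls", {
  cfg <- small_sim_config(seed = 19, error_rate = 0,
                          het_model = list(intercept = -50, slope = 0,
                                           class_mult = c(A = 1),
                                           max_p = 0.95),
                          nrup_rate = 0)
  sim <- generate_reference(cfg)
  sim <- diploidize(sim)
  expect_identical(as.character(sim$haplotype2), as.character(sim$reference))
  sim <- simulate_reads(sim, sam = tempfile(fileext = ".sam"))
  ctl <- catalog_genome(sim$reference)
  calls <- call_variants(sim$sam, ctl$loci, sim$reference)
  st <- calls$genotypes$status
  expect_true(all(st %in% c("homozygous", "unassayable")))
  expect_equal(nrow(calls$nrups), 0L)
  expect_equal(calls$log$n_singleton_repeat, 0L)
  expect_equal(calls$log$n_singleton_snp, 0L)
})

test_that("summaries bin heterozygosity by motif size, repeat number and class", {
  g <- data.frame(
    locus_id = sprintf("L%d", 1:10),
    seq_id = "s", start = 0L, end = 0L,
    motif = c(rep("A", 5), rep("GA", 5)),
    motif_size = c(rep(1L, 5), rep(2L, 5)),
    repeat_number = rep(c(8L, 8L, 8L, 8L, 10L), 2),
    array_length = 16L,
    status = c("homozygous", "het_unit", "het_multistep", "unassayable",
               "discarded_multiallelic",
               "homozygous", "homozygous", "het_unit", "het_unit",
               "homozygous"),
    stringsAsFactors = FALSE)
  s <- summarize_heterozygosity(g)
  hp8 <- s$by_bin[s$by_bin$motif_size == 1 & s$by_bin$repeat_number == 8, ]
  expect_equal(hp8$n_assayed, 3L)   # one unassayable excluded
  expect_equal(hp8$n_het, 2L)
  expect_equal(hp8$pct_multistep_of_het, 50)
  expect_equal(hp8$n_discarded, 0L)
  di <- s$by_class_total[s$by_class_total$class == "AG", ]
  expect_equal(di$n_het, 2L)
  expect_equal(di$pct_het, 100 * 2 / 5)
  expect_equal(di$pct_multistep_of_het, 0)
  # bins without heterozygotes report no multistep fraction
  hp10 <- s$by_bin[s$by_bin$motif_size == 1 & s$by_bin$repeat_number == 10, ]
  expect_true(is.na(hp10$pct_multistep_of_het))
  expect_equal(s$overall$discard_frequency, 1 / 9)
  # the published worked ratio: 2129 multistep of 17544 het loci
  expect_equal(round(proportion_of(2129, 17544), 2), 12.14)
})
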