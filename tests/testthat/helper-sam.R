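# Construct small SAM fixtures in code.
write_mini_sam <- function(records, seqlens, path = tempfile(fileext = ".sam")) {
  hdr <- c("@HD\tVN:1.6",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlens), seqlens))
  rec <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
                 records$qname, records$flag, records$rname, records$pos,
                 records$cigar, records$seq, strrep("I", nchar(records$seq)))
  writeLines(c(hdr, rec), path)
  path
}

sam_record <- function(qname, rname, pos, cigar, seq, flag = 0L) {
  data.frame(qname = qname, flag = flag, rname = rname, pos = pos,
             cigar = cigar, seq = seq, stringsAsFactors = FALSE)
}

# A small diploid simulation shared by several tests.
small_sim_config <- function(seed = 7, coverage = 12, ...) {
  sim_config(
    seed = seed, genome_length = 120000, n_scaffolds = 2,
    planted = data.frame(
      motif = c("A", "C", "AC", "AG", "AAC"),
      repeat_number = c(8L, 10L, 10L, 12L, 5L),
      count = c(60L, 60L, 50L, 40L, 30L),
      stringsAsFactors = FALSE),
    coverage = coverage, ...)
}
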