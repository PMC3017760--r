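# End-to-end orchestration: simulate (optional) -> catalogue -> genotype ->
# statistics, with report tables written as TSV/JSON.

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full SSR survey pipeline
#'
#' Executes the stages in order and writes all module outputs plus report
#' tables: the locus catalogue and summary, per-locus genotypes, binned
#' heterozygosity/multistep series, starting-preference tests per motif
#' class, observed-versus-expected end/middle NRUP positions, scaffold
#' abundance flags and the recombination-density regression.  With
#' `mode = "synthetic"` the inputs are generated by the simulator first and
#' the truth tables are written alongside.
#'
#' @param config a list, or path to a YAML file, with elements:
#'   * `mode`: `"synthetic"` (default) or `"real"`;
#'   * `out_dir`: output directory (created);
#'   * `sim`: arguments for [sim_config()] (synthetic mode);
#'   * `fasta`, `sam`, `map`: input paths (real mode; `map` optional TSV
#'     with columns seq_id, phys_start, phys_end, cm);
#'   * `catalog`: `min_repeats`, `max_motif` overrides;
#'   * `caller`: `flank`, `min_identity`, `min_depth`, `max_depth`,
#'     `min_support` overrides;
#'   * `map_mode`: `"independent"` or `"coupled"` (synthetic mode).
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with every stage result: `catalog`, `calls`,
#'   `het`, `stats`, and in synthetic mode `sim`; plus `files`, the named
#'   vector of written paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$out_dir))
  mode <- config$mode %||% "synthetic"
  say <- if (quiet) function(...) invisible() else .msg
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  stage <- function(name, expr) {
    say("stage %s", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  sim <- NULL
  if (mode == "synthetic") {
    cfg <- do.call(sim_config, config$sim %||% list())
    sim <- stage("simulate", {
      s <- generate_reference(cfg)
      s <- diploidize(s)
      s <- simulate_reads(s, fastq = file.path(out, "reads.fastq"),
                          sam = file.path(out, "truth.sam"))
      Biostrings::writeXStringSet(s$reference,
                                  file.path(out, "reference.fasta"))
      .write_tsv(s$truth, file.path(out, "truth_loci.tsv"))
      s
    })
    fasta <- file.path(out, "reference.fasta")
    sam <- sim$sam
    map_tbl <- generate_map(sim, mode = config$map_mode %||% "independent")
    files <- c(files, reference = fasta, reads = sim$fastq, sam = sam,
               truth = file.path(out, "truth_loci.tsv"))
  } else {
    fasta <- config$fasta
    sam <- config$sam
    map_tbl <- if (!is.null(config$map))
      read.table(config$map, sep = "\t", header = TRUE,
                 stringsAsFactors = FALSE)
    else NULL
    if (is.null(fasta) || !file.exists(fasta)) stop("missing input: fasta")
    if (is.null(sam) || !file.exists(sam)) stop("missing input: sam")
  }

  cat_par <- config$catalog %||% list()
  ctl <- stage("catalog", catalog_genome(
    fasta, min_repeats = cat_par$min_repeats %||% 3L,
    max_motif = cat_par$max_motif %||% 100L))
  files["catalog"] <- .write_tsv(ctl$loci, file.path(out, "catalog.tsv"))
  jsonlite::write_json(
    list(counts_by_motif_size = as.list(ctl$summary$counts_by_motif_size),
         total_loci = ctl$summary$total_loci,
         bases_covered = ctl$summary$bases_covered,
         genome_size = ctl$summary$genome_size,
         fraction_covered = ctl$summary$fraction_covered),
    file.path(out, "catalog_summary.json"), auto_unbox = TRUE, digits = NA)
  files["catalog_summary"] <- file.path(out, "catalog_summary.json")

  cp <- config$caller %||% list()
  calls <- stage("genotype", call_variants(
    sam, ctl$loci, fasta,
    flank = cp$flank %||% 5L, min_identity = cp$min_identity %||% 0.90,
    min_depth = cp$min_depth %||% 4L, max_depth = cp$max_depth %||% 16L,
    min_support = cp$min_support %||% 2L))
  files["genotypes"] <- .write_tsv(calls$genotypes,
                                   file.path(out, "genotypes.tsv"))
  files["nrups"] <- .write_tsv(calls$nrups, file.path(out, "nrups.tsv"))
  jsonlite::write_json(calls$log, file.path(out, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)

  het <- stage("summarize", summarize_heterozygosity(calls))
  files["het_by_bin"] <- .write_tsv(het$by_bin,
                                    file.path(out, "het_by_bin.tsv"))
  files["het_by_class"] <- .write_tsv(het$by_class,
                                      file.path(out, "het_by_class.tsv"))
  files["het_overall"] <- .write_tsv(het$overall,
                                     file.path(out, "het_overall.tsv"))

  stats <- stage("stats", {
    res <- list()
    # starting-nucleotide preference per motif class (dimers and trimers)
    loci <- ctl$loci
    small <- loci[loci$motif_size %in% c(1L, 2L, 3L), , drop = FALSE]
    if (nrow(small)) {
      small$class <- motif_class_label(small$motif)
      pref <- lapply(split(small$motif, small$class), function(motifs) {
        members <- motif_class_members(motifs[1L])$members
        counts <- table(factor(motifs, levels = members))
        r <- starting_preference_test(setNames(as.numeric(counts),
                                               names(counts)))
        data.frame(class = r$class,
                   members = paste(names(r$observed), collapse = ","),
                   observed = paste(r$observed, collapse = ","),
                   expected = r$expected,
                   expected_rounded = r$expected_rounded,
                   statistic = r$statistic, df = r$df, p = r$p,
                   stringsAsFactors = FALSE)
      })
      res$starting_preference <- do.call(rbind, pref)
      rownames(res$starting_preference) <- NULL
    }
    # end/middle NRUP positions per motif size x repeat number
    if (nrow(calls$nrups)) {
      nr <- calls$nrups
      keys <- split(nr, paste(nr$motif_size, nr$repeat_number, sep = "\r"))
      em <- lapply(keys, function(df) {
        endo <- sum(df$position_class == "end")
        mido <- sum(df$position_class == "middle")
        tst <- end_middle_test(endo, mido, df$repeat_number[1L])
        data.frame(motif_size = df$motif_size[1L],
                   repeat_number = df$repeat_number[1L],
                   end_obs = endo, middle_obs = mido,
                   end_exp = tst$expected["end"],
                   middle_exp = tst$expected["middle"],
                   p = tst$p, stringsAsFactors = FALSE)
      })
      res$end_middle <- do.call(rbind, em)
      res$end_middle <- res$end_middle[order(res$end_middle$motif_size,
                                             res$end_middle$repeat_number), ]
      rownames(res$end_middle) <- NULL
    }
    # heterozygosity-vs-repeat-number curve fits per motif size
    hb <- het$by_bin[!is.na(het$by_bin$pct_het), , drop = FALSE]
    fits <- lapply(split(hb, hb$motif_size), function(df) {
      pts <- data.frame(repeat_number = df$repeat_number, het = df$pct_het)
      if (nrow(pts) < 3 || length(unique(pts$repeat_number)) < 2)
        return(NULL)
      f <- tryCatch(select_het_model(pts), error = function(e) NULL)
      if (is.null(f)) return(NULL)
      data.frame(motif_size = df$motif_size[1L], model = f$model,
                 r2 = f$r2, p = f$p, n = f$n, stringsAsFactors = FALSE)
    })
    fits <- fits[!vapply(fits, is.null, logical(1))]
    if (length(fits)) res$het_fits <- do.call(rbind, fits)
    # scaffold abundance flags
    sizes <- setNames(Biostrings::width(Biostrings::readDNAStringSet(fasta)),
                      sub("\\s.*$", "",
                          names(Biostrings::readDNAStringSet(fasta))))
    if (length(sizes) >= 2)
      res$scaffold_flags <- scaffold_abundance_flags(loci, sizes)
    # recombination correlation
    if (!is.null(map_tbl))
      res$recombination <- density_recombination_correlation(
        loci, map_tbl, seq_lengths = sizes)
    res
  })
  if (!is.null(stats$starting_preference))
    files["starting_preference"] <- .write_tsv(
      stats$starting_preference, file.path(out, "starting_preference.tsv"))
  if (!is.null(stats$end_middle))
    files["end_middle"] <- .write_tsv(stats$end_middle,
                                      file.path(out, "end_middle.tsv"))
  if (!is.null(stats$het_fits))
    files["het_fits"] <- .write_tsv(stats$het_fits,
                                    file.path(out, "het_fits.tsv"))
  if (!is.null(stats$scaffold_flags))
    files["scaffold_flags"] <- .write_tsv(stats$scaffold_flags,
                                          file.path(out, "scaffold_flags.tsv"))
  if (!is.null(stats$recombination)) {
    files["recombination"] <- .write_tsv(
      stats$recombination$table, file.path(out, "recombination.tsv"))
    jsonlite::write_json(stats$recombination$fit[c("slope", "intercept",
                                                   "r2", "p", "n")],
                         file.path(out, "recombination_fit.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  say("pipeline complete: %d loci, %d assayed", nrow(ctl$loci),
      sum(calls$genotypes$status != "unassayable"))
  invisible(list(catalog = ctl, calls = calls, het = het, stats = stats,
                 sim = sim, map = map_tbl, files = files))
}
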