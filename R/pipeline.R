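#' Run the full paired-metastasis comparison pipeline
#'
#' Orchestrates every stage on a trio (matched normal + two metastases):
#' genotyping of all three pileup tables, the somatic filtering cascade
#' per metastasis, the concordance table, mutation spectrum and
#' dinucleotide scan, pseudo-CGH windows / log2 ratios / CBS
#' segmentation / DLRS / between-metastasis difference calling, LOH
#' binning with copy-neutral flagging, and gene-set enrichment on the
#' merged SNV+CNV gene hits. All thresholds default to the method's
#' standard values. Rerunning with the same inputs and seed reproduces
#' every output exactly.
#'
#' @param trio a `met_trio` from [generate_trio()], or an equivalent
#'   list with the same components read from disk.
#' @param out_dir optional directory; when given, all reports are
#'   written there along with a JSON manifest (thresholds, seed,
#'   package version, output checksums).
#' @param panel,known_sites common-variant filtering inputs (see
#'   [filter_known()]); `NULL` disables that stage's removals.
#' @param min_mpg,min_ratio genotype quality gate.
#' @param reads_per_window pseudo-CGH block size.
#' @param diff_threshold log2 difference for a copy-number difference
#'   call (strict).
#' @param bin_width,min_sites LOH bin geometry.
#' @param cbs_alpha,n_permutations,min_width CBS parameters.
#' @param enrich_alpha adjusted-p significance level.
#' @param seed integer seed covering every stochastic step (CBS
#'   permutations).
#' @return list of class `pairmet_run` with components `genotypes`,
#'   `somatic`, `concordance`, `spectrum`, `dinucleotides`, `windows`,
#'   `profiles`, `segments`, `dlrs`, `diff`, `loh`, `enrichment`,
#'   `shared_sets`, `manifest`.
#' @export
run_pipeline <- function(trio, out_dir = NULL,
                         panel = NULL, known_sites = NULL,
                         min_mpg = 10, min_ratio = 0.5,
                         reads_per_window = 1000, diff_threshold = 0.35,
                         bin_width = 5e6, min_sites = 10,
                         cbs_alpha = 0.01, n_permutations = 1000,
                         min_width = 2, enrich_alpha = 0.05, seed = 1) {
  set.seed(seed)
  gts <- lapply(trio$pileups, call_genotypes)

  som1 <- somatic_cascade(gts$met1, gts$met2, gts$normal, panel, known_sites,
                          trio$genes, trio$reference,
                          min_mpg = min_mpg, min_ratio = min_ratio)
  som2 <- somatic_cascade(gts$met2, gts$met1, gts$normal, panel, known_sites,
                          trio$genes, trio$reference,
                          min_mpg = min_mpg, min_ratio = min_ratio)

  conc <- compare_metastases(som1$variants, som2$variants)
  all_vars <- rbind(som1$variants, som2$variants)
  all_vars <- all_vars[!duplicated(paste(all_vars$chrom, all_vars$pos,
                                         all_vars$ref, all_vars$alt)), ]
  spectrum <- mutation_spectrum(all_vars)
  dinucs <- find_dinucleotides(all_vars)

  windows <- define_windows(trio$reads$normal, reads_per_window)
  profiles <- list(met1 = compute_log2_ratios(windows, trio$reads$met1),
                   met2 = compute_log2_ratios(windows, trio$reads$met2))
  segments <- lapply(profiles, segment_profile, alpha = cbs_alpha,
                     n_permutations = n_permutations, min_width = min_width)
  noise <- lapply(profiles, dlrs)
  diffs <- diff_segments(segments$met1, segments$met2, windows,
                         threshold = diff_threshold)

  loh <- list(
    met1 = flag_cn_loh(loh_bins(gts$normal, gts$met1, trio$chrom_lengths,
                                bin_width, min_sites, min_mpg, min_ratio),
                       segments$met1),
    met2 = flag_cn_loh(loh_bins(gts$normal, gts$met2, trio$chrom_lengths,
                                bin_width, min_sites, min_mpg, min_ratio),
                       segments$met2))

  universe <- unique(trio$genes$gene)
  enr <- NULL; shared <- NULL
  if (length(trio$gene_sets)) {
    enr <- list(
      met1 = enrich(merge_gene_hits(som1$variants, segments$met1,
                                    trio$genes),
                    trio$gene_sets, universe, enrich_alpha),
      met2 = enrich(merge_gene_hits(som2$variants, segments$met2,
                                    trio$genes),
                    trio$gene_sets, universe, enrich_alpha))
    shared <- shared_enriched(enr$met1, enr$met2)
  }

  manifest <- list(
    package = "pairmet",
    version = as.character(utils::packageVersion("pairmet")),
    seed = seed,
    thresholds = list(min_mpg = min_mpg, min_ratio = min_ratio,
                      reads_per_window = reads_per_window,
                      diff_threshold = diff_threshold,
                      bin_width = bin_width, min_sites = min_sites,
                      cbs_alpha = cbs_alpha,
                      n_permutations = n_permutations,
                      enrich_alpha = enrich_alpha),
    stages = list(concordance = "compare_metastases",
                  spectrum = "mutation_spectrum",
                  segments = "segment_profile", dlrs = "dlrs",
                  diff = "diff_segments", loh = "loh_bins/flag_cn_loh",
                  enrichment = "enrich"),
    tallies = list(met1 = som1$tally, met2 = som2$tally))

  run <- list(genotypes = gts,
              somatic = list(met1 = som1, met2 = som2),
              concordance = conc, spectrum = spectrum,
              dinucleotides = dinucs,
              windows = windows, profiles = profiles, segments = segments,
              dlrs = noise, diff = diffs, loh = loh,
              enrichment = enr, shared_sets = shared,
              manifest = manifest)
  class(run) <- "pairmet_run"

  if (!is.null(out_dir)) {
    run$manifest$checksums <- .write_run(run, out_dir)
    jsonlite::write_json(run$manifest,
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         dataframe = "rows")
  }
  run
}

.write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  bed <- function(df, name, cols) {
    path <- file.path(out_dir, name)
    out <- data.frame(chrom = df$chrom, start = df$start - 1L,
                      end = df$end, df[, cols, drop = FALSE])
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    path
  }
  paths <- c(
    tsv(run$concordance, "concordance.tsv"),
    tsv(data.frame(class = names(run$spectrum$counts),
                   count = as.integer(run$spectrum$counts)),
        "spectrum.tsv"),
    tsv(run$dinucleotides, "dinucleotides.tsv"),
    tsv(run$somatic$met1$variants, "somatic_met1.tsv"),
    tsv(run$somatic$met2$variants, "somatic_met2.tsv"),
    tsv(cbind(run$windows,
              met1_log2 = run$profiles$met1$log2ratio,
              met2_log2 = run$profiles$met2$log2ratio), "windows.tsv"),
    bed(run$segments$met1, "segments_met1.bed", "mean_log2"),
    bed(run$segments$met2, "segments_met2.bed", "mean_log2"),
    if (nrow(run$diff$regions))
      bed(run$diff$regions, "diff_regions.bed", "mean_delta")
    else tsv(run$diff$regions, "diff_regions.bed"),
    tsv(run$loh$met1, "loh_met1.tsv"),
    tsv(run$loh$met2, "loh_met2.tsv"),
    if (!is.null(run$enrichment)) tsv(run$enrichment$met1, "enrich_met1.tsv"),
    if (!is.null(run$enrichment)) tsv(run$enrichment$met2, "enrich_met2.tsv"),
    tsv(window_summary(run$windows), "window_summary.tsv"))
  sums <- tools::md5sum(paths)
  as.list(stats::setNames(unname(sums), basename(paths)))
}

#' @export
print.pairmet_run <- function(x, ...) {
  cat("pairmet pipeline run\n")
  cat(sprintf("  somatic variants: met1 %d, met2 %d\n",
              nrow(x$somatic$met1$variants), nrow(x$somatic$met2$variants)))
  both <- x$concordance$pct_both[x$concordance$class == "NS+S"]
  cat(sprintf("  concordance (NS+S): %.2f%% shared\n", both))
  cat(sprintf("  windows: %d; DLRS met1 %.3f, met2 %.3f\n",
              nrow(x$windows), x$dlrs$met1, x$dlrs$met2))
  cat(sprintf("  copy-number difference: %.2f%% of windows\n",
              x$diff$percent_windows))
  invisible(x)
}
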