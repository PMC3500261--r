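#' Build a common-variant panel from population calls
#'
#' Filters a population call set (e.g. a low-coverage multi-sample
#' release genotyped by several analysis methods) down to high-confidence
#' common variants: a record is kept iff it was called by at least
#' `min_callers` of the project's analysis methods AND its minor allele
#' frequency is strictly above `min_maf`.
#'
#' @param population_calls data frame with columns `chrom`, `pos`, `alt`,
#'   `caller_support` (0..4) and `maf` (0..0.5). Records with missing
#'   fields are skipped and tallied in the `n_skipped` attribute.
#' @param min_callers minimum analysis-method support (default 3).
#' @param min_maf MAF must exceed this (strict; default 0.05).
#' @return data frame of retained records, attribute `n_skipped`.
#' @export
build_common_panel <- function(population_calls, min_callers = 3,
                               min_maf = 0.05) {
  req <- c("chrom", "pos", "alt", "caller_support", "maf")
  stopifnot(all(req %in% names(population_calls)))
  ok <- stats::complete.cases(population_calls[, req])
  n_skipped <- sum(!ok)
  df <- population_calls[ok, , drop = FALSE]
  keep <- df$caller_support >= min_callers & df$maf > min_maf
  panel <- df[keep, , drop = FALSE]
  rownames(panel) <- NULL
  attr(panel, "n_skipped") <- n_skipped
  panel
}

.variant_key <- function(df) paste(df$chrom, df$pos, df$alt, sep = ":")

#' Remove variants present in known-site panels
#'
#' Exact (chrom, pos, alt) set difference against a common-variant panel
#' and/or an extra known-sites table (e.g. a dbSNP extract).
#'
#' @param variants data frame with `chrom`, `pos`, `alt`.
#' @param panel data frame from [build_common_panel()]; may be `NULL`.
#' @param known_sites additional data frame with `chrom`, `pos`, `alt`;
#'   may be `NULL`.
#' @return `variants` minus the matched records; attribute `n_removed`.
#' @export
filter_known <- function(variants, panel = NULL, known_sites = NULL) {
  known <- character(0)
  if (!is.null(panel) && nrow(panel)) known <- c(known, .variant_key(panel))
  if (!is.null(known_sites) && nrow(known_sites))
    known <- c(known, .variant_key(known_sites))
  keep <- !(.variant_key(variants) %in% known)
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Per-sample genotype quality gate
#'
#' A position is reliably evaluable only when the genotype call is
#' confident in every sample of the trio: MPG score at least `min_mpg`
#' and MPG/coverage ratio strictly above `min_ratio` in both matched
#' tumors and the normal.
#'
#' @param mpg,ratio numeric vectors (one element per sample, or one per
#'   position when used vectorised on a single sample).
#' @param min_mpg minimum MPG score (default 10, inclusive).
#' @param min_ratio MPG/coverage ratio must exceed this (strict,
#'   default 0.5).
#' @return logical; `NA` mpg or ratio (uncovered position) fails.
#' @export
quality_pass <- function(mpg, ratio, min_mpg = 10, min_ratio = 0.5) {
  ok <- mpg >= min_mpg & ratio > min_ratio
  ok[is.na(ok)] <- FALSE
  ok
}

#' Decide somatic status from a tumor/normal genotype pair
#'
#' A candidate alternate allele is somatic iff it is present in the
#' tumor genotype and absent from the matched normal genotype (allele-
#' level comparison, so a tumor-homozygous allele that was one of two
#' normal heterozygous alleles is germline at that allele, while the
#' loss itself is picked up by [classify_zygosity()]).
#'
#' @param tumor_gt,normal_gt two-character genotype strings.
#' @param alt the candidate alternate allele.
#' @return logical.
#' @export
is_somatic <- function(tumor_gt, normal_gt, alt) {
  t_all <- strsplit(tumor_gt, "")
  n_all <- strsplit(normal_gt, "")
  mapply(function(t, n, a) a %in% t && !(a %in% n), t_all, n_all, alt,
         USE.NAMES = FALSE)
}

#' Classify tumor zygosity at a variant site
#'
#' Sites are labelled `"heterozygous"` when the tumor genotype carries
#' two different alleles and `"LOH"` when the tumor is homozygous —
#' either homozygous for the alternate allele or reduced to one allele
#' of a normal heterozygote (loss of heterozygosity).
#'
#' @param normal_gt,tumor_gt two-character genotype strings.
#' @return character: `"heterozygous"` or `"LOH"`.
#' @export
classify_zygosity <- function(normal_gt, tumor_gt) {
  t_all <- strsplit(tumor_gt, "")
  ifelse(vapply(t_all, function(a) a[1] != a[2], logical(1)),
         "heterozygous", "LOH")
}

#' Annotate coding effects against a gene model
#'
#' Classifies each variant by its consequence on the coding sequence.
#' Substitutions inside an exon are translated through the standard
#' genetic code (stop gain is `nonsense`, amino-acid change `missense`,
#' silent `synonymous`); intronic positions within `splice_window` bp of
#' an exon boundary are `splice_site`; insertions/deletions overlapping
#' an exon are `frameshift` or `inframe_indel` by length modulo 3.
#' In-gene positions beyond the splice window are `intronic` and
#' positions outside every gene are `intergenic`; both are excluded from
#' non-synonymous/synonymous counting downstream.
#'
#' @param variants data frame with `chrom`, `pos`, `ref`, `alt`
#'   (multi-base ref or alt marks an indel).
#' @param gene_model data frame of exon records: `gene`, `chrom`,
#'   `strand` ("+"/"-"), `start`, `end` (1-based inclusive). Exon
#'   lengths per gene must sum to a multiple of 3.
#' @param reference a [Biostrings::DNAStringSet] named by chromosome (or
#'   a named character vector of chromosome sequences).
#' @param splice_window bp into the intron counted as splice site
#'   (default 2, the canonical dinucleotide).
#' @return `variants` with `gene` and `effect` columns appended.
#' @export
annotate_effect <- function(variants, gene_model, reference,
                            splice_window = 2) {
  ref_seqs <- .as_ref_strings(reference)
  genes <- split(gene_model, gene_model$gene)
  cds_cache <- new.env(parent = emptyenv())
  n <- nrow(variants)
  gene_out <- rep(NA_character_, n)
  effect <- rep("intergenic", n)
  for (i in seq_len(n)) {
    chrom <- variants$chrom[i]; pos <- variants$pos[i]
    vref <- variants$ref[i]; valt <- variants$alt[i]
    hit <- NULL
    for (g in genes) {
      if (g$chrom[1] != chrom) next
      if (pos >= min(g$start) - splice_window &&
          pos <= max(g$end) + splice_window) { hit <- g; break }
    }
    if (is.null(hit)) next
    gene_out[i] <- hit$gene[1]
    in_exon <- any(pos >= hit$start & pos <= hit$end)
    is_indel <- nchar(vref) != nchar(valt)
    if (is_indel) {
      if (in_exon) {
        effect[i] <- if ((abs(nchar(vref) - nchar(valt)) %% 3) == 0)
          "inframe_indel" else "frameshift"
      } else effect[i] <- "intronic"
      next
    }
    if (!in_exon) {
      near <- any((pos >= hit$start - splice_window & pos < hit$start) |
                  (pos > hit$end & pos <= hit$end + splice_window))
      effect[i] <- if (near) "splice_site" else "intronic"
      next
    }
    effect[i] <- .codon_effect(hit, pos, valt, ref_seqs, cds_cache)
  }
  variants$gene <- gene_out
  variants$effect <- effect
  variants
}

.as_ref_strings <- function(reference) {
  if (is.character(reference)) return(reference)
  stats::setNames(as.character(reference), names(reference))
}

# translate the ref and alt codon of an exonic SNV
.codon_effect <- function(exons, pos, alt, ref_seqs, cache) {
  exons <- exons[order(exons$start), ]
  key <- exons$gene[1]
  if (is.null(cache[[key]])) {
    seqs <- vapply(seq_len(nrow(exons)), function(j)
      substr(ref_seqs[[exons$chrom[j]]], exons$start[j], exons$end[j]),
      character(1))
    cds <- paste(seqs, collapse = "")
    if (exons$strand[1] == "-") cds <- .revcomp(cds)
    cache[[key]] <- cds
  }
  cds <- cache[[key]]
  # position within the genomic-order concatenation
  prior <- 0L
  for (j in seq_len(nrow(exons))) {
    if (pos >= exons$start[j] && pos <= exons$end[j]) {
      offset <- prior + (pos - exons$start[j] + 1L)
      break
    }
    prior <- prior + (exons$end[j] - exons$start[j] + 1L)
  }
  total <- sum(exons$end - exons$start + 1L)
  if (exons$strand[1] == "-") {
    cds_pos <- total - offset + 1L
    alt <- .revcomp(alt)
  } else cds_pos <- offset
  codon_i <- (cds_pos - 1L) %/% 3L
  within <- (cds_pos - 1L) %% 3L + 1L
  codon <- substr(cds, codon_i * 3L + 1L, codon_i * 3L + 3L)
  alt_codon <- codon
  substr(alt_codon, within, within) <- alt
  code <- Biostrings::GENETIC_CODE
  aa_ref <- code[[codon]]
  aa_alt <- code[[alt_codon]]
  if (aa_alt == "*" && aa_ref != "*") "nonsense"
  else if (aa_alt == aa_ref) "synonymous"
  else "missense"
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Run the full somatic filtering cascade for one metastasis
#'
#' Candidate variants are every confident non-reference tumor genotype;
#' the cascade then (1) removes known/common germline sites by exact
#' position+allele match, (2) applies the trio-wide quality gate (MPG
#' and MPG/coverage thresholds in the tumor under test, the other
#' metastasis and the normal), (3) removes alleles present in the
#' matched normal, and finally annotates zygosity class and coding
#' effect. Variant conservation holds at every stage: input = passed +
#' failed, with per-reason tallies returned alongside.
#'
#' @param tumor_calls genotype table for the metastasis under test
#'   (from [call_genotypes()]).
#' @param other_tumor_calls genotype table for the paired metastasis.
#' @param normal_calls genotype table for the matched normal.
#' @param panel,known_sites passed to [filter_known()].
#' @param gene_model,reference,splice_window passed to
#'   [annotate_effect()]; `gene_model = NULL` skips annotation.
#' @param min_mpg,min_ratio quality gate thresholds (see
#'   [quality_pass()]).
#' @return list with `variants` (data frame: chrom, pos, ref, alt,
#'   zygosity, gene, effect, per-sample mpg/ratio) and `tally` (data
#'   frame of per-stage input/passed/failed counts).
#' @export
somatic_cascade <- function(tumor_calls, other_tumor_calls, normal_calls,
                            panel = NULL, known_sites = NULL,
                            gene_model = NULL, reference = NULL,
                            min_mpg = 10, min_ratio = 0.5,
                            splice_window = 2) {
  cand <- candidate_variants(tumor_calls)
  tally <- data.frame(stage = "candidates", input = nrow(cand),
                      passed = nrow(cand), failed = 0L)

  kept <- filter_known(cand, panel, known_sites)
  tally <- rbind(tally, data.frame(
    stage = "filter_known", input = nrow(cand),
    passed = nrow(kept), failed = attr(kept, "n_removed")))

  key <- function(df) paste(df$chrom, df$pos)
  idx_t <- match(key(kept), key(tumor_calls))
  idx_o <- match(key(kept), key(other_tumor_calls))
  idx_n <- match(key(kept), key(normal_calls))
  qp <- quality_pass(tumor_calls$mpg[idx_t], tumor_calls$mpg_cov_ratio[idx_t],
                     min_mpg, min_ratio) &
        quality_pass(other_tumor_calls$mpg[idx_o],
                     other_tumor_calls$mpg_cov_ratio[idx_o],
                     min_mpg, min_ratio) &
        quality_pass(normal_calls$mpg[idx_n],
                     normal_calls$mpg_cov_ratio[idx_n],
                     min_mpg, min_ratio)
  qp[is.na(qp)] <- FALSE  # uncovered in some sample
  hq <- kept[qp, , drop = FALSE]
  tally <- rbind(tally, data.frame(
    stage = "quality_filter", input = nrow(kept),
    passed = nrow(hq), failed = sum(!qp)))

  idx_t <- match(key(hq), key(tumor_calls))
  idx_n <- match(key(hq), key(normal_calls))
  som <- is_somatic(tumor_calls$genotype[idx_t],
                    normal_calls$genotype[idx_n], hq$alt)
  out <- hq[som, , drop = FALSE]
  tally <- rbind(tally, data.frame(
    stage = "normal_subtraction", input = nrow(hq),
    passed = nrow(out), failed = sum(!som)))

  idx_t <- match(key(out), key(tumor_calls))
  idx_n <- match(key(out), key(normal_calls))
  out$zygosity <- if (nrow(out)) classify_zygosity(
    normal_calls$genotype[idx_n], tumor_calls$genotype[idx_t]) else character(0)
  out$tumor_mpg <- tumor_calls$mpg[idx_t]
  out$tumor_ratio <- tumor_calls$mpg_cov_ratio[idx_t]
  out$normal_genotype <- normal_calls$genotype[idx_n]
  out$tumor_genotype <- tumor_calls$genotype[idx_t]
  if (!is.null(gene_model)) {
    out <- annotate_effect(out, gene_model, reference, splice_window)
  }
  rownames(out) <- NULL
  list(variants = out, tally = tally)
}

#' Candidate variant positions from a genotype table
#'
#' One record per non-reference allele of each confident genotype call
#' (no-calls excluded); indel alleles are passed through untouched.
#'
#' @param calls genotype table from [call_genotypes()].
#' @return data frame `chrom`, `pos`, `ref`, `alt`.
#' @export
candidate_variants <- function(calls) {
  called <- calls[!is.na(calls$genotype), , drop = FALSE]
  alleles <- strsplit(called$genotype, "")
  rows <- lapply(seq_len(nrow(called)), function(i) {
    alt <- setdiff(unique(alleles[[i]]), called$ref[i])
    if (!length(alt)) return(NULL)
    data.frame(chrom = called$chrom[i], pos = called$pos[i],
               ref = called$ref[i], alt = alt, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0))
  rownames(out) <- NULL
  out
}
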