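#' Configuration for a synthetic matched normal/metastasis trio
#'
#' Describes a simulated patient: one matched normal and two anatomically
#' distinct metastases derived from a common founder clone. Founder
#' mutations are planted in both metastases, private mutations in exactly
#' one, so the expected mutation concordance is
#' `n_founder / (n_founder + 2 * n_private)`. The substitution spectrum
#' is ultraviolet-biased (a configurable fraction of C>T changes at C:G
#' pairs plus adjacent CC>TT dinucleotide events), and copy-number and
#' LOH segments are planted per metastasis with known log2 ratios.
#'
#' @param genome_length bp per chromosome.
#' @param n_chromosomes number of chromosomes (named chr1, chr2, ...).
#' @param n_genes protein-coding genes, placed without overlap.
#' @param n_founder_mutations somatic substitutions shared by both
#'   metastases.
#' @param n_private_mutations_per_met substitutions private to each
#'   metastasis; overridden when `shared_fraction` is given.
#' @param shared_fraction target fraction of mutations shared by both
#'   metastases; when non-`NULL`, private counts are derived from it and
#'   `n_founder_mutations`.
#' @param uv_ct_fraction fraction of substitutions forced to be C>T at a
#'   C:G pair (UV signature).
#' @param dinucleotide_rate number of adjacent CC>TT (founder) events.
#' @param mean_depth mean sequencing depth at assayed positions.
#' @param base_error_rate per-base miscall probability; base qualities
#'   are emitted at the matching phred value.
#' @param het_site_spacing mean spacing (bp) of germline heterozygous
#'   sites planted genome-wide for LOH analysis.
#' @param n_background_sites extra homozygous-reference pileup positions.
#' @param n_reads_normal aligned-read library size per sample for the
#'   read-position (copy-number) track.
#' @param cnv_segments data frame `chrom`, `start`, `end`, `log2_ratio`,
#'   `which_met` ("met1", "met2" or "both"); `NULL` for the built-in
#'   default set, `"none"`-style empty data frame for none.
#' @param loh_segments data frame `chrom`, `start`, `end`, `which_met`.
#' @param tumor_purity fraction of tumor cells in the tumor samples
#'   (default 1, i.e. pure).
#' @param n_gene_sets,gene_set_size random gene-set collection emitted
#'   for the enrichment stage.
#' @param seed integer RNG seed; the same seed reproduces the trio
#'   exactly.
#' @return a validated list of class `simulation_config`.
#' @export
simulation_config <- function(genome_length = 2e7,
                              n_chromosomes = 2,
                              n_genes = 200,
                              n_founder_mutations = 480,
                              n_private_mutations_per_met = 10,
                              shared_fraction = NULL,
                              uv_ct_fraction = 0.65,
                              dinucleotide_rate = 6,
                              mean_depth = 103,
                              base_error_rate = 0.001,
                              het_site_spacing = 1e4,
                              n_background_sites = 1000,
                              n_reads_normal = 2e5,
                              cnv_segments = NULL,
                              loh_segments = NULL,
                              tumor_purity = 1,
                              n_gene_sets = 25,
                              gene_set_size = 15,
                              seed = 1) {
  if (!is.null(shared_fraction)) {
    stopifnot(shared_fraction > 0, shared_fraction <= 1)
    n_private_mutations_per_met <- round(
      n_founder_mutations * (1 - shared_fraction) / (2 * shared_fraction))
  }
  if (is.null(cnv_segments)) {
    cnv_segments <- data.frame(
      chrom = c("chr1", "chr1", "chr2", "chr2"),
      start = c(4e6 + 1, 1.2e7 + 1, 2e6 + 1, 1e7 + 1),
      end = c(7e6, 1.5e7, 5e6, 1.4e7),
      log2_ratio = c(-1, 1, 0.58, -1),
      which_met = c("met1", "met1", "met2", "both"),
      stringsAsFactors = FALSE)
    cnv_segments <- cnv_segments[cnv_segments$end <= genome_length &
      cnv_segments$chrom %in% paste0("chr", seq_len(n_chromosomes)), ]
  }
  if (is.null(loh_segments)) {
    loh_segments <- data.frame(
      chrom = c("chr1", "chr2"),
      start = c(1.6e7 + 1, 1e7 + 1),
      end = c(2e7, 1.4e7),
      which_met = c("met1", "met2"),
      stringsAsFactors = FALSE)
    loh_segments <- loh_segments[loh_segments$end <= genome_length &
      loh_segments$chrom %in% paste0("chr", seq_len(n_chromosomes)), ]
  }
  cfg <- list(genome_length = genome_length, n_chromosomes = n_chromosomes,
              n_genes = n_genes,
              n_founder_mutations = n_founder_mutations,
              n_private_mutations_per_met = n_private_mutations_per_met,
              uv_ct_fraction = uv_ct_fraction,
              dinucleotide_rate = dinucleotide_rate,
              mean_depth = mean_depth, base_error_rate = base_error_rate,
              het_site_spacing = het_site_spacing,
              n_background_sites = n_background_sites,
              n_reads_normal = n_reads_normal,
              cnv_segments = cnv_segments, loh_segments = loh_segments,
              tumor_purity = tumor_purity,
              n_gene_sets = n_gene_sets, gene_set_size = gene_set_size,
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  counts <- c(cfg$n_genes, cfg$n_founder_mutations,
              cfg$n_private_mutations_per_met, cfg$dinucleotide_rate,
              cfg$n_background_sites)
  stopifnot(all(counts >= 0), cfg$genome_length > 0,
            cfg$n_chromosomes >= 1,
            cfg$uv_ct_fraction >= 0, cfg$uv_ct_fraction <= 1,
            cfg$mean_depth > 0,
            cfg$base_error_rate >= 0, cfg$base_error_rate < 0.75,
            cfg$tumor_purity > 0, cfg$tumor_purity <= 1)
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  for (seg in list(cfg$cnv_segments, cfg$loh_segments)) {
    if (!nrow(seg)) next
    stopifnot(all(seg$chrom %in% chroms),
              all(seg$start >= 1), all(seg$end <= cfg$genome_length),
              all(seg$start <= seg$end))
  }
  # contradictory (overlapping) CNV segments for the same metastasis
  cs <- cfg$cnv_segments
  if (nrow(cs) > 1) {
    for (met in c("met1", "met2")) {
      s <- cs[cs$which_met %in% c(met, "both"), , drop = FALSE]
      s <- s[order(s$chrom, s$start), ]
      if (nrow(s) > 1) {
        same <- s$chrom[-1] == s$chrom[-nrow(s)]
        if (any(same & s$start[-1] <= s$end[-nrow(s)]))
          stop("overlapping CNV segments for the same metastasis")
      }
    }
  }
  invisible(cfg)
}

#' Generate a matched normal + two-metastasis synthetic dataset
#'
#' Produces, from one seeded configuration, everything the analysis
#' consumes: a random reference genome, a non-overlapping exon model,
#' per-sample pileup tables at every assayed position (germline
#' heterozygous sites, planted somatic sites and background
#' homozygous-reference sites), per-sample aligned-read start positions
#' whose local rate follows the planted copy-number segments, a random
#' gene-set collection, and the full ground truth.
#'
#' @param config a `simulation_config`.
#' @return list of class `met_trio`: `config`, `reference` (named
#'   character vector of chromosome sequences), `chrom_lengths`, `genes`
#'   (exon table), `pileups` (list `normal`, `met1`, `met2`), `reads`
#'   (list of data frames `chrom`, `pos`), `gene_sets`, and `truth`
#'   (list `mutations`, `het_sites`, `cnv_segments`, `loh_segments`).
#' @export
generate_trio <- function(config) {
  validate_config(config)
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  len <- stats::setNames(rep(config$genome_length, length(chroms)), chroms)

  reference <- vapply(chroms, function(ch)
    paste(sample(BASES, len[[ch]], replace = TRUE), collapse = ""),
    character(1))

  genes <- .place_genes(config, chroms, len)
  het_sites <- .plant_het_sites(config, reference, chroms, len)
  muts <- .plant_mutations(config, reference, genes, het_sites)

  # per-sample genotypes at every assayed position
  sites <- .assemble_sites(config, reference, chroms, len, het_sites, muts)
  pileups <- lapply(c(normal = "normal", met1 = "met1", met2 = "met2"),
                    function(s) .simulate_pileup(config, sites, s))
  reads <- lapply(c(normal = "normal", met1 = "met1", met2 = "met2"),
                  function(s) .simulate_reads(config, chroms, len, s))
  gene_sets <- .make_gene_sets(config, genes)

  trio <- list(config = config, reference = reference, chrom_lengths = len,
               genes = genes, pileups = pileups, reads = reads,
               gene_sets = gene_sets,
               truth = list(mutations = muts, het_sites = het_sites,
                            cnv_segments = config$cnv_segments,
                            loh_segments = config$loh_segments))
  class(trio) <- "met_trio"
  trio
}

# non-overlapping 1-3 exon genes on alternating strands; CDS length
# is a multiple of 3 so every exonic position has a defined codon
.place_genes <- function(config, chroms, len) {
  if (config$n_genes == 0)
    return(data.frame(gene = character(0), chrom = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0)))
  per_chrom <- diff(round(seq(0, config$n_genes,
                              length.out = length(chroms) + 1)))
  rows <- list()
  gi <- 0L
  for (ci in seq_along(chroms)) {
    ng <- per_chrom[ci]
    if (ng == 0) next
    slot <- len[[ci]] %/% ng
    for (k in seq_len(ng)) {
      gi <- gi + 1L
      n_exons <- sample(1:3, 1)
      exon_len <- 3 * sample(60:240, n_exons, replace = TRUE)
      span <- sum(exon_len) + (n_exons - 1) * 500
      lo <- (k - 1) * slot + 1
      start <- lo + sample.int(max(1L, slot - span - 10L), 1)
      strand <- sample(c("+", "-"), 1)
      s <- start
      for (e in seq_len(n_exons)) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = sprintf("GENE%04d", gi), chrom = chroms[ci],
          strand = strand, start = s, end = s + exon_len[e] - 1L,
          stringsAsFactors = FALSE)
        s <- s + exon_len[e] + 500L
      }
    }
  }
  do.call(rbind, rows)
}

.plant_het_sites <- function(config, reference, chroms, len) {
  rows <- lapply(chroms, function(ch) {
    n <- len[[ch]] %/% config$het_site_spacing
    if (n == 0) return(NULL)
    pos <- (seq_len(n) - 1L) * config$het_site_spacing +
      sample.int(config$het_site_spacing, n, replace = TRUE)
    pos <- pos[pos <= len[[ch]]]
    ref <- .ref_base(reference, ch, pos)
    alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1), character(1))
    retained <- ifelse(stats::runif(length(pos)) < 0.5, ref, alt)
    data.frame(chrom = ch, pos = pos, ref = ref, alt = alt,
               retained = retained, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.ref_base <- function(reference, chrom, pos) {
  substring(reference[[chrom]], pos, pos)
}

.in_segments <- function(segs, chrom, pos, met = NULL) {
  if (is.null(segs) || !nrow(segs)) return(rep(FALSE, length(pos)))
  if (!is.null(met)) segs <- segs[segs$which_met %in% c(met, "both"), ,
                                  drop = FALSE]
  hit <- rep(FALSE, length(pos))
  for (k in seq_len(nrow(segs))) {
    hit <- hit | (chrom == segs$chrom[k] &
                  pos >= segs$start[k] & pos <= segs$end[k])
  }
  hit
}

# plant founder/private substitutions and CC>TT dinucleotides in exons;
# planted sites are kept >= 3 bp apart so no accidental dinucleotide forms
.plant_mutations <- function(config, reference, genes, het_sites) {
  n_tot <- config$n_founder_mutations + 2 * config$n_private_mutations_per_met
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      founder = logical(0), in_met1 = logical(0),
                      in_met2 = logical(0), dinucleotide = logical(0))
  if (n_tot + config$dinucleotide_rate == 0 || !nrow(genes)) return(empty)
  exon_pos <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i)
    data.frame(chrom = genes$chrom[i],
               pos = seq(genes$start[i], genes$end[i]),
               stringsAsFactors = FALSE)))
  het_key <- paste(het_sites$chrom, het_sites$pos)
  exon_pos <- exon_pos[!(paste(exon_pos$chrom, exon_pos$pos) %in% het_key), ]
  ref_vec <- character(nrow(exon_pos))
  for (ch in unique(exon_pos$chrom)) {
    sel <- exon_pos$chrom == ch
    ref_vec[sel] <- substring(reference[[ch]], exon_pos$pos[sel],
                              exon_pos$pos[sel])
  }
  exon_pos$ref <- ref_vec

  taken <- new.env(hash = TRUE, parent = emptyenv())
  is_free <- function(ch, p) {
    for (d in -2:2) if (!is.null(taken[[paste(ch, p + d)]])) return(FALSE)
    TRUE
  }
  block <- function(ch, p) assign(paste(ch, p), TRUE, envir = taken)
  pick_spaced <- function(cand_idx, n) {
    chosen <- integer(0)
    for (i in sample(cand_idx)) {
      if (length(chosen) >= n) break
      if (!is_free(exon_pos$chrom[i], exon_pos$pos[i])) next
      chosen <- c(chosen, i)
      block(exon_pos$chrom[i], exon_pos$pos[i])
    }
    if (length(chosen) < n)
      stop("not enough exonic positions to plant mutations")
    chosen
  }

  n_uv <- round(n_tot * config$uv_ct_fraction)
  uv_idx <- pick_spaced(which(exon_pos$ref %in% c("C", "G")), n_uv)
  other_idx <- pick_spaced(seq_len(nrow(exon_pos)), n_tot - n_uv)
  idx <- c(uv_idx, other_idx)
  ref <- exon_pos$ref[idx]
  alt <- character(length(idx))
  is_uv <- seq_along(idx) <= length(uv_idx)
  alt[is_uv] <- ifelse(ref[is_uv] == "C", "T", "A")
  alt[!is_uv] <- vapply(ref[!is_uv], function(r)
    sample(setdiff(BASES, r), 1), character(1))

  assign_met <- sample(c(rep("both", config$n_founder_mutations),
                         rep("met1", config$n_private_mutations_per_met),
                         rep("met2", config$n_private_mutations_per_met)))
  muts <- data.frame(chrom = exon_pos$chrom[idx], pos = exon_pos$pos[idx],
                     ref = ref, alt = alt,
                     founder = assign_met == "both",
                     in_met1 = assign_met %in% c("both", "met1"),
                     in_met2 = assign_met %in% c("both", "met2"),
                     dinucleotide = FALSE, stringsAsFactors = FALSE)

  if (config$dinucleotide_rate > 0) {
    cc <- which(exon_pos$ref == "C")
    cc <- cc[cc < nrow(exon_pos) &
             exon_pos$chrom[cc + 1L] == exon_pos$chrom[cc] &
             exon_pos$pos[cc + 1L] == exon_pos$pos[cc] + 1L &
             exon_pos$ref[cc + 1L] == "C"]
    sel <- integer(0)
    for (i in sample(cc)) {
      if (length(sel) >= config$dinucleotide_rate) break
      if (!is_free(exon_pos$chrom[i], exon_pos$pos[i]) ||
          !is_free(exon_pos$chrom[i], exon_pos$pos[i] + 1L)) next
      sel <- c(sel, i)
      block(exon_pos$chrom[i], exon_pos$pos[i])
      block(exon_pos$chrom[i], exon_pos$pos[i] + 1L)
    }
    if (length(sel) < config$dinucleotide_rate)
      stop("not enough CC contexts for the requested dinucleotide events")
    di <- data.frame(chrom = rep(exon_pos$chrom[sel], each = 2),
                     pos = as.integer(rbind(exon_pos$pos[sel],
                                            exon_pos$pos[sel] + 1L)),
                     ref = "C", alt = "T",
                     founder = TRUE, in_met1 = TRUE, in_met2 = TRUE,
                     dinucleotide = TRUE, stringsAsFactors = FALSE)
    muts <- rbind(muts, di)
  }
  muts <- muts[order(muts$chrom, muts$pos), ]
  rownames(muts) <- NULL
  muts
}

# one row per assayed position per sample-genotype
.assemble_sites <- function(config, reference, chroms, len, het_sites, muts) {
  bg <- NULL
  if (config$n_background_sites > 0) {
    used <- c(paste(het_sites$chrom, het_sites$pos),
              paste(muts$chrom, muts$pos))
    per <- diff(round(seq(0, config$n_background_sites,
                          length.out = length(chroms) + 1)))
    bg <- do.call(rbind, lapply(seq_along(chroms), function(ci) {
      pos <- sample.int(len[[ci]], per[ci])
      data.frame(chrom = chroms[ci], pos = pos, stringsAsFactors = FALSE)
    }))
    bg <- bg[!(paste(bg$chrom, bg$pos) %in% used), , drop = FALSE]
    bg$ref <- unlist(lapply(seq_len(nrow(bg)), function(i)
      .ref_base(reference, bg$chrom[i], bg$pos[i])))
  }
  sites <- data.frame(
    chrom = c(het_sites$chrom, muts$chrom, bg$chrom),
    pos = c(het_sites$pos, muts$pos, bg$pos),
    ref = c(het_sites$ref, muts$ref, bg$ref),
    stringsAsFactors = FALSE)
  gt <- function(a, b) paste0(pmin(a, b), pmax(a, b))
  n_h <- nrow(het_sites); n_m <- nrow(muts)
  n_b <- if (is.null(bg)) 0L else nrow(bg)
  sites$gt_normal <- c(gt(het_sites$ref, het_sites$alt),
                       gt(muts$ref, muts$ref),
                       if (n_b) gt(bg$ref, bg$ref))
  tumor_gt <- function(met) {
    in_met <- muts[[paste0("in_", met)]]
    loh_h <- .in_segments(config$loh_segments, het_sites$chrom,
                          het_sites$pos, met)
    g_h <- ifelse(loh_h, gt(het_sites$retained, het_sites$retained),
                  gt(het_sites$ref, het_sites$alt))
    loh_m <- .in_segments(config$loh_segments, muts$chrom, muts$pos, met)
    g_m <- ifelse(!in_met, gt(muts$ref, muts$ref),
                  ifelse(loh_m, gt(muts$alt, muts$alt),
                         gt(muts$ref, muts$alt)))
    c(g_h, g_m, if (n_b) gt(bg$ref, bg$ref))
  }
  sites$gt_met1 <- tumor_gt("met1")
  sites$gt_met2 <- tumor_gt("met2")
  sites <- sites[order(sites$chrom, sites$pos), ]
  rownames(sites) <- NULL
  sites
}

# draw a pileup table for one sample from its per-site genotypes
.simulate_pileup <- function(config, sites, sample_name) {
  n <- nrow(sites)
  gt <- sites[[paste0("gt_", sample_name)]]
  mult <- rep(1, n)
  if (sample_name != "normal") {
    segs <- config$cnv_segments
    if (!is.null(segs) && nrow(segs)) {
      segs <- segs[segs$which_met %in% c(sample_name, "both"), , drop = FALSE]
      for (k in seq_len(nrow(segs))) {
        hit <- sites$chrom == segs$chrom[k] & sites$pos >= segs$start[k] &
          sites$pos <= segs$end[k]
        mult[hit] <- 2^segs$log2_ratio[k]
      }
    }
  }
  depth <- stats::rpois(n, config$mean_depth * mult)
  q <- max(2L, round(-10 * log10(max(config$base_error_rate, 1e-6))))
  e <- config$base_error_rate
  a1 <- substr(gt, 1, 1); a2 <- substr(gt, 2, 2)
  purity <- config$tumor_purity
  gt_n <- sites$gt_normal
  bases <- character(n); quals <- character(n)
  for (i in seq_len(n)) {
    d <- depth[i]
    if (d == 0L) { bases[i] <- ""; quals[i] <- ""; next }
    if (sample_name != "normal" && purity < 1) {
      from_tumor <- stats::runif(d) < purity
      al1 <- ifelse(from_tumor, a1[i], substr(gt_n[i], 1, 1))
      al2 <- ifelse(from_tumor, a2[i], substr(gt_n[i], 2, 2))
      obs <- ifelse(stats::runif(d) < 0.5, al1, al2)
    } else {
      obs <- ifelse(stats::runif(d) < 0.5, a1[i], a2[i])
    }
    err <- stats::runif(d) < e
    if (any(err)) {
      obs[err] <- vapply(obs[err], function(b)
        sample(setdiff(BASES, b), 1), character(1))
    }
    bases[i] <- paste(obs, collapse = "")
    quals[i] <- encode_quals(rep(q, d))
  }
  data.frame(chrom = sites$chrom, pos = sites$pos, ref = sites$ref,
             bases = bases, quals = quals, stringsAsFactors = FALSE)
}

# aligned-read start positions whose rate tracks the planted copy ratios
.simulate_reads <- function(config, chroms, len, sample_name) {
  total_len <- sum(len)
  base_rate <- config$n_reads_normal / total_len
  segs <- config$cnv_segments
  if (sample_name == "normal" || is.null(segs) || !nrow(segs)) {
    segs <- segs[0, , drop = FALSE]
  } else {
    segs <- segs[segs$which_met %in% c(sample_name, "both"), , drop = FALSE]
  }
  rows <- lapply(chroms, function(ch) {
    s <- segs[segs$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), ]
    bounds <- sort(unique(c(1, s$start, s$end + 1, len[[ch]] + 1)))
    pos <- integer(0)
    for (k in seq_len(length(bounds) - 1L)) {
      lo <- bounds[k]; hi <- bounds[k + 1L] - 1L
      if (hi < lo) next
      mult <- 1
      sk <- which(s$start <= lo & s$end >= hi)
      if (length(sk)) mult <- 2^s$log2_ratio[sk[1]]
      n <- stats::rpois(1, base_rate * (hi - lo + 1) * mult)
      if (n > 0) pos <- c(pos, lo + sample.int(hi - lo + 1L, n,
                                               replace = TRUE) - 1L)
    }
    data.frame(chrom = ch, pos = sort(pos), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.make_gene_sets <- function(config, genes) {
  universe <- unique(genes$gene)
  if (config$n_gene_sets == 0 || !length(universe)) return(list())
  sets <- lapply(seq_len(config$n_gene_sets), function(i)
    sample(universe, min(config$gene_set_size, length(universe))))
  names(sets) <- sprintf("SET%03d", seq_along(sets))
  sets
}

#' Write a synthetic trio to disk
#'
#' Emits the formats consumed by the pipeline's file interfaces:
#' reference FASTA, exon model TSV, per-sample pileup TSVs, per-sample
#' read-position BED (0-based half-open single-bp intervals with a
#' sample column), gene sets GMT, and tab-delimited ground truth.
#'
#' @param trio a `met_trio` from [generate_trio()].
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
write_trio <- function(trio, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- Biostrings::DNAStringSet(trio$reference)
  Biostrings::writeXStringSet(ref, file.path(dir, "reference.fa"))
  utils::write.table(trio$genes, file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (s in names(trio$pileups)) {
    write_pileup(trio$pileups[[s]],
                 file.path(dir, sprintf("pileup_%s.tsv", s)))
    bed <- data.frame(chrom = trio$reads[[s]]$chrom,
                      start = trio$reads[[s]]$pos - 1L,
                      end = trio$reads[[s]]$pos, sample = s)
    utils::write.table(bed, file.path(dir, sprintf("reads_%s.bed", s)),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  write_gmt(trio$gene_sets, file.path(dir, "gene_sets.gmt"))
  utils::write.table(trio$truth$mutations,
                     file.path(dir, "truth_mutations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(trio$truth$cnv_segments,
                     file.path(dir, "truth_cnv.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(trio$truth$loh_segments,
                     file.path(dir, "truth_loh.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
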