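small_cfg <- function(cnv_segments = data.frame(
                        chrom = "chr1", start = 5e5 + 1, end = 1e6,
                        log2_ratio = 1, which_met = "met1"),
                      loh_segments = data.frame(
                        chrom = "chr1", start = 1.5e6 + 1, end = 2e6,
                        which_met = "met2"),
                      ...) {
  simulation_config(
    genome_length = 2e6, n_chromosomes = 1, n_genes = 30,
    n_founder_mutations = 20, n_private_mutations_per_met = 2,
    dinucleotide_rate = 1, het_site_spacing = 1e4,
    n_background_sites = 100, n_reads_normal = 1e4,
    cnv_segments = cnv_segments, loh_segments = loh_segments,
    seed = 9, ...)
}

test_that("the same seed reproduces the trio exactly", {
  a <- generate_trio(small_cfg())
  b <- generate_trio(small_cfg())
  expect_identical(a$reference, b$reference)
  expect_identical(a$pileups, b$pileups)
  expect_identical(a$reads, b$reads)
  expect_identical(a$truth, b$truth)
})

test_that("planted mutation counts reproduce the configuration", {
  trio <- generate_trio(small_cfg())
  m <- trio$truth$mutations
  expect_identical(sum(m$founder & !m$dinucleotide), 20L)
  expect_identical(sum(m$in_met1 & !m$in_met2), 2L)
  expect_identical(sum(m$in_met2 & !m$in_met1), 2L)
  expect_identical(sum(m$dinucleotide), 2L)  # one event, two substitutions
  # every variant appears exactly once in the ground truth
  expect_false(any(duplicated(paste(m$chrom, m$pos))))
  # founders are in both metastases, privates in exactly one
  expect_true(all(m$in_met1[m$founder] & m$in_met2[m$founder]))
  expect_true(all(xor(m$in_met1[!m$founder], m$in_met2[!m$founder])))
})

test_that("shared_fraction overrides the private count", {
  cfg <- simulation_config(shared_fraction = 0.96,
                           n_founder_mutations = 480)
  expect_identical(cfg$n_private_mutations_per_met, 10)
  expect_equal(480 / (480 + 2 * cfg$n_private_mutations_per_met), 0.96)
})

test_that("a configuration without mutations yields no somatic variants", {
  cfg <- small_cfg()
  cfg$n_founder_mutations <- 0L
  cfg$n_private_mutations_per_met <- 0L
  cfg$dinucleotide_rate <- 0L
  trio <- generate_trio(cfg)
  expect_identical(nrow(trio$truth$mutations), 0L)
  gts <- lapply(trio$pileups, call_genotypes)
  res <- somatic_cascade(gts$met1, gts$met2, gts$normal)
  expect_identical(nrow(res$variants), 0L)
})

test_that("pileup depth tracks the configured mean", {
  trio <- generate_trio(small_cfg())
  depth <- nchar(trio$pileups$normal$bases)
  expect_gt(length(depth), 300)
  expect_lt(abs(mean(depth) - 103) / 103, 0.05)
})

test_that("planted LOH regions lose the non-retained allele in the tumor pileup", {
  trio <- generate_trio(small_cfg())
  hs <- trio$truth$het_sites
  in_loh <- hs$pos > 1.5e6 & hs$pos <= 2e6
  pu <- trio$pileups$met2
  for (i in which(in_loh)) {
    row <- pu[pu$pos == hs$pos[i], ]
    obs <- strsplit(row$bases, "")[[1]]
    lost <- setdiff(c(hs$ref[i], hs$alt[i]), hs$retained[i])
    # any residual observation of the lost allele is sequencing error
    expect_lt(mean(obs == lost), 0.05)
    expect_gt(mean(obs == hs$retained[i]), 0.9)
  }
  # outside the region the heterozygote balance is preserved on average
  out_rows <- pu[pu$pos %in% hs$pos[!in_loh], ]
  fracs <- mapply(function(b, a) mean(strsplit(b, "")[[1]] == a),
                  out_rows$bases, hs$alt[!in_loh])
  expect_lt(abs(mean(fracs) - 0.5), 0.05)
})

test_that("tumor read density follows the planted copy ratio", {
  trio <- generate_trio(small_cfg())
  in_seg <- function(df) mean(df$pos > 5e5 & df$pos <= 1e6)
  # met1 carries a 2x amplification of one quarter of the genome
  expect_gt(in_seg(trio$reads$met1), 0.33)
  expect_lt(abs(in_seg(trio$reads$normal) - 0.25), 0.03)
  expect_lt(abs(in_seg(trio$reads$met2) - 0.25), 0.03)
})

test_that("contradictory overlapping CNV segments are rejected", {
  expect_error(small_cfg(
    cnv_segments = data.frame(
      chrom = "chr1", start = c(1e5, 2e5), end = c(3e5, 4e5),
      log2_ratio = c(1, -1), which_met = c("met1", "met1"))),
    "overlapping")
  # overlap across different metastases is fine
  ok <- small_cfg(cnv_segments = data.frame(
    chrom = "chr1", start = c(1e5, 2e5), end = c(3e5, 4e5),
    log2_ratio = c(1, -1), which_met = c("met1", "met2")))
  expect_s3_class(ok, "simulation_config")
})

test_that("out-of-bounds segments and bad fractions are rejected", {
  expect_error(small_cfg(loh_segments = data.frame(
    chrom = "chr1", start = 1, end = 3e6, which_met = "met1")))
  expect_error(simulation_config(shared_fraction = 1.2))
  expect_error(simulation_config(uv_ct_fraction = -0.1))
})

test_that("written trios land in the documented formats", {
  trio <- generate_trio(small_cfg())
  dir <- withr::local_tempdir()
  write_trio(trio, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "reference.fa", "genes.tsv", "pileup_normal.tsv", "pileup_met1.tsv",
    "pileup_met2.tsv", "reads_normal.bed", "gene_sets.gmt",
    "truth_mutations.tsv")))))
  ref <- Biostrings::readDNAStringSet(file.path(dir, "reference.fa"))
  expect_identical(as.character(ref[["chr1"]]), trio$reference[["chr1"]])
  pu <- read_pileup(file.path(dir, "pileup_met1.tsv"))
  expect_equal(pu, trio$pileups$met1, ignore_attr = TRUE)
  bed <- read.table(file.path(dir, "reads_normal.bed"), sep = "\t")
  expect_equal(bed$V3, trio$reads$normal$pos, ignore_attr = TRUE)
  # 0-based half-open intervals
  expect_equal(bed$V2, trio$reads$normal$pos - 1, ignore_attr = TRUE)
})
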