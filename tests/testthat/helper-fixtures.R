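# Shared fixtures, built once per test run.

# A small matched trio with known ground truth: 96 founder + 2x2 private
# substitutions (planted sharing 96/100), 2 CC>TT dinucleotides, one
# deletion private to met1, one shared amplification, and one LOH region
# private to met1.
tiny_trio <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(
        genome_length = 4e6, n_chromosomes = 2, n_genes = 60,
        n_founder_mutations = 96, n_private_mutations_per_met = 2,
        dinucleotide_rate = 2, het_site_spacing = 4e3,
        n_background_sites = 200, n_reads_normal = 4e4,
        cnv_segments = data.frame(
          chrom = c("chr1", "chr2"), start = c(1e6 + 1, 1e6 + 1),
          end = c(2e6, 2.5e6), log2_ratio = c(-1, 1),
          which_met = c("met1", "both"), stringsAsFactors = FALSE),
        loh_segments = data.frame(
          chrom = "chr1", start = 2.5e6 + 1, end = 4e6,
          which_met = "met1", stringsAsFactors = FALSE),
        seed = 42)
      cache <<- generate_trio(cfg)
    }
    cache
  }
})

tiny_genotypes <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- lapply(tiny_trio()$pileups, call_genotypes)
    cache
  }
})

# Handcrafted 100 bp reference with one plus-strand two-exon gene and one
# minus-strand single-exon gene, for coding-effect tests.
#   G1 (+): exon1 11-19 "ATGGTGCAA", intron 20-29, exon2 30-38 "GGCTGCTAA"
#           CDS: ATG GTG CAA GGC TGC TAA = M V Q G C *
#   G2 (-): exon 60-77, CDS = revcomp(genomic) = ATG GTG CAA GGC TGC TAA
gene_fixture <- function() {
  ref <- paste0(strrep("A", 10), "ATGGTGCAA", "GTAAGTAAAG", "GGCTGCTAA",
                strrep("A", 21), "TTAGCAGCCTTGCACCAT", strrep("A", 23))
  stopifnot(nchar(ref) == 100)
  model <- data.frame(
    gene = c("G1", "G1", "G2"), chrom = "chrT",
    strand = c("+", "+", "-"),
    start = c(11, 30, 60), end = c(19, 38, 77),
    stringsAsFactors = FALSE)
  list(reference = c(chrT = ref), model = model)
}

variant_df <- function(chrom, pos, ref, alt) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}
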