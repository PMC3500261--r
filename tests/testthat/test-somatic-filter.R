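test_that("common-variant panel keeps only well-supported common records", {
  calls <- data.frame(
    chrom = "chr1", pos = 1:5, alt = "T",
    caller_support = c(3, 2, 4, 3, NA),
    maf = c(0.06, 0.30, 0.04, 0.051, 0.2))
  panel <- build_common_panel(calls)
  expect_identical(panel$pos, c(1L, 4L))  # support>=3 AND maf>0.05
  expect_identical(attr(panel, "n_skipped"), 1L)
  # boundary: maf exactly 0.05 is not "above 5%"
  expect_identical(nrow(build_common_panel(
    data.frame(chrom = "c", pos = 1, alt = "T", caller_support = 4,
               maf = 0.05))), 0L)
})

test_that("known-site filtering is an exact set difference", {
  v <- variant_df("chr1", 1:10, "A", "T")
  panel <- variant_df("chr1", c(2, 5), "A", "T")
  panel$caller_support <- 3; panel$maf <- 0.2
  known <- variant_df("chr1", 9, "A", "T")
  out <- filter_known(v, panel, known)
  expect_identical(out$pos, setdiff(1:10, c(2, 5, 9)))
  expect_identical(attr(out, "n_removed"), 3L)
  # allele must match, not just position
  known_other_allele <- variant_df("chr1", 1, "A", "G")
  expect_identical(nrow(filter_known(v, NULL, known_other_allele)), 10L)
  # empty panel is the identity
  expect_identical(filter_known(v, NULL, NULL)$pos, v$pos)
})

test_that("the quality gate is inclusive on MPG and strict on the ratio", {
  expect_true(all(quality_pass(c(12, 15, 20), c(0.6, 0.7, 0.8))))
  expect_identical(quality_pass(c(9, 15, 20), c(0.6, 0.7, 0.8)),
                   c(FALSE, TRUE, TRUE))
  expect_true(quality_pass(10, 0.51))    # "10 or greater"
  expect_false(quality_pass(10, 0.5))    # "above 0.5" is strict
  expect_false(quality_pass(NA, 0.9))    # uncovered
})

test_that("somatic status and zygosity follow the tumor/normal genotypes", {
  expect_true(is_somatic("AG", "AA", "G"))
  expect_false(is_somatic("AG", "AG", "G"))   # germline
  expect_false(is_somatic("AA", "AA", "G"))   # not a variant
  expect_identical(classify_zygosity("AG", "GG"), "LOH")
  expect_identical(classify_zygosity("AG", "AG"), "heterozygous")
  expect_identical(classify_zygosity("AA", "AG"), "heterozygous")
})

test_that("coding effects are classified through the genetic code", {
  fx <- gene_fixture()
  cases <- rbind(
    data.frame(pos = 17, ref = "C", alt = "T", want = "nonsense"),   # CAA>TAA
    data.frame(pos = 16, ref = "G", alt = "A", want = "synonymous"), # GTG>GTA
    data.frame(pos = 11, ref = "A", alt = "C", want = "missense"),   # ATG>CTG
    data.frame(pos = 21, ref = "A", alt = "C", want = "splice_site"),
    data.frame(pos = 25, ref = "T", alt = "C", want = "intronic"),
    data.frame(pos = 3,  ref = "A", alt = "C", want = "intergenic"),
    data.frame(pos = 77, ref = "T", alt = "C", want = "missense"),   # minus strand
    data.frame(pos = 72, ref = "C", alt = "T", want = "synonymous")) # minus strand
  got <- annotate_effect(variant_df("chrT", cases$pos, cases$ref, cases$alt),
                         fx$model, fx$reference)
  expect_identical(got$effect, cases$want)
  expect_identical(got$gene[1], "G1")
  expect_identical(got$gene[7], "G2")
})

test_that("indels overlapping an exon are typed by length modulo 3", {
  fx <- gene_fixture()
  v <- variant_df("chrT", c(12, 12), c("TG", "TGGT"), c("T", "T"))
  got <- annotate_effect(v, fx$model, fx$reference)
  expect_identical(got$effect, c("frameshift", "inframe_indel"))
})

test_that("the cascade conserves variants at every stage and has no germline leakage", {
  trio <- tiny_trio()
  gts <- tiny_genotypes()
  res <- somatic_cascade(gts$met1, gts$met2, gts$normal,
                         gene_model = trio$genes,
                         reference = trio$reference)
  tal <- res$tally
  expect_true(all(tal$input == tal$passed + tal$failed))
  # each stage consumes the previous stage's survivors
  expect_identical(tal$input[-1], tal$passed[-nrow(tal)])

  truth <- trio$truth$mutations
  planted <- truth[truth$in_met1, ]
  got_key <- paste(res$variants$chrom, res$variants$pos, res$variants$alt)
  want_key <- paste(planted$chrom, planted$pos, planted$alt)
  # recall: every planted mutation recovered
  expect_gte(mean(want_key %in% got_key), 0.99)
  # no germline leakage: nothing outside the planted set
  expect_identical(sort(got_key), sort(want_key))
})

test_that("known-site and quality filters commute", {
  gts <- tiny_genotypes()
  trio <- tiny_trio()
  truth <- trio$truth$mutations
  # use a few planted sites as a fake known panel
  known <- variant_df(truth$chrom[1:5], truth$pos[1:5], truth$ref[1:5],
                      truth$alt[1:5])
  a <- somatic_cascade(gts$met1, gts$met2, gts$normal, known_sites = known)
  # manual reversal: quality gate first, then known-site removal
  cand <- candidate_variants(gts$met1)
  key <- function(df) paste(df$chrom, df$pos)
  qp <- quality_pass(gts$met1$mpg[match(key(cand), key(gts$met1))],
                     gts$met1$mpg_cov_ratio[match(key(cand), key(gts$met1))]) &
        quality_pass(gts$met2$mpg[match(key(cand), key(gts$met2))],
                     gts$met2$mpg_cov_ratio[match(key(cand), key(gts$met2))]) &
        quality_pass(gts$normal$mpg[match(key(cand), key(gts$normal))],
                     gts$normal$mpg_cov_ratio[match(key(cand), key(gts$normal))])
  qp[is.na(qp)] <- FALSE
  rev_order <- filter_known(cand[qp, ], NULL, known)
  som <- is_somatic(
    gts$met1$genotype[match(key(rev_order), key(gts$met1))],
    gts$normal$genotype[match(key(rev_order), key(gts$normal))],
    rev_order$alt)
  expect_identical(
    sort(paste(a$variants$chrom, a$variants$pos, a$variants$alt)),
    sort(paste(rev_order$chrom[som], rev_order$pos[som], rev_order$alt[som])))
})
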