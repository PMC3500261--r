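NS_EFFECTS <- c("missense", "nonsense", "splice_site")
S_EFFECTS <- "synonymous"

#' Round half away from zero
#'
#' Printed summary percentages use commercial (half-up) rounding rather
#' than banker's rounding.
#' @param x numeric.
#' @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Concordance table from per-class shared/private counts
#'
#' Builds the standard metastasis-vs-metastasis summary (one row per
#' class: non-synonymous, synonymous, and their union) from counts of
#' variants private to each metastasis and shared by both.
#'
#' @param only_a,only_b,both named numeric vectors with elements `NS`
#'   and `S`.
#' @return data frame with columns `class`, `total`, `only_a`, `only_b`,
#'   `both`, `pct_both` (2 decimals, half-up).
#' @export
concordance_from_counts <- function(only_a, only_b, both) {
  cls <- c("NS", "S", "NS+S")
  oa <- c(only_a["NS"], only_a["S"], sum(only_a))
  ob <- c(only_b["NS"], only_b["S"], sum(only_b))
  bo <- c(both["NS"], both["S"], sum(both))
  total <- oa + ob + bo
  data.frame(class = cls, total = as.numeric(total),
             only_a = as.numeric(oa), only_b = as.numeric(ob),
             both = as.numeric(bo),
             pct_both = ifelse(total > 0,
                               round_half_up(100 * bo / total, 2), NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare the somatic variant sets of two metastases
#'
#' Exact set arithmetic on (chrom, pos, ref, alt) keys, split by coding
#' class. Non-synonymous counts missense, nonsense and splice-site
#' substitutions; synonymous counts silent substitutions; intergenic and
#' intronic changes are excluded. Indels are excluded from the
#' substitution table and reported in the `indels` attribute.
#'
#' @param variants_a,variants_b annotated variant data frames (columns
#'   `chrom`, `pos`, `ref`, `alt`, `effect`); duplicate keys within one
#'   set are an error.
#' @return data frame as in [concordance_from_counts()], with attribute
#'   `indels` giving per-set and shared indel counts.
#' @export
compare_metastases <- function(variants_a, variants_b) {
  key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
  ka <- key(variants_a); kb <- key(variants_b)
  if (anyDuplicated(ka) || anyDuplicated(kb))
    stop("duplicate variant keys within one metastasis set")
  is_indel <- function(df) nchar(df$ref) != nchar(df$alt)
  ia <- is_indel(variants_a); ib <- is_indel(variants_b)
  class_of <- function(df) ifelse(df$effect %in% NS_EFFECTS, "NS",
                           ifelse(df$effect %in% S_EFFECTS, "S", NA))
  ca <- class_of(variants_a); cb <- class_of(variants_b)
  count <- function(keys, classes, keep) {
    keys <- keys[keep]; classes <- classes[keep]
    c(NS = sum(classes == "NS", na.rm = TRUE),
      S = sum(classes == "S", na.rm = TRUE))
  }
  subs_a <- !ia & !is.na(ca); subs_b <- !ib & !is.na(cb)
  shared <- ka %in% kb
  only_a <- count(ka, ca, subs_a & !shared)
  both <- count(ka, ca, subs_a & shared)
  only_b <- count(kb, cb, subs_b & !(kb %in% ka))
  tab <- concordance_from_counts(only_a, only_b, both)
  attr(tab, "indels") <- c(a = sum(ia), b = sum(ib),
                           shared = sum(ka[ia] %in% kb[ib]))
  tab
}

#' Non-synonymous to synonymous ratio
#'
#' The N/S ratio, reported to one decimal; roughly 2:1 is expected for
#' unselected passenger substitutions, so values at or below that are
#' consistent with most alterations being passengers.
#'
#' @param ns_count,s_count substitution counts.
#' @return numeric ratio (1 decimal, half-up); `NA` when `s_count` is 0.
#' @examples
#' ns_ratio(490, 260) # 1.9
#' @export
ns_ratio <- function(ns_count, s_count) {
  if (s_count == 0) return(NA_real_)
  round_half_up(ns_count / s_count, 1)
}

# 12 raw substitutions -> 6 pyrimidine-anchored classes
SPECTRUM_CLASSES <- c("C:G>T:A", "C:G>A:T", "C:G>G:C",
                      "T:A>C:G", "T:A>A:T", "T:A>G:C")

.class_of_sub <- function(ref, alt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  # anchor on the pyrimidine of the reference pair
  pyr_ref <- ifelse(ref %in% c("C", "T"), ref, comp[ref])
  pyr_alt <- ifelse(ref %in% c("C", "T"), alt, comp[alt])
  paste0(pyr_ref, ":", comp[pyr_ref], ">", pyr_alt, ":", comp[pyr_alt])
}

#' Mutation spectrum over the six substitution classes
#'
#' Collapses every single-base substitution onto its pyrimidine-anchored
#' class (G>A counts as C:G>T:A, etc.) and tests for the
#' ultraviolet-characteristic excess of C:G>T:A transitions against the
#' uniform null proportion of 1/6.
#'
#' @param variants data frame with `ref` and `alt`; indels are skipped.
#' @param test `"binomial"` (exact, default) or `"chisq"` (all-class
#'   goodness of fit).
#' @return list: `counts` (named vector over the six classes),
#'   `n_classified`, `transition_test_p`.
#' @export
mutation_spectrum <- function(variants, test = c("binomial", "chisq")) {
  test <- match.arg(test)
  snv <- variants[nchar(variants$ref) == 1 & nchar(variants$alt) == 1 &
                  variants$ref != variants$alt, , drop = FALSE]
  cls <- .class_of_sub(snv$ref, snv$alt)
  counts <- table(factor(cls, levels = SPECTRUM_CLASSES))
  counts <- stats::setNames(as.integer(counts), SPECTRUM_CLASSES)
  n <- sum(counts)
  p <- if (n == 0) NA_real_
  else if (test == "binomial")
    stats::binom.test(unname(counts["C:G>T:A"]), n, p = 1 / 6,
                      alternative = "greater")$p.value
  else stats::chisq.test(counts)$p.value
  list(counts = counts, n_classified = n, transition_test_p = p)
}

#' Find dinucleotide substitution events
#'
#' Two substitutions at adjacent positions on the same chromosome form
#' one dinucleotide event; runs of adjacent substitutions are paired
#' left to right without overlap. CC>TT and its reverse complement
#' GG>AA are flagged as the ultraviolet signature.
#'
#' @param variants data frame with `chrom`, `pos`, `ref`, `alt`
#'   (single-base substitutions considered; others ignored).
#' @return data frame: `chrom`, `pos` (first position), `ref2`, `alt2`,
#'   `uv_signature`.
#' @export
find_dinucleotides <- function(variants) {
  snv <- variants[nchar(variants$ref) == 1 & nchar(variants$alt) == 1, ,
                  drop = FALSE]
  snv <- snv[order(snv$chrom, snv$pos), , drop = FALSE]
  out <- list()
  i <- 1L
  while (i < nrow(snv)) {
    if (snv$chrom[i] == snv$chrom[i + 1L] &&
        snv$pos[i + 1L] == snv$pos[i] + 1L) {
      ref2 <- paste0(snv$ref[i], snv$ref[i + 1L])
      alt2 <- paste0(snv$alt[i], snv$alt[i + 1L])
      out[[length(out) + 1L]] <- data.frame(
        chrom = snv$chrom[i], pos = snv$pos[i], ref2 = ref2, alt2 = alt2,
        uv_signature = (ref2 == "CC" && alt2 == "TT") ||
                       (ref2 == "GG" && alt2 == "AA"),
        stringsAsFactors = FALSE)
      i <- i + 2L
    } else i <- i + 1L
  }
  if (!length(out))
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref2 = character(0), alt2 = character(0),
                      uv_signature = logical(0)))
  do.call(rbind, out)
}

#' Percent agreement between two measurement methods
#'
#' Simple validation-rate arithmetic: the percentage of tested cases in
#' which an orthogonal assay agreed with the sequencing-based call.
#'
#' @param n_agree,n_total counts.
#' @param digits decimals (half-up, default 1).
#' @export
percent_agreement <- function(n_agree, n_total, digits = 1) {
  stopifnot(n_total > 0, n_agree >= 0, n_agree <= n_total)
  round_half_up(100 * n_agree / n_total, digits)
}

#' Write a concordance report
#' @param tab data frame from [compare_metastases()].
#' @param path output path.
#' @export
write_concordance <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
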