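#' @useDynLib pairmet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

BASES <- c("A", "C", "G", "T")

#' The ten unordered diploid genotypes over {A,C,G,T}
#'
#' Lexicographically ordered ("AA", "AC", ..., "TT"); ties in the
#' posterior are broken toward the earlier state so calls are
#' reproducible.
#' @keywords internal
GENOTYPES <- {
  g <- t(outer(BASES, BASES, paste0))
  g[lower.tri(g, diag = TRUE)]
}

# allele matrix: 10 x 2, alleles of each genotype
.GT_ALLELES <- do.call(rbind, strsplit(GENOTYPES, ""))

# The MPG score is a natural-log likelihood gap. With base-quality error
# probability e, one concordant read separates a homozygous genotype from
# the best heterozygous alternative by ln(2(1-e)/(1-e+e/3)) ~ ln 2 = 0.69,
# so confident homozygous calls sit just above the standard MPG/coverage
# gate of 0.5; a log10 gap (cap 0.30) would put every homozygous call,
# including the matched normal at somatic sites, below that gate.

#' Call the most probable genotype (MPG) at one position
#'
#' Bayesian diploid genotyping from a pileup column. Each read supports
#' its observed base with probability \eqn{1 - e} and each of the three
#' other bases with probability \eqn{e/3}, where \eqn{e = 10^{-q/10}} is
#' the phred error probability. A diploid genotype emits a read from
#' either allele with equal probability, so the per-read likelihood is
#' the mean of the two allele likelihoods. The MPG score is the gap in
#' natural-log posterior between the best and second-best of the ten
#' genotypes (with a flat prior this is the log-likelihood gap); on this
#' scale a clean homozygous read contributes about ln 2 = 0.69 to the
#' score, so confident calls of either zygosity clear an MPG/coverage
#' ratio of 0.5.
#'
#' @param ref reference base (single character, one of A/C/G/T);
#'   informational only under a flat prior.
#' @param bases character vector of observed bases.
#' @param quals numeric vector of phred base qualities (same length).
#' @param prior optional numeric vector of length 10 (named by
#'   [GENOTYPES] or in that order) of prior probabilities; default flat.
#' @return list with `genotype` (two-character string, alleles sorted;
#'   `NA` for a no-call), `mpg` (natural-log posterior gap, >= 0), `coverage`
#'   (number of reads used), `mpg_cov_ratio` (`mpg/coverage`, `NA` at
#'   coverage 0), `n_skipped` (non-ACGT observations dropped) and
#'   `posterior_rank` (genotype order, best first).
#' @examples
#' call_genotype("A", rep("A", 30), rep(30, 30))
#' @export
call_genotype <- function(ref, bases, quals, prior = NULL) {
  stopifnot(length(bases) == length(quals))
  keep <- bases %in% BASES
  n_skipped <- sum(!keep)
  if (n_skipped > 0L) {
    warning(sprintf("skipped %d non-ACGT observation(s)", n_skipped))
    bases <- bases[keep]
    quals <- quals[keep]
  }
  cov <- length(bases)
  if (cov == 0L) {
    return(list(genotype = NA_character_, mpg = 0, coverage = 0L,
                mpg_cov_ratio = NA_real_, n_skipped = n_skipped,
                posterior_rank = GENOTYPES))
  }
  if (any(quals < 0)) stop("negative base quality")
  e <- 10^(-quals / 10)
  # 4 x n matrix: P(observed base | true allele); each column is one read
  pa <- matrix(rep(e / 3, each = 4L), nrow = 4L,
               dimnames = list(BASES, NULL))
  pa[cbind(match(bases, BASES), seq_len(cov))] <- 1 - e
  # 10 x n: per-read likelihood of each genotype
  lik <- (pa[.GT_ALLELES[, 1L], , drop = FALSE] +
          pa[.GT_ALLELES[, 2L], , drop = FALSE]) / 2
  ll <- rowSums(log(lik))
  if (!is.null(prior)) {
    if (!is.null(names(prior))) prior <- prior[GENOTYPES]
    stopifnot(length(prior) == 10L, all(prior > 0))
    ll <- ll + log(prior / sum(prior))
  }
  ord <- order(ll, decreasing = TRUE)  # ties -> earlier (lexicographic) state
  mpg <- unname(ll[ord[1L]] - ll[ord[2L]])
  list(genotype = GENOTYPES[ord[1L]],
       mpg = mpg,
       coverage = cov,
       mpg_cov_ratio = mpg / cov,
       n_skipped = n_skipped,
       posterior_rank = GENOTYPES[ord])
}

#' Genotype every position of a pileup table
#'
#' @param pileup data frame with columns `chrom`, `pos`, `ref`, `bases`,
#'   `quals` as produced by [read_pileup()] or [generate_trio()]: `bases`
#'   is a string of observed bases and `quals` the matching string of
#'   phred+33 quality characters.
#' @param prior optional genotype prior passed to [call_genotype()].
#' @return data frame with one row per position: `chrom`, `pos`, `ref`,
#'   `genotype`, `mpg`, `coverage`, `mpg_cov_ratio`.
#' @export
call_genotypes <- function(pileup, prior = NULL) {
  n <- nrow(pileup)
  gt <- character(n); mpg <- numeric(n); cov <- integer(n)
  base_lists <- strsplit(pileup$bases, "")
  qual_lists <- lapply(pileup$quals, decode_quals)
  for (i in seq_len(n)) {
    call <- call_genotype(pileup$ref[i], base_lists[[i]], qual_lists[[i]],
                          prior = prior)
    gt[i] <- call$genotype
    mpg[i] <- call$mpg
    cov[i] <- call$coverage
  }
  data.frame(chrom = pileup$chrom, pos = pileup$pos, ref = pileup$ref,
             genotype = gt, mpg = mpg, coverage = cov,
             mpg_cov_ratio = ifelse(cov > 0, mpg / cov, NA_real_),
             stringsAsFactors = FALSE)
}

#' MPG/coverage ratio
#'
#' The exact quotient of the MPG score by the read coverage; the
#' per-position confidence measure used by the somatic quality gate.
#'
#' @param mpg numeric MPG score(s).
#' @param coverage integer coverage(s); positions with coverage 0 return
#'   `NA` (no-call).
#' @return numeric ratio, unrounded.
#' @examples
#' mpg_coverage_ratio(10, 25) # 0.4
#' @export
mpg_coverage_ratio <- function(mpg, coverage) {
  ifelse(coverage > 0, mpg / coverage, NA_real_)
}

#' Read a pileup table
#'
#' Tab-delimited, samtools-pileup-like dialect: columns `chrom`, `pos`
#' (1-based), `ref`, `bases` (string of observed bases, one character
#' per read) and `quals` (phred+33 encoded qualities, same length).
#'
#' @param path file path.
#' @return data frame with those five columns.
#' @export
read_pileup <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "integer", "character",
                                         "character", "character"),
                          quote = "", comment.char = "")
  stopifnot(all(c("chrom", "pos", "ref", "bases", "quals") %in% names(df)))
  df
}

#' @rdname read_pileup
#' @param pileup pileup data frame.
#' @export
write_pileup <- function(pileup, path) {
  utils::write.table(pileup, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# phred+33 string -> numeric qualities
decode_quals <- function(s) {
  if (length(s) == 1L && is.character(s)) {
    as.integer(charToRaw(s)) - 33L
  } else {
    as.numeric(s)
  }
}

encode_quals <- function(q) {
  rawToChar(as.raw(as.integer(q) + 33L))
}

#' Write a per-position genotype table
#'
#' VCF-like flat table: chrom, pos, ref, genotype, MPG, coverage, ratio.
#' @param calls data frame from [call_genotypes()].
#' @param path output path.
#' @export
write_genotypes <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
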