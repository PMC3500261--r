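#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t")
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, character(1), 1L)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional character vector (defaults to set names).
#' @export
write_gmt <- function(sets, path, descriptions = names(sets)) {
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Merge mutated and copy-altered genes into one hit list
#'
#' The gene list carried into enrichment is the union of genes bearing a
#' non-synonymous somatic substitution (or a frameshift/in-frame indel)
#' and genes overlapping copy-number segments whose absolute mean log2
#' ratio exceeds `log2_cutoff`.
#'
#' @param somatic_variants annotated variant data frame (`gene`,
#'   `effect`).
#' @param segments `segment_set` (may be `NULL`).
#' @param gene_model exon table (`gene`, `chrom`, `start`, `end`).
#' @param log2_cutoff segment amplitude for a CNV gene hit
#'   (default 0.35, strict).
#' @return deduplicated character vector of gene identifiers.
#' @export
merge_gene_hits <- function(somatic_variants, segments, gene_model,
                            log2_cutoff = 0.35) {
  damaging <- c(NS_EFFECTS, "frameshift", "inframe_indel")
  snv_genes <- unique(stats::na.omit(
    somatic_variants$gene[somatic_variants$effect %in% damaging]))
  cnv_genes <- character(0)
  if (!is.null(segments) && nrow(segments)) {
    hot <- segments[abs(segments$mean_log2) > log2_cutoff, , drop = FALSE]
    if (nrow(hot)) {
      hit <- vapply(seq_len(nrow(gene_model)), function(i)
        any(hot$chrom == gene_model$chrom[i] &
            hot$start <= gene_model$end[i] &
            hot$end >= gene_model$start[i]), logical(1))
      cnv_genes <- unique(gene_model$gene[hit])
    }
  }
  union(snv_genes, cnv_genes)
}

#' Gene-set over-representation with Benjamini-Hochberg control
#'
#' For each set, the upper-tail hypergeometric probability of observing
#' at least the seen overlap between the hit list and the set, drawing
#' `length(hits)` genes from the universe. P-values are adjusted across
#' all tested sets by the Benjamini-Hochberg step-up procedure; adjusted
#' values below `alpha` are significant.
#'
#' @param hits character vector of hit genes; must all be in `universe`.
#' @param gene_sets named list of character vectors (members outside the
#'   universe are ignored).
#' @param universe character vector of all assayed genes.
#' @param alpha significance level on the adjusted p (default 0.05).
#' @return data frame sorted by adjusted p: `set`, `set_size`,
#'   `overlap`, `p`, `p_adjusted`, `neg_log10_adjusted`, `significant`.
#' @export
enrich <- function(hits, gene_sets, universe, alpha = 0.05) {
  hits <- unique(hits)
  bad <- setdiff(hits, universe)
  if (length(bad))
    stop("hit genes outside the universe: ", paste(bad, collapse = ", "))
  N <- length(unique(universe))
  k <- length(hits)
  rows <- lapply(names(gene_sets), function(nm) {
    members <- intersect(gene_sets[[nm]], universe)
    K <- length(members)
    x <- length(intersect(hits, members))
    p <- stats::phyper(x - 1, K, N - K, k, lower.tail = FALSE)
    data.frame(set = nm, set_size = K, overlap = x, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p, method = "BH")
  out$neg_log10_adjusted <- -log10(out$p_adjusted)
  out$significant <- out$p_adjusted < alpha
  out <- out[order(out$p_adjusted, out$p), ]
  rownames(out) <- NULL
  out
}

#' Gene sets significant in every sample
#'
#' Intersects the significant sets of several enrichment results (one
#' per tumor) and reports each sample's -log10 adjusted p for the shared
#' sets, ready for plotting against the 1.3 significance line
#' (-log10 0.05).
#'
#' @param ... two or more data frames from [enrich()].
#' @return list: `sets` (character vector, possibly empty) and `scores`
#'   (matrix of -log10 adjusted p, sets x samples).
#' @export
shared_enriched <- function(...) {
  results <- list(...)
  if (length(results) == 1L && is.list(results[[1]]) &&
      !is.data.frame(results[[1]])) results <- results[[1]]
  stopifnot(length(results) >= 2L)
  sig <- lapply(results, function(r) r$set[r$significant])
  shared <- Reduce(intersect, sig)
  scores <- vapply(results, function(r)
    r$neg_log10_adjusted[match(shared, r$set)], numeric(length(shared)))
  scores <- matrix(scores, nrow = length(shared),
                   dimnames = list(shared, names(results)))
  list(sets = shared, scores = scores)
}

#' Bar plot of enrichment scores
#'
#' -log10 adjusted p per set with a reference line at 1.3 (adjusted
#' p = 0.05).
#' @param result data frame from [enrich()].
#' @param top number of sets to show (default 20).
#' @export
plot_enrichment <- function(result, top = 20) {
  r <- utils::head(result, top)
  graphics::barplot(rev(r$neg_log10_adjusted), names.arg = rev(r$set),
                    horiz = TRUE, las = 1, xlab = "-log10 adjusted p")
  graphics::abline(v = -log10(0.05), lty = 2)
  invisible(NULL)
}
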