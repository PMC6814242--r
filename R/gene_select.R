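#' Build a differential-expression table for one contrast
#'
#' Computes per-gene linear fold change between the mean abundance
#' (FPKM/RPKM) of a treatment condition and a reference condition, with a
#' pseudocount guarding against division by zero, plus the maximum
#' condition-mean abundance across all conditions (the "expressed in at
#' least one sample" filter input). Significance calling is pluggable:
#' supply precomputed flags (e.g. from an external empirical-Bayes DE
#' caller run on counts) via `significant`; otherwise a built-in
#' per-gene Welch t-test on log2(x + pseudocount) across replicates with
#' Benjamini-Hochberg correction is used (intended for synthetic data with
#' several replicates, not as a substitute for a count-based caller).
#'
#' @param expr genes-by-samples numeric matrix with rownames = gene ids.
#' @param conditions character vector, one condition label per column.
#' @param condition treatment condition of the contrast.
#' @param reference reference condition (e.g. the pluripotent sample).
#' @param significant optional logical vector per gene (overrides the
#'   built-in test).
#' @param pseudocount added to condition means before the ratio
#'   (default 0.01).
#' @param alpha BH-adjusted significance level of the built-in test.
#' @return data.frame of class `de_table` with columns `gene`,
#'   `fold_change`, `log2_fc`, `direction`, `significant`,
#'   `max_abundance`.
#' @export
de_table <- function(expr, conditions, condition, reference,
                     significant = NULL, pseudocount = 0.01, alpha = 0.05) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)),
            length(conditions) == ncol(expr), all(expr >= 0),
            !anyDuplicated(rownames(expr)))
  a <- expr[, conditions == condition, drop = FALSE]
  b <- expr[, conditions == reference, drop = FALSE]
  if (!ncol(a) || !ncol(b)) stop("condition or reference not found")
  ma <- rowMeans(a); mb <- rowMeans(b)
  fc <- (ma + pseudocount) / (mb + pseudocount)
  cond_means <- vapply(unique(conditions),
                       function(cc) rowMeans(expr[, conditions == cc, drop = FALSE]),
                       numeric(nrow(expr)))
  if (is.null(significant)) {
    if (ncol(a) < 2 || ncol(b) < 2)
      stop("built-in test needs >= 2 replicates per condition; supply `significant` flags instead")
    la <- log2(a + pseudocount); lb <- log2(b + pseudocount)
    p <- vapply(seq_len(nrow(expr)), function(i) {
      if (stats::sd(la[i, ]) == 0 && stats::sd(lb[i, ]) == 0) return(1)
      tryCatch(stats::t.test(la[i, ], lb[i, ])$p.value, error = function(e) 1)
    }, 0)
    significant <- stats::p.adjust(p, "BH") <= alpha
  }
  out <- data.frame(gene = rownames(expr), fold_change = unname(fc),
                    log2_fc = unname(log2(fc)),
                    direction = ifelse(fc >= 1, "up", "down"),
                    significant = unname(significant),
                    max_abundance = unname(apply(cond_means, 1, max)),
                    stringsAsFactors = FALSE)
  class(out) <- c("de_table", "data.frame")
  out
}

#' Filter a DE table on significance, fold change and abundance
#'
#' Retains genes that are significant, change at least `fc_min`-fold in
#' either direction (inclusive: a gene at exactly 2-fold passes), and reach
#' `abundance_min` FPKM in at least one condition.
#'
#' @param det a [de_table()].
#' @param fc_min minimum linear fold change (default 2).
#' @param abundance_min minimum condition-mean abundance (default 1 FPKM).
#' @export
filter_de <- function(det, fc_min = 2, abundance_min = 1) {
  keep <- det$significant & abs(det$log2_fc) >= log2(fc_min) &
    det$max_abundance >= abundance_min
  out <- det[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

rank_genes <- function(det, direction) {
  d <- det[det$direction == direction &
             (if (direction == "up") det$fold_change >= 1 else det$fold_change <= 1), ]
  ord <- if (direction == "up")
    order(-d$fold_change, d$gene) else order(d$fold_change, d$gene)
  d$gene[ord]
}

#' Union of per-condition top differentially expressed genes
#'
#' For each condition's filtered DE table, takes the `n_top` most
#' up-regulated genes (ranked by descending fold change) and the `n_top`
#' most down-regulated (ascending fold change), and returns the union
#' across conditions -- the construction behind the set of most
#' differentially expressed genes shared by the BMP-treated conditions.
#' Ties in fold change break lexicographically by gene id.
#'
#' @param de_list named list of filtered [de_table()]s, one per condition.
#' @param n_top genes per direction per condition (default 100).
#' @return list with `genes` (sorted union), `size`, and `per_condition`
#'   (the top up/down lists actually used).
#' @export
union_top_set <- function(de_list, n_top = 100) {
  per <- lapply(de_list, function(det) {
    up <- rank_genes(det, "up")
    dn <- rank_genes(det, "down")
    if (length(up) < n_top || length(dn) < n_top)
      warning(sprintf("fewer than %d genes available in a direction; taking all", n_top))
    list(up = utils::head(up, n_top), down = utils::head(dn, n_top))
  })
  genes <- sort(unique(unlist(per)))
  list(genes = genes, size = length(genes), per_condition = per)
}

#' Three-set Venn region counts
#'
#' @param sets named list of three gene-id vectors.
#' @return named integer vector of the 7 region counts, names like
#'   `"A"`, `"A&B"`, `"A&B&C"` built from the set names, plus the union
#'   size as attribute `union`.
#' @export
venn_overlap <- function(sets) {
  stopifnot(length(sets) == 3, !is.null(names(sets)))
  sets <- lapply(sets, unique)
  nm <- names(sets)
  univ <- unique(unlist(sets))
  memb <- vapply(sets, function(s) univ %in% s, logical(length(univ)))
  if (length(univ) == 1L) memb <- matrix(memb, nrow = 1)
  key <- memb %*% c(1, 2, 4)
  counts <- vapply(1:7, function(k) sum(key == k), 0L)
  names(counts) <- vapply(1:7, function(k) {
    paste(nm[which(bitwAnd(k, c(1, 2, 4)) > 0)], collapse = "&")
  }, "")
  attr(counts, "union") <- length(univ)
  counts
}

#' Pairwise Pearson correlation of samples over a gene set
#'
#' @param expr genes-by-samples matrix.
#' @param gene_set gene ids (must all be present).
#' @param transform `"raw"`, `"log2"` (log2(x + pseudocount) + 1, the
#'   log-normalized read count convention; the shift does not affect
#'   correlations), or `"zscore"` (per-gene z-scores across samples).
#' @param pseudocount for the log transform (default 1).
#' @return samples-by-samples correlation matrix; pairs involving a
#'   constant vector are NA.
#' @export
correlation_matrix <- function(expr, gene_set,
                               transform = c("raw", "log2", "zscore"),
                               pseudocount = 1) {
  transform <- match.arg(transform)
  missing <- setdiff(gene_set, rownames(expr))
  if (length(missing))
    stop(sprintf("%d genes of gene_set absent from the matrix", length(missing)))
  x <- expr[gene_set, , drop = FALSE]
  x <- switch(transform,
              raw = x,
              log2 = log2(x + pseudocount) + 1,
              zscore = t(scale(t(x))))
  if (transform == "zscore") x <- x[stats::complete.cases(x), , drop = FALSE]
  suppressWarnings(stats::cor(x))
}

#' Lineage-specific gene selection for blastocyst lineages
#'
#' Selects, per lineage (e.g. epiblast, primitive endoderm,
#' trophectoderm), genes that (i) are differentially expressed versus at
#' least one other lineage (fold change > 5, strict, at the caller's FDR),
#' (ii) are *not* differentially expressed across the time points within
#' the lineage, and (iii) are well expressed in that lineage (abundance >=
#' `min_abundance` in at least 2 of the 3 time points). DE calls are
#' pluggable; the built-in fallback compares lineage means (between) and
#' day means within a lineage (within) with the same strict fold-change
#' rule.
#'
#' @param expr genes-by-samples matrix.
#' @param lineages,days character vectors per column (3 lineages x 3 days
#'   expected; every lineage must have all days).
#' @param de_between optional genes-by-lineages logical matrix of
#'   "DE versus >= 1 other lineage" calls.
#' @param de_within optional genes-by-lineages logical matrix of
#'   "DE across time points within the lineage" calls.
#' @param fc_min strict fold-change threshold for the built-in calls
#'   (default 5).
#' @param min_abundance expression floor (default 10 RPKM).
#' @param pseudocount for fold-change ratios.
#' @return list with `per_lineage` (named list of gene vectors), `genes`
#'   (the union), `size`.
#' @export
lineage_specific_genes <- function(expr, lineages, days,
                                   de_between = NULL, de_within = NULL,
                                   fc_min = 5, min_abundance = 10,
                                   pseudocount = 0.01) {
  lin <- unique(lineages); dy <- sort(unique(days))
  for (L in lin)
    if (!all(dy %in% days[lineages == L]))
      stop(sprintf("lineage %s is missing a time point", L))
  day_means <- function(L) vapply(dy, function(d)
    rowMeans(expr[, lineages == L & days == d, drop = FALSE]),
    numeric(nrow(expr)))
  lin_mean <- vapply(lin, function(L)
    rowMeans(expr[, lineages == L, drop = FALSE]), numeric(nrow(expr)))
  per <- lapply(lin, function(L) {
    dm <- day_means(L)
    between <- if (!is.null(de_between)) de_between[, L] else {
      others <- setdiff(lin, L)
      Reduce(`|`, lapply(others, function(M)
        (lin_mean[, L] + pseudocount) / (lin_mean[, M] + pseudocount) > fc_min))
    }
    within <- if (!is.null(de_within)) de_within[, L] else {
      (apply(dm, 1, max) + pseudocount) / (apply(dm, 1, min) + pseudocount) > fc_min
    }
    expressed <- rowSums(dm >= min_abundance) >= 2
    rownames(expr)[between & !within & expressed]
  })
  names(per) <- lin
  genes <- sort(unique(unlist(per)))
  list(per_lineage = per, genes = genes, size = length(genes))
}

#' Read / write expression matrices and gene sets
#'
#' Expression matrices are CSV/TSV with gene ids in the first column and a
#' header row of sample ids; gene sets are plain text, one id per line.
#'
#' @param path file path.
#' @param sep field separator (`","` or `"\t"`, guessed from extension).
#' @export
read_expression <- function(path, sep = if (grepl("\\.tsv$", path)) "\t" else ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_expression
#' @param genes character vector of gene ids.
#' @export
write_gene_set <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}
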