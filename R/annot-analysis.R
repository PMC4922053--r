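#' Construct a homology hit table
#'
#' @param query,subject Gene identifiers.
#' @param bitscore Bit scores (>= 0).
#' @param identity Optional percent identity.
#' @return Validated hit-table data.frame.
#' @export
hit_table <- function(query, subject, bitscore, identity = NA_real_) {
  df <- data.frame(query = as.character(query),
                   subject = as.character(subject),
                   bitscore = as.numeric(bitscore),
                   identity = as.numeric(identity),
                   stringsAsFactors = FALSE)
  stopifnot(all(df$bitscore >= 0))
  df
}

# best hit per query; ties kept (all rows at the top score)
best_hits <- function(tab, exclude_self = TRUE) {
  if (exclude_self) tab <- tab[tab$query != tab$subject, , drop = FALSE]
  if (nrow(tab) == 0L) return(tab)
  sp <- split(seq_len(nrow(tab)), tab$query)
  idx <- unlist(lapply(sp, function(i) {
    i[tab$bitscore[i] == max(tab$bitscore[i])]
  }), use.names = FALSE)
  tab[idx, , drop = FALSE]
}

#' Reciprocal best hits between two hit tables
#'
#' A pair `(x, y)` is reported when `y` is `x`'s unique top-bitscore hit
#' in `a_vs_b` and `x` is `y`'s unique top hit in `b_vs_a`. Queries whose
#' top score is tied between several subjects form no pair and are
#' reported in a tie list for auditability.
#'
#' @param a_vs_b,b_vs_a Hit tables (see [hit_table()]); self-hits are
#'   removed.
#' @return List with `pairs` (data.frame `gene_a`, `gene_b`) and `ties`
#'   (character vector of queries with tied top hits).
#' @export
reciprocal_best_hits <- function(a_vs_b, b_vs_a) {
  top <- function(tab) {
    bh <- best_hits(tab)
    sp <- split(bh$subject, bh$query)
    list(unique = vapply(sp, function(s) if (length(unique(s)) == 1L)
      s[1] else NA_character_, character(1)),
      ties = names(sp)[vapply(sp, function(s) length(unique(s)) > 1L,
                              logical(1))])
  }
  ta <- top(a_vs_b); tb <- top(b_vs_a)
  pairs <- list()
  for (x in names(ta$unique)) {
    y <- ta$unique[[x]]
    if (is.na(y)) next
    back <- tb$unique[y]
    if (!is.na(back) && !is.na(back[[1]]) && identical(unname(back[[1]]), x))
      pairs[[length(pairs) + 1L]] <- data.frame(gene_a = x, gene_b = y,
                                                stringsAsFactors = FALSE)
  }
  out <- if (length(pairs)) do.call(rbind, pairs)
         else data.frame(gene_a = character(0), gene_b = character(0))
  # deduplicate symmetric duplicates when both tables describe one species
  key <- apply(out, 1L, function(r) paste(sort(r), collapse = "\r"))
  out <- out[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  list(pairs = out, ties = unique(c(ta$ties, tb$ties)))
}

#' Genes whose closest paralog beats their best cross-species hit
#'
#' A gene is included when its best within-species non-self bitscore is
#' strictly greater than its best cross-species bitscore. Genes with no
#' cross-species hit are excluded from the denominator (their duplication
#' age cannot be polarised).
#'
#' @param self_hits Within-species hit table.
#' @param ortho_hits Cross-species hit table.
#' @return List with `genes` (character vector), `n_eligible` (genes with
#'   a cross-species hit) and `fraction`.
#' @export
closer_paralog_genes <- function(self_hits, ortho_hits) {
  bs <- best_hits(self_hits)
  bo <- best_hits(ortho_hits, exclude_self = FALSE)
  self_top <- tapply(bs$bitscore, bs$query, max)
  ortho_top <- tapply(bo$bitscore, bo$query, max)
  eligible <- names(ortho_top)
  genes <- eligible[!is.na(self_top[eligible]) &
                      self_top[eligible] > ortho_top[eligible]]
  list(genes = unname(genes), n_eligible = length(eligible),
       fraction = if (length(eligible)) length(genes) / length(eligible)
                  else NA_real_)
}

#' Fraction of paralog pairs sharing the same cross-species best hit
#'
#' @param pairs Data.frame with `gene_a`, `gene_b` (e.g. RBH pairs).
#' @param ortho_hits Cross-species hit table; reduced internally to the
#'   unique best hit per query.
#' @return List with `count`, `n_pairs` and `percentage` (one-decimal
#'   rounding).
#' @export
shared_best_hit_fraction <- function(pairs, ortho_hits) {
  if (nrow(pairs) == 0L) stop("undefined percentage: empty pair list")
  bo <- best_hits(ortho_hits, exclude_self = FALSE)
  sp <- split(bo$subject, bo$query)
  top1 <- vapply(sp, function(s) if (length(unique(s)) == 1L) s[1]
                 else NA_character_, character(1))
  ha <- top1[pairs$gene_a]; hb <- top1[pairs$gene_b]
  count <- sum(!is.na(ha) & !is.na(hb) & ha == hb)
  list(count = count, n_pairs = nrow(pairs),
       percentage = round(100 * count / nrow(pairs), 1))
}

#' Compare heterozygous SNV counts between duplicate and singleton genes
#'
#' Reports per-class mean, nearest-rank 70 per cent quantile, and Welch's
#' two-sample t statistic with Welch-Satterthwaite degrees of freedom.
#' Genes duplicated in the genome but collapsed in the assembly
#' accumulate excess heterozygous SNVs (reads from two loci pile onto
#' one), whereas uncollapsed haplotypes show the opposite pattern, so the
#' direction of this contrast discriminates real duplication from
#' assembly artifacts.
#'
#' @param snv_counts Named numeric vector: heterozygous SNV count per
#'   gene.
#' @param duplicates,singletons Disjoint character vectors of gene names.
#' @param quantile_p Quantile to report (default 0.7).
#' @return List with `mean_dup`, `mean_single`, `q_dup`, `q_single`,
#'   `t`, `df`, `p_value`.
#' @export
snv_class_comparison <- function(snv_counts, duplicates, singletons,
                                 quantile_p = 0.7) {
  if (length(intersect(duplicates, singletons)))
    stop("duplicate and singleton gene sets must be disjoint")
  x <- snv_counts[duplicates]; x <- x[!is.na(x)]
  y <- snv_counts[singletons]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("insufficient data: each class needs >= 2 genes with counts")
  stopifnot(all(x >= 0), all(y >= 0))
  nearest_rank <- function(v, p) unname(sort(v)[ceiling(p * length(v))])
  tt <- t.test(x, y, var.equal = FALSE)
  list(mean_dup = mean(x), mean_single = mean(y),
       q_dup = nearest_rank(x, quantile_p),
       q_single = nearest_rank(y, quantile_p),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' Filter candidate long non-coding RNAs
#'
#' Keeps transcripts longer than 200 bp whose length is covered by small
#' ncRNA annotations for less than 80 per cent.
#'
#' @param transcripts Data.frame with `id`, `length`,
#'   `small_ncrna_fraction` in `[0, 1]`.
#' @return The kept subset of `transcripts`.
#' @export
lncrna_filter <- function(transcripts) {
  stopifnot(all(transcripts$small_ncrna_fraction >= 0),
            all(transcripts$small_ncrna_fraction <= 1))
  transcripts[transcripts$length > 200 &
                transcripts$small_ncrna_fraction < 0.8, , drop = FALSE]
}

#' Transcripts-per-gene ratio
#'
#' @param n_transcripts,n_genes Counts; `n_genes` must be positive.
#' @param digits Decimals for the truncated presentation value
#'   (default 2).
#' @return List with `ratio` (full precision) and `truncated`
#'   (presentation value, truncated not rounded).
#' @examples
#' transcripts_per_gene(89982, 56349)$truncated  # 1.59
#' @export
transcripts_per_gene <- function(n_transcripts, n_genes, digits = 2L) {
  if (n_genes <= 0) stop("division error: n_genes must be positive")
  r <- n_transcripts / n_genes
  list(ratio = r, truncated = trunc(r * 10^digits) / 10^digits)
}
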