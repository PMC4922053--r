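#' Configuration for the read-pair consistency check
#'
#' @param sigma_mult Multiplier for the sigma bounds and for the
#'   inconsistent-evidence extension (default 3, i.e. `mean +/- 3 sd`).
#' @param min_region Minimum net-negative run length (bp) that triggers an
#'   excision (default 50).
#' @param end_slack Distance (bp) from a scaffold end within which
#'   cross-scaffold evidence is ignored; `NULL` (default) uses the upper
#'   insert bound `hi` of the library.
#' @param min_block Retained blocks shorter than this are dropped
#'   (default 200).
#' @return A `consistency_config` list.
#' @export
consistency_config <- function(sigma_mult = 3, min_region = 50L,
                               end_slack = NULL, min_block = 200L) {
  stopifnot(sigma_mult > 0, min_region >= 1)
  structure(list(sigma_mult = sigma_mult, min_region = as.integer(min_region),
                 end_slack = end_slack, min_block = as.integer(min_block)),
            class = "consistency_config")
}

#' Score per-base read-pair support over an assembly
#'
#' Each read pair votes on the assembly. A pair is consistent when both
#' mates map to the same scaffold, in the expected orientation, with an
#' insert inside the library bounds `[lo, hi]`; it adds +1 to the
#' consistent vector `C` over the full span `[min(pos), max(end))`. Every
#' other pair is inconsistent: each mate adds +1 to the inconsistent
#' vector `I` over the interval extending `mu + sigma_mult * sigma` bp from
#' its alignment in the direction its mate should lie, clipped to the
#' scaffold. Cross-scaffold pairs whose two mates both point toward a
#' scaffold end within `end_slack` are ignored (they are what legitimate
#' scaffolding gaps look like). The net support is `N = C - I`.
#'
#' @param assembly FASTA path or `DNAStringSet`.
#' @param pairs Pair-alignment data.frame aligned to `assembly`.
#' @param dist An `insert_distribution` for the library.
#' @param cfg A `consistency_config`.
#' @return A `support_profile`: list with `C`, `I`, `N` (RleList, one run-length
#'   encoded integer vector per scaffold) and `scaffold_lengths`.
#' @export
score_support <- function(assembly, pairs, dist, cfg = consistency_config()) {
  asm <- as_assembly(assembly)
  lens <- setNames(Biostrings::width(asm), names(asm))
  refs <- unique(c(pairs$scaffold_a, pairs$scaffold_b))
  missing_ref <- setdiff(refs, names(lens))
  if (length(missing_ref))
    stop("reference mismatch: alignments name scaffolds absent from the ",
         "assembly: ", paste(head(missing_ref, 3), collapse = ", "))
  slack <- cfg$end_slack %||% dist$hi
  ext <- dist$mu + cfg$sigma_mult * dist$sigma

  same <- pairs$scaffold_a == pairs$scaffold_b
  orient_ok <- rep(FALSE, nrow(pairs))
  orient_ok[same] <- pair_orientation_ok(pairs[same, , drop = FALSE],
                                         dist$expected_orientation)
  ins <- pair_insert(pairs)
  consistent <- same & orient_ok & ins >= dist$lo & ins <= dist$hi

  # mate extension interval: from the alignment, ext bp toward where the
  # missing mate should be (downstream of a + mate, upstream of a - mate)
  mate_interval <- function(pos, end, strand) {
    s <- ifelse(strand == "+", pos, pmax(0, end - ext))
    e <- ifelse(strand == "+", pos + ext, end)
    data.frame(start = s, end = e)
  }
  # cross-scaffold pair pointing at a nearby end on both sides -> ignore
  near_end <- function(scaf, pos, end, strand) {
    len <- lens[scaf]
    ifelse(strand == "+", len - end <= slack, pos <= slack)
  }
  cross <- !same
  ignore <- rep(FALSE, nrow(pairs))
  if (any(cross)) {
    ig <- near_end(pairs$scaffold_a[cross], pairs$pos_a[cross],
                   pairs$end_a[cross], pairs$strand_a[cross]) &
      near_end(pairs$scaffold_b[cross], pairs$pos_b[cross],
               pairs$end_b[cross], pairs$strand_b[cross])
    ignore[cross] <- ig
  }
  incons <- !consistent & !ignore

  cov_ranges <- function(scaf, start, end) {
    # start/end 0-based half-open -> IRanges 1-based; clip to scaffold
    keep <- end > start
    scaf <- scaf[keep]; start <- start[keep]; end <- end[keep]
    len <- lens[scaf]
    start <- pmax(start, 0); end <- pmin(end, len)
    keep <- end > start
    ir <- IRanges::IRanges(start = start[keep] + 1L, end = end[keep])
    rl <- S4Vectors::splitAsList(ir, factor(scaf[keep], levels = names(lens)))
    IRanges::coverage(rl, width = as.list(lens))
  }
  Cc <- cov_ranges(pairs$scaffold_a[consistent],
                   pmin(pairs$pos_a, pairs$pos_b)[consistent],
                   pmax(pairs$end_a, pairs$end_b)[consistent])
  ia <- mate_interval(pairs$pos_a[incons], pairs$end_a[incons],
                      pairs$strand_a[incons])
  ib <- mate_interval(pairs$pos_b[incons], pairs$end_b[incons],
                      pairs$strand_b[incons])
  Ic <- cov_ranges(c(pairs$scaffold_a[incons], pairs$scaffold_b[incons]),
                   c(ia$start, ib$start), c(ia$end, ib$end))
  structure(list(C = Cc, I = Ic, N = Cc - Ic, scaffold_lengths = lens),
            class = "support_profile")
}

#' Break an assembly at net-negative support regions
#'
#' Maximal runs where the net support `N = C - I` is negative and at least
#' `min_region` bp long are excised from the assembly; the flanking
#' retained blocks become separate sequences named `<scaffold>_partN`.
#' Retained blocks shorter than `min_block` bp are dropped.
#'
#' @param assembly FASTA path or `DNAStringSet`.
#' @param prof A `support_profile` from [score_support()].
#' @param cfg A `consistency_config`.
#' @return List with `assembly` (broken `DNAStringSet`) and `result`, a
#'   `break_result` holding `blocks` and `breakpoints` data.frames
#'   (0-based half-open coordinates in the input assembly) and the
#'   before/after block counts.
#' @export
break_assembly <- function(assembly, prof, cfg = consistency_config()) {
  asm <- as_assembly(assembly)
  stopifnot(inherits(prof, "support_profile"))
  if (!all(names(asm) %in% names(prof$N)))
    stop("profile does not cover all assembly scaffolds")
  blocks <- list(); breaks <- list()
  out_seqs <- list(); out_names <- character(0)
  for (sc in names(asm)) {
    n <- prof$N[[sc]]
    len <- length(n)
    stopifnot(len == Biostrings::width(asm[sc]))
    neg <- S4Vectors::Rle(as.vector(n < 0))
    rl <- S4Vectors::runLength(neg); rv <- S4Vectors::runValue(neg)
    ends <- cumsum(rl); starts <- ends - rl + 1L
    bad <- rv & rl >= cfg$min_region
    cut <- data.frame(start = starts[bad] - 1L, end = ends[bad])  # 0-based
    if (nrow(cut)) {
      breaks[[sc]] <- data.frame(scaffold = sc, start = cut$start,
                                 end = cut$end)
      keep_start <- c(0, cut$end)
      keep_end <- c(cut$start, len)
    } else {
      keep_start <- 0; keep_end <- len
    }
    ok <- keep_end - keep_start >= cfg$min_block &
      keep_end > keep_start
    ks <- keep_start[ok]; ke <- keep_end[ok]
    if (length(ks)) {
      nm <- if (length(ks) == 1L && !nrow(cut)) sc
            else paste0(sc, "_part", seq_along(ks))
      seqs <- Biostrings::extractAt(
        asm[[sc]], IRanges::IRanges(start = ks + 1L, end = ke))
      for (i in seq_along(nm)) {
        out_seqs[[length(out_seqs) + 1L]] <- seqs[[i]]
        out_names <- c(out_names, nm[i])
      }
      blocks[[sc]] <- data.frame(scaffold = sc, start = ks, end = ke,
                                 name = nm)
    }
  }
  out <- if (length(out_seqs)) Biostrings::DNAStringSet(out_seqs)
         else Biostrings::DNAStringSet()
  names(out) <- out_names
  res <- structure(list(
    blocks = if (length(blocks)) do.call(rbind, blocks)
             else data.frame(scaffold = character(0), start = numeric(0),
                             end = numeric(0), name = character(0)),
    breakpoints = if (length(breaks)) do.call(rbind, breaks)
                  else data.frame(scaffold = character(0), start = numeric(0),
                                  end = numeric(0)),
    n_blocks_before = length(asm),
    n_blocks_after = length(out)),
    class = "break_result")
  rownames(res$blocks) <- NULL; rownames(res$breakpoints) <- NULL
  list(assembly = out, result = res)
}

#' Sum support profiles from multiple libraries
#'
#' Profiles computed per library (e.g. short paired-end plus mate-pair
#' libraries) over the same assembly are combined by elementwise addition.
#'
#' @param ... `support_profile` objects over identical scaffolds.
#' @return A combined `support_profile`.
#' @export
combine_profiles <- function(...) {
  ps <- list(...)
  stopifnot(length(ps) >= 1L, all(vapply(ps, inherits, logical(1),
                                         "support_profile")))
  out <- ps[[1]]
  for (p in ps[-1]) {
    stopifnot(identical(names(out$N), names(p$N)))
    out$C <- out$C + p$C
    out$I <- out$I + p$I
  }
  out$N <- out$C - out$I
  out
}
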