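#' Screening configuration
#'
#' @param erode_bp Bases eroded from each contig end after exploding
#'   scaffolds at gaps (default 50).
#' @param min_contig Minimum contig length kept after erosion
#'   (default 200).
#' @param min_scaffold Minimum scaffold length kept in final filtering
#'   (default 500).
#' @param drop_fraction Scaffolds with at least this fraction covered by
#'   contaminant hits are deleted (default 0.5).
#' @param depth_flag_threshold Mean depth at or above which a scaffold
#'   carrying an organelle-class hit is deleted (default 6000); organelle
#'   genomes are sequenced at orders of magnitude above the nuclear depth.
#' @return A `screen_config` list.
#' @export
screen_config <- function(erode_bp = 50L, min_contig = 200L,
                          min_scaffold = 500L, drop_fraction = 0.5,
                          depth_flag_threshold = 6000) {
  stopifnot(erode_bp >= 0, min_contig >= 0, min_scaffold >= 0,
            drop_fraction >= 0, depth_flag_threshold >= 0)
  structure(list(erode_bp = as.integer(erode_bp),
                 min_contig = as.integer(min_contig),
                 min_scaffold = as.integer(min_scaffold),
                 drop_fraction = drop_fraction,
                 depth_flag_threshold = depth_flag_threshold),
            class = "screen_config")
}

hits_by_scaffold <- function(hits, lens) {
  bad <- setdiff(unique(hits$scaffold), names(lens))
  if (length(bad))
    stop("hits reference unknown scaffolds: ", paste(head(bad, 3),
                                                     collapse = ", "))
  if (any(hits$start < 0) ||
      any(hits$end > lens[hits$scaffold]))
    stop("coordinate error: hit interval outside scaffold bounds")
  S4Vectors::splitAsList(IRanges::IRanges(start = hits$start + 1L,
                                          end = hits$end),
                         factor(hits$scaffold, levels = names(lens)))
}

#' Mask contaminant hit intervals with Ns
#'
#' Every hit interval is replaced by Ns (overlapping hits are unioned);
#' sequence lengths are unchanged, so masking produces gaps rather than
#' coordinate shifts.
#'
#' @param assembly `DNAStringSet` or FASTA path.
#' @param hits Hit-interval data.frame (see [hit_intervals()]).
#' @return Masked `DNAStringSet`.
#' @export
mask_hits <- function(assembly, hits) {
  asm <- as_assembly(assembly)
  if (nrow(hits) == 0L) return(asm)
  lens <- setNames(Biostrings::width(asm), names(asm))
  hl <- hits_by_scaffold(hits, lens)
  for (sc in names(hl)) {
    ir <- IRanges::reduce(hl[[sc]])
    if (length(ir) == 0L) next
    asm[[sc]] <- Biostrings::replaceAt(
      asm[[sc]], ir, strrep("N", IRanges::width(ir)))
  }
  asm
}

#' Delete or trim scaffolds flagged by contamination screening
#'
#' A scaffold is deleted when the fraction of it covered by hits reaches
#' `drop_fraction`, or when its mean read depth reaches
#' `depth_flag_threshold` and it carries an organelle-class (`plastid` or
#' `mito`) hit. Otherwise hit regions touching a scaffold end are excised
#' (trimmed) and interior hit regions are masked with Ns.
#'
#' @param assembly `DNAStringSet` or FASTA path.
#' @param hits Hit-interval data.frame.
#' @param depth Optional named numeric vector of mean per-scaffold depth.
#' @param cfg A `screen_config`.
#' @return List with `assembly` (clean `DNAStringSet`), `removed`
#'   (data.frame of deleted scaffolds with reasons) and `trimmed`
#'   (data.frame of scaffolds whose ends were excised).
#' @export
drop_or_trim_scaffolds <- function(assembly, hits, depth = NULL,
                                   cfg = screen_config()) {
  asm <- as_assembly(assembly)
  lens <- setNames(Biostrings::width(asm), names(asm))
  hl <- if (nrow(hits)) hits_by_scaffold(hits, lens) else NULL
  removed <- list(); trimmed <- list()
  out <- list()
  organelle <- c("plastid", "mito")
  for (sc in names(asm)) {
    ir <- if (is.null(hl)) IRanges::IRanges() else IRanges::reduce(hl[[sc]])
    covered <- sum(IRanges::width(ir)) / lens[[sc]]
    dep <- if (!is.null(depth) && sc %in% names(depth)) depth[[sc]] else NA
    has_org <- any(hits$scaffold == sc & hits$db %in% organelle)
    if (covered >= cfg$drop_fraction) {
      removed[[sc]] <- data.frame(scaffold = sc, reason = "hit_fraction",
                                  value = covered)
      next
    }
    if (!is.na(dep) && dep >= cfg$depth_flag_threshold && has_org) {
      removed[[sc]] <- data.frame(scaffold = sc, reason = "organelle_depth",
                                  value = dep)
      next
    }
    s <- asm[[sc]]
    if (length(ir)) {
      lead <- IRanges::start(ir) == 1L
      trail <- IRanges::end(ir) == lens[[sc]]
      terminal <- ir[lead | trail]
      interior <- ir[!(lead | trail)]
      if (length(interior))
        s <- Biostrings::replaceAt(
          s, interior, strrep("N", IRanges::width(interior)))
      if (length(terminal)) {
        keep_from <- if (any(lead)) max(IRanges::end(ir[lead])) + 1L else 1L
        keep_to <- if (any(trail)) min(IRanges::start(ir[trail])) - 1L
                   else lens[[sc]]
        if (keep_to < keep_from) {
          removed[[sc]] <- data.frame(scaffold = sc, reason = "all_terminal",
                                      value = covered)
          next
        }
        s <- Biostrings::subseq(s, keep_from, keep_to)
        trimmed[[sc]] <- data.frame(scaffold = sc,
                                    kept_start = keep_from - 1L,
                                    kept_end = keep_to)
      }
    }
    out[[sc]] <- s
  }
  clean <- if (length(out)) Biostrings::DNAStringSet(out)
           else Biostrings::DNAStringSet()
  bind0 <- function(l, proto) if (length(l)) {
    x <- do.call(rbind, l); rownames(x) <- NULL; x
  } else proto
  list(assembly = clean,
       removed = bind0(removed, data.frame(scaffold = character(0),
                                           reason = character(0),
                                           value = numeric(0))),
       trimmed = bind0(trimmed, data.frame(scaffold = character(0),
                                           kept_start = numeric(0),
                                           kept_end = numeric(0))))
}

#' Explode scaffolds into contigs, erode ends, and length-filter
#'
#' Scaffolds are split at N runs of any length; each resulting contig
#' loses `erode_bp` from both ends (assembly edges are enriched in
#' errors), and contigs shorter than `min_contig` are dropped.
#'
#' @param assembly `DNAStringSet` or FASTA path.
#' @param cfg A `screen_config`.
#' @return Contig `DNAStringSet`, named `<scaffold>_ctgN`.
#' @export
explode_erode_filter <- function(assembly, cfg = screen_config()) {
  asm <- as_assembly(assembly)
  out_seqs <- character(0); out_names <- character(0)
  for (sc in names(asm)) {
    s <- as.character(asm[[sc]])
    parts <- strsplit(s, "N+")[[1]]
    parts <- parts[nchar(parts) > 0]
    for (i in seq_along(parts)) {
      p <- parts[i]
      n <- nchar(p)
      if (n - 2L * cfg$erode_bp < cfg$min_contig) next
      out_seqs <- c(out_seqs, substr(p, cfg$erode_bp + 1L, n - cfg$erode_bp))
      out_names <- c(out_names, paste0(sc, "_ctg", i))
    }
  }
  out <- Biostrings::DNAStringSet(out_seqs)
  names(out) <- out_names
  out
}

#' Extract read pairs where both mates failed to map
#'
#' Primary records are grouped by query name; pairs with both mates
#' unmapped are emitted as a read-pair set, while reads whose mate mapped
#' (or is missing) go to a singleton set.
#'
#' @param alignments SAM/BAM path or a record data.frame from
#'   [read_sam_records()].
#' @return List with `pairs` (list of data.frames `r1`, `r2` holding
#'   `qname`, `seq`, `qual`) and `singletons` (same columns).
#' @export
extract_unmapped_pairs <- function(alignments) {
  rec <- if (is.data.frame(alignments)) alignments
         else read_sam_records(alignments)
  r1 <- rec[rec$first, , drop = FALSE]
  r2 <- rec[!rec$first, , drop = FALSE]
  m <- match(r1$qname, r2$qname)
  paired1 <- r1[!is.na(m), , drop = FALSE]
  paired2 <- r2[m[!is.na(m)], , drop = FALSE]
  orphans <- rbind(r1[is.na(m), , drop = FALSE],
                   r2[!(r2$qname %in% r1$qname), , drop = FALSE])
  if (nrow(orphans))
    warning(nrow(orphans), " orphan records routed to singletons")
  both_un <- paired1$unmapped & paired2$unmapped
  one_un <- xor(paired1$unmapped, paired2$unmapped)
  pick <- function(df) df[, c("qname", "seq", "qual"), drop = FALSE]
  single <- rbind(
    pick(paired1[one_un & paired1$unmapped, , drop = FALSE]),
    pick(paired2[one_un & paired2$unmapped, , drop = FALSE]),
    pick(orphans[orphans$unmapped, , drop = FALSE]))
  list(pairs = list(r1 = pick(paired1[both_un, , drop = FALSE]),
                    r2 = pick(paired2[both_un, , drop = FALSE])),
       singletons = single)
}

#' Recruitment configuration
#' @param max_softclip_fraction Maximum clipped fraction of the read
#'   (soft plus hard clips over the full read length; default 1/3).
#' @param require_both_mates Emit a pair only when both mates pass
#'   (default TRUE).
#' @return A `recruit_config` list.
#' @export
recruit_config <- function(max_softclip_fraction = 1 / 3,
                           require_both_mates = TRUE) {
  stopifnot(max_softclip_fraction >= 0, max_softclip_fraction <= 1)
  structure(list(max_softclip_fraction = max_softclip_fraction,
                 require_both_mates = require_both_mates),
            class = "recruit_config")
}

#' Recruit well-anchored read pairs from alignments to a reference panel
#'
#' A mate passes when it is mapped and its clipped fraction (soft plus
#' hard clipped bases over the full read length) does not exceed
#' `max_softclip_fraction`; a pair is recruited only when both mates pass.
#' Large clips signal partial or foreign matches, so this keeps only reads
#' that genuinely belong to the panel.
#'
#' @param alignments SAM/BAM path or record data.frame from
#'   [read_sam_records()].
#' @param cfg A `recruit_config`.
#' @return List with `pairs` (data.frames `r1`, `r2`: `qname`, `seq`,
#'   `qual`) and `n_pairs_in`, `n_pairs_out`.
#' @export
recruit_reads <- function(alignments, cfg = recruit_config()) {
  rec <- if (is.data.frame(alignments)) alignments
         else read_sam_records(alignments)
  clip <- cigar_clip(rec$cigar)
  read_len <- nchar(rec$seq) + clip[, "hard"]
  read_len[read_len == 0] <- NA
  frac <- (clip[, "soft"] + clip[, "hard"]) / read_len
  pass <- !rec$unmapped & !is.na(frac) & frac <= cfg$max_softclip_fraction
  r1 <- rec[rec$first, , drop = FALSE]; p1 <- pass[rec$first]
  r2 <- rec[!rec$first, , drop = FALSE]; p2 <- pass[!rec$first]
  m <- match(r1$qname, r2$qname)
  ok1 <- !is.na(m)
  a <- r1[ok1, , drop = FALSE]; pa <- p1[ok1]
  b <- r2[m[ok1], , drop = FALSE]; pb <- p2[m[ok1]]
  keep <- if (cfg$require_both_mates) pa & pb else pa | pb
  pick <- function(df) df[, c("qname", "seq", "qual"), drop = FALSE]
  list(pairs = list(r1 = pick(a[keep, , drop = FALSE]),
                    r2 = pick(b[keep, , drop = FALSE])),
       n_pairs_in = nrow(a), n_pairs_out = sum(keep))
}

#' Keep only uniquely mapping records
#'
#' Records are kept when the second-best alignment score (`XS`) is absent
#' or worse than the best (`AS`) by at least `margin`. When no score tags
#' are available the filter falls back to a mapping-quality threshold
#' with a warning.
#'
#' @param alignments SAM/BAM path or record data.frame including `AS`/`XS`
#'   columns.
#' @param margin Minimum score advantage of the best hit (default 1; a tie
#'   is not unique).
#' @param fallback_mapq Mapping-quality threshold used when score tags are
#'   missing (default 20).
#' @return List with `kept` and `dropped` record data.frames.
#' @export
unique_mapping_filter <- function(alignments, margin = 1L,
                                  fallback_mapq = 20L) {
  rec <- if (is.data.frame(alignments)) alignments
         else read_sam_records(alignments, tags = c("AS", "XS"))
  if (!("AS" %in% names(rec)) || all(is.na(rec$AS))) {
    warning("no AS score annotations; falling back to mapq >= ",
            fallback_mapq)
    keep <- !rec$unmapped & !is.na(rec$mapq) & rec$mapq >= fallback_mapq
  } else {
    keep <- !rec$unmapped &
      (is.na(rec$XS) | (rec$AS - rec$XS) >= margin)
  }
  list(kept = rec[keep, , drop = FALSE],
       dropped = rec[!keep, , drop = FALSE])
}

#' Drop sequences shorter than a minimum length
#'
#' @param assembly `DNAStringSet` or FASTA path.
#' @param min_len Minimum length kept (default 500).
#' @return Filtered `DNAStringSet`.
#' @export
filter_by_length <- function(assembly, min_len = 500L) {
  asm <- as_assembly(assembly)
  asm[Biostrings::width(asm) >= min_len]
}
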