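#' Select homozygous alternative variants for polishing
#'
#' Keeps PASS (or unfiltered) records whose genotype is homozygous for a
#' non-reference allele; heterozygous, half-called and homozygous-reference
#' records are dropped. Multiallelic records keep only the
#' genotype-selected allele. Polishing a consensus with heterozygous calls
#' would randomly pick alleles, so only confident homozygous differences
#' from the draft are applied.
#'
#' @param vcf Path to a VCF (v4.x, plain or gzipped), a `vcfR` object, or
#'   a data.frame with columns `scaffold`, `pos` (0-based), `ref`, `alt`,
#'   `gt`, `filter`.
#' @return Data.frame of variants with columns `scaffold`, `pos`
#'   (0-based), `ref`, `alt`; attribute `n_skipped` counts malformed
#'   records.
#' @export
select_polishing_variants <- function(vcf) {
  tab <- if (is.data.frame(vcf)) {
    vcf
  } else {
    v <- if (methods::is(vcf, "vcfR")) vcf else vcfR::read.vcfR(vcf,
                                                                verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    gt <- if (ncol(v@gt) >= 2L) vcfR::extract.gt(v, element = "GT")[, 1]
          else rep(NA_character_, nrow(fix))
    data.frame(scaffold = fix$CHROM, pos = as.numeric(fix$POS) - 1,
               ref = fix$REF, alt = fix$ALT, gt = gt,
               filter = fix$FILTER %||% ".", stringsAsFactors = FALSE)
  }
  n_skipped <- 0L
  keep <- list()
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    if (is.na(r$ref) || is.na(r$alt) || is.na(r$gt) ||
        !grepl("^[ACGTN]+$", r$ref)) { n_skipped <- n_skipped + 1L; next }
    if (!(is.na(r$filter) || r$filter %in% c("PASS", "."))) next
    alleles <- strsplit(r$gt, "[/|]")[[1]]
    if (length(alleles) != 2L || any(alleles == ".")) next  # half-call -> het
    if (alleles[1] != alleles[2]) next                      # het
    ai <- suppressWarnings(as.integer(alleles[1]))
    if (is.na(ai) || ai == 0L) next                         # hom-ref
    alts <- strsplit(r$alt, ",")[[1]]
    if (ai > length(alts)) { n_skipped <- n_skipped + 1L; next }
    alt <- alts[ai]
    if (!grepl("^[ACGTN]+$", alt)) { n_skipped <- n_skipped + 1L; next }
    keep[[length(keep) + 1L]] <- data.frame(
      scaffold = r$scaffold, pos = r$pos, ref = r$ref, alt = alt,
      stringsAsFactors = FALSE)
  }
  out <- if (length(keep)) do.call(rbind, keep)
         else data.frame(scaffold = character(0), pos = numeric(0),
                         ref = character(0), alt = character(0))
  if (n_skipped) warning(n_skipped, " malformed records skipped")
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Apply variants to an assembly
#'
#' Substitutions and indels are applied left to right per scaffold with
#' cumulative offset tracking. A variant whose reference allele does not
#' match the assembly is rejected (reported, not fatal); when variants
#' overlap, the leftmost is applied and later conflicting ones are
#' skipped. Untouched positions are byte-identical to the input.
#'
#' @param assembly `DNAStringSet` or FASTA path.
#' @param variants Data.frame with `scaffold`, `pos` (0-based), `ref`,
#'   `alt` (e.g. from [select_polishing_variants()]).
#' @return List with `assembly` (polished `DNAStringSet`) and `report`
#'   data.frame (`scaffold`, `pos`, `ref`, `alt`, `status` one of
#'   `applied`/`skipped_overlap`/`rejected_ref_mismatch`).
#' @export
apply_variants <- function(assembly, variants) {
  asm <- as_assembly(assembly)
  status <- character(nrow(variants))
  if (nrow(variants)) {
    ord <- order(variants$scaffold, variants$pos)
    variants <- variants[ord, , drop = FALSE]
    status <- character(nrow(variants))
    for (sc in unique(variants$scaffold)) {
      idx <- which(variants$scaffold == sc)
      if (!(sc %in% names(asm))) { status[idx] <- "rejected_ref_mismatch"; next }
      s <- as.character(asm[[sc]])
      len <- nchar(s)
      apply_at <- integer(0); apply_end <- integer(0)
      apply_alt <- character(0)
      last_end <- -1
      for (i in idx) {
        p <- variants$pos[i]; ref <- variants$ref[i]; alt <- variants$alt[i]
        pe <- p + nchar(ref)
        if (p < 0 || pe > len ||
            substr(s, p + 1L, pe) != ref) {
          status[i] <- "rejected_ref_mismatch"; next
        }
        if (p < last_end) { status[i] <- "skipped_overlap"; next }
        apply_at <- c(apply_at, p); apply_end <- c(apply_end, pe)
        apply_alt <- c(apply_alt, alt)
        status[i] <- "applied"
        last_end <- pe
      }
      if (length(apply_at)) {
        asm[[sc]] <- Biostrings::replaceAt(
          asm[[sc]],
          IRanges::IRanges(start = apply_at + 1L, end = apply_end),
          apply_alt)
      }
    }
  }
  report <- cbind(variants[, c("scaffold", "pos", "ref", "alt"),
                           drop = FALSE],
                  data.frame(status = status, stringsAsFactors = FALSE))
  rownames(report) <- NULL
  list(assembly = asm, report = report)
}
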