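test_that("exact dovetail overlaps are found with correct geometry", {
  set.seed(3)
  S <- rand_seq(9000)
  ctg <- Biostrings::DNAStringSet(c(A = substr(S, 1, 6000),
                                    B = substr(S, 3001, 9000)))
  ov <- find_overlaps(ctg, merge_config())
  expect_equal(nrow(ov), 1L)
  expect_equal(ov$length, 3000)
  expect_equal(ov$edit_distance, 0)
  expect_equal(ov$a_start, 3000)
  expect_equal(ov$a_end, 6000)
  expect_equal(ov$b_start, 0)
  expect_equal(ov$b_end, 3000)
  expect_equal(ov$type, "dovetail")
  expect_error(find_overlaps(Biostrings::DNAStringSet(
    setNames(c("ACGT", "ACGT"), c("x", "x")))), "duplicate")
})

test_that("divergent overlaps respect the edit-distance threshold", {
  set.seed(4)
  S <- rand_seq(9000)
  B <- mutate_seq(substr(S, 3001, 9000), 0.01)
  ctg <- Biostrings::DNAStringSet(c(A = substr(S, 1, 6000), B = B))
  ov <- find_overlaps(ctg, merge_config(max_divergence = 0.015))
  expect_equal(nrow(ov), 1L)
  expect_lt(abs(ov$divergence - 0.01), 0.005)
  ov2 <- find_overlaps(ctg, merge_config(max_divergence = 0.005))
  expect_equal(nrow(ov2), 0L)
})

test_that("reverse-complement overlaps are reported with strand=opposite", {
  set.seed(5)
  S <- rand_seq(9000)
  B <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(S, 3001, 9000))))
  ctg <- Biostrings::DNAStringSet(c(A = substr(S, 1, 6000), B = B))
  ov <- find_overlaps(ctg, merge_config())
  expect_equal(nrow(ov), 1L)
  expect_equal(ov$strand, "opposite")
  expect_equal(ov$length, 3000)
  expect_equal(ov$edit_distance, 0)
})

test_that("unrelated contigs produce no overlaps", {
  set.seed(6)
  ctg <- Biostrings::DNAStringSet(setNames(replicate(20, rand_seq(2000)),
                                           paste0("r", 1:20)))
  ov <- find_overlaps(ctg, merge_config(min_overlap = 500,
                                        max_divergence = 0.015))
  expect_equal(nrow(ov), 0L)
})

test_that("merge_round absorbs containments and concatenates tilings", {
  set.seed(7)
  S <- rand_seq(20000)
  # identical copies collapse to one
  two <- Biostrings::DNAStringSet(c(u = S, v = S))
  mr <- merge_round(two, find_overlaps(two, merge_config()),
                    round = c(2400, 0.015))
  expect_equal(length(mr$contigs), 1L)
  expect_equal(unname(Biostrings::width(mr$contigs)), 20000)
  # three tiling contigs reconstruct the genome exactly
  ctg <- Biostrings::DNAStringSet(c(c1 = substr(S, 1, 8000),
                                    c2 = substr(S, 5001, 14000),
                                    c3 = substr(S, 11001, 20000)))
  mr2 <- merge_round(ctg, find_overlaps(ctg, merge_config()),
                     round = c(2400, 0.015))
  expect_equal(length(mr2$contigs), 1L)
  expect_equal(as.character(mr2$contigs[[1]]), S)
})

test_that("links resolve repeat branches; unsupported branches stay split", {
  set.seed(8)
  X <- rand_seq(4000); R <- rand_seq(5000); Y <- rand_seq(4000)
  Z <- rand_seq(4000)
  ctg <- Biostrings::DNAStringSet(c(
    cX = paste0(X, substr(R, 1, 3000)),
    cR = R,
    cY = paste0(substr(R, 2001, 5000), Y),
    cZ = paste0(substr(R, 2001, 5000), Z)))
  ov <- find_overlaps(ctg, merge_config())
  links <- data.frame(contig_a = "cR", orient_a = "+",
                      contig_b = "cY", orient_b = "+", gap = 0)
  mr <- merge_round(ctg, ov, round = c(2400, 0.015), links = links)
  seqs <- as.character(mr$contigs)
  expect_true(paste0(X, R, Y) %in% seqs)
  expect_true(any(grepl(Z, seqs, fixed = TRUE)))
  expect_false(any(grepl(paste0(R, Z), seqs, fixed = TRUE)))
  # without links the branch terminates: no contig contains R joined to Y
  mr0 <- merge_round(ctg, ov, round = c(2400, 0.015))
  expect_false(paste0(X, R, Y) %in% as.character(mr0$contigs))
})

test_that("tips absorb at the overlap threshold and spare interior nodes", {
  set.seed(9)
  S <- rand_seq(10000)
  tip <- substr(S, 9701, 10000)  # exactly matches the end, 300 bp
  ctg <- Biostrings::DNAStringSet(c(big = S, t = tip))
  ov <- find_overlaps(ctg, merge_config(min_overlap = 250,
                                        tip_min_overlap = 250))
  tm <- tip_merge(ctg, ov, tip_min_overlap = 250)
  expect_equal(tm$absorbed, "t")
  expect_equal(names(tm$contigs), "big")
  # 200 bp overlap below the 250 threshold: kept separate
  tip2 <- paste0(substr(S, 9801, 10000), rand_seq(400))
  ctg2 <- Biostrings::DNAStringSet(c(big = S, t2 = tip2))
  ov2 <- find_overlaps(ctg2, merge_config(min_overlap = 150,
                                          tip_min_overlap = 150))
  tm2 <- tip_merge(ctg2, ov2, tip_min_overlap = 250)
  expect_equal(length(tm2$contigs), 2L)
  # non-tip nodes are never removed
  chain <- Biostrings::DNAStringSet(c(a = substr(S, 1, 5000),
                                      b = substr(S, 2001, 8000),
                                      c = substr(S, 5001, 10000),
                                      t = tip))
  ov3 <- find_overlaps(chain, merge_config(min_overlap = 250,
                                           tip_min_overlap = 250))
  tm3 <- tip_merge(chain, ov3, tip_min_overlap = 250)
  # b and c are interior (degree >= 2): never modified or removed
  expect_true(all(c("b", "c") %in% names(tm3$contigs)))
  expect_true("t" %in% tm3$absorbed)
})

test_that("haplotype collapse keeps one copy below the divergence cap", {
  set.seed(10)
  hapA <- rand_seq(10000)
  hapB <- mutate_seq(hapA, 0.01)
  asm <- Biostrings::DNAStringSet(c(a = hapA, b = hapB))
  col <- collapse_haplotypes(asm, min_overlap = 4000, max_divergence = 0.03)
  expect_equal(length(col$contigs), 1L)
  expect_equal(unname(Biostrings::width(col$contigs)), 10000)
  # above threshold: both kept
  hapC <- mutate_seq(hapA, 0.05)
  asm2 <- Biostrings::DNAStringSet(c(a = hapA, b = hapC))
  col2 <- collapse_haplotypes(asm2, 4000, 0.03)
  expect_equal(length(col2$contigs), 2L)
  # total length never increases
  expect_lte(sum(Biostrings::width(col$contigs)),
             sum(Biostrings::width(asm)))
  expect_lte(sum(Biostrings::width(col2$contigs)),
             sum(Biostrings::width(asm2)))
})

test_that("pipeline identities: single input, self-merge, containment", {
  set.seed(12)
  S <- rand_seq(30000)
  one <- Biostrings::DNAStringSet(c(x = substr(S, 1, 15000),
                                    y = substr(S, 17001, 30000)))
  res <- merge_pipeline(one)
  expect_equal(sort(unname(as.character(res$contigs))),
               sort(unname(as.character(one))))
  # merging an assembly with itself is the identity
  res2 <- merge_pipeline(list(one, one))
  expect_equal(sort(unname(as.character(res2$contigs))),
               sort(unname(as.character(one))))
  # strict subset input is absorbed by the superset
  sub <- one[1]
  res3 <- merge_pipeline(list(one, sub))
  expect_equal(sort(unname(as.character(res3$contigs))),
               sort(unname(as.character(one))))
})

test_that("pool assemblies tiling a genome merge toward the truth", {
  set.seed(13)
  G <- 1e5
  S <- rand_seq(G)
  pools <- lapply(1:10, function(p) {
    starts <- sort(sample.int(G - 10000, 4))
    Biostrings::DNAStringSet(setNames(
      vapply(starts, function(s) substr(S, s + 1, s + 10000), ""),
      sprintf("p%d_c%d", p, seq_along(starts))))
  })
  res <- merge_pipeline(pools)
  w <- Biostrings::width(res$contigs)
  input_n50 <- 10000
  expect_lt(abs(sum(w) - G) / G, 0.1)
  expect_gte(n50(w), 3 * input_n50)
  # idempotence on the merged result
  res2 <- merge_pipeline(res$contigs)
  expect_equal(sort(unname(as.character(res2$contigs))),
               sort(unname(as.character(res$contigs))))
})
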