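# String-graph construction and unitig merging over contig overlaps.
#
# Nodes are oriented contigs ("name+" / "name-"); a dovetail overlap
# contributes an edge u -> v meaning "v extends the path after u", with
# ext = the number of bases v adds beyond the overlap. Every edge has a
# reverse-complement twin.

node_id <- function(contig, orient) paste0(contig, orient)
node_contig <- function(node) substr(node, 1L, nchar(node) - 1L)
node_orient <- function(node) substr(node, nchar(node), nchar(node))
flip_node <- function(node) {
  o <- node_orient(node)
  node_id(node_contig(node), if (o == "+") "-" else "+")
}

# dovetail overlap rows -> directed edge table (both twins)
build_edges <- function(ovl, lens) {
  dv <- ovl[ovl$type == "dovetail", , drop = FALSE]
  if (nrow(dv) == 0L)
    return(data.frame(from = character(0), to = character(0),
                      ovl_from = numeric(0), ovl_to = numeric(0),
                      ext = numeric(0), stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(dv)), function(i) {
    r <- dv[i, ]
    la <- lens[[r$contig_a]]; lb <- lens[[r$contig_b]]
    same <- r$strand == "same"
    # diag > 0: suffix of A+ matches prefix of oriented B
    if (r$diag > 0) {
      from <- node_id(r$contig_a, "+")
      to <- node_id(r$contig_b, if (same) "+" else "-")
    } else {
      from <- node_id(r$contig_b, if (same) "+" else "-")
      to <- node_id(r$contig_a, "+")
    }
    ovl_from <- if (r$diag > 0) r$length else r$length_b
    ovl_to <- if (r$diag > 0) r$length_b else r$length
    lt <- lens[[node_contig(to)]]
    e1 <- data.frame(from = from, to = to, ovl_from = ovl_from,
                     ovl_to = ovl_to, ext = lt - ovl_to,
                     stringsAsFactors = FALSE)
    lf <- lens[[node_contig(from)]]
    e2 <- data.frame(from = flip_node(to), to = flip_node(from),
                     ovl_from = ovl_to, ovl_to = ovl_from,
                     ext = lf - ovl_from, stringsAsFactors = FALSE)
    rbind(e1, e2)
  })
  ed <- do.call(rbind, rows)
  ed <- ed[ed$ext > 0, , drop = FALSE]          # degenerate dovetails out
  ed[!duplicated(ed[, c("from", "to")]), , drop = FALSE]
}

# remove contained contigs; equal-length mutual containments keep the
# lexicographically smaller name
contained_contigs <- function(ovl, lens) {
  drop <- character(0)
  ct <- ovl[ovl$type %in% c("contains", "contained"), , drop = FALSE]
  for (i in seq_len(nrow(ct))) {
    r <- ct[i, ]
    la <- lens[[r$contig_a]]; lb <- lens[[r$contig_b]]
    inner <- if (la == lb) max(r$contig_a, r$contig_b)
             else if (r$type == "contains") r$contig_b else r$contig_a
    drop <- c(drop, inner)
  }
  unique(drop)
}

# path-based transitive reduction: an edge u->w is redundant when w is
# reachable from another out-neighbour of u with matching accumulated
# extension (within fuzz bp)
reduce_transitive <- function(edges, fuzz = 200) {
  if (nrow(edges) == 0L) return(edges)
  adj <- split(seq_len(nrow(edges)), edges$from)
  redundant <- rep(FALSE, nrow(edges))
  for (u in names(adj)) {
    eidx <- adj[[u]]
    if (length(eidx) < 2L) next
    ord <- order(edges$ext[eidx])
    eidx <- eidx[ord]
    exts <- edges$ext[eidx]
    targets <- edges$to[eidx]
    maxext <- exts[length(exts)] + fuzz
    # BFS from the nearest target(s) along the graph
    for (si in seq_len(length(eidx) - 1L)) {
      if (redundant[eidx[si]]) next
      start <- targets[si]
      dist <- setNames(exts[si], start)
      frontier <- start
      steps <- 0L
      while (length(frontier) && steps < 60L) {
        steps <- steps + 1L
        nxt <- character(0)
        for (v in frontier) {
          dv <- unname(dist[v])
          for (ei in adj[[v]] %||% integer(0)) {
            wv <- edges$to[ei]
            ndist <- dv + edges$ext[ei]
            if (ndist > maxext) next
            cur <- unname(dist[wv])
            if (is.na(cur) || ndist < cur) {
              dist[wv] <- ndist
              nxt <- c(nxt, wv)
            }
          }
        }
        frontier <- unique(nxt)
      }
      for (ti in seq_along(eidx)) {
        if (ti == si) next
        dw <- unname(dist[targets[ti]])
        if (!is.na(dw) && abs(dw - exts[ti]) <= fuzz)
          redundant[eidx[ti]] <- TRUE
      }
    }
  }
  edges[!redundant, , drop = FALSE]
}

# does the link set support the step contig(u)->contig(v) with these
# orientations?
link_supports <- function(links, u, v) {
  if (is.null(links) || nrow(links) == 0L) return(FALSE)
  cu <- node_contig(u); ou <- node_orient(u)
  cv <- node_contig(v); ov <- node_orient(v)
  fwd <- links$contig_a == cu & links$contig_b == cv &
    links$orient_a == ou & links$orient_b == ov
  flip <- function(o) ifelse(o == "+", "-", "+")
  rev <- links$contig_a == cv & links$contig_b == cu &
    links$orient_a == flip(ov) & links$orient_b == flip(ou)
  any(fwd | rev)
}

# choose the unique continuation from node u, or NA
choose_step <- function(u, edges, adj, radj, links) {
  eidx <- adj[[u]] %||% integer(0)
  if (length(eidx) == 0L) return(NA_integer_)
  if (length(eidx) > 1L) {
    supported <- eidx[vapply(eidx, function(ei)
      link_supports(links, u, edges$to[ei]), logical(1))]
    if (length(supported) != 1L) return(NA_integer_)
    eidx <- supported
  }
  v <- edges$to[eidx]
  back <- radj[[v]] %||% integer(0)
  if (length(back) > 1L) {
    supported <- back[vapply(back, function(ei)
      link_supports(links, edges$from[ei], v), logical(1))]
    if (!(length(supported) == 1L && supported == eidx)) return(NA_integer_)
  }
  eidx
}

oriented_seq <- function(seqs, node) {
  s <- seqs[[node_contig(node)]]
  if (node_orient(node) == "+") s else rc_chr(s)
}

# concatenate a node path into one sequence; across each overlap the copy
# from the longer contig is retained
path_sequence <- function(path, path_edges, seqs, lens, edges) {
  cur <- oriented_seq(seqs, path[1])
  prev_len <- lens[[node_contig(path[1])]]
  for (i in seq_along(path_edges)) {
    ei <- path_edges[i]
    v <- path[i + 1L]
    sv <- oriented_seq(seqs, v)
    lv <- lens[[node_contig(v)]]
    o_from <- edges$ovl_from[ei]; o_to <- edges$ovl_to[ei]
    if (lv >= prev_len) {
      cur <- paste0(substr(cur, 1L, nchar(cur) - o_from), sv)
    } else {
      cur <- paste0(cur, substr(sv, o_to + 1L, lv))
    }
    prev_len <- lv
  }
  cur
}

#' One round of overlap-graph merging
#'
#' Contained contigs are absorbed, transitive edges reduced, and simple
#' paths of the remaining dovetail graph concatenated into unitigs. At a
#' branch the walk continues only when the scaffold link set supports
#' exactly one outgoing branch; otherwise the unitig ends there and the
#' repeat stays collapsed as a single copy. Across each retained overlap
#' the sequence of the longer contig wins.
#'
#' @param contigs `DNAStringSet` (or FASTA path).
#' @param overlaps Overlap table from [find_overlaps()], computed on (at
#'   least) these contigs at the round's thresholds.
#' @param round Numeric pair `c(min_overlap, max_divergence)` used to
#'   re-filter `overlaps`.
#' @param links Optional link data.frame (`contig_a`, `orient_a`,
#'   `contig_b`, `orient_b`, `gap`).
#' @return List with `contigs` (merged `DNAStringSet`), `n_merged`,
#'   `dropped_contained` (names).
#' @export
merge_round <- function(contigs, overlaps, round = c(2400, 0.015),
                        links = NULL) {
  ctg <- as_assembly(contigs)
  seqs <- as.character(ctg)
  lens <- nchar(seqs); names(lens) <- names(seqs)
  ovl <- overlaps[overlaps$length >= round[1] &
                    overlaps$divergence <= round[2], , drop = FALSE]
  drop <- contained_contigs(ovl, lens)
  keep <- setdiff(names(seqs), drop)
  ovl <- ovl[ovl$contig_a %in% keep & ovl$contig_b %in% keep, , drop = FALSE]
  edges <- build_edges(ovl, lens)
  edges <- reduce_transitive(edges)
  adj <- split(seq_len(nrow(edges)), edges$from)
  radj <- split(seq_len(nrow(edges)), edges$to)
  visited <- setNames(rep(FALSE, length(keep)), keep)
  out_seqs <- character(0); out_names <- character(0)
  n_merged <- 0L
  for (start_contig in keep) {
    if (visited[[start_contig]]) next
    node <- node_id(start_contig, "+")
    # walk backwards to the path start
    seen <- node_contig(node)
    repeat {
      # a backward step is a forward step from the flipped node
      ei <- choose_step(flip_node(node), edges, adj, radj, links)
      if (is.na(ei)) break
      prev <- flip_node(edges$to[ei])
      if (node_contig(prev) %in% seen) break   # cycle guard
      node <- prev
      seen <- c(seen, node_contig(node))
    }
    # walk forwards collecting the path
    path <- node
    path_edges <- integer(0)
    repeat {
      ei <- choose_step(path[length(path)], edges, adj, radj, links)
      if (is.na(ei)) break
      v <- edges$to[ei]
      if (node_contig(v) %in% node_contig(path)) break
      path <- c(path, v)
      path_edges <- c(path_edges, ei)
    }
    pcontigs <- node_contig(path)
    if (any(visited[pcontigs])) {
      # partial revisit (shared repeat end); emit only if start unvisited
      unv <- !visited[pcontigs]
      path <- path[unv]
      path_edges <- integer(0)
      if (length(path) > 1L) path <- path[1]
      if (length(path) == 0L) next
      pcontigs <- node_contig(path)
    }
    visited[pcontigs] <- TRUE
    if (length(path) == 1L) {
      out_seqs <- c(out_seqs, seqs[[pcontigs]])
      out_names <- c(out_names, pcontigs)
    } else {
      n_merged <- n_merged + 1L
      out_seqs <- c(out_seqs, path_sequence(path, path_edges, seqs, lens,
                                            edges))
      out_names <- c(out_names, paste0("merge_", n_merged, "_", pcontigs[1]))
    }
  }
  out <- Biostrings::DNAStringSet(out_seqs)
  names(out) <- out_names
  list(contigs = out, n_merged = n_merged, dropped_contained = drop)
}

#' Absorb dead-end tips into longer paths
#'
#' A tip is a contig with at most one overlap neighbour. When its overlap
#' with a longer contig is at least `tip_min_overlap` bp it is absorbed:
#' contained tips are dropped, dovetailing tips are concatenated onto the
#' longer contig. Interior (non-tip) contigs are never modified.
#'
#' @param contigs `DNAStringSet` (or FASTA path).
#' @param overlaps Overlap table from [find_overlaps()] computed down to
#'   `tip_min_overlap`.
#' @param tip_min_overlap Minimum overlap for absorption (default 250).
#' @return List with `contigs` and `absorbed` (character vector of tip
#'   names that were merged away).
#' @export
tip_merge <- function(contigs, overlaps, tip_min_overlap = 250L) {
  ctg <- as_assembly(contigs)
  seqs <- as.character(ctg)
  lens <- nchar(seqs); names(lens) <- names(seqs)
  ovl <- overlaps[overlaps$length >= tip_min_overlap |
                    overlaps$length_b >= tip_min_overlap, , drop = FALSE]
  if (nrow(ovl) == 0L) return(list(contigs = ctg, absorbed = character(0)))
  nb <- table(c(ovl$contig_a, ovl$contig_b))
  deg <- setNames(rep(0L, length(seqs)), names(seqs))
  deg[names(nb)] <- as.integer(nb)
  tips <- names(deg)[deg <= 1L & deg > 0L]
  absorbed <- character(0)
  for (t in tips) {
    if (t %in% absorbed) next
    rows <- ovl[ovl$contig_a == t | ovl$contig_b == t, , drop = FALSE]
    if (nrow(rows) != 1L) next
    r <- rows[1, ]
    other <- if (r$contig_a == t) r$contig_b else r$contig_a
    if (other %in% absorbed) next
    if (lens[[other]] <= lens[[t]]) next
    if (r$type %in% c("contains", "contained")) {
      inner <- if (r$type == "contains") r$contig_b else r$contig_a
      if (inner == t) absorbed <- c(absorbed, t)
      next
    }
    # dovetail: extend `other` with the tip's overhang
    ed <- build_edges(r, lens)
    ed <- ed[node_contig(ed$from) == other & node_orient(ed$from) == "+", ,
             drop = FALSE]
    if (nrow(ed) == 1L) {
      seqs[[other]] <- path_sequence(c(ed$from, ed$to), 1L, seqs, lens,
                                     ed)
    } else {
      ed2 <- build_edges(r, lens)
      ed2 <- ed2[node_contig(ed2$to) == other & node_orient(ed2$to) == "+", ,
                 drop = FALSE]
      if (nrow(ed2) != 1L) next
      seqs[[other]] <- path_sequence(c(ed2$from, ed2$to), 1L, seqs, lens,
                                     ed2)
    }
    absorbed <- c(absorbed, t)
  }
  out <- Biostrings::DNAStringSet(seqs[setdiff(names(seqs), absorbed)])
  list(contigs = out, absorbed = absorbed)
}

#' Collapse uncollapsed haplotypes within one assembly
#'
#' Finds self-overlaps of the assembly at a long minimum overlap and low
#' divergence (so only near-identical allelic copies, assembly artifacts
#' and near-identical repeats match), drops contained copies keeping the
#' longer contig, and merges dovetailing haplotype copies. Total assembly
#' length never increases.
#'
#' @param assembly `DNAStringSet` or FASTA path.
#' @param min_overlap Minimum overlap (default 4000 bp).
#' @param max_divergence Maximum divergence (default 0.03, a close-match
#'   criterion).
#' @return List with `contigs` (collapsed `DNAStringSet`), `n_merged`,
#'   `dropped_contained`.
#' @export
collapse_haplotypes <- function(assembly, min_overlap = 4000L,
                                max_divergence = 0.03) {
  ctg <- as_assembly(assembly)
  cfg <- merge_config(min_overlap = min_overlap,
                      max_divergence = max_divergence,
                      tip_min_overlap = min(250L, min_overlap),
                      rounds = list(c(min_overlap, max_divergence)))
  ovl <- find_overlaps(ctg, cfg)
  merge_round(ctg, ovl, round = c(min_overlap, max_divergence))
}

#' Merge multiple assemblies through the full pipeline
#'
#' Concatenates the input assemblies (prefixing contig names when they
#' collide), then per configured round finds overlaps and merges unitigs,
#' then absorbs tips down to `tip_min_overlap`, and finally reinserts
#' scaffold links that remain coherent (both endpoints survive as output
#' sequences with their relative orientation preserved) as N-gapped joins.
#'
#' @param assemblies A list of `DNAStringSet`/FASTA paths (or a single
#'   one).
#' @param links Optional link data.frame (`contig_a`, `orient_a`,
#'   `contig_b`, `orient_b`, `gap`).
#' @param cfg A `merge_config`.
#' @return List with `contigs` (merged `DNAStringSet`) and `log` (list of
#'   per-stage summaries).
#' @export
merge_pipeline <- function(assemblies, links = NULL, cfg = merge_config()) {
  if (!is.list(assemblies) || methods::is(assemblies, "DNAStringSet"))
    assemblies <- list(assemblies)
  sets <- lapply(assemblies, as_assembly)
  all_names <- unlist(lapply(sets, names))
  if (anyDuplicated(all_names)) {
    sets <- lapply(seq_along(sets), function(i) {
      s <- sets[[i]]
      names(s) <- paste0("a", i, ":", names(s))
      s
    })
    if (!is.null(links) && nrow(links))
      warning("contig names collide across inputs; links referring to ",
              "renamed contigs may not resolve")
  }
  contigs <- do.call(c, sets)
  log <- list()
  for (ri in seq_along(cfg$rounds)) {
    rd <- cfg$rounds[[ri]]
    rcfg <- cfg
    rcfg$min_overlap <- as.integer(rd[1])
    rcfg$max_divergence <- rd[2]
    ovl <- find_overlaps(contigs, rcfg)
    mr <- merge_round(contigs, ovl, round = rd, links = links)
    log[[paste0("round", ri)]] <- list(
      n_in = length(contigs), n_out = length(mr$contigs),
      n_merged = mr$n_merged, n_contained = length(mr$dropped_contained))
    contigs <- mr$contigs
  }
  tcfg <- cfg
  tcfg$min_overlap <- cfg$tip_min_overlap
  tcfg$max_divergence <- max(vapply(cfg$rounds, `[`, numeric(1), 2))
  ovl <- find_overlaps(contigs, tcfg)
  tm <- tip_merge(contigs, ovl, cfg$tip_min_overlap)
  log$tips <- list(absorbed = length(tm$absorbed))
  contigs <- tm$contigs
  if (!is.null(links) && nrow(links)) {
    contigs <- reinsert_links(contigs, links)
    log$links <- list(n_after = length(contigs))
  }
  list(contigs = contigs, log = log)
}

# join surviving link endpoints with N gaps
reinsert_links <- function(contigs, links) {
  seqs <- as.character(contigs)
  used <- character(0)
  for (i in seq_len(nrow(links))) {
    l <- links[i, ]
    if (!(l$contig_a %in% names(seqs)) || !(l$contig_b %in% names(seqs)))
      next
    if (l$contig_a %in% used || l$contig_b %in% used) next
    gap <- max(as.numeric(l$gap %||% 10), 10)
    sa <- if (l$orient_a == "+") seqs[[l$contig_a]] else rc_chr(seqs[[l$contig_a]])
    sb <- if (l$orient_b == "+") seqs[[l$contig_b]] else rc_chr(seqs[[l$contig_b]])
    joined <- paste0(sa, strrep("N", gap), sb)
    nm <- paste0(l$contig_a, "_", l$contig_b)
    seqs <- seqs[setdiff(names(seqs), c(l$contig_a, l$contig_b))]
    seqs[[nm]] <- joined
    used <- c(used, l$contig_a, l$contig_b)
  }
  out <- Biostrings::DNAStringSet(seqs)
  out
}
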