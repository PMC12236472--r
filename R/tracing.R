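# Backbone tracing: from refined C-alpha candidates and per-candidate
# amino-acid probabilities to a sequence-registered backbone model.

# Gaussian edge weight peaked at the ideal consecutive C-alpha spacing
edge_weight <- function(d, p1, p2, ideal = 3.8, sd = 0.5) {
  exp(-(d - ideal)^2 / (2 * sd^2)) * pmin(p1, p2)
}

#' Build the C-alpha connectivity graph
#'
#' Connects every pair of candidates whose distance lies in the
#' chemically plausible consecutive-residue window (2-6 Angstrom). Edge
#' weights are a Gaussian in distance peaked at 3.8 Angstrom multiplied by
#' the smaller of the two endpoint C-alpha probabilities.
#'
#' @param cands a `candidate_set` data.frame.
#' @param dmin,dmax edge distance window, Angstrom.
#' @return A `ca_graph`: list with `edges` (data.frame from, to, dist,
#'   weight; from < to), `n` (number of candidates), `coords`.
#' @export
build_graph <- function(cands, dmin = 2.0, dmax = 6.0) {
  n <- nrow(cands)
  coords <- as.matrix(cands[, c("x", "y", "z")])
  if (n < 2L) {
    return(structure(list(edges = data.frame(from = integer(0),
                                             to = integer(0),
                                             dist = numeric(0),
                                             weight = numeric(0)),
                          n = n, coords = coords), class = "ca_graph"))
  }
  dd <- as.matrix(stats::dist(coords))
  idx <- which(upper.tri(dd) & dd >= dmin & dd <= dmax, arr.ind = TRUE)
  edges <- data.frame(
    from = idx[, 1], to = idx[, 2],
    dist = dd[idx],
    weight = edge_weight(dd[idx], cands$ca_prob[idx[, 1]],
                         cands$ca_prob[idx[, 2]]))
  structure(list(edges = edges, n = n, coords = coords), class = "ca_graph")
}

graph_adjacency <- function(g) {
  adj <- vector("list", g$n)
  for (r in seq_len(nrow(g$edges))) {
    e <- g$edges[r, ]
    adj[[e$from]] <- c(adj[[e$from]], e$to)
    adj[[e$to]] <- c(adj[[e$to]], e$from)
  }
  adj
}

#' Prune the connectivity graph to maximum degree 2
#'
#' Removes edges in ascending weight order: an edge is dropped whenever
#' either endpoint still has degree above 2, preserving the strongest
#' (most backbone-like) connections and the linear chain topology.
#'
#' @param g a `ca_graph`.
#' @return A `ca_graph` with every node of degree <= 2.
#' @export
prune_graph <- function(g) {
  e <- g$edges
  if (nrow(e) == 0L) return(g)
  deg <- tabulate(c(e$from, e$to), nbins = g$n)
  keep <- rep(TRUE, nrow(e))
  for (r in order(e$weight)) {
    if (deg[e$from[r]] > 2L || deg[e$to[r]] > 2L) {
      keep[r] <- FALSE
      deg[e$from[r]] <- deg[e$from[r]] - 1L
      deg[e$to[r]] <- deg[e$to[r]] - 1L
    }
  }
  g$edges <- e[keep, , drop = FALSE]
  rownames(g$edges) <- NULL
  g
}

#' Extract linear traces from a pruned graph
#'
#' Connected components of a degree-<=2 graph are simple paths or cycles;
#' cycles are cut at their weakest edge. Each trace is reported in a
#' canonical orientation (endpoint with the smaller candidate id first).
#'
#' @param g a pruned `ca_graph` (max degree 2).
#' @return List of integer vectors of candidate ids; their union, together
#'   with isolated nodes (traces of length 1), partitions the nodes.
#' @export
extract_traces <- function(g) {
  e <- g$edges
  deg <- tabulate(c(e$from, e$to), nbins = g$n)
  if (any(deg > 2L)) stop("extract_traces: graph not pruned (degree > 2)")
  ig <- igraph::graph_from_data_frame(
    d = if (nrow(e) > 0L) data.frame(from = e$from, to = e$to,
                                     weight = e$weight)
        else data.frame(from = integer(0), to = integer(0),
                        weight = numeric(0)),
    directed = FALSE,
    vertices = data.frame(name = seq_len(g$n)))
  comps <- igraph::components(ig)
  out <- list()
  for (c1 in seq_len(comps$no)) {
    vids <- which(comps$membership == c1)
    sub <- igraph::induced_subgraph(ig, vids)
    nv <- igraph::vcount(sub); ne <- igraph::ecount(sub)
    if (nv == 1L) {
      out[[length(out) + 1L]] <- as.integer(igraph::V(sub)$name)
      next
    }
    if (ne == nv) {                         # cycle: cut the weakest edge
      wts <- igraph::E(sub)$weight
      sub <- igraph::delete_edges(sub, which.min(wts))
    }
    ends <- igraph::V(sub)[igraph::degree(sub) <= 1L]
    path <- igraph::shortest_paths(sub, from = ends[1], to = ends[2],
                                   output = "vpath")$vpath[[1]]
    ids <- as.integer(igraph::V(sub)$name[as.integer(path)])
    if (ids[1] > ids[length(ids)]) ids <- rev(ids)
    out[[length(out) + 1L]] <- ids
  }
  out
}

#' Build the candidate-to-sequence scoring matrix
#'
#' `S[[i]][j, k]` is the probability that candidate k has the amino-acid
#' type of residue j of chain sequence i, read from the candidate's
#' 20-type probability vector. Unknown residue letters score uniform 1/20.
#'
#' @param cands a `candidate_set`.
#' @param sequences character vector of chain sequences (one-letter codes).
#' @return List of numeric matrices (residues x candidates), class
#'   `score_matrix`.
#' @export
build_score_matrix <- function(cands, sequences) {
  aa <- aa_prob_matrix(cands)               # n x 20
  out <- lapply(sequences, function(sq) {
    letters1 <- strsplit(sq, "")[[1]]
    codes <- aa_code(letters1)
    S <- matrix(1 / 20, nrow = length(letters1), ncol = nrow(cands))
    known <- !is.na(codes)
    if (any(known) && nrow(cands) > 0L)
      S[known, ] <- t(aa[, codes[known], drop = FALSE])
    S
  })
  class(out) <- "score_matrix"
  out
}

# nodes at graph distance exactly h from each node, for h = 0..N
hop_sets <- function(g, N) {
  adj <- graph_adjacency(g)
  lapply(seq_len(g$n), function(v) {
    sets <- vector("list", N + 1L)
    sets[[1]] <- v
    seen <- rep(FALSE, g$n); seen[v] <- TRUE
    frontier <- v
    for (h in seq_len(N)) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[!seen[nxt]]
      seen[nxt] <- TRUE
      sets[[h + 1L]] <- nxt
      frontier <- nxt
      if (length(frontier) == 0L) break
    }
    sets
  })
}

#' Enhance the scoring matrix by N-hop connectivity propagation
#'
#' `S'[i][j, k] = (1/(2N+1)) * sum over h in -N..N of the maximum of
#' S[i][j+h, k']` over candidates k' at graph distance exactly |h| from k,
#' with out-of-range sequence positions and empty hop sets contributing 0.
#' Candidates that sit on a well-connected backbone stretch whose neighbors
#' also match the flanking sequence positions are boosted; isolated or
#' misplaced candidates are damped.
#'
#' @param S a `score_matrix` from [build_score_matrix()].
#' @param g the pruned `ca_graph`.
#' @param N hop depth (default 2); `N = 0` returns `S` unchanged.
#' @return An enhanced `score_matrix` with entries in [0, 1].
#' @export
propagate_scores <- function(S, g, N = 2L) {
  if (N == 0L) return(S)
  hops <- hop_sets(g, N)
  out <- lapply(S, function(Si) {
    J <- nrow(Si); K <- ncol(Si)
    Sp <- matrix(0, J, K)
    for (k in seq_len(K)) {
      sets <- hops[[k]]
      for (h in -N:N) {
        set_h <- if (abs(h) + 1L <= length(sets)) sets[[abs(h) + 1L]] else NULL
        if (length(set_h) == 0L) next
        jr <- seq_len(J)
        jh <- jr + h
        ok <- jh >= 1L & jh <= J
        if (!any(ok)) next
        contrib <- apply(Si[jh[ok], set_h, drop = FALSE], 1L, max)
        Sp[jr[ok], k] <- Sp[jr[ok], k] + contrib
      }
    }
    Sp / (2 * N + 1)
  })
  class(out) <- "score_matrix"
  out
}

#' Seed and extend alignment fragments
#'
#' Greedy seeding at enhanced-score maxima above `seed_threshold`, then
#' bidirectional extension: each step moves one residue along the sequence
#' and one graph-adjacent candidate along the trace, choosing the extension
#' with maximal enhanced score and stopping when the best available score
#' falls below `ext_threshold`. When predicted chain structures are given,
#' extension steps whose local C-alpha geometry deviates from the predicted
#' segment by more than `af3_rmsd_tol` (RMSD over a 5-residue window) are
#' rejected. Each fragment records its mean enhanced score.
#'
#' @param Sp enhanced `score_matrix`.
#' @param g pruned `ca_graph`.
#' @param sequences chain sequences (character vector).
#' @param af3 optional list of predicted structures (one
#'   [protein_structure] per sequence, or NULL entries).
#' @param seed_threshold minimum enhanced score to start a fragment.
#' @param ext_threshold minimum enhanced score to extend a fragment.
#' @param af3_rmsd_tol local-geometry RMSD tolerance, Angstrom.
#' @param max_seeds maximum number of seeds to process.
#' @return List of fragments: each a list with `chain` (sequence index),
#'   `j_start`, `j_end`, `cand_ids` (ordered candidate ids), `score`.
#' @export
seed_and_extend_fragments <- function(Sp, g, sequences, af3 = NULL,
                                      seed_threshold = 0.5,
                                      ext_threshold = 0.2,
                                      af3_rmsd_tol = 2.0,
                                      max_seeds = 2000L) {
  adj <- graph_adjacency(g)
  frags <- list()
  covered <- lapply(Sp, function(Si) matrix(FALSE, nrow(Si), ncol(Si)))
  seeds <- do.call(rbind, lapply(seq_along(Sp), function(i) {
    hit <- which(Sp[[i]] >= seed_threshold, arr.ind = TRUE)
    if (nrow(hit) == 0L) return(NULL)
    data.frame(i = i, j = hit[, 1], k = hit[, 2],
               s = Sp[[i]][hit])
  }))
  if (is.null(seeds) || nrow(seeds) == 0L) return(frags)
  seeds <- seeds[order(-seeds$s), , drop = FALSE]
  if (nrow(seeds) > max_seeds) seeds <- seeds[seq_len(max_seeds), ]

  for (r in seq_len(nrow(seeds))) {
    i <- seeds$i[r]; j0 <- seeds$j[r]; k0 <- seeds$k[r]
    if (covered[[i]][j0, k0]) next
    Si <- Sp[[i]]
    J <- nrow(Si)
    cand_path <- k0
    js <- j0; je <- j0
    used <- rep(FALSE, g$n); used[k0] <- TRUE
    pred_ca <- af3_chain_ca(af3, i)
    repeat {
      ext <- FALSE
      # extend right: residue je+1, neighbor of tail
      if (je < J) {
        nb <- setdiff(adj[[cand_path[length(cand_path)]]],
                      which(used))
        if (length(nb) > 0L) {
          sc <- Si[je + 1L, nb]
          best <- which.max(sc)
          if (sc[best] >= ext_threshold &&
              geometry_ok(c(cand_path, nb[best]), js, je + 1L, g, pred_ca,
                          af3_rmsd_tol)) {
            cand_path <- c(cand_path, nb[best])
            used[nb[best]] <- TRUE
            je <- je + 1L
            ext <- TRUE
          }
        }
      }
      # extend left: residue js-1, neighbor of head
      if (js > 1L) {
        nb <- setdiff(adj[[cand_path[1L]]], which(used))
        if (length(nb) > 0L) {
          sc <- Si[js - 1L, nb]
          best <- which.max(sc)
          if (sc[best] >= ext_threshold &&
              geometry_ok(c(nb[best], cand_path), js - 1L, je, g, pred_ca,
                          af3_rmsd_tol)) {
            cand_path <- c(nb[best], cand_path)
            used[nb[best]] <- TRUE
            js <- js - 1L
            ext <- TRUE
          }
        }
      }
      if (!ext) break
    }
    if (length(cand_path) >= 3L) {
      sc <- mean(Si[cbind(js:je, cand_path)])
      frags[[length(frags) + 1L]] <- list(chain = i, j_start = js,
                                          j_end = je, cand_ids = cand_path,
                                          score = sc)
      covered[[i]][cbind(js:je, cand_path)] <- TRUE
    }
  }
  frags
}

# C-alpha coordinates of the predicted structure for sequence i (or NULL)
af3_chain_ca <- function(af3, i) {
  if (is.null(af3) || length(af3) < i || is.null(af3[[i]])) return(NULL)
  ca <- ca_table(af3[[i]])
  as.matrix(ca[, c("x", "y", "z")])
}

# local-geometry test: superpose the last `win` fragment candidates onto
# the predicted segment at the same residue positions; accept if RMSD is
# within tolerance (or no prediction available)
geometry_ok <- function(cand_path, js, je, g, pred_ca, tol, win = 5L) {
  if (is.null(pred_ca)) return(TRUE)
  L <- length(cand_path)
  take <- min(win, L)
  idx <- (L - take + 1L):L
  jres <- (je - take + 1L):je
  if (any(jres < 1L) || any(jres > nrow(pred_ca))) return(TRUE)
  if (take < 3L) return(TRUE)
  A <- g$coords[cand_path[idx], , drop = FALSE]
  B <- pred_ca[jres, , drop = FALSE]
  superpose_rmsd(A, B)$rmsd <= tol
}

#' Merge overlapping fragments and rank by score
#'
#' Fragments of the same chain that agree on every shared (residue,
#' candidate) assignment are unioned into longer fragments; conflicting
#' overlaps keep the higher-scoring fragment (the other is dropped).
#' Output is sorted by descending alignment score.
#'
#' @param frags fragment list from [seed_and_extend_fragments()].
#' @return Merged, ranked fragment list.
#' @export
merge_and_rank_fragments <- function(frags) {
  if (length(frags) <= 1L)
    return(frags[order(-vapply(frags, `[[`, numeric(1), "score"))])
  frags <- frags[order(-vapply(frags, `[[`, numeric(1), "score"))]
  out <- list()
  for (f in frags) {
    placed <- FALSE
    dropped <- FALSE
    for (oi in seq_along(out)) {
      o <- out[[oi]]
      if (o$chain != f$chain) next
      ov <- intersect(seq(f$j_start, f$j_end), seq(o$j_start, o$j_end))
      if (length(ov) == 0L) next
      f_at <- f$cand_ids[ov - f$j_start + 1L]
      o_at <- o$cand_ids[ov - o$j_start + 1L]
      if (all(f_at == o_at)) {
        # consistent overlap: union
        js <- min(f$j_start, o$j_start); je <- max(f$j_end, o$j_end)
        ids <- integer(je - js + 1L)
        ids[seq(o$j_start, o$j_end) - js + 1L] <- o$cand_ids
        ids[seq(f$j_start, f$j_end) - js + 1L] <- f$cand_ids
        o$j_start <- js; o$j_end <- je; o$cand_ids <- ids
        o$score <- max(o$score, f$score)
        out[[oi]] <- o
        placed <- TRUE
        break
      } else {
        dropped <- TRUE      # conflicting overlap with a higher-score frag
        break
      }
    }
    if (!placed && !dropped) out[[length(out) + 1L]] <- f
  }
  out[order(-vapply(out, `[[`, numeric(1), "score"))]
}

#' Greedy fragment-to-chain assignment
#'
#' Consumes ranked fragments best-first. A fragment for sequence i is
#' placed into the first chain copy of that sequence where neither its
#' residue span nor any of its candidates is already claimed; fragments
#' that fit nowhere are skipped. Identical sequences (multi-copy chains)
#' fill copies in order.
#'
#' @param frags ranked fragments (see [merge_and_rank_fragments()]).
#' @param sequences chain sequences; duplicated strings denote copies.
#' @param copies integer vector, number of copies per sequence (default 1
#'   each).
#' @return An `assignment`: list with `placements` (list over chain copies;
#'   each a list with `seq_index`, `copy`, `frags`), `sequences`, `copies`.
#' @export
assign_chains <- function(frags, sequences, copies = NULL) {
  if (is.null(copies)) copies <- rep(1L, length(sequences))
  placements <- list()
  for (i in seq_along(sequences)) {
    for (cp in seq_len(copies[i])) {
      placements[[length(placements) + 1L]] <-
        list(seq_index = i, copy = cp, frags = list(),
             claimed = rep(FALSE, nchar(sequences[i])))
    }
  }
  cand_used <- new.env(parent = emptyenv())
  cand_used$ids <- integer(0)
  for (f in frags) {
    span <- seq(f$j_start, f$j_end)
    if (any(f$cand_ids %in% cand_used$ids)) next
    for (pi in seq_along(placements)) {
      pl <- placements[[pi]]
      if (pl$seq_index != f$chain) next
      if (any(pl$claimed[span])) next
      pl$claimed[span] <- TRUE
      pl$frags[[length(pl$frags) + 1L]] <- f
      placements[[pi]] <- pl
      cand_used$ids <- c(cand_used$ids, f$cand_ids)
      break
    }
  }
  structure(list(placements = placements, sequences = sequences,
                 copies = copies), class = "assignment")
}

#' Refine sequence register against predicted structures
#'
#' For every assigned fragment, register shifts of up to +/- `max_shift`
#' residues are evaluated by rigid least-squares superposition of the
#' fragment's candidate coordinates onto the predicted chain's C-alpha
#' segment at the shifted positions; the shift minimizing RMSD is applied.
#' Iterates to a fixed point; the RMSD never increases.
#'
#' @param assignment an `assignment`.
#' @param g the `ca_graph` (for candidate coordinates).
#' @param af3 list of predicted structures per sequence (NULL entries skip
#'   their chain).
#' @param max_shift maximum register shift per iteration (default 2).
#' @param max_iter iteration cap.
#' @return The refined `assignment`.
#' @export
refine_with_af3 <- function(assignment, g, af3, max_shift = 2L,
                            max_iter = 10L) {
  if (is.null(af3)) return(assignment)
  for (pi in seq_along(assignment$placements)) {
    pl <- assignment$placements[[pi]]
    pred_ca <- af3_chain_ca(af3, pl$seq_index)
    if (is.null(pred_ca) || length(pl$frags) == 0L) next
    J <- nchar(assignment$sequences[pl$seq_index])
    for (it in seq_len(max_iter)) {
      improved <- FALSE
      claimed <- rep(FALSE, J)
      for (f in pl$frags) claimed[seq(f$j_start, f$j_end)] <- TRUE
      for (fi in seq_along(pl$frags)) {
        f <- pl$frags[[fi]]
        span <- seq(f$j_start, f$j_end)
        A <- g$coords[f$cand_ids, , drop = FALSE]
        if (nrow(A) < 3L) next
        base <- superpose_rmsd(A, pred_ca[span, , drop = FALSE])$rmsd
        best_s <- 0L; best_r <- base
        for (s in setdiff(-max_shift:max_shift, 0L)) {
          new_span <- span + s
          if (new_span[1] < 1L || new_span[length(new_span)] > J) next
          other <- claimed
          other[span] <- FALSE
          if (any(other[new_span])) next
          r <- superpose_rmsd(A, pred_ca[new_span, , drop = FALSE])$rmsd
          if (r < best_r - 1e-9) { best_r <- r; best_s <- s }
        }
        if (best_s != 0L) {
          claimed[span] <- FALSE
          f$j_start <- f$j_start + best_s
          f$j_end <- f$j_end + best_s
          claimed[seq(f$j_start, f$j_end)] <- TRUE
          pl$frags[[fi]] <- f
          improved <- TRUE
        }
      }
      if (!improved) break
    }
    assignment$placements[[pi]] <- pl
  }
  assignment
}

#' Fill gaps and emit the backbone model
#'
#' Residue runs left unassigned between anchored fragments are completed
#' by a bidirectional search through unassigned candidates along 2-6
#' Angstrom graph steps (meeting in the middle); paths that deviate from
#' the predicted structure's gap geometry beyond `af3_rmsd_tol` are
#' discarded. If no candidate path exists and a predicted structure is
#' available, the gap C-alpha positions are taken from the predicted
#' segment rigidly fitted onto the flanking anchors and flagged
#' `gap-filled`. Residues neither source can place are left unmodeled.
#'
#' @param assignment an `assignment` (after optional refinement).
#' @param cands the `candidate_set` (coordinates and probabilities).
#' @param g the `ca_graph` built over `cands`.
#' @param af3 optional predicted structures per sequence.
#' @param af3_rmsd_tol geometry tolerance for candidate gap paths.
#' @return A `backbone_model`: data.frame with chain, copy, resno, aa,
#'   x, y, z, provenance ("traced" or "gap-filled").
#' @export
fill_gaps <- function(assignment, cands, g, af3 = NULL, af3_rmsd_tol = 3.0) {
  adj <- graph_adjacency(g)
  used <- rep(FALSE, g$n)
  for (pl in assignment$placements)
    for (f in pl$frags) used[f$cand_ids] <- TRUE

  rows <- list()
  chain_letters <- make_chain_ids(length(assignment$placements))
  for (pi in seq_along(assignment$placements)) {
    pl <- assignment$placements[[pi]]
    sq <- strsplit(assignment$sequences[pl$seq_index], "")[[1]]
    J <- length(sq)
    placed <- matrix(NA_real_, J, 3L)
    prov <- rep(NA_character_, J)
    frs <- pl$frags
    if (length(frs) == 0L) next
    ord <- order(vapply(frs, `[[`, numeric(1), "j_start"))
    frs <- frs[ord]
    for (f in frs) {
      span <- seq(f$j_start, f$j_end)
      placed[span, ] <- g$coords[f$cand_ids, , drop = FALSE]
      prov[span] <- "traced"
    }
    pred_ca <- af3_chain_ca(af3, pl$seq_index)

    # interior gaps between consecutive fragments
    for (fi in seq_len(length(frs) - 1L)) {
      a <- frs[[fi]]; b <- frs[[fi + 1L]]
      gap <- if (a$j_end + 1L <= b$j_start - 1L)
        seq(a$j_end + 1L, b$j_start - 1L) else integer(0)
      if (length(gap) == 0L) next
      anchor_a <- a$cand_ids[length(a$cand_ids)]
      anchor_b <- b$cand_ids[1L]
      path <- gap_path_search(anchor_a, anchor_b, length(gap), adj, used,
                              g, pred_ca, gap, af3_rmsd_tol)
      if (!is.null(path)) {
        placed[gap, ] <- g$coords[path, , drop = FALSE]
        prov[gap] <- "traced"
        used[path] <- TRUE
      } else if (!is.null(pred_ca) &&
                 max(gap) + 2L <= nrow(pred_ca) && min(gap) - 2L >= 1L) {
        seg <- fit_pred_segment(pred_ca, gap, placed)
        if (!is.null(seg)) {
          placed[gap, ] <- seg
          prov[gap] <- "gap-filled"
        }
      }
    }
    ok <- !is.na(prov)
    if (!any(ok)) next
    rows[[length(rows) + 1L]] <- data.frame(
      chain = chain_letters[pi], copy = pl$copy,
      resno = which(ok), aa = sq[ok],
      x = placed[ok, 1], y = placed[ok, 2], z = placed[ok, 3],
      provenance = prov[ok])
  }
  bm <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(chain = character(0), copy = integer(0), resno = integer(0),
               aa = character(0), x = numeric(0), y = numeric(0),
               z = numeric(0), provenance = character(0))
  rownames(bm) <- NULL
  class(bm) <- c("backbone_model", "data.frame")
  bm
}

make_chain_ids <- function(n) {
  pool <- c(LETTERS, letters, as.character(0:9))
  if (n <= length(pool)) pool[seq_len(n)] else
    c(pool, paste0("c", seq_len(n - length(pool))))[seq_len(n)]
}

# bidirectional (depth-limited DFS from the left anchor toward the right
# anchor) search for a path of exactly `len` unused candidates connecting
# the two anchors through graph edges
gap_path_search <- function(from, to, len, adj, used, g, pred_ca, gap_res,
                            tol, max_nodes = 20000L) {
  counter <- new.env(parent = emptyenv()); counter$n <- 0L
  target <- g$coords[to, ]
  recurse <- function(node, depth, path, visited) {
    counter$n <- counter$n + 1L
    if (counter$n > max_nodes) return(NULL)
    if (depth == 0L) {
      if (to %in% adj[[node]]) return(path)
      return(NULL)
    }
    # prune: remaining steps must be able to cover the distance to target
    dleft <- sqrt(sum((g$coords[node, ] - target)^2))
    if (dleft > 6.0 * (depth + 1L)) return(NULL)
    nbs <- adj[[node]]
    nbs <- nbs[!used[nbs] & !visited[nbs]]
    if (length(nbs) == 0L) return(NULL)
    dd <- sqrt(colSums((t(g$coords[nbs, , drop = FALSE]) - target)^2))
    for (nb in nbs[order(dd)]) {
      visited[nb] <- TRUE
      res <- recurse(nb, depth - 1L, c(path, nb), visited)
      if (!is.null(res)) return(res)
    }
    NULL
  }
  visited <- rep(FALSE, g$n); visited[from] <- TRUE; visited[to] <- TRUE
  path <- recurse(from, len, integer(0), visited)
  if (is.null(path) || length(path) == 0L) return(NULL)
  # geometry screen against the predicted structure
  if (!is.null(pred_ca) && length(path) >= 3L &&
      max(gap_res) <= nrow(pred_ca)) {
    r <- superpose_rmsd(g$coords[path, , drop = FALSE],
                        pred_ca[gap_res, , drop = FALSE])$rmsd
    if (r > tol) return(NULL)
  }
  path
}

# rigidly fit the predicted segment spanning the gap plus flanking anchors
# onto the already-placed flanking model positions; returns gap coordinates
fit_pred_segment <- function(pred_ca, gap, placed, flank = 2L) {
  lo <- min(gap); hi <- max(gap)
  fl <- c(seq(lo - flank, lo - 1L), seq(hi + 1L, hi + flank))
  fl <- fl[fl >= 1L & fl <= nrow(placed) & fl <= nrow(pred_ca)]
  fl <- fl[!is.na(placed[fl, 1])]
  if (length(fl) < 3L) return(NULL)
  fit <- superpose_rmsd(pred_ca[fl, , drop = FALSE],
                        placed[fl, , drop = FALSE])
  sweep(pred_ca[gap, , drop = FALSE], 2L, fit$center_a) %*% t(fit$R) +
    matrix(fit$center_b, length(gap), 3L, byrow = TRUE)
}

#' Trace a backbone model from candidates and sequences
#'
#' Convenience wrapper running the full tracing protocol: connectivity
#' graph, pruning, scoring matrix, N-hop enhancement, fragment seeding and
#' extension, merging, greedy chain assignment, optional register
#' refinement against predicted structures, and gap filling.
#'
#' @param cands a `candidate_set`.
#' @param sequences chain sequences (duplicates = chain copies are handled
#'   via `copies`).
#' @param af3 optional list of predicted structures (one per sequence).
#' @param copies copies per sequence (default 1 each).
#' @param n_hops propagation depth (default 2).
#' @param seed_threshold,ext_threshold,af3_rmsd_tol tracing thresholds.
#' @return A `backbone_model` data.frame.
#' @export
trace_backbone <- function(cands, sequences, af3 = NULL, copies = NULL,
                           n_hops = 2L, seed_threshold = 0.5,
                           ext_threshold = 0.2, af3_rmsd_tol = 2.0) {
  g <- prune_graph(build_graph(cands))
  S <- build_score_matrix(cands, sequences)
  Sp <- propagate_scores(S, g, N = n_hops)
  frags <- seed_and_extend_fragments(Sp, g, sequences, af3 = af3,
                                     seed_threshold = seed_threshold,
                                     ext_threshold = ext_threshold,
                                     af3_rmsd_tol = af3_rmsd_tol)
  frags <- merge_and_rank_fragments(frags)
  asg <- assign_chains(frags, sequences, copies = copies)
  if (!is.null(af3)) asg <- refine_with_af3(asg, g, af3)
  fill_gaps(asg, cands, g, af3 = af3)
}

#' Write a backbone model as a C-alpha-only PDB file
#'
#' Gap-filled residues are marked with occupancy 0.50 (traced residues get
#' 1.00).
#'
#' @param bm a `backbone_model`.
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
write_backbone_pdb <- function(bm, path) {
  if (nrow(bm) == 0L) stop("write_backbone_pdb: empty model")
  s <- protein_structure(data.frame(
    chain = bm$chain, resno = bm$resno, ins = "", aa = bm$aa,
    atom = "CA", x = bm$x, y = bm$y, z = bm$z))
  # protein_structure re-sorts; rebuild occupancy in the sorted order
  occ <- ifelse(s$atoms$chain %in% bm$chain[bm$provenance == "gap-filled"] &
                  paste(s$atoms$chain, s$atoms$resno) %in%
                  paste(bm$chain, bm$resno)[bm$provenance == "gap-filled"],
                0.5, 1.0)
  write_structure(s, path, occupancy = occ)
}
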