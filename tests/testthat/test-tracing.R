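cand_set <- function(xyz, ca_prob = NULL, aa = NULL) {
  n <- nrow(xyz)
  if (is.null(ca_prob)) ca_prob <- rep(0.9, n)
  m <- matrix(1 / 20, n, 20L)
  if (!is.null(aa)) {
    m[] <- 0.01 / 19
    m[cbind(seq_len(n), aa_code(aa))] <- 0.99
    m <- m / rowSums(m)
  }
  cs <- data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   ca_prob = ca_prob, backbone_score = ca_prob,
                   cluster_id = seq_len(n))
  cs[paste0("aa_", 1:20)] <- m
  class(cs) <- c("candidate_set", "data.frame")
  cs
}

# straight-line candidates at 3.8 A spacing
line_cands <- function(n, spacing = 3.8, aa = NULL) {
  cand_set(cbind((seq_len(n) - 1) * spacing, 0, 0), aa = aa)
}

test_that("connectivity edges obey the 2-6 A window (brute-force oracle)", {
  cs <- cand_set(rbind(c(0, 0, 0), c(3.8, 0, 0)))
  expect_equal(nrow(build_graph(cs)$edges), 1L)
  cs2 <- cand_set(rbind(c(0, 0, 0), c(1.5, 0, 0)))
  expect_equal(nrow(build_graph(cs2)$edges), 0L)

  set.seed(23)
  xyz <- matrix(runif(3 * 40, 0, 15), ncol = 3L)
  g <- build_graph(cand_set(xyz))
  dd <- as.matrix(dist(xyz))
  want <- which(upper.tri(dd) & dd >= 2 & dd <= 6, arr.ind = TRUE)
  got <- as.matrix(g$edges[, c("from", "to")])
  expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE],
               want[order(want[, 1], want[, 2]), , drop = FALSE],
               ignore_attr = TRUE)
})

test_that("pruning enforces degree <= 2, keeping the strongest edges", {
  # star: center 1 with four spokes at varying distances (weights differ)
  xyz <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(0, 3.8, 0), c(0, 0, 5.2),
               c(-4.6, 0, 0))
  g <- prune_graph(build_graph(cand_set(xyz)))
  deg <- tabulate(c(g$edges$from, g$edges$to), nbins = 5L)
  expect_true(all(deg <= 2L))
  # center keeps its two best spokes (the 3.8 A ones)
  kept <- g$edges[g$edges$from == 1L | g$edges$to == 1L, ]
  expect_setequal(setdiff(unlist(kept[, c("from", "to")]), 1L), c(2L, 3L))

  # path graph unchanged
  gp <- build_graph(line_cands(6L))
  expect_equal(nrow(prune_graph(gp)$edges), nrow(gp$edges))

  # random geometric graphs: contract holds
  for (seed in 1:3) {
    set.seed(seed)
    gr <- prune_graph(build_graph(cand_set(matrix(runif(90, 0, 12), ncol = 3L))))
    expect_true(all(tabulate(c(gr$edges$from, gr$edges$to), nbins = 30L) <= 2L))
  }
})

test_that("traces are simple paths; cycles are cut at the weakest edge", {
  tr <- extract_traces(prune_graph(build_graph(line_cands(5L))))
  expect_equal(length(tr), 1L)
  expect_equal(tr[[1]], 1:5)

  # 4-cycle with one weaker edge (longer distance)
  xyz <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(3.8, 4.6, 0), c(0, 4.6, 0))
  g <- prune_graph(build_graph(cand_set(xyz)))
  expect_equal(nrow(g$edges), 4L)        # still a cycle after pruning
  tr <- extract_traces(g)
  expect_equal(length(tr), 1L)
  expect_equal(length(tr[[1]]), 4L)
  # the strong (3.8 A) edges 1-2 and 3-4 survive the cut: they remain
  # consecutive in the extracted path
  consec <- cbind(tr[[1]][-4], tr[[1]][-1])
  pairs <- apply(consec, 1L, function(p) paste(sort(p), collapse = "-"))
  expect_true(all(c("1-2", "3-4") %in% pairs))
  # node sets partition the graph
  set.seed(4)
  gr <- prune_graph(build_graph(cand_set(matrix(runif(120, 0, 14), ncol = 3L))))
  trs <- extract_traces(gr)
  expect_setequal(unlist(trs), seq_len(gr$n))
  expect_equal(anyDuplicated(unlist(trs)), 0L)
})

test_that("trace extraction is invariant under candidate relabeling", {
  set.seed(31)
  xyz <- matrix(runif(60, 0, 10), ncol = 3L)
  cs <- cand_set(xyz)
  perm <- sample(nrow(xyz))
  csp <- cand_set(xyz[perm, , drop = FALSE])
  tr1 <- extract_traces(prune_graph(build_graph(cs)))
  tr2 <- extract_traces(prune_graph(build_graph(csp)))
  canon <- function(trs, relabel = identity) {
    vapply(trs, function(t) paste(sort(relabel(t)), collapse = ","),
           character(1))
  }
  expect_setequal(canon(tr1), canon(tr2, relabel = function(t) perm[t]))
})

test_that("score matrix equals the direct triple-loop construction", {
  cs <- line_cands(3L, aa = c("G", "A", "Y"))
  S <- build_score_matrix(cs, c("GA", "YG"))
  aa <- aa_prob_matrix(cs)
  for (i in 1:2) {
    sq <- strsplit(c("GA", "YG")[i], "")[[1]]
    for (j in seq_along(sq)) for (k in 1:3)
      expect_equal(S[[i]][j, k], unname(aa[k, aa_code(sq[j])]))
  }
  # one-hot candidate: S ~ 1 on its own letter
  expect_gt(S[[1]][1, 1], 0.98)
  expect_lt(S[[1]][2, 1], 0.01)
  # unknown residue letter scores uniform 1/20
  Su <- build_score_matrix(cs, "GXA")
  expect_equal(Su[[1]][2, ], rep(1 / 20, 3L))
  # uniform aa probabilities give flat 0.05
  csu <- line_cands(2L)
  expect_true(all(abs(build_score_matrix(csu, "AC")[[1]] - 0.05) < 1e-12))
})

test_that("N-hop propagation follows its formula (brute-force oracle)", {
  # independent oracle: walk hop sets by BFS distance, average shifted maxima
  prop_oracle <- function(S, g, N) {
    adj <- matrix(FALSE, g$n, g$n)
    if (nrow(g$edges) > 0L)
      adj[cbind(c(g$edges$from, g$edges$to),
                c(g$edges$to, g$edges$from))] <- TRUE
    distm <- matrix(Inf, g$n, g$n)
    diag(distm) <- 0
    for (v in seq_len(g$n)) {
      frontier <- v; d <- 0L
      while (length(frontier) > 0L) {
        d <- d + 1L
        nxt <- unique(unlist(lapply(frontier, function(q) which(adj[q, ]))))
        nxt <- nxt[distm[v, nxt] > d]
        distm[v, nxt] <- d
        frontier <- nxt
      }
    }
    lapply(S, function(Si) {
      J <- nrow(Si); K <- ncol(Si)
      Sp <- matrix(0, J, K)
      for (j in 1:J) for (k in 1:K) {
        acc <- 0
        for (h in -N:N) {
          if (j + h < 1L || j + h > J) next
          ks <- which(distm[k, ] == abs(h))
          if (length(ks) > 0L) acc <- acc + max(Si[j + h, ks])
        }
        Sp[j, k] <- acc / (2 * N + 1)
      }
      Sp
    })
  }

  # isolated candidate, N = 1: only the h = 0 term -> S/3 where in range
  cs1 <- cand_set(matrix(c(0, 0, 0), 1L), aa = "G")
  g1 <- build_graph(cs1)
  S1 <- build_score_matrix(cs1, "GAG")
  P1 <- propagate_scores(S1, g1, N = 1L)
  expect_equal(P1[[1]][2, 1], S1[[1]][2, 1] / 3, tolerance = 1e-12)

  # perfect one-hot chain: interior diagonal reaches 1
  aa <- c("G", "A", "Y", "C", "W")
  cs <- line_cands(5L, aa = aa)
  g <- prune_graph(build_graph(cs))
  S <- build_score_matrix(cs, paste(aa, collapse = ""))
  P <- propagate_scores(S, g, N = 2L)
  expect_gt(P[[1]][3, 3], 0.98)
  # full agreement with the oracle
  expect_equal(P, prop_oracle(S, g, 2L), tolerance = 1e-12,
               ignore_attr = TRUE)

  # N = 0 is the identity
  expect_identical(propagate_scores(S, g, N = 0L), S)

  # random case against the oracle
  set.seed(41)
  xyz <- matrix(runif(45, 0, 10), ncol = 3L)
  csr <- cand_set(xyz, aa = sample(aa_alphabet(), 15L, TRUE))
  gr <- prune_graph(build_graph(csr))
  Sr <- build_score_matrix(csr, paste(sample(aa_alphabet(), 8L, TRUE),
                                      collapse = ""))
  expect_equal(propagate_scores(Sr, gr, 2L), prop_oracle(Sr, gr, 2L),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("fragments recover a clean 10-residue chain end to end", {
  aa <- c("G", "A", "Y", "C", "W", "M", "F", "H", "K", "D")
  cs <- line_cands(10L, aa = aa)
  g <- prune_graph(build_graph(cs))
  Sp <- propagate_scores(build_score_matrix(cs, paste(aa, collapse = "")),
                         g, N = 2L)
  frags <- seed_and_extend_fragments(Sp, g, paste(aa, collapse = ""))
  expect_gte(length(frags), 1L)
  best <- frags[[which.max(vapply(frags, `[[`, numeric(1), "score"))]]
  expect_equal(best$j_start, 1L)
  expect_equal(best$j_end, 10L)
  expect_equal(best$cand_ids, 1:10)
  # injectivity: no candidate assigned twice within a fragment
  for (f in frags) expect_equal(anyDuplicated(f$cand_ids), 0L)
  # seeds below threshold -> no fragments
  none <- seed_and_extend_fragments(
    lapply(Sp, function(S) S * 0 + 0.1), g, paste(aa, collapse = ""))
  expect_equal(length(none), 0L)
})

test_that("fragment merging unions agreement and resolves conflicts", {
  f1 <- list(chain = 1L, j_start = 1L, j_end = 5L, cand_ids = 1:5,
             score = 0.9)
  f2 <- list(chain = 1L, j_start = 4L, j_end = 8L, cand_ids = 4:8,
             score = 0.8)
  merged <- merge_and_rank_fragments(list(f1, f2))
  expect_equal(length(merged), 1L)
  expect_equal(merged[[1]]$j_start, 1L)
  expect_equal(merged[[1]]$j_end, 8L)
  expect_equal(merged[[1]]$cand_ids, 1:8)

  # disjoint fragments: unchanged, sorted by score
  f3 <- list(chain = 1L, j_start = 20L, j_end = 24L, cand_ids = 21:25,
             score = 0.95)
  out <- merge_and_rank_fragments(list(f1, f3))
  expect_equal(length(out), 2L)
  expect_equal(out[[1]]$score, 0.95)

  # conflicting overlap: lower-score fragment dropped
  f4 <- list(chain = 1L, j_start = 4L, j_end = 8L, cand_ids = c(9L, 10:13),
             score = 0.5)
  out2 <- merge_and_rank_fragments(list(f1, f4))
  expect_equal(length(out2), 1L)
  expect_equal(out2[[1]]$score, 0.9)
})

test_that("greedy assignment prevents conflicts and fills chain copies", {
  seqs <- c("AAAAAAAAAA")
  f1 <- list(chain = 1L, j_start = 1L, j_end = 5L, cand_ids = 1:5,
             score = 0.9)
  f2 <- list(chain = 1L, j_start = 6L, j_end = 10L, cand_ids = 6:10,
             score = 0.8)
  asg <- assign_chains(list(f1, f2), seqs)
  expect_equal(length(asg$placements[[1]]$frags), 2L)

  # two fragments claiming residue 5: only the higher-scoring accepted
  f3 <- list(chain = 1L, j_start = 5L, j_end = 9L, cand_ids = 11:15,
             score = 0.7)
  asg2 <- assign_chains(list(f1, f3), seqs)
  expect_equal(length(asg2$placements[[1]]$frags), 1L)
  expect_equal(asg2$placements[[1]]$frags[[1]]$score, 0.9)

  # homodimer: two disjoint traces fill the two copies in order
  asg3 <- assign_chains(list(f1, list(chain = 1L, j_start = 1L, j_end = 5L,
                                      cand_ids = 21:25, score = 0.85)),
                        seqs, copies = 2L)
  expect_equal(length(asg3$placements), 2L)
  expect_equal(length(asg3$placements[[1]]$frags), 1L)
  expect_equal(length(asg3$placements[[2]]$frags), 1L)
  # a candidate never serves two copies
  ids1 <- asg3$placements[[1]]$frags[[1]]$cand_ids
  ids2 <- asg3$placements[[2]]$frags[[1]]$cand_ids
  expect_equal(length(intersect(ids1, ids2)), 0L)
})

test_that("register refinement corrects an off-by-one against prediction", {
  # predicted chain of 12 residues on a curved (self-avoiding) walk, so a
  # register shift changes the local geometry; fragment candidates match
  # residues 3..7 but were seeded at 4..8 (register +1)
  n <- 12L
  pred <- gen_toy_structure(synthetic_spec(n_residues = n, seed = 29L))
  pred_xyz <- as.matrix(ca_table(pred)[, c("x", "y", "z")])
  set.seed(30)
  cs <- cand_set(pred_xyz[3:7, , drop = FALSE] +
                   matrix(rnorm(15, sd = 0.05), 5L))
  g <- build_graph(cs)
  frag <- list(chain = 1L, j_start = 4L, j_end = 8L, cand_ids = 1:5,
               score = 0.5)
  asg <- assign_chains(list(frag), paste(rep("A", n), collapse = ""))
  before <- superpose_rmsd(g$coords[1:5, ], pred_xyz[4:8, ])$rmsd
  ref <- refine_with_af3(asg, g, list(pred))
  f <- ref$placements[[1]]$frags[[1]]
  expect_equal(f$j_start, 3L)
  expect_equal(f$j_end, 7L)
  after <- superpose_rmsd(g$coords[1:5, ], pred_xyz[3:7, ])$rmsd
  expect_lt(after, before)
  # already optimal -> fixed point
  ref2 <- refine_with_af3(ref, g, list(pred))
  expect_equal(ref2$placements[[1]]$frags[[1]]$j_start, 3L)
})

test_that("gap filling closes candidate gaps and falls back to prediction", {
  aa <- strsplit("GAYCWMFHKDGA", "")[[1]]
  n <- length(aa)
  xyz <- cbind((seq_len(n) - 1) * 3.8, 0, 0)
  cs <- cand_set(xyz, aa = aa)
  g <- prune_graph(build_graph(cs))
  # fragments covering 1..4 and 9..12 leave a 4-residue interior gap with
  # candidates 5..8 available
  f1 <- list(chain = 1L, j_start = 1L, j_end = 4L, cand_ids = 1:4,
             score = 0.9)
  f2 <- list(chain = 1L, j_start = 9L, j_end = 12L, cand_ids = 9:12,
             score = 0.9)
  asg <- assign_chains(list(f1, f2), paste(aa, collapse = ""))
  bm <- fill_gaps(asg, cs, g)
  expect_equal(nrow(bm), n)
  expect_true(all(bm$provenance == "traced"))
  expect_equal(bm$resno, seq_len(n))
  expect_equal(max(abs(as.matrix(bm[, c("x", "y", "z")]) - xyz)), 0)

  # no candidates in the gap: positions come from the fitted prediction
  cs2 <- cand_set(xyz[c(1:4, 9:12), , drop = FALSE],
                  aa = aa[c(1:4, 9:12)])
  g2 <- prune_graph(build_graph(cs2))
  pred <- protein_structure(data.frame(
    chain = "A", resno = seq_len(n), ins = "", aa = aa, atom = "CA",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
  f1b <- list(chain = 1L, j_start = 1L, j_end = 4L, cand_ids = 1:4,
              score = 0.9)
  f2b <- list(chain = 1L, j_start = 9L, j_end = 12L, cand_ids = 5:8,
              score = 0.9)
  asg2 <- assign_chains(list(f1b, f2b), paste(aa, collapse = ""))
  bm2 <- fill_gaps(asg2, cs2, g2, af3 = list(pred))
  expect_equal(nrow(bm2), n)
  filled <- bm2[bm2$provenance == "gap-filled", ]
  expect_equal(filled$resno, 5:8)
  expect_equal(max(abs(as.matrix(filled[, c("x", "y", "z")]) -
                         xyz[5:8, ])), 0, tolerance = 1e-6)

  # zero-length gap: adjacent fragments -> identity
  f3 <- list(chain = 1L, j_start = 5L, j_end = 8L, cand_ids = 5:8,
             score = 0.8)
  asg3 <- assign_chains(list(f1, f3, f2), paste(aa, collapse = ""))
  bm3 <- fill_gaps(asg3, cs, g)
  expect_equal(nrow(bm3), n)
  expect_true(all(bm3$provenance == "traced"))
})

test_that("backbone models never reuse candidates or residue slots", {
  fx <- toy_fixture()
  cands <- extract_candidates(fx$pred, fx$map)
  bm <- trace_backbone(cands, fx$sequences)
  expect_equal(anyDuplicated(bm[, c("chain", "copy", "resno")]), 0L)
  coords <- paste(round(bm$x, 6), round(bm$y, 6), round(bm$z, 6))
  expect_equal(anyDuplicated(coords[bm$provenance == "traced"]), 0L)
})

test_that("backbone PDB export marks gap-filled residues by occupancy", {
  bm <- data.frame(chain = "A", copy = 1L, resno = 1:4,
                   aa = c("G", "A", "Y", "C"),
                   x = c(0, 3.8, 7.6, 11.4), y = 0, z = 0,
                   provenance = c("traced", "gap-filled", "traced", "traced"))
  class(bm) <- c("backbone_model", "data.frame")
  f <- tempfile(fileext = ".pdb")
  write_backbone_pdb(bm, f)
  txt <- readLines(f)
  atom <- grep("^ATOM", txt, value = TRUE)
  occ <- as.numeric(substr(atom, 55, 60))
  expect_equal(occ, c(1, 0.5, 1, 1))
  unlink(f)
})
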