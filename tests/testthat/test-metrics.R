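line_structure <- function(n, aa = NULL, spacing = 3.8) {
  if (is.null(aa)) aa <- rep("A", n)
  protein_structure(data.frame(
    chain = "A", resno = seq_len(n), ins = "", aa = aa, atom = "CA",
    x = (seq_len(n) - 1) * spacing, y = 0, z = 0))
}

test_that("superposition recovers rigid transforms exactly", {
  set.seed(2)
  A <- matrix(rnorm(30), ncol = 3L)
  R <- random_rotation(5)
  B <- A %*% t(R) + matrix(c(3, -1, 7), 10L, 3L, byrow = TRUE)
  fit <- superpose_rmsd(A, B)
  expect_lt(fit$rmsd, 1e-10)
  expect_equal(fit$transformed, B, tolerance = 1e-10)
  expect_equal(det(fit$R), 1, tolerance = 1e-10)
})

test_that("CA pairing is one-to-one, tie-broken, and optimal on toys", {
  s <- line_structure(5L)
  p <- ca_correspondence(s, s)
  expect_equal(nrow(p), 5L)
  expect_true(all(p$dist == 0))

  # one model atom equidistant to two truth atoms: lexicographic tie-break
  model <- protein_structure(data.frame(
    chain = "A", resno = 1L, ins = "", aa = "A", atom = "CA",
    x = 1, y = 0, z = 0))
  truth <- protein_structure(data.frame(
    chain = "A", resno = 1:2, ins = "", aa = "A", atom = "CA",
    x = c(0, 2), y = 0, z = 0))
  p2 <- ca_correspondence(model, truth)
  expect_equal(p2$truth_idx, 1L)

  # pairing count equals exhaustive optimal matching on <= 6-atom toys
  brute_max <- function(M, TT, cutoff) {
    dd <- as.matrix(stats::dist(rbind(M, TT)))[seq_len(nrow(M)),
                                               nrow(M) + seq_len(nrow(TT)),
                                               drop = FALSE]
    best <- 0L
    perms <- function(v) if (length(v) <= 1L) list(v) else
      do.call(c, lapply(seq_along(v), function(i)
        lapply(perms(v[-i]), function(p) c(v[i], p))))
    for (sz in rev(seq_len(min(nrow(M), nrow(TT))))) {
      if (sz <= best) break
      combm <- utils::combn(nrow(M), sz, simplify = FALSE)
      combt <- utils::combn(nrow(TT), sz, simplify = FALSE)
      for (cm in combm) for (ct in combt) for (pp in perms(ct)) {
        if (all(dd[cbind(cm, pp)] <= cutoff)) { best <- sz; break }
      }
    }
    best
  }
  for (seed in 1:5) {
    set.seed(seed)
    M <- matrix(runif(9, 0, 5), ncol = 3L)
    TT <- matrix(runif(12, 0, 5), ncol = 3L)
    sm <- protein_structure(data.frame(chain = "A", resno = 1:3, ins = "",
                                       aa = "A", atom = "CA",
                                       x = M[, 1], y = M[, 2], z = M[, 3]))
    st <- protein_structure(data.frame(chain = "A", resno = 1:4, ins = "",
                                       aa = "A", atom = "CA",
                                       x = TT[, 1], y = TT[, 2], z = TT[, 3]))
    got <- nrow(ca_correspondence(sm, st, cutoff = 3.0))
    expect_equal(got, brute_max(M, TT, 3.0), label = paste("seed", seed))
  }
})

test_that("ca_match follows its cutoff contract", {
  s <- line_structure(10L)
  expect_equal(ca_match(s, s), 100)
  # rigid 10 A shift (perpendicular to the chain) with 3 A cutoff and no
  # superposition -> 0
  shifted <- transform_structure(s, diag(3), c(0, 10, 0))
  expect_equal(ca_match(shifted, s), 0)
  # half the atoms displaced by 5 A -> 50
  a <- s$atoms
  a$y[a$resno <= 5] <- 5
  expect_equal(ca_match(protein_structure(a), s), 50)
  # monotone non-increasing as the cutoff tightens
  set.seed(3)
  a2 <- s$atoms
  a2$x <- a2$x + rnorm(10, sd = 1.5)
  noisy <- protein_structure(a2)
  cuts <- c(4, 3, 2, 1, 0.5)
  vals <- vapply(cuts, function(cc) ca_match(noisy, s, cutoff = cc),
                 numeric(1))
  expect_true(all(diff(vals) <= 0))
})

test_that("ca_quality_score is precision times coverage", {
  expect_equal(ca_quality_score(100, 568, 568), 100)
  expect_equal(ca_quality_score(50, 100, 200), 25)
  expect_error(ca_quality_score(90, 10, 0), "> 0")
})

test_that("sequence metrics count identical paired residues", {
  aa <- c("G", "A", "Y", "C", "W", "M", "F", "H", "K", "D")
  s <- line_structure(10L, aa = aa)
  expect_equal(sequence_match(s, s), 100)
  si <- sequence_identity(s, s)
  expect_equal(si$sequence_identity, 1.0)
  expect_equal(si$aligned_length, 10L)
  # half the types wrong -> 50
  a <- s$atoms
  a$aa[1:5] <- "P"
  half <- protein_structure(a)
  expect_equal(sequence_match(half, s), 50)
  # no pairs -> 0 with warning
  far <- transform_structure(s, diag(3), c(100, 0, 0))
  expect_warning(sm <- sequence_match(far, s), "no paired")
  expect_equal(sm, 0)
})

test_that("TM-score: identity, rigid invariance, closed-form case", {
  aa <- sample(aa_alphabet(), 30L, TRUE)
  s <- line_structure(30L, aa = aa)
  expect_equal(tm_score(s, s)$tm, 1.0, tolerance = 1e-12)

  # rigidly moved copy still scores 1 (pairing supplied: superposition-based)
  R <- random_rotation(11)
  moved <- transform_structure(s, R, c(5, -3, 2))
  pairing <- data.frame(model_idx = 1:30, truth_idx = 1:30, dist = 0)
  expect_equal(tm_score(moved, s, pairing = pairing)$tm, 1.0,
               tolerance = 1e-9)

  # joint rigid motion of both structures leaves map-frame metrics fixed
  t2 <- transform_structure(s, R, c(5, -3, 2))
  expect_equal(ca_match(moved, t2), ca_match(s, s))
  expect_equal(tm_score(moved, t2)$tm, tm_score(s, s)$tm, tolerance = 1e-9)

  # closed form: truth on a ring, model radially inflated by exactly d0
  # after superposition each pair sits at distance d0 -> each term 1/2
  L <- 100L
  th <- 2 * pi * (seq_len(L) - 1) / L
  r <- 40
  ring <- cbind(r * cos(th), r * sin(th), 0)
  d0 <- 1.24 * (L - 15)^(1 / 3) - 1.8
  truth <- protein_structure(data.frame(
    chain = "A", resno = seq_len(L), ins = "", aa = "A", atom = "CA",
    x = ring[, 1], y = ring[, 2], z = ring[, 3]))
  infl <- ring * (1 + d0 / r)
  model_full <- protein_structure(data.frame(
    chain = "A", resno = seq_len(L), ins = "", aa = "A", atom = "CA",
    x = infl[, 1], y = infl[, 2], z = infl[, 3]))
  pr <- data.frame(model_idx = seq_len(L), truth_idx = seq_len(L), dist = 0)
  expect_equal(tm_score(model_full, truth, pairing = pr)$tm, 0.5,
               tolerance = 1e-6)

  # paired fraction scales the score: model = every other ring vertex
  half_idx <- seq(1L, L, by = 2L)
  model_half <- protein_structure(data.frame(
    chain = "A", resno = seq_along(half_idx), ins = "", aa = "A",
    atom = "CA", x = infl[half_idx, 1], y = infl[half_idx, 2],
    z = infl[half_idx, 3]))
  pr2 <- data.frame(model_idx = seq_along(half_idx), truth_idx = half_idx,
                    dist = 0)
  expect_equal(tm_score(model_half, truth, pairing = pr2)$tm, 0.25,
               tolerance = 1e-6)

  # < 3 pairs -> undefined, reported as 0 with flag
  tiny <- tm_score(line_structure(2L), line_structure(2L))
  expect_true(tiny$undefined)
  expect_equal(tiny$tm, 0)
})

test_that("external alignment result files parse and round-trip", {
  f <- tempfile(fileext = ".txt")
  writeLines(c(
    "Name of Structure_1: model.pdb",
    "Name of Structure_2: truth.pdb",
    "Length of Structure_1: 98 residues",
    "Length of Structure_2: 100 residues",
    "",
    "Aligned length= 95, RMSD=   1.23, Seq_ID=n_identical/n_aligned= 0.963",
    "TM-score= 0.91234 (normalized by length of Structure_1)",
    "TM-score= 0.89321 (normalized by length of Structure_2)"), f)
  res <- parse_usalign(f)
  expect_equal(res$aligned_length, 95)
  expect_equal(res$sequence_identity, 0.963)
  expect_equal(res$tm, 0.89321)
  unlink(f)
})

test_that("evaluate_model assembles a consistent report", {
  fx <- toy_fixture()
  cands <- extract_candidates(fx$pred, fx$map)
  bm <- trace_backbone(cands, fx$sequences)
  rep <- evaluate_model(bm, fx$structure)
  expect_s3_class(rep, "eval_report")
  expect_equal(rep$ca_quality_score,
               rep$ca_match * rep$model_length / rep$reference_length,
               tolerance = 1e-12)
  expect_true(rep$tm_score >= 0 && rep$tm_score <= 1)
  expect_true(rep$ca_match >= 0 && rep$ca_match <= 100)
  expect_equal(rep$reference_length, 40L)
})
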