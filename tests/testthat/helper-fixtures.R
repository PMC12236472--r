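# Shared fixtures, built once per test run.

# small toy fixture: 40-residue single chain, clean oracle volumes
toy_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- synthetic_fixture(synthetic_spec(n_residues = 40L, seed = 7L))
    cache
  }
})

# a hand-built one-residue glycine structure with atoms in distinct voxels
single_gly <- function(ca = c(5, 5, 5)) {
  protein_structure(data.frame(
    chain = "A", resno = 1L, ins = "", aa = "G",
    atom = c("N", "CA", "C", "O"),
    x = c(ca[1] - 1.5, ca[1], ca[1] + 1.5, ca[1] + 1.5),
    y = c(ca[2], ca[2], ca[2], ca[2] + 1.2),
    z = c(ca[3], ca[3], ca[3], ca[3])))
}

flat_map <- function(n = 12L, value = 0.5, origin = c(0, 0, 0)) {
  density_map(array(value, rep(n, 3L)), origin = origin)
}

# independent brute-force DBSCAN oracle: density-reachability closure
dbscan_oracle <- function(xyz, eps, min_samples) {
  n <- nrow(xyz)
  dd <- as.matrix(stats::dist(xyz))
  nb <- dd <= eps
  core <- rowSums(nb) >= min_samples
  labels <- integer(n)
  cl <- 0L
  for (p in seq_len(n)) {
    if (labels[p] != 0L || !core[p]) next
    cl <- cl + 1L
    # reachability closure by repeated expansion over core points
    members <- p
    repeat {
      grown <- unique(c(members,
                        unlist(lapply(members[core[members]], function(q)
                          which(nb[q, ])))))
      grown <- grown[labels[grown] == 0L]
      if (length(grown) == length(members)) break
      members <- grown
    }
    labels[members] <- cl
  }
  for (p in which(labels == 0L)) { cl <- cl + 1L; labels[p] <- cl }
  labels
}

# partition-agnostic comparison of two clusterings
same_partition <- function(a, b) {
  length(a) == length(b) &&
    identical(as.integer(factor(a, levels = unique(a))),
              as.integer(factor(b, levels = unique(b))))
}

# rigid transform helpers for invariance tests
random_rotation <- function(seed) {
  set.seed(seed)
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3L, 3L, byrow = TRUE)
}

transform_structure <- function(s, R, t) {
  a <- s$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  a$x <- xyz[, 1] + t[1]; a$y <- xyz[, 2] + t[2]; a$z <- xyz[, 3] + t[3]
  protein_structure(a)
}
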