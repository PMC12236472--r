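#' Synthetic fixture specification
#'
#' Parameters of the synthetic generators: toy C-alpha-walk proteins,
#' Gaussian-splat density maps in the 1-4 Angstrom operating range, and
#' perturbed predicted-structure surrogates.
#'
#' @param n_residues residues per chain (>= 3).
#' @param n_chains number of chains.
#' @param resolution simulated map resolution, Angstrom (in [1, 4]).
#' @param noise_sd additive map noise, as a fraction of the density peak.
#' @param perturbation_sd coordinate jitter of the predicted-structure
#'   surrogate, Angstrom.
#' @param seed integer seed; every generator draws only from it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_residues = 100L, n_chains = 1L,
                           resolution = 3.0, noise_sd = 0.0,
                           perturbation_sd = 0.0, seed = 1L) {
  stopifnot(n_residues >= 3L, resolution >= 1, resolution <= 4)
  structure(list(n_residues = as.integer(n_residues),
                 n_chains = as.integer(n_chains),
                 resolution = resolution, noise_sd = noise_sd,
                 perturbation_sd = perturbation_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a toy protein structure
#'
#' Self-avoiding C-alpha random walk with consecutive distances drawn from
#' 3.8 +/- 0.1 Angstrom and all non-consecutive C-alpha pairs at least
#' 4.0 Angstrom apart. Backbone N, C and O atoms are placed at fixed ideal
#' offsets from each C-alpha; the sequence is drawn uniformly from the 20
#' canonical types. Deterministic given the spec seed.
#'
#' @param spec a [synthetic_spec()].
#' @return A [protein_structure] with `n_chains` chains.
#' @export
gen_toy_structure <- function(spec) {
  set.seed(spec$seed)
  rows <- list()
  chain_ids <- make_chain_ids(spec$n_chains)
  # fixed local offsets for N, C, O relative to each CA (A)
  off_n <- c(-1.46, 0.0, 0.0); off_c <- c(1.52, 0.0, 0.0)
  off_o <- c(1.52, 1.23, 0.0)
  for (ch in seq_len(spec$n_chains)) {
    ca <- ca_walk(spec$n_residues,
                  existing = if (length(rows) > 0L)
                    do.call(rbind, lapply(rows, function(r)
                      as.matrix(r[r$atom == "CA", c("x", "y", "z")])))
                  else NULL)
    sq <- sample(aa_alphabet(), spec$n_residues, replace = TRUE)
    rows[[ch]] <- do.call(rbind, lapply(seq_len(spec$n_residues), function(r) {
      p <- ca[r, ]
      data.frame(chain = chain_ids[ch], resno = r, ins = "", aa = sq[r],
                 atom = c("N", "CA", "C", "O"),
                 x = p[1] + c(off_n[1], 0, off_c[1], off_o[1]),
                 y = p[2] + c(off_n[2], 0, off_c[2], off_o[2]),
                 z = p[3] + c(off_n[3], 0, off_c[3], off_o[3]))
    }))
  }
  protein_structure(do.call(rbind, rows))
}

# self-avoiding CA walk: consecutive spacing 3.8 +/- 0.1 A, non-consecutive
# separation >= min_sep; bounded restarts then error
ca_walk <- function(n, min_sep = 4.0, max_tries = 200L, existing = NULL) {
  for (t in seq_len(max_tries)) {
    pts <- matrix(NA_real_, n, 3L)
    pts[1, ] <- stats::runif(3, -2, 2)
    dir <- rand_unit()
    ok <- TRUE
    for (r in 2:n) {
      placed <- FALSE
      for (a in seq_len(30L)) {
        # bias direction changes to stay chain-like but wander
        cand_dir <- norm1(dir + 0.8 * rand_unit())
        step <- stats::runif(1, 3.7, 3.9)
        cand <- pts[r - 1L, ] + step * cand_dir
        prev <- pts[seq_len(max(r - 2L, 0L)), , drop = FALSE]
        clash <- FALSE
        if (nrow(prev) > 0L)
          clash <- min(sqrt(rowSums(sweep(prev, 2L, cand)^2))) < min_sep
        if (!clash && !is.null(existing) && nrow(existing) > 0L)
          clash <- min(sqrt(rowSums(sweep(existing, 2L, cand)^2))) < min_sep
        if (!clash) {
          pts[r, ] <- cand
          dir <- cand_dir
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(pts)
  }
  stop("ca_walk: failed to place a self-avoiding chain after ", max_tries,
       " restarts")
}

rand_unit <- function() norm1(stats::rnorm(3))
norm1 <- function(v) v / sqrt(sum(v^2))

#' Simulate a density map from a structure
#'
#' Sum of per-atom isotropic Gaussians with sigma = 0.425 * resolution,
#' sampled on a 1 Angstrom grid with at least `margin` Angstrom of padding
#' around the structure, plus optional additive Gaussian noise scaled to
#' the density peak. A physically simple stand-in for an experimental map:
#' enough to exercise normalization, labeling and candidate extraction.
#'
#' @param structure a [protein_structure].
#' @param spec a [synthetic_spec()] (uses `resolution`, `noise_sd`, `seed`).
#' @param margin padding around the structure, Angstrom.
#' @return A [density_map] at 1 Angstrom voxels.
#' @export
simulate_density <- function(structure, spec, margin = 5) {
  a <- structure$atoms
  if (nrow(a) == 0L) {
    return(density_map(array(0, c(8L, 8L, 8L)), resolution = spec$resolution))
  }
  lo <- c(min(a$x), min(a$y), min(a$z)) - margin
  hi <- c(max(a$x), max(a$y), max(a$z)) + margin
  origin <- floor(lo)
  dims_xyz <- as.integer(ceiling(hi - origin)) + 1L
  d <- rev(dims_xyz)                       # nz, ny, nx
  sigma <- 0.425 * spec$resolution
  vol <- array(0, d)
  gx <- origin[1] + 0:(dims_xyz[1] - 1L)
  gy <- origin[2] + 0:(dims_xyz[2] - 1L)
  gz <- origin[3] + 0:(dims_xyz[3] - 1L)
  r3 <- ceiling(3 * sigma)
  for (r in seq_len(nrow(a))) {
    xs <- which(abs(gx - a$x[r]) <= r3)
    ys <- which(abs(gy - a$y[r]) <= r3)
    zs <- which(abs(gz - a$z[r]) <= r3)
    if (length(xs) == 0L || length(ys) == 0L || length(zs) == 0L) next
    ex <- exp(-(gx[xs] - a$x[r])^2 / (2 * sigma^2))
    ey <- exp(-(gy[ys] - a$y[r])^2 / (2 * sigma^2))
    ez <- exp(-(gz[zs] - a$z[r])^2 / (2 * sigma^2))
    vol[zs, ys, xs] <- vol[zs, ys, xs] + outer(ez, outer(ey, ex))
  }
  if (spec$noise_sd > 0) {
    set.seed(spec$seed + 7L)
    vol <- vol + array(stats::rnorm(length(vol),
                                    sd = spec$noise_sd * max(vol)), d)
  }
  density_map(vol, origin = origin, voxel_size = c(1, 1, 1),
              resolution = spec$resolution)
}

#' Perturb a structure into a predicted-structure surrogate
#'
#' Jitters every atom with isotropic Gaussian noise of sd
#' `perturbation_sd`; optionally displaces one contiguous residue segment
#' rigidly (a surrogate for an incorrectly predicted domain). The sequence
#' is unchanged.
#'
#' @param structure a [protein_structure].
#' @param spec a [synthetic_spec()] (uses `perturbation_sd`, `seed`).
#' @param displace_segment if TRUE one random contiguous segment (about a
#'   quarter of the chain) is shifted by `segment_shift` Angstrom.
#' @param segment_shift rigid displacement of the bad segment, Angstrom.
#' @return A [protein_structure].
#' @export
perturb_structure <- function(structure, spec, displace_segment = FALSE,
                              segment_shift = 5.0) {
  set.seed(spec$seed + 13L)
  a <- structure$atoms
  if (spec$perturbation_sd > 0) {
    a$x <- a$x + stats::rnorm(nrow(a), sd = spec$perturbation_sd)
    a$y <- a$y + stats::rnorm(nrow(a), sd = spec$perturbation_sd)
    a$z <- a$z + stats::rnorm(nrow(a), sd = spec$perturbation_sd)
  }
  if (displace_segment) {
    ch <- a$chain == a$chain[1]
    res <- sort(unique(a$resno[ch]))
    seg_len <- max(3L, length(res) %/% 4L)
    start <- sample(seq_len(length(res) - seg_len + 1L), 1L)
    seg <- res[start:(start + seg_len - 1L)]
    shift <- segment_shift * rand_unit()
    sel <- ch & a$resno %in% seg
    a$x[sel] <- a$x[sel] + shift[1]
    a$y[sel] <- a$y[sel] + shift[2]
    a$z[sel] <- a$z[sel] + shift[3]
  }
  protein_structure(a)
}

#' Oracle prediction volumes from label masks
#'
#' Probability volumes a perfectly trained network would emit, derived
#' directly from the label masks: `calpha_p` equals `sharpness` at C-alpha
#' voxels (label 3) and a low background elsewhere; `backbone_p` likewise
#' from the backbone mask; `amino_p` puts `sharpness` mass on the true type
#' at labeled voxels (rest spread uniformly) and is uniform elsewhere.
#' Degrading `sharpness` exercises thresholding and tracing under
#' uncertainty.
#'
#' @param masks a `label_masks` list.
#' @param sharpness probability mass on the true class, in (0.05, 1).
#' @param background probability assigned off-structure (default 0.02).
#' @return A `prediction_volumes` list.
#' @export
oracle_prediction_volumes <- function(masks, sharpness = 0.99,
                                      background = 0.02) {
  if (sharpness <= 0.05 || sharpness >= 1)
    stop("oracle_prediction_volumes: sharpness must be in (0.05, 1)")
  d <- dim(masks$calpha)
  calpha_p <- array(background * sharpness / 0.99, d)
  calpha_p[masks$calpha == 3L] <- sharpness
  backbone_p <- array(background * sharpness / 0.99, d)
  backbone_p[masks$backbone == 3L] <- sharpness
  amino_p <- array(1 / 20, c(20L, d))
  lab <- which(masks$amino > 0L)
  if (length(lab) > 0L) {
    rest <- (1 - sharpness) / 19
    codes <- masks$amino[lab]
    for (v in seq_along(lab)) {
      ijk <- arrayInd(lab[v], d)
      col <- rep(rest, 20L)
      col[codes[v]] <- sharpness
      amino_p[, ijk[1], ijk[2], ijk[3]] <- col
    }
  }
  structure(list(backbone_p = backbone_p, calpha_p = calpha_p,
                 amino_p = amino_p),
            class = "prediction_volumes")
}

#' Generate a complete synthetic fixture
#'
#' Toy structure, simulated map, normalized map, label masks, oracle
#' prediction volumes and a perturbed predicted-structure surrogate in one
#' call.
#'
#' @param spec a [synthetic_spec()].
#' @param sharpness oracle sharpness (see [oracle_prediction_volumes()]).
#' @return List with `structure`, `map` (normalized), `raw_map`, `masks`,
#'   `pred` (oracle `prediction_volumes`), `af3` (perturbed surrogate),
#'   `sequences`.
#' @export
synthetic_fixture <- function(spec, sharpness = 0.99) {
  truth <- gen_toy_structure(spec)
  raw <- simulate_density(truth, spec)
  map <- normalize_map(raw)
  masks <- make_label_masks(truth, map)
  pred <- oracle_prediction_volumes(masks, sharpness = sharpness)
  af3 <- perturb_structure(truth, spec)
  list(structure = truth, map = map, raw_map = raw, masks = masks,
       pred = pred, af3 = af3,
       sequences = unname(structure_sequences(truth)))
}
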