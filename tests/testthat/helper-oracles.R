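# Independent brute-force oracles the implementation is checked against.

# Direct dense 3D convolution with a separable kernel given as the full
# 3D weight array, symmetric boundary handling, looping over output
# voxels. Deliberately naive.
brute_convolve3 <- function(arr, kern3) {
  d <- dim(arr)
  kd <- dim(kern3)
  r <- (kd - 1L) %/% 2L
  refl <- function(j, n) {
    m <- (j - 1L) %% (2L * n)
    ifelse(m < n, m + 1L, 2L * n - m)
  }
  out <- array(0, d)
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    zz <- refl(z - r[1] + 0:(kd[1] - 1L), d[1])
    yy <- refl(y - r[2] + 0:(kd[2] - 1L), d[2])
    xx <- refl(x - r[3] + 0:(kd[3] - 1L), d[3])
    out[z, y, x] <- sum(arr[zz, yy, xx] * kern3)
  }
  out
}

# Flood-fill connected-component labelling by explicit BFS over a
# queue; independent of the graph-based implementation.
flood_fill_label <- function(fg, connectivity = 6L) {
  d <- dim(fg)
  offs <- if (connectivity == 6L) {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
          c(0, 0, 1), c(0, 0, -1))
  } else {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    g[rowSums(abs(g)) > 0, , drop = FALSE]
  }
  lab <- array(0L, d)
  next_lab <- 0L
  for (lin in which(fg)) {
    if (lab[lin] != 0L) next
    next_lab <- next_lab + 1L
    queue <- matrix(arrayInd(lin, d), ncol = 3)
    lab[lin] <- next_lab
    while (nrow(queue)) {
      cur <- queue[1, ]
      queue <- queue[-1, , drop = FALSE]
      for (i in seq_len(nrow(offs))) {
        nb <- cur + offs[i, ]
        if (any(nb < 1) || any(nb > d)) next
        if (fg[nb[1], nb[2], nb[3]] && lab[nb[1], nb[2], nb[3]] == 0L) {
          lab[nb[1], nb[2], nb[3]] <- next_lab
          queue <- rbind(queue, nb)
        }
      }
    }
  }
  lab
}

# Do two labelings induce the same partition of the foreground?
same_partition <- function(lab1, lab2) {
  f1 <- which(lab1 > 0L)
  f2 <- which(lab2 > 0L)
  if (!identical(f1, f2)) return(FALSE)
  key <- paste(lab1[f1], lab2[f2])
  length(unique(key)) == length(unique(lab1[f1])) &&
    length(unique(key)) == length(unique(lab2[f2]))
}

# Exhaustive longest-common-subsequence of k permutations: try every
# subset of ids, in the order given by the first sample, and test
# order-conservation in all samples. Exponential; n <= 12 only.
brute_lcs_permutations <- function(orderings) {
  n <- length(orderings[[1]])
  ids1 <- orderings[[1]]
  pos <- lapply(orderings, function(o) {
    p <- integer(n)
    p[o] <- seq_len(n)
    p
  })
  best <- 0L
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (length(sel) <= best) next
    sq <- ids1[sel]  # in sample-1 order
    ok <- all(vapply(pos, function(p) all(diff(p[sq]) > 0), logical(1)))
    if (ok) best <- length(sel)
  }
  best
}

# Exhaustive enumeration of all order-conserved sequences of length L.
brute_enumerate <- function(orderings, L) {
  n <- length(orderings[[1]])
  ids1 <- orderings[[1]]
  pos <- lapply(orderings, function(o) {
    p <- integer(n)
    p[o] <- seq_len(n)
    p
  })
  res <- list()
  for (sel in utils::combn(n, L, simplify = FALSE)) {
    sq <- ids1[sel]
    if (all(vapply(pos, function(p) all(diff(p[sq]) > 0), logical(1))))
      res[[length(res) + 1L]] <- sq
  }
  res
}

# Small helpers reused across test files -------------------------------

# A 64^3 test scene: ellipsoidal brain atlas, planted bright blobs well
# inside the erosion-refined mask, mild noise. Amplitude defaults to the
# calibrated contrast at which each blob's suprathreshold footprint
# matches its 2-sigma ground-truth ball.
make_test_scene <- function(n_blobs = 20L, seed = 42L, shape = c(64, 64, 64),
                            amplitude = NULL, brain_background = 20,
                            outside_background = 2, noise_sd = 0.5,
                            sigma_vox = 1.6) {
  atl <- make_toy_atlas(shape, pitch_um = 8.3, n_regions = 4L)
  if (is.null(amplitude))
    amplitude <- calibrate_spot_amplitude(
      atl, sigma_vox = sigma_vox, brain_background = brain_background,
      outside_background = outside_background, noise_sd = noise_sd,
      seed = seed)
  set.seed(seed)
  ctr <- (shape + 1) / 2
  centers <- matrix(NA_real_, n_blobs, 3)
  i <- 0L
  while (i < n_blobs) {
    cand <- round(ctr + stats::runif(3, -0.3, 0.3) * shape)
    # stay deep inside the ellipsoid so 10 erosions cannot reach the blob
    if (sqrt(sum(((cand - ctr) / (shape / 2 - 0.5))^2)) > 0.55) next
    if (i > 0) {
      dmin <- min(sqrt(rowSums(sweep(centers[seq_len(i), , drop = FALSE],
                                     2, cand)^2)))
      if (dmin < 10) next
    }
    i <- i + 1L
    centers[i, ] <- cand
  }
  spots <- lapply(seq_len(n_blobs), function(j)
    planted_spot(centers[j, ], amplitude = amplitude, sigma_vox = sigma_vox))
  sim <- make_tau_volume(atl, spots, brain_background = brain_background,
                         outside_background = outside_background,
                         noise_sd = noise_sd, seed = seed)
  list(atlas = atl, sim = sim, centers = centers, spots = spots)
}
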