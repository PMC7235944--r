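# Independent oracles and small fixture builders used across the suite.

# brute-force foreground count by explicit triple loop (independent of any
# vectorised counting in the package)
oracle_voxel_count <- function(a) {
  d <- dim(a)
  n <- 0L
  for (x in seq_len(d[3]))
    for (y in seq_len(d[2]))
      for (z in seq_len(d[1]))
        if (a[z, y, x] != 0) n <- n + 1L
  n
}

# flood-fill connected-component labeling in plain R (queue-based)
oracle_label_components <- function(a, connectivity = 26) {
  d <- dim(a)
  lab <- array(0L, d)
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
  nextlab <- 0L
  for (x in seq_len(d[3])) for (y in seq_len(d[2])) for (z in seq_len(d[1])) {
    if (a[z, y, x] == 0 || lab[z, y, x] != 0) next
    nextlab <- nextlab + 1L
    queue <- matrix(c(z, y, x), ncol = 3)
    lab[z, y, x] <- nextlab
    while (nrow(queue) > 0) {
      p <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(nrow(offs))) {
        q <- p + as.integer(offs[k, ])
        if (any(q < 1) || any(q > d)) next
        if (a[q[1], q[2], q[3]] != 0 && lab[q[1], q[2], q[3]] == 0) {
          lab[q[1], q[2], q[3]] <- nextlab
          queue <- rbind(queue, q)
        }
      }
    }
  }
  lab
}

# a mixed bag of small seeded phantoms for batch-style checks
phantom_bag <- function(n, dims = 64, seed0 = 100) {
  lapply(seq_len(n), function(i) {
    kind <- c("isotropic_foam", "sphere", "plate_stack")[(i %% 3) + 1]
    params <- switch(kind,
      isotropic_foam = list(bvtv = 0.15 + 0.02 * (i %% 5), corr_length = 3),
      sphere = list(r = dims %/% 4 + (i %% min(4, dims %/% 8))),
      plate_stack = list(t = 3 + 2 * (i %% 3),
                         g = min(8 + 2 * (i %% 5), dims - 7 - 2 * (i %% 3))))
    make_phantom(kind, dims = dims, params = params, seed = seed0 + i)
  })
}

# analytic closed UV-sphere mesh (smooth reference surface, all triangles
# interior) wrapped as a tri_mesh
uv_sphere_mesh <- function(r, n_theta = 40, n_phi = 80, h = 1) {
  theta <- seq(0, pi, length.out = n_theta + 1)[2:n_theta]   # exclude poles
  phi <- seq(0, 2 * pi, length.out = n_phi + 1)[seq_len(n_phi)]
  ring <- function(th) cbind(r * sin(th) * cos(phi), r * sin(th) * sin(phi),
                             rep(r * cos(th), n_phi))
  V <- rbind(c(0, 0, r), do.call(rbind, lapply(theta, ring)), c(0, 0, -r))
  top <- 1L
  bot <- nrow(V)
  idx <- function(i, j) 1L + (i - 1L) * n_phi + ((j - 1L) %% n_phi) + 1L
  tris <- list()
  for (j in seq_len(n_phi))
    tris[[length(tris) + 1L]] <- c(top, idx(1, j), idx(1, j + 1))
  for (i in seq_len(length(theta) - 1))
    for (j in seq_len(n_phi)) {
      tris[[length(tris) + 1L]] <- c(idx(i, j), idx(i + 1, j), idx(i, j + 1))
      tris[[length(tris) + 1L]] <- c(idx(i + 1, j), idx(i + 1, j + 1),
                                     idx(i, j + 1))
    }
  nlast <- length(theta)
  for (j in seq_len(n_phi))
    tris[[length(tris) + 1L]] <- c(bot, idx(nlast, j + 1), idx(nlast, j))
  Tm <- do.call(rbind, tris)
  structure(list(vertices = V, triangles = Tm,
                 is_boundary = rep(FALSE, nrow(Tm)), voxel_size = h,
                 dims = NULL, capped = TRUE),
            class = "tri_mesh")
}

# seeded random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function(seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# forward-generate an exact ellipsoidal MIL distribution from tensor A
mil_from_tensor <- function(A, dirs, noise_sd = 0) {
  mil <- 1 / sqrt(rowSums((dirs %*% A) * dirs))
  if (noise_sd > 0) mil <- mil * (1 + rnorm(nrow(dirs), 0, noise_sd))
  trabemorph:::new_mil_distribution(dirs, mil, rep(NA_real_, nrow(dirs)),
                                    rep(1L, nrow(dirs)), "test_lines",
                                    nrow(dirs))
}
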