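# Shared fixtures, built once per test run.

# Small head phantom (12 mm cells) for pipeline tests.
fixture_phantom <- local({
  ph <- NULL
  function() {
    if (is.null(ph)) ph <<- build_synthetic_head(target_edge = 0.012)
    ph
  }
})

# Six-antenna array keeps operator tests light (M = 36 rows).
fixture_array <- function() antenna_array(Ma = 6, ring_angles = c(30, 60))

fixture_operator <- local({
  op <- NULL
  function() {
    if (is.null(op)) op <<- system_operator(fixture_phantom(), fixture_array())
    op
  }
})

# Tiny random labelled mesh: n tets with random geometry, all white matter.
random_tet_mesh <- function(n, seed = 1) {
  set.seed(seed)
  verts <- NULL
  tets <- matrix(0L, n, 4)
  for (i in seq_len(n)) {
    repeat {
      v <- matrix(runif(12, -0.05, 0.05), 4, 3)
      vol <- abs(det(rbind(v[2, ] - v[1, ], v[3, ] - v[1, ], v[4, ] - v[1, ]))) / 6
      if (vol > 1e-9) break
    }
    verts <- rbind(verts, v)
    tets[i, ] <- (i - 1L) * 4L + 1:4
  }
  tet_mesh(verts, tets, rep("white_matter", n))
}

# Phantom wrapper around an arbitrary labelled mesh.
mesh_phantom <- function(mesh, tissues = tissue_table()) {
  mwistroke:::new_head_phantom(mesh, tissues)
}

# Structured two-tissue slab: nx x ny x nz cells, label by x-position.
slab_phantom <- function(nx = 10, ny = 4, nz = 4, h = 0.003, split = 5) {
  grid <- mwistroke:::build_cube_tets(c(0, 0, 0), rep(h, 3), c(nx, ny, nz))
  bary <- (grid$vertices[grid$tets[, 1], ] + grid$vertices[grid$tets[, 2], ] +
           grid$vertices[grid$tets[, 3], ] + grid$vertices[grid$tets[, 4], ]) / 4
  label <- ifelse(bary[, 1] < split * h, "white_matter", "grey_matter")
  mesh_phantom(tet_mesh(grid$vertices, grid$tets, label))
}

# Brute-force differential S-parameters: term-by-term sum of
# K_mn (E_p . E_q) dV_n dchi_n, written independently of the operator code.
brute_force_ds <- function(mesh, eps_b, array, fields, dchi) {
  Ma <- array$Ma
  omega <- 2 * pi * fields$frequency
  out <- matrix(0 + 0i, Ma, Ma)
  for (p in seq_len(Ma)) {
    for (q in seq_len(Ma)) {
      acc <- 0 + 0i
      for (n in seq_along(dchi)) {
        K <- -1i * omega * (8.8541878128e-12 * eps_b[n]) /
          (2 * array$power_waves[p] * array$power_waves[q])
        dot <- sum(fields$E[[p]][n, ] * fields$E[[q]][n, ])
        acc <- acc + K * dot * mesh$volumes[n] * dchi[n]
      }
      out[p, q] <- acc
    }
  }
  out
}
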