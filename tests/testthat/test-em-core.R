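test_that("complex permittivity follows eps_r - j sigma/(omega eps0)", {
  tab <- tibble::tibble(name = "x", eps_r = 36.00, sigma = 0.72, frequency = 1e9)
  expect_equal(complex_permittivity(tab), 36.00 - 12.94i, tolerance = 1e-3)
  tab$eps_r <- 63.41; tab$sigma <- 1.58
  expect_equal(complex_permittivity(tab), 63.41 - 28.40i, tolerance = 1e-3)
  tab$sigma <- 0
  expect_identical(Im(complex_permittivity(tab)), 0)
})

test_that("dipole field decays with distance and is symmetric between points", {
  eps_c <- 18.42 - 0.9i
  pos <- c(0, 0, 0); axis <- c(0, 0, 1)
  # broadside points at r and 2r, well beyond the near-field peak
  pts <- rbind(c(0.2, 0, 0), c(0.4, 0, 0))
  E <- dipole_field(pos, axis, pts, eps_c, 1e9)
  amp <- sqrt(rowSums(abs(E)^2))
  expect_gte(amp[1] / amp[2], 2)

  # identical dipoles: field of p at q's position equals field of q at p's
  p1 <- c(0, 0, 0); p2 <- c(0.1, 0.05, 0.02)
  E12 <- dipole_field(p1, axis, matrix(p2, 1), eps_c, 1e9)
  E21 <- dipole_field(p2, axis, matrix(p1, 1), eps_c, 1e9)
  expect_equal(E12, E21, tolerance = 1e-12)

  expect_error(dipole_field(p1, axis, matrix(p1, 1), eps_c, 1e9), "singular")
})

test_that("dipole field matches an independently coded closed form", {
  # textbook Hertzian dipole (z-oriented, spherical components), coded
  # separately from the implementation
  eps_c <- 20 - 2i; f <- 1e9
  omega <- 2 * pi * f
  eps <- 8.8541878128e-12 * eps_c
  k <- omega * sqrt(4e-7 * pi * 8.8541878128e-12) * sqrt(eps_c)
  if (Im(k) > 0) k <- -k
  eta <- sqrt((4e-7 * pi) / eps)
  moment <- 3.2e-12                      # C m
  Il <- 1i * omega * moment              # current element I*l = j omega p
  pt <- c(0.04, 0.03, 0.05)
  r <- sqrt(sum(pt^2)); theta <- acos(pt[3] / r); phi <- atan2(pt[2], pt[1])
  Er <- eta * Il * cos(theta) / (2 * pi * r^2) * (1 + 1 / (1i * k * r)) *
    exp(-1i * k * r)
  Eth <- 1i * eta * k * Il * sin(theta) / (4 * pi * r) *
    (1 + 1 / (1i * k * r) - 1 / (k * r)^2) * exp(-1i * k * r)
  rhat <- pt / r
  thhat <- c(cos(theta) * cos(phi), cos(theta) * sin(phi), -sin(theta))
  E_ref <- Er * rhat + Eth * thhat
  E <- dipole_field(c(0, 0, 0), c(0, 0, 1), matrix(pt, 1), eps_c, f,
                    moment = moment)
  expect_equal(as.vector(E), E_ref, tolerance = 1e-10)
})

test_that("operator has Ma^2 rows and zero fields give zero rows", {
  mesh <- random_tet_mesh(5)
  arr <- antenna_array(Ma = 24)
  fs <- field_set(arr, mesh)
  op <- assemble_operator(mesh, rep(38 - 10i, 5), arr, fs)
  expect_equal(dim(op$S), c(576L, 5L))

  fs0 <- fs
  fs0$E[[3]] <- fs0$E[[3]] * 0
  op0 <- assemble_operator(mesh, rep(38 - 10i, 5), arr, fs0)
  rows_p3 <- which(op0$index_map$p == 3 | op0$index_map$q == 3)
  expect_true(all(op0$S[rows_p3, ] == 0))
  expect_true(any(op0$S[-rows_p3, ] != 0))
})

test_that("a single operator entry equals the hand-computed K (Ep.Eq) dV", {
  mesh <- random_tet_mesh(1)
  arr <- fixture_array()
  n <- 1
  Ep <- matrix(complex(real = 1:3, imaginary = c(0.5, -1, 2)), 1, 3)
  Eq <- matrix(complex(real = c(-1, 0.2, 4), imaginary = c(1, 0, -0.3)), 1, 3)
  E <- rep(list(matrix(0 + 0i, 1, 3)), arr$Ma)
  E[[2]] <- Ep; E[[5]] <- Eq
  fs <- field_set(arr, mesh, E = E)
  eps_b <- 40 - 8i
  op <- assemble_operator(mesh, eps_b, arr, fs)
  omega <- 2 * pi * 1e9
  K <- -1i * omega * (8.8541878128e-12 * eps_b) / 2
  expected <- K * sum(Ep * Eq) * mesh$volumes[1]
  m <- which(op$index_map$p == 2 & op$index_map$q == 5)
  expect_equal(op$S[m, 1], expected, tolerance = 1e-14)
})

test_that("forward map is linear, exact at zero, and matches brute force", {
  mesh <- random_tet_mesh(50, seed = 4)
  arr <- fixture_array()
  fs <- field_set(arr, mesh)
  eps_b <- complex(real = runif(50, 35, 55), imaginary = -runif(50, 5, 20))
  op <- assemble_operator(mesh, eps_b, arr, fs)

  expect_true(all(unclass(forward(op, rep(0 + 0i, 50))) == 0))

  set.seed(5)
  x1 <- complex(real = rnorm(50), imaginary = rnorm(50)) * 0.1
  x2 <- complex(real = rnorm(50), imaginary = rnorm(50)) * 0.1
  lhs <- unclass(forward(op, (2 + 1i) * x1 + (0.5 - 3i) * x2))
  rhs <- (2 + 1i) * unclass(forward(op, x1)) +
    (0.5 - 3i) * unclass(forward(op, x2))
  expect_equal(lhs, rhs, tolerance = 1e-12)

  bf <- brute_force_ds(mesh, eps_b, arr, fs, x1)
  fw <- unclass(forward(op, x1))
  expect_lt(max(abs(fw - bf)) / max(abs(bf)), 1e-12)

  expect_error(forward(op, x1[1:10]), "length")
})

test_that("operator rows respect reciprocity with a symmetric field provider", {
  op <- fixture_operator()
  im <- op$index_map
  set.seed(8)
  for (i in sample(nrow(im), 20)) {
    p <- im$p[i]; q <- im$q[i]
    m_pq <- which(im$p == p & im$q == q)
    m_qp <- which(im$p == q & im$q == p)
    expect_equal(op$S[m_pq, ], op$S[m_qp, ], tolerance = 1e-12)
  }
})

test_that("dS scales with tet volumes and inversely with power waves squared", {
  mesh <- random_tet_mesh(10, seed = 9)
  arr <- fixture_array()
  fs <- field_set(arr, mesh)
  eps_b <- rep(40 - 10i, 10)
  op <- assemble_operator(mesh, eps_b, arr, fs)
  set.seed(10)
  x <- complex(real = rnorm(10), imaginary = rnorm(10))
  base <- unclass(forward(op, x))

  mesh2 <- mesh
  mesh2$volumes <- mesh$volumes * 2
  op2 <- assemble_operator(mesh2, eps_b, arr, fs)
  expect_equal(unclass(forward(op2, x)), 2 * base, tolerance = 1e-12)

  arr3 <- antenna_array(Ma = 6, ring_angles = c(30, 60), power_waves = 3)
  fs3 <- fs  # same fields, only the power waves change
  op3 <- assemble_operator(mesh, eps_b, arr3, fs3)
  expect_equal(unclass(forward(op3, x)), base / 9, tolerance = 1e-12)
})

test_that("total S-parameters add background and differential elementwise", {
  op <- fixture_operator()
  Sb <- background_sparams(fixture_array())
  z <- sparams(matrix(0 + 0i, 6, 6), role = "differential")
  expect_equal(unclass(total_sparams(Sb, z)), unclass(Sb),
               ignore_attr = TRUE)

  set.seed(12)
  x1 <- complex(real = rnorm(op$n_tets), imaginary = rnorm(op$n_tets)) * 0.01
  x2 <- complex(real = rnorm(op$n_tets), imaginary = rnorm(op$n_tets)) * 0.01
  d1 <- forward(op, x1); d2 <- forward(op, x2)
  stacked <- total_sparams(total_sparams(Sb, d1), d2)
  expect_equal(unclass(stacked), unclass(Sb) + unclass(d1) + unclass(d2),
               tolerance = 1e-14, ignore_attr = TRUE)
})

test_that("background S-parameters are reciprocal, decaying, and match the Green's function", {
  arr <- antenna_array(Ma = 24)
  Sb <- background_sparams(arr, eps_c = 18.42 - 0.9i, coupling = 0.02,
                           reflection = 0.3 + 0i)
  expect_equal(unclass(Sb), t(unclass(Sb)))

  d <- as.matrix(dist(arr$positions))
  off <- upper.tri(d)
  # larger separation -> smaller |S| in the lossy medium
  o <- order(d[off])
  amp <- abs(unclass(Sb)[off])[o]
  expect_true(all(diff(amp) < 1e-12))

  # hand-evaluated scalar Green's function for one pair
  k <- wavenumber(18.42 - 0.9i, 1e9)
  d12 <- sqrt(sum((arr$positions[1, ] - arr$positions[2, ])^2))
  expect_equal(unclass(Sb)[1, 2], 0.02 * exp(-1i * k * d12) / (4 * pi * d12),
               tolerance = 1e-12)
})

test_that("Born error metric has the stated closed form and floor", {
  A <- sparams(matrix(0.5 + 0i, 3, 3), "test")
  expect_true(all(born_error(A, A) == -300))
  B <- unclass(A); B[1, 2] <- B[1, 2] + 1e-4; B[2, 2] <- B[2, 2] + 1
  eta <- born_error(sparams(B, "test"), A)
  expect_equal(eta[1, 2], -80)
  expect_equal(eta[2, 2], 0)
})

test_that("operator round-trips through plain-text persistence", {
  mesh <- random_tet_mesh(4)
  arr <- fixture_array()
  op <- assemble_operator(mesh, rep(40 - 9i, 4), arr, field_set(arr, mesh))
  dir <- withr::local_tempdir()
  write_operator(op, dir)
  back <- read_operator(dir)
  expect_equal(back$S, op$S, tolerance = 1e-14)
  expect_equal(back$Ma, op$Ma)
  expect_equal(back$frequency, op$frequency)
})
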