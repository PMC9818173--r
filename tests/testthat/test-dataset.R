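test_that("vectorization keeps the independent upper triangle", {
  set.seed(101)
  z <- matrix(complex(real = rnorm(576), imaginary = rnorm(576)), 24, 24)
  z[lower.tri(z)] <- t(z)[lower.tri(z)]      # reciprocal matrix
  S <- sparams(z, "test")
  vc <- vectorize(S, "complex")
  va <- vectorize(S, "amplitude")
  expect_length(vc, 600)
  expect_length(va, 300)
  expect_named(vc, sprintf("f%03d", 0:599))

  # amplitude mode equals sqrt(Re^2 + Im^2) of the complex features
  expect_equal(unname(va),
               sqrt(unname(vc[c(TRUE, FALSE)])^2 + unname(vc[c(FALSE, TRUE)])^2))

  # round-trip through reciprocity
  back <- devectorize(vc, 24)
  expect_equal(unclass(back), z, tolerance = 1e-15, ignore_attr = TRUE)

  # row-major p <= q ordering: first element is S11, second S12
  expect_equal(unname(vc[1]) + 1i * unname(vc[2]), z[1, 1])
  expect_equal(unname(vc[3]) + 1i * unname(vc[4]), z[1, 2])

  expect_error(vectorize(sparams(matrix(0i, 2, 2), "test")[, 1, drop = FALSE]),
               "square")
})

test_that("training sets honour composition, determinism and background rotation", {
  ph <- fixture_phantom()
  op <- fixture_operator()
  Sb <- background_sparams(fixture_array())
  comp <- setNames(c(4L, rep(2L, 8)), class_levels())
  ds1 <- generate_training_set(op, ph, Sb, composition = comp, seed = 5)
  ds2 <- generate_training_set(op, ph, Sb, composition = comp, seed = 5)
  expect_identical(as.data.frame(ds1), as.data.frame(ds2))
  expect_identical(dataset_manifest(ds1), dataset_manifest(ds2))
  expect_equal(as.vector(table(ds1$label)), unname(comp))
  expect_equal(ncol(ds1) - 1, 6 * 7)       # complex mode, Ma = 6

  # healthy records carry no stroke geometry; strokes match their class
  man <- dataset_manifest(ds1)
  expect_true(all(is.na(man$radius[man$class == "N"])))
  expect_true(all(man$quadrant[man$class != "N"] ==
                  sub("^[IH]_", "", man$class[man$class != "N"])))

  # several backgrounds: records distributed equally round-robin
  set.seed(7)
  fam <- model_family(ph, n_shapes = 2, vars = 0.3)
  bgs <- lapply(fam, model_background, op = op, phantom = ph, Sb_nominal = Sb)
  ds3 <- generate_training_set(op, ph, bgs, composition = comp, seed = 5)
  expect_equal(unname(table(dataset_manifest(ds3)$background)), c(10L, 10L),
               ignore_attr = TRUE)
})

test_that("amplitude features of the same records match the complex ones", {
  ph <- fixture_phantom()
  op <- fixture_operator()
  Sb <- background_sparams(fixture_array())
  comp <- setNames(c(2L, rep(1L, 8)), class_levels())
  dc <- generate_training_set(op, ph, Sb, composition = comp, mode = "complex",
                              seed = 9)
  da <- generate_training_set(op, ph, Sb, composition = comp,
                              mode = "amplitude", seed = 9)
  xc <- as.matrix(as.data.frame(dc)[, -1])
  xa <- as.matrix(as.data.frame(da)[, -1])
  expect_equal(unname(xa),
               unname(sqrt(xc[, c(TRUE, FALSE)]^2 + xc[, c(FALSE, TRUE)]^2)),
               tolerance = 1e-12)
})

test_that("stratified split has consistent per-class sizes and is reproducible", {
  ph <- fixture_phantom()
  op <- fixture_operator()
  Sb <- background_sparams(fixture_array())
  comp <- setNames(c(10L, rep(10L, 8)), class_levels())
  ds <- generate_training_set(op, ph, Sb, composition = comp, seed = 13)
  sp <- split_dataset(ds, 0.8, seed = 1)
  expect_equal(nrow(sp$train), 72)
  expect_equal(nrow(sp$validation), 18)
  expect_true(all(table(sp$train$label) == 8))
  expect_true(all(table(sp$validation$label) == 2))
  sp2 <- split_dataset(ds, 0.8, seed = 1)
  expect_identical(as.data.frame(sp$train), as.data.frame(sp2$train))
  expect_error(split_dataset(ds, 1.2), "fraction")
})

test_that("testing sets follow the case manifest with noise replication", {
  cases <- test_case_manifest()
  expect_equal(sum(cases$kind == "ischemic"), 12)
  expect_equal(sum(cases$kind == "haemorrhagic"), 11)

  ph <- fixture_phantom()
  arr <- fixture_array()
  op <- fixture_operator()
  Sb <- background_sparams(arr)
  set.seed(15)
  ps <- perturb_system(arr, std = 2.00)
  op_t <- system_operator(ph, arr, eps_c = ps$eps_c)
  Sb_t <- background_sparams(arr, eps_c = ps$eps_c)
  sub <- cases[cases$kind == "ischemic", ]
  ts <- generate_testing_set(op_t, ph, Sb, Sb_t, cases = sub, n_noise = 5,
                             n_healthy = 10, seed = 15)
  expect_equal(nrow(ts), 10 + 12 * 5)
  expect_equal(sum(ts$label != "N"), 60)
  man <- dataset_manifest(ts)
  expect_identical(as.character(ts$label), man$class)
  expect_error(generate_testing_set(op_t, ph, NULL, Sb_t), "calibration")
})

test_that("nominal system with calibration and no noise reproduces training features", {
  ph <- fixture_phantom()
  op <- fixture_operator()
  Sb <- background_sparams(fixture_array())
  cases <- test_case_manifest()[1, ]
  ts <- generate_testing_set(op, ph, Sb, Sb, cases = cases, n_noise = 1,
                             n_healthy = 1, levels = -Inf, seed = 21)
  x <- as.matrix(as.data.frame(ts)[, -1])
  # healthy record: exactly the vectorized background
  expect_equal(unname(x[1, ]), unname(vectorize(Sb, "complex")),
               tolerance = 1e-12)
  # stroke record: background + forward-mapped contrast, as in training
  man <- dataset_manifest(ts)
  expect_equal(man$class[2], "I_FL")
})

test_that("datasets round-trip through CSV + JSON", {
  ph <- fixture_phantom()
  op <- fixture_operator()
  Sb <- background_sparams(fixture_array())
  comp <- setNames(c(2L, rep(1L, 8)), class_levels())
  ds <- generate_training_set(op, ph, Sb, composition = comp, seed = 23)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(as.data.frame(back)$label, as.data.frame(ds)$label)
  expect_equal(as.matrix(as.data.frame(back)[, -1]),
               as.matrix(as.data.frame(ds)[, -1]), tolerance = 1e-12)
  expect_equal(attr(back, "mode"), "complex")
})
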