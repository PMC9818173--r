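#' The nine scenario classes
#'
#' Healthy (`N`) plus ischemic (`I_`) and haemorrhagic (`H_`) strokes in
#' each head quadrant (FL, FR, BL, BR).
#' @return Character vector of the 9 class labels, in canonical order.
#' @export
class_levels <- function() {
  c("N", "I_FL", "I_FR", "I_BL", "I_BR", "H_FL", "H_FR", "H_BL", "H_BR")
}

#' Macro-class of each 9-class label
#' @param labels Character or factor of 9-class labels.
#' @return Factor with levels `healthy`, `ischemic`, `haemorrhagic`.
#' @export
macro_class <- function(labels) {
  labels <- as.character(labels)
  out <- ifelse(labels == "N", "healthy",
                ifelse(startsWith(labels, "I_"), "ischemic", "haemorrhagic"))
  factor(out, levels = c("healthy", "ischemic", "haemorrhagic"))
}

upper_tri_pairs <- function(Ma) {
  p <- rep(seq_len(Ma), times = Ma - seq_len(Ma) + 1)
  q <- unlist(lapply(seq_len(Ma), function(i) i:Ma))
  cbind(p, q)
}

#' Vectorize an S-parameter matrix into classifier features
#'
#' By reciprocity only the upper triangle (including the diagonal) of the
#' Ma x Ma matrix is independent: Ma(Ma+1)/2 complex elements, taken in
#' row-major order (p <= q). In `"complex"` mode each element contributes
#' its real and imaginary part as two adjacent features (600 features for
#' Ma = 24); in `"amplitude"` mode its modulus only (300 features).
#'
#' @param S An [sparams()] object (square).
#' @param mode `"complex"` or `"amplitude"`.
#' @return Named numeric vector (`f000`, `f001`, ...).
#' @export
vectorize <- function(S, mode = c("complex", "amplitude")) {
  mode <- match.arg(mode)
  S <- as.matrix(S)
  if (nrow(S) != ncol(S)) abort("S must be square")
  ut <- upper_tri_pairs(nrow(S))
  v <- S[ut]
  out <- if (mode == "complex") {
    as.vector(rbind(Re(v), Im(v)))
  } else {
    abs(v)
  }
  names(out) <- sprintf("f%03d", seq_along(out) - 1)
  out
}

#' Reassemble an S-parameter matrix from complex-mode features
#'
#' Inverse of [vectorize()] in complex mode, filling the lower triangle by
#' reciprocity.
#' @param v Feature vector from `vectorize(mode = "complex")`.
#' @param Ma Antenna count.
#' @param role Role tag of the result.
#' @return An [sparams()] object.
#' @export
devectorize <- function(v, Ma, role = "test") {
  stopifnot(length(v) == Ma * (Ma + 1))
  z <- complex(real = v[c(TRUE, FALSE)], imaginary = v[c(FALSE, TRUE)])
  S <- matrix(0 + 0i, Ma, Ma)
  ut <- upper_tri_pairs(Ma)
  S[ut] <- z
  S[ut[, c(2, 1)]] <- z
  sparams(S, role = role)
}

new_stroke_dataset <- function(features, labels, manifest, mode, Ma) {
  ds <- tibble::as_tibble(as.data.frame(features))
  ds$label <- factor(labels, levels = class_levels())
  ds <- dplyr::relocate(ds, "label")
  structure(ds, class = c("stroke_dataset", class(ds)),
            manifest = manifest, mode = mode, Ma = Ma)
}

#' @export
print.stroke_dataset <- function(x, ...) {
  cat("<stroke_dataset> ", nrow(x), " records x ", ncol(x) - 1,
      " features (mode=", attr(x, "mode"), ")\n", sep = "")
  print(table(x$label))
  invisible(x)
}

#' Manifest of a generated dataset
#' @param x A `stroke_dataset`.
#' @return Tibble with one row per record (class, geometry, noise, seed).
#' @export
dataset_manifest <- function(x) attr(x, "manifest")

#' Default per-class composition of the training set
#'
#' 1000 healthy records plus 1125 for each of the eight stroke classes,
#' 10,000 in total.
#' @return Named integer vector over [class_levels()].
#' @export
training_composition <- function() {
  setNames(c(1000L, rep(1125L, 8)), class_levels())
}

sample_stroke_case <- function(phantom, kind, quadrant, radii_m,
                               max_tries = 1000) {
  for (i in seq_len(max_tries)) {
    centre <- sample_centre(phantom, quadrant = quadrant)
    radius <- radii_m[sample.int(length(radii_m), 1)]
    spec <- stroke_spec(kind, centre, radius = radius,
                        tissues = phantom$tissues)
    tets <- collect_tets(phantom, spec)
    if (!is.null(tets)) return(list(spec = spec, tets = tets))
  }
  abort("could not place a stroke after max_tries attempts")
}

#' Generate a labelled training dataset
#'
#' Implements the training-set flow: for each stroke record, sample a
#' centre uniformly among brain tetrahedra of the class quadrant and a
#' radius from `radii_m`, collect the stroke tetrahedra (resampling
#' rejected placements), build the dielectric contrast, add
#' contrast-domain noise at a level drawn from `levels`, map through the
#' linearized operator to differential S-parameters, add the background
#' S-parameters, and vectorize. Healthy (`N`) records are background plus
#' noise only. With several backgrounds, records are distributed equally
#' (round-robin) across them. Every record is reproducible from the seed
#' recorded in the manifest.
#'
#' @param op Scattering operator on `phantom`.
#' @param phantom The `head_phantom` used for stroke placement.
#' @param backgrounds A single background [sparams()] or a list of them
#'   (one per head model).
#' @param composition Named per-class record counts
#'   (default [training_composition()]).
#' @param radii_m Candidate stroke radii in metres.
#' @param levels Candidate noise levels (dB).
#' @param mode Feature mode, `"complex"` or `"amplitude"`.
#' @param seed RNG seed for the whole generation.
#' @return A `stroke_dataset` tibble (label + features) with a manifest
#'   attribute ([dataset_manifest()]).
#' @export
generate_training_set <- function(op, phantom, backgrounds,
                                  composition = training_composition(),
                                  radii_m = c(1, 1.5, 2, 2.5, 3) / 100,
                                  levels = noise_levels(),
                                  mode = c("complex", "amplitude"),
                                  seed = 1L) {
  mode <- match.arg(mode)
  if (inherits(backgrounds, "sparams")) backgrounds <- list(backgrounds)
  stopifnot(length(backgrounds) >= 1, all(composition >= 0),
            all(names(composition) %in% class_levels()))
  set.seed(seed)
  nm <- noise_model(op)
  n_total <- sum(composition)
  classes <- rep(names(composition), times = composition)
  bg_id <- rep_len(seq_along(backgrounds), n_total)   # round-robin
  seeds <- sample.int(.Machine$integer.max, n_total)
  feats <- matrix(NA_real_, n_total,
                  if (mode == "complex") op$Ma * (op$Ma + 1) else op$Ma * (op$Ma + 1) / 2)
  man <- vector("list", n_total)
  for (r in seq_len(n_total)) {
    set.seed(seeds[r])
    cls <- classes[r]
    level <- pick_level(levels)
    dS <- sample_ds_noise(nm, level)
    if (cls == "N") {
      man[[r]] <- tibble::tibble(record = r, class = cls, kind = NA_character_,
                                 quadrant = NA_character_, radius = NA_real_,
                                 x = NA_real_, y = NA_real_, z = NA_real_,
                                 level_db = level, background = bg_id[r],
                                 seed = seeds[r])
    } else {
      kind <- if (startsWith(cls, "I_")) "ischemic" else "haemorrhagic"
      quadrant <- sub("^[IH]_", "", cls)
      case <- sample_stroke_case(phantom, kind, quadrant, radii_m)
      dchi <- build_contrast(phantom, case$tets, case$spec, sparse = TRUE)
      dS <- dS + as.vector(forward(op, dchi))
      man[[r]] <- tibble::tibble(record = r, class = cls, kind = kind,
                                 quadrant = quadrant, radius = case$spec$radius,
                                 x = case$spec$centre[1], y = case$spec$centre[2],
                                 z = case$spec$centre[3], level_db = level,
                                 background = bg_id[r], seed = seeds[r])
    }
    St <- total_sparams(backgrounds[[bg_id[r]]],
                        sparams(vec_to_smatrix(dS, op$Ma), role = "differential"))
    feats[r, ] <- vectorize(St, mode)
  }
  colnames(feats) <- sprintf("f%03d", seq_len(ncol(feats)) - 1)
  new_stroke_dataset(feats, classes, dplyr::bind_rows(man), mode, op$Ma)
}

#' Default stroke case list of the testing set
#'
#' The shipped per-class case list: 12 ischemic and 11 haemorrhagic cases
#' with the listed spherical radii and axis-aligned ellipsoid semi-axes
#' (cm, converted to metres).
#' @return Tibble with columns `class`, `kind`, `quadrant`, `shape`,
#'   `radius`, `sa_x`, `sa_y`, `sa_z` (metres, NA where not applicable).
#' @export
test_case_manifest <- function() {
  sph <- function(cls, r_cm) {
    tibble::tibble(class = cls,
                   kind = ifelse(startsWith(cls, "I"), "ischemic", "haemorrhagic"),
                   quadrant = sub("^[IH]_", "", cls), shape = "sphere",
                   radius = r_cm / 100, sa_x = NA_real_, sa_y = NA_real_,
                   sa_z = NA_real_)
  }
  ell <- function(cls, sa_cm) {
    tibble::tibble(class = cls,
                   kind = ifelse(startsWith(cls, "I"), "ischemic", "haemorrhagic"),
                   quadrant = sub("^[IH]_", "", cls), shape = "ellipsoid",
                   radius = NA_real_, sa_x = sa_cm[1] / 100,
                   sa_y = sa_cm[2] / 100, sa_z = sa_cm[3] / 100)
  }
  dplyr::bind_rows(
    sph("I_FL", c(2, 2)),
    sph("I_FR", c(1, 1.5, 2.5)),
    sph("I_BL", c(1, 1)), ell("I_BL", c(0.75, 1, 1)),
    sph("I_BR", c(1.5, 2.5, 2.5, 2.5)),
    sph("H_FL", c(1, 1, 1.5, 2.5)),
    sph("H_FR", c(1, 2)),
    sph("H_BL", c(1.5, 2.5)), ell("H_BL", c(0.75, 1, 1.5)),
    sph("H_BR", c(3, 3))
  )
}

#' Assemble the scattering operator of a (possibly perturbed) system
#'
#' Convenience wrapper: background fields from the analytic dipole provider
#' in the coupling medium (per-antenna permittivities for a
#' [perturb_system()] result), then [assemble_operator()].
#'
#' @param phantom A `head_phantom`.
#' @param array An [antenna_array()].
#' @param eps_c Coupling permittivity, scalar or per-antenna (e.g.
#'   `system$eps_c`).
#' @param frequency Frequency (Hz).
#' @param per_tet Optional per-tet property table for the background
#'   permittivity map.
#' @return A scattering operator.
#' @export
system_operator <- function(phantom, array, eps_c = 18.42 - 0.9i,
                            frequency = 1e9, per_tet = NULL) {
  fs <- field_set(array, phantom$mesh, eps_c = eps_c, frequency = frequency)
  assemble_operator(phantom$mesh, permittivity_map(phantom, per_tet),
                    array, fs)
}

#' Generate a testing dataset from a perturbed system with calibration
#'
#' Test records go through the full non-nominal pipeline: the perturbed
#' system's own operator and background produce the scenario-under-test
#' S-parameters, independent noise draws dS1 and dS2 are added, and the
#' measurements are calibrated back to the nominal system before
#' vectorization. Each stroke case in `cases` is replicated
#' `n_noise` times with fresh noise; `n_healthy` healthy records are
#' generated the same way without a stroke.
#'
#' @param op_tilde Operator of the system under test (nominal or from
#'   [system_operator()] with perturbed `eps_c`).
#' @param phantom The `head_phantom`.
#' @param Sb_nominal Nominal background [sparams()] (calibration reference).
#' @param Sb_tilde Background of the system under test.
#' @param cases Stroke case manifest (default [test_case_manifest()]).
#' @param n_noise Noise replication factor per stroke case.
#' @param n_healthy Number of healthy records.
#' @param levels Candidate noise levels (dB).
#' @param mode Feature mode.
#' @param apply_calibration Calibrate to the nominal system (default TRUE).
#' @param seed RNG seed.
#' @return A `stroke_dataset` with manifest.
#' @export
generate_testing_set <- function(op_tilde, phantom, Sb_nominal, Sb_tilde,
                                 cases = test_case_manifest(), n_noise = 5,
                                 n_healthy = 10, levels = noise_levels(),
                                 mode = c("complex", "amplitude"),
                                 apply_calibration = TRUE, seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(Sb_nominal)) abort("missing nominal calibration reference")
  set.seed(seed)
  nm <- noise_model(op_tilde)
  Ma <- op_tilde$Ma
  n_total <- n_healthy + nrow(cases) * n_noise
  feats <- matrix(NA_real_, n_total,
                  if (mode == "complex") Ma * (Ma + 1) else Ma * (Ma + 1) / 2)
  labels <- character(n_total)
  man <- vector("list", n_total)
  r <- 0L
  emit <- function(St_tilde, cls, level, info) {
    dS1 <- vec_to_smatrix(sample_ds_noise(nm, level), Ma)
    dS2 <- vec_to_smatrix(sample_ds_noise(nm, level), Ma)
    S_out <- if (apply_calibration) {
      calibrate(Sb_nominal, Sb_tilde, St_tilde, dS1, dS2)
    } else {
      sparams(unclass(St_tilde) + dS2, role = "test")
    }
    r <<- r + 1L
    feats[r, ] <<- vectorize(S_out, mode)
    labels[r] <<- cls
    man[[r]] <<- tibble::tibble(record = r, class = cls, level_db = level,
                                !!!info)
  }
  for (i in seq_len(n_healthy)) {
    emit(Sb_tilde, "N", pick_level(levels),
         list(shape = NA_character_, radius = NA_real_))
  }
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    case <- repeat_place_case(phantom, cs)
    dchi <- build_contrast(phantom, case$tets, case$spec, sparse = TRUE)
    St_tilde <- total_sparams(Sb_tilde, forward(op_tilde, dchi))
    for (j in seq_len(n_noise)) {
      emit(St_tilde, cs$class, pick_level(levels),
           list(shape = cs$shape, radius = cs$radius))
    }
  }
  colnames(feats) <- sprintf("f%03d", seq_len(ncol(feats)) - 1)
  new_stroke_dataset(feats, labels, dplyr::bind_rows(man), mode, Ma)
}

repeat_place_case <- function(phantom, cs, max_tries = 1000) {
  for (t in seq_len(max_tries)) {
    centre <- sample_centre(phantom, quadrant = cs$quadrant)
    spec <- if (cs$shape == "sphere") {
      stroke_spec(cs$kind, centre, radius = cs$radius, tissues = phantom$tissues)
    } else {
      stroke_spec(cs$kind, centre, semi_axes = c(cs$sa_x, cs$sa_y, cs$sa_z),
                  tissues = phantom$tissues)
    }
    tets <- collect_tets(phantom, spec)
    if (!is.null(tets)) return(list(spec = spec, tets = tets))
  }
  abort("could not place the test case")
}

#' Stratified train/validation split
#'
#' Splits record indices class by class: a fraction `fraction` of each
#' class goes to the training set (floor per class), the rest to
#' validation. Deterministic given the seed.
#'
#' @param dataset A `stroke_dataset` (or tibble with a `label` column).
#' @param fraction Training fraction in (0, 1); default 0.8.
#' @param seed RNG seed.
#' @return List with elements `train` and `validation`.
#' @export
split_dataset <- function(dataset, fraction = 0.8, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  set.seed(seed)
  lab <- dataset$label
  counts <- table(lab)
  if (any(counts > 0 & counts < 2)) abort("every present class needs >= 2 records")
  train_idx <- unlist(lapply(levels(lab)[counts > 0], function(cl) {
    idx <- which(lab == cl)
    sample(idx, round(fraction * length(idx)))
  }))
  train_idx <- sort(train_idx)
  list(train = dataset[train_idx, , drop = FALSE],
       validation = dataset[-train_idx, , drop = FALSE])
}

#' Write / read a dataset as CSV + JSON manifest
#'
#' `features.csv` holds `label` plus the feature columns; `manifest.json`
#' the per-record generation metadata and the feature mode.
#' @param dataset A `stroke_dataset`.
#' @param dir Output directory (created if needed).
#' @return `write_dataset()` returns `dir` invisibly; `read_dataset()` a
#'   `stroke_dataset`.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(as.data.frame(dataset), file.path(dir, "features.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(mode = attr(dataset, "mode"), Ma = attr(dataset, "Ma"),
         manifest = dataset_manifest(dataset)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  df <- read.csv(file.path(dir, "features.csv"), stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "manifest.json"),
                              simplifyVector = TRUE)
  new_stroke_dataset(as.matrix(df[, -1, drop = FALSE]), df$label,
                     tibble::as_tibble(meta$manifest), meta$mode, meta$Ma)
}
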