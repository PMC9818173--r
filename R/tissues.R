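#' Dielectric properties of head tissues at the working frequency
#'
#' Returns the default tissue table used throughout the package: relative
#' permittivity `eps_r` and conductivity `sigma` (S/m) of the six head
#' tissues at 1 GHz, taken from the standard Gabriel parametric database.
#' The table is a plain tibble, so individual values can be overridden with
#' ordinary dplyr verbs, or replaced wholesale via [read_tissue_table()].
#'
#' The two stroke tissues are also included (`ischemic`, `haemorrhagic`);
#' their values at 1 GHz are eps_r 36.00 / sigma 0.72 for ischemia and
#' eps_r 63.41 / sigma 1.58 for blood.
#'
#' @param frequency Working frequency in Hz (stored in the table; the
#'   dielectric values themselves are the 1 GHz ones and are not dispersive
#'   in this package — see Details).
#'
#' @details The package works at a single frequency; no dispersion model is
#'   applied. If you need a different frequency, supply your own table with
#'   the appropriate values.
#'
#' @return A tibble with columns `name`, `eps_r`, `sigma`, `frequency`.
#' @examples
#' tissue_table()
#' @export
tissue_table <- function(frequency = 1e9) {
  stopifnot(frequency > 0)
  tibble::tibble(
    name = c("skin", "skull", "csf", "grey_matter", "white_matter",
             "cerebellum", "ischemic", "haemorrhagic"),
    eps_r = c(40.936, 12.363, 68.438, 52.282, 38.577, 48.858, 36.00, 63.41),
    sigma = c(0.8998, 0.15566, 2.4552, 0.98541, 0.62174, 1.3083, 0.72, 1.58),
    frequency = frequency
  )
}

#' Labels of the tissues forming the brain region
#'
#' Stroke centres are drawn from, and stroke tetrahedra restricted to,
#' this subset of tissues.
#' @return Character vector of tissue labels.
#' @export
brain_tissues <- function() c("white_matter", "grey_matter", "cerebellum")

tissue_props <- function(tissues, name) {
  row <- tissues[tissues$name == name, ]
  if (nrow(row) != 1L) {
    abort(paste0("tissue '", name, "' not found (or duplicated) in the tissue table"))
  }
  row
}

validate_tissue_table <- function(tissues) {
  stopifnot(is.data.frame(tissues),
            all(c("name", "eps_r", "sigma", "frequency") %in% names(tissues)))
  if (any(tissues$eps_r < 1)) abort("tissue eps_r must be >= 1")
  if (any(tissues$sigma < 0)) abort("tissue sigma must be >= 0")
  if (any(tissues$frequency <= 0)) abort("tissue frequency must be > 0")
  if (anyDuplicated(tissues$name)) abort("duplicated tissue names")
  invisible(tissues)
}

#' Complex relative permittivity of a tissue
#'
#' Converts (eps_r, sigma) at frequency f to the complex relative
#' permittivity `eps_r - j sigma / (omega eps0)` with `omega = 2 pi f`,
#' using the exp(+j omega t) time convention (lossy media have a negative
#' imaginary part).
#'
#' @param props A one-row data frame with columns `eps_r`, `sigma`,
#'   `frequency` (e.g. a row of [tissue_table()]), or a full tissue table
#'   (vectorized over rows).
#' @return Complex vector, one value per row of `props`.
#' @examples
#' complex_permittivity(dplyr::filter(tissue_table(), name == "ischemic"))
#' @export
complex_permittivity <- function(props) {
  stopifnot(all(c("eps_r", "sigma", "frequency") %in% names(props)),
            all(props$frequency > 0))
  complex(real = props$eps_r,
          imaginary = -props$sigma / (2 * pi * props$frequency * EPS0))
}

#' Read / write a tissue table as CSV
#'
#' CSV with columns `name,eps_r,sigma` (and optionally `frequency`).
#' @param path File path.
#' @param frequency Frequency assigned when the CSV has no frequency column.
#' @return `read_tissue_table()` returns a validated tibble;
#'   `write_tissue_table()` returns `path` invisibly.
#' @export
read_tissue_table <- function(path, frequency = 1e9) {
  df <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  if (!"frequency" %in% names(df)) df$frequency <- frequency
  validate_tissue_table(df)
  df
}

#' @rdname read_tissue_table
#' @param tissues Tissue table to write.
#' @export
write_tissue_table <- function(tissues, path) {
  validate_tissue_table(tissues)
  write.csv(tissues, path, row.names = FALSE)
  invisible(path)
}
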