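#' Label vocabularies
#'
#' The five ordinal maturity levels of a fresh leaf (harvest-readiness
#' grades, from least to most mature) and the three stalk positions.
#' Labels are stored and exchanged as lowercase tokens drawn exactly from
#' these vocabularies.
#'
#' @return character vector of valid tokens, in canonical order.
#' @export
maturity_levels <- function() c("unripe", "mature", "ripe", "mellow", "overmature")

#' @rdname maturity_levels
#' @export
leaf_positions <- function() c("upper", "middle", "lower")

#' A single leaf's replicate spot spectra
#'
#' Each sampled leaf is scanned at several spots (six in the reference
#' acquisition protocol); the leaf's working spectrum is the per-wavelength
#' arithmetic mean of its spot spectra.
#'
#' @param sample_id opaque identifier string.
#' @param position one of [leaf_positions()].
#' @param maturity one of [maturity_levels()].
#' @param spot_spectra numeric matrix, one row per spot scan, one column
#'   per wavelength.  A single spectrum may be given as a vector.
#' @return An object of class `spectrum_record` with fields `sample_id`,
#'   `position`, `maturity`, `spot_spectra` and the derived `mean_spectrum`.
#' @export
spectrum_record <- function(sample_id, position, maturity, spot_spectra) {
  if (is.vector(spot_spectra)) spot_spectra <- matrix(spot_spectra, nrow = 1)
  check(is.matrix(spot_spectra) && nrow(spot_spectra) >= 1,
        "spot_spectra must be a matrix with at least one row")
  check(all(is.finite(spot_spectra)),
        "record '%s': spectra contain missing or non-finite values", sample_id)
  check(position %in% leaf_positions(),
        "record '%s': unknown position token '%s'", sample_id, position)
  check(maturity %in% maturity_levels(),
        "record '%s': unknown maturity token '%s'", sample_id, maturity)
  structure(list(sample_id = as.character(sample_id),
                 position = position, maturity = maturity,
                 spot_spectra = unname(spot_spectra),
                 mean_spectrum = colMeans(spot_spectra)),
            class = "spectrum_record")
}

#' Average replicate spot spectra
#'
#' @param record a [spectrum_record()].
#' @return numeric vector: the per-wavelength arithmetic mean across spots.
#' @export
average_replicates <- function(record) {
  stopifnot(inherits(record, "spectrum_record"))
  colMeans(record$spot_spectra)
}

#' A labelled collection of spectra on one wavelength grid
#'
#' @param grid a [make_grid()] wavelength grid.
#' @param records list of [spectrum_record()] objects, all conforming to
#'   `grid`.
#' @return An object of class `spectra_set`.
#' @examples
#' g <- make_grid(0, 10, 1)
#' r <- spectrum_record("leaf1", "upper", "ripe",
#'                      matrix(rnorm(30), 3, 10))
#' s <- spectra_set(g, list(r))
#' dim(spectra_matrix(s))
#' @export
spectra_set <- function(grid, records) {
  stopifnot(inherits(grid, "wavelength_grid"))
  check(length(records) > 0, "a spectra_set must contain at least one record")
  for (i in seq_along(records)) {
    r <- records[[i]]
    check(inherits(r, "spectrum_record"), "records[[%d]] is not a spectrum_record", i)
    check(ncol(r$spot_spectra) == grid$n_points,
          "record '%s' has %d points but the grid has %d",
          r$sample_id, ncol(r$spot_spectra), grid$n_points)
  }
  structure(list(grid = grid, records = records), class = "spectra_set")
}

#' Extract the matrix of leaf-mean spectra
#'
#' @param set a [spectra_set()].
#' @return numeric matrix, one row per record (leaf), columns named by
#'   wavelength.
#' @export
spectra_matrix <- function(set) {
  stopifnot(inherits(set, "spectra_set"))
  m <- do.call(rbind, lapply(set$records, `[[`, "mean_spectrum"))
  colnames(m) <- format(wavelengths(set$grid), trim = TRUE)
  rownames(m) <- vapply(set$records, `[[`, "", "sample_id")
  m
}

#' Per-record maturity labels as a factor with the canonical five levels
#' @param set a [spectra_set()].
#' @export
maturity_labels <- function(set) {
  stopifnot(inherits(set, "spectra_set"))
  factor(vapply(set$records, `[[`, "", "maturity"), levels = maturity_levels())
}

#' Per-record position labels
#' @param set a [spectra_set()].
#' @export
position_labels <- function(set) {
  stopifnot(inherits(set, "spectra_set"))
  factor(vapply(set$records, `[[`, "", "position"), levels = leaf_positions())
}

#' @export
print.spectra_set <- function(x, ...) {
  mat <- table(maturity_labels(x))
  cat(sprintf("<spectra_set> %d leaves, grid %s (%d points)\n",
              length(x$records), format(x$grid), x$grid$n_points))
  cat("  maturity counts:", paste(names(mat), mat, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @export
length.spectra_set <- function(x) length(x$records)

#' Subset a spectra_set by record index
#' @param x a [spectra_set()].
#' @param i integer or logical index over records.
#' @param ... unused.
#' @export
`[.spectra_set` <- function(x, i, ...) spectra_set(x$grid, x$records[i])

# ---- CSV interchange --------------------------------------------------------
# Wide dialect: comma-separated, UTF-8, header
#   sample_id,position,maturity,<wl1>,<wl2>,...
# one row per spot scan; wavelengths printed with <= 4 decimals.  Spot rows
# sharing a sample_id form one record.

#' Read and write spectral datasets as wide CSV
#'
#' The canonical interchange format is a wide CSV with one row per spot
#' scan: three metadata columns `sample_id`, `position`, `maturity`
#' followed by one column per wavelength, the header row holding the
#' wavelengths themselves (strictly increasing, equally spaced, printed
#' with at most 4 decimals).  Rows sharing a `sample_id` are collected
#' into one record.  Missing values are not permitted.
#'
#' @param path file path.
#' @return `read_spectra_csv()` returns a [spectra_set()].
#' @examples
#' \donttest{
#' s <- easy_benchmark(seed = 1)
#' f <- tempfile(fileext = ".csv")
#' write_spectra_csv(s, f)
#' s2 <- read_spectra_csv(f)
#' }
#' @export
read_spectra_csv <- function(path) {
  check(file.exists(path), "file not found: %s", path)
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(unique(nf)) > 1) {
    bad <- which(nf != nf[1])[1]
    stop(sprintf("%s: ragged row %d (%d fields, expected %d)",
                 path, bad, nf[bad], nf[1]), call. = FALSE)
  }
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  check(ncol(df) > 3, "%s: no wavelength columns found", path)
  meta_cols <- c("sample_id", "position", "maturity")
  check(identical(names(df)[1:3], meta_cols),
        "%s: first three columns must be %s", path,
        paste(meta_cols, collapse = ","))
  wl <- suppressWarnings(as.numeric(names(df)[-(1:3)]))
  check(!anyNA(wl), "%s: non-numeric wavelength in header", path)
  grid <- grid_from_wavelengths(wl, where = path, tol = 1e-3)

  for (col in c("position", "maturity")) {
    vocab <- if (col == "position") leaf_positions() else maturity_levels()
    bad <- which(!(df[[col]] %in% vocab))
    if (length(bad)) {
      stop(sprintf("%s: unknown %s token '%s' at data row %d",
                   path, col, df[[col]][bad[1]], bad[1]), call. = FALSE)
    }
  }
  vals <- suppressWarnings(
    matrix(as.numeric(as.matrix(df[-(1:3)])), nrow = nrow(df)))
  if (anyNA(vals)) {
    bad <- which(rowSums(is.na(vals)) > 0)[1]
    stop(sprintf("%s: non-numeric or missing spectral value at data row %d",
                 path, bad), call. = FALSE)
  }
  ids <- df$sample_id
  records <- lapply(unique(ids), function(id) {
    rows <- which(ids == id)
    check(length(unique(df$position[rows])) == 1 &&
            length(unique(df$maturity[rows])) == 1,
          "%s: sample '%s' has inconsistent labels across spot rows", path, id)
    spectrum_record(id, df$position[rows[1]], df$maturity[rows[1]],
                    vals[rows, , drop = FALSE])
  })
  spectra_set(grid, records)
}

#' @param set a [spectra_set()] to serialise.
#' @rdname read_spectra_csv
#' @export
write_spectra_csv <- function(set, path) {
  stopifnot(inherits(set, "spectra_set"))
  wl <- round(wavelengths(set$grid), 4)
  header <- c("sample_id", "position", "maturity",
              sprintf("%.10g", wl))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(header, collapse = ","), con)
  for (r in set$records) {
    for (s in seq_len(nrow(r$spot_spectra))) {
      vals <- sprintf("%.15g", r$spot_spectra[s, ])
      writeLines(paste(c(r$sample_id, r$position, r$maturity, vals),
                       collapse = ","), con)
    }
  }
  invisible(path)
}
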