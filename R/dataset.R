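#' Assemble a spectral dataset
#'
#' The container every stage of the workflow exchanges: a wavelength grid,
#' a reflectance matrix (samples x wavelengths), and a table of reference
#' target values keyed by indicator name (e.g. `tvbn` in mg/100 g, or the
#' CIELAB coordinates `L`, `a`, `b`). Targets may contain per-indicator
#' `NA`s; modelling operations drop rows missing their own indicator.
#'
#' @param grid A [make_grid()] object.
#' @param reflectance Numeric matrix, `n_samples x length(grid$values)`,
#'   no missing values.
#' @param targets `data.frame` with one row per sample; columns are
#'   indicator names. TVB-N values, when present, must be positive.
#' @param sample_ids Character vector of unique sample labels.
#' @return An object of class `spectral_dataset`.
#' @export
spectral_dataset <- function(grid, reflectance, targets, sample_ids) {
  stopifnot(inherits(grid, "wavelength_grid"))
  reflectance <- as.matrix(reflectance)
  if (ncol(reflectance) != length(grid$values)) {
    stop(sprintf("reflectance has %d columns but grid has %d wavelengths",
                 ncol(reflectance), length(grid$values)))
  }
  if (anyNA(reflectance)) stop("reflectance contains missing values")
  targets <- as.data.frame(targets)
  if (nrow(targets) != nrow(reflectance)) {
    stop("targets row count must equal the number of samples")
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(reflectance)) {
    stop("sample_ids length must equal the number of samples")
  }
  if (anyDuplicated(sample_ids)) {
    stop(sprintf("duplicate sample id \"%s\"",
                 sample_ids[duplicated(sample_ids)][1]))
  }
  if ("tvbn" %in% names(targets)) {
    tv <- targets$tvbn
    if (any(!is.na(tv) & tv <= 0)) stop("TVB-N values must be positive")
  }
  rownames(reflectance) <- sample_ids
  structure(
    list(grid = grid, reflectance = reflectance, targets = targets,
         sample_ids = sample_ids),
    class = "spectral_dataset"
  )
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf(
    "<spectral_dataset> %d samples x %d wavelengths (%g-%g nm), indicators: %s\n",
    nrow(x$reflectance), ncol(x$reflectance),
    x$grid$start_nm, x$grid$stop_nm,
    paste(names(x$targets), collapse = ", ")
  ))
  invisible(x)
}

#' Extract target values for one indicator
#'
#' Drops samples whose value for this indicator is missing and reports how
#' many were dropped.
#'
#' @param ds A [spectral_dataset()].
#' @param indicator Column name in `ds$targets`.
#' @return List with `y` (numeric), `rows` (integer row indices kept) and
#'   `n_dropped`.
#' @export
indicator_values <- function(ds, indicator) {
  stopifnot(inherits(ds, "spectral_dataset"))
  if (!indicator %in% names(ds$targets)) {
    stop(sprintf("indicator \"%s\" not present in targets (have: %s)",
                 indicator, paste(names(ds$targets), collapse = ", ")))
  }
  y <- ds$targets[[indicator]]
  keep <- which(!is.na(y))
  n_dropped <- length(y) - length(keep)
  if (n_dropped > 0) {
    message(sprintf("dropping %d sample(s) missing indicator \"%s\"",
                    n_dropped, indicator))
  }
  list(y = y[keep], rows = keep, n_dropped = n_dropped)
}

#' Read wide-format spectra plus a reference table
#'
#' The spectra CSV is wide: first column `sample_id`, remaining column names
#' are numeric wavelengths in nm (`sample_id,400,404,...,1800`). The
#' references CSV shares the `sample_id` column and carries one column per
#' indicator (`sample_id,tvbn,L,a,b`, any subset). The two files are
#' inner-joined on sample id; spectra row order is preserved and any id
#' present in only one file is reported.
#'
#' @param spectra_path Path to the spectra CSV.
#' @param references_path Path to the reference-values CSV.
#' @param grid Optional [make_grid()] object; when supplied the header must
#'   match it, otherwise the grid is inferred from the header.
#' @return A [spectral_dataset()].
#' @export
read_spectra_csv <- function(spectra_path, references_path, grid = NULL) {
  if (!file.exists(spectra_path)) {
    stop(sprintf("spectra file not found: %s", spectra_path))
  }
  if (!file.exists(references_path)) {
    stop(sprintf("references file not found: %s", references_path))
  }
  sp <- utils::read.csv(spectra_path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (ncol(sp) < 3) stop("spectra CSV needs sample_id plus >=2 wavelengths")
  header <- names(sp)[-1]
  wl <- suppressWarnings(as.numeric(header))
  if (anyNA(wl)) {
    stop(sprintf("non-numeric wavelength header cell \"%s\"",
                 header[which(is.na(wl))[1]]))
  }
  inferred <- grid_from_values(wl)
  if (!is.null(grid)) {
    if (!isTRUE(all.equal(grid$values, inferred$values))) {
      stop("wavelength header does not match the supplied grid")
    }
    inferred <- grid
  }
  ids <- as.character(sp[[1]])
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate sample id \"%s\" in spectra CSV",
                 ids[duplicated(ids)][1]))
  }
  refs <- utils::read.csv(references_path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(refs)) {
    stop("references CSV must contain a sample_id column")
  }
  rid <- as.character(refs$sample_id)
  if (anyDuplicated(rid)) {
    stop(sprintf("duplicate sample id \"%s\" in references CSV",
                 rid[duplicated(rid)][1]))
  }
  only_sp <- setdiff(ids, rid)
  only_ref <- setdiff(rid, ids)
  if (length(only_sp) || length(only_ref)) {
    stop(sprintf(
      "sample id mismatch between files: %d only in spectra (%s), %d only in references (%s)",
      length(only_sp), paste(utils::head(only_sp, 3), collapse = ","),
      length(only_ref), paste(utils::head(only_ref, 3), collapse = ",")
    ))
  }
  refl <- as.matrix(sp[, -1, drop = FALSE])
  storage.mode(refl) <- "double"
  targets <- refs[match(ids, rid), setdiff(names(refs), "sample_id"),
                  drop = FALSE]
  rownames(targets) <- NULL
  spectral_dataset(inferred, refl, targets, ids)
}

#' Write a selection mask to CSV
#'
#' Two columns: `wavelength_nm` and `selected` (0/1). Round-trips losslessly
#' through [read_mask()].
#'
#' @param mask Logical vector over the grid positions.
#' @param grid The matching [make_grid()] object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_mask <- function(mask, grid, path) {
  mask <- as.logical(mask)
  if (length(mask) != length(grid$values)) {
    stop(sprintf("mask length %d does not match grid length %d",
                 length(mask), length(grid$values)))
  }
  utils::write.csv(
    data.frame(wavelength_nm = grid$values, selected = as.integer(mask)),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read a selection mask written by [write_mask()]
#'
#' @param path CSV path.
#' @param grid Optional grid to validate the wavelength column against.
#' @return Logical vector.
#' @export
read_mask <- function(path, grid = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("wavelength_nm", "selected") %in% names(df))) {
    stop("mask CSV must have columns wavelength_nm and selected")
  }
  if (!is.null(grid) && !isTRUE(all.equal(df$wavelength_nm, grid$values))) {
    stop("mask wavelengths do not match the supplied grid")
  }
  df$selected == 1
}

#' Write a spectral dataset to a pair of CSVs
#'
#' Inverse of [read_spectra_csv()].
#'
#' @param ds A [spectral_dataset()].
#' @param spectra_path,references_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_spectra_csv <- function(ds, spectra_path, references_path) {
  stopifnot(inherits(ds, "spectral_dataset"))
  sp <- data.frame(sample_id = ds$sample_ids, check.names = FALSE)
  refl <- as.data.frame(ds$reflectance)
  names(refl) <- format(ds$grid$values, trim = TRUE, scientific = FALSE)
  sp <- cbind(sp, refl)
  utils::write.csv(sp, spectra_path, row.names = FALSE, quote = FALSE)
  refs <- cbind(data.frame(sample_id = ds$sample_ids), ds$targets)
  utils::write.csv(refs, references_path, row.names = FALSE, quote = FALSE)
  invisible(c(spectra_path, references_path))
}
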