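#' Labelled spectral dataset on a shared wavenumber grid
#'
#' A `spectra` object holds a set of absorbance spectra measured on one common
#' wavenumber grid, together with a binary diagnosis label per sample. The
#' grid is always stored from high to low wavenumber (the conventional
#' plotting direction for mid-IR spectra); constructors reorder their input
#' if needed.
#'
#' @param absorbance Numeric matrix, one row per sample, one column per
#'   wavenumber (unitless absorbance). A single spectrum may be given as a
#'   vector.
#' @param wavenumber Numeric vector of wavenumbers in cm^-1, strictly
#'   monotone; length must equal `ncol(absorbance)`.
#' @param labels Character or factor vector of per-sample class labels.
#'   Matched case-insensitively against `"benign"` and `"malignant"`.
#' @param ids Character vector of per-sample identifiers. Defaults to
#'   `"s1", "s2", ...`.
#'
#' @return An object of class `spectra`: a list with elements `wavenumber`
#'   (high to low), `absorbance` (N x L matrix with `ids` as rownames),
#'   `labels` (factor with levels benign, malignant) and `ids`.
#' @examples
#' s <- spectra(matrix(rnorm(20), 4), seq(1008, 1000, by = -2),
#'              c("benign", "benign", "malignant", "malignant"))
#' n_samples(s)
#' @export
spectra <- function(absorbance, wavenumber, labels, ids = NULL) {
  if (is.vector(absorbance) && is.numeric(absorbance)) {
    absorbance <- matrix(absorbance, nrow = 1)
  }
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  wavenumber <- as.numeric(wavenumber)
  if (length(wavenumber) != ncol(absorbance)) {
    stop("length(wavenumber) must equal ncol(absorbance)", call. = FALSE)
  }
  if (length(wavenumber) < 1) stop("grid must have at least 1 wavenumber", call. = FALSE)
  if (length(wavenumber) > 1) {
    dw <- diff(wavenumber)
    if (any(dw == 0) || (any(dw > 0) && any(dw < 0))) {
      stop("wavenumber grid must be strictly monotone", call. = FALSE)
    }
    if (dw[1] > 0) { # stored low->high: normalize to high->low
      wavenumber <- rev(wavenumber)
      absorbance <- absorbance[, rev(seq_len(ncol(absorbance))), drop = FALSE]
    }
  }
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(absorbance)))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("sample ids must be unique", call. = FALSE)
  labels <- normalize_labels(labels)
  if (length(labels) != nrow(absorbance) || length(ids) != nrow(absorbance)) {
    stop("labels and ids must have one entry per sample", call. = FALSE)
  }
  if (!all(is.finite(absorbance))) stop("absorbance values must be finite", call. = FALSE)
  rownames(absorbance) <- ids
  colnames(absorbance) <- NULL
  structure(
    list(wavenumber = wavenumber, absorbance = absorbance,
         labels = labels, ids = ids),
    class = "spectra"
  )
}

label_levels <- c("benign", "malignant")

normalize_labels <- function(labels) {
  if (length(labels) == 0) stop("labels must be non-empty", call. = FALSE)
  lab <- tolower(trimws(as.character(labels)))
  bad <- setdiff(unique(lab), label_levels)
  if (length(bad) > 0) {
    stop("unknown label token(s): ", paste(bad, collapse = ", "),
         " (expected benign/malignant)", call. = FALSE)
  }
  factor(lab, levels = label_levels)
}

#' @export
print.spectra <- function(x, ...) {
  cat(sprintf(
    "<spectra> %d samples x %d wavenumbers (%.6g to %.6g cm^-1)\n",
    nrow(x$absorbance), ncol(x$absorbance),
    x$wavenumber[1], x$wavenumber[length(x$wavenumber)]
  ))
  cat(sprintf("labels: %s\n",
              paste(sprintf("%s=%d", levels(x$labels), tabulate(x$labels, 2)),
                    collapse = ", ")))
  invisible(x)
}

#' Number of samples / channels in a spectra object
#' @param x A `spectra` object.
#' @return Integer count.
#' @export
n_samples <- function(x) nrow(x$absorbance)

#' @rdname n_samples
#' @export
n_channels <- function(x) ncol(x$absorbance)

#' Long-format tibble view of a spectral dataset
#'
#' @param x A `spectra` object.
#' @param ... Unused.
#' @return A tibble with columns `sample_id`, `label`, `wavenumber_cm1`,
#'   `absorbance`.
#' @importFrom tibble as_tibble
#' @export
as_tibble.spectra <- function(x, ...) {
  tibble::tibble(
    sample_id = rep(x$ids, each = length(x$wavenumber)),
    label = rep(as.character(x$labels), each = length(x$wavenumber)),
    wavenumber_cm1 = rep(x$wavenumber, times = length(x$ids)),
    absorbance = as.vector(t(x$absorbance))
  )
}

#' Subset a spectral dataset by class or by sample index
#'
#' `class_subset()` keeps the samples carrying one diagnosis label,
#' preserving sample order; `subset_samples()` keeps samples by index.
#'
#' @param x A `spectra` object.
#' @param label `"benign"` or `"malignant"` (case-insensitive).
#' @return A `spectra`-like object with the retained samples (possibly zero
#'   rows).
#' @export
class_subset <- function(x, label) {
  stopifnot(inherits(x, "spectra"))
  label <- tolower(trimws(as.character(label)))
  if (!label %in% label_levels) {
    stop("label must be one of: ", paste(label_levels, collapse = ", "), call. = FALSE)
  }
  subset_samples(x, which(as.character(x$labels) == label))
}

#' @rdname class_subset
#' @param idx Integer vector of sample indices (duplicates allowed, e.g. for
#'   bootstrap resamples; ids are made unique).
#' @export
subset_samples <- function(x, idx) {
  out <- x
  out$absorbance <- x$absorbance[idx, , drop = FALSE]
  out$labels <- x$labels[idx]
  out$ids <- make.unique(x$ids[idx])
  rownames(out$absorbance) <- out$ids
  out
}

#' Per-wavenumber median spectrum
#'
#' Each channel of the result is the median absorbance across samples; for an
#' even number of samples the midpoint of the two middle order statistics is
#' used.
#'
#' @param x A `spectra` object with at least one sample.
#' @return A tibble with columns `wavenumber_cm1` and `absorbance`.
#' @export
median_spectrum <- function(x) {
  stopifnot(inherits(x, "spectra"))
  if (nrow(x$absorbance) < 1) stop("median of an empty dataset is undefined", call. = FALSE)
  tibble::tibble(
    wavenumber_cm1 = x$wavenumber,
    absorbance = apply(x$absorbance, 2, stats::median)
  )
}

# ---- on-disk formats --------------------------------------------------------

#' Read a labelled spectral dataset
#'
#' The canonical CSV layout is wide: first column `wavenumber_cm1`, one
#' column per sample named by its id, plus a companion labels CSV with
#' columns `sample_id,label`. JCAMP-DX input (one file per sample, standard
#' uncompressed `##XYDATA=(X++(Y..Y))` blocks) is read-only.
#'
#' @param path CSV file path, or for `format = "jcamp"` a directory or a
#'   character vector of JCAMP-DX files.
#' @param labels_path Path to the labels CSV. Defaults to `labels.csv` next
#'   to `path`.
#' @param format `"csv"` or `"jcamp"`.
#' @return A [spectra] object.
#' @export
read_spectra <- function(path, labels_path = NULL, format = c("csv", "jcamp")) {
  format <- match.arg(format)
  if (format == "csv") read_spectra_csv(path, labels_path) else read_spectra_jcamp(path, labels_path)
}

default_labels_path <- function(path) {
  dir <- if (length(path) == 1 && dir.exists(path)) path else dirname(path[1])
  file.path(dir, "labels.csv")
}

read_labels_csv <- function(labels_path) {
  if (!file.exists(labels_path)) stop("labels file not found: ", labels_path, call. = FALSE)
  lab <- utils::read.csv(labels_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "label") %in% names(lab))) {
    stop("labels file must have columns sample_id,label", call. = FALSE)
  }
  lab
}

read_spectra_csv <- function(path, labels_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (ncol(raw) < 2) stop("spectra CSV needs a wavenumber column and at least one sample column", call. = FALSE)
  if (names(raw)[1] != "wavenumber_cm1") {
    stop("first CSV column must be named wavenumber_cm1", call. = FALSE)
  }
  num <- suppressWarnings(vapply(raw, as.numeric, numeric(nrow(raw))))
  if (nrow(raw) == 1) num <- matrix(num, nrow = 1, dimnames = list(NULL, names(raw)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric value at row %d, column '%s'",
                 bad[1, 1], names(raw)[bad[1, 2]]), call. = FALSE)
  }
  ids <- names(raw)[-1]
  if (is.null(labels_path)) labels_path <- default_labels_path(path)
  lab <- read_labels_csv(labels_path)
  missing <- setdiff(ids, lab$sample_id)
  if (length(missing) > 0) {
    stop("no label for sample(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  labels <- lab$label[match(ids, lab$sample_id)]
  spectra(t(num[, -1, drop = FALSE]), num[, 1], labels, ids)
}

#' Write a spectral dataset as CSV
#'
#' Writes the wide-format spectra CSV and the companion labels CSV. Values
#' are written with 17 significant digits so a read/write round trip
#' reproduces the dataset exactly (well within 1e-12).
#'
#' @param x A [spectra] object with at least one sample.
#' @param path Output CSV path.
#' @param labels_path Output labels CSV path; defaults to `labels.csv` next
#'   to `path`.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(x, path, labels_path = NULL) {
  stopifnot(inherits(x, "spectra"))
  if (nrow(x$absorbance) < 1) stop("refusing to write an empty dataset", call. = FALSE)
  if (anyNA(x$labels)) stop("all samples must carry a label", call. = FALSE)
  if (is.null(labels_path)) labels_path <- default_labels_path(path)
  fmt <- function(v) sprintf("%.17g", v)
  tab <- cbind(fmt(x$wavenumber), apply(x$absorbance, 1, fmt))
  if (length(x$wavenumber) == 1) tab <- matrix(tab, nrow = 1)
  colnames(tab) <- c("wavenumber_cm1", x$ids)
  ok <- try(utils::write.table(tab, path, sep = ",", quote = FALSE,
                               row.names = FALSE, col.names = TRUE),
            silent = TRUE)
  if (inherits(ok, "try-error")) stop("cannot write to ", path, call. = FALSE)
  utils::write.table(
    data.frame(sample_id = x$ids, label = as.character(x$labels)),
    labels_path, sep = ",", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

# Minimal JCAMP-DX reader: uncompressed (AFFN) X++(Y..Y) tables, one spectrum
# per file. XFACTOR/YFACTOR scaling honoured; compressed (DIFDUP) forms are out
# of scope.
read_spectra_jcamp <- function(path, labels_path = NULL) {
  files <- if (length(path) == 1 && dir.exists(path)) {
    list.files(path, pattern = "\\.(jdx|dx|jcm)$", ignore.case = TRUE, full.names = TRUE)
  } else path
  if (length(files) == 0) stop("no JCAMP-DX files found", call. = FALSE)
  if (!all(file.exists(files))) {
    stop("file not found: ", files[!file.exists(files)][1], call. = FALSE)
  }
  one <- lapply(files, read_jcamp_file)
  grid <- one[[1]]$x
  for (s in one[-1]) {
    if (length(s$x) != length(grid) || max(abs(s$x - grid)) > 1e-6) {
      stop("JCAMP-DX files are not on a common wavenumber grid", call. = FALSE)
    }
  }
  ids <- vapply(one, `[[`, character(1), "id")
  if (is.null(labels_path)) labels_path <- default_labels_path(path)
  lab <- read_labels_csv(labels_path)
  missing <- setdiff(ids, lab$sample_id)
  if (length(missing) > 0) {
    stop("no label for sample(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  labels <- lab$label[match(ids, lab$sample_id)]
  spectra(do.call(rbind, lapply(one, `[[`, "y")), grid, labels, ids)
}

read_jcamp_file <- function(file) {
  lines <- readLines(file, warn = FALSE)
  field <- function(key, default = NA_character_) {
    hit <- grep(paste0("^##", key, "="), lines, ignore.case = TRUE, value = TRUE)
    if (length(hit) == 0) return(default)
    trimws(sub("^##[^=]*=", "", hit[1]))
  }
  xfactor <- as.numeric(field("XFACTOR", "1"))
  yfactor <- as.numeric(field("YFACTOR", "1"))
  id <- field("TITLE", tools::file_path_sans_ext(basename(file)))
  start <- grep("^##XYDATA=", lines, ignore.case = TRUE)
  if (length(start) == 0) stop("no ##XYDATA block in ", file, call. = FALSE)
  body <- lines[(start[1] + 1):length(lines)]
  end <- grep("^##", body)
  if (length(end) > 0) body <- body[seq_len(end[1] - 1)]
  xs <- c(); ys <- c()
  for (ln in body) {
    vals <- as.numeric(strsplit(trimws(ln), "[ \t,]+")[[1]])
    if (length(vals) < 2 || anyNA(vals)) {
      stop("cannot parse XYDATA line in ", file, ": ", ln, call. = FALSE)
    }
    x0 <- vals[1] * xfactor
    yv <- vals[-1] * yfactor
    npt <- as.numeric(field("NPOINTS", NA_character_))
    dx <- if (!is.na(as.numeric(field("DELTAX", NA_character_)))) {
      as.numeric(field("DELTAX"))
    } else if (!is.na(npt) && npt > 1) {
      (as.numeric(field("LASTX")) - as.numeric(field("FIRSTX"))) / (npt - 1)
    } else NA_real_
    if (is.na(dx)) stop("cannot infer x spacing in ", file, call. = FALSE)
    xs <- c(xs, x0 + dx * (seq_along(yv) - 1))
    ys <- c(ys, yv)
  }
  list(id = id, x = xs, y = ys)
}
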