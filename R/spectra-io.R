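# Spectral tables and hierarchical sample metadata -------------------------

#' Site and region codes
#'
#' The sampling design covers seven sites in three regions of the northern
#' UK: four in West Scotland (WS), two in North West England (NWE) and one
#' in North East England (NEE). The mapping is fixed.
#'
#' @format `SITE_CODES` is a character vector of the seven site codes;
#'   `REGION_CODES` the three region codes; `SITE_REGION` a named character
#'   vector mapping site -> region.
#' @export
SITE_CODES <- c("SOM", "SAP", "SLM", "SRC", "EDB", "ESA", "ESB")

#' @rdname SITE_CODES
#' @export
REGION_CODES <- c("NEE", "NWE", "WS")

#' @rdname SITE_CODES
#' @export
SITE_REGION <- c(
  SOM = "WS", SAP = "WS", SLM = "WS", SRC = "WS",
  EDB = "NEE",
  ESA = "NWE", ESB = "NWE"
)

LEAF_POSITIONS <- c("New", "Height", "Mature")
LEAF_SIDES <- c("upper", "lower", "unknown")

#' Map a site code to its region
#'
#' @param site character vector of site codes (e.g. `"SRC"`).
#' @return character vector of region codes (`"WS"`, `"NWE"` or `"NEE"`).
#' @examples
#' region_of("SRC")  # "WS"
#' region_of(c("EDB", "ESA"))
#' @export
region_of <- function(site) {
  site <- as.character(site)
  bad <- setdiff(unique(site), names(SITE_REGION))
  if (length(bad)) {
    stop("unknown site code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  unname(SITE_REGION[site])
}

# Wavenumber grid ------------------------------------------------------------

#' Construct a wavenumber grid
#'
#' A grid is a strictly monotone, uniformly spaced vector of wavenumbers
#' (cm^-1). Ascending input is accepted and canonicalised to descending,
#' the spectroscopic plotting convention used throughout the package.
#'
#' @param values numeric vector of wavenumbers.
#' @param rel_tol relative tolerance on spacing uniformity.
#' @return an object of class `wavenumber_grid`: the (descending) values
#'   with attribute `spacing` (positive, cm^-1).
#' @export
wavenumber_grid <- function(values, rel_tol = 1e-6) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("grid needs at least 2 points", call. = FALSE)
  d <- diff(values)
  if (any(d == 0) || (any(d > 0) && any(d < 0))) {
    stop("wavenumber grid must be strictly monotone", call. = FALSE)
  }
  step <- mean(abs(d))
  if (max(abs(abs(d) - step)) > rel_tol * step) {
    stop("wavenumber grid spacing is not uniform", call. = FALSE)
  }
  if (d[1] > 0) values <- rev(values)  # canonical order: descending
  structure(values, spacing = step, class = "wavenumber_grid")
}

is_descending <- function(x) all(diff(as.numeric(x)) < 0)

# Sample metadata ------------------------------------------------------------

#' Parse spectrum labels into sample metadata
#'
#' The default label scheme is `SITE_c<cane>_<position>_<side>_r<rep>`,
#' e.g. `"SRC_c1_New_upper_r03"`. The side field may be absent
#' (`SRC_c1_New_r03`), in which case the side is recorded as `"unknown"`.
#' A custom regular expression with named groups `site`, `cane`,
#' `position`, `side`, `rep` may be supplied for other schemes.
#'
#' @param labels character vector of per-spectrum labels.
#' @param pattern optional PCRE with the five named capture groups above.
#' @return a data.frame with columns `label`, `site`, `region`, `cane`,
#'   `leaf_position`, `leaf_side`, `replicate`.
#' @export
parse_labels <- function(labels, pattern = NULL) {
  labels <- as.character(labels)
  if (is.null(pattern)) {
    pattern <- paste0(
      "^(?<site>[A-Z]{3})_c(?<cane>\\d+)_(?<position>New|Height|Mature)",
      "(?:_(?<side>upper|lower))?_r(?<rep>\\d+)$"
    )
  }
  ok <- grepl(pattern, labels, perl = TRUE)
  if (!all(ok)) {
    stop("unparseable spectrum label at row(s) ",
         paste(which(!ok), collapse = ", "), ": ",
         paste(utils::head(labels[!ok], 3), collapse = ", "),
         call. = FALSE)
  }
  cap <- regmatches(labels, gregexec(pattern, labels, perl = TRUE))
  get_group <- function(name) {
    vapply(cap, function(x) {
      rn <- rownames(x)
      if (name %in% rn) x[rn == name, 1][1] else ""
    }, character(1))
  }
  site <- get_group("site")
  side <- get_group("side")
  side[!nzchar(side)] <- "unknown"
  out <- data.frame(
    label = labels,
    site = site,
    region = region_of(site),
    cane = as.integer(get_group("cane")),
    leaf_position = get_group("position"),
    leaf_side = side,
    replicate = as.integer(get_group("rep")),
    stringsAsFactors = FALSE
  )
  out
}

format_labels <- function(meta) {
  side <- meta$leaf_side
  mid <- ifelse(side == "unknown", "", paste0("_", side))
  sprintf("%s_c%d_%s%s_r%02d",
          meta$site, meta$cane, meta$leaf_position, mid, meta$replicate)
}

# Spectral dataset -----------------------------------------------------------

#' Construct a spectral dataset
#'
#' Bundles an absorbance matrix (rows = spectra), its shared wavenumber
#' grid, per-spectrum metadata and a free-text provenance log. Ascending
#' grids are canonicalised to descending together with the matrix columns.
#'
#' @param absorbance numeric matrix, `n_spectra x n_points`.
#' @param grid numeric vector or `wavenumber_grid` of length `n_points`.
#' @param meta data.frame with one row per spectrum (see [parse_labels()]),
#'   or `NULL` for anonymous spectra.
#' @param provenance character vector of processing-log lines.
#' @return object of class `spectral_dataset` with elements `grid`,
#'   `absorbance`, `meta`, `provenance`.
#' @export
spectral_dataset <- function(absorbance, grid, meta = NULL,
                             provenance = character()) {
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  raw <- as.numeric(grid)
  g <- wavenumber_grid(raw)
  if (ncol(absorbance) != length(g)) {
    stop("absorbance has ", ncol(absorbance), " columns but grid has ",
         length(g), " points", call. = FALSE)
  }
  if (!isTRUE(all.equal(raw, as.numeric(g), tolerance = 0))) {
    # grid was flipped to descending: flip columns accordingly
    if (all(rev(raw) == as.numeric(g))) {
      absorbance <- absorbance[, rev(seq_len(ncol(absorbance))), drop = FALSE]
    }
  }
  if (anyNA(absorbance)) stop("absorbance contains missing values",
                              call. = FALSE)
  if (!is.null(meta)) {
    meta <- as.data.frame(meta, stringsAsFactors = FALSE)
    if (nrow(meta) != nrow(absorbance)) {
      stop("metadata rows (", nrow(meta), ") != spectra rows (",
           nrow(absorbance), ")", call. = FALSE)
    }
  }
  colnames(absorbance) <- format(as.numeric(g), trim = TRUE)
  structure(
    list(grid = g, absorbance = absorbance, meta = meta,
         provenance = as.character(provenance)),
    class = "spectral_dataset"
  )
}

#' @export
print.spectral_dataset <- function(x, ...) {
  g <- as.numeric(x$grid)
  cat(sprintf("<spectral_dataset> %d spectra x %d points, %g-%g cm^-1 (step %g)\n",
              nrow(x$absorbance), length(g), g[1], g[length(g)],
              attr(x$grid, "spacing")))
  if (!is.null(x$meta) && "region" %in% names(x$meta)) {
    cat("  regions:", paste(sprintf("%s=%d", names(table(x$meta$region)),
                                    table(x$meta$region)), collapse = " "), "\n")
  }
  if (length(x$provenance)) {
    cat("  provenance:\n")
    for (p in x$provenance) cat("   -", p, "\n")
  }
  invisible(x)
}

#' @export
dim.spectral_dataset <- function(x) dim(x$absorbance)

log_step <- function(ds, msg) {
  ds$provenance <- c(ds$provenance, msg)
  ds
}

subset_spectra <- function(ds, rows) {
  spectral_dataset(ds$absorbance[rows, , drop = FALSE], as.numeric(ds$grid),
                   if (!is.null(ds$meta)) ds$meta[rows, , drop = FALSE],
                   ds$provenance)
}

#' Class labels of a dataset
#'
#' @param ds a `spectral_dataset` with parsed metadata.
#' @param label_field `"region"` or `"site"`.
#' @return character vector of labels, one per spectrum.
#' @export
dataset_labels <- function(ds, label_field = c("region", "site")) {
  label_field <- match.arg(label_field)
  if (is.null(ds$meta) || !label_field %in% names(ds$meta)) {
    stop("dataset has no '", label_field, "' metadata", call. = FALSE)
  }
  ds$meta[[label_field]]
}

# Readers and writers --------------------------------------------------------

#' Read a spectral table
#'
#' Supported dialects:
#' * `wide_csv` / `wide_tsv`: first column `label`, remaining column names
#'   numeric wavenumbers, one row per spectrum.
#' * `two_column_txt_per_spectrum`: `path` is a directory of per-spectrum
#'   text files, two whitespace/comma-separated columns
#'   (wavenumber, absorbance); the file name (minus extension) is the label.
#'
#' Labels are parsed into hierarchical metadata with [parse_labels()];
#' pass `label_pattern` for non-default naming schemes, or
#' `parse_meta = FALSE` to keep labels opaque.
#'
#' @param path file (wide dialects) or directory (two-column dialect).
#' @param dialect one of `"wide_csv"`, `"wide_tsv"`,
#'   `"two_column_txt_per_spectrum"`.
#' @param parse_meta parse labels into site/cane/... metadata?
#' @param label_pattern optional regex forwarded to [parse_labels()].
#' @return a [spectral_dataset()].
#' @export
read_spectra_table <- function(path,
                               dialect = c("wide_csv", "wide_tsv",
                                           "two_column_txt_per_spectrum"),
                               parse_meta = TRUE, label_pattern = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "two_column_txt_per_spectrum") {
    if (!dir.exists(path)) stop("directory not found: ", path, call. = FALSE)
    files <- sort(list.files(path, pattern = "\\.(txt|csv|dat)$",
                             full.names = TRUE))
    if (!length(files)) stop("no per-spectrum files in ", path, call. = FALSE)
    mats <- lapply(files, function(f) {
      d <- utils::read.table(f, header = FALSE, sep = "",
                             col.names = c("w", "a"))
      d
    })
    grid0 <- mats[[1]]$w
    for (i in seq_along(mats)) {
      if (!isTRUE(all.equal(mats[[i]]$w, grid0, tolerance = 1e-9))) {
        stop("file ", files[i], " uses a different wavenumber grid",
             call. = FALSE)
      }
    }
    A <- do.call(rbind, lapply(mats, function(d) d$a))
    labels <- sub("\\.[^.]*$", "", basename(files))
  } else {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    sep <- if (dialect == "wide_csv") "," else "\t"
    d <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
    if (!ncol(d) >= 3) stop("wide table needs a label column plus >= 2 ",
                            "wavenumber columns", call. = FALSE)
    wn <- suppressWarnings(as.numeric(names(d)[-1]))
    if (anyNA(wn)) {
      stop("non-numeric wavenumber header(s): ",
           paste(names(d)[-1][is.na(wn)], collapse = ", "), call. = FALSE)
    }
    labels <- as.character(d[[1]])
    A <- as.matrix(d[, -1, drop = FALSE])
    if (!is.numeric(A)) stop("ragged or non-numeric data rows", call. = FALSE)
    grid0 <- wn
  }
  if (anyNA(A)) stop("missing absorbance values in ", path, call. = FALSE)
  meta <- if (parse_meta) parse_labels(labels, label_pattern) else
    data.frame(label = labels, stringsAsFactors = FALSE)
  spectral_dataset(A, grid0, meta,
                   provenance = sprintf("read %d spectra from %s [%s]",
                                        nrow(A), path, dialect))
}

#' Write a spectral table
#'
#' Inverse of [read_spectra_table()]; the round trip preserves grid,
#' absorbance and label-encoded metadata to full double precision.
#'
#' @param ds a [spectral_dataset()].
#' @param path output file (wide dialects) or directory (two-column).
#' @param dialect see [read_spectra_table()].
#' @export
write_spectra_table <- function(ds, path,
                                dialect = c("wide_csv", "wide_tsv",
                                            "two_column_txt_per_spectrum")) {
  dialect <- match.arg(dialect)
  labels <- if (!is.null(ds$meta) && "label" %in% names(ds$meta)) {
    ds$meta$label
  } else if (!is.null(ds$meta) && "site" %in% names(ds$meta)) {
    format_labels(ds$meta)
  } else {
    sprintf("spectrum_%04d", seq_len(nrow(ds$absorbance)))
  }
  g <- as.numeric(ds$grid)
  if (dialect == "two_column_txt_per_spectrum") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(labels)) {
      f <- file.path(path, paste0(labels[i], ".txt"))
      utils::write.table(
        data.frame(w = format(g, trim = TRUE),
                   a = format(ds$absorbance[i, ], digits = 17, trim = TRUE)),
        f, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    }
  } else {
    sep <- if (dialect == "wide_csv") "," else "\t"
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(c("label", format(g, trim = TRUE)), collapse = sep), con)
    body <- apply(ds$absorbance, 1, function(r)
      paste(format(r, digits = 17, trim = TRUE), collapse = sep))
    writeLines(paste(labels, body, sep = sep), con)
  }
  invisible(NULL)
}
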