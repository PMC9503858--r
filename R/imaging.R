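#' Construct a planar whole-body scan
#'
#' Bundles the anterior/posterior count matrices of a conjugate-view planar
#' acquisition with the metadata every downstream stage needs: pixel spacing,
#' acquisition duration, time post administration and patient data. A single
#' view may be supplied (`posterior = NULL`); it is then used as-is by
#' [geometric_mean_image()] with a warning, for cameras that store one
#' pre-combined whole-body frame.
#'
#' Image coordinates are row-major with row 1 cranial; if a file stores the
#' scan feet-up, flip it at load time (`read_planar_scan(flip_axis = )`).
#'
#' @param anterior Integer-valued, non-negative count matrix.
#' @param posterior Matrix of the same shape as `anterior`, or `NULL` for a
#'   single-view acquisition.
#' @param pixel_spacing_mm Numeric pair, both entries positive.
#' @param acquisition_duration_s Positive scalar, seconds.
#' @param time_post_admin_h Non-negative scalar: hours between administration
#'   and the scan (the single observation time used by
#'   [solve_scale_factors()]).
#' @param radionuclide Identifier string, e.g. `"Lu-177"`, `"I-131"`.
#' @param patient List with `sex` (`"M"` or `"F"`), `weight_kg` (> 0) and
#'   `administered_activity_MBq` (> 0).
#' @param integer_counts Require integer-valued counts (default `TRUE`, as
#'   for any acquired scan); the noiseless phantom simulator disables it,
#'   since expected counts are real-valued.
#' @return An object of class `planar_scan`.
#' @export
planar_scan <- function(anterior, posterior = NULL,
                        pixel_spacing_mm = c(1, 1),
                        acquisition_duration_s,
                        time_post_admin_h,
                        radionuclide = "Lu-177",
                        patient = list(sex = "M", weight_kg = 70,
                                       administered_activity_MBq = 7400),
                        integer_counts = TRUE) {
  anterior <- as.matrix(anterior)
  check_count_matrix(anterior, "anterior", integer_counts)
  if (!is.null(posterior)) {
    posterior <- as.matrix(posterior)
    check_count_matrix(posterior, "posterior", integer_counts)
    if (!identical(dim(anterior), dim(posterior)))
      stop("anterior and posterior views have different shapes: ",
           paste(dim(anterior), collapse = "x"), " vs ",
           paste(dim(posterior), collapse = "x"))
  }
  pixel_spacing_mm <- as.numeric(pixel_spacing_mm)
  if (length(pixel_spacing_mm) != 2 || any(!is.finite(pixel_spacing_mm)) ||
      any(pixel_spacing_mm <= 0))
    stop("pixel_spacing_mm must be a positive pair")
  if (!is_positive_scalar(acquisition_duration_s))
    stop("acquisition_duration_s must be a positive scalar")
  if (!is_nonneg_scalar(time_post_admin_h))
    stop("time_post_admin_h must be a non-negative scalar")
  patient <- validate_patient(patient)
  structure(list(
    anterior = anterior,
    posterior = posterior,
    pixel_spacing_mm = pixel_spacing_mm,
    acquisition_duration_s = as.numeric(acquisition_duration_s),
    time_post_admin_h = as.numeric(time_post_admin_h),
    radionuclide = as.character(radionuclide),
    patient = patient
  ), class = "planar_scan")
}

check_count_matrix <- function(m, name, integer_counts = TRUE) {
  if (!is.matrix(m) || !is.numeric(m))
    stop(name, " view must be a numeric matrix")
  if (any(!is.finite(m))) stop(name, " view contains non-finite values")
  if (any(m < 0)) stop(name, " view contains negative counts")
  if (integer_counts && any(abs(m - round(m)) > 1e-9))
    stop(name, " view contains non-integer counts")
  invisible(m)
}

is_positive_scalar <- function(x) is.numeric(x) && length(x) == 1 &&
  is.finite(x) && x > 0
is_nonneg_scalar <- function(x) is.numeric(x) && length(x) == 1 &&
  is.finite(x) && x >= 0

validate_patient <- function(patient) {
  if (!is.list(patient)) stop("patient must be a list")
  need <- c("sex", "weight_kg", "administered_activity_MBq")
  miss <- setdiff(need, names(patient))
  if (length(miss)) stop("patient metadata missing: ",
                         paste(miss, collapse = ", "))
  if (!patient$sex %in% c("M", "F")) stop("patient$sex must be 'M' or 'F'")
  if (!is_positive_scalar(patient$weight_kg))
    stop("patient$weight_kg must be > 0")
  if (!is_positive_scalar(patient$administered_activity_MBq))
    stop("patient$administered_activity_MBq must be > 0")
  patient[need]
}

#' @export
print.planar_scan <- function(x, ...) {
  cat("planar_scan:", paste(dim(x$anterior), collapse = " x "),
      if (is.null(x$posterior)) "(single view)" else "(ant/post pair)", "\n")
  cat("  radionuclide:", x$radionuclide,
      " t_post_admin:", x$time_post_admin_h, "h",
      " duration:", x$acquisition_duration_s, "s\n")
  cat("  patient:", x$patient$sex, x$patient$weight_kg, "kg,",
      x$patient$administered_activity_MBq, "MBq administered\n")
  invisible(x)
}

#' Read a planar scan from disk
#'
#' Reads a scan directory (or explicit file paths) holding the two views and
#' a YAML sidecar. Supported pixel formats: plain CSV integer matrices
#' (`anterior.csv`, `posterior.csv`) or 16-bit grayscale PNG (`anterior.png`,
#' `posterior.png`, requires the `png` package). The sidecar `meta.yaml`
#' supplies `pixel_spacing_mm`, `acquisition_duration_s`,
#' `time_post_admin_h`, `radionuclide` and `patient`; any of these may be
#' overridden (or supplied when absent) through `metadata_overrides`.
#'
#' @param path Directory containing the view files and `meta.yaml`.
#' @param format_hint `"csv"`, `"png"` or `"auto"` (default: whichever files
#'   are present, CSV preferred).
#' @param metadata_overrides Named list merged over the sidecar metadata.
#' @param flip_axis `"none"` (default), `"rows"` or `"cols"`: axis flip
#'   applied to both views at load, for scans stored feet-up or mirrored.
#' @return A [planar_scan()].
#' @export
read_planar_scan <- function(path, format_hint = c("auto", "csv", "png"),
                             metadata_overrides = list(),
                             flip_axis = c("none", "rows", "cols")) {
  format_hint <- match.arg(format_hint)
  flip_axis <- match.arg(flip_axis)
  if (!dir.exists(path)) stop("scan directory not found: ", path)
  fmt <- format_hint
  if (fmt == "auto") {
    fmt <- if (file.exists(file.path(path, "anterior.csv"))) "csv"
           else if (file.exists(file.path(path, "anterior.png"))) "png"
           else stop("no anterior.csv or anterior.png in ", path)
  }
  read_view <- function(stem) {
    f <- file.path(path, paste0(stem, ".", fmt))
    if (!file.exists(f)) return(NULL)
    m <- if (fmt == "csv") read_count_csv(f) else read_count_png(f)
    switch(flip_axis, none = m,
           rows = m[nrow(m):1, , drop = FALSE],
           cols = m[, ncol(m):1, drop = FALSE])
  }
  ant <- read_view("anterior")
  if (is.null(ant)) stop("anterior view missing in ", path)
  post <- read_view("posterior")

  meta_file <- file.path(path, "meta.yaml")
  meta <- if (file.exists(meta_file)) yaml::read_yaml(meta_file) else list()
  meta <- utils::modifyList(meta, metadata_overrides)
  need <- c("pixel_spacing_mm", "acquisition_duration_s", "time_post_admin_h",
            "radionuclide", "patient")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("required metadata missing (sidecar meta.yaml or overrides): ",
         paste(miss, collapse = ", "))
  planar_scan(ant, post,
              pixel_spacing_mm = unlist(meta$pixel_spacing_mm),
              acquisition_duration_s = meta$acquisition_duration_s,
              time_post_admin_h = meta$time_post_admin_h,
              radionuclide = meta$radionuclide,
              patient = meta$patient)
}

read_count_csv <- function(f) {
  m <- as.matrix(utils::read.csv(f, header = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- "double"
  m
}

read_count_png <- function(f) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("reading PNG views requires the 'png' package")
  a <- png::readPNG(f)
  if (length(dim(a)) == 3) a <- a[, , 1]
  round(a * 65535)
}

#' Write a planar scan to a directory (CSV matrices + YAML sidecar)
#'
#' Inverse of [read_planar_scan()]; CSV round-trips are count-exact.
#'
#' @param scan A [planar_scan()].
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_planar_scan <- function(scan, path) {
  stopifnot(inherits(scan, "planar_scan"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_count_csv <- function(m, f)
    utils::write.table(m, f, sep = ",", row.names = FALSE, col.names = FALSE)
  write_count_csv(scan$anterior, file.path(path, "anterior.csv"))
  if (!is.null(scan$posterior))
    write_count_csv(scan$posterior, file.path(path, "posterior.csv"))
  meta <- list(pixel_spacing_mm = as.numeric(scan$pixel_spacing_mm),
               acquisition_duration_s = scan$acquisition_duration_s,
               time_post_admin_h = scan$time_post_admin_h,
               radionuclide = scan$radionuclide,
               patient = scan$patient)
  yaml::write_yaml(meta, file.path(path, "meta.yaml"))
  invisible(path)
}

#' Geometric-mean count image of the two conjugate views
#'
#' Pixelwise `sqrt(anterior * posterior)` after mirroring the posterior view
#' left-right (the standard conjugate-view convention: the posterior camera
#' sees the patient mirrored). Zero wherever either view is zero. For a
#' single-view scan the anterior matrix is returned unchanged with a
#' warning.
#'
#' @param scan A [planar_scan()].
#' @param mirror_posterior Mirror the posterior view left-right before the
#'   geometric mean (default `TRUE`); set `FALSE` for pre-registered data.
#' @return A `count_image`: list with `values` (non-negative matrix) and
#'   `pixel_spacing_mm`.
#' @export
geometric_mean_image <- function(scan, mirror_posterior = TRUE) {
  stopifnot(inherits(scan, "planar_scan"))
  if (is.null(scan$posterior)) {
    warning("single-view scan: using the anterior view as the count image")
    vals <- scan$anterior
  } else {
    post <- scan$posterior
    if (mirror_posterior) post <- post[, ncol(post):1, drop = FALSE]
    vals <- sqrt(scan$anterior * post)
  }
  count_image(vals, scan$pixel_spacing_mm)
}

#' @rdname geometric_mean_image
#' @param values Non-negative real matrix.
#' @param pixel_spacing_mm Positive pair.
#' @export
count_image <- function(values, pixel_spacing_mm = c(1, 1)) {
  values <- as.matrix(values)
  if (any(!is.finite(values)) || any(values < 0))
    stop("count image values must be finite and non-negative")
  structure(list(values = values,
                 pixel_spacing_mm = as.numeric(pixel_spacing_mm)),
            class = "count_image")
}

#' @export
print.count_image <- function(x, ...) {
  cat("count_image:", paste(dim(x$values), collapse = " x "),
      " max:", max(x$values), "\n")
  invisible(x)
}
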