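#' Threshold index of a count threshold
#'
#' Normalizes a count threshold against the image maximum:
#' `ThI = (Cmax - Cthr) / Cmax`, so that `ThI = 0` places the threshold at
#' the hottest pixel and `ThI = 1` at zero counts.
#'
#' @param c_thr Count threshold, in `[0, c_max]`.
#' @param c_max Maximum pixel value of the image, > 0.
#' @return Threshold index in `[0, 1]`.
#' @export
threshold_index <- function(c_thr, c_max) {
  if (!is.numeric(c_max) || any(c_max <= 0)) stop("c_max must be > 0")
  if (any(c_thr < 0) || any(c_thr > c_max))
    stop("c_thr must lie in [0, c_max]")
  (c_max - c_thr) / c_max
}

#' Label connected components of a binary mask
#'
#' 4- or 8-connected labeling. Built on an igraph pixel-adjacency graph;
#' labels are positive integers in first-encounter order, 0 = background.
#'
#' @param mask Logical matrix.
#' @param connectivity 4 (edge neighbours) or 8 (edge + diagonal).
#' @return Integer matrix of component labels, same shape as `mask`.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask))
  mask <- mask & !is.na(mask)
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  n <- sum(mask)
  if (n == 0) return(lab)
  idmat <- matrix(0L, nr, nc)
  idmat[mask] <- seq_len(n)

  offsets <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8) offsets <- c(offsets, list(c(1L, 1L), c(1L, -1L)))
  edges <- integer(0)
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    r1 <- seq_len(nr - dr)
    c1 <- if (dc >= 0) seq_len(nc - dc) else seq.int(1 - dc, nc)
    a <- idmat[r1, c1, drop = FALSE]
    b <- idmat[r1 + dr, c1 + dc, drop = FALSE]
    keep <- a > 0L & b > 0L
    if (any(keep)) edges <- c(edges, rbind(a[keep], b[keep]))
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  memb <- igraph::components(g)$membership
  # relabel in first-encounter (column-major) order for determinism
  first <- !duplicated(memb)
  relab <- integer(max(memb))
  relab[memb[first]] <- seq_len(sum(first))
  lab[mask] <- relab[memb]
  lab
}

#' Number of uptake foci above a count threshold
#'
#' Counts the connected components of the super-threshold mask
#' `{pixels with counts > c_thr}` ("overcome" is strict: ties fall below).
#'
#' @param image A `count_image` (or bare matrix).
#' @param c_thr Count threshold.
#' @param connectivity 4 or 8 (default 8).
#' @return Non-negative integer.
#' @export
count_uptake_foci <- function(image, c_thr, connectivity = 8) {
  vals <- image_values(image)
  mask <- vals > c_thr
  if (!any(mask)) return(0L)
  max(label_components(mask, connectivity))
}

image_values <- function(image) {
  if (inherits(image, "count_image")) image$values
  else if (is.matrix(image)) image
  else stop("expected a count_image or a matrix")
}

#' Sweep the threshold index and build the nNUF curve
#'
#' Evaluates the number of uptake foci (NUF) at `n_steps` equally spaced
#' threshold indices in `[0, 1]` (`Cthr = Cmax * (1 - ThI)`), and normalizes
#' by the maximum over the sweep (nNUF).
#'
#' @param image A `count_image` with positive maximum.
#' @param n_steps Number of sweep points (>= 2), default 100.
#' @param connectivity 4 or 8.
#' @return A `nuf_curve`: data.frame with columns `ThI`, `Cthr`, `NUF`,
#'   `nNUF`; `max(nNUF) == 1`.
#' @export
nuf_curve <- function(image, n_steps = 100, connectivity = 8) {
  vals <- image_values(image)
  cmax <- max(vals)
  if (cmax <= 0) stop("cannot sweep an all-zero image")
  if (n_steps < 2) stop("n_steps must be >= 2")
  thi <- seq(0, 1, length.out = n_steps)
  cthr <- cmax * (1 - thi)
  nuf <- vapply(cthr, function(ct) count_uptake_foci(vals, ct, connectivity),
                integer(1))
  curve <- data.frame(ThI = thi, Cthr = cthr, NUF = nuf,
                      nNUF = nuf / max(nuf))
  class(curve) <- c("nuf_curve", "data.frame")
  curve
}

#' Select the segmentation threshold from the nNUF curve
#'
#' Returns the smallest threshold index at which the normalized number of
#' uptake foci reaches `nnuf_cutoff`. Because NUF explodes once the
#' threshold enters the background noise, this crossing sits at the top of
#' the background count distribution and separates focal uptake from the
#' body background.
#'
#' @param curve A [nuf_curve()].
#' @param nnuf_cutoff Cutoff in `(0, 1]`, default 0.5.
#' @return List with `chosen_Cthr` and `chosen_ThI`.
#' @export
select_segmentation_threshold <- function(curve, nnuf_cutoff = 0.5) {
  if (!inherits(curve, "nuf_curve") || nrow(curve) == 0)
    stop("curve must be a non-empty nuf_curve")
  if (!is_positive_scalar(nnuf_cutoff) || nnuf_cutoff > 1)
    stop("nnuf_cutoff must lie in (0, 1]")
  hit <- which(curve$nNUF >= nnuf_cutoff)
  i <- hit[which.min(curve$ThI[hit])]
  list(chosen_Cthr = curve$Cthr[i], chosen_ThI = curve$ThI[i])
}

#' Plateau-based threshold selection
#'
#' Selects the count threshold at the centre of the widest stable plateau
#' of the NUF sweep: the longest run of consecutive sweep points with an
#' identical, positive number of uptake foci. Between the focal count
#' level and the top of the background distribution the focus count is
#' constant, so this plateau spans exactly the thresholds that separate
#' the two compartments; its centre is maximally far both from the focal
#' levels (where foci fragment under counting noise) and from the
#' background (where noise speckle inflates NUF). On noiseless phantoms any
#' plateau point reproduces the planted partition exactly. This is the
#' package's default selection strategy; the nNUF-cutoff rule
#' ([select_segmentation_threshold()]) is the configurable alternative.
#'
#' @param curve A [nuf_curve()].
#' @return List with `chosen_Cthr`, `chosen_ThI` and `NUF_plateau` (the
#'   focus count along the selected plateau).
#' @export
select_plateau_threshold <- function(curve) {
  if (!inherits(curve, "nuf_curve") || nrow(curve) == 0)
    stop("curve must be a non-empty nuf_curve")
  r <- rle(curve$NUF)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ok <- r$values >= 1
  if (!any(ok)) stop("no uptake foci at any threshold")
  best <- which(ok)[which.max(r$lengths[ok])]
  i0 <- starts[best]; i1 <- ends[best]
  list(chosen_Cthr = (curve$Cthr[i0] + curve$Cthr[i1]) / 2,
       chosen_ThI = (curve$ThI[i0] + curve$ThI[i1]) / 2,
       NUF_plateau = r$values[best])
}

#' Body outline mask
#'
#' Thresholds at a small fraction of the image maximum, fills interior
#' holes, and keeps the largest connected component. No anatomical prior.
#'
#' @param image A `count_image`.
#' @param body_fraction Fraction of `Cmax` in `[0, 1)`, default 0.01.
#' @param connectivity 4 or 8 for the component steps.
#' @return Logical matrix.
#' @export
body_mask <- function(image, body_fraction = 0.01, connectivity = 8) {
  vals <- image_values(image)
  cmax <- max(vals)
  if (cmax <= 0) stop("cannot derive a body mask from an all-zero image")
  if (body_fraction < 0 || body_fraction >= 1)
    stop("body_fraction must lie in [0, 1)")
  mask <- vals > body_fraction * cmax
  if (!any(mask)) stop("empty body mask")
  lab <- label_components(mask, connectivity)
  sizes <- tabulate(lab[lab > 0L])
  mask <- lab == which.max(sizes)
  fill_holes(mask)
}

# Interior holes: background components (4-connected complement) that do not
# touch the image border.
fill_holes <- function(mask) {
  bg <- label_components(!mask, 4)
  if (max(bg) == 0L) return(mask)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border <- border[border > 0L]
  mask | (bg > 0L & !(bg %in% border))
}

#' Split the body into high- and low-uptake compartments
#'
#' The high compartment is every in-body pixel whose counts strictly exceed
#' the chosen threshold; the low compartment is the remainder of the body.
#' Per-compartment counts (and count rates, when the acquisition duration is
#' known) and the labeled high-uptake foci are reported.
#'
#' @param image A `count_image` (normally the geometric-mean image).
#' @param chosen_Cthr Count threshold, e.g. from
#'   [select_segmentation_threshold()].
#' @param body Logical body mask covering all super-threshold pixels
#'   (default: [body_mask()] of the image).
#' @param connectivity 4 or 8 for focus labeling.
#' @param acquisition_duration_s Optional; enables `cps_high`/`cps_low`.
#' @return A `segmentation_result`: masks, chosen threshold, per-compartment
#'   counts and cps, and `foci` (list of pixel-index vectors, one per
#'   labeled high-uptake component).
#' @export
segment_compartments <- function(image, chosen_Cthr, body = NULL,
                                 connectivity = 8,
                                 acquisition_duration_s = NULL) {
  vals <- image_values(image)
  if (is.null(body)) body <- body_mask(image)
  stopifnot(is.matrix(body), identical(dim(body), dim(vals)))
  high <- vals > chosen_Cthr
  if (any(high & !body))
    stop("high-uptake pixels fall outside the body mask; ",
         "enlarge body_fraction or check the mask")
  low <- body & !high
  lab <- label_components(high, connectivity)
  nfoci <- max(lab)
  foci <- if (nfoci > 0)
    split(which(lab > 0L), lab[lab > 0L]) else list()
  counts_high <- sum(vals[high])
  counts_low <- sum(vals[low])
  res <- list(body_mask = body, high_mask = high, low_mask = low,
              chosen_Cthr = chosen_Cthr,
              chosen_ThI = threshold_index(min(chosen_Cthr, max(vals)),
                                           max(vals)),
              counts_high = counts_high, counts_low = counts_low,
              cps_high = if (is.null(acquisition_duration_s)) NA_real_
                         else counts_high / acquisition_duration_s,
              cps_low = if (is.null(acquisition_duration_s)) NA_real_
                        else counts_low / acquisition_duration_s,
              foci = foci,
              skeletal_lesion_labels = integer(0))
  class(res) <- "segmentation_result"
  res
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("segmentation_result: Cthr =", format(x$chosen_Cthr),
      " (ThI =", format(round(x$chosen_ThI, 4)), ")\n")
  cat("  foci:", length(x$foci),
      " counts high/low:", format(x$counts_high), "/",
      format(x$counts_low), "\n")
  invisible(x)
}

#' Measured high/low counts ratio of a segmentation
#'
#' The counts ratio equals the cps ratio (both compartments share one
#' acquisition), which is the self-calibrated activity ratio fed to
#' [solve_scale_factors()]; no camera calibration factor is involved.
#'
#' @param seg A `segmentation_result`.
#' @return `counts_high / counts_low`.
#' @export
counts_ratio <- function(seg) {
  stopifnot(inherits(seg, "segmentation_result"))
  if (seg$counts_low <= 0) stop("low compartment has no counts")
  seg$counts_high / seg$counts_low
}

#' Write / read segmentation artifacts
#'
#' `write_nuf_curve()` stores the sweep as CSV (`ThI,Cthr,NUF,nNUF`);
#' `write_mask_rle()`/`read_mask_rle()` store a boolean mask as a run-length
#' CSV over the column-major pixel order (`value,length` rows, with `nrow`
#' and `ncol` header comments).
#'
#' @param curve A [nuf_curve()].
#' @param path Output file.
#' @export
write_nuf_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve)[, c("ThI", "Cthr", "NUF", "nNUF")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_nuf_curve
#' @param mask Logical matrix.
#' @export
write_mask_rle <- function(mask, path) {
  r <- rle(as.vector(mask))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# nrow=", nrow(mask)), paste0("# ncol=", ncol(mask)),
               "value,length"), con)
  utils::write.table(data.frame(value = as.integer(r$values),
                                length = r$lengths),
                     con, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_nuf_curve
#' @export
read_mask_rle <- function(path) {
  hdr <- readLines(path, n = 2)
  nr <- as.integer(sub("# nrow=", "", hdr[1]))
  nc <- as.integer(sub("# ncol=", "", hdr[2]))
  d <- utils::read.csv(path, skip = 2)
  matrix(inverse.rle(list(values = as.logical(d$value),
                          lengths = d$length)), nr, nc)
}
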