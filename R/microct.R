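#' Raw micro-CT volume
#'
#' A 3-D grid of scanner intensities in arbitrary units, axis order (z, y, x),
#' with an isotropic voxel size in mm (0.061 mm for the scans this pipeline
#' targets). Raw intensities are only meaningful relative to the water/air
#' calibration references scanned alongside the sample.
#'
#' @param data 3-D numeric array, axis order (z, y, x).
#' @param voxel_size_mm isotropic voxel edge length, mm.
#' @return a `raw_volume`.
#' @export
raw_volume <- function(data, voxel_size_mm = 0.061) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_msg("data must be a 3-D array (z, y, x)")
  if (!is.finite(voxel_size_mm) || voxel_size_mm <= 0)
    stop_msg("voxel size must be positive")
  structure(list(data = data, voxel_size_mm = voxel_size_mm),
            class = "raw_volume")
}

#' Box region of interest
#'
#' Inclusive index ranges along each axis (z, y, x), 1-based.
#'
#' @param z,y,x length-2 integer vectors `c(from, to)`.
#' @export
roi_box <- function(z, y, x) {
  stopifnot(length(z) == 2L, length(y) == 2L, length(x) == 2L)
  structure(list(z = as.integer(z), y = as.integer(y), x = as.integer(x)),
            class = "roi_box")
}

roi_values <- function(vol_data, roi) {
  vol_data[roi$z[1]:roi$z[2], roi$y[1]:roi$y[2], roi$x[1]:roi$x[2]]
}

roi_overlap <- function(a, b) {
  all(vapply(c("z", "y", "x"), function(ax)
    a[[ax]][1] <= b[[ax]][2] && b[[ax]][1] <= a[[ax]][2], logical(1)))
}

#' Calibrate a raw volume to Hounsfield units
#'
#' Uses the mean raw intensity inside water and air reference regions to map
#' the volume onto the Hounsfield scale by the affine transform
#' `HU(x) = 1000 (x - mean_water) / (mean_water - mean_air)`, so the water
#' reference maps to 0 HU and the air reference to -1000 HU exactly. The
#' calibration is invariant under any affine rescaling of the raw intensities
#' (applied to volume and references together).
#'
#' @param v a [raw_volume()].
#' @param water_roi,air_roi [roi_box()] regions covering the reference tubes;
#'   must be nonempty and disjoint.
#' @return an `hu_volume` (list with `data` in HU, `voxel_size_mm`, and a
#'   `calibration` record).
#' @export
calibrate_hu <- function(v, water_roi, air_roi) {
  stopifnot(inherits(v, "raw_volume"))
  if (roi_overlap(water_roi, air_roi)) stop_msg("water and air ROIs overlap")
  w <- roi_values(v$data, water_roi)
  a <- roi_values(v$data, air_roi)
  if (!length(w) || !length(a)) stop_msg("reference ROI is empty")
  mw <- mean(w); ma <- mean(a)
  if (mw == ma) stop_msg("degenerate calibration: water and air ROI means equal")
  hu <- 1000 * (v$data - mw) / (mw - ma)
  structure(list(data = hu, voxel_size_mm = v$voxel_size_mm,
                 calibration = list(water_mean = mw, air_mean = ma,
                                    water_roi = water_roi,
                                    air_roi = air_roi)),
            class = "hu_volume")
}

#' Per-region radiodensity statistics
#'
#' Computes, for each labeled region, the mean and population standard
#' deviation of the calibrated radiodensity and the voxel count. Empty labels
#' (present in `levels` but with no voxels) are flagged and excluded.
#'
#' @param v an `hu_volume` from [calibrate_hu()].
#' @param labels integer array congruent with the volume; 0 = unlabeled.
#' @param names optional named character vector mapping label values to
#'   region names.
#' @return a `region_report` data frame with columns `label`, `region`,
#'   `mean_HU`, `sd_HU`, `n_voxels`.
#' @export
region_stats <- function(v, labels, names = NULL) {
  stopifnot(inherits(v, "hu_volume"))
  if (!identical(dim(v$data), dim(labels)))
    stop_msg("label grid not congruent with volume")
  labs <- sort(unique(labels[labels > 0]))
  rows <- lapply(labs, function(l) {
    vals <- v$data[labels == l]
    data.frame(label = l,
               region = if (!is.null(names) && as.character(l) %in% names(names))
                 names[[as.character(l)]] else paste0("region_", l),
               mean_HU = mean(vals),
               sd_HU = sqrt(mean((vals - mean(vals))^2)),
               n_voxels = length(vals))
  })
  rep <- do.call(rbind, rows)
  if (is.null(rep)) rep <- data.frame(label = integer(0), region = character(0),
                                      mean_HU = numeric(0), sd_HU = numeric(0),
                                      n_voxels = integer(0))
  class(rep) <- c("region_report", "data.frame")
  rep
}

#' Classify regions or voxels as vitrified vs frozen
#'
#' Vitrified CPA-equilibrated tissue is markedly more radiodense than frozen
#' (ice-laden) tissue, so a radiodensity threshold separates the two states.
#' Regions (or voxels) with mean HU at or above the threshold are called
#' `vitrified`, below it `frozen`. The default threshold of 400 HU sits
#' between the radiodensity of vitrified VMP-loaded kidney (~507 HU) and icy
#' adherent fat (~267 HU); it is a heuristic for IONP-free scans and must be
#' shifted for nanoparticle-loaded organs, whose absolute radiodensity is
#' raised by the iron oxide.
#'
#' Applied to a `region_report`, returns the report with a `state` column;
#' applied to an `hu_volume`, returns a per-voxel state map plus the
#' connected components of frozen voxels with their sizes.
#'
#' @param x a `region_report` or an `hu_volume`.
#' @param threshold_HU decision threshold, HU.
#' @export
classify_state <- function(x, threshold_HU = 400) {
  if (threshold_HU < -1000 || threshold_HU > 3000)
    stop_msg("threshold outside plausible HU range")
  if (inherits(x, "region_report")) {
    x$state <- ifelse(x$mean_HU >= threshold_HU, "vitrified", "frozen")
    return(x)
  }
  stopifnot(inherits(x, "hu_volume"))
  frozen <- x$data < threshold_HU
  comp <- label_components(frozen)
  sizes <- if (comp$n > 0) tabulate(comp$labels[comp$labels > 0], comp$n)
           else integer(0)
  list(state = ifelse(frozen, "frozen", "vitrified"),
       frozen_components = data.frame(component = seq_len(comp$n),
                                      n_voxels = sizes),
       threshold_HU = threshold_HU)
}

# 6-connected component labeling by iterative minimum-label propagation over
# the masked voxel list; cheap for the sparse masks this package produces.
label_components <- function(mask) {
  idx <- which(mask)
  nv <- length(idx)
  if (nv == 0L) return(list(labels = array(0L, dim(mask)), n = 0L))
  d <- dim(mask)
  rank <- array(0L, d)
  rank[idx] <- seq_len(nv)
  ai <- arrayInd(idx, d)
  pairs <- NULL
  for (ax in 1:3) {
    nb <- ai
    nb[, ax] <- nb[, ax] + 1L
    ok <- nb[, ax] <= d[ax]
    if (!any(ok)) next
    nbl <- rank[nb[ok, , drop = FALSE]]
    keep <- nbl > 0L
    if (any(keep))
      pairs <- rbind(pairs, cbind(which(ok)[keep], nbl[keep]))
  }
  lab <- seq_len(nv)
  if (!is.null(pairs)) {
    repeat {
      # propagate the smaller label across each adjacency, both directions
      m1 <- tapply(lab[pairs[, 2]], pairs[, 1], min)
      m2 <- tapply(lab[pairs[, 1]], pairs[, 2], min)
      new <- lab
      i1 <- as.integer(names(m1)); new[i1] <- pmin(new[i1], m1)
      i2 <- as.integer(names(m2)); new[i2] <- pmin(new[i2], m2)
      if (identical(new, lab)) break
      lab <- new
    }
  }
  lab <- match(lab, sort(unique(lab)))
  out <- array(0L, d)
  out[idx] <- lab
  list(labels = out, n = max(lab))
}

#' Detect low-radiodensity discontinuities (crack/ice candidates)
#'
#' Flags connected components of anomalously low-HU voxels - the signature of
#' ice crystallization pockets or cracks through vitrified material - and
#' scores their spatial extent and elongation. A voxel is a candidate when
#' its HU falls below `low_hu` (default: median minus 4 robust SDs of the
#' whole volume). Components whose maximum bounding-box extent reaches
#' `min_extent_mm` are reported with their voxel count, extent and an
#' elongation ratio (extent over thickness; large values indicate planar or
#' linear structures rather than blobs). A homogeneous volume yields an
#' empty report.
#'
#' @param v an `hu_volume`.
#' @param min_extent_mm minimum reported extent, mm.
#' @param low_hu optional explicit low-HU threshold.
#' @return data frame with one row per candidate: `component`, `n_voxels`,
#'   `extent_mm`, `thickness_mm`, `elongation`, `mean_HU`.
#' @export
detect_discontinuities <- function(v, min_extent_mm = 1, low_hu = NULL) {
  stopifnot(inherits(v, "hu_volume"))
  if (is.null(low_hu)) {
    med <- stats::median(v$data)
    rsd <- stats::mad(v$data)
    low_hu <- med - 4 * rsd
  }
  mask <- v$data < low_hu
  comp <- label_components(mask)
  if (comp$n == 0L)
    return(data.frame(component = integer(0), n_voxels = integer(0),
                      extent_mm = numeric(0), thickness_mm = numeric(0),
                      elongation = numeric(0), mean_HU = numeric(0)))
  rows <- lapply(seq_len(comp$n), function(k) {
    ci <- which(comp$labels == k)
    ai <- arrayInd(ci, dim(v$data))
    span <- apply(ai, 2, function(z) diff(range(z)) + 1L)
    data.frame(component = k, n_voxels = length(ci),
               extent_mm = max(span) * v$voxel_size_mm,
               thickness_mm = min(span) * v$voxel_size_mm,
               elongation = max(span) / min(span),
               mean_HU = mean(v$data[ci]))
  })
  out <- do.call(rbind, rows)
  out <- out[out$extent_mm >= min_extent_mm, , drop = FALSE]
  rownames(out) <- NULL
  out
}
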