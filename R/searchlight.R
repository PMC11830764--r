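# Cubic searchlights (radius 2 -> 5x5x5 = 125 voxels when fully interior),
# group-level one-tailed statistics with FDR over all retained centers,
# and conjunction / disjunction region logic.

#' Enumerate searchlight centers and their member voxels
#'
#' Members are all voxels within the cube of the given Chebyshev radius
#' around the center, intersected with the mask; centers themselves must
#' be in the mask and are retained only if they keep at least
#' `min_members` members (the default, 63, is just over half a full
#' 125-voxel cube).
#'
#' @param mask Logical 3D array.
#' @param radius Cube radius in voxels (2 -> 5x5x5).
#' @param min_members Minimum member count for a center to be retained.
#' @return List with `centers` (n x 3 integer matrix of 1-based voxel
#'   coordinates), `members` (list of linear voxel index vectors) and
#'   `geometry` (shape, radius, min_members, mask).
#' @export
searchlight_centers <- function(mask, radius = 2L, min_members = 63L) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L, is.logical(mask))
  shape <- dim(mask)
  cand <- which(mask, arr.ind = TRUE)
  off <- as.matrix(expand.grid(dx = -radius:radius, dy = -radius:radius,
                               dz = -radius:radius))
  n_off <- nrow(off)
  memmat <- matrix(NA_integer_, nrow(cand), n_off)
  for (j in seq_len(n_off)) {
    x <- cand[, 1L] + off[j, 1L]
    y <- cand[, 2L] + off[j, 2L]
    z <- cand[, 3L] + off[j, 3L]
    ok <- x >= 1L & x <= shape[1L] & y >= 1L & y <= shape[2L] &
      z >= 1L & z <= shape[3L]
    li <- rep(NA_integer_, length(ok))
    li[ok] <- (z[ok] - 1L) * shape[1L] * shape[2L] + (y[ok] - 1L) * shape[1L] + x[ok]
    li[ok][!mask[li[ok]]] <- NA_integer_
    memmat[, j] <- li
  }
  counts <- rowSums(!is.na(memmat))
  keep <- which(counts >= min_members)
  members <- lapply(keep, function(i) {
    m <- memmat[i, ]
    sort(m[!is.na(m)])
  })
  list(
    centers = cand[keep, , drop = FALSE],
    members = members,
    geometry = list(shape = shape, radius = as.integer(radius),
                    min_members = as.integer(min_members), mask = mask)
  )
}

#' Run code contrasts in every searchlight
#'
#' For each retained center, patterns are restricted to the member
#' voxels, leave-one-wedding-out templates are rebuilt, and every
#' requested code contrast is evaluated at participant scope.
#'
#' @param data A `pattern_dataset` (needs a layout, or supply `mask`).
#' @param codes Codes to evaluate (default: all five).
#' @param mask Logical 3D array; defaults to the full layout grid.
#' @param radius,min_members See [searchlight_centers()].
#' @return A `searchlight_result`: list with `values` (participants x
#'   centers x codes array), `centers`, `members`, `codes`, `geometry`.
#' @export
run_searchlights <- function(data, codes = code_names(), mask = NULL,
                             radius = 2L, min_members = 63L) {
  stopifnot(inherits(data, "pattern_dataset"))
  codes <- match.arg(codes, code_names(), several.ok = TRUE)
  if (is.null(mask)) {
    if (is.null(data$layout)) stop("supply a mask or a dataset with a layout")
    mask <- array(TRUE, data$layout$shape)
  }
  sl <- searchlight_centers(mask, radius, min_members)
  if (length(sl$members) == 0L) stop("no retained searchlight centers")
  frame <- comparison_frame(data$schedule)
  pre <- .sim_precompute(data$design, frame, data$schedule)
  W <- do.call(cbind, lapply(codes, function(cd)
    contrast_weight_matrix(frame, cd, "participant")))
  n_p <- length(data$patterns)
  n_c <- length(sl$members)
  vals <- array(NA_real_, c(n_p, n_c, length(codes)),
                dimnames = list(NULL, NULL, codes))
  for (j in seq_len(n_c)) {
    vox <- sl$members[[j]]
    for (p in seq_len(n_p)) {
      sims <- .center_sims(data$patterns[[p]], vox, pre)
      vals[p, j, ] <- crossprod(W, sims)
    }
  }
  structure(list(values = vals, centers = sl$centers, members = sl$members,
                 codes = codes, geometry = sl$geometry),
            class = "searchlight_result")
}

#' @export
print.searchlight_result <- function(x, ...) {
  cat("searchlight_result:", dim(x$values)[1L], "participants x",
      dim(x$values)[2L], "centers x", length(x$codes), "codes\n")
  invisible(x)
}

#' Group-level statistic map
#'
#' One-sample t against zero per center across participants, one-tailed
#' (`greater`) p, and FDR q over all retained centers. Centers with zero
#' variance across participants (or undefined contrasts) are flagged
#' missing and excluded from the FDR family rather than assigned p = 1,
#' to keep the family size honest.
#'
#' @param values A `searchlight_result`, or a participants x centers
#'   matrix.
#' @param code Which code to map (when `values` is a result object).
#' @param centers n x 3 coordinate matrix (when `values` is a matrix).
#' @param tail Only `"greater"` is used by the pipeline (contrast > 0).
#' @param method FDR procedure, Benjamini-Hochberg by default.
#' @param geometry Optional geometry list to attach.
#' @return A `stat_map` data frame: x, y, z, n, mean, sd, t, p, q, ok.
#' @export
group_map <- function(values, code = NULL, centers = NULL,
                      tail = c("greater"), method = c("BH", "BY"),
                      geometry = NULL) {
  tail <- match.arg(tail)
  method <- match.arg(method)
  if (inherits(values, "searchlight_result")) {
    if (is.null(code)) stop("give the code to map")
    centers <- values$centers
    geometry <- values$geometry
    values <- values$values[, , code, drop = TRUE]
    if (is.null(dim(values))) values <- matrix(values, ncol = 1L)
  }
  stopifnot(is.matrix(values))
  n <- nrow(values)
  if (n < 3L) stop("need at least 3 participants")
  if (is.null(centers)) {
    centers <- cbind(seq_len(ncol(values)), 1L, 1L)
  }
  m <- colMeans(values)
  s <- sqrt(colSums(sweep(values, 2L, m)^2) / (n - 1L))
  ok <- is.finite(m) & is.finite(s) & s > 0
  t_stat <- ifelse(ok, m / (s / sqrt(n)), NA_real_)
  p <- ifelse(ok, stats::pt(t_stat, df = n - 1L, lower.tail = FALSE), NA_real_)
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = method)
  out <- data.frame(x = centers[, 1L], y = centers[, 2L], z = centers[, 3L],
                    n = n, mean = m, sd = s, t = t_stat, p = p, q = q,
                    ok = ok)
  attr(out, "geometry") <- geometry
  attr(out, "tail") <- tail
  attr(out, "fdr_method") <- method
  class(out) <- c("stat_map", "data.frame")
  out
}

.check_same_geometry <- function(a, b) {
  if (nrow(a) != nrow(b) ||
      !all(a$x == b$x & a$y == b$y & a$z == b$z)) {
    stop("stat maps have mismatching searchlight geometry")
  }
}

.region_mask <- function(map, sel, name) {
  out <- data.frame(x = map$x, y = map$y, z = map$z)[which(sel), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "geometry") <- attr(map, "geometry")
  attr(out, "region_name") <- name
  class(out) <- c("region_mask", "data.frame")
  out
}

#' Threshold a stat map into a region mask
#'
#' @param map A `stat_map`.
#' @param q_thresh FDR threshold.
#' @return A `region_mask` of significant centers.
#' @export
threshold_map <- function(map, q_thresh = 0.05) {
  sel <- !is.na(map$q) & map$q < q_thresh
  .region_mask(map, sel, paste0("q<", q_thresh))
}

#' Conjunction of two code maps
#'
#' Centers FDR-significant for both codes.
#'
#' @param mapA,mapB `stat_map`s over the same centers.
#' @param q_thresh FDR threshold applied to both maps.
#' @return A `region_mask`.
#' @export
conjunction <- function(mapA, mapB, q_thresh = 0.05) {
  .check_same_geometry(mapA, mapB)
  sel <- !is.na(mapA$q) & mapA$q < q_thresh &
    !is.na(mapB$q) & mapB$q < q_thresh
  .region_mask(mapA, sel, "conjunction")
}

#' Disjunction (exclusive) map
#'
#' Centers FDR-significant for the primary code while failing even a
#' liberal uncorrected threshold for the excluded code (one-tailed p
#' above `p_liberal`, same tail convention as the primary maps).
#'
#' @param map_primary,map_excluded `stat_map`s over the same centers.
#' @param q_thresh FDR threshold for the primary map.
#' @param p_liberal Uncorrected threshold the excluded code must fail.
#' @return A `region_mask`.
#' @export
disjunction <- function(map_primary, map_excluded, q_thresh = 0.05,
                        p_liberal = 0.1) {
  .check_same_geometry(map_primary, map_excluded)
  sel <- !is.na(map_primary$q) & map_primary$q < q_thresh &
    !is.na(map_excluded$p) & map_excluded$p > p_liberal
  .region_mask(map_primary, sel, "disjunction")
}

#' Write a stat map as tidy CSV plus NIfTI volumes
#'
#' @param map A `stat_map` with geometry.
#' @param prefix Output path prefix; writes `<prefix>.csv` and
#'   `<prefix>_<stat>.nii` for t and q.
#' @return Invisibly, written paths.
#' @export
write_stat_map <- function(map, prefix) {
  files <- paste0(prefix, ".csv")
  utils::write.csv(as.data.frame(map), files, row.names = FALSE)
  geom <- attr(map, "geometry")
  if (!is.null(geom)) {
    for (stat in c("t", "q")) {
      vol <- array(NA_real_, geom$shape)
      vol[cbind(map$x, map$y, map$z)] <- map[[stat]]
      vol[is.na(vol)] <- 0
      f <- paste0(prefix, "_", stat, ".nii")
      write_nifti(vol, f, datatype = "float64")
      files <- c(files, f)
    }
  }
  invisible(files)
}

#' Write a region mask as CSV and NIfTI
#'
#' @param region A `region_mask`.
#' @param prefix Output path prefix.
#' @return Invisibly, written paths.
#' @export
write_region_mask <- function(region, prefix) {
  csv <- paste0(prefix, ".csv")
  utils::write.csv(as.data.frame(region), csv, row.names = FALSE)
  files <- csv
  geom <- attr(region, "geometry")
  if (!is.null(geom)) {
    vol <- array(0L, geom$shape)
    if (nrow(region)) vol[cbind(region$x, region$y, region$z)] <- 1L
    f <- paste0(prefix, ".nii")
    write_nifti(vol, f, datatype = "int32")
    files <- c(files, f)
  }
  invisible(files)
}

#' Read a region mask written by [write_region_mask()]
#'
#' @param csv Path to the region CSV.
#' @param geometry Optional geometry list to attach.
#' @return A `region_mask`.
#' @export
read_region_mask <- function(csv, geometry = NULL) {
  out <- utils::read.csv(csv)
  if (!all(c("x", "y", "z") %in% names(out))) {
    stop("region mask CSV must have x, y, z columns")
  }
  attr(out, "geometry") <- geometry
  class(out) <- c("region_mask", "data.frame")
  out
}
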