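# Synthetic multivoxel pattern generator. Patterns are generated directly
# at the ritual (stage) level -- one vector per wedding x stage -- which is
# the granularity the analysis operates on; there is no TR-level time
# series and no HRF model.

.REGION_NAMES <- c("schema", "path", "rotated_current", "current_only",
                   "rotated_only")
.REGION_BASIS_K <- c(2L, 4L, 6L, 6L, 6L)  # vectors per region label 1..5

#' Region layout for the synthetic volume
#'
#' Labels: 0 background (noise only), 1 schema region, 2 path region,
#' 3 rotated + current-ritual region, 4 current-ritual-only region,
#' 5 rotated-only region. Each block must be at least 5 voxels wide in
#' every dimension so a full 5x5x5 searchlight fits inside it.
#'
#' @param grid Integer triple, the voxel grid shape.
#' @param blocks List of `list(label =, corner =, size =)` cuboid blocks
#'   (1-based corners). The default places the five code regions on a
#'   20x20x20 grid with >= 6-voxel gaps so searchlights never straddle
#'   two regions.
#' @return A `region_layout`: list with `shape`, `labels` (integer array)
#'   and `blocks`.
#' @export
region_layout <- function(grid = c(20L, 20L, 20L), blocks = NULL) {
  grid <- as.integer(grid)
  stopifnot(length(grid) == 3L, all(grid >= 1L))
  if (is.null(blocks)) {
    blocks <- list(
      list(label = 1L, corner = c(3L, 3L, 3L),    size = c(5L, 5L, 5L)),
      list(label = 2L, corner = c(3L, 3L, 14L),   size = c(5L, 5L, 5L)),
      list(label = 3L, corner = c(3L, 14L, 3L),   size = c(5L, 5L, 5L)),
      list(label = 4L, corner = c(14L, 3L, 3L),   size = c(5L, 5L, 5L)),
      list(label = 5L, corner = c(14L, 14L, 14L), size = c(5L, 5L, 5L))
    )
  }
  labels <- array(0L, grid)
  for (b in blocks) {
    lab <- as.integer(b$label)
    if (!lab %in% 1:5) stop("region label must be in 1..5, got ", lab)
    corner <- as.integer(b$corner); size <- as.integer(b$size)
    if (any(size < 5L)) {
      stop("region ", lab, " too small for a searchlight: every dimension ",
           "must be >= 5 voxels")
    }
    hi <- corner + size - 1L
    if (any(corner < 1L) || any(hi > grid)) {
      stop("region ", lab, " does not fit inside the grid")
    }
    sub <- labels[corner[1]:hi[1], corner[2]:hi[2], corner[3]:hi[3]]
    if (any(sub != 0L)) stop("region ", lab, " overlaps another region")
    labels[corner[1]:hi[1], corner[2]:hi[2], corner[3]:hi[3]] <- lab
  }
  structure(list(shape = grid, labels = labels, blocks = blocks),
            class = "region_layout")
}

#' Generator configuration
#'
#' Defaults describe the simulated analogue of the study: 40 participants,
#' the 12-wedding interleaved day-2 schedule, unit-norm code components of
#' amplitude 8 against unit per-voxel noise (about 0.7 signal SD per voxel
#' inside a 125-voxel region), per-wedding multiplicative jitter (SD 0.5)
#' on the schema component, and memory scores coupled to that jitter with
#' slope 2 against unit score noise.
#'
#' @param n_participants Number of simulated participants (>= 2).
#' @param schedule A `wedding_schedule`; defaults to the day-2 schedule.
#' @param layout A `region_layout`.
#' @param beta_schema,beta_path,beta_ritual,beta_rotated Non-negative code
#'   amplitudes, in pattern units (the basis vectors are unit norm).
#' @param noise_sd Per-voxel Gaussian noise SD.
#' @param amplitude_jitter_sd SD of the per-wedding multiplicative jitter
#'   on the schema amplitude: `a_w = max(0, 1 + N(0, sd))`.
#' @param gamma_details,gamma_rituals Slopes coupling memory scores to the
#'   per-wedding schema amplitude `a_w`.
#' @param behavior_noise_sd SD of the additive noise on memory scores.
#' @param base_details,base_rituals Baseline memory scores before rounding.
#' @param carryover_sign -1 plants the rotated ("photo-negative")
#'   preceding-ritual trace; +1 plants a non-rotated carryover instead.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_participants = 40L,
                             schedule = NULL,
                             layout = region_layout(),
                             beta_schema = 8, beta_path = 8,
                             beta_ritual = 8, beta_rotated = 8,
                             noise_sd = 1,
                             amplitude_jitter_sd = 0.5,
                             gamma_details = 2, gamma_rituals = 1,
                             behavior_noise_sd = 1,
                             base_details = 6, base_rituals = 3,
                             carryover_sign = -1,
                             seed = 1L) {
  if (is.null(schedule)) schedule <- make_schedule(2L, seed = seed)
  n_participants <- as.integer(n_participants)
  if (n_participants < 2L) stop("n_participants must be >= 2")
  betas <- c(beta_schema, beta_path, beta_ritual, beta_rotated)
  if (any(betas < 0)) stop("code amplitudes must be non-negative")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (!carryover_sign %in% c(-1, 1)) stop("carryover_sign must be -1 or +1")
  structure(list(
    n_participants = n_participants, schedule = schedule, layout = layout,
    beta_schema = beta_schema, beta_path = beta_path,
    beta_ritual = beta_ritual, beta_rotated = beta_rotated,
    noise_sd = noise_sd, amplitude_jitter_sd = amplitude_jitter_sd,
    gamma_details = gamma_details, gamma_rituals = gamma_rituals,
    behavior_noise_sd = behavior_noise_sd,
    base_details = base_details, base_rituals = base_rituals,
    carryover_sign = carryover_sign, seed = as.integer(seed)
  ), class = "generator_config")
}

#' Assemble a pattern dataset from raw pieces
#'
#' @param patterns List (one element per participant) of voxel x volume
#'   matrices, volumes ordered wedding-major then stage.
#' @param schedule The `wedding_schedule` the volumes follow.
#' @param layout Optional `region_layout` (required for searchlights).
#' @param amplitudes Optional participant x wedding matrix of schema
#'   amplitudes (filled by the generator).
#' @return A `pattern_dataset`.
#' @export
pattern_dataset <- function(patterns, schedule, layout = NULL,
                            amplitudes = NULL) {
  design <- volume_design(schedule)
  n_vol <- nrow(design)
  for (p in seq_along(patterns)) {
    if (!is.matrix(patterns[[p]]) || ncol(patterns[[p]]) != n_vol) {
      stop("participant ", p, ": patterns must be a voxel x ", n_vol,
           " matrix (one column per wedding-stage volume)")
    }
  }
  if (!is.null(layout) && nrow(patterns[[1L]]) != prod(layout$shape)) {
    stop("pattern rows (", nrow(patterns[[1L]]),
         ") do not match the layout grid (", prod(layout$shape), " voxels)")
  }
  structure(list(patterns = patterns, design = design, schedule = schedule,
                 layout = layout, amplitudes = amplitudes),
            class = "pattern_dataset")
}

#' @export
print.pattern_dataset <- function(x, ...) {
  cat("pattern_dataset:", length(x$patterns), "participants,",
      nrow(x$schedule), "weddings x 3 stages,",
      nrow(x$patterns[[1L]]), "voxels\n")
  invisible(x)
}

.region_voxels <- function(layout) {
  lapply(1:5, function(lab) which(as.vector(layout$labels) == lab))
}

# Orthonormal basis (columns) over n voxels via QR of a Gaussian draw.
.orthonormal_basis <- function(n, k) {
  qr.Q(qr(matrix(stats::rnorm(n * k), n, k)))
}

#' Generate planted-code multivoxel patterns
#'
#' Each participant gets fixed unit-norm, mutually orthogonal basis
#' vectors per region (Gram-Schmidt on Gaussian draws) so planted
#' components have analytically computable overlaps. The pattern of
#' wedding `w` at stage `s`, restricted to each region, is
#' `a_w * beta_schema * u_schema` (region 1), `beta_path * u_path`
#' (region 2), `beta_ritual * u_ritual(current)` (regions 3 and 4), and,
#' for stages 3 and 4, `carryover_sign * beta_rotated *
#' u_ritual(preceding)` (regions 3 and 5); Gaussian noise is added
#' everywhere. `a_w = max(0, 1 + jitter)` is the per-wedding schema
#' amplitude that the behavior generator couples to.
#'
#' @param config A `generator_config`.
#' @return A `pattern_dataset` carrying the amplitude matrix and config.
#' @export
generate_patterns <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  layout <- config$layout
  design <- volume_design(config$schedule)
  n_vox <- prod(layout$shape)
  n_vol <- nrow(design)
  n_wed <- nrow(config$schedule)
  regions <- .region_voxels(layout)
  for (lab in 1:5) {
    nv <- length(regions[[lab]])
    if (nv > 0L && nv < 125L) {
      stop("region ", lab, " too small for a searchlight (", nv,
           " voxels, need >= 125)")
    }
  }
  set.seed(config$seed)
  ritual_names <- .RITUAL_TABLE$name
  prev_ritual <- ifelse(design$stage >= 3L,
                        mapply(function(p, s) path_rituals(p)[s - 2L],
                               design$path, design$stage),
                        NA_character_)
  patterns <- vector("list", config$n_participants)
  amplitudes <- matrix(NA_real_, config$n_participants, n_wed)
  for (p in seq_len(config$n_participants)) {
    basis <- vector("list", 5L)
    for (lab in 1:5) {
      nv <- length(regions[[lab]])
      if (nv > 0L) basis[[lab]] <- .orthonormal_basis(nv, .REGION_BASIS_K[lab])
    }
    a <- pmax(0, 1 + stats::rnorm(n_wed, 0, config$amplitude_jitter_sd))
    amplitudes[p, ] <- a
    X <- matrix(stats::rnorm(n_vox * n_vol, 0, config$noise_sd), n_vox, n_vol)
    for (v in seq_len(n_vol)) {
      w <- design$wedding_id[v]
      sch_i <- match(design$schema[v], .SCHEMAS)
      path_i <- match(design$path[v], .PATH_TABLE$id)
      rit_i <- match(design$ritual[v], ritual_names)
      if (length(regions[[1L]])) {
        X[regions[[1L]], v] <- X[regions[[1L]], v] +
          a[w] * config$beta_schema * basis[[1L]][, sch_i]
      }
      if (length(regions[[2L]])) {
        X[regions[[2L]], v] <- X[regions[[2L]], v] +
          config$beta_path * basis[[2L]][, path_i]
      }
      for (lab in c(3L, 4L)) {
        if (length(regions[[lab]])) {
          X[regions[[lab]], v] <- X[regions[[lab]], v] +
            config$beta_ritual * basis[[lab]][, rit_i]
        }
      }
      if (design$stage[v] >= 3L) {
        prev_i <- match(prev_ritual[v], ritual_names)
        for (lab in c(3L, 5L)) {
          if (length(regions[[lab]])) {
            X[regions[[lab]], v] <- X[regions[[lab]], v] +
              config$carryover_sign * config$beta_rotated *
                basis[[lab]][, prev_i]
          }
        }
      }
    }
    patterns[[p]] <- X
  }
  out <- pattern_dataset(patterns, config$schedule, layout, amplitudes)
  out$config <- config
  out
}

#' Generate memory scores coupled to the planted schema amplitude
#'
#' `details_score = round(base_details + gamma_details * a_w + noise)` and
#' analogously for `rituals_score`. Coupling acts only through the schema
#' amplitude jitter, so brain-behavior nulls for the other codes are true
#' by construction.
#'
#' @param config The `generator_config` used for `data`.
#' @param data The `pattern_dataset` returned by [generate_patterns()]
#'   (supplies the per-wedding amplitudes).
#' @return Data frame with `participant`, `wedding_id`, `details_score`,
#'   `rituals_score`.
#' @export
generate_behavior <- function(config, data) {
  stopifnot(inherits(config, "generator_config"),
            inherits(data, "pattern_dataset"))
  if (is.null(data$amplitudes)) {
    stop("data carries no schema amplitudes; generate it with generate_patterns()")
  }
  if (!is.null(data$config) && data$config$seed != config$seed) {
    stop("config seed does not match the seed the dataset was generated with")
  }
  a <- data$amplitudes
  n_p <- nrow(a); n_w <- ncol(a)
  set.seed(config$seed + 1000003L)
  details <- round(config$base_details + config$gamma_details * a +
                     matrix(stats::rnorm(n_p * n_w, 0, config$behavior_noise_sd),
                            n_p, n_w))
  rituals_s <- round(config$base_rituals + config$gamma_rituals * a +
                       matrix(stats::rnorm(n_p * n_w, 0, config$behavior_noise_sd),
                              n_p, n_w))
  data.frame(
    participant = rep(seq_len(n_p), each = n_w),
    wedding_id = rep(seq_len(n_w), n_p),
    details_score = as.vector(t(details)),
    rituals_score = as.vector(t(rituals_s))
  )
}

#' Write a synthetic dataset to disk
#'
#' Per participant: a 4D NIfTI of patterns (volumes wedding-major then
#' stage) and an events TSV sidecar (`volume_index` is 0-based). Shared:
#' `mask.nii`, `region_labels.nii`, `behavior.tsv`, `schedule.tsv` and
#' `config.yaml`. Everything round-trips through [read_dataset()].
#'
#' @param data A `pattern_dataset` with a layout.
#' @param behavior Behavior table from [generate_behavior()] (or NULL).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the list of written files.
#' @export
write_dataset <- function(data, behavior, out_dir) {
  stopifnot(inherits(data, "pattern_dataset"))
  if (is.null(data$layout)) stop("dataset has no region layout")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  shape <- data$layout$shape
  files <- character(0)
  for (p in seq_along(data$patterns)) {
    nii <- file.path(out_dir, sprintf("sub-%02d_patterns.nii", p))
    arr <- array(data$patterns[[p]], c(shape, ncol(data$patterns[[p]])))
    write_nifti(arr, nii, datatype = "float64")
    ev <- file.path(out_dir, sprintf("sub-%02d_events.tsv", p))
    events <- data.frame(volume_index = data$design$volume - 1L,
                         data$design[, c("wedding_id", "stage", "schema",
                                         "path", "ritual")])
    utils::write.table(events, ev, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, nii, ev)
  }
  mask_f <- file.path(out_dir, "mask.nii")
  write_nifti(array(1L, shape), mask_f, datatype = "int32")
  lab_f <- file.path(out_dir, "region_labels.nii")
  write_nifti(data$layout$labels, lab_f, datatype = "int32")
  sch_f <- file.path(out_dir, "schedule.tsv")
  write_schedule_tsv(data$schedule, sch_f)
  files <- c(files, mask_f, lab_f, sch_f)
  if (!is.null(behavior)) {
    beh_f <- file.path(out_dir, "behavior.tsv")
    utils::write.table(behavior, beh_f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, beh_f)
  }
  if (!is.null(data$config)) {
    cfg <- data$config
    scalars <- cfg[!names(cfg) %in% c("schedule", "layout")]
    cfg_f <- file.path(out_dir, "config.yaml")
    yaml::write_yaml(c(scalars, list(grid = as.integer(shape))), cfg_f)
    files <- c(files, cfg_f)
  }
  invisible(files)
}
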