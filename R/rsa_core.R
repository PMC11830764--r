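# Leave-one-wedding-out template RSA: 12 (ritual x schema) template
# patterns averaged over all weddings but one, correlated with the three
# stage patterns of the held-out wedding -> 36 labeled comparisons per
# held-out wedding.

.template_cells <- function() {
  out <- expand.grid(schema = .SCHEMAS, ritual = .RITUAL_TABLE$name,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[, c("ritual", "schema")]
  out$stage <- ritual_stage(out$ritual)
  out$path <- mapply(path_of, out$ritual, out$schema)
  out$cell <- seq_len(nrow(out))
  out$name <- paste(out$ritual, out$schema, sep = "-")
  rownames(out) <- NULL
  out
}

# Labels of the 12 template cells against one held-out (path, stage) cell.
.comparison_labels <- function(cells, heldout_path, heldout_stage) {
  hp <- path_rituals(heldout_path)
  heldout_ritual <- hp[heldout_stage - 1L]
  heldout_schema <- .PATH_TABLE$schema[.PATH_TABLE$id == heldout_path]
  same_schema <- cells$schema == heldout_schema
  on_held_path <- cells$ritual %in% hp
  path_relation <- ifelse(cells$path == heldout_path, 1L,
                     ifelse(same_schema, 2L,
                       ifelse(on_held_path, 4L, 3L)))
  pred <- if (heldout_stage > 2L) hp[heldout_stage - 2L] else NA_character_
  succ <- if (heldout_stage < 4L) hp[heldout_stage] else NA_character_
  template_pred <- ifelse(cells$stage >= 3L,
                          mapply(function(p, s) path_rituals(p)[s - 2L],
                                 cells$path, cells$stage),
                          NA_character_)
  heldout_pred <- if (heldout_stage >= 3L) hp[heldout_stage - 2L] else NA_character_
  data.frame(
    template_ritual = cells$ritual,
    template_schema = cells$schema,
    template_stage = cells$stage,
    template_path = cells$path,
    cell = cells$cell,
    heldout_stage = heldout_stage,
    heldout_ritual = heldout_ritual,
    heldout_schema = heldout_schema,
    heldout_path = heldout_path,
    stage_relation = ifelse(cells$stage == heldout_stage, "within", "across"),
    path_relation = path_relation,
    same_schema = same_schema,
    same_ritual = cells$ritual == heldout_ritual,
    same_preceding = !is.na(heldout_pred) & !is.na(template_pred) &
      template_pred == heldout_pred,
    template_is_predecessor = !is.na(pred) & cells$ritual == pred,
    template_is_successor = !is.na(succ) & cells$ritual == succ,
    stringsAsFactors = FALSE
  )
}

#' Labeled comparison structure of a schedule
#'
#' For every held-out wedding, the 36 (12 templates x 3 held-out stages)
#' comparisons with the full sorting taxonomy: stage relation
#' (within/across), path relation (1 same path; 2 different path, same
#' schema; 3 different schema, template ritual not on the held-out path;
#' 4 different schema, template ritual on the held-out path), same
#' preceding ritual, and predecessor/successor match flags (ritual
#' identity only; schema ignored).
#'
#' @param schedule A `wedding_schedule`.
#' @return Data frame with `36 * nrow(schedule)` rows; no similarities yet.
#' @export
comparison_frame <- function(schedule) {
  cells <- .template_cells()
  out <- vector("list", nrow(schedule) * 3L)
  k <- 0L
  for (i in seq_len(nrow(schedule))) {
    for (st in 2:4) {
      k <- k + 1L
      lab <- .comparison_labels(cells, schedule$path[i], st)
      lab <- cbind(held_out = schedule$wedding_id[i], lab)
      out[[k]] <- lab
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Leave-one-wedding-out template patterns
#'
#' One mean pattern per (ritual, schema) cell, averaged over all weddings
#' except `held_out`, restricted to `voxels`.
#'
#' @param data A `pattern_dataset`.
#' @param held_out Wedding id to leave out.
#' @param voxels Integer voxel indices (default: all voxels).
#' @param participant Which participant's patterns to use.
#' @return Voxel x 12 matrix, columns named `<ritual>-<schema>`, with an
#'   `n_contributing` attribute.
#' @export
build_templates <- function(data, held_out, voxels = NULL, participant = 1L) {
  stopifnot(inherits(data, "pattern_dataset"))
  X <- data$patterns[[participant]]
  if (is.null(voxels)) voxels <- seq_len(nrow(X))
  design <- data$design
  cells <- .template_cells()
  out <- matrix(NA_real_, length(voxels), nrow(cells),
                dimnames = list(NULL, cells$name))
  n_contrib <- integer(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sel <- design$schema == cells$schema[i] & design$ritual == cells$ritual[i] &
      design$wedding_id != held_out
    if (!any(sel)) {
      stop("unestimable template: no contributing wedding for cell ",
           cells$name[i], " with wedding ", held_out, " held out")
    }
    out[, i] <- rowMeans(X[voxels, design$volume[sel], drop = FALSE])
    n_contrib[i] <- sum(sel)
  }
  attr(out, "n_contributing") <- stats::setNames(n_contrib, cells$name)
  out
}

#' Pearson pattern similarity
#'
#' @param a,b Voxel vectors of equal length (>= 3), non-constant. A
#'   constant pattern raises an error rather than returning NA, because it
#'   signals an upstream masking bug.
#' @return Pearson's r.
#' @export
pattern_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("patterns differ in length")
  if (length(a) < 3L) stop("patterns must have at least 3 voxels")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("undefined similarity: constant pattern")
  }
  stats::cor(a, b)
}

# Precompute, for one schedule, the machinery of the fast similarity path:
#  A:    volume x (held-out block x cell) template averaging weights
#  ridx: for each comparison row, the linear index into the
#        cor(templates, volumes) matrix (n_cells*n_wed x n_vol)
.sim_precompute <- function(design, frame, schedule) {
  cells <- .template_cells()
  n_cell <- nrow(cells)
  n_wed <- nrow(schedule)
  n_vol <- nrow(design)
  A <- matrix(0, n_vol, n_cell * n_wed)
  for (b in seq_len(n_wed)) {
    w <- schedule$wedding_id[b]
    for (i in seq_len(n_cell)) {
      sel <- design$schema == cells$schema[i] &
        design$ritual == cells$ritual[i] & design$wedding_id != w
      if (!any(sel)) {
        stop("unestimable template: no contributing wedding for cell ",
             cells$name[i], " with wedding ", w, " held out")
      }
      A[design$volume[sel], (b - 1L) * n_cell + i] <- 1 / sum(sel)
    }
  }
  block <- match(frame$held_out, schedule$wedding_id)
  vol <- design$volume[match(paste(frame$held_out, frame$heldout_stage),
                             paste(design$wedding_id, design$stage))]
  trow <- (block - 1L) * n_cell + frame$cell
  ridx <- (vol - 1L) * (n_cell * n_wed) + trow
  list(A = A, ridx = ridx, n_templates = n_cell * n_wed)
}

# All 36*n_wed similarities for one participant over one voxel set.
.center_sims <- function(X, voxels, pre) {
  V <- X[voxels, , drop = FALSE]
  Tm <- V %*% pre$A
  R <- suppressWarnings(stats::cor(Tm, V))
  R[pre$ridx]
}

#' Compute every labeled template comparison
#'
#' Loops over every held-out wedding and participant, producing the 36
#' similarity records per held-out wedding with the full label taxonomy.
#'
#' @param data A `pattern_dataset`.
#' @param voxels Integer voxel indices (default: all voxels).
#' @return A `comparison_table` data frame: [comparison_frame()] columns
#'   plus `participant` and `similarity`.
#' @export
compare_all <- function(data, voxels = NULL) {
  stopifnot(inherits(data, "pattern_dataset"))
  if (is.null(voxels)) voxels <- seq_len(nrow(data$patterns[[1L]]))
  if (length(voxels) < 3L) stop("need at least 3 voxels")
  frame <- comparison_frame(data$schedule)
  pre <- .sim_precompute(data$design, frame, data$schedule)
  n_p <- length(data$patterns)
  out <- vector("list", n_p)
  for (p in seq_len(n_p)) {
    sims <- .center_sims(data$patterns[[p]], voxels, pre)
    if (anyNA(sims)) {
      stop("undefined similarity for participant ", p,
           ": constant pattern or template over the voxel set")
    }
    out[[p]] <- cbind(participant = p, frame, similarity = sims)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' Same-preceding-ritual flag for two template cells
#'
#' TRUE iff both cells sit at stage 3 or 4 and the rituals immediately
#' preceding them on their paths are identical (e.g. torch-North and
#' coin-South are both preceded by flower). Stage-2 cells have no
#' analyzed predecessor and return FALSE.
#'
#' @param template_ritual,template_schema First cell.
#' @param heldout_ritual,heldout_schema Second cell.
#' @return Logical flag.
#' @export
label_same_preceding <- function(template_ritual, template_schema,
                                 heldout_ritual, heldout_schema) {
  s1 <- ritual_stage(template_ritual)
  s2 <- ritual_stage(heldout_ritual)
  if (s1 == 2L || s2 == 2L) return(FALSE)
  p1 <- path_rituals(path_of(template_ritual, template_schema))
  p2 <- path_rituals(path_of(heldout_ritual, heldout_schema))
  p1[s1 - 2L] == p2[s2 - 2L]
}

#' Write a comparison table as CSV
#'
#' @param table A `comparison_table`.
#' @param path Output CSV path.
#' @export
write_comparison_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
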