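# The five scalar code strengths, each a difference of mean Pearson
# similarities over comparison cells selected by the label taxonomy.
# Similarities are averaged raw (no Fisher z); differences of means are
# the statistic throughout.

.CODES <- c("schema", "path", "current_ritual", "rotated_preceding",
            "nonrotated_preceding_upcoming")

#' Code names
#' @return Character vector of the five code identifiers.
#' @export
code_names <- function() .CODES

.mean_diff <- function(sim, pos, neg, code, what) {
  if (!any(pos)) stop(code, ": empty positive cell (", what, ")")
  if (!any(neg)) stop(code, ": empty negative cell (", what, ")")
  mean(sim[pos]) - mean(sim[neg])
}

# Score of one code over one record subset (a participant, or one
# held-out wedding of a participant).
.score_one <- function(sub, code) {
  sim <- sub$similarity
  switch(code,
    schema = .mean_diff(sim, sub$same_schema, !sub$same_schema,
                        code, "schema match"),
    path = .mean_diff(sim, sub$path_relation == 1L, sub$path_relation == 2L,
                      code, "path relation"),
    current_ritual = {
      within <- sub$stage_relation == "within"
      .mean_diff(sim, within & sub$same_ritual, within & !sub$same_ritual,
                 code, "within-stage ritual match")
    },
    rotated_preceding = {
      a <- sub$template_stage == 2L & sub$heldout_stage == 3L
      b <- sub$template_stage == 3L & sub$heldout_stage == 2L
      d1 <- .mean_diff(sim, a & !sub$template_is_predecessor,
                       a & sub$template_is_predecessor,
                       code, "stage-2 template vs held-out stage 3")
      d2 <- .mean_diff(sim, b & !sub$template_is_successor,
                       b & sub$template_is_successor,
                       code, "stage-3 template vs held-out stage 2")
      (d1 + d2) / 2
    },
    nonrotated_preceding_upcoming = -.score_one(sub, "rotated_preceding"),
    stop("unknown code: ", code)
  )
}

#' Code strength from a comparison table
#'
#' Computes the requested contrast per participant (pooling all held-out
#' weddings) or per wedding (each held-out wedding's own 36 records).
#'
#' Codes: `schema` = mean(same-schema) - mean(different-schema) over all
#' comparisons; `path` = mean(same path, same schema) - mean(different
#' path, same schema), different-schema comparisons omitted;
#' `current_ritual` = within-stage same-ritual minus other-ritual;
#' `rotated_preceding` = average of the two cross-stage mismatch-minus-
#' match differences between stages 2 and 3 (positive when the preceding
#' ritual's trace is anticorrelated -- the "photo-negative" signature);
#' `nonrotated_preceding_upcoming` = its sign flip.
#'
#' @param table A `comparison_table` from [compare_all()].
#' @param code One of [code_names()].
#' @param scope `"participant"` or `"wedding"`.
#' @return Data frame with `participant`, optionally `wedding_id`, `code`
#'   and `value`.
#' @export
code_score <- function(table, code = .CODES,
                       scope = c("participant", "wedding")) {
  code <- match.arg(code)
  scope <- match.arg(scope)
  if (nrow(table) == 0L) stop("empty comparison table")
  if (scope == "participant") {
    groups <- split(seq_len(nrow(table)), table$participant)
    out <- data.frame(
      participant = as.integer(names(groups)),
      code = code,
      value = vapply(groups, function(i) .score_one(table[i, ], code),
                     numeric(1)),
      stringsAsFactors = FALSE
    )
  } else {
    key <- interaction(table$participant, table$held_out, drop = TRUE)
    groups <- split(seq_len(nrow(table)), key)
    out <- data.frame(
      participant = vapply(groups, function(i) table$participant[i[1L]], 0L),
      wedding_id = vapply(groups, function(i) table$held_out[i[1L]], 0L),
      code = code,
      value = vapply(groups, function(i) .score_one(table[i, ], code),
                     numeric(1)),
      stringsAsFactors = FALSE
    )
    out <- out[order(out$participant, out$wedding_id), ]
  }
  rownames(out) <- NULL
  out
}

#' @rdname code_score
#' @param ... Passed to [code_score()].
#' @export
schema_score <- function(table, ...) code_score(table, "schema", ...)

#' @rdname code_score
#' @export
path_score <- function(table, ...) code_score(table, "path", ...)

#' @rdname code_score
#' @export
current_ritual_score <- function(table, ...) code_score(table, "current_ritual", ...)

#' @rdname code_score
#' @export
rotated_preceding_score <- function(table, ...) code_score(table, "rotated_preceding", ...)

#' @rdname code_score
#' @export
nonrotated_score <- function(table, ...) code_score(table, "nonrotated_preceding_upcoming", ...)

# Per-record weights reproducing code_score as a linear functional of the
# similarity vector; the fast searchlight path uses these.
.weights_one <- function(sub, code) {
  w <- numeric(nrow(sub))
  add <- function(w, pos, neg) {
    w[pos] <- w[pos] + 1 / sum(pos)
    w[neg] <- w[neg] - 1 / sum(neg)
    w
  }
  switch(code,
    schema = add(w, sub$same_schema, !sub$same_schema),
    path = add(w, sub$path_relation == 1L, sub$path_relation == 2L),
    current_ritual = {
      within <- sub$stage_relation == "within"
      add(w, within & sub$same_ritual, within & !sub$same_ritual)
    },
    rotated_preceding = {
      a <- sub$template_stage == 2L & sub$heldout_stage == 3L
      b <- sub$template_stage == 3L & sub$heldout_stage == 2L
      w <- add(w, a & !sub$template_is_predecessor,
               a & sub$template_is_predecessor)
      w <- add(w, b & !sub$template_is_successor,
               b & sub$template_is_successor)
      w / 2
    },
    nonrotated_preceding_upcoming = -.weights_one(sub, "rotated_preceding"),
    stop("unknown code: ", code)
  )
}

# frame: one participant's comparison frame (no similarity needed).
# Returns n_records x 1 (participant scope) or n_records x n_weddings.
contrast_weight_matrix <- function(frame, code, scope = "participant") {
  if (scope == "participant") {
    matrix(.weights_one(frame, code), ncol = 1L)
  } else {
    weds <- unique(frame$held_out)
    W <- matrix(0, nrow(frame), length(weds),
                dimnames = list(NULL, as.character(weds)))
    for (j in seq_along(weds)) {
      i <- which(frame$held_out == weds[j])
      W[i, j] <- .weights_one(frame[i, ], code)
    }
    W
  }
}

#' Predicted similarity matrix of a code
#'
#' The 12 template cells against the three stage patterns of a held-out
#' wedding on the given path: +1 where the code predicts high similarity,
#' -1 where it predicts low similarity, NA where the comparison is
#' omitted from the contrast.
#'
#' @param code One of [code_names()].
#' @param heldout_path Path of the held-out wedding ("A".."D").
#' @return 12 x 3 matrix (template cells x held-out stages 2:4).
#' @export
predicted_matrix <- function(code = .CODES, heldout_path = "A") {
  code <- match.arg(code)
  cells <- .template_cells()
  out <- matrix(NA_real_, 12L, 3L,
                dimnames = list(cells$name, paste0("stage", 2:4)))
  for (st in 2:4) {
    lab <- .comparison_labels(cells, heldout_path, st)
    lab$similarity <- 0
    w <- .weights_one(lab, code)
    out[, st - 1L] <- ifelse(w > 0, 1, ifelse(w < 0, -1, NA))
  }
  out
}

#' Stage-2 same-successor elevation (prospective-code check)
#'
#' Among within-stage stage-2 comparisons whose template ritual differs
#' from the held-out ritual, compares similarity when the template's
#' successor (under the template schema) matches the held-out wedding's
#' upcoming stage-3 ritual versus when it does not. A prospective
#' (upcoming-ritual) code predicts elevation; a purely retrospective
#' rotated trace predicts none.
#'
#' @param table A `comparison_table`.
#' @return Data frame with `participant` and `value` (match minus
#'   mismatch mean similarity).
#' @export
successor_elevation_score <- function(table) {
  sub <- table[table$heldout_stage == 2L & table$template_stage == 2L &
                 !table$same_ritual, ]
  if (nrow(sub) == 0L) stop("no stage-2 within-stage records")
  succ_tpl <- mapply(next_ritual, sub$template_schema, sub$template_ritual)
  succ_held <- vapply(sub$heldout_path, function(p) path_rituals(p)[2L], "")
  match_succ <- succ_tpl == succ_held
  groups <- split(seq_len(nrow(sub)), sub$participant)
  data.frame(
    participant = as.integer(names(groups)),
    value = vapply(groups, function(i) {
      .mean_diff(sub$similarity[i], match_succ[i], !match_succ[i],
                 "successor_elevation", "stage-2 successor match")
    }, numeric(1)),
    row.names = NULL
  )
}

#' Write predicted matrices for all codes
#'
#' One CSV (and PNG heat map) per code, for documentation.
#'
#' @param out_dir Output directory.
#' @param heldout_path Held-out path used for the per-wedding view.
#' @return Invisibly, the written file paths.
#' @export
write_predicted_matrices <- function(out_dir, heldout_path = "A") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (code in .CODES) {
    m <- predicted_matrix(code, heldout_path)
    f <- file.path(out_dir, paste0("predicted_", code, ".csv"))
    utils::write.csv(m, f)
    p <- file.path(out_dir, paste0("predicted_", code, ".png"))
    grDevices::png(p, width = 480, height = 640)
    graphics::image(t(m[12:1, ]), axes = FALSE, zlim = c(-1, 1),
                    col = grDevices::gray.colors(3, 0.2, 0.9),
                    main = paste("predicted:", code))
    graphics::axis(2, at = seq(0, 1, length.out = 12),
                   labels = rev(rownames(m)), las = 2, cex.axis = 0.7)
    graphics::axis(1, at = seq(0, 1, length.out = 3), labels = colnames(m))
    grDevices::dev.off()
    files <- c(files, f, p)
  }
  invisible(files)
}
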