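# Within-participant brain-behavior link: per-wedding code strengths in a
# significant region, Spearman correlation with memory scores across
# weddings within each participant, permutation test of the
# across-participant mean correlation, and the behavioral scoring
# arithmetic.

#' Per-wedding neural code strengths over a region
#'
#' For every participant and wedding, the wedding-scope contrast for the
#' code, evaluated in each searchlight of the region and averaged
#' (unweighted) across the region's centers. `pool = "voxels"` instead
#' pools all member voxels of the region into a single pattern vector
#' before running the contrast.
#'
#' @param data A `pattern_dataset`.
#' @param region A `region_mask` (with geometry), e.g. from
#'   [threshold_map()], [conjunction()] or [disjunction()].
#' @param code One of [code_names()].
#' @param pool `"centers"` (default) or `"voxels"`.
#' @return Participants x weddings matrix of strengths.
#' @export
per_wedding_strengths <- function(data, region, code = code_names(),
                                  pool = c("centers", "voxels")) {
  stopifnot(inherits(data, "pattern_dataset"), inherits(region, "region_mask"))
  code <- match.arg(code)
  pool <- match.arg(pool)
  if (nrow(region) == 0L) stop("empty region mask")
  geom <- attr(region, "geometry")
  if (is.null(geom)) stop("region mask carries no searchlight geometry")
  shape <- geom$shape
  r <- geom$radius
  mask <- geom$mask
  members <- lapply(seq_len(nrow(region)), function(i) {
    xs <- max(1L, region$x[i] - r):min(shape[1L], region$x[i] + r)
    ys <- max(1L, region$y[i] - r):min(shape[2L], region$y[i] + r)
    zs <- max(1L, region$z[i] - r):min(shape[3L], region$z[i] + r)
    g <- expand.grid(x = xs, y = ys, z = zs)
    li <- (g$z - 1L) * shape[1L] * shape[2L] + (g$y - 1L) * shape[1L] + g$x
    sort(li[mask[li]])
  })
  frame <- comparison_frame(data$schedule)
  pre <- .sim_precompute(data$design, frame, data$schedule)
  W <- contrast_weight_matrix(frame, code, "wedding")
  n_p <- length(data$patterns)
  n_w <- ncol(W)
  out <- matrix(0, n_p, n_w,
                dimnames = list(NULL, colnames(W)))
  if (pool == "voxels") {
    vox <- sort(unique(unlist(members)))
    for (p in seq_len(n_p)) {
      sims <- .center_sims(data$patterns[[p]], vox, pre)
      out[p, ] <- crossprod(W, sims)
    }
  } else {
    for (j in seq_along(members)) {
      for (p in seq_len(n_p)) {
        sims <- .center_sims(data$patterns[[p]], members[[j]], pre)
        out[p, ] <- out[p, ] + crossprod(W, sims)
      }
    }
    out <- out / length(members)
  }
  if (anyNA(out)) stop("undefined strengths: constant pattern in region")
  out
}

.behavior_measure_col <- function(measure) {
  switch(measure,
         details = "details_score",
         rituals = "rituals_score",
         stop("unknown behavior measure: ", measure))
}

.behavior_matrix <- function(behavior, measure, participants, weddings) {
  col <- .behavior_measure_col(measure)
  need <- c("participant", "wedding_id", col)
  miss <- setdiff(need, names(behavior))
  if (length(miss)) stop("behavior table missing columns: ",
                         paste(miss, collapse = ", "))
  out <- matrix(NA_real_, length(participants), length(weddings))
  idx <- match(paste(rep(participants, each = length(weddings)),
                     rep(weddings, length(participants))),
               paste(behavior$participant, behavior$wedding_id))
  if (anyNA(idx)) stop("behavior table incomplete over participants x weddings")
  matrix(behavior[[col]][idx], length(participants), length(weddings),
         byrow = TRUE)
}

#' Within-participant Spearman correlation of strength and memory
#'
#' Spearman's rho (average ranks for ties) across weddings within each
#' participant, plus the across-participant mean and SEM.
#'
#' @param strengths Participants x weddings matrix from
#'   [per_wedding_strengths()].
#' @param behavior Behavior table (`participant`, `wedding_id`,
#'   `details_score`, `rituals_score`).
#' @param measure `"details"` or `"rituals"`.
#' @return List with `rho` (per participant), `r_mean`, `sem`.
#' @export
strength_behavior_correlation <- function(strengths, behavior,
                                          measure = c("details", "rituals")) {
  measure <- match.arg(measure)
  n_p <- nrow(strengths)
  if (ncol(strengths) < 3L) stop("need at least 3 weddings per participant")
  weds <- suppressWarnings(as.integer(colnames(strengths)))
  if (length(weds) != ncol(strengths) || anyNA(weds)) {
    weds <- seq_len(ncol(strengths))
  }
  B <- .behavior_matrix(behavior, measure, seq_len(n_p), weds)
  rho <- numeric(n_p)
  for (p in seq_len(n_p)) {
    if (stats::sd(strengths[p, ]) == 0) {
      stop("constant strengths for participant ", p)
    }
    if (stats::sd(B[p, ]) == 0) {
      stop("constant behavior scores for participant ", p)
    }
    rho[p] <- stats::cor(strengths[p, ], B[p, ], method = "spearman")
  }
  list(rho = rho, r_mean = mean(rho), sem = stats::sd(rho) / sqrt(n_p))
}

#' Permutation test of the mean within-participant correlation
#'
#' Null distribution: `n_perm` resamples, each independently shuffling
#' the behavior scores across weddings within every participant and
#' recomputing the mean Spearman rho. One-tailed p = proportion of null
#' means at or above the observed mean (`add_one` uses (k+1)/(n+1)).
#'
#' @inheritParams strength_behavior_correlation
#' @param n_perm Number of shuffles (1000 by default).
#' @param seed Integer seed for the shuffles.
#' @param add_one Use the (k+1)/(n_perm+1) convention.
#' @param bf_clip Optional |rho| clip before the Fisher-z Bayes factor
#'   (perfect correlations make atanh infinite).
#' @return A `brain_behavior_result` list: `measure`, `rho`, `r_mean`,
#'   `sem`, `p_perm`, `n_perm`, `seed`, `bf01`.
#' @export
strength_permutation_test <- function(strengths, behavior,
                                      measure = c("details", "rituals"),
                                      n_perm = 1000L, seed = 1L,
                                      add_one = FALSE, bf_clip = NULL) {
  measure <- match.arg(measure)
  obs <- strength_behavior_correlation(strengths, behavior, measure)
  n_p <- nrow(strengths)
  n_w <- ncol(strengths)
  weds <- suppressWarnings(as.integer(colnames(strengths)))
  if (length(weds) != n_w || anyNA(weds)) weds <- seq_len(n_w)
  B <- .behavior_matrix(behavior, measure, seq_len(n_p), weds)
  # standardized ranks: Pearson on ranks == Spearman with average ranks
  zs <- t(apply(strengths, 1L, function(v) scale(rank(v))[, 1L]))
  zb <- t(apply(B, 1L, function(v) scale(rank(v))[, 1L]))
  set.seed(as.integer(seed))
  null_means <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    acc <- 0
    for (p in seq_len(n_p)) {
      acc <- acc + sum(zs[p, ] * zb[p, sample.int(n_w)])
    }
    null_means[i] <- acc / (n_p * (n_w - 1L))
  }
  k <- sum(null_means >= obs$r_mean)
  p_perm <- if (add_one) (k + 1) / (n_perm + 1) else k / n_perm
  bf <- tryCatch(fisherz_bf(obs$rho, clip = bf_clip)$bf01,
                 error = function(e) NA_real_)
  structure(list(measure = measure, rho = obs$rho, r_mean = obs$r_mean,
                 sem = obs$sem, p_perm = p_perm, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), bf01 = bf,
                 null_means = null_means),
            class = "brain_behavior_result")
}

#' @export
print.brain_behavior_result <- function(x, ...) {
  cat(sprintf("brain-behavior (%s): mean rho = %.3f (SEM %.3f), p_perm = %.4g, BF-01 = %.3g\n",
              x$measure, x$r_mean, x$sem, x$p_perm, x$bf01))
  invisible(x)
}

#' Bayes factor on Fisher-z transformed correlations
#'
#' One-sample, one-tailed (positive) JZS Bayes factor on
#' `atanh(rho)` across participants; reports BF-01.
#'
#' @param rho Per-participant correlation values, |rho| < 1.
#' @param clip Optional clip bound applied to |rho| before the transform;
#'   without it, |rho| = 1 is an error.
#' @return As [jzs_bf01()].
#' @export
fisherz_bf <- function(rho, clip = NULL) {
  if (!is.null(clip)) rho <- pmax(-clip, pmin(clip, rho))
  if (any(abs(rho) >= 1)) {
    stop("|rho| = 1 makes the Fisher z transform infinite; use clip")
  }
  jzs_bf01(atanh(rho), tail = "greater")
}

#' Memory scores from annotation counts
#'
#' Correct-minus-incorrect remembered details and rituals per wedding.
#'
#' @param annotations Data frame with `participant`, `wedding_id`,
#'   `correct_details`, `incorrect_details`, `correct_rituals`,
#'   `incorrect_rituals` (all counts >= 0).
#' @return Behavior table with `details_score` and `rituals_score`.
#' @export
memory_scores <- function(annotations) {
  need <- c("participant", "wedding_id", "correct_details",
            "incorrect_details", "correct_rituals", "incorrect_rituals")
  miss <- setdiff(need, names(annotations))
  if (length(miss)) stop("annotation table missing columns: ",
                         paste(miss, collapse = ", "))
  counts <- annotations[, need[-(1:2)]]
  if (any(counts < 0)) stop("annotation counts must be non-negative")
  data.frame(
    participant = annotations$participant,
    wedding_id = annotations$wedding_id,
    details_score = annotations$correct_details - annotations$incorrect_details,
    rituals_score = annotations$correct_rituals - annotations$incorrect_rituals
  )
}

#' Score the end-of-study schema test
#'
#' Eight questions; each allocates 100 percent across the six ritual
#' options. Returns the mean percentage assigned to the correct option,
#' to the opposite-schema option, and to the remaining four options
#' divided by 4 (so the three numbers are comparable per-option rates).
#'
#' @param allocations 8 x 6 matrix or data frame, rows in
#'   [schema_test_key()] order, columns named by ritual.
#' @return List with `pct_correct`, `pct_opposite`, `pct_other_div4` and
#'   `per_question`.
#' @export
schema_test_score <- function(allocations) {
  key <- schema_test_key()
  allocations <- as.matrix(allocations)
  if (nrow(allocations) != 8L) stop("expected 8 question rows")
  if (!all(.RITUAL_TABLE$name %in% colnames(allocations))) {
    stop("allocation columns must be named by the six rituals")
  }
  allocations <- allocations[, .RITUAL_TABLE$name]
  sums <- rowSums(allocations)
  if (any(abs(sums - 100) > 0.01)) {
    stop("each question's allocations must sum to 100 (row ",
         which(abs(sums - 100) > 0.01)[1L], " sums to ",
         sums[which(abs(sums - 100) > 0.01)[1L]], ")")
  }
  correct <- allocations[cbind(1:8, match(key$correct_next, colnames(allocations)))]
  opposite <- allocations[cbind(1:8, match(key$opposite_next, colnames(allocations)))]
  other <- (sums - correct - opposite) / 4
  list(pct_correct = mean(correct), pct_opposite = mean(opposite),
       pct_other_div4 = mean(other),
       per_question = data.frame(key, correct = correct, opposite = opposite,
                                 other_div4 = other))
}
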