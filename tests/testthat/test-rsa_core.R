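test_that("templates are leave-one-out cell means with the right counts", {
  fx <- tiny_dataset(n_participants = 1L, seed = 3L)
  tpl <- build_templates(fx$data, held_out = 1L)
  expect_identical(ncol(tpl), 12L)
  # balanced 12-wedding schedule: 3 weddings per cell minus any held-out
  # contribution (brute-force count over the schedule)
  sched <- fx$data$schedule
  design <- fx$data$design
  for (w in sched$wedding_id) {
    counts <- attr(build_templates(fx$data, held_out = w), "n_contributing")
    cells <- schemarsa:::.template_cells()
    manual <- vapply(seq_len(12), function(i) {
      sum(design$schema == cells$schema[i] & design$ritual == cells$ritual[i] &
            design$wedding_id != w)
    }, 0)
    expect_identical(unname(counts), as.integer(manual))
    expect_true(all(counts %in% c(2L, 3L)))
  }
  # identical patterns across weddings -> every template equals them
  X <- fx$data$patterns[[1]]
  X[] <- rep(X[, 1], ncol(X))
  d2 <- pattern_dataset(list(X), fx$data$schedule)
  tpl2 <- build_templates(d2, held_out = 2L)
  expect_true(all(abs(tpl2 - X[, 1]) < 1e-12))
})

test_that("removing the only wedding of a cell is an explicit error", {
  # artificial 4-wedding schedule: one wedding per path
  sched <- make_schedule(2L, seed = 1L)[1:4, ]
  sched <- sched[match(c("A", "B", "C", "D"), sched$path), ]
  sched$wedding_id <- 1:4
  sched$position <- 1:4
  class(sched) <- c("wedding_schedule", "data.frame")
  set.seed(1)
  X <- matrix(rnorm(20 * 12), 20, 12)
  d <- pattern_dataset(list(X), sched)
  expect_error(build_templates(d, held_out = 1L), "unestimable template")
})

test_that("pattern similarity is Pearson r with strict input checks", {
  expect_equal(pattern_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(pattern_similarity(c(1, 2, 3), c(3, 2, 1)), -1)
  # independent closed-form oracle
  expect_equal(pattern_similarity(c(1, 2, 4), c(2, 1, 3)),
               oracle_pearson(c(1, 2, 4), c(2, 1, 3)), tolerance = 1e-12)
  set.seed(8)
  for (i in 1:20) {
    a <- rnorm(11); b <- rnorm(11)
    expect_equal(pattern_similarity(a, b), oracle_pearson(a, b),
                 tolerance = 1e-12)
  }
  expect_error(pattern_similarity(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pattern_similarity(1:2, 1:2), "at least 3")
  expect_error(pattern_similarity(1:3, 1:4), "length")
})

test_that("compare_all yields 36 labeled records per held-out wedding", {
  fx <- tiny_dataset(n_participants = 2L, seed = 9L)
  tab <- compare_all(fx$data)
  expect_identical(nrow(tab), 2L * 12L * 36L)
  counts <- table(tab$participant, tab$held_out)
  expect_true(all(counts == 36L))
  # similarities match per-pair brute force on a 5-voxel toy dataset
  set.seed(10)
  X <- matrix(rnorm(5 * 36), 5, 36)
  toy <- pattern_dataset(list(X), fx$data$schedule)
  tt <- compare_all(toy)
  for (i in sample(nrow(tt), 60)) {
    tpl <- build_templates(toy, held_out = tt$held_out[i])
    cell_name <- paste(tt$template_ritual[i], tt$template_schema[i], sep = "-")
    v <- toy$design$volume[toy$design$wedding_id == tt$held_out[i] &
                             toy$design$stage == tt$heldout_stage[i]]
    expect_equal(tt$similarity[i], oracle_pearson(tpl[, cell_name], X[, v]),
                 tolerance = 1e-12)
  }
})

test_that("the four path relations partition all comparisons", {
  frame <- comparison_frame(make_schedule(2L, seed = 2L))
  expect_true(all(frame$path_relation %in% 1:4))
  # per held-out wedding and stage: 3 same-path cells, 3 rel-2, and the
  # remaining 6 different-schema cells split by on-path ritual match
  per <- table(frame$held_out, frame$path_relation)
  expect_true(all(per[, "1"] == 9L))
  expect_true(all(per[, "2"] == 9L))
  expect_true(all(per[, "3"] + per[, "4"] == 18L))
  expect_true(all(frame$same_schema == (frame$path_relation %in% 1:2)))
  # rel 4 requires the template ritual on the held-out path
  r4 <- frame[frame$path_relation == 4L, ]
  on_path <- mapply(function(r, p) r %in% path_rituals(p),
                    r4$template_ritual, r4$heldout_path)
  expect_true(all(on_path))
})

test_that("label taxonomy reproduces the worked examples", {
  frame <- comparison_frame(make_schedule(2L, seed = 2L))
  # template north-coin vs a held-out wedding on path C (campfire,torch,egg)
  i <- frame$template_ritual == "coin" & frame$template_schema == "North" &
    frame$heldout_path == "C"
  expect_true(all(frame$path_relation[i] == 3L))
  # ... vs path D (flower,coin,painting): within-stage ritual match only
  i <- frame$template_ritual == "coin" & frame$template_schema == "North" &
    frame$heldout_path == "D"
  expect_true(all(frame$path_relation[i] == 4L))
  # within-stage: same_ritual iff rituals match, schema ignored
  w <- frame[frame$stage_relation == "within", ]
  expect_identical(w$same_ritual, w$template_ritual == w$heldout_ritual)
  # predecessor flag: ritual identity only, implies adjacent stages
  p <- frame[frame$template_is_predecessor, ]
  expect_true(all(p$template_stage == p$heldout_stage - 1L))
  pred_ritual <- mapply(function(path, st) path_rituals(path)[st - 2L],
                        p$heldout_path, p$heldout_stage)
  expect_identical(p$template_ritual, unname(pred_ritual))
})

test_that("same-preceding flag follows the path table", {
  expect_true(label_same_preceding("torch", "North", "coin", "South"))
  expect_true(label_same_preceding("coin", "North", "torch", "South"))
  expect_false(label_same_preceding("coin", "North", "coin", "South"))
  expect_false(label_same_preceding("campfire", "North", "coin", "South"))
  # brute force over all stage-3/4 cell pairs
  cells <- schemarsa:::.template_cells()
  cells <- cells[cells$stage >= 3L, ]
  for (i in seq_len(nrow(cells))) {
    for (j in seq_len(nrow(cells))) {
      pred_i <- path_rituals(cells$path[i])[cells$stage[i] - 2L]
      pred_j <- path_rituals(cells$path[j])[cells$stage[j] - 2L]
      expect_identical(
        label_same_preceding(cells$ritual[i], cells$schema[i],
                             cells$ritual[j], cells$schema[j]),
        pred_i == pred_j
      )
    }
  }
})

test_that("constant patterns raise rather than propagate NaN", {
  fx <- tiny_dataset(n_participants = 1L, seed = 3L)
  X <- fx$data$patterns[[1]]
  X[, 5] <- 2
  d <- pattern_dataset(list(X), fx$data$schedule)
  expect_error(compare_all(d), "constant pattern")
})
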