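# Fixtures are built in code at test time; nothing is stored on disk.

# A single-region layout: whole 5x5x5 grid carries one planted code.
tiny_layout <- function(label = 1L, grid = c(5L, 5L, 5L)) {
  region_layout(grid, blocks = list(list(label = label, corner = c(1L, 1L, 1L),
                                         size = grid)))
}

# Small planted dataset; defaults keep everything fast. n_participants = 1
# is allowed here (the generator itself requires >= 2) by subsetting.
tiny_dataset <- function(n_participants = 2L, label = 1L, seed = 1L,
                         noise_sd = 0.5, schedule_seed = 1L, ...) {
  cfg <- generator_config(
    n_participants = max(2L, n_participants),
    schedule = make_schedule(2L, seed = schedule_seed),
    layout = tiny_layout(label),
    noise_sd = noise_sd, seed = seed, ...
  )
  data <- generate_patterns(cfg)
  if (n_participants < 2L) {
    data$patterns <- data$patterns[1L]
    data$amplitudes <- data$amplitudes[1L, , drop = FALSE]
  }
  list(config = cfg, data = data)
}

# A comparison table with pseudo-random similarities: exercises the
# contrast arithmetic without any pattern data.
random_table <- function(n_participants = 3L, seed = 42L, schedule_seed = 1L) {
  frame <- comparison_frame(make_schedule(2L, seed = schedule_seed))
  set.seed(seed)
  out <- do.call(rbind, lapply(seq_len(n_participants), function(p) {
    cbind(participant = p, frame, similarity = stats::runif(nrow(frame), -1, 1))
  }))
  class(out) <- c("comparison_table", "data.frame")
  out
}

# A comparison table whose similarities are a constant per label group;
# used to force known contrast values.
forced_table <- function(values_fn, schedule_seed = 1L) {
  frame <- comparison_frame(make_schedule(2L, seed = schedule_seed))
  frame$similarity <- values_fn(frame)
  out <- cbind(participant = 1L, frame)
  class(out) <- c("comparison_table", "data.frame")
  out
}
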