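test_that("generator is deterministic under seed and validates config", {
  fx1 <- tiny_dataset(seed = 7L)
  fx2 <- tiny_dataset(seed = 7L)
  expect_identical(fx1$data$patterns, fx2$data$patterns)
  expect_identical(fx1$data$amplitudes, fx2$data$amplitudes)
  b1 <- generate_behavior(fx1$config, fx1$data)
  b2 <- generate_behavior(fx2$config, fx2$data)
  expect_identical(b1, b2)
  fx3 <- tiny_dataset(seed = 8L)
  expect_false(identical(fx1$data$patterns, fx3$data$patterns))
  expect_error(generator_config(n_participants = 1L), "n_participants")
  expect_error(generator_config(noise_sd = -1), "noise_sd")
  expect_error(region_layout(c(20, 20, 20),
                             blocks = list(list(label = 1, corner = c(1, 1, 1),
                                                size = c(4, 5, 5)))),
               "too small for a searchlight")
})

test_that("pure current-ritual code gives unit same-ritual similarity at zero noise", {
  fx <- tiny_dataset(label = 4L, noise_sd = 0, seed = 2L,
                     beta_schema = 0, beta_path = 0, beta_ritual = 1,
                     beta_rotated = 0)
  tab <- compare_all(fx$data)
  within <- tab[tab$stage_relation == "within", ]
  expect_true(all(abs(within$similarity[within$same_ritual] - 1) < 1e-10))
  expect_true(all(within$similarity[!within$same_ritual] < 1 - 1e-6))
})

test_that("with all betas zero every contrast has mean zero over replicates", {
  # simulation oracle: empirical mean within 3 Monte-Carlo SEs of 0
  n_rep <- 60L
  scores <- matrix(NA_real_, n_rep, 5L, dimnames = list(NULL, code_names()))
  for (i in seq_len(n_rep)) {
    fx <- tiny_dataset(n_participants = 2L, seed = 1000L + i, noise_sd = 1,
                       beta_schema = 0, beta_path = 0, beta_ritual = 0,
                       beta_rotated = 0, amplitude_jitter_sd = 0)
    tab <- compare_all(fx$data)
    for (cd in code_names()) {
      scores[i, cd] <- mean(code_score(tab, cd)$value)
    }
  }
  for (cd in code_names()) {
    se <- sd(scores[, cd]) / sqrt(n_rep)
    expect_lt(abs(mean(scores[, cd])), 3 * se + 1e-12)
  }
})

test_that("planted rotated component anticorrelates stage patterns with predecessor templates", {
  # closed-form expectation: in the rotated+current region the stage-3
  # pattern contains -beta * u(predecessor), so its similarity to the
  # true predecessor's template is lower than to the other stage-2
  # template; with noise_sd = 0 the rotated score is strictly positive.
  fx <- tiny_dataset(label = 3L, noise_sd = 0, seed = 4L,
                     beta_schema = 0, beta_path = 0, beta_ritual = 1,
                     beta_rotated = 1)
  tab <- compare_all(fx$data)
  a <- tab[tab$template_stage == 2 & tab$heldout_stage == 3, ]
  expect_lt(mean(a$similarity[a$template_is_predecessor]),
            mean(a$similarity[!a$template_is_predecessor]))
  expect_true(all(code_score(tab, "rotated_preceding")$value > 0))
  # rotation-sign invariant: never positive-matching when planted rotated
  expect_true(all(a$similarity[a$template_is_predecessor] < 0))
})

test_that("a rotated-only region carries no detectable rotated contrast", {
  # region 5 plants only the carried trace: stage-2 patterns are pure
  # noise, so the stage-2 templates the contrast relies on carry no
  # signal and the expected score is 0 (closed-form; see the vignette)
  n_rep <- 30L
  vals <- vapply(seq_len(n_rep), function(i) {
    fx <- tiny_dataset(n_participants = 2L, label = 5L, seed = 3000L + i,
                       noise_sd = 0.5, beta_schema = 0, beta_path = 0,
                       beta_ritual = 1, beta_rotated = 1)
    mean(code_score(compare_all(fx$data), "rotated_preceding")$value)
  }, numeric(1))
  se <- sd(vals) / sqrt(n_rep)
  expect_lt(abs(mean(vals)), 3 * se + 1e-12)
})

test_that("non-rotated carryover variant flips the contrast sign", {
  fx <- tiny_dataset(label = 3L, noise_sd = 0, seed = 4L,
                     beta_schema = 0, beta_path = 0, beta_ritual = 1,
                     beta_rotated = 1, carryover_sign = +1)
  tab <- compare_all(fx$data)
  expect_true(all(code_score(tab, "rotated_preceding")$value < 0))
  expect_true(all(code_score(tab, "nonrotated_preceding_upcoming")$value > 0))
})

test_that("behavior coupling recovers a perfect within-participant rank link", {
  fx <- tiny_dataset(n_participants = 3L, seed = 5L,
                     amplitude_jitter_sd = 0.5)
  cfg <- fx$config
  cfg$behavior_noise_sd <- 0
  beh <- generate_behavior(cfg, fx$data)
  for (p in 1:3) {
    a <- fx$data$amplitudes[p, ]
    d <- beh$details_score[beh$participant == p][order(beh$wedding_id[beh$participant == p])]
    # the unrounded latent score is an exact monotone transform of a_w;
    # rounding to integer scores introduces ties, so the observed rank
    # link is near-perfect rather than exactly 1
    latent <- fx$config$base_details + fx$config$gamma_details * a
    expect_equal(cor(a, latent, method = "spearman"), 1)
    expect_gte(cor(a, d, method = "spearman"), 0.9)
  }
  # gamma = 0 decouples behavior from amplitudes
  cfg0 <- fx$config
  cfg0$gamma_details <- 0
  beh0 <- generate_behavior(cfg0, fx$data)
  expect_true(sd(beh0$details_score) > 0)
})

test_that("written datasets round-trip through the readers", {
  fx <- tiny_dataset(n_participants = 2L, seed = 6L)
  beh <- generate_behavior(fx$config, fx$data)
  out <- withr::local_tempdir()
  write_dataset(fx$data, beh, out)
  expect_identical(length(list.files(out, "patterns\\.nii$")), 2L)
  rd <- read_dataset(
    sort(list.files(out, "patterns\\.nii$", full.names = TRUE)),
    sort(list.files(out, "events\\.tsv$", full.names = TRUE)),
    mask = file.path(out, "mask.nii"),
    labels = file.path(out, "region_labels.nii")
  )
  expect_equal(rd$patterns, fx$data$patterns)
  expect_identical(rd$layout$labels, fx$data$layout$labels)
  expect_equal(as.data.frame(rd$schedule)[c("wedding_id", "schema", "path")],
               as.data.frame(fx$data$schedule)[c("wedding_id", "schema", "path")])
  ev <- utils::read.delim(file.path(out, "sub-01_events.tsv"))
  expect_identical(nrow(ev), 36L)
  expect_true(all(ev$schema %in% c("North", "South")))
  beh_rt <- read_behavior_tsv(file.path(out, "behavior.tsv"))
  expect_equal(beh_rt, beh)
})
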