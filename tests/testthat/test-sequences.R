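test_that("condition specs carry the 2x2 design defaults", {
  hh <- make_condition("high", "high")
  ll <- make_condition("low", "low")
  lh <- make_condition("low", "high")
  expect_equal(hh$mean_chunk_length, 15)
  expect_equal(hh$obs_variance, 1.75)
  expect_equal(ll$mean_chunk_length, 25)
  expect_equal(ll$obs_variance, 0.25)
  expect_equal(lh$mean_chunk_length, 25)
  expect_equal(lh$obs_variance, 1.75)
  expect_equal(hh$length_jitter, 3)
  expect_equal(hh$mean_range, c(3.5, 10.5))
  expect_equal(hh$intensity_range, c(1L, 13L))
  expect_equal(hh$n_trials, 80L)
  expect_equal(hh$min_mean_separation, 2)
  expect_error(make_condition("medium", "low"))
  expect_named(all_conditions(),
               c("lowS_lowV", "highS_lowV", "lowS_highV", "highS_highV"))
})

test_that("impossible specs are rejected with a message", {
  expect_error(make_condition("low", "low", min_mean_separation = 10),
               "min_mean_separation")
  expect_error(make_condition("low", "low", mean_chunk_length = 2,
                              length_jitter = 3), "below 1")
})

test_that("generated sequences satisfy the structural invariants", {
  for (spec in all_conditions()) {
    for (seed in c(1, 42, 999)) {
      s <- generate_sequence(spec, seed = seed)
      expect_equal(nrow(s), 80)
      expect_true(all(s$intensity >= 1 & s$intensity <= 13))
      expect_equal(s$intensity, as.integer(round(s$pre_disc)))
      means <- attr(s, "chunk_means")
      expect_true(all(abs(diff(means)) >= 2))
      lens <- attr(s, "chunk_lengths")
      expect_true(all(abs(lens - spec$mean_chunk_length) <= 3))
      expect_gte(sum(lens), 80)
      # trials per chunk in the table agree with the drawn lengths
      tab <- as.integer(table(s$chunk_index))
      expect_equal(tab[-length(tab)], lens[seq_len(length(tab) - 1)])
    }
  }
})

test_that("zero-noise, zero-jitter sequences degenerate to chunk means", {
  spec <- make_condition("high", "low", obs_variance = 0, length_jitter = 0)
  s <- generate_sequence(spec, seed = 7)
  expect_equal(s$pre_disc, s$chunk_mean)
  expect_true(all(table(s$chunk_index)[-length(unique(s$chunk_index))] == 15))
})

test_that("pre-discretisation noise matches the condition's variance", {
  # pooled across 120 sequences the within-chunk variance estimate has
  # relative Monte-Carlo error ~1.5%
  pooled_var <- function(spec, seeds) {
    dev <- unlist(lapply(seeds, function(sd) {
      s <- generate_sequence(spec, seed = sd)
      s$pre_disc - s$chunk_mean
    }))
    var(dev)
  }
  vh <- pooled_var(make_condition("high", "high"), 1:120)
  vl <- pooled_var(make_condition("high", "low"), 1:120)
  expect_equal(vh, 1.75, tolerance = 0.05)
  expect_equal(vl, 0.25, tolerance = 0.05)
})

test_that("chunk means and lengths follow their generative distributions", {
  specs <- all_conditions()
  means <- unlist(lapply(1:60, function(sd) {
    unlist(lapply(specs, function(sp) {
      attr(generate_sequence(sp, seed = sd), "chunk_means")
    }))
  }))
  expect_equal(mean(means), 7, tolerance = 0.02)
  expect_true(all(means >= 3.5 & means <= 10.5))

  lens_hi <- unlist(lapply(1:80, function(sd) {
    attr(generate_sequence(specs$highS_highV, seed = sd), "chunk_lengths")
  }))
  lens_lo <- unlist(lapply(1:80, function(sd) {
    attr(generate_sequence(specs$lowS_lowV, seed = sd), "chunk_lengths")
  }))
  expect_equal(mean(lens_hi), 15, tolerance = 0.05)
  expect_equal(mean(lens_lo), 25, tolerance = 0.05)
})

test_that("schedules balance the two response types and permute by seed", {
  s <- generate_schedule(80, seed = 3)
  expect_equal(sum(s$response_type == "perception"), 40)
  expect_equal(sum(s$response_type == "prediction"), 40)
  s2 <- generate_schedule(2, seed = 5)
  expect_setequal(s2$response_type, c("perception", "prediction"))
  a <- generate_schedule(80, seed = 1)$response_type
  b <- generate_schedule(80, seed = 2)$response_type
  expect_equal(sort(a), sort(b))
  expect_false(all(a == b))
  expect_error(generate_schedule(81, seed = 1), "even")
})

test_that("sequence generation is reproducible and records its seed", {
  spec <- make_condition("high", "low")
  a <- generate_sequence(spec, seed = 123)
  b <- generate_sequence(spec, seed = 123)
  expect_equal(a$pre_disc, b$pre_disc)
  expect_equal(attr(a, "seed"), 123L)
  # and does not disturb the caller's RNG stream
  set.seed(1)
  x1 <- rnorm(1)
  set.seed(1)
  invisible(generate_sequence(spec, seed = 9))
  expect_identical(rnorm(1), x1)
})
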