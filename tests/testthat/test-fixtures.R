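test_that("the moxifloxacin program matches its published summary", {
  g <- fixture_moxifloxacin()
  expect_equal(nrow(g$studies), 19L)
  expect_true(all(g$studies$status == "completed"))
  expect_equal(min(g$studies$year), 1998L)
  expect_equal(max(g$studies$year), 2009L)
  expect_equal(nrow(g$edges), 25L)
  expect_equal(sum(g$edges$same_report), 1L)

  g4 <- fixture_moxifloxacin("figure4")
  expect_equal(nrow(g4$studies), 23L)
  expect_setequal(g4$studies$id[g4$studies$status == "contemplated"],
                  c("A", "B", "C", "D"))
  expect_equal(
    g4$studies$phase[match(c("A", "B", "C", "D"), g4$studies$id)],
    c("in_vivo", "phase1", "phase2", "phase3"))
})

test_that("the toy snapshots carry the stated studies, outcomes and spans", {
  f1 <- fixture_toy("figure1")
  expect_equal(nrow(f1$studies), 8L)
  expect_equal(nrow(f1$edges), 0L)
  expect_equal(diff(range(f1$studies$year)) + 1L, 5L)

  f2 <- fixture_toy("figure2")
  expect_equal(nrow(f2$studies), 11L)
  expect_equal(diff(range(f2$studies$year)) + 1L, 6L)
  expect_equal(detect_orphans(f2), "d3")

  f3 <- fixture_toy("figure3")
  comp <- f3$studies[f3$studies$status == "completed", ]
  expect_equal(nrow(comp), 12L)
  expect_equal(sum(comp$outcome == "positive"), 7L)
  expect_equal(diff(range(comp$year)) + 1L, 6L)
  expect_setequal(f3$studies$id[f3$studies$status == "contemplated"],
                  c("d4", "e2"))
})

test_that("the generator is seed-deterministic", {
  a <- aero_generate(n_per_phase = c(3, 4, 4, 3, 1), seed = 42)
  b <- aero_generate(n_per_phase = c(3, 4, 4, 3, 1), seed = 42)
  expect_identical(write_study_table(a, format = "csv"),
                   write_study_table(b, format = "csv"))
  c_ <- aero_generate(n_per_phase = c(3, 4, 4, 3, 1), seed = 43)
  expect_false(identical(write_study_table(a, format = "csv"),
                         write_study_table(c_, format = "csv")))
})

test_that("generated outcome frequencies follow the configured probabilities", {
  g <- aero_generate(n_per_phase = rep(400, 5),
                     p_outcomes = c(positive = 0.6, negative = 0.25,
                                    inconclusive = 0.15),
                     seed = 7)
  expect_equal(nrow(g$studies), 2000L)
  # binomial 99% bound at n = 2000 for p = 0.6 is about +/- 0.028
  expect_lt(abs(mean(g$studies$outcome == "positive") - 0.6), 0.03)
})

test_that("fuzzed generator output always passes graph validation", {
  for (seed in 1:150) {
    g <- aero_generate(
      n_per_phase = c(2, 3, 3, 2, 1),
      p_backtrack = (seed %% 3) / 5,
      p_orphan = (seed %% 4) / 10,
      p_contemplated = (seed %% 2) / 4,
      seed = seed
    )
    expect_silent(validate_aero_graph(g))
    ord <- temporal_order(g)
    strict <- !g$edges$same_report
    expect_true(all(match(g$edges$parent, ord)[strict] <
                      match(g$edges$child, ord)[strict]))
  }
})

test_that("generator guards its configuration", {
  expect_error(aero_generate(p_outcomes = c(0.5, 0.2, 0.2), seed = 1),
               class = "aero_error_input")
  expect_error(aero_generate(max_parents = 0, seed = 1),
               class = "aero_error_input")
  expect_error(
    aero_generate(n_per_phase = c(0, 3, 3), p_backtrack = 0, p_orphan = 0,
                  seed = 1),
    class = "aero_error_input")
  # orphans disabled: nothing above the lowest phase is parentless
  for (seed in 1:20) {
    g <- aero_generate(n_per_phase = c(2, 3, 3), p_orphan = 0, seed = seed)
    expect_equal(detect_orphans(g), character())
  }
})

test_that("the generator leaves the global random stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(aero_generate(seed = 99))
  expect_identical(.Random.seed, before)
})
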