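moxi <- fixture_moxifloxacin()
fig1 <- fixture_toy("figure1")
fig2 <- fixture_toy("figure2")
fig3 <- fixture_toy("figure3")

test_that("phase counts tally completed studies by outcome, zeros included", {
  pc <- phase_counts(moxi)
  got <- pc[match(c("in_vitro", "in_vivo", "phase1", "phase2"), pc$phase),
            c("n_completed", "n_positive", "n_negative", "n_inconclusive")]
  expect_equal(unname(as.matrix(got)),
               matrix(c(3, 3, 0, 0,
                        5, 3, 0, 2,
                        6, 3, 2, 1,
                        5, 3, 2, 0), 4, byrow = TRUE))
  expect_equal(pc$n_completed[pc$phase == "phase3"], 0L)

  pc1 <- phase_counts(fig1)
  expect_equal(pc1$n_positive[pc1$phase == "in_vitro"], 2L)
  expect_equal(pc1$n_completed[pc1$phase == "in_vivo"], 3L)
  expect_equal(pc1$n_positive[pc1$phase == "in_vivo"], 2L)
  expect_equal(pc1$n_positive[pc1$phase == "phase1"], 2L)

  pc0 <- phase_counts(aero_graph())
  expect_true(all(pc0$n_completed == 0L))
  expect_equal(nrow(pc0), 5L)

  # contemplated studies never enter the tallies
  expect_equal(phase_counts(fixture_moxifloxacin("figure4")), pc)
})

test_that("within-phase consistency needs two completed studies sharing an outcome", {
  cons <- assess_consistency(moxi)
  occupied <- cons$phase %in% c("in_vitro", "in_vivo", "phase1", "phase2")
  expect_true(all(cons$has_consistency[occupied]))
  expect_true(cons$is_fully_consistent[cons$phase == "in_vitro"])
  expect_false(cons$is_fully_consistent[cons$phase == "phase1"])
  # both the positive pair and the inconclusive pair repeat in vivo
  expect_setequal(cons$consistent_outcomes[cons$phase == "in_vivo"][[1]],
                  c("positive", "inconclusive"))

  # one positive, one negative, one inconclusive: no consistency at all
  cons2 <- assess_consistency(fig2)
  expect_false(cons2$has_consistency[cons2$phase == "phase2"])

  single <- aero_graph(tibble::tibble(id = "a", phase = "phase1",
                                      year = 2000, outcome = "positive"))
  expect_false(assess_consistency(single)$has_consistency[3])
})

test_that("concordance classifies directed lineage paths by outcome agreement", {
  r <- classify_path(fig2, c("a1", "a2", "b3", "g3", "d2"))
  expect_equal(r$classification, "perfectly_concordant")
  expect_equal(nrow(r$discordant_steps), 0L)

  r2 <- classify_path(fig2, c("a1", "b1"))
  expect_equal(r2$classification, "discordant")
  expect_equal(r2$discordant_steps$from, "a1")
  expect_equal(r2$discordant_steps$to, "b1")

  expect_equal(classify_path(fig2, "a1")$classification, "perfectly_concordant")

  expect_error(classify_path(fig2, c("a1", "g3")), class = "aero_error_path")
  expect_error(classify_path(fixture_toy("figure3"), c("e1", "d4")),
               class = "aero_error_path") # contemplated node on path
})

test_that("classify_path agrees with a brute-force outcome-equality check", {
  for (seed in 1:10) {
    g <- random_dag(n = 8, seed = seed, p_edge = 0.25)
    for (path in enumerate_paths(g)) {
      oc <- g$studies$outcome[match(path, g$studies$id)]
      expected <- if (length(unique(oc)) == 1L) "perfectly_concordant" else "discordant"
      expect_equal(classify_path(g, path)$classification, expected)
    }
  }
})

test_that("de-facto thresholds count positives accumulated before the next phase opened", {
  expect_equal(de_facto_threshold(moxi, "in_vivo")$n_positive_before, 3L)
  th <- de_facto_threshold(moxi, "phase1")
  expect_equal(th$first_target_study, "x1")
  # w4 (2006) precedes x1 (2006) because it is x1's parent
  expect_equal(th$n_positive_before, 3L)

  th2 <- de_facto_threshold(fig2, "phase1")
  expect_equal(th2$first_target_study, "d1")
  expect_equal(th2$n_positive_before, 1L)

  # transition not yet taken: threshold is undefined
  expect_true(is.na(de_facto_threshold(moxi, "phase2")$n_positive_before))
  expect_error(de_facto_threshold(moxi, "phase9"), class = "aero_error_validate")
  expect_error(de_facto_threshold(moxi, "phase3"), class = "aero_error_validate")
})

test_that("adding one earlier positive source study raises the threshold by one", {
  g <- add_study(moxi, "v0", "in_vivo", 2000, outcome = "positive")
  expect_equal(de_facto_threshold(g, "in_vivo")$n_positive_before,
               de_facto_threshold(moxi, "in_vivo")$n_positive_before + 1L)
})

test_that("orphans are parentless studies above the program's lowest phase", {
  expect_equal(detect_orphans(fig2), "d3")
  expect_equal(detect_orphans(moxi), character())
  expect_equal(detect_orphans(aero_graph()), character())
})

test_that("monochromatic sub-trajectories are maximal same-outcome weak components", {
  st <- monochromatic_subtrajectories(moxi)
  neg <- st[st$outcome == "negative", ]
  expect_equal(nrow(neg), 1L)
  expect_setequal(neg$studies[[1]], c("w3", "x1", "w5", "x4"))
  expect_setequal(edge_key(neg$edges[[1]]), c("w3 x1", "x1 w5", "x1 x4"))

  pos2 <- monochromatic_subtrajectories(fig2)
  pos2 <- pos2[pos2$outcome == "positive", ]
  with_a1 <- pos2$studies[vapply(pos2$studies, function(s) "a1" %in% s, TRUE)]
  expect_setequal(with_a1[[1]], c("a1", "a2", "b2", "b3", "g1", "g3", "d2"))

  chain <- aero_graph(
    tibble::tibble(id = c("a", "b", "c"), phase = "in_vitro",
                   year = 2000:2002, outcome = "positive"),
    tibble::tibble(parent = c("a", "b"), child = c("b", "c"))
  )
  stc <- monochromatic_subtrajectories(chain)
  expect_equal(nrow(stc), 1L)
  expect_setequal(stc$studies[[1]], c("a", "b", "c"))
})

test_that("same-outcome components partition the completed studies of each outcome", {
  for (seed in 1:20) {
    g <- aero_generate(n_per_phase = c(3, 3, 3, 3), seed = seed)
    st <- monochromatic_subtrajectories(g)
    for (oc in c("positive", "negative", "inconclusive")) {
      members <- unlist(st$studies[st$outcome == oc])
      expect_false(anyDuplicated(members) > 0)
      all_oc <- g$studies$id[g$studies$outcome == oc &
                               g$studies$status == "completed"]
      expect_true(all(members %in% all_oc))
      # studies not in a listed component have no same-outcome neighbor
      singles <- setdiff(all_oc, members)
      e <- g$edges
      for (id in singles) {
        nb <- c(e$child[e$parent == id], e$parent[e$child == id])
        expect_false(any(nb %in% all_oc))
      }
    }
  }
})

test_that("the outcome trend reports counts and a guarded positive:negative ratio", {
  tr <- trend_ratio(moxi)
  expect_equal(as.integer(tr[1, 1:3]), c(12L, 4L, 3L))
  expect_equal(tr$pos_neg_ratio, 3)
  expect_equal(tr$ratio_display, "3:1")

  tr3 <- trend_ratio(fig3)
  expect_equal(tr3$n_positive, 7L)
  expect_equal(tr3$n_positive + tr3$n_negative + tr3$n_inconclusive, 12L)

  allpos <- aero_graph(tibble::tibble(id = c("a", "b"), phase = "in_vitro",
                                      year = 2000, outcome = "positive"))
  expect_true(is.na(trend_ratio(allpos)$pos_neg_ratio))
})

test_that("what-if assignment completes contemplated studies in a copy", {
  g4 <- fixture_moxifloxacin("figure4")
  w <- whatif(g4, A = "positive", C = "positive")
  pc <- w$report$phase_summary
  expect_equal(pc$n_positive[pc$phase == "in_vivo"], 4L)
  expect_equal(pc$n_positive[pc$phase == "phase2"], 4L)
  expect_equal(w$report$n_completed, 21L)
  # the original is untouched
  expect_equal(sum(g4$studies$status == "contemplated"), 4L)

  # empty assignment is the identity on the report
  expect_equal(report_to_json(whatif(g4)$report),
               report_to_json(aero_analyze(g4)))

  expect_error(whatif(g4, u1 = "negative"), class = "aero_error_whatif")
  expect_error(whatif(g4, Z9 = "positive"), class = "aero_error_validate")
})

test_that("the aggregated report conserves counts and serializes", {
  r <- aero_analyze(moxi)
  expect_equal(r$n_completed, 19L)
  expect_equal(sum(r$phase_summary$n_completed), r$n_completed)
  expect_equal(sum(r$phase_summary$n_positive), r$trend$n_positive)
  expect_equal(sum(r$phase_summary$n_negative), r$trend$n_negative)
  expect_equal(sum(r$phase_summary$n_inconclusive), r$trend$n_inconclusive)
  expect_equal(r$year_span, 12L)

  r4 <- aero_analyze(fixture_moxifloxacin("figure4"))
  expect_equal(r4$n_completed, 19L)
  expect_equal(r4$n_contemplated, 4L)
  expect_equal(r4$year_span, 12L)

  r0 <- aero_analyze(aero_graph())
  expect_equal(r0$n_studies, 0L)
  expect_s3_class(r0, "aero_report")

  js <- jsonlite::fromJSON(report_to_json(r))
  expect_equal(js$n_completed, 19)
  expect_equal(js$trend$pos_neg_ratio, 3)
  expect_equal(js$schema_version, "1.0")
})

test_that("tidy and glance summarize the report as tibbles", {
  r <- aero_analyze(moxi)
  td <- generics::tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 5L)
  expect_true(all(c("n_completed", "has_consistency") %in% names(td)))
  gl <- generics::glance(r)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$pos_neg_ratio, 3)
  expect_equal(gl$n_orphans, 0L)
})
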