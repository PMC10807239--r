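mk_scores <- function(scores, immune = NULL) {
  lapply(seq_along(scores), function(i) {
    s <- scores[i]
    structure(list(z_index = i - 1L, depth_um = (i - 1) * 1.4,
                   tumor_area_px = 10000L,
                   immune_area_px = if (is.null(immune)) 500L else immune[i],
                   immune_in_tumor_px = 200L,
                   pdl1_ic_area_px = as.integer(round(s * 100)),
                   ic_score_pct = if (is.na(s)) NA_real_ else s,
                   category = if (is.na(s)) NA_character_ else categorize(s),
                   no_tumor = is.na(s)),
              class = "layer_score")
  })
}

test_that("select_layers implements the acquisition/analysis stride", {
  idx <- select_layers(143, 1.4, 7)
  expect_equal(idx[1:3], c(0, 5, 10))
  expect_equal(length(idx), 29)
  expect_equal(max(idx), 140)
  expect_equal(select_layers(4, 1.4, 1.4), 0:3)   # interval = spacing
  expect_equal(select_layers(1, 1.4, 7), 0)
  expect_error(select_layers(10, 1.4, 0.7), ">= z spacing")
  expect_error(select_layers(10, 0, 7), "> 0")
})

test_that("build_profile summarises depth profiles", {
  p <- build_profile("a", mk_scores(c(1, 2, 3)))
  expect_equal(p$average_score_pct, 2)
  expect_equal(p$range, 2)
  expect_false(p$crossing_1pct)     # min already >= 1
  p2 <- build_profile("b", mk_scores(c(0.2, 0.8, 1.5)))
  expect_true(p2$crossing_1pct)
  p3 <- build_profile("c", mk_scores(c(0, 0, 0)))
  expect_equal(p3$pattern, "uniform_negative")
  expect_equal(p3$average_score_pct, 0)
  expect_error(build_profile("d", mk_scores(c(NA, NA))), "no-tumor")
})

test_that("no-tumor layers do not contribute to profile summaries", {
  p <- build_profile("a", mk_scores(c(2, NA, 4)))
  expect_equal(p$n_scored, 2)
  expect_equal(p$average_score_pct, 3)
  expect_equal(p$min_score, 2)
})

test_that("pattern_label classifies presence/absence and crossing", {
  r <- pattern_label(c("negative", "negative", "positive"))
  expect_equal(r$pattern, "heterogeneous_presence")
  expect_true(r$crossing)
  r2 <- pattern_label(c("positive", "positive"))
  expect_equal(r2$pattern, "uniform_expressed")
  expect_false(r2$crossing)
  r3 <- pattern_label(c("borderline", "negative"))
  expect_equal(r3$pattern, "heterogeneous_presence")
  expect_false(r3$crossing)   # no layer at or above 1%
  r4 <- pattern_label(c("borderline", "positive"))
  expect_equal(r4$pattern, "uniform_expressed")
  expect_true(r4$crossing)
  expect_error(pattern_label(character(0)), "at least one")
  expect_error(pattern_label("weird"), "unknown category")
})

test_that("immune_area_variation is (max - min) / max", {
  expect_equal(immune_area_variation(c(100, 95, 90)), 0.10)
  expect_equal(immune_area_variation(c(70, 70, 70)), 0)
  expect_equal(immune_area_variation(c(50, 100)), 0.5)
  expect_error(immune_area_variation(c(0, 0)), "zero")
})

test_that("discordance compares categories on the ordinal scale", {
  expect_equal(discordance_2d_3d(2, list(score = 0)), "3d_higher")
  expect_equal(discordance_2d_3d(2, list(score = 5)), "concordant")
  expect_equal(discordance_2d_3d(0, list(score = 0.5)), "3d_lower")
  expect_equal(discordance_2d_3d(0.4, list(category = "negative")), "3d_higher")
})

test_that("agreement_table counts and percent agreement are exact", {
  ref <- c(rep("positive", 10), rep("negative", 8), "borderline", "borderline")
  prd <- ref
  prd[1] <- "negative"; prd[11] <- "positive"   # 2 of 20 discordant
  at <- agreement_table(ref, prd)
  expect_equal(at$overall_percent_agreement, 90)
  expect_equal(at$n_cases, 20)
  expect_equal(sum(at$confusion), 20)
  expect_equal(100 * sum(diag(at$confusion)) / 20, at$overall_percent_agreement)
  expect_equal(agreement_table(ref, ref)$overall_percent_agreement, 100)
  prd2 <- ref; prd2[1:4] <- c("negative", "negative", "borderline", "negative")
  expect_equal(agreement_table(ref, prd2)$overall_percent_agreement, 80)
  expect_error(agreement_table(ref, prd[1:3]), "length")
  expect_error(agreement_table(c("positive"), c("high")), "unknown category")
})

test_that("profile summaries are invariant to layer order where they should be", {
  sc <- c(0.3, 1.4, 0.0, 2.2, 0.9)
  p1 <- build_profile("a", mk_scores(sc))
  set.seed(4)
  for (k in 1:5) {
    p2 <- build_profile("a", mk_scores(sample(sc)))
    expect_equal(p2$average_score_pct, p1$average_score_pct)
    expect_equal(p2$min_score, p1$min_score)
    expect_equal(p2$max_score, p1$max_score)
    expect_equal(p2$crossing_1pct, p1$crossing_1pct)
    expect_equal(p2$pattern, p1$pattern)
  }
})

test_that("gradient and constant phantoms drive the expected 3D patterns", {
  # rising 0 -> 3%: crossing + heterogeneous
  n_z <- 6
  pg <- phantom_params(image_shape = c(n_z, 192, 192),
                       pdl1_fraction_profile = gradient_profile(0, 0.03, n_z),
                       seed = 70)
  rep_g <- run_case(generate_case(pg)$stack, truth = generate_case(pg)$truth,
                    config = list(analysis_interval_um = 1.4))
  expect_true(rep_g$summary$crossing_1pct)
  expect_equal(rep_g$summary$pattern, "heterogeneous_presence")
  # constant 5%: uniform, no crossing
  pc <- phantom_params(image_shape = c(3, 192, 192),
                       pdl1_fraction_profile = 0.05, seed = 71)
  rep_c <- run_case(generate_case(pc)$stack, truth = generate_case(pc)$truth,
                    config = list(analysis_interval_um = 1.4))
  expect_false(rep_c$summary$crossing_1pct)
  expect_equal(rep_c$summary$pattern, "uniform_expressed")
  # all-zero: uniform negative
  pz <- phantom_params(image_shape = c(3, 192, 192),
                       pdl1_fraction_profile = 0, seed = 72)
  rep_z <- run_case(generate_case(pz)$stack, truth = generate_case(pz)$truth,
                    config = list(analysis_interval_um = 1.4))
  expect_equal(rep_z$summary$pattern, "uniform_negative")
  expect_equal(rep_z$summary$average_score_pct, 0)
})

test_that("superficial-borderline/deep-positive phantom shows 3d_higher discordance", {
  n_z <- 5
  frac <- c(0.005, rep(0.02, n_z - 1))
  p <- phantom_params(image_shape = c(n_z, 192, 192),
                      pdl1_fraction_profile = frac, seed = 73)
  case <- generate_case(p)
  rep <- run_case(case$stack, truth = case$truth,
                  config = list(analysis_interval_um = 1.4))
  expect_equal(rep$summary$reference_2d$category, "borderline")
  expect_equal(rep$summary$average_category, "positive")
  expect_equal(rep$summary$discordance, "3d_higher")
})

test_that("cohort_table flattens case profiles", {
  case <- small_phantom(n_z = 3, fraction = 0.02, seed = 42)
  rep <- run_case(case$stack, truth = case$truth, config = list(case_id = "x"))
  tab <- cohort_table(list(rep))
  expect_equal(nrow(tab), 1)
  expect_equal(tab$case_id, "x")
  expect_equal(tab$average_score_pct, rep$summary$average_score_pct)
})
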