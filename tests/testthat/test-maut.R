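test_that("curvature solving hits the midpoint anchor", {
  # symmetric midpoint: linear limit
  expect_identical(solve_curvature(0, 0.5, 1), Inf)
  # concave anchor set: v(v_mid) = 0.5 to 1e-10
  rho <- solve_curvature(0, 0.25, 1)
  expect_true(is.finite(rho) && rho > 0)
  expect_equal(savf_score(0.25, 0, 0.25, 1, rho = rho), 0.5, tolerance = 1e-10)
  # convex mirror
  rho2 <- solve_curvature(0, 0.75, 1)
  expect_true(rho2 < 0)
  expect_equal(savf_score(0.75, 0, 0.75, 1, rho = rho2), 0.5, tolerance = 1e-10)
  # curvature grows as the midpoint approaches the minimum
  mids <- c(0.4, 0.3, 0.2, 0.1)
  rhos <- vapply(mids, function(m) solve_curvature(0, m, 1), 0)
  expect_true(all(diff(rhos) < 0)) # smaller rho = more concave
  expect_error(solve_curvature(0, 1.5, 1), class = "rhizorank_domain_error")
})

test_that("scores hit the anchors, respect direction and clamp", {
  expect_equal(savf_score(c(0, 0.5, 1), 0, 0.5, 1), c(0, 0.5, 1))
  expect_equal(savf_score(0.25, 0, 0.5, 1), 0.25)
  expect_equal(savf_score(c(0, 1), 0, 0.5, 1, direction = "decreasing"), c(1, 0))
  # clamping outside the anchor interval
  expect_equal(savf_score(c(-10, 10), 0, 0.5, 1), c(0, 1))
  # anchors for a non-linear spec
  rho <- solve_curvature(2, 3, 8)
  expect_equal(savf_score(c(2, 3, 8), 2, 3, 8, rho = rho), c(0, 0.5, 1),
               tolerance = 1e-9)
})

test_that("savf properties hold for random anchor sets", {
  set.seed(2024)
  for (i in 1:50) {
    a <- random_anchor()
    rho <- solve_curvature(a$v_min, a$v_mid, a$v_max)
    got <- savf_score(c(a$v_min, a$v_mid, a$v_max), a$v_min, a$v_mid, a$v_max,
                      rho = rho)
    expect_equal(got, c(0, 0.5, 1), tolerance = 1e-9)
    grid <- seq(a$v_min, a$v_max, length.out = 100)
    sc <- savf_score(grid, a$v_min, a$v_mid, a$v_max, rho = rho)
    expect_true(all(diff(sc) >= -1e-12))
    expect_true(all(sc >= -1e-12 & sc <= 1 + 1e-12))
    # linear limit at the exact midpoint
    mid <- (a$v_min + a$v_max) / 2
    lin <- savf_score(grid, a$v_min, mid, a$v_max)
    expect_lt(max(abs(lin - (grid - a$v_min) / (a$v_max - a$v_min))), 1e-6)
  }
})

test_that("score matrices map anchors to 0/1 and match the closed form", {
  specs <- attribute_specs(tibble::tibble(
    attribute = c("a1", "a2"), criterion = c("plant_growth", "persistence"),
    direction = "increasing", v_min = 0, v_mid = c(0.25, 0.5), v_max = 1
  ))
  at_max <- tibble::tibble(strain = rep(c("X", "Y"), 2),
                           attribute = rep(c("a1", "a2"), each = 2),
                           value = 1)
  expect_equal(score_matrix(at_max, specs)$score, rep(1, 4))
  at_min <- dplyr::mutate(at_max, value = 0)
  expect_equal(score_matrix(at_min, specs)$score, rep(0, 4))
  # independent closed-form evaluation
  perf <- tibble::tibble(strain = "X", attribute = c("a1", "a2"),
                         value = c(0.6, 0.3))
  sm <- score_matrix(perf, specs)
  rho1 <- solve_curvature(0, 0.25, 1)
  manual1 <- (1 - exp(-0.6 / rho1)) / (1 - exp(-1 / rho1))
  expect_equal(sm$score[sm$attribute == "a1"], manual1, tolerance = 1e-9)
  expect_equal(sm$score[sm$attribute == "a2"], 0.3, tolerance = 1e-9)
  expect_error(score_matrix(tibble::tibble(strain = "X", attribute = "zz", value = 1),
                            specs),
               class = "rhizorank_completeness_error")
})

test_that("criterion weights split equally across their attributes", {
  specs3 <- attribute_specs(tibble::tibble(
    attribute = c("a", "b", "c"),
    criterion = c("plant_growth", "colonization", "persistence"),
    direction = "increasing", v_min = 0, v_mid = 0.5, v_max = 1
  ))
  w <- attribute_weights(c(plant_growth = 1, colonization = 1, persistence = 1), specs3)
  expect_equal(w$weight, rep(1 / 3, 3))
  # 0.5/0.25/0.25 over 9/4/25 attributes
  specs_big <- attribute_specs(tibble::tibble(
    attribute = sprintf("x%02d", 1:38),
    criterion = rep(c("plant_growth", "colonization", "persistence"), c(9, 4, 25)),
    direction = "increasing", v_min = 0, v_mid = 0.5, v_max = 1
  ))
  wb <- attribute_weights(c(plant_growth = 0.5, colonization = 0.25,
                            persistence = 0.25), specs_big)
  expect_equal(unique(wb$weight[wb$criterion == "plant_growth"]), 0.5 / 9)
  expect_equal(unique(wb$weight[wb$criterion == "colonization"]), 0.0625)
  expect_equal(unique(wb$weight[wb$criterion == "persistence"]), 0.01)
  expect_equal(sum(wb$weight), 1)
  # raw weights are normalized first
  wr <- attribute_weights(c(plant_growth = 2, colonization = 1, persistence = 1),
                          specs3)
  expect_equal(wr$weight[wr$criterion == "plant_growth"], 0.5)
  # positive weight on an empty criterion
  specs_no_col <- attribute_specs(tibble::tibble(
    attribute = c("a", "c"), criterion = c("plant_growth", "persistence"),
    direction = "increasing", v_min = 0, v_mid = 0.5, v_max = 1
  ))
  expect_error(
    attribute_weights(c(plant_growth = 1, colonization = 1, persistence = 1),
                      specs_no_col),
    class = "rhizorank_config_error"
  )
})

test_that("totals are weighted sums with deterministic ranks", {
  specs3 <- attribute_specs(tibble::tibble(
    attribute = c("a", "b", "c"),
    criterion = c("plant_growth", "colonization", "persistence"),
    direction = "increasing", v_min = 0, v_mid = 0.5, v_max = 1
  ))
  perf <- tibble::tibble(strain = "X", attribute = c("a", "b", "c"),
                         value = c(0.2, 0.5, 0.8))
  sm <- score_matrix(perf, specs3)
  w <- attribute_weights(c(plant_growth = 1, colonization = 1, persistence = 1),
                         specs3)
  tot <- total_scores(sm, w)
  expect_equal(tot$total, 0.5)
  expect_equal(tot$total,
               tot$sub_plant_growth + tot$sub_colonization + tot$sub_persistence)
  # all scores 1: total 1 regardless of weights
  perf1 <- dplyr::mutate(perf, value = 1)
  w2 <- attribute_weights(c(plant_growth = 5, colonization = 1, persistence = 3),
                          specs3)
  expect_equal(total_scores(score_matrix(perf1, specs3), w2)$total, 1)
  # tie flag and lexicographic order
  perf2 <- tibble::tibble(strain = rep(c("B", "A"), each = 3),
                          attribute = rep(c("a", "b", "c"), 2),
                          value = rep(0.5, 6))
  tot2 <- total_scores(score_matrix(perf2, specs3), w)
  expect_equal(tot2$strain, c("A", "B"))
  expect_true(all(tot2$tied))
  expect_equal(tot2$rank, c(1, 2))
})

test_that("weight-splitting and rescaling invariances hold", {
  specs <- attribute_specs(tibble::tibble(
    attribute = c("a", "c1"), criterion = c("plant_growth", "persistence"),
    direction = "increasing", v_min = 0, v_mid = 0.5, v_max = 1
  ))
  perf <- tibble::tibble(strain = c("X", "X", "Y", "Y"),
                         attribute = rep(c("a", "c1"), 2),
                         value = c(0.9, 0.4, 0.3, 0.8))
  w <- attribute_weights(c(plant_growth = 0.6, persistence = 0.4), specs)
  tot <- total_scores(score_matrix(perf, specs), w)
  # duplicate the persistence attribute: criterion weight splits equally,
  # totals are unchanged
  specs_dup <- attribute_specs(tibble::tibble(
    attribute = c("a", "c1", "c2"),
    criterion = c("plant_growth", "persistence", "persistence"),
    direction = "increasing", v_min = 0, v_mid = 0.5, v_max = 1
  ))
  perf_dup <- dplyr::bind_rows(perf,
    tibble::tibble(strain = c("X", "Y"), attribute = "c2", value = c(0.4, 0.8)))
  w_dup <- attribute_weights(c(plant_growth = 0.6, persistence = 0.4), specs_dup)
  tot_dup <- total_scores(score_matrix(perf_dup, specs_dup), w_dup)
  expect_equal(tot$total, tot_dup$total, tolerance = 1e-12)
  # strictly positive rescaling of raw weights leaves the ranking unchanged
  w_scaled <- attribute_weights(c(plant_growth = 6, persistence = 4), specs)
  tot_scaled <- total_scores(score_matrix(perf, specs), w_scaled)
  expect_equal(tot$rank, tot_scaled$rank)
  expect_equal(tot$total, tot_scaled$total, tolerance = 1e-12)
})

test_that("constructed dominance reverses between scenarios", {
  # X dominates plant growth + colonization, Y dominates persistence
  specs <- attribute_specs(tibble::tibble(
    attribute = c("pg", "co", "pe"),
    criterion = c("plant_growth", "colonization", "persistence"),
    direction = "increasing", v_min = 0, v_mid = 0.5, v_max = 1
  ))
  # X leads plant growth strongly; Y leads persistence strongly
  perf <- tibble::tibble(
    strain = rep(c("X", "Y"), each = 3),
    attribute = rep(c("pg", "co", "pe"), 2),
    value = c(0.9, 0.55, 0.1, 0.3, 0.5, 0.9)
  )
  sm <- score_matrix(perf, specs)
  w1 <- attribute_weights(c(plant_growth = 0.5, colonization = 0.25,
                            persistence = 0.25), specs)
  weq <- attribute_weights(c(plant_growth = 1, colonization = 1,
                             persistence = 1), specs)
  r1 <- total_scores(sm, w1, scenario = "S1")
  req <- total_scores(sm, weq, scenario = "S3")
  expect_equal(r1$strain[r1$rank == 1], "X")
  expect_equal(req$strain[req$rank == 1], "Y")
  both <- dplyr::bind_rows(r1, req)
  cmp <- compare_scenarios(both)
  expect_true(cmp$reversal)
  expect_true(cmp$top_changed)
})

test_that("scenario comparison handles identity and degenerate cases", {
  specs <- attribute_specs(tibble::tibble(
    attribute = "a", criterion = "plant_growth", direction = "increasing",
    v_min = 0, v_mid = 0.5, v_max = 1
  ))
  perf <- tibble::tibble(strain = c("X", "Y"), attribute = "a", value = c(0.8, 0.2))
  sm <- score_matrix(perf, specs)
  w <- attribute_weights(c(plant_growth = 1), specs)
  ra <- total_scores(sm, w, scenario = "A")
  rb <- total_scores(sm, w, scenario = "B")
  cmp <- compare_scenarios(dplyr::bind_rows(ra, rb))
  expect_false(cmp$reversal)
  expect_false(cmp$top_changed)
  # single strain: rank 1 everywhere
  perf1 <- perf[1, ]
  r1 <- total_scores(score_matrix(perf1, specs), w, scenario = "A")
  expect_equal(r1$rank, 1)
  # inconsistent strain sets
  rbad <- total_scores(score_matrix(perf1, specs), w, scenario = "B")
  expect_error(compare_scenarios(dplyr::bind_rows(ra, rbad)),
               class = "rhizorank_integrity_error")
})

test_that("default scenarios are normalized and the YAML config round-trips", {
  scen <- scenario_weights()
  sums <- tapply(scen$weight, scen$scenario, sum)
  expect_equal(as.numeric(sums), rep(1, 3))
  s1 <- scen[scen$scenario == "S1", ]
  expect_equal(s1$weight[s1$criterion == "plant_growth"], 0.5)
  specs <- default_attribute_specs()
  expect_equal(nrow(specs), 38)
  expect_equal(unname(table(specs$criterion)[c("plant_growth", "colonization",
                                               "persistence")]),
               c(9L, 3L, 26L), ignore_attr = TRUE)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_maut_config(specs, scen, path)
  back <- read_maut_config(path)
  expect_equal(as.data.frame(back$attributes), as.data.frame(specs))
  expect_equal(as.data.frame(back$scenarios), as.data.frame(scen))
})
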