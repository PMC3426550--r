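test_that("one-pass outlier rejection recomputes the mean once on survivors", {
  # 200 sits 2.04 SD from the first-pass mean 116.67 (SD 40.82): removed
  a <- aggregate_strain(c(100, 100, 100, 100, 100, 200))
  expect_equal(a$n_raw, 6); expect_equal(a$n_kept, 5)
  expect_equal(a$mean, 100); expect_equal(a$sd, 0)
  # max |z| ~ 1.46: nothing removed
  b <- aggregate_strain(c(300, 310, 290, 305, 295, 300))
  expect_equal(b$n_kept, 6); expect_equal(b$mean, 300)
  # all equal: SD 0, nothing removed
  cc <- aggregate_strain(rep(42, 5))
  expect_equal(cc$n_kept, 5); expect_equal(cc$mean, 42); expect_equal(cc$sd, 0)
  expect_error(aggregate_strain(7), "insufficient replicates")
})

test_that("grouped aggregation matches the scalar reference on random groups", {
  set.seed(31)
  dt <- data.table::data.table(
    strain_id = rep(sprintf("S%02d", 1:25), each = 10),
    query_name = "control",
    normalized_size = rlnorm(250, log(300), 0.25))
  got <- sgaepsilon:::.aggregate_groups(dt, "normalized_size",
                                        by = c("strain_id", "query_name"))
  for (s in unique(dt$strain_id)) {
    want <- aggregate_strain(dt[strain_id == s, normalized_size])
    row <- got[strain_id == s]
    expect_equal(row$n_kept, want$n_kept)
    expect_equal(row$mean, want$mean)
    expect_equal(row$sd, want$sd)
  }
})

test_that("Welch test reproduces the textbook statistic and t.test exactly", {
  r <- welch_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, -3.674, tolerance = 1e-3)
  expect_equal(r$df, 4)
  expect_equal(r$p, 0.0213, tolerance = 1e-2)

  set.seed(11)
  for (i in 1:25) {
    x <- rnorm(sample(3:12, 1), 100, runif(1, 1, 20))
    y <- rnorm(sample(3:12, 1), 100 + rnorm(1, 0, 10), runif(1, 1, 20))
    ours <- welch_test(x, y)
    ref <- t.test(x, y, var.equal = FALSE)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("degenerate zero-variance groups follow the documented convention", {
  expect_equal(welch_test(c(5, 5, 5), c(5, 5, 5)), list(t = 0, df = NA_real_, p = 1))
  r <- welch_test(c(5, 5, 5), c(6, 6, 6))
  expect_equal(r$p, 0)
  expect_error(welch_test(5, c(1, 2)), "insufficient replicates")
})

test_that("fitness and epsilon arithmetic", {
  expect_equal(fitness_of(343, 343), 1)
  expect_equal(fitness_of(300, 343), 0.8746, tolerance = 1e-4)
  expect_equal(fitness_of(0, 343), 0)
  expect_error(fitness_of(300, 0), "must be > 0")

  expect_equal(epsilon_score(0.5 * 0.9, 0.5, 0.9), 0)
  expect_equal(epsilon_score(0, 1, 1), -1)       # synthetic lethal bound
  expect_equal(epsilon_score(0.78, 0.48, 0.89), 0.3528)
  expect_error(epsilon_score(-0.1, 1, 1), ">= 0")
})

test_that("epsilon is antisymmetric around the multiplicative expectation", {
  set.seed(5)
  for (i in 1:50) {
    Wx <- runif(1, 0.2, 1.2); Wq <- runif(1, 0.5, 1.1)
    Wobs <- runif(1, 0, 1.5)
    mirror <- 2 * Wx * Wq - Wobs
    if (mirror < 0) next
    expect_equal(epsilon_score(Wobs, Wx, Wq),
                 -epsilon_score(mirror, Wx, Wq), tolerance = 1e-14)
  }
})

test_that("stringent classification applies the three criteria jointly, thresholds inclusive", {
  # the three canonical example records
  expect_equal(classify_interaction(50, 0.005, -0.15),
               list(class = "aggravating", stringent_flag = TRUE))
  expect_equal(classify_interaction(39, 0.001, -0.50),
               list(class = "aggravating", stringent_flag = FALSE))  # pixel rule fails
  expect_equal(classify_interaction(80, 0.005, 0.25),
               list(class = "alleviating", stringent_flag = TRUE))
  # exactly at each threshold -> included
  expect_true(classify_interaction(40, 0.01, -0.12)$stringent_flag)
  expect_true(classify_interaction(-40, 0.01, 0.2)$stringent_flag)
  # just inside each gate -> excluded
  expect_false(classify_interaction(40, 0.0101, -0.12)$stringent_flag)
  expect_false(classify_interaction(40, 0.01, -0.119)$stringent_flag)
  expect_equal(classify_interaction(40, 0.01, -0.119)$class, "none")
})

test_that("score_interactions assembles fitness, epsilon and flags per strain", {
  ctl <- data.table::data.table(
    strain_id = c("A", "B", "dead1", "dub1"),
    n_raw = 10L, n_kept = 10L,
    mean = c(343, 343, 10, 343), sd = c(10, 10, 2, 10))
  qry <- data.table::data.table(
    strain_id = c("A", "B", "dead1", "dub1"),
    n_raw = 6L, n_kept = 6L,
    mean = c(343, 200, 8, 200), sd = c(10, 10, 2, 10))
  rec <- score_interactions(ctl, qry, Wq = 0.9, W_control_median = 343,
                            query_name = "q1", dubious_strains = "dub1")
  expect_equal(nrow(rec), 4)
  a <- rec[array_gene == "A"]
  expect_equal(a$W_observed, 0.9)               # Wq re-introduced after plate scaling
  expect_equal(a$epsilon, 0.9 - 1 * 0.9)
  expect_equal(a$class, "none")
  b <- rec[array_gene == "B"]
  expect_equal(b$delta_pixels, 143)
  expect_equal(b$epsilon, 0.9 * 200 / 343 - 0.9, tolerance = 1e-12)
  expect_true(b$stringent_flag)
  expect_equal(b$class, "aggravating")
  # dead strains are scored but never stringent; dubious strains flagged
  expect_true(rec[array_gene == "dead1", dead_flag])
  expect_false(rec[array_gene == "dead1", stringent_flag])
  expect_true(rec[array_gene == "dub1", dubious_flag])
  expect_true(rec[array_gene == "dub1", stringent_flag])  # retained for QC
  # BH column is monotone with p and informational only
  expect_true(all(rec$bh_q >= rec$p_value - 1e-15))
})

test_that("score_screens recovers query fitness and planted interactions end to end", {
  pe <- data.frame(strain_id = rep(c("STR0005", "STR0006"), each = 3),
                   query_name = rep(c("scs3d", "yft2d", "scs3d_yft2d"), 2),
                   epsilon = rep(c(-0.45, 0.45), each = 3))
  # one plate per screen here, so keep the plate effect small: the raw-median
  # query-fitness measurement has only 3-5 plates to average over
  cfg <- sga_sim_config(n_array_strains = 120, planted_effects = pe,
                        noise_cv = 0.08, plate_effect_sd = 0.02,
                        n_dubious_pairs = 0, seed = 21)
  sim <- simulate_screen_set(cfg)
  nr <- normalize_screens(sim$colonies, sim$layout)
  sc <- score_screens(nr$colonies, sim$layout)
  expect_equal(sc$query_fitness[order(query)]$Wq, c(0.95, 0.89, 0.96),
               tolerance = 0.05)
  neg <- sc$records[array_gene == "STR0005"]
  expect_true(all(neg$class == "aggravating"))
  expect_true(all(neg$stringent_flag))
  expect_equal(mean(neg$epsilon), -0.45, tolerance = 0.08)
  pos <- sc$records[array_gene == "STR0006"]
  expect_true(all(pos$class == "alleviating"))
  expect_equal(mean(pos$epsilon), 0.45, tolerance = 0.08)
})

test_that("clustergram table is genes x queries with epsilon values", {
  sim <- simulate_screen_set(tiny_config(40, seed = 13))
  nr <- normalize_screens(sim$colonies, sim$layout)
  sc <- score_screens(nr$colonies, sim$layout)
  wide <- clustergram_table(sc$records, stringent_only = FALSE)
  expect_equal(names(wide), c("array_gene", "scs3d", "scs3d_yft2d", "yft2d"))
  expect_equal(nrow(wide), 40)
  one <- sc$records[array_gene == "STR0010" & query == "yft2d", epsilon]
  expect_equal(wide[array_gene == "STR0010", yft2d], one)
})
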