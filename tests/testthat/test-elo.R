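test_that("score function recovers a noiseless exponential decay", {
  ranks <- 1:12
  counts <- 1000 * exp(-0.5 * ranks)
  tab <- toy_table(matrix(counts, ncol = 1), genus = sprintf("g%02d", ranks))
  sf <- fit_score_function(tab)
  expect_equal(sf$b, 0.5, tolerance = 1e-6)
  expect_equal(sf$r_squared, 1, tolerance = 1e-9)
  expect_true(all(diff(predict(sf, 1:10)) < 0))
  # two distinct ranks: two parameters interpolate exactly
  sf2 <- fit_score_function(toy_table(matrix(c(30, 10), ncol = 1),
                                      genus = c("a", "b")))
  expect_equal(sf2$r_squared, 1, tolerance = 1e-8)
  # degenerate data cannot identify a decay
  expect_error(fit_score_function(toy_table(matrix(c(5, 5, 5), ncol = 1),
                                            genus = letters[1:3])),
               "fit failure")
})

test_that("score fit attains R^2 >= 0.8 on a default simulated experiment", {
  e <- simulate_experiment(sim_config(seed = 7))
  sf <- fit_score_function(e$tables[paste0("C", 0:6)])
  expect_gte(sf$r_squared, 0.8)
  g <- glance(sf)
  expect_identical(names(g), c("a", "b", "r_squared", "n_points"))
})

test_that("match scores are normalised and share tied ranks", {
  sf <- structure(list(a = 1, b = 0.5, r_squared = 1, n_points = 10),
                  class = "score_function")
  sc <- match_scores(sf, c(gA = 30, gB = 20, gC = 10))
  expect_equal(sum(sc), 1, tolerance = 1e-12)
  expect_true(all(diff(sc) < 0))
  tied <- match_scores(sf, c(gA = 20, gB = 20, gC = 5))
  expect_equal(tied[["gA"]], tied[["gB"]])
  expect_equal(sum(tied), 1, tolerance = 1e-12)
  # the tied pair shares the mean of the rank-1 and rank-2 scores
  raw <- predict(sf, 1:3)
  expect_equal(unname(tied["gA"]), mean(raw[1:2]) / (mean(raw[1:2]) * 2 + raw[3]))
})

test_that("the update reduces to classical Elo for two players", {
  st <- elo_state(c("gA", "gB"))
  up <- match_update(st, scores = c(gA = 1, gB = 0))
  expect_equal(unname(up$ratings[c("gA", "gB")]), c(1016, 984))
  # across a grid of rating gaps the two-player update is classical Elo
  for (gap in seq(-800, 800, by = 100)) {
    st <- elo_state(K = 32, D = 400)
    st$ratings <- c(gA = 1000 + gap, gB = 1000)
    up <- match_update(st, scores = c(gA = 1, gB = 0))
    expected <- 32 * (1 - 1 / (1 + 10^((1000 - (1000 + gap)) / 400)))
    expect_equal(unname(up$ratings["gA"] - (1000 + gap)), expected,
                 tolerance = 1e-9)
  }
})

test_that("the multiplayer update matches the K(N-1)(So - Se) form", {
  st <- elo_state(c("gA", "gB", "gC"))
  up <- match_update(st, scores = c(gA = 0.5, gB = 0.3, gC = 0.2))
  # equal ratings: rating-based and uniform expectations both give 1/3
  expect_equal(unname(up$ratings - 1000), c(10 + 2 / 3, -(2 + 2 / 15), -(8 + 8 / 15)),
               tolerance = 1e-9)
  stu <- elo_state(c("gA", "gB", "gC"), mode = "uniform")
  upu <- match_update(stu, scores = c(gA = 0.5, gB = 0.3, gC = 0.2))
  expect_equal(upu$ratings, up$ratings, tolerance = 1e-9)
  # fixed point: observed equal to expected leaves ratings unchanged
  fix <- match_update(st, scores = c(gA = 1 / 3, gB = 1 / 3, gC = 1 / 3))
  expect_equal(unname(fix$ratings), rep(1000, 3), tolerance = 1e-12)
  expect_warning(one <- match_update(st, scores = c(gA = 1)), "single participant")
  expect_identical(one$ratings, st$ratings)
})

test_that("total rating is conserved in every match", {
  withr::with_seed(31, {
    for (i in 1:200) {
      n <- sample(2:8, 1)
      mode <- sample(c("rating", "uniform"), 1)
      st <- elo_state(mode = mode)
      st$ratings <- stats::setNames(rnorm(n, 1000, 120), paste0("g", 1:n))
      sc <- runif(n); sc <- sc / sum(sc); names(sc) <- names(st$ratings)
      up <- match_update(st, scores = sc)
      expect_lt(abs(sum(up$ratings) - sum(st$ratings)), 1e-9)
    }
  })
})

test_that("a better rank never yields a lower updated rating", {
  sf <- structure(list(a = 0.4, b = 0.4, r_squared = 1, n_points = 10),
                  class = "score_function")
  withr::with_seed(8, {
    for (i in 1:50) {
      n <- sample(3:8, 1)
      ab <- sort(rexp(n, 1 / 50), decreasing = TRUE) + seq(n, 1) # distinct
      names(ab) <- paste0("g", 1:n)
      st <- elo_state()
      st$ratings <- stats::setNames(rnorm(n, 1000, 100), names(ab))
      k <- sample(n - 1, 1)
      better <- ab
      worse <- ab
      worse[c(k, k + 1)] <- worse[c(k + 1, k)] # focal genus g<k> demoted
      up_b <- match_update(st, abundances = better, score_function = sf)
      up_w <- match_update(st, abundances = worse, score_function = sf)
      g <- paste0("g", k)
      expect_gte(up_b$ratings[[g]], up_w$ratings[[g]])
    }
  })
})

test_that("permutation averaging over microcosm orders behaves as expected", {
  sf <- structure(list(a = 0.4, b = 0.4, r_squared = 1, n_points = 10),
                  class = "score_function")
  # single microcosm: order cannot matter
  tab <- toy_table(matrix(c(30, 20, 10), 3, 1), genus = c("a", "b", "c"))
  r1 <- rate_cycle(elo_state(), tab, sf, n_perm = 20, seed = 1)
  expect_true(all(r1$summary$sd == 0))
  # the abundance floor excludes genera below 0.1% everywhere
  m <- matrix(c(6000, 3997, 3, 5000, 4996, 4), 3, 2)
  tabf <- toy_table(m, genus = c("a", "b", "tiny"))
  rf <- rate_cycle(elo_state(), tabf, sf, n_perm = 10, seed = 1)
  expect_false("tiny" %in% rf$summary$genus)
  expect_false("tiny" %in% names(rf$state$ratings))
  # two microcosms with reversed rankings: symmetric, so mean deltas vanish
  tab2 <- toy_table(matrix(c(30, 10, 10, 30), 2, 2), genus = c("a", "b"))
  r2 <- rate_cycle(elo_state(), tab2, sf, n_perm = 400, seed = 2)
  expect_true(all(abs(r2$summary$rating - 1000) < r2$summary$sd + 1e-9))
  # enumeration oracle: the permutation mean is the average over both orders
  run_order <- function(ord) {
    st <- elo_state()
    for (j in ord) {
      st <- match_update(st, abundances = count_matrix(tab2)[, j],
                         score_function = sf)
    }
    st$ratings[c("a", "b")]
  }
  exact <- (run_order(1:2) + run_order(2:1)) / 2
  expect_equal(stats::setNames(r2$summary$rating, r2$summary$genus)[c("a", "b")],
               exact, tolerance = 0.5)
  expect_error(rate_cycle(elo_state(), tab2, sf, n_perm = 0), "n_perm")
})

test_that("rating an experiment chains cycles and respects the rated set", {
  e <- simulate_experiment(sim_config(n_genera = 12, n_microcosms = 5,
                                      n_cycles = 1, carrying_capacity = 1e4,
                                      inoculum_cells = 100, read_depth = 500,
                                      seed = 4))
  sf <- fit_score_function(e$tables)
  tr <- rate_experiment(e, cycles = 0, score_function = sf, n_perm = 30, seed = 7)
  rc <- withr::with_seed(7, {
    m <- count_matrix(e$tables$C0)
    rel <- sweep(m, 2, pmax(colSums(m), 1), "/")
    rated <- rownames(m)[apply(rel > 0.001, 1, any) & rowSums(m) > 0]
    rate_cycle(elo_state(), e$tables$C0, sf, n_perm = 30, rated_genera = rated)
  })
  expect_equal(tidy(tr), tr$trajectory)
  expect_identical(unique(tr$trajectory$cycle), 0)
  expect_equal(stats::setNames(tr$trajectory$rating, tr$trajectory$genus),
               stats::setNames(rc$summary$rating, rc$summary$genus))
  # genera never above the floor are absent from the trajectory
  m <- count_matrix(e$tables$C0)
  absent <- rownames(m)[rowSums(m) == 0]
  expect_false(any(absent %in% tr$trajectory$genus))
  expect_error(rate_experiment(e, cycles = c(0, 9)), "C9")
})

test_that("final ratings recover a known fitness hierarchy", {
  cfg <- sim_config(n_genera = 20, n_microcosms = 10, n_cycles = 4,
                    interaction_strength = 0, abundance_sdlog = 0,
                    founder_sd = 0, carrying_capacity = 1e5,
                    inoculum_cells = 500, seed = 2)
  e <- simulate_experiment(cfg)
  tr <- rate_experiment(e, cycles = c(0, 2, 4), n_perm = 100, seed = 2)
  last <- dplyr::filter(tr$trajectory, cycle == 4)
  truth <- e$pool$fitness[match(last$genus, e$pool$genus)]
  expect_gte(cor(last$rating, truth, method = "spearman"), 0.8)
})

test_that("competitiveness trends are called from Spearman correlations", {
  tr <- tibble::tibble(genus = rep(c("up", "down", "flat"), each = 4),
                       cycle = rep(c(0, 1, 4, 6), 3),
                       rating = c(990, 1000, 1010, 1020,
                                  1039, 1021, 1005, 996,
                                  1000, 1000, 1000, 1000),
                       sd = 0)
  res <- elo_trend(tr)
  expect_equal(res$rho[res$genus == "up"], 1)
  expect_identical(res$direction[res$genus == "up"], "increasing")
  expect_equal(res$rho[res$genus == "down"], -1)
  expect_identical(res$direction[res$genus == "down"], "decreasing")
  expect_identical(res$direction[res$genus == "flat"], "none")
  expect_true(is.na(res$rho[res$genus == "flat"]))
  # genera rated in too few cycles are dropped
  short <- dplyr::filter(tr, !(genus == "up" & cycle > 1))
  expect_false("up" %in% elo_trend(short)$genus)
  expect_error(elo_trend(dplyr::filter(tr, cycle == 0)), "no genus")
})

test_that("the trend test is calibrated under the null", {
  n_genera <- 1000
  traj <- withr::with_seed(12, tibble::tibble(
    genus = rep(sprintf("g%04d", 1:n_genera), each = 8),
    cycle = rep(0:7, n_genera),
    rating = rnorm(8 * n_genera, 1000, 10),
    sd = 0))
  res <- elo_trend(traj, exact = TRUE)
  frac <- mean(res$p_value < 0.05, na.rm = TRUE)
  se <- sqrt(0.05 * 0.95 / n_genera)
  expect_lt(abs(frac - 0.05), 2 * se)
})
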