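star4 <- clade_genealogy(data.frame(
  parent = "root", child = paste0("s", 1:4), mutations = 1))

test_that("rho equals the mean root-to-leaf mutation distance", {
  single <- clade_genealogy(data.frame(parent = "root", child = "s1",
                                       mutations = 3))
  expect_equal(rho(single), 3)
  expect_equal(rho(star4), 1)

  set.seed(5)
  for (i in 1:20) {
    g <- random_genealogy(sample(5:30, 1))
    sums <- naive_leaf_sums(g$edges, g$root)
    expect_equal(rho(g), mean(sums[g$leaves]))
  }
})

test_that("sigma matches the Saillard closed forms and brute force", {
  expect_equal(sigma(star4), 0.5)
  single <- clade_genealogy(data.frame(parent = "root", child = "s1",
                                       mutations = 7))
  expect_equal(sigma(single), sqrt(7))

  set.seed(6)
  for (i in 1:20) {
    g <- random_genealogy(sample(5:30, 1))
    nb <- naive_subtended(g$edges, g$root)
    expect_equal(sigma(g)^2, sum(g$edges$mutations * (nb / g$n)^2))
  }
})

test_that("rho and sigma are invariant under branch subdivision", {
  set.seed(8)
  for (i in 1:10) {
    g <- random_genealogy(10)
    # split one internal-or-leaf branch into two summing to the same m
    e <- sample(which(g$edges$mutations >= 1), 1)
    m <- g$edges$mutations[e]
    m1 <- sample(0:m, 1)
    mid <- "splitnode"
    edges2 <- g$edges
    child <- edges2$child[e]
    edges2$child[e] <- mid
    edges2$mutations[e] <- m1
    edges2 <- rbind(edges2, data.frame(parent = mid, child = child,
                                       mutations = m - m1))
    g2 <- clade_genealogy(edges2)
    expect_equal(rho(g2), rho(g))
    expect_equal(sigma(g2), sigma(g))
  }
})

test_that("genealogy construction validates its input", {
  expect_error(clade_genealogy(data.frame(parent = "a", child = "b",
                                          mutations = -1)), "negative")
  expect_error(clade_genealogy(data.frame(
    parent = c("a", "c"), child = c("b", "d"),
    mutations = 0)), "root")
  g <- clade_genealogy(data.frame(parent = c("r", "r"),
                                  child = c("a", "b"), mutations = 1))
  rt <- read_genealogy(withr::local_tempfile(
    lines = c("parent\tchild\tmutations", "r\ta\t1", "r\tb\t1")))
  expect_equal(rho(rt), rho(g))
})

test_that("rho ages follow the clock arithmetic with a floored CI", {
  # rho = 2, sigma = 1 by construction: two leaves at distances 3 and 1
  # would not give sigma 1, so build it directly from a star of n=4 with
  # total 8 mutations on one branch pattern; instead check the formula
  # through a genealogy with known rho and sigma
  g <- clade_genealogy(data.frame(parent = "root", child = paste0("s", 1:4),
                                  mutations = 2))
  clock <- clock_model("complete")
  a <- age_from_rho(g, clock)
  expect_equal(a$rho_or_ml, 2)
  expect_equal(a$sigma, sqrt(8 * (1 / 4)^2))
  expect_equal(a$age_years, 2 * 3624)
  expect_equal(a$ci95_low, (2 - 1.96 * a$sigma) * 3624)
  expect_equal(a$ci95_high, (2 + 1.96 * a$sigma) * 3624)

  empty <- clade_genealogy(data.frame(parent = "root", child = "s1",
                                      mutations = 0))
  a0 <- age_from_rho(empty, clock)
  expect_equal(a0$age_years, 0)
  expect_equal(a0$ci95_low, 0)
  expect_equal(a0$ci95_high, 0)
})

test_that("the CI lower bound never goes below zero", {
  g <- clade_genealogy(data.frame(parent = "root", child = paste0("s", 1:2),
                                  mutations = c(1, 0)))
  a <- age_from_rho(g, clock_model("complete"))
  expect_gte(a$ci95_low, 0)
  expect_true(a$ci95_low <= a$age_years && a$age_years <= a$ci95_high)
})

test_that("ML dating recovers the Poisson closed forms", {
  clock <- clock_model("complete")
  rate <- 1 / clock$years_per_mutation
  single <- clade_genealogy(data.frame(parent = "root", child = "s1",
                                       mutations = 5))
  ml <- ml_tmrca(single, clock, ci = FALSE)
  expect_equal(ml$age_years, 5 / rate, tolerance = 1e-4)

  # star: MLE equals rho / rate; grid search confirms
  g <- clade_genealogy(data.frame(parent = "root", child = paste0("s", 1:5),
                                  mutations = c(3, 1, 2, 0, 4)))
  ml <- ml_tmrca(g, clock, ci = FALSE)
  expect_equal(ml$age_years, rho(g) / rate, tolerance = 1e-4)
  grid <- seq(1000, 30000, by = 10)
  ll <- vapply(grid, function(T)
    sum(stats::dpois(g$edges$mutations, rate * T, log = TRUE)), numeric(1))
  expect_equal(ml$age_years, grid[which.max(ll)], tolerance = 1e-2)
})

test_that("ML profile-likelihood CI brackets the estimate", {
  clock <- clock_model("complete")
  g <- clade_genealogy(data.frame(
    parent = c("root", "root", "a", "a"),
    child = c("a", "s1", "s2", "s3"),
    mutations = c(2, 3, 1, 2)))
  ml <- ml_tmrca(g, clock)
  expect_true(ml$ci95_low < ml$age_years)
  expect_true(ml$ci95_high > ml$age_years)
  # parent must be older than children at the optimum (positive durations
  # are enforced by the parameterisation, so the age exceeds rho of the
  # subtree only when the data demand it); sanity: finite and positive
  expect_gt(ml$age_years, 0)
})

test_that("a mutationless genealogy dates to zero with a likelihood bound", {
  clock <- clock_model("complete")
  g <- clade_genealogy(data.frame(parent = "root", child = paste0("s", 1:3),
                                  mutations = 0))
  ml <- ml_tmrca(g, clock)
  expect_equal(ml$age_years, 0)
  expect_equal(ml$ci95_low, 0)
  expect_equal(ml$ci95_high, 1.92 / (3 / clock$years_per_mutation))
})

test_that("rho-age CIs reach near-nominal coverage on star clades", {
  set.seed(31)
  hits <- replicate(300, {
    g <- simulate_clade(simulation_config(
      seed = NULL, clade_age_years = 8000, n_samples = 10,
      topology = "star"))$genealogy
    a <- age_from_rho(g)
    a$ci95_low <= 8000 && 8000 <= a$ci95_high
  })
  expect_gte(mean(hits), 0.90)
  expect_lte(mean(hits), 1.00)
})

test_that("rho-age bias on star clades stays under 5% of the true age", {
  set.seed(32)
  ages <- replicate(500, age_from_rho(simulate_clade(simulation_config(
    seed = NULL, clade_age_years = 8000, n_samples = 10,
    topology = "star"))$genealogy)$age_years)
  expect_lt(abs(mean(ages) - 8000) / 8000, 0.05)
})

test_that("clock models validate and label their rates", {
  expect_equal(clock_model("complete")$years_per_mutation, 3624)
  expect_error(clock_model("custom", years_per_mutation = -1), "positive")
  expect_equal(clock_model("custom", years_per_mutation = 1000)$label,
               "custom")
})
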