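test_that("population draws recover the target moments", {
  sc <- default_breeding_scenario()
  mat <- sc$maternal; mat$n <- 10000L
  tab <- generate_population(mat, seed = 101)
  # plant height at the published maternal moments (72.48 +/- 16.23)
  expect_equal(mean(tab$height_cm), 72.48, tolerance = 0.5 / 72.48)
  expect_lt(abs(sd(tab$height_cm) - 16.23), 0.5)
  for (tr in trait_names()) {
    expect_lt(abs(mean(tab[[tr]]) - mat$mean[tr]), 0.01 * abs(mat$mean[tr]) + 1e-9,
              label = paste("mean recovery", tr))
    expect_lt(abs(sd(tab[[tr]]) - mat$sd[tr]), 0.03 * mat$sd[tr] + 1e-9,
              label = paste("sd recovery", tr))
  }
})

test_that("moment recovery tightens with sample size", {
  sc <- default_breeding_scenario()
  err <- sapply(c(1e3, 1e4), function(n) {
    spec <- sc$f1; spec$n <- as.integer(n)
    reps <- sapply(1:20, function(s) {
      mean(generate_population(spec, seed = 1000 + s * 7 + n)$height_cm)
    })
    sd(reps)
  })
  expect_lt(err[2], err[1]) # Monte-Carlo rate
})

test_that("independent specs give near-zero sample correlations", {
  sc <- default_breeding_scenario()
  spec <- population_spec(sc$f1$mean, sc$f1$sd, diag(6), n = 10000,
                          generation = "F1")
  tab <- generate_population(spec, seed = 102)
  r <- cor(as.data.frame(tab)[trait_names()])
  diag(r) <- 0
  expect_lt(max(abs(r)), 0.04)
})

test_that("target correlations are recovered at Monte-Carlo accuracy", {
  sc <- default_breeding_scenario()
  spec <- sc$f1; spec$n <- 5000L
  tab <- generate_population(spec, seed = 103)
  r <- cor(as.data.frame(tab)[trait_names()])
  expect_equal(r["height_cm", "branches"], 0.49, tolerance = 0.04 / 0.49)
  expect_equal(r["dry_weight_g", "height_cm"], 0.35, tolerance = 0.04 / 0.35)
  expect_equal(r["dry_weight_g", "fhr"], -0.26, tolerance = 0.04 / 0.26)
})

test_that("one seed governs every draw, reproducibly", {
  sc <- default_breeding_scenario(seed = 9)
  t1 <- suppressMessages(generate_scenario(sc))
  t2 <- suppressMessages(generate_scenario(sc))
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  t3 <- suppressMessages(generate_scenario(default_breeding_scenario(seed = 10)))
  expect_false(identical(t1$dry_weight_g, t3$dry_weight_g))

  p1 <- generate_population(sc$f1, seed = 5)
  p2 <- generate_population(sc$f1, seed = 5)
  expect_identical(p1, p2)
})

test_that("constant traits and infeasible specs are policed", {
  sc <- default_breeding_scenario()
  pat <- generate_population(sc$paternal, seed = 104)
  expect_true(all(pat$mf_pct == 0)) # paternal line carries no multifoliolate leaves
  R <- diag(6); R[1, 5] <- R[5, 1] <- 0.3
  mu <- sc$paternal$mean; sd <- sc$paternal$sd # mf sd = 0
  expect_error(population_spec(mu, sd, R, n = 10, generation = "P_paternal"),
               "infeasible")
})

test_that("clamping is reported and heavy clamping warns", {
  sc <- default_breeding_scenario()
  tab <- generate_population(sc$f1, seed = 105)
  expect_named(attr(tab, "clamp_rate"), trait_names())
  low <- sc$f1$mean; low["mf_pct"] <- 2 # mass below the [0, 100] bound
  spec <- population_spec(low, sc$f1$sd, sc$f1$R, n = 2000, generation = "F1")
  expect_warning(clamped <- generate_population(spec, seed = 106),
                 "mf_pct")
  expect_gt(attr(clamped, "clamp_rate")["mf_pct"], 0.05)
  expect_true(all(clamped$mf_pct >= 0))
})

test_that("non-PSD correlation matrices are repaired transparently", {
  # an impossible correlation triangle forces the eigenvalue-clipping repair
  expect_message(fixed <- correlation_from_pairs(
    data.frame(trait_a = c("height_cm", "branches", "height_cm"),
               trait_b = c("branches", "fhr", "fhr"),
               rho = c(0.9, 0.9, -0.9))), "repaired")
  expect_equal(unname(diag(fixed)), rep(1, 6), tolerance = 1e-9)
  expect_gte(min(eigen(fixed, symmetric = TRUE)$values), -1e-9)
  expect_gt(attr(fixed, "repair_delta"), 0)
})

test_that("zero heritability yields no lineage divergence (type-I sanity)", {
  sc <- default_breeding_scenario()
  sc$h2[] <- 0
  nonsig <- sapply(1:100, function(s) {
    sc$seed <- 200 + s
    tab <- suppressMessages(generate_scenario(sc))
    f2s <- tab$dry_weight_g[tab$generation == "F2" & tab$group == "selected"]
    f2u <- tab$dry_weight_g[tab$generation == "F2" & tab$group == "unselected"]
    two_sample_ttest(f2s, f2u)$p_value >= 0.05
  })
  expect_gte(mean(nonsig), 0.90)
})

test_that("default response separates the F2 lineages (power sanity)", {
  wins <- sapply(1:100, function(s) {
    tab <- suppressMessages(generate_scenario(default_breeding_scenario(seed = 300 + s)))
    mean(tab$dry_weight_g[tab$generation == "F2" & tab$group == "selected"]) >
      mean(tab$dry_weight_g[tab$generation == "F2" & tab$group == "unselected"])
  })
  expect_gte(mean(wins), 0.95)
})

test_that("the calibrated default scenario tracks the published F2 dry weight", {
  dw <- sapply(1:25, function(s) {
    tab <- suppressMessages(generate_scenario(default_breeding_scenario(seed = 400 + s)))
    mean(tab$dry_weight_g[tab$generation == "F2" & tab$group == "selected"])
  })
  expect_lt(abs(mean(dw) - 143.69), 0.10 * 143.69)
})

test_that("full heritability transmits the whole selection differential", {
  # select on dry weight alone at h2 = 1: F2 mean shift equals the realized
  # differential, which itself tracks the analytic truncation value i * sigma
  sc <- default_breeding_scenario(seed = 11, n_f1 = 5000, n_f2 = 5000)
  sc$h2[] <- 0; sc$h2["dry_weight_g"] <- 1
  dw_only <- build_index(
    matrix(as.numeric(trait_names() == "dry_weight_g"), ncol = 1,
           dimnames = list(trait_names(), "PC1")), variance_pct = 100)
  tab <- suppressMessages(generate_scenario(sc, index_model = dw_only))
  f1 <- tab$dry_weight_g[tab$generation == "F1"]
  f2s <- tab$dry_weight_g[tab$generation == "F2" & tab$group == "selected"]
  s_real <- attr(tab, "differentials")$selected["dry_weight_g"]
  shift <- mean(f2s) - mean(f1)
  expect_equal(shift, unname(s_real), tolerance = 0.05)
  frac <- 28 / 90
  i_analytic <- dnorm(qnorm(1 - frac)) / frac
  expect_equal(unname(s_real), i_analytic * sd(f1), tolerance = 0.05)
})

test_that("response is monotone in heritability at a fixed seed", {
  shifts <- sapply(c(0, 0.25, 0.5, 0.75, 1), function(h) {
    sc <- default_breeding_scenario(seed = 12)
    sc$h2[] <- 0.3; sc$h2["dry_weight_g"] <- h
    tab <- suppressMessages(generate_scenario(sc))
    mean(tab$dry_weight_g[tab$generation == "F2" & tab$group == "selected"])
  })
  expect_true(all(diff(shifts) >= 0))
})

test_that("selection rules that keep zero or every individual are rejected", {
  sc <- default_breeding_scenario(seed = 13)
  sc$selection_rule <- select_threshold(1e6)
  expect_error(suppressMessages(generate_scenario(sc)), "0 of")
  sc$selection_rule <- select_threshold(-1e6)
  expect_error(suppressMessages(generate_scenario(sc)), "both lineages")
})
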