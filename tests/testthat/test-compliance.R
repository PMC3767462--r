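panel <- drugs95_panel()

test_that("a mid-range profile earns zero stars; one excursion earns one", {
  prof <- midrange_profile(panel)
  res <- evaluate_compliance(prof, panel)
  expect_equal(res$stars$stars, 0)
  prof$S_mol <- 1200  # range 300-1000
  res <- evaluate_compliance(prof, panel)
  expect_equal(res$stars$stars, 1)
  expect_equal(
    res$status$status[res$status$descriptor == "S_mol"], "out_of_range")
})

test_that("printed endpoints are in range (closed bounds)", {
  prof <- midrange_profile(panel)
  prof$S_mol <- 1000
  prof$logS_wat <- -6.0
  expect_equal(evaluate_compliance(prof, panel)$stars$stars, 0)
  prof$S_mol <- 1000.0001
  expect_equal(evaluate_compliance(prof, panel)$stars$stars, 1)
})

test_that("stars agree with a brute-force per-descriptor oracle", {
  prof <- random_profiles(200, seed = 101)
  expect_equal(evaluate_compliance(prof, panel)$stars$stars,
               oracle_stars(prof, panel))
  for (s in 1:5) {
    pan <- random_panel(seed = 200 + s)
    expect_equal(evaluate_compliance(prof, pan)$stars$stars,
                 oracle_stars(prof, pan))
  }
})

test_that("widening ranges or dropping star members never raises stars", {
  prof <- random_profiles(100, seed = 7)
  base <- evaluate_compliance(prof, panel)$stars$stars
  wide <- panel
  wide$lower <- wide$lower - 5
  wide$upper <- wide$upper + 5
  expect_true(all(evaluate_compliance(prof, wide)$stars$stars <= base))
  drop1 <- panel
  drop1$star[drop1$descriptor == "MW"] <- FALSE
  expect_true(all(evaluate_compliance(prof, drop1)$stars$stars <= base))
})

test_that("missing descriptors follow the missing policy", {
  prof <- midrange_profile(panel)
  prof$MW <- NA_real_
  res <- evaluate_compliance(prof, panel, missing = "skip")
  expect_equal(res$stars$stars, 0)
  expect_equal(res$stars$evaluated, sum(panel$star) - 1)
  expect_error(evaluate_compliance(prof, panel, missing = "fail"), "MW")
})

test_that("percent compliance counts only compounds carrying the descriptor", {
  prof <- tibble::tibble(id = paste0("c", 1:4),
                         logS_wat = c(-3, -7, NA, -2))
  pc <- percent_compliance(prof, "logS_wat", panel)
  expect_equal(pc$n_present, 3)
  expect_equal(pc$percent, 66.67)
  expect_equal(pc$fraction, 2 / 3)
  all_in <- tibble::tibble(id = "a", logS_wat = -3)
  expect_equal(percent_compliance(all_in, "logS_wat", panel)$percent, 100)
  none <- tibble::tibble(id = "a", logS_wat = NA_real_)
  expect_error(percent_compliance(none, "logS_wat", panel), "undefined")
})

test_that("a planted 70% library reports exactly 70.00", {
  cfg <- synthetic_config(n = 1000, seed = 5,
                          planted_compliance = c(logS_wat = 0.7))
  prof <- generate_profiles(cfg)
  expect_equal(percent_compliance(prof, "logS_wat", panel)$n_in_range, 700)
  expect_equal(percent_compliance(prof, "logS_wat", panel)$percent, 70.00)
})

test_that("stars distribution counts and conserves the library", {
  prof <- random_profiles(500, seed = 42)
  dist <- stars_distribution(prof, panel)
  expect_equal(sum(dist$count), 500)
  expect_true(all(dist$stars >= 0 & dist$stars == round(dist$stars)))
  manual <- table(oracle_stars(prof, panel))
  expect_equal(dist$count[dist$count > 0],
               as.integer(manual))
  expect_error(stars_distribution(prof[0, ], panel), "non-empty")
  all_ok <- midrange_profile(panel)
  expect_equal(stars_distribution(all_ok, panel)$stars, 0)
})

test_that("the two shipped panel variants differ where the source does", {
  res <- drugs95_panel("results")
  expect_equal(panel$upper[panel$descriptor == "logK_HSA"], 1.2)
  expect_equal(res$upper[res$descriptor == "logK_HSA"], 1.5)
  expect_equal(res$upper[res$descriptor == "logBB"], 1.2)
  expect_equal(res$lower[res$descriptor == "n_metab"], 1)
  expect_equal(res$upper[res$descriptor == "n_metab"], 8)
})

test_that("glance reports library-level compliance percentages", {
  prof <- random_profiles(50, seed = 9)
  g <- glance(evaluate_compliance(prof, panel))
  st <- oracle_stars(prof, panel)
  expect_equal(g$pct_stars0, round(100 * mean(st == 0), 2))
  expect_equal(g$pct_stars_le2, round(100 * mean(st <= 2), 2))
  expect_gte(g$pct_stars_le2, g$pct_stars0)
})
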