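test_that("library means exclude missing values from both sides", {
  prof <- tibble::tibble(id = c("a", "b", "c"),
                         MW = c(1, 2, 3), logP = c(0.5, NA, 1.5))
  m <- summarize_means(prof)
  expect_equal(m$mean[m$descriptor == "MW"], 2)
  expect_equal(m$mean[m$descriptor == "logP"], 1)
  expect_equal(m$n_present[m$descriptor == "logP"], 2)
  same <- tibble::tibble(id = c("x", "y"), MW = c(7, 7), HBA = c(2, 2))
  expect_equal(summarize_means(same)$mean, c(7, 2))
  expect_error(summarize_means(prof[0, ]), "non-empty")
})

test_that("sample means of a big seeded library sit within 3 SE of target", {
  marg <- list(logP = list(dist = "normal", mean = 4.18, sd = 2.0,
                           lower = -Inf, upper = Inf, integer = FALSE),
               logBB = list(dist = "normal", mean = -1.30, sd = 1.0,
                            lower = -Inf, upper = Inf, integer = FALSE))
  prof <- generate_profiles(synthetic_config(n = 10000, seed = 2,
                                             marginals = marg))
  m <- summarize_means(prof)
  expect_lt(abs(m$mean[m$descriptor == "logP"] - 4.18), 3 * 2.0 / 100)
  expect_lt(abs(m$mean[m$descriptor == "logBB"] + 1.30), 3 * 1.0 / 100)
})

test_that("the compliance table reports per-subset percentages honestly", {
  panel <- drugs95_panel()
  all_in <- dplyr::bind_rows(lapply(1:5, function(i) {
    dplyr::mutate(midrange_profile(panel), id = paste0("c", i))
  }))
  tab <- summarize_compliance(all_in, panel, subsets = FALSE)
  cells <- tab$total[tab$descriptor %in% panel$descriptor]
  expect_true(all(cells == 100))
  expect_equal(tab$total[tab$descriptor == "stars0"], 100)
  # planted half-compliant descriptor shows 50.00
  cfg <- synthetic_config(n = 200, seed = 8,
                          planted_compliance = c(logK_p = 0.5))
  planted <- generate_profiles(cfg)
  tab2 <- summarize_compliance(planted, panel, subsets = FALSE)
  expect_equal(tab2$total[tab2$descriptor == "logK_p"], 50.00)
  # empty subset -> NA cells, never zero
  membership <- tibble::tibble(id = planted$id, nothing = FALSE)
  tab3 <- summarize_compliance(planted, panel, subsets = membership)
  expect_true(all(is.na(tab3$nothing)))
  expect_false(any(tab3$nothing %in% 0))
  # stars <= 2 row always dominates the stars = 0 row
  expect_gte(tab2$total[tab2$descriptor == "stars_le2"],
             tab2$total[tab2$descriptor == "stars0"])
})

test_that("histograms are left-closed, lower-edge labelled and conservative", {
  h <- histogram_counts(c(0, 0, 1, 2), width = 1, origin = 0)
  expect_equal(h$lower_edge, c(0, 1, 2))
  expect_equal(h$count, c(2L, 1L, 1L))
  # a value exactly on an edge belongs to the bin it opens
  h2 <- histogram_counts(c(0.5, 1.0, 1.5), width = 0.5, origin = 0)
  expect_equal(h2$lower_edge[h2$count > 0], c(0.5, 1.0, 1.5))
  set.seed(99)
  h3 <- histogram_counts(runif(1000), width = 0.1, origin = 0)
  expect_equal(sum(h3$count), 1000)
  expect_error(histogram_counts(c(1, NaN, 2)), "position")
  expect_error(histogram_counts(numeric(0)), "non-empty")
})

test_that("report rendering is deterministic and format-checked", {
  prof <- random_profiles(20, seed = 3)
  means <- summarize_means(prof)
  comp <- summarize_compliance(prof, subsets = FALSE)
  hist <- list(stars = histogram_counts(
    evaluate_compliance(prof)$stars$stars))
  for (fmt in c("csv", "json", "markdown")) {
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    f1 <- render_report(means, comp, hist, d1, fmt)
    f2 <- render_report(means, comp, hist, d2, fmt)
    expect_length(f1, 3)
    expect_identical(readLines(f1[1]), readLines(f2[1]))
    expect_identical(readLines(f1[3]), readLines(f2[3]))
  }
  d3 <- withr::local_tempdir()
  expect_length(render_report(means, comp, list(), d3, "csv"), 2)
  expect_error(render_report(means, comp, list(), d3, "pdf"))
})

test_that("plot builders return ggplot objects", {
  prof <- random_profiles(30, seed = 12)
  p1 <- plot_stars_distribution(total = prof)
  expect_s3_class(p1, "ggplot")
  p2 <- plot_descriptor_histogram(prof, "logS_wat", width = 0.5)
  expect_s3_class(p2, "ggplot")
  p3 <- ggplot2::autoplot(evaluate_compliance(prof))
  expect_s3_class(p3, "ggplot")
})
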