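test_that("Pearson correlations match a hand computation and normalization
           scales column maxima to 1", {
  params <- data.frame(
    cell_line = c("OVCAR3", "SKOV3", "CAG", "FADU"),
    ligand = c(2, 45, 80, 95),
    segregation_20 = c(0.10, 0.35, 0.48, 0.52),
    ca_influx = c(0.2, 0.9, 1.4, 1.5),
    excess_killing = c(0, 0.25, 0.42, 0.40))
  pm <- normalize_and_correlate(params)

  # every normalized column peaks at exactly 1
  expect_equal(unname(vapply(pm$normalized, max, numeric(1))),
               rep(1, ncol(pm$normalized)))

  # brute-force Pearson r, written out from the definition
  hand_r <- function(a, b) {
    am <- a - mean(a); bm <- b - mean(b)
    sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
  }
  cols <- names(params)[-1]
  for (i in seq_along(cols)) for (j in seq_along(cols)) {
    expect_equal(pm$correlation[i, j],
                 hand_r(params[[cols[i]]], params[[cols[j]]]),
                 tolerance = 1e-12)
  }

  # structural invariants of a correlation matrix
  expect_equal(pm$correlation, t(pm$correlation))
  expect_equal(unname(diag(pm$correlation)), rep(1, length(cols)))
  expect_true(all(abs(pm$correlation) <= 1 + 1e-12))
  expect_true(all(eigen(pm$correlation, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-10))

  # Pearson r is invariant to normalization (positive rescaling) and
  # normalization is idempotent
  raw_r <- stats::cor(as.matrix(params[cols]))
  expect_equal(pm$correlation, raw_r, tolerance = 1e-12)
  again <- normalize_and_correlate(pm$normalized)
  expect_equal(again$normalized, pm$normalized, tolerance = 1e-12)

  # perfectly proportional and anti-proportional columns
  prop <- data.frame(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8),
                     c = c(4, 3, 2, 1))
  r <- normalize_and_correlate(prop)$correlation
  expect_equal(r["a", "b"], 1)
  expect_equal(r["a", "c"], -1)

  expect_error(normalize_and_correlate(data.frame(a = c(0, 0, 0),
                                                  b = c(1, 2, 3))),
               "'a'")
  expect_error(normalize_and_correlate(params[1:2, ]), "at least 3")
})

test_that("excess killing subtracts the reference line", {
  k <- c(OVCAR3 = 0.2, SKOV3 = 0.6, CAG = 0.55, FADU = 0.2)
  e <- excess_killing(k, "OVCAR3")
  expect_equal(e[["OVCAR3"]], 0)
  expect_equal(e[["SKOV3"]], 0.4)
  expect_equal(unname(excess_killing(c(a = 1, b = 1, c = 1), "b")),
               c(0, 0, 0))
  expect_error(excess_killing(k, "HELA"), "reference")
})

test_that("condition aggregation reports means, SEMs and reference-relative
           p-values with conventional stars", {
  set.seed(91)
  cells <- data.frame(
    condition = rep(c("off_target", "on_target"), each = 20),
    self_clustering = c(rnorm(20, 5, 1), rnorm(20, 9, 1)),
    eom_20 = c(rnorm(20, 0.8, 0.1), rnorm(20, 0.3, 0.1)))
  s <- aggregate_condition(cells, reference = "off_target")
  on_sc <- s[s$condition == "on_target" & s$metric == "self_clustering", ]
  expect_lt(on_sc$p_value, 0.001)
  expect_equal(on_sc$stars, "***")
  expect_equal(on_sc$n, 20)
  expect_equal(on_sc$mean, mean(cells$self_clustering[21:40]))
  expect_equal(on_sc$sem, sd(cells$self_clustering[21:40]) / sqrt(20))
  # the reference tests as NA against itself
  expect_true(is.na(s$p_value[s$condition == "off_target"][1]))
  expect_error(aggregate_condition(cells, reference = "missing"), "unknown")

  # identical conditions give roughly uniform p-values
  reps <- replicate(200, {
    null <- data.frame(condition = rep(c("a", "b"), each = 8),
                       m = rnorm(16))
    aggregate_condition(null, "a")$p_value[2]
  })
  expect_gt(mean(reps < 0.05), 0.005)
  expect_lt(mean(reps < 0.05), 0.12)
  expect_gt(mean(reps), 0.35) # uniform mean 0.5, generous band

  # single-cell condition: SEM undefined and flagged as NA
  one <- rbind(cells, data.frame(condition = "lonely",
                                 self_clustering = 1, eom_20 = 0.5))
  s1 <- aggregate_condition(one, "off_target")
  expect_true(is.na(s1$sem[s1$condition == "lonely"][1]))

  # a 3-SEM shift is detectable at n = 30 cells
  set.seed(92)
  shift <- data.frame(
    condition = rep(c("ref", "shifted"), each = 30),
    m = c(rnorm(30, 5, 1), rnorm(30, 5 + 3 / sqrt(30), 1)))
  ps <- replicate(60, {
    shift$m <- c(rnorm(30, 5, 1), rnorm(30, 5 + 3 / sqrt(30), 1))
    aggregate_condition(shift, "ref")$p_value[2]
  })
  expect_gt(mean(ps < 0.05), 0.35) # well above the 5% null rate

  # Benjamini-Hochberg option never decreases p-values
  s_bh <- aggregate_condition(cells, "off_target", p_adjust = "BH")
  expect_true(all(s_bh$p_value >= s$p_value, na.rm = TRUE))
})
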