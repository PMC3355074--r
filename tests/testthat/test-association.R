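# KS association, size-matched permutation, distance decay, enrichment folds,
# case-control contrasts, RR/AR, and the generic permutation enrichment.

test_that("KS D equals a brute-force empirical-CDF max-gap oracle", {
  withr::with_seed(140, {
    for (rep in 1:5) {
      g <- fake_grid(c(a = 3e6), ws = 1e4)
      lv <- rbeta(300, 5, 2)
      m <- fake_methylome(g, lv)
      flag <- seq_len(300) %in% sample.int(300, 60)
      res <- ks_methylation_association(m, flag)
      x <- lv[flag]; y <- lv[!flag]
      grid_pts <- sort(c(x, y))
      d_oracle <- max(abs(vapply(grid_pts, function(t) mean(x <= t) - mean(y <= t),
                                 numeric(1))))
      expect_equal(res$statistic, d_oracle, tolerance = 1e-12)
    }
  })
})

test_that("a strongly shifted element group drives D toward 1", {
  g <- fake_grid(c(a = 2e6), ws = 1e4)
  lv <- c(runif(20, 0, 0.05), runif(180, 0.6, 0.9))
  m <- fake_methylome(g, lv)
  res <- ks_methylation_association(m, seq_len(200) <= 20)
  expect_equal(res$statistic, 1)
  expect_equal(res$extra$direction, "elements_lower")
  expect_warning(r0 <- ks_methylation_association(m, rep(FALSE, 200)), "empty")
  expect_true(is.na(r0$p_value))
})

test_that("element levels are event-weighted means over valid windows", {
  g <- fake_grid(c(a = 3e4), ws = 1e4)
  m <- fake_methylome(g, c(0.2, 0.8, NA), events = c(100, 300, 200))
  el <- tibble::tibble(chrom = "a", start = 5000, end = 15000)
  expect_equal(element_methylation_levels(el, m),
               (0.2 * 100 + 0.8 * 300) / 400)
  # element over an invalid window only
  el2 <- tibble::tibble(chrom = "a", start = 21000, end = 22000)
  expect_true(is.na(element_methylation_levels(el2, m)))
})

test_that("permutation association is seeded, deterministic, and detects planted elements", {
  withr::with_seed(141, {
    g <- fake_grid(c(a = 5e6), ws = 1e4)
    lv <- rbeta(500, 8, 3)
    m <- fake_methylome(g, lv)
    # plant 40 elements exclusively in the lowest-decile windows
    low <- order(lv)[1:50]
    els <- tibble::tibble(chrom = "a", start = g$start[sample(low, 40, TRUE)] + 100,
                          end = 0)
    els$end <- els$start + 2000
    r1 <- permutation_association(els, m, n_per_element = 100, seed = 9)
    r2 <- permutation_association(els, m, n_per_element = 100, seed = 9)
    expect_identical(tidy(r1), tidy(r2))
    expect_gte(r1$statistic, 0.8)
    expect_lt(r1$p_value, 1e-6)
    expect_equal(r1$extra$direction, "elements_lower")
  })
})

test_that("distance decay is null on a flat methylome", {
  withr::with_seed(142, {
    g <- fake_grid(c(a = 5e6), ws = 1e4)
    m <- fake_methylome(g, rbeta(500, 50, 17)) # tight around 0.75
    els <- tibble::tibble(chrom = "a", start = floor(runif(30) * 4.5e6) + 2e5,
                          end = 0)
    els$end <- els$start + 1e4
    dec <- distance_decay(els, m, distances = c(1e4, 5e4), n_per_element = 50,
                          seed = 4)
    expect_equal(nrow(dec), 2)
    expect_true(all(dec$d_max < 0.3))
  })
})

test_that("enrichment fold reproduces the 1%-stratum tenfold construction", {
  g <- fake_grid(c(a = 1e7), ws = 1e4)       # 1000 windows
  stratum <- seq_len(1000) <= 10             # 1% of windows
  # 100 elements, 10 in the stratum -> fold (10/100)/(10/1000) = 10
  els <- tibble::tibble(chrom = "a",
                        start = c(g$start[1:10], g$start[101:190]) + 100,
                        end = c(g$start[1:10], g$start[101:190]) + 600)
  res <- enrichment_fold(els, stratum, g)
  expect_equal(res$estimate, 10)
  # chi-square against brute-force contingency
  tab <- matrix(c(10, 90, 10, 990), nrow = 2, byrow = TRUE)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$statistic, sum((tab - e)^2 / e))
})

test_that("uniform elements give fold about 1", {
  withr::with_seed(143, {
    g <- fake_grid(c(a = 1e7), ws = 1e4)
    stratum <- seq_len(1000) %in% sample.int(1000, 100)
    els <- tibble::tibble(chrom = "a", start = floor(runif(800) * (1e7 - 1000)),
                          end = 0)
    els$end <- els$start + 500
    res <- enrichment_fold(els, stratum, g)
    expect_lt(abs(res$estimate - 1), 0.35)
    expect_gt(res$p_value, 1e-4)
  })
})

test_that("case-control contrast equals its contingency oracle and sees planted folds", {
  withr::with_seed(144, {
    g <- fake_grid(c(a = 1e7), ws = 1e4)
    stratum <- seq_len(1000) <= 100
    place <- function(n, p_in) {
      inside <- runif(n) < p_in
      w <- ifelse(inside, sample(1:100, n, TRUE), sample(101:1000, n, TRUE))
      tibble::tibble(chrom = "a", start = g$start[w] + 10, end = g$start[w] + 500)
    }
    cases <- place(400, 0.30)
    controls <- place(400, 0.10)
    res <- case_control_enrichment(cases, controls, stratum, g)
    ka <- res$extra$case_in; kb <- res$extra$control_in
    tab <- matrix(c(ka, 400 - ka, kb, 400 - kb), 2, byrow = TRUE)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(res$statistic, sum((tab - e)^2 / e))
    expect_equal(res$estimate, (ka / 400) / (kb / 400))
    expect_gt(res$estimate, 2)
    expect_lt(res$estimate, 4.5)
    expect_lt(res$p_value, 0.001)
  })
})

test_that("RR and AR: independence, the tenfold ratio case, and the count-table oracle", {
  # exact independence: a occurs at the same rate in and out of exposure
  groups <- tibble::tibble(window_id = 1:200,
                           a = rep(c(TRUE, FALSE, TRUE, FALSE), c(10, 90, 10, 90)),
                           b = rep(c(TRUE, FALSE), c(100, 100)),
                           c = FALSE)
  res <- relative_attributable_risk(groups, "b")
  expect_equal(res$estimate, 1)
  expect_equal(res$extra$ar, 0)
  # P(a|e) = 0.10, P(a|not e) = 0.01 -> RR 10
  g2 <- tibble::tibble(window_id = 1:1100,
                       a = c(rep(TRUE, 10), rep(FALSE, 90),
                             rep(TRUE, 10), rep(FALSE, 990)),
                       b = rep(c(TRUE, FALSE), c(100, 1000)), c = FALSE)
  r2 <- relative_attributable_risk(g2, "b")
  expect_equal(r2$estimate, 10)
  # random labelings against a brute-force 2x2-count computation
  withr::with_seed(145, {
    for (rep in 1:20) {
      n <- 150
      gg <- tibble::tibble(window_id = 1:n, a = runif(n) < 0.3,
                           b = runif(n) < 0.4, c = runif(n) < 0.2)
      for (expo in c("b", "c")) {
        e <- gg[[expo]]
        if (!any(e) || all(e) || sum(gg$a & !e) == 0) next
        rr <- relative_attributable_risk(gg, expo)
        n11 <- sum(gg$a & e); n10 <- sum(!gg$a & e)
        n01 <- sum(gg$a & !e); n00 <- sum(!gg$a & !e)
        rr_want <- (n11 / (n11 + n10)) / (n01 / (n01 + n00))
        ar_want <- ((n11 + n01) / n - n01 / (n01 + n00)) / ((n11 + n01) / n)
        expect_equal(rr$estimate, rr_want)
        expect_equal(rr$extra$ar, ar_want)
        expect_equal(rr$extra$excess_risk,
                     n11 / (n11 + n10) - n01 / (n01 + n00))
      }
    }
  })
})

test_that("infinite RR is flagged, not silently produced", {
  gg <- tibble::tibble(window_id = 1:50, a = rep(c(TRUE, FALSE), c(10, 40)),
                       b = rep(c(TRUE, FALSE), c(10, 40)), c = FALSE)
  expect_warning(r <- relative_attributable_risk(gg, "b"), "infinite")
  expect_identical(r$estimate, Inf)
})

test_that("window_groups restricts to valid windows and labels all three sets", {
  g <- fake_grid(c(a = 1e5), ws = 1e4)
  m <- fake_methylome(g, c(NA, rbeta(9, 5, 2)))
  els <- tibble::tibble(chrom = "a", start = 25000, end = 26000)
  des <- call_deserts(m, 0.2)
  dp <- tibble::tibble(chrom = "a", start = 81000, end = 89000)
  wg <- window_groups(m, els, des, dp)
  expect_equal(nrow(wg), 9)
  expect_true(wg$a[wg$window_id == 3])
  expect_true(wg$c[wg$window_id == 9])
})

test_that("permutation enrichment: add-one p, never zero, fold near 1 under the null", {
  withr::with_seed(146, {
    g <- fake_grid(c(a = 2e6), ws = 1e4)
    stratum <- seq_len(200) <= 20
    # every feature inside the stratum: p hits its resampling floor
    feats <- tibble::tibble(chrom = "a", start = g$start[1:15] + 10,
                            end = g$start[1:15] + 800)
    res <- feature_enrichment_permutation(feats, stratum, g, n_perm = 199,
                                          seed = 2)
    expect_equal(res$p_value, 1 / 200)
    expect_gt(res$estimate, 3)
    # uniform features: fold near 1, p comfortably away from the floor
    featsu <- tibble::tibble(chrom = "a", start = floor(runif(60) * (2e6 - 1e3)),
                             end = 0)
    featsu$end <- featsu$start + 800
    resu <- feature_enrichment_permutation(featsu, stratum, g, n_perm = 199,
                                           seed = 2)
    expect_gt(resu$p_value, 0.01)
    expect_lt(abs(resu$estimate - 1), 0.6)
    # determinism under the seed
    resu2 <- feature_enrichment_permutation(featsu, stratum, g, n_perm = 199,
                                            seed = 2)
    expect_identical(tidy(resu), tidy(resu2))
  })
})

test_that("tidy and glance return one-row summaries", {
  g <- fake_grid(c(a = 1e6), ws = 1e4)
  m <- fake_methylome(g, rbeta(100, 5, 2))
  res <- ks_methylation_association(m, seq_len(100) <= 10)
  td <- tidy(res)
  expect_equal(nrow(td), 1)
  expect_named(td, c("kind", "statistic", "p_value", "estimate",
                     "estimate_name", "n_case", "n_control"))
  gl <- glance(res)
  expect_equal(gl$n, 100)
})
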