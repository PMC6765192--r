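sim_cells <- function(n, means = c(0, 0, 0, 0), sd = 1) {
  grid <- expand.grid(osmolyte = c("mannitol", "glucose"),
                      snp = c(FALSE, TRUE))
  dplyr::bind_rows(lapply(seq_len(4), function(i) {
    tibble::tibble(larva_id = paste0(i, "_", seq_len(n)),
                   osmolyte = as.character(grid$osmolyte[i]),
                   snp = grid$snp[i],
                   value = rnorm(n, means[i], sd))
  }))
}

test_that("the Shapiro-Wilk gate accepts normal and rejects exponential cells", {
  set.seed(101)
  ok <- 0L
  for (i in 1:100) {
    d <- sim_cells(50)
    res <- suppressWarnings(normality_check(d))
    if (all(res$p > 0.05)) ok <- ok + 1L
  }
  expect_gte(ok, 60)  # each of 4 cells at n=50: all-pass most of the time

  rejected <- 0L
  for (i in 1:50) {
    d <- sim_cells(100)
    d$value <- rexp(nrow(d))
    res <- suppressWarnings(normality_check(d))
    if (all(res$p < 0.05)) rejected <- rejected + 1L
  }
  expect_gte(rejected, 45)

  const <- sim_cells(5); const$value <- 1
  expect_error(normality_check(const), "constant")
  expect_warning(normality_check({
    set.seed(3); d <- sim_cells(30); d$value <- rexp(nrow(d)); d
  }), "Shapiro-Wilk failed")
})

test_that("Sidak adjustment has its identity and monotonicity properties", {
  p <- c(0.001, 0.01, 0.04, 0.2, 0.9)
  expect_equal(sidak_adjust(p, 1), p)
  for (m in c(2, 4, 6))
    expect_true(all(sidak_adjust(p, m) >= sidak_adjust(p, m - 1)))
  expect_true(all(diff(sidak_adjust(p, 4)) > 0))
  expect_true(all(sidak_adjust(p, 4) >= p))
  expect_equal(sidak_adjust(0.05, 4), 1 - (1 - 0.05)^4)
})

test_that("the balanced 2x2 ANOVA matches the textbook decomposition", {
  # integer data, n = 3 per cell
  d <- tibble::tibble(
    larva_id = as.character(1:12),
    osmolyte = rep(c("mannitol", "glucose"), each = 6),
    snp = rep(c(FALSE, TRUE, FALSE, TRUE), each = 3),
    value = c(4, 5, 6, 7, 8, 9, 10, 12, 14, 6, 7, 8))
  res <- two_way_anova_sidak(d, pairs = NULL, check_normality = FALSE)
  # textbook sums of squares computed independently
  y <- d$value
  A <- ifelse(d$osmolyte == "glucose", 1, 2)
  B <- ifelse(d$snp, 1, 2)
  gm <- mean(y)
  ssa <- sum(tapply(y, A, function(v) length(v) * (mean(v) - gm)^2))
  ssb <- sum(tapply(y, B, function(v) length(v) * (mean(v) - gm)^2))
  cellm <- tapply(y, interaction(A, B), mean)
  ssab <- 3 * sum((cellm - rep(tapply(y, A, mean), 2) -
                     rep(tapply(y, B, mean), each = 2) + gm)^2)
  sse <- sum((y - ave(y, interaction(A, B)))^2)
  Fs <- c(ssa, ssb, ssab) / (sse / 8)
  expect_equal(res$anova$F, unname(Fs), tolerance = 1e-9)
  expect_equal(res$anova$p,
               unname(pf(Fs, 1, 8, lower.tail = FALSE)), tolerance = 1e-9)
})

test_that("a single configured comparison passes through unadjusted", {
  set.seed(7)
  d <- sim_cells(10, means = c(0, 2, 0, 0))
  r1 <- two_way_anova_sidak(d, pairs = list(c("mannitol", "glucose")),
                            check_normality = FALSE)
  expect_equal(r1$pairwise$p_sidak, r1$pairwise$p)
  r4 <- two_way_anova_sidak(d, check_normality = FALSE)
  expect_equal(nrow(r4$pairwise), 4)
  expect_true(all(r4$pairwise$p_sidak >= r4$pairwise$p))
})

test_that("empty design cells are named in the error", {
  set.seed(8)
  d <- sim_cells(5)
  d <- d[!(d$osmolyte == "glucose" & d$snp), ]
  expect_error(two_way_anova_sidak(d, check_normality = FALSE),
               "glucose\\+SNP")
})

test_that("a strong osmolyte effect is detected with high power", {
  set.seed(202)
  hits <- 0L
  for (i in 1:200) {
    d <- sim_cells(12, means = c(0, 2, 0, 2), sd = 1)  # Cohen's d = 2
    r <- two_way_anova_sidak(d, pairs = NULL, check_normality = FALSE)
    if (r$anova$p[r$anova$term == "osmolyte"] < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.99)
})

test_that("significance stars follow the figure-legend convention", {
  expect_equal(significance_stars(c(0.04, 0.0009, 0.2, 0.009, 5e-5)),
               c("*", "***", "", "**", "****"))
  set.seed(9)
  d <- sim_cells(8, means = c(0, 3, 0, 0))
  rep <- stats_report(two_way_anova_sidak(d, check_normality = FALSE))
  expect_setequal(unique(rep$type), c("anova", "pairwise"))
  expect_true(all(c("endpoint", "term", "p", "stars") %in% names(rep)))
})

test_that("endpoint extraction returns one value per larva", {
  well <- well_geometry()
  cohort <- simulate_cohort(n_per_group = 2, seed = 30, duration = 120)
  feats <- cohort_features(cohort$trajectories, well)
  et <- endpoint_table(feats, "pct_time", zone = "light")
  expect_equal(nrow(et), 8)
  expect_setequal(names(et), c("larva_id", "osmolyte", "snp", "value"))
  tr <- endpoint_table(feats, "transitions", zone = NULL)
  expect_equal(nrow(tr), 8)
})
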