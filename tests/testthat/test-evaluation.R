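test_that("scoring power: closed forms and direct-formula oracle", {
  lin <- data.frame(score = 1:10, affinity = 3 + 0.5 * (1:10))
  sp <- scoring_power(lin)
  expect_equal(sp$pcc, 1)
  expect_equal(sp$rmse, 0, tolerance = 1e-12)

  anti <- data.frame(score = 1:10, affinity = -(1:10))
  expect_equal(scoring_power(anti)$pcc, -1)

  set.seed(8)
  d <- data.frame(score = rnorm(10), affinity = rnorm(10))
  sp2 <- scoring_power(d)
  # textbook formulas evaluated independently
  pcc_direct <- sum((d$score - mean(d$score)) * (d$affinity - mean(d$affinity))) /
    sqrt(sum((d$score - mean(d$score))^2) * sum((d$affinity - mean(d$affinity))^2))
  beta <- pcc_direct * sd(d$affinity) / sd(d$score)
  alpha <- mean(d$affinity) - beta * mean(d$score)
  rmse_direct <- sqrt(mean((d$affinity - alpha - beta * d$score)^2))
  expect_equal(sp2$pcc, pcc_direct, tolerance = 1e-12)
  expect_equal(sp2$rmse, rmse_direct, tolerance = 1e-12)

  expect_error(scoring_power(d[1:2, ]), class = "dfire_domain")
  expect_error(scoring_power(data.frame(score = rep(1, 5),
                                        affinity = rnorm(5))),
               class = "dfire_domain")
})

test_that("enrichment factor: worked example, bounds, and null mean", {
  # 1000 compounds, 20 actives, 4 actives in the top 1% (10 selected)
  set <- data.frame(
    score = seq(1000, 1, -1),
    is_active = c(rep(c(TRUE, FALSE), c(4, 6)),           # top 10
                  rep(FALSE, 490),
                  rep(c(TRUE, FALSE), c(16, 484))))
  ef <- enrichment_factor(set, 1)
  expect_equal(ef$n_selected, 10L)
  expect_equal(ef$n_true, 4L)
  expect_equal(ef$ef, (4 / 10) / (20 / 1000))   # = 20
  expect_equal(ef$ef, 20)
  # EF at 100% is identically 1
  expect_equal(enrichment_factor(set, 100)$ef, 1)

  # perfect classifier attains the small-case maximum
  tiny <- data.frame(score = 10:1, is_active = rep(c(TRUE, FALSE), c(3, 7)))
  for (x in c(10, 20, 30, 50)) {
    n_sel <- ceiling(x / 100 * 10)
    ef_max <- (min(3, n_sel) / n_sel) / (3 / 10)
    expect_equal(enrichment_factor(tiny, x)$ef, ef_max)
  }

  # random scores enrich nothing on average (permutation oracle)
  set.seed(99)
  efs <- replicate(1000, {
    shuf <- set
    shuf$score <- sample(shuf$score)
    enrichment_factor(shuf, 10)$ef
  })
  expect_equal(mean(efs), 1, tolerance = 0.05)

  expect_error(enrichment_factor(data.frame(score = 1:5,
                                            is_active = rep(FALSE, 5)), 1),
               class = "dfire_domain")
})

test_that("ROC AUC: brute-force pairs, label flip, tie handling", {
  toy <- data.frame(score = c(5, 4, 4, 3, 2, 1),
                    is_active = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(roc_auc(toy), oracle_auc(toy))
  flipped <- toy
  flipped$is_active <- !toy$is_active
  expect_equal(roc_auc(flipped), 1 - roc_auc(toy))
  perfect <- data.frame(score = 6:1,
                        is_active = rep(c(TRUE, FALSE), c(3, 3)))
  expect_equal(roc_auc(perfect), 1)
  set.seed(4)
  rnd <- data.frame(score = rnorm(10000), is_active = rep(c(TRUE, FALSE), 5000))
  expect_equal(roc_auc(rnd), 0.5, tolerance = 0.02)
})

test_that("logAUC: perfect, inverted and random-score analytic value", {
  n <- 10000
  perfect <- data.frame(score = seq(n, 1),
                        is_active = rep(c(TRUE, FALSE), c(200, n - 200)))
  expect_equal(log_auc(perfect), 100, tolerance = 1e-9)

  inverted <- perfect
  inverted$is_active <- rev(perfect$is_active)
  expect_lt(log_auc(inverted), 1)

  # random scores: analytic area of TPR = FPR on a log axis,
  # 100 * (1 - lambda) / ln(1/lambda) ~= 14.46%, nowhere near 50%
  set.seed(12)
  rnd <- data.frame(score = rnorm(n), is_active = rep(c(TRUE, FALSE), n / 2))
  analytic <- 100 * (1 - 0.001) / log(1 / 0.001)
  expect_equal(analytic, 14.462, tolerance = 1e-4)
  expect_equal(log_auc(rnd), analytic, tolerance = 0.1 * analytic)

  # numeric cross-check of the analytic value by direct integration
  num <- integrate(function(f) f / (f * log(10)), 0.001, 1)$value /
    log10(1 / 0.001) * 100
  expect_equal(num, analytic, tolerance = 1e-6)
})

test_that("screening metrics are invariant under monotone score transforms", {
  set.seed(31)
  set <- simulate_screening_set(n_actives = 30, n_decoys = 300,
                                effect = 0.8, seed = 31)
  mono <- function(s) exp(2 * s) - 5
  tr <- set
  tr$score <- mono(set$score)
  expect_equal(roc_auc(tr), roc_auc(set))
  expect_equal(log_auc(tr), log_auc(set), tolerance = 1e-12)
  expect_equal(enrichment_factor(tr, 5)$ef, enrichment_factor(set, 5)$ef)
})

test_that("docking power applies the strict 2 A any-of rule", {
  pt <- dplyr::bind_rows(
    # best-scored pose already near-native: success at every depth
    tibble::tibble(complex_id = "c1", score = c(9, 8, 7),
                   rmsd = c(1.2, 3.5, 4.0)),
    # only the third pose is near-native
    tibble::tibble(complex_id = "c2", score = c(9, 8, 7),
                   rmsd = c(3.1, 2.5, 1.9)),
    # exactly 2.0 A everywhere: the boundary is strict, never a success
    tibble::tibble(complex_id = "c3", score = c(9, 8, 7),
                   rmsd = c(2.0, 2.0, 2.0)))
  dp <- docking_power(pt, top_n = 1:3)
  expect_equal(dp$success_rate, 100 * c(1, 1, 2) / 3)
  # ranking is by score, not input order
  scrambled <- pt[order(pt$rmsd), ]
  expect_equal(docking_power(scrambled, 1:3), dp)
  expect_error(docking_power(pt, top_n = 4), class = "dfire_domain")
  pt$rmsd[2] <- NA
  expect_error(docking_power(pt, 1), class = "dfire_domain")
})

test_that("ranking power over all orderings of a 3-member cluster", {
  # exhaustive permutation oracle: of the 6 prediction orders, exactly 1
  # ranks the whole cluster correctly and 2 put the best binder first
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  res <- purrr::map_dfr(perms, function(p) {
    ranking_power(data.frame(cluster_id = "t1",
                             affinity = c(9, 6, 3)[p],
                             score = c(9, 6, 3)))
  })
  expect_equal(sum(res$high_level == 100), 1L)
  expect_equal(sum(res$low_level == 100), 2L)

  # mixed clusters aggregate; tied affinities are skipped with a warning
  rec <- data.frame(
    cluster_id = rep(c("a", "b", "c"), each = 3),
    affinity = c(9, 6, 3, 9, 6, 3, 5, 5, 1),
    score = c(9, 6, 3, 9, 3, 6, 1, 2, 3))
  expect_warning(rp <- ranking_power(rec), "tied")
  expect_equal(rp$n_clusters, 2L)
  expect_equal(rp$n_skipped, 1L)
  expect_equal(rp$high_level, 50)
  expect_equal(rp$low_level, 100)
})
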