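test_that("correlation coefficients match hand oracles", {
  # classic rank example: sum d^2 = 4, r_s = 1 - 6*4/(5*24) = 0.8
  dm <- as_data_matrix(cbind(x = c(1, 2, 3, 4, 5), y = c(2, 1, 4, 3, 5)))
  cr <- correlate(dm, method = "spearman")
  expect_equal(cr$r["x", "y"], 0.8)
  expect_equal(diag(cr$r), c(x = 1, y = 1))

  # perfect anticorrelation for both parametric and rank methods
  dm2 <- as_data_matrix(cbind(x = 1:6, y = -(1:6)))
  expect_equal(correlate(dm2, method = "pearson")$r["x", "y"], -1)
  expect_equal(correlate(dm2, method = "spearman")$r["x", "y"], -1)
  expect_equal(correlate(dm2, method = "pearson")$p_raw["x", "y"], 0)

  # kendall: perfectly concordant series
  expect_equal(correlate(dm2, method = "kendall")$r["x", "y"], -1)
})

test_that("spearman equals pearson on average-ranked data (random matrices)", {
  withr::local_seed(101)
  for (rep in 1:25) {
    x <- matrix(rnorm(8 * 5), 8, 5, dimnames = list(NULL, paste0("v", 1:5)))
    x[sample(length(x), 3)] <- x[sample(length(x), 3)] # inject ties sometimes
    dm <- as_data_matrix(x)
    rs <- correlate(dm, method = "spearman", min_pairs = 3)$r
    ranked <- apply(x, 2, rank)
    rp <- correlate(as_data_matrix(ranked), method = "pearson",
                    min_pairs = 3)$r
    expect_lt(max(abs(rs - rp)), 1e-10)
  }
})

test_that("p-value adjustment matches its oracles and dominates raw p", {
  expect_equal(adjust_pvalues(0.02, method = "bonferroni", m = 10), 0.2)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
               rep(0.04, 4))
  expect_error(adjust_pvalues(c(0.2, 1.3)), "outside")

  withr::local_seed(7)
  for (rep in 1:50) {
    m <- sample(2:50, 1)
    p <- runif(m)
    expect_equal(adjust_pvalues(p, method = "BH"), oracle_bh(p))
    expect_true(all(adjust_pvalues(p, method = "BH") >= p))
    expect_true(all(adjust_pvalues(p, method = "bonferroni") >= p))
    expect_true(all(adjust_pvalues(p, method = "BH") <= 1))
  }
})

test_that("correlate adjusts over m = v(v-1)/2 unique pairs, symmetrically", {
  withr::local_seed(11)
  x <- matrix(rnorm(20 * 6), 20, 6, dimnames = list(NULL, paste0("v", 1:6)))
  cr <- correlate(as_data_matrix(x), method = "pearson", adjust_method = "BH")
  expect_equal(cr$r, t(cr$r))
  expect_equal(cr$p_adj, t(cr$p_adj))
  expect_equal(cr$n_pairs, t(cr$n_pairs))
  ut <- upper.tri(cr$p_raw)
  expect_equal(cr$p_adj[ut], oracle_bh(cr$p_raw[ut], m = 15))
  expect_true(all(cr$p_adj[ut] >= cr$p_raw[ut]))
  # bonferroni multiplies by the pair count, not v^2
  crb <- correlate(as_data_matrix(x), method = "pearson",
                   adjust_method = "bonferroni")
  expect_equal(crb$p_adj[ut], pmin(1, cr$p_raw[ut] * 15))
})

test_that("missing values use pairwise-complete observations and min_pairs", {
  x <- cbind(a = c(1, 2, 3, 4, 5, 6),
             b = c(2, 4, 6, 8, 10, 12),
             c = c(1, NA, NA, NA, 5, 2))
  x[1, "a"] <- NA
  cr <- correlate(as_data_matrix(x), method = "pearson", min_pairs = 4)
  expect_equal(cr$n_pairs["a", "b"], 5L)
  expect_equal(cr$r["a", "b"], 1) # b = 2a on the complete pairs
  # a-c has only 2 complete pairs -> undefined, never selectable
  expect_equal(cr$n_pairs["a", "c"], 2L)
  expect_true(is.na(cr$r["a", "c"]))
  edges <- select_edges(cr, r_min = 0, p_max = 1, strict_p = FALSE)
  expect_false(any(edges$source == "a" & edges$target == "c"))
})

test_that("constant variables trigger a warning and undefined correlations", {
  x <- cbind(a = 1:8, b = rep(3, 8), c = 8:1)
  expect_warning(cr <- correlate(as_data_matrix(x), method = "pearson"),
                 "constant")
  expect_true(is.na(cr$r["a", "b"]))
  expect_equal(cr$r["a", "c"], -1)
})

test_that("permuting a variable breaks its correlations and gives uniform p", {
  withr::local_seed(42)
  n <- 30
  f <- rnorm(n)
  x <- cbind(a = f + rnorm(n, sd = 0.3),
             b = f + rnorm(n, sd = 0.3),
             c = rnorm(n))
  base_r <- correlate(as_data_matrix(x), method = "pearson")$r["a", "b"]
  expect_gt(abs(base_r), 0.7)
  r_perm <- numeric(200)
  p_perm <- numeric(200)
  for (i in 1:200) {
    xp <- x
    xp[, "a"] <- xp[sample(n), "a"]
    crp <- correlate(as_data_matrix(xp), method = "pearson")
    r_perm[i] <- crp$r["a", "b"]
    p_perm[i] <- crp$p_raw["a", "b"]
  }
  expect_lt(median(abs(r_perm)), 0.25)
  ks <- suppressWarnings(stats::ks.test(p_perm, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("normality screen recommends pearson for normal data, spearman otherwise", {
  withr::local_seed(5)
  xn <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(NULL, paste0("v", 1:4)))
  scr <- normality_screen(as_data_matrix(xn))
  expect_true(all(scr$tests$testable))
  expect_true(all(scr$tests$W > 0 & scr$tests$W <= 1))
  expect_equal(scr$recommended_method, "pearson")

  xe <- cbind(xn, skew = rexp(30, rate = 1)^2)
  scr2 <- normality_screen(as_data_matrix(xe))
  expect_false(scr2$tests$normal[scr2$tests$variable == "skew"])
  expect_equal(scr2$recommended_method, "spearman")

  # a variable with < 3 observations is untestable and forces spearman
  xu <- xn
  xu[3:30, 1] <- NA
  scr3 <- normality_screen(as_data_matrix(xu))
  untest <- scr3$tests[scr3$tests$variable == "v1", ]
  expect_false(untest$testable)
  expect_false(untest$normal)
  expect_equal(scr3$recommended_method, "spearman")
})
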