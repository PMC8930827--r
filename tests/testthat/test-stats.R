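# build a GC-like trial table: n_trials per state, 20 pairs, overall band
make_gc_table <- function(values_by_state, sessions_per_state = 2) {
  chans <- c("A", "B", "C", "D", "E")
  pairs <- expand.grid(source = chans, target = chans,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  rows <- list()
  for (st in names(values_by_state)) {
    v <- values_by_state[[st]]
    for (i in seq_along(v)) {
      sess <- sprintf("%s-%d", st, ((i - 1) %% sessions_per_state) + 1)
      rows[[length(rows) + 1L]] <- data.frame(
        state = st, session = sess, segment = i,
        source = pairs$source, target = pairs$target,
        band = "overall", value = v[i] * (1 + 0.01 * seq_len(nrow(pairs))),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

test_that("the outlier filter removes gain-inflated trials and keeps clean ones", {
  set.seed(81)
  clean <- abs(rnorm(95, mean = 0.05, sd = 0.005))
  bad <- abs(rnorm(5, mean = 0.05, sd = 0.005)) * 10
  tab <- make_gc_table(list(naive = c(clean, bad)))
  res <- filter_outliers(tab, k = 3)
  excluded_idx <- as.integer(sub(".*/", "", res$excluded))
  expect_gte(sum(excluded_idx > 95), 4)      # >= 4 of 5 artifact trials out
  expect_lte(sum(excluded_idx <= 95), 2)     # <= 2 clean trials out
})

test_that("identical trials are never excluded (MAD = 0 guard)", {
  tab <- make_gc_table(list(naive = rep(0.07, 10)))
  res <- filter_outliers(tab, k = 3)
  expect_length(res$excluded, 0)
  expect_equal(nrow(res$kept), nrow(tab))
})

test_that("the filter never removes a majority of a state's trials", {
  set.seed(82)
  tab <- make_gc_table(list(naive = abs(rnorm(20, 0.05, 0.02)),
                            mild = abs(rnorm(20, 0.08, 0.03))))
  res <- filter_outliers(tab, k = 3)
  for (st in c("naive", "mild")) {
    n_exc <- sum(grepl(paste0("^", st, "/"), res$excluded))
    expect_lt(n_exc, 10)
  }
})

test_that("state compilation reproduces hand-computed mean/SEM/CI", {
  tab <- data.frame(state = "naive", session = "s1", segment = 1:3,
                    channel = "A", band = "overall", value = c(1, 2, 3))
  cs <- compile_state(tab)
  expect_equal(cs$mean, 2)
  expect_equal(cs$sem, 1 / sqrt(3), tolerance = 1e-12)
  expect_equal(cs$ci95, 1.96 / sqrt(3), tolerance = 1e-12)
  expect_equal(cs$n_trials, 3)
  tab2 <- tab; tab2$value <- 5
  expect_equal(compile_state(tab2)$sem, 0)
  tab1 <- tab[1, ]
  expect_warning(cs1 <- compile_state(tab1), "single")
  expect_true(is.na(cs1$sem))
})

test_that("band metrics are computed per trial before state averaging", {
  # mean of per-trial band values must equal the compiled state mean
  set.seed(83)
  vals <- runif(6, 0.1, 0.3)
  tab <- data.frame(state = "naive", session = rep(c("s1", "s2"), 3),
                    segment = 1:6, channel = "A", band = "peakA",
                    value = vals)
  cs <- compile_state(tab)
  expect_equal(cs$mean, mean(vals), tolerance = 1e-12)
})

test_that("LMM with one trial per session reduces exactly to OLS", {
  set.seed(84)
  df <- data.frame(state = rep(c("naive", "mild"), each = 8),
                   session = paste0("s", 1:16), segment = 1,
                   channel = "A", band = "overall",
                   value = c(rnorm(8, 0), rnorm(8, 0.5)))
  cmp <- lmm_compare(df, transitions = list(c("naive", "mild")))
  ols <- summary(lm(value ~ state,
                    data = transform(df, state = factor(state,
                      levels = c("naive", "mild")))))$coefficients
  expect_equal(cmp$estimate, ols[2, 1], tolerance = 1e-6)
  expect_equal(cmp$p, ols[2, 4], tolerance = 1e-6)
})

test_that("LMM recovers planted variance components", {
  set.seed(85)
  ok <- c()
  for (rep in 1:15) {
    n_sess <- 20; n_trial <- 10
    sess_eff <- rnorm(n_sess, sd = 1)
    df <- data.frame(
      state = rep(rep(c("naive", "mild"), each = n_sess / 2), each = n_trial),
      session = rep(paste0("s", 1:n_sess), each = n_trial),
      value = rep(sess_eff, each = n_trial) + rnorm(n_sess * n_trial, sd = 1))
    fit <- suppressMessages(lmerTest::lmer(value ~ state + (1 | session),
                                           data = df, REML = TRUE))
    vc <- as.data.frame(lme4::VarCorr(fit))
    sb2 <- vc$vcov[vc$grp == "session"]
    s2 <- vc$vcov[vc$grp == "Residual"]
    ok <- c(ok, abs(sb2 - 1) < 0.5 && abs(s2 - 1) < 0.5)
  }
  expect_gte(mean(ok), 0.5)   # median replicate within 50% of truth
})

test_that("LMM type-I error under a planted null is near nominal", {
  set.seed(86)
  pvals <- replicate(400, {
    n_sess <- 10; n_trial <- 5
    df <- data.frame(
      state = rep(rep(c("naive", "mild"), each = n_sess / 2), each = n_trial),
      session = rep(paste0("s", 1:n_sess), each = n_trial),
      value = rep(rnorm(n_sess, sd = 0.5), each = n_trial) +
        rnorm(n_sess * n_trial))
    lfpgc:::fit_transition_lmm(df, "naive", "mild")$p
  })
  rate <- mean(pvals < 0.05)
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.09)
})

test_that("Mann-Whitney p-values match full enumeration for small groups", {
  # canonical example: x = {1,2}, y = {3,4} -> exact two-sided p = 1/3
  tab <- data.frame(state = rep(c("naive", "mild"), each = 3),
                    session = "s", segment = rep(1:3, 2), channel = "A",
                    band = "overall", value = c(1, 2, 2.5, 3, 4, 5))
  cmp <- mwu_compare(tab, transitions = list(c("naive", "mild")))
  expect_equal(cmp$p, mwu_enum(c(1, 2, 2.5), c(3, 4, 5)), tolerance = 1e-12)
  expect_equal(wilcox.test(c(3, 4), c(1, 2), exact = TRUE)$p.value, 1 / 3,
               tolerance = 1e-12)
  set.seed(87)
  for (rep in 1:10) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1), mean = 0.5)
    tab <- data.frame(state = c(rep("naive", length(x)),
                                rep("mild", length(y))),
                      session = "s",
                      segment = seq_len(length(x) + length(y)),
                      channel = "A", band = "overall", value = c(x, y))
    cmp <- mwu_compare(tab, transitions = list(c("naive", "mild")))
    expect_equal(cmp$p, mwu_enum(x, y), tolerance = 1e-9)
  }
})

test_that("large-sample MWU approximation is close to exact at n = 8", {
  set.seed(88)
  for (rep in 1:5) {
    x <- rnorm(8); y <- rnorm(8, 0.3)
    p_exact <- wilcox.test(x, y, exact = TRUE)$p.value
    p_norm <- wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    expect_lt(abs(p_exact - p_norm), 0.02)
  }
})

test_that("tied groups give p = 1 with a warning", {
  tab <- data.frame(state = rep(c("naive", "mild"), each = 3),
                    session = "s", segment = rep(1:3, 2), channel = "A",
                    band = "overall", value = rep(2, 6))
  expect_warning(cmp <- mwu_compare(tab,
                                    transitions = list(c("naive", "mild"))),
                 "tied")
  expect_equal(cmp$p, 1)
})

test_that("the subsampling cap limits group sizes deterministically", {
  set.seed(89)
  tab <- data.frame(state = rep(c("naive", "mild"), each = 600),
                    session = "s", segment = rep(1:600, 2), channel = "A",
                    band = "overall",
                    value = c(rnorm(600), rnorm(600, 0.2)))
  c1 <- mwu_compare(tab, transitions = list(c("naive", "mild")),
                    cap = 512, subsample_seed = 42)
  c2 <- mwu_compare(tab, transitions = list(c("naive", "mild")),
                    cap = 512, subsample_seed = 42)
  expect_identical(c1$p, c2$p)
})

test_that("BH adjustment equals the brute-force step-up on random families", {
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03, 0.005)),
               c(0.02, 0.04, 0.04, 0.02), tolerance = 1e-12)
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.05, 10)), rep(0.05, 10))
  set.seed(90)
  for (rep in 1:25) {
    p <- runif(sample(1:12, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_brute(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))   # order preserving
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("MWU is invariant under strictly monotone transforms", {
  set.seed(91)
  x <- abs(rnorm(12)); y <- abs(rnorm(12, 0.4))
  tab <- function(v) data.frame(
    state = rep(c("naive", "mild"), times = c(12, 12)), session = "s",
    segment = 1:24, channel = "A", band = "overall", value = v)
  p1 <- mwu_compare(tab(c(x, y)),
                    transitions = list(c("naive", "mild")))$p
  p2 <- mwu_compare(tab(log(c(x, y))),
                    transitions = list(c("naive", "mild")))$p
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("the delta report flags only significant cells with directions", {
  tab <- data.frame(state = rep(c("naive", "mild"), each = 6),
                    session = rep(c("s1", "s2", "s3", "s4"), 3),
                    segment = rep(1:3, 4),
                    source = "L-STN", target = "L-PMC", band = "peakB",
                    value = c(rnorm(6, 0, 1e-3), rnorm(6, 1, 1e-3)))
  cmp <- adjust_comparison(suppressWarnings(
    lmm_compare(tab, transitions = list(c("naive", "mild")))))
  rep1 <- build_delta_report(cmp)
  expect_equal(rep1$deltas[["naive -> mild"]][["peakB"]]["L-STN", "L-PMC"], 1)
  # all-null family: nothing significant
  cmp$p <- 1; cmp$p_adj <- NULL; cmp$significant <- NULL
  rep0 <- build_delta_report(cmp)
  m <- rep0$deltas[["naive -> mild"]][["peakB"]]
  expect_equal(sum(abs(m), na.rm = TRUE), 0)
  expect_equal(rownames(m),
               c("L-PMC", "L-M1", "R-PMC", "R-M1", "L-STN"))
})
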