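dct <- example_delta_ct()
marker_vals <- function(marker)
  split(dct$delta_ct[dct$marker == marker], dct$group[dct$marker == marker])

test_that("compute_delta_ct subtracts the reference CT", {
  man <- data.frame(sample_id = c("s1", "s2"), group = c("tumor", "control"))
  m <- data.frame(sample_id = c("s1", "s2"), marker = "M",
                  ct_target = c(28.5, 20.0), ct_ref = c(20.0, 20.0))
  out <- compute_delta_ct(m, man)
  expect_equal(out$delta_ct, c(8.5, 0))
  expect_equal(out$group, c("tumor", "control"))

  # censored target imputed at the run's cycle count and flagged
  cens <- data.frame(sample_id = "s1", marker = "M",
                     ct_target = NA_real_, ct_ref = 20)
  outc <- compute_delta_ct(cens, man)
  expect_equal(outc$delta_ct, 23)
  expect_true(outc$censored)

  noref <- data.frame(sample_id = "s9", marker = "M",
                      ct_target = 30, ct_ref = NA_real_)
  expect_error(compute_delta_ct(noref), "missing reference CT.*s9")
})

test_that("delta-CT reproduces the demo table when fed matching CTs", {
  ct <- data.frame(sample_id = dct$sample_id, marker = dct$marker,
                   ct_target = 20 + dct$delta_ct, ct_ref = 20)
  man <- unique(dct[c("sample_id", "group")])
  out <- compute_delta_ct(ct, man)
  expect_equal(out$delta_ct, dct$delta_ct, tolerance = 1e-12)
  expect_equal(
    out$delta_ct[out$sample_id == "T-0085-C" & out$marker == "ZNF529"], 4.98)
})

test_that("group_test is a two-sided Welch test", {
  same <- data.frame(group = rep(c("tumor", "control"), each = 3),
                     delta_ct = rep(c(1, 2, 3), 2))
  expect_equal(group_test(same)$p_raw, 1)

  sep <- data.frame(group = rep(c("control", "tumor"), each = 3),
                    delta_ct = c(20, 21, 19, 2, 3, 4))
  res <- group_test(sep)
  expect_lt(res$p_raw, 0.001)
  expect_equal(res$p_raw, oracle_welch(c(2, 3, 4), c(20, 21, 19)),
               tolerance = 1e-12)

  one <- data.frame(group = c("tumor", "control", "control"),
                    delta_ct = c(1, 2, 3))
  expect_error(group_test(one), ">= 2 records per group")
  flat <- data.frame(group = rep(c("tumor", "control"), each = 2),
                     delta_ct = c(1, 1, 2, 2))
  expect_error(group_test(flat), "zero variance")
})

test_that("bonferroni_adjust caps at one and preserves order", {
  expect_equal(bonferroni_adjust(0.004, m = 6), 0.024)
  expect_equal(bonferroni_adjust(0.2, m = 6), 1)
  expect_equal(bonferroni_adjust(numeric(0)), numeric(0))
  p <- c(0.01, 0.2, 0.03)
  adj <- bonferroni_adjust(p)
  expect_equal(adj, pmin(1, 3 * p))
  expect_true(all(adj >= p))
  expect_error(bonferroni_adjust(1.2), "\\[0, 1\\]")
})

test_that("roc_auc counts ordered pairs with tumor-low orientation", {
  znf <- marker_vals("ZNF529")
  expect_equal(roc_auc(data.frame(group = rep(c("tumor", "control"), each = 3),
                                  delta_ct = c(znf$tumor, znf$control))), 1)
  kcn <- marker_vals("KCNB1")
  expect_equal(roc_auc(data.frame(group = rep(c("tumor", "control"), each = 3),
                                  delta_ct = c(kcn$tumor, kcn$control))),
               6 / 9)
  ties <- data.frame(group = rep(c("tumor", "control"), each = 2),
                     delta_ct = c(5, 7, 5, 7))
  expect_equal(roc_auc(ties), 0.5)
})

test_that("youden_optimal_cutpoint matches the exhaustive search", {
  znf <- marker_vals("ZNF529")
  res <- youden_optimal_cutpoint(
    data.frame(group = rep(c("tumor", "control"), each = 3),
               delta_ct = c(znf$tumor, znf$control)))
  expect_equal(res$youden_j, 1)
  expect_equal(res$sensitivity, 1)
  expect_equal(res$specificity, 1)
  expect_equal(res$cutpoint, (4.98 + 9.92) / 2)  # margin midpoint 7.45

  kcn <- marker_vals("KCNB1")
  resk <- youden_optimal_cutpoint(
    data.frame(group = rep(c("tumor", "control"), each = 3),
               delta_ct = c(kcn$tumor, kcn$control)))
  expect_equal(resk$youden_j, 2 / 3, tolerance = 1e-12)
  expect_equal(resk$sensitivity, 2 / 3, tolerance = 1e-12)
  expect_equal(resk$specificity, 1)

  degenerate <- data.frame(group = c("tumor", "control"), delta_ct = c(5, 5))
  expect_equal(youden_optimal_cutpoint(degenerate)$youden_j, 0)
})

test_that("statistics invariants hold on random fixtures", {
  withr::local_seed(17)
  for (rep in 1:60) {
    nt <- sample(2:15, 1); nc <- sample(2:15, 1)
    tumor <- round(rnorm(nt, 5, 4), 2)
    control <- round(rnorm(nc, 12, 4), 2)
    rec <- data.frame(group = rep(c("tumor", "control"), c(nt, nc)),
                      delta_ct = c(tumor, control))
    auc <- roc_auc(rec)
    expect_equal(auc, oracle_auc(tumor, control), tolerance = 1e-12)

    cp <- youden_optimal_cutpoint(rec)
    # J recomputable from the returned cutpoint
    sens <- mean(tumor <= cp$cutpoint)
    spec <- mean(control > cp$cutpoint)
    expect_equal(cp$youden_j, sens + spec - 1, tolerance = 1e-12)
    expect_equal(cp$youden_j, cp$sensitivity + cp$specificity - 1,
                 tolerance = 1e-12)
    expect_equal(cp$youden_j, oracle_best_j(tumor, control), tolerance = 1e-12)

    # invariance under a strictly increasing transform
    f <- function(x) exp(x / 10) + 0.3 * x
    rec2 <- transform(rec, delta_ct = f(delta_ct))
    expect_equal(roc_auc(rec2), auc, tolerance = 1e-12)
    expect_equal(youden_optimal_cutpoint(rec2)$youden_j, cp$youden_j,
                 tolerance = 1e-12)

    # perfect separation implies J = 1 and AUC = 1
    shifted <- data.frame(group = rec$group,
                          delta_ct = c(tumor, control + 100))
    expect_equal(youden_optimal_cutpoint(shifted)$youden_j, 1)
    expect_equal(roc_auc(shifted), 1)
  }
})

test_that("summarize_markers reports ranges, separation and adjusted p", {
  smry <- summarize_markers(dct)
  expect_equal(smry$range_control[smry$marker == "ZNF529"], 10.9)
  expect_equal(smry$range_tumor[smry$marker == "KCNB1"], 19.62)
  expect_true(smry$separated[smry$marker == "FLI1"])   # 11.93 > 7.16
  expect_false(smry$separated[smry$marker == "KCNB1"])
  expect_equal(smry$p_adj, pmin(1, 6 * smry$p_raw))
  expect_equal(smry$youden_j, smry$sensitivity + smry$specificity - 1,
               tolerance = 1e-12)
})
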