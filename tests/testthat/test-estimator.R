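test_that("Sobol' sequence matches frozen direction-number oracle values", {
  # first points of the unscrambled 2-D sequence
  expect_equal(sobol_sequence(4, 2),
               rbind(c(0, 0), c(0.5, 0.5), c(0.75, 0.25), c(0.25, 0.75)))
  # frozen reference points for 6 dimensions (independent direction-
  # number implementation)
  ref6 <- rbind(
    c(0,     0,     0,     0,     0,     0),
    c(0.5,   0.5,   0.5,   0.5,   0.5,   0.5),
    c(0.75,  0.25,  0.25,  0.25,  0.75,  0.75),
    c(0.25,  0.75,  0.75,  0.75,  0.25,  0.25),
    c(0.375, 0.375, 0.625, 0.875, 0.375, 0.125),
    c(0.875, 0.875, 0.125, 0.375, 0.875, 0.625),
    c(0.625, 0.125, 0.875, 0.625, 0.625, 0.875),
    c(0.125, 0.625, 0.375, 0.125, 0.125, 0.375))
  expect_equal(sobol_sequence(8, 6), ref6)

  # determinism and extension without reshuffling
  expect_identical(sobol_sequence(16, 5, skip = 3),
                   sobol_sequence(16, 5, skip = 3))
  expect_identical(sobol_sequence(16, 5)[1:8, ], sobol_sequence(8, 5))
})

test_that("sobol_starts maps into bounds and validates them", {
  lo <- c(1e3, 1e2); hi <- c(1e5, 1e4)
  X <- sobol_starts(32, lo, hi)
  expect_true(all(t(X) >= lo & t(X) <= hi))
  expect_identical(X, sobol_starts(32, lo, hi))
  expect_error(sobol_starts(4, c(0, 1), c(Inf, 2)), "finite")
  # log-scale spacing: medians near the geometric center
  expect_lt(abs(stats::median(log(X[, 1])) - mean(log(c(1e3, 1e5)))), 1)
})

test_that("the termination decision table covers B3-B6 and B1", {
  opts <- estimation_options(reinit_limit = 3)
  # B3: unchanged on re-evaluation
  expect_equal(decide_termination(1.0000000, 1.0000000, NULL, 0, opts), "B3")
  expect_equal(decide_termination(5e-15, 1e-16, NULL, 0, opts), "B3")
  # first attempt, changed: B1 (B4/B5 skipped without a previous value)
  expect_equal(decide_termination(1.0, 0.8, NULL, 0, opts), "B1")
  # B4: decreases, but insufficiently
  expect_equal(decide_termination(1.0, 0.7999, 0.8, 1, opts), "B4")
  # sufficient decrease: continue (B1)
  expect_equal(decide_termination(1.0, 0.5, 0.8, 1, opts), "B1")
  # B5: increase over the previous attempt
  expect_equal(decide_termination(1.0, 0.9, 0.8, 1, opts), "B5")
  # B6: reinitialisation limit
  expect_equal(decide_termination(1.0, 0.5, 0.8, 3, opts), "B6")
})

test_that("structures are scheduled by decreasing estimated cost", {
  expect_equal(schedule_structures(c(3, 1, 2)), c(1, 3, 2))
  # ties broken by input order (stable)
  expect_equal(schedule_structures(c(2, 2, 1, 2)), c(1, 2, 4, 3))
  expect_equal(schedule_structures(rep(1, 4)), 1:4)
})

# -- mocked control flow (mocks defined in helper-mocks.R) -----------------

test_that("run_local terminates via B3 when the re-evaluation is unchanged", {
  opts <- scripted_opts(tmf_opt = 0.5, tmf_re = 0.5)
  fit <- run_local(c(1, 1), mock_entries(2), mock_pots(), opts)
  expect_equal(fit$status, "B3_converged")
  expect_equal(fit$TMF_final, 0.5)
  expect_equal(fit$attempts, 1)
})

test_that("run_local terminates via B4 on an insufficient decrease", {
  opts <- scripted_opts(tmf_opt = c(0.4, 0.3), tmf_re = c(0.8, 0.7999))
  fit <- run_local(c(1, 1), mock_entries(2), mock_pots(), opts)
  expect_equal(fit$status, "B4_slow_decrease")
  expect_equal(fit$TMF_final, 0.7999)
  expect_equal(fit$attempts, 2)
})

test_that("run_local terminates via B5 keeping the better estimates", {
  opts <- scripted_opts(tmf_opt = c(0.4, 0.3), tmf_re = c(0.8, 0.9))
  fit <- run_local(c(1, 1), mock_entries(2), mock_pots(), opts)
  expect_equal(fit$status, "B5_increase")
  # the previous attempt's value is kept
  expect_equal(fit$TMF_final, 0.8)
})

test_that("run_local terminates via B6 at the reinitialisation limit", {
  opts <- scripted_opts(tmf_opt = rep(0.4, 10),
                        tmf_re = c(0.8, 0.41, 0.2, 0.1),
                        reinit_limit = 1)
  fit <- run_local(c(1, 1), mock_entries(2), mock_pots(), opts)
  expect_equal(fit$status, "B6_reinit_limit")
  expect_equal(fit$attempts, 2)
})

test_that("a failing structure is removed (D3) and reintroduced (A3-A5)", {
  opts <- scripted_opts(tmf_opt = 0.5, tmf_re = 0.5, fail_first = 2)
  fit <- run_local(c(1, 1), mock_entries(3), mock_pots(), opts)
  expect_equal(fit$status, "B3_converged")
  phases <- vapply(fit$removed_history, function(h) h$phase, "")
  labels <- vapply(fit$removed_history, function(h) h$label, "")
  expect_true(any(phases == "removed" & labels == "s2"))
  expect_true(any(phases == "reintroduced" & labels == "s2"))
  # the final pass covers the full training set again
  expect_equal(fit$trace$n_active[nrow(fit$trace)], 3)
})

test_that("all structures removed yields a failed estimation", {
  k <- 0
  opts <- estimation_options(
    inner_solver = function(p_start, entries, st) {
      k <<- k + 1
      stop(crystalfit:::lm_failure_condition(k, paste0("s", k), p_start))
    },
    reevaluator = function(p) 1)
  fit <- run_local(c(1, 1), mock_entries(2), mock_pots(), opts)
  expect_equal(fit$status, "failed")
})

# -- real (tiny) problems --------------------------------------------------

test_that("run_local is deterministic and exact from the true parameters", {
  fix <- toy_fixture(2)
  p_true <- get_params(fix$pots)
  opts <- estimation_options(lm_opts = fast_lm_opts())
  fit1 <- run_local(p_true, fix$entries, fix$pots, opts)
  fit2 <- run_local(p_true, fix$entries, fix$pots, opts)
  expect_equal(fit1$status, "B3_converged")
  expect_lt(fit1$TMF_final, 1e-12)
  expect_identical(fit1$p_hat, fit2$p_hat)
  expect_identical(fit1$TMF_final, fit2$TMF_final)
})

test_that("multistart wiring: Sobol' starts within bounds, runs clustered", {
  opts <- scripted_opts(tmf_opt = 0.5, tmf_re = 0.5)
  opts$sobol_span <- 5
  ms <- run_multistart(4, mock_entries(2), mock_pots(), opts)
  expect_length(ms$runs, 4)
  p_ref <- get_params(mock_pots())
  expect_true(all(t(ms$starts) >= p_ref / 5 & t(ms$starts) <= p_ref * 5))
  expect_setequal(unlist(ms$clusters), 1:4)
  expect_false(is.null(ms$best))
})

test_that("clusters partition the non-failed multistart results", {
  mk <- function(tmf, p, status = "B3_converged")
    structure(list(TMF_final = tmf, p_hat = p, status = status),
              class = "xtl_estimation")
  runs <- list(mk(1e-12, c(1, 2)), mk(1.0000001e-12, c(1.000001, 2.000001)),
               mk(0.5, c(9, 9)), mk(NA, c(0, 0), "failed"),
               mk(0.5004, c(9.001, 9.002)))
  cl <- cluster_minima(runs)$clusters
  all_idx <- sort(unlist(cl))
  expect_equal(all_idx, c(1, 2, 3, 5))
  expect_equal(length(unlist(cl)), length(unique(unlist(cl))))
  expect_equal(length(cl), 2)
  # best cluster first
  expect_true(1 %in% cl[[1]])
})
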