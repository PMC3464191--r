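test_that("binary traces keep only ever-bound molecules of the class", {
  assign_ <- matrix(NA_integer_, 3, 100)
  assign_[1, 11:21] <- 1L          # bound frames 11-21 in cavity 1
  assign_[2, 40:45] <- 2L          # bound in cavity 2 only
  cavs <- list(chan_cavity(matrix(0, 1, 3), 1, class = "intra"),
               chan_cavity(matrix(0, 1, 3), 1, class = "inter"))
  tr <- binary_traces(assign_, cavs, class = "intra", dt = 1)
  expect_equal(nrow(tr), 1)        # molecule 3 never bound, 2 wrong class
  expect_equal(sum(tr), 11)
  tr_any <- binary_traces(assign_, dt = 1)
  expect_equal(nrow(tr_any), 2)
})

test_that("autocorrelation limits: all-ones and alternating traces", {
  ones <- matrix(1L, 2, 30)
  ac <- occupancy_autocorrelation(ones, max_lag = 10)
  expect_equal(ac$C, rep(1, 11))

  # hand-enumerated oracle on a 6-frame alternating trace:
  # numerator(lag) = sum_t b(t) b(t+lag), denominator = sum_{t<=T-lag} b(t)
  b <- matrix(c(1L, 0L, 1L, 0L, 1L, 0L), 1)
  ac2 <- occupancy_autocorrelation(b, max_lag = 4)
  oracle <- vapply(0:4, function(l) {
    t_ <- 1:(6 - l)
    sum(b[t_] * b[t_ + l]) / sum(b[t_])
  }, numeric(1))
  expect_equal(ac2$C, oracle)
  expect_equal(ac2$C, c(1, 0, 1, 0, 1))

  expect_error(occupancy_autocorrelation(matrix(0L, 2, 10)), "no occupied")
})

test_that("C(0) = 1 and C stays in [0, 1] on random traces", {
  for (s in 1:5) {
    d <- simulate_dwell_traces(20, 300, 1, 30, 90, 3, seed = s)
    tr <- binary_traces(d$assign, dt = 1)
    ac <- occupancy_autocorrelation(tr)
    expect_equal(ac$C[1], 1)
    expect_true(all(ac$C >= 0 & ac$C <= 1 + 1e-12, na.rm = TRUE))
  }
})

test_that("autocorrelation decay follows two-state Markov theory", {
  # tau_u >> tau_b: C(lag) ~ exp(-lag / tau_b) for lags << trajectory
  d <- simulate_dwell_traces(200, 3000, 1, tau_b = 40, tau_u = 4000,
                             n_cav = 5, seed = 12)
  tr <- binary_traces(d$assign, dt = 1)
  ac <- occupancy_autocorrelation(tr, max_lag = 120)
  theory <- exp(-(0:120) / 40)
  # pointwise within 3 binomial-ish SE of the conditional probability
  den <- rowSums(ac$den)
  se <- sqrt(pmax(theory * (1 - theory), 1e-6) / pmax(den / 40, 1))
  expect_true(all(abs(ac$C - theory) <= pmax(3 * se, 0.05)))
})

test_that("noiseless exponential curves are recovered", {
  lag <- 0:400
  mkac <- function(C) structure(
    list(lag = lag, C = C, dt = 1, n_molecules = 1, num = NULL, den = NULL),
    class = "chan_autocorrelation")
  f <- fit_double_exponential(mkac(0.4 * exp(-lag / 5) +
                                     0.6 * exp(-lag / 100)), n_boot = 0)
  expect_equal(f$A_f, 0.4, tolerance = 0.01)
  expect_equal(f$tau_f, 5, tolerance = 0.05)
  expect_equal(f$tau_s, 100, tolerance = 1)
  expect_false(f$degenerate)

  fs <- fit_double_exponential(mkac(exp(-lag / 50)), n_boot = 0)
  expect_true(fs$degenerate)
  expect_equal(fs$tau_s, 50, tolerance = 0.5)

  expect_error(fit_double_exponential(mkac(0.5 * exp(-lag / 9))), "C\\(0\\)")
  short <- structure(list(lag = 0:5, C = exp(-(0:5)), dt = 1,
                          n_molecules = 1, num = NULL, den = NULL),
                     class = "chan_autocorrelation")
  expect_error(fit_double_exponential(short), "10 lag")
})

test_that("exchange times are recovered across dwell scales", {
  # fitted tau_s over 10 generator seeds within 20% of the bound dwell
  for (tb in c(20, 150)) {
    taus <- vapply(1:10, function(s) {
      d <- simulate_dwell_traces(100, 1000, 1, tb, 10 * tb, n_cav = 10,
                                 seed = s)
      tr <- binary_traces(d$assign, dt = 1)
      fit_double_exponential(occupancy_autocorrelation(tr), n_boot = 0)$tau_s
    }, numeric(1))
    # median over seeds: the fit distribution is right-skewed (occasional
    # realizations carry genuinely slow episodes)
    expect_lt(abs(median(taus) - tb) / tb, 0.2)
  }
})

test_that("bootstrap SE shrinks with molecule count", {
  mkfit <- function(n_mol) {
    d <- simulate_dwell_traces(n_mol, 800, 1, 60, 600, 10, seed = 3)
    tr <- binary_traces(d$assign, dt = 1)
    fit_double_exponential(occupancy_autocorrelation(tr), n_boot = 100,
                           seed = 9)
  }
  f50 <- mkfit(50)
  f200 <- mkfit(200)
  expect_lt(f200$se_tau_s, f50$se_tau_s)
  expect_gt(f50$se_tau_s, 0)
})

test_that("few-molecule fits degrade to jackknife with a warning", {
  d <- simulate_dwell_traces(4, 600, 1, 50, 300, 1, seed = 5)
  tr <- binary_traces(d$assign, dt = 1)
  expect_warning(
    f <- fit_double_exponential(occupancy_autocorrelation(tr), n_boot = 50),
    "jackknife")
  expect_true(is.finite(f$se_tau_s))
})
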