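# minimal effective-activation wrapper for direct window arithmetic
ea_of <- function(F) structure(list(F = F), class = "effective_activation")

test_that("window bookkeeping: l + alpha windows, alpha windows per site", {
  par <- simple_params(E_A = 3, global = global_params(alpha = 50))
  l <- 200
  sites <- manual_sites(100, 110)
  N <- window_adaptors(ea_of(matrix(1, 1, 2)), sites, par, l = l)
  expect_equal(nrow(N), l + 50)
  expect_equal(attr(N, "window_start"), seq(-50, l - 1))
  # F * E_A = 3: exactly alpha windows hold the midpoint, each with N = 3
  expect_equal(sum(N[, 1] > 0), 50)
  expect_equal(unique(N[N > 0]), 3)
  mid <- floor((100 + 110) / 2)
  covered <- attr(N, "window_start")[N[, 1] > 0]
  expect_true(all(covered <= mid & mid < covered + 50))

  # no activating sites -> N identically zero
  N0 <- window_adaptors(ea_of(matrix(0, 1, 2)), sites, par, l = l)
  expect_true(all(N0 == 0))
})

test_that("the Arrhenius window rate has the right midpoint, leak and saturation", {
  expect_equal(window_rate(15, theta = 15, Rmax = 10), 5)     # N = theta
  expect_equal(window_rate(0, theta = 25, Rmax = 1), 1 / (1 + exp(25)))
  expect_equal(window_rate(1e4, theta = 25, Rmax = 7), 7)     # saturation
  expect_true(all(diff(window_rate(seq(0, 30, 0.5), 15, 1)) > 0))
})

test_that("time fractions normalise to S/(1+S) and recover the relative limit", {
  expect_equal(window_time(matrix(0, 4, 2), beta = 1),
               matrix(0, 4, 2))                       # promoter never engaged
  expect_equal(window_time(matrix(c(1, 1), 2, 1), beta = 1)[, 1],
               c(1, 1) / 3)
  N <- matrix(runif(12, 0, 5), 4, 3)
  Tf <- window_time(N, beta = 0.2)
  S <- 0.2 * colSums(N)
  expect_equal(colSums(Tf), S / (1 + S), tolerance = 1e-14)
  # beta -> infinity: T approaches the relative weighting N / sum(N)
  Tbig <- window_time(N, beta = 1e9)
  expect_equal(Tbig, sweep(N, 2, colSums(N), "/"), tolerance = 1e-6)
})

test_that("the total rate is the contribution sum and bounded by the best window", {
  N <- matrix(c(0, 3, 0, 0, 8, 0), 3, 2)
  R <- window_rate(N, theta = 5, Rmax = 100)
  Tf <- window_time(N, beta = 0.5)
  out <- locus_rate(R, Tf, positions = c(10, 20))
  expect_equal(out$prediction$rate, colSums(R * Tf))
  expect_true(all(out$prediction$rate <= apply(R, 2, max)))
  # single nonzero window: R_total is exactly that window's R * T
  expect_equal(out$prediction$rate[1], R[2, 1] * Tf[2, 1])
  expect_error(locus_rate(R, Tf[1:2, ]), "shapes")
})

test_that("the full pipeline matches an independent step-by-step recomputation", {
  # 200 bp locus, three hand-placed sites (activator, repressor, activator),
  # recomputed here with scalar arithmetic straight from the model equations
  par <- param_set(
    tf_params(c("act", "rep"), role = c("activator", "repressor"),
              A = c(0.8, 0.6), lambda = c(1, 2), E_A = c(4, 0),
              E_Q = c(0, 0.7)),
    global_params(theta = 6, beta = 0.02, Rmax = 50, alpha = 40))
  l <- 200
  sites <- manual_sites(c(50, 80, 120), c(60, 90, 130),
                        tf = c("act", "rep", "act"),
                        score = c(2, 1, 3), s_max = c(3, 2, 3))
  prof <- tibble::tibble(position = c(40, 60), act = c(2, 1), rep = c(1, 3))

  q <- site_weights(sites, par, prof)
  occ <- occupancy_dp(sites, q)
  ea <- effective_activation(occ, sites, par)
  N <- window_adaptors(ea, sites, par, l = l)
  R <- window_rate(N, 6, 50)
  Tf <- window_time(N, 0.02)
  attr(R, "window_start") <- attr(N, "window_start")
  out <- locus_rate(R, Tf, prof$position)

  for (x in 1:2) {
    # statistical weights by hand
    qa <- function(A, conc, s, smax, lam) A * conc * exp((s - smax) / lam)
    q1 <- qa(0.8, prof$act[x], 2, 3, 1)
    q2 <- qa(0.6, prof$rep[x], 1, 2, 2)
    q3 <- qa(0.8, prof$act[x], 3, 3, 1)
    # all sites disjoint: independent occupancies
    f1 <- q1 / (1 + q1); f2 <- q2 / (1 + q2); f3 <- q3 / (1 + q3)
    # repressor at centre 85 quenches both activators (within 100 bp)
    F1 <- f1 * (1 - 0.7 * f2)
    F3 <- f3 * (1 - 0.7 * f2)
    expect_equal(ea$F[1, x], F1)
    expect_equal(ea$F[3, x], F3)
    # explicit loop over all l + alpha windows
    mid <- c(55, 85, 125)
    contrib <- c(F1 * 4, 0, F3 * 4)
    rt <- 0; Ssum <- 0
    Ns <- numeric(l + 40)
    for (w in seq_len(l + 40)) {
      ws <- w - 40 - 1
      Ns[w] <- sum(contrib[mid >= ws & mid < ws + 40])
      Ssum <- Ssum + 0.02 * Ns[w]
    }
    for (w in seq_len(l + 40)) {
      rt <- rt + (50 / (1 + exp(6 - Ns[w]))) * (0.02 * Ns[w] / (1 + Ssum))
    }
    expect_equal(out$prediction$rate[x], rt, tolerance = 1e-12)
  }
})

test_that("without competition a short locus reduces to the Arrhenius law on total N", {
  b <- benchmark_fixture()
  frag <- locus_sequence(substr(b$seq$bases, 1101, 1700))
  comp <- predict_locus(frag, b$pwms, b$params, b$profiles)
  nocomp <- predict_locus(frag, b$pwms, b$params, b$profiles,
                          mode = "no_competition")
  # fragment shorter than alpha: some window holds every site, so the
  # maximal window N equals the no-competition total N
  expect_equal(apply(comp$N, 2, max), nocomp$N[1, ], ignore_attr = TRUE)
  g <- b$params$global
  expect_equal(nocomp$prediction$rate,
               g$Rmax / (1 + exp(g$theta - nocomp$N[1, ])),
               ignore_attr = TRUE)
})

test_that("zero concentrations give basal leak without competition and silence with", {
  b <- benchmark_fixture()
  prof0 <- b$profiles
  for (nm in names(prof0)[-1]) prof0[[nm]] <- rep(0, nrow(prof0))
  frag <- locus_sequence(substr(b$seq$bases, 1, 1500))
  comp <- predict_locus(frag, b$pwms, b$params, prof0)
  nocomp <- predict_locus(frag, b$pwms, b$params, prof0,
                          mode = "no_competition")
  g <- b$params$global
  expect_equal(comp$prediction$rate, rep(0, 58))
  expect_equal(nocomp$prediction$rate,
               rep(g$Rmax / (1 + exp(g$theta)), 58))
})

test_that("competing enhancers drive less than the sum of their parts", {
  b <- benchmark_fixture()
  # partition the locus into its two enhancer-bearing halves so that every
  # site belongs to exactly one fragment
  half <- b$seq$length %/% 2
  fragA <- locus_sequence(substr(b$seq$bases, 1, half))
  fragB <- locus_sequence(substr(b$seq$bases, half + 1, b$seq$length))
  outA <- predict_locus(fragA, b$pwms, b$params, b$profiles)$prediction$rate
  outB <- predict_locus(fragB, b$pwms, b$params, b$profiles)$prediction$rate
  outAB <- predict_locus(b$seq, b$pwms, b$params, b$profiles)$prediction$rate
  expect_true(all(outAB <= outA + outB + 1e-9))
  expect_lt(sum(outAB), sum(outA) + sum(outB))
})

test_that("the benchmark drives two separated expression domains", {
  b <- benchmark_fixture()
  r <- predict_locus(b$seq, b$pwms, b$params, b$profiles)$prediction$rate
  third <- length(r) %/% 3
  trough <- min(r[(third + 1):(2 * third)])
  expect_gt(max(r[1:third]), 2 * trough)
  expect_gt(max(r[(2 * third + 1):length(r)]), 2 * trough)
})

test_that("total output is monotone in beta", {
  b <- benchmark_fixture()
  st <- scan_sites(b$pwms, b$seq, 0)
  rates <- vapply(c(0.001, 0.005, 0.05), function(beta) {
    p <- b$params
    p$global$beta <- beta
    sum(predict_locus(b$seq, b$pwms, p, b$profiles, sites = st,
                      details = FALSE)$prediction$rate)
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
})
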