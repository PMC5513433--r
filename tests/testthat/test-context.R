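# two-factor parameter set with a coactivated repressor ("h" switched by "a")
coact_params <- function(E_C = 1, E_Q_h = 0, E_Q_r = 1, E_A_a = 1) {
  param_set(tf_params(c("a", "h", "r"),
                      role = c("activator", "repressor", "repressor"),
                      coactivated_by = list(character(), "a", character()),
                      E_A = c(E_A_a, 1, 0), E_Q = c(0, E_Q_h, E_Q_r),
                      E_C = c(0, E_C, 0)))
}

# hand-built occupancy table
occ_of <- function(f) structure(list(f = f, logZ = rep(0, ncol(f))),
                                class = "occupancy_table")

test_that("coactivation follows the complement-product switching rule", {
  par <- coact_params(E_C = 1)
  # h at 0-8; coactivator a at 100-108 (within d_coact = 150); second a far
  sites <- manual_sites(c(0, 100, 1000), c(8, 108, 1008), tf = c("h", "a", "a"))
  f <- matrix(c(0.8, 1, 0.3), 3, 1)
  ea <- coactivate(occ_of(f), sites, par)
  # one fully bound coactivator in range: full switch
  expect_equal(ea$f_act[1, 1], 0.8)
  expect_equal(ea$f_rep[1, 1], 0)
  # activators activate with full occupancy, far site irrelevant
  expect_equal(ea$f_act[2, 1], 1)

  # no coactivator in range: pure repression
  sites2 <- manual_sites(c(0, 1000), c(8, 1008), tf = c("h", "a"))
  ea2 <- coactivate(occ_of(matrix(c(0.8, 1), 2, 1)), sites2, par)
  expect_equal(ea2$f_act[1, 1], 0)
  expect_equal(ea2$f_rep[1, 1], 0.8)

  # two half-bound coactivators: 1 - (1 - .5)^2 = 0.75
  sites3 <- manual_sites(c(0, 60, 120), c(8, 68, 128), tf = c("h", "a", "a"))
  ea3 <- coactivate(occ_of(matrix(c(0.8, 0.5, 0.5), 3, 1)), sites3, par)
  expect_equal(ea3$f_act[1, 1], 0.8 * 0.75)
  expect_equal(ea3$f_rep[1, 1], 0.8 * 0.25)
})

test_that("partial coactivation efficiency scales the switched fraction", {
  par <- coact_params(E_C = 0.4)
  sites <- manual_sites(c(0, 100), c(8, 108), tf = c("h", "a"))
  ea <- coactivate(occ_of(matrix(c(0.5, 1), 2, 1)), sites, par)
  expect_equal(ea$f_act[1, 1], 0.5 * 0.4)
  # conservation holds everywhere
  expect_equal(ea$f_act + ea$f_rep, ea$f)
})

test_that("quenching attenuates activators by nearby repressing occupancy", {
  par <- coact_params(E_Q_r = 1)
  # activator at 0; repressor r at 50 (within d_quench = 100)
  sites <- manual_sites(c(0, 50), c(8, 58), tf = c("a", "r"))
  ea <- effective_activation(occ_of(matrix(c(0.9, 1), 2, 1)), sites, par)
  expect_equal(ea$F[1, 1], 0)               # complete quenching
  expect_equal(ea$F[2, 1], 0)               # repressors never activate

  par2 <- coact_params(E_Q_r = 0.5)
  ea2 <- effective_activation(occ_of(matrix(c(0.9, 0.6), 2, 1)), sites, par2)
  expect_equal(ea2$F[1, 1], 0.9 * (1 - 0.5 * 0.6))
})

test_that("the quenching range cut is inclusive at d and strict beyond", {
  par <- coact_params(E_Q_r = 1)
  d <- par$config$d_quench
  # centres exactly d apart -> quenched; one bp further -> untouched
  at_d <- manual_sites(c(0, d), c(8, d + 8), tf = c("a", "r"))
  past_d <- manual_sites(c(0, d + 1), c(8, d + 9), tf = c("a", "r"))
  f <- matrix(c(0.9, 1), 2, 1)
  expect_equal(effective_activation(occ_of(f), at_d, par)$F[1, 1], 0)
  expect_equal(effective_activation(occ_of(f), past_d, par)$F[1, 1], 0.9)
})

test_that("a coactivated site's own repressing part does not quench itself", {
  par <- coact_params(E_C = 0.5, E_Q_h = 1)
  sites <- manual_sites(c(0, 60), c(8, 68), tf = c("h", "a"))
  f <- matrix(c(0.8, 0.5), 2, 1)
  ea <- effective_activation(occ_of(f), sites, par)
  f_act_h <- 0.8 * 0.5 * 0.5
  f_rep_h <- 0.8 - f_act_h
  expect_equal(ea$F[1, 1], f_act_h)                    # no self-quenching
  expect_equal(ea$F[2, 1], 0.5 * (1 - f_rep_h))        # but h quenches a
})

test_that("with all efficiencies zero the model reduces to raw activator occupancy", {
  set.seed(21)
  par <- coact_params(E_C = 0, E_Q_h = 0, E_Q_r = 0)
  n <- 8
  starts <- sort(sample(0:400, n)) * 2
  sites <- manual_sites(starts, starts + 8,
                        tf = sample(c("a", "h", "r"), n, replace = TRUE))
  f <- matrix(runif(n * 3), n, 3)
  ea <- effective_activation(occ_of(f), sites, par)
  act <- sites$tf == "a"
  expect_equal(ea$F[act, ], f[act, ])
  expect_equal(ea$F[!act, ], matrix(0, sum(!act), 3), ignore_attr = TRUE)
})

test_that("adding a repressor site weakly decreases every F", {
  set.seed(22)
  par <- coact_params(E_C = 0.7, E_Q_h = 0.6, E_Q_r = 0.8)
  starts <- c(0, 40, 90, 140)
  sites <- manual_sites(starts, starts + 8, tf = c("a", "h", "a", "a"))
  f <- matrix(runif(4 * 2), 4, 2)
  base <- effective_activation(occ_of(f), sites, par)
  sites2 <- dplyr::bind_rows(sites, manual_sites(60, 68, tf = "r"))
  sites2$site_id <- 1:5
  f2 <- rbind(f, runif(2))
  more <- effective_activation(occ_of(f2), sites2, par)
  expect_true(all(more$F[1:4, ] <= base$F + 1e-12))
})

test_that("uniform coactivated-repressor input gives non-monotone window output", {
  # construct with paired h+coactivator sites plus distal unpaired h sites:
  # raising uniform [h] first adds coactivated activation, then the distal
  # sites load and quench it away
  par <- param_set(
    tf_params(c("cad", "h"), role = c("activator", "repressor"),
              coactivated_by = list(character(), "cad"),
              A = c(1, 1), E_A = c(2, 4), E_Q = c(0, 1), E_C = c(0, 1)),
    global_params(theta = 8, beta = 0.01, Rmax = 100, alpha = 1000))
  # h at 160 is paired (within d_coact of cad); h at 260 is unpaired
  # (160 bp from cad) but within d_quench of the paired h site
  sites <- manual_sites(c(100, 160, 260), c(110, 170, 270),
                        tf = c("cad", "h", "h"))
  hb_levels <- c(0.02, 0.1, 0.3, 1, 3, 10, 50)
  out <- vapply(hb_levels, function(hb) {
    prof <- tibble::tibble(position = 1, cad = 5, h = hb)
    q <- site_weights(sites, par, prof)
    occ <- occupancy_dp(sites, q)
    ea <- effective_activation(occ, sites, par)
    E_A <- par$tf$E_A[match(sites$tf, par$tf$tf)]
    sum(ea$F[, 1] * E_A)
  }, numeric(1))
  peak <- which.max(out)
  expect_gt(peak, 1)
  expect_lt(peak, length(out))
  expect_gt(out[peak], out[1])
  expect_gt(out[peak], out[length(out)])
})
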