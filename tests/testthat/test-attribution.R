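test_that("an inert factor has zero rate derivative", {
  # a factor with zero efficiencies whose sites overlap nothing else has no
  # effect on output, so the derivative in its level vanishes
  par <- param_set(
    tf_params(c("act", "null"), role = c("activator", "repressor"),
              E_A = c(3, 0), E_Q = c(0, 0), E_C = c(0, 0)),
    global_params(theta = 6, beta = 0.02, Rmax = 50, alpha = 100))
  cons_act <- pwm_record("act", log(matrix(c(0.97, 0.01, 0.01, 0.01),
                                           8, 4, byrow = TRUE) / 0.25))
  cons_null <- pwm_record("null", log(matrix(c(0.01, 0.97, 0.01, 0.01),
                                             8, 4, byrow = TRUE) / 0.25))
  # TA background scores below threshold for both factors on both strands,
  # so the two planted runs yield non-overlapping site clusters
  seqs <- paste0(strrep("TA", 20), "AAAAAAAA", strrep("TA", 30), "CCCCCCCC",
                 strrep("TA", 20))
  prof <- tibble::tibble(position = 1:3, act = c(1, 2, 3), null = c(5, 5, 5))
  d <- rate_derivative(par, seqs, list(cons_act, cons_null), prof,
                       tf = "null", position = 2, h = 1e-3)
  expect_equal(d, 0)
  # while the activator's derivative is positive
  d2 <- rate_derivative(par, seqs, list(cons_act, cons_null), prof,
                        tf = "act", position = 2, h = 1e-3)
  expect_gt(d2, 0)
  # at zero concentration the forward quotient is used without error
  prof0 <- prof
  prof0$act <- c(0, 0, 0)
  d3 <- rate_derivative(par, seqs, list(cons_act, cons_null), prof0,
                        tf = "act", position = 2, h = 1e-3)
  expect_gte(d3, 0)
})

test_that("derivative estimates are stable across step sizes", {
  b <- benchmark_fixture()
  sw <- derivative_convergence(b$params, b$seq, b$pwms, b$profiles,
                               tf = "repM", position = 20,
                               h_values = c(1e-3, 1e-6))
  expect_equal(sw$derivative[1], sw$derivative[2],
               tolerance = 1e-4)
})

test_that("border contributions vanish for uniform factors and sign-match repressors", {
  b <- benchmark_fixture()
  bc <- border_contributions(b$params, b$seq, b$pwms, b$profiles,
                             tfs = c("actU", "repN"))
  u <- dplyr::filter(bc, .data$tf == "actU")
  expect_equal(u$contribution, rep(0, nrow(u)))  # spatially uniform factor
  # repN falls along the axis (anterior repressor): its level declines, and
  # since it represses, the declining repression contributes positively
  rn <- dplyr::filter(bc, .data$tf == "repN")
  mid <- rn$position > 45 & rn$position < 70
  expect_true(all(rn$delta[mid] < 0))
  expect_true(all(rn$derivative[mid] <= 1e-9))
  expect_true(sum(rn$contribution[mid]) > 0)
})

test_that("per-factor border contributions sum to the first-order output change", {
  b <- benchmark_fixture()
  st <- scan_sites(b$pwms, b$seq, 0)
  bc <- border_contributions(b$params, b$seq, b$pwms, b$profiles)
  tot <- dplyr::summarise(dplyr::group_by(bc, .data$position),
                          contribution = sum(.data$contribution))
  r <- predict_locus(b$seq, b$pwms, b$params, b$profiles,
                     details = FALSE)$prediction$rate
  P <- length(r)

  # the summed contributions are exactly the directional derivative of the
  # rate along the local profile-change direction (gradient identity)
  tfs <- intersect(b$params$tf$tf, names(b$profiles))
  dir_deriv <- function(i, s = 1e-3) {
    shift <- function(sgn) {
      pf <- b$profiles
      for (tf in tfs) {
        conc <- pf[[tf]]
        d <- (conc[i + 1] - conc[i - 1]) / 2
        pf[[tf]][i] <- max(conc[i] + sgn * s * d, 0)
      }
      predict_locus(b$seq, b$pwms, b$params, pf, sites = st,
                    details = FALSE)$prediction$rate[i]
    }
    (shift(1) - shift(-1)) / (2 * s)
  }
  for (i in c(8, 15, 25, 40, 50)) {
    expect_equal(tot$contribution[i], dir_deriv(i), tolerance = 1e-3)
  }

  # and they track the realised change between adjacent positions closely
  # in aggregate (the residual is higher-order path curvature)
  dr <- (r[3:P] - r[1:(P - 2)]) / 2
  pred_dr <- tot$contribution[2:(P - 1)]
  expect_lt(sqrt(sum((pred_dr - dr)^2) / sum(dr^2)), 0.1)
})

test_that("the literal-average delta reading is available behind the flag", {
  b <- benchmark_fixture()
  bc <- border_contributions(b$params, b$seq, b$pwms, b$profiles,
                             tfs = "actU", delta_method = "literal_average")
  u <- dplyr::filter(bc, .data$tf == "actU")
  # literal average of a uniform profile is the level itself, not zero
  expect_true(all(u$delta == 150))
})

test_that("activation shares decompose the time-weighted adaptor total exactly", {
  b <- benchmark_fixture()
  st <- scan_sites(b$pwms, b$seq, 0)
  sh <- activation_shares(b$params, b$seq, b$pwms, b$profiles, sites = st)
  out <- predict_locus(b$seq, b$pwms, b$params, b$profiles, sites = st)
  Tf <- window_time(out$N, b$params$global$beta)
  total <- colSums(out$N * Tf)
  by_pos <- dplyr::summarise(dplyr::group_by(sh, .data$position),
                             N = sum(.data$N_a))
  expect_equal(by_pos$N, unname(total), tolerance = 1e-12)
  # the maximal share is 100 wherever there is any activation
  mx <- dplyr::summarise(dplyr::group_by(sh, .data$position),
                         m = max(.data$percent))
  expect_true(all(mx$m[total > 0] == 100))
  # the graded activator dominates anteriorly, where its sites are loaded
  aA <- dplyr::filter(sh, .data$tf == "actA")
  expect_gt(aA$N_a[5], aA$N_a[50])
})

test_that("fragment assays standardise to a unit maximum", {
  b <- benchmark_fixture()
  pa <- b$spec$enhancers$stripeA$position
  frag <- locus_sequence(substr(b$seq$bases, pa - 300, pa + 600))
  fa <- fragment_assay(b$params, frag, b$pwms, b$profiles)
  expect_equal(max(fa$prediction$standardized), 1)
  expect_true(all(fa$prediction$standardized >= 0 &
                    fa$prediction$standardized <= 1))
  # whole locus as the fragment: identical to predict, then standardised
  fl <- fragment_assay(b$params, b$seq, b$pwms, b$profiles)
  out <- predict_locus(b$seq, b$pwms, b$params, b$profiles)
  expect_equal(fl$prediction$standardized,
               out$prediction$rate / max(out$prediction$rate))
  # fragment with no called sites is silent
  empty <- fragment_assay(b$params, strrep("G", 300), b$pwms, b$profiles)
  expect_equal(unique(empty$prediction$standardized), 0)
})

test_that("trans-environment edits apply cleanly and leave the input untouched", {
  b <- benchmark_fixture()
  before <- b$profiles
  ed <- perturb_trans(b$profiles, list(
    list(tf = "hbC", op = "set_uniform", value = 180),
    list(tf = "repN", op = "scale", value = 0.6),
    list(tf = "repM", op = "zero")
  ))
  expect_equal(ed$hbC, rep(180, nrow(ed)))
  expect_equal(ed$repN, before$repN * 0.6)
  expect_equal(ed$repM, rep(0, nrow(ed)))
  expect_equal(b$profiles, before)
  # scaling by 1 is the identity; unknown names error
  expect_equal(perturb_trans(b$profiles, list(list(tf = "actA", op = "scale",
                                                   value = 1))),
               b$profiles)
  expect_error(perturb_trans(b$profiles, list(list(tf = "nope", op = "zero"))),
               "unknown factor")
})
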