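test_that("neighbour graph and auto-covariate follow the stated geometry", {
  stn <- toy_stations(3)
  stn$x <- c(0, 800, 1600); stn$y <- 0
  g <- build_neighbor_graph(stn, 1000)
  expect_equal(g$n, c(1L, 2L, 1L))
  expect_equal(g$neighbors[[2]], c(1L, 3L))

  g2 <- build_neighbor_graph(stn[1:2, ], 100)
  expect_equal(g2$n, c(0L, 0L))
  expect_warning(D <- auto_covariate(c(1, 1), g2), "isolated")
  expect_equal(D, c(0, 0))

  expect_equal(auto_covariate(c(1, 0, 1), g)[2], 1)
  expect_equal(suppressWarnings(auto_covariate(c(1, 0, 1), g))[1], 0)
  # mean of neighbours' states
  stn4 <- toy_stations(4)
  stn4$x <- c(0, 100, 200, 300); stn4$y <- 0
  g4 <- build_neighbor_graph(stn4, 5000)
  expect_equal(auto_covariate(c(9, 1, 0, 1) * 0 + c(0, 1, 0, 1), g4)[1], 2 / 3)
})

test_that("single-site single-season likelihood matches the closed forms", {
  stn <- toy_stations(1)
  sp <- occu_spec()
  psi <- 0.37; p <- 0.62
  th <- c(qlogis(psi), qlogis(p))

  y1 <- array(c(1), c(1, 1, 1))
  h1 <- history_from_y(y1)
  expect_equal(dynamic_loglik(th, sp, h1, stn), log(psi * p), tolerance = 1e-12)

  y0 <- array(c(0, 0), c(1, 1, 2))
  h0 <- history_from_y(y0)
  expect_equal(dynamic_loglik(th, sp, h0, stn),
               log(psi * (1 - p)^2 + (1 - psi)), tolerance = 1e-12)
})

test_that("marginal likelihood equals brute-force enumeration on random toys", {
  for (seed in 1:40) {
    toy <- random_toy(seed)
    h <- history_from_y(toy$y)
    stn <- toy_stations(toy$n, seed)
    sp <- occu_spec()
    th <- if (toy$Tn == 1) qlogis(c(toy$psi1, toy$p))
          else qlogis(c(toy$psi1, toy$gamma, toy$epsilon, toy$p))
    expect_equal(dynamic_loglik(th, sp, h, stn),
                 brute_force_loglik(toy$psi1, toy$gamma, toy$epsilon, toy$p,
                                    toy$y),
                 tolerance = 1e-10)
  }
})

test_that("with no turnover the dynamic likelihood factorizes over seasons with shared z", {
  set.seed(3)
  n <- 5; Tn <- 3; K <- 4
  y <- array(rbinom(n * Tn * K, 1, 0.3), c(n, Tn, K))
  h <- history_from_y(y)
  stn <- toy_stations(n)
  psi <- 0.45; p <- 0.55
  # gamma -> 0, epsilon -> 0 on the logit scale
  ll <- dynamic_loglik(c(qlogis(psi), -30, -30, qlogis(p)), occu_spec(), h, stn)
  per_site <- sapply(seq_len(n), function(i) {
    e1 <- prod(p^y[i, , ] * (1 - p)^(1 - y[i, , ]))
    e0 <- as.numeric(all(y[i, , ] == 0))
    log(psi * e1 + (1 - psi) * e0)
  })
  expect_equal(ll, sum(per_site), tolerance = 1e-8)
})

test_that("split Gelman-Rubin behaves at its reference points", {
  set.seed(5)
  ch <- matrix(rnorm(4000), 2000, 2)
  expect_equal(unname(gelman_rubin(list(ch, ch))), c(1, 1), tolerance = 0.01)

  chains <- lapply(1:3, function(i) matrix(rnorm(5000), 5000, 1))
  expect_lt(gelman_rubin(chains)[1], 1.01)

  far <- list(matrix(rnorm(1000, 0), 1000, 1), matrix(rnorm(1000, 10), 1000, 1))
  expect_gt(gelman_rubin(far)[1], 3)

  expect_error(gelman_rubin(list(matrix(rnorm(10), 10, 1))), "two chains")
})

test_that("posterior mean tracks the ML estimate under diffuse priors", {
  set.seed(14)
  stn <- simulate_landscape(80, seed = 14)
  des <- toy_design(stn$id, Tn = 2)
  tr <- synthetic_truth(psi1 = c("(Intercept)" = qlogis(0.6)),
                        gamma = c("(Intercept)" = qlogis(0.25)),
                        epsilon = c("(Intercept)" = qlogis(0.3)),
                        p = c("(Intercept)" = qlogis(0.55)),
                        diel = list(t1 = list(type = "uniform")))
  sim <- simulate_dynamics(tr, stn, des, seed = 15)
  sp <- occu_spec()
  fit <- fit_occu(sp, sim$history, stn,
                  control = mcmc_control(n_chains = 2, n_iter = 1500,
                                         n_burn = 500, seed = 16))
  ml <- fit_occu_ml(sp, sim$history, stn)
  expect_equal(unname(plogis(coef(fit))), unname(plogis(ml$par)),
               tolerance = 0.07)
})

test_that("a site with no observations gets its prior-predictive occupancy", {
  set.seed(20)
  n <- 60
  y <- array(rbinom(n * 4, 1, 0.5 * 0.5), c(n, 1, 4))
  y[1, , ] <- NA  # site 1 never surveyed
  h <- history_from_y(y)
  stn <- toy_stations(n)
  fit <- fit_occu(occu_spec(), h, stn,
                  control = mcmc_control(n_chains = 2, n_iter = 1500,
                                         n_burn = 400, z_draws = 1500,
                                         seed = 21))
  psi_draws <- plogis(fit$samples[, "psi1.(Intercept)"])
  expect_equal(mean(fit$z_draws[, 1, 1]), mean(psi_draws), tolerance = 0.05)
})

test_that("posterior mean bias shrinks from 100 to 500 sites", {
  mae <- sapply(c(100, 500), function(n) {
    errs <- sapply(1:3, function(r) {
      stn <- simulate_landscape(n, seed = 30 + r)
      des <- toy_design(stn$id, Tn = 2)
      tr <- synthetic_truth(psi1 = c("(Intercept)" = qlogis(0.6)),
                            gamma = c("(Intercept)" = qlogis(0.2)),
                            epsilon = c("(Intercept)" = qlogis(0.3)),
                            p = c("(Intercept)" = qlogis(0.5)),
                            diel = list(t1 = list(type = "uniform")))
      sim <- simulate_dynamics(tr, stn, des, seed = 40 + r)
      fit <- fit_occu(occu_spec(), sim$history, stn,
                      control = mcmc_control(n_chains = 2, n_iter = 800,
                                             n_burn = 300, z_draws = 200,
                                             seed = 50 + r))
      abs(plogis(coef(fit)[["psi1.(Intercept)"]]) - 0.6)
    })
    mean(errs)
  })
  expect_lt(mae[2], mae[1] + 0.01)
})

test_that("posterior ranks of a prior-drawn truth are not extreme (SBC smoke test)", {
  set.seed(60)
  ranks <- sapply(1:16, function(r) {
    b_psi <- rnorm(1, 0, 1.2); b_p <- rnorm(1, 0, 1.2)
    n <- 50
    z <- rbinom(n, 1, plogis(b_psi))
    y <- array(rbinom(n * 4, 1, rep(z, 4) * plogis(b_p)), c(n, 1, 4))
    h <- history_from_y(y)
    fit <- quiet_fit(occu_spec(), h, toy_stations(n),
                     control = mcmc_control(n_chains = 2, n_iter = 600,
                                            n_burn = 300, z_draws = 10,
                                            prior_sd = 1.2, seed = 600 + r))
    mean(fit$samples[, "psi1.(Intercept)"] < b_psi)
  })
  expect_gt(mean(ranks), 0.25)
  expect_lt(mean(ranks), 0.75)
  expect_gt(max(ranks), 0.2)
  expect_lt(min(ranks), 0.8)
})

test_that("latent-state engine agrees with the marginal engine without the auto-covariate", {
  set.seed(70)
  stn <- simulate_landscape(60, seed = 70)
  des <- toy_design(stn$id, Tn = 2)
  tr <- synthetic_truth(psi1 = c("(Intercept)" = 0),
                        gamma = c("(Intercept)" = qlogis(0.25)),
                        epsilon = c("(Intercept)" = qlogis(0.35)),
                        p = c("(Intercept)" = 0),
                        diel = list(t1 = list(type = "uniform")))
  sim <- simulate_dynamics(tr, stn, des, seed = 71)
  ctl <- mcmc_control(n_chains = 2, n_iter = 1200, n_burn = 400, seed = 72)
  fit_m <- fit_occu(occu_spec(), sim$history, stn, control = ctl)
  # auto-covariate present but with the coefficient pinned by a tight prior
  # is not available; instead compare against the latent engine via a spec
  # whose auto coefficient is estimated on data simulated without the effect
  graph <- build_neighbor_graph(stn, 1500)
  fit_l <- quiet_fit(occu_spec(auto = "gamma"), sim$history, stn,
                     graph = graph, control = ctl)
  shared <- intersect(colnames(fit_m$samples), colnames(fit_l$samples))
  shared <- setdiff(shared, "gamma.(Intercept)")  # absorbs the auto term
  expect_equal(plogis(colMeans(fit_m$samples[, shared])),
               plogis(colMeans(fit_l$samples[, shared])), tolerance = 0.08)
})

test_that("posterior matches an independent JAGS fit on a single-season model", {
  skip_if_not_installed("rjags")
  set.seed(80)
  n <- 150; K <- 4
  psi_t <- 0.55; p_t <- 0.45
  z <- rbinom(n, 1, psi_t)
  y <- array(rbinom(n * K, 1, rep(z, K) * p_t), c(n, 1, K))
  h <- history_from_y(y)
  fit <- fit_occu(occu_spec(), h, toy_stations(n),
                  control = mcmc_control(n_chains = 2, n_iter = 3000,
                                         n_burn = 600, z_draws = 10,
                                         seed = 81))
  model_str <- "model {
    lpsi ~ dnorm(0, 0.001); lp ~ dnorm(0, 0.001)
    psi <- ilogit(lpsi); p <- ilogit(lp)
    for (i in 1:n) {
      z[i] ~ dbern(psi)
      for (k in 1:K) { y[i,k] ~ dbern(z[i] * p) }
    }
  }"
  jm <- rjags::jags.model(textConnection(model_str),
                          data = list(y = y[, 1, ], n = n, K = K),
                          inits = list(z = rep(1, n)),
                          n.chains = 2, quiet = TRUE)
  update(jm, 1000, progress.bar = "none")
  ss <- rjags::coda.samples(jm, c("psi", "p"), 6000, progress.bar = "none")
  jags_means <- colMeans(as.matrix(ss))
  expect_equal(plogis(coef(fit)[["psi1.(Intercept)"]]),
               unname(jags_means["psi"]), tolerance = 0.05)
  expect_equal(plogis(coef(fit)[["p.(Intercept)"]]),
               unname(jags_means["p"]), tolerance = 0.05)
})

test_that("response curves reflect the fitted structure", {
  set.seed(90)
  stn <- simulate_landscape(120, seed = 90)
  des <- toy_design(stn$id, Tn = 1)
  tr <- synthetic_truth(psi1 = c("(Intercept)" = 0.3, dist_freshwater = -1),
                        gamma = c("(Intercept)" = 0),
                        epsilon = c("(Intercept)" = 0),
                        p = c("(Intercept)" = 0.4),
                        diel = list(t1 = list(type = "uniform")))
  sim <- simulate_dynamics(tr, stn, des, seed = 91)
  fit <- fit_occu(occu_spec(psi1 = ~dist_freshwater), sim$history, stn,
                  control = mcmc_control(n_chains = 2, n_iter = 1000,
                                         n_burn = 300, z_draws = 100,
                                         seed = 92))
  rc <- response_curve(fit, "psi1", "dist_freshwater", grid = 20)
  expect_equal(nrow(rc), 20)
  expect_true(all(rc$mean >= 0 & rc$mean <= 1))
  # monotone slope: curve monotone over the grid
  expect_true(all(diff(rc$mean) < 0))
  expect_error(response_curve(fit, "psi1", "slope"), "not in the psi1")
  expect_error(response_curve(fit, "p", "dist_freshwater"), "not in the p")

  # quadratic vertex at -b/(2c) on the standardized scale
  fitq <- fit_occu(occu_spec(psi1 = ~ dist_freshwater + I(dist_freshwater^2)),
                   sim$history, stn,
                   control = mcmc_control(n_chains = 2, n_iter = 1000,
                                          n_burn = 300, z_draws = 100,
                                          seed = 93))
  b <- coef(fitq)[["psi1.dist_freshwater"]]
  cc <- coef(fitq)[["psi1.I(dist_freshwater^2)"]]
  rcq <- response_curve(fitq, "psi1", "dist_freshwater", grid = 200)
  std <- (rcq$covariate - fitq$scaling$mean[1]) / fitq$scaling$sd[1]
  eta <- coef(fitq)[["psi1.(Intercept)"]] + b * std + cc * std^2
  expect_equal(rcq$mean[which.max(eta)],
               max(rcq$mean), tolerance = 0.05)
})

test_that("PAO equals naive occupancy when detection is perfect", {
  set.seed(100)
  n <- 80
  z <- rbinom(n, 1, 0.5)
  y <- array(rep(z, 4), c(n, 1, 4))  # p = 1: z observed directly
  h <- history_from_y(y)
  fit <- fit_occu(occu_spec(), h, toy_stations(n),
                  control = mcmc_control(n_chains = 2, n_iter = 800,
                                         n_burn = 300, seed = 101))
  expect_equal(pao(fit, 1)$mean, mean(z), tolerance = 1e-9)
  expect_error(pao(fit, 5), "season")
  # all z draws 1 => PAO 1
  fit2 <- fit
  fit2$z_draws[] <- 1L
  expect_equal(pao(fit2, 1)$mean, 1)
})
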