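test_that("update follows the masked weighted sum with sgn(0) = +1", {
  # 3-neuron toy net checked against hand arithmetic
  w <- matrix(c(0, 1, -1,
                2, 0, 0,
                0, 0, 0), 3, 3, byrow = TRUE)
  s <- c(1, -1, 1)
  # fields: (0*1 + 1*-1 + -1*1, 2*1, 0) = (-2, 2, 0) -> (-1, 1, 1)
  expect_equal(update_state(s, w), c(-1, 1, 1))
  # zero field maps to +1 everywhere
  expect_equal(update_state(s, matrix(0, 3, 3)), c(1, 1, 1))
  # threshold tips the zero-field sign
  expect_equal(update_state(s, matrix(0, 3, 3), theta = 0.01), c(-1, -1, -1))
  expect_error(update_state(c(1, -1), w), "consistency error")
  expect_error(update_state(c(1, 0, 1), w), "consistency error")
})

test_that("embedded states advance one phase and orbits have period L", {
  net <- small_net()
  ps <- net$ps
  s0 <- ps$xi[, pattern_index(3, 1, ps$L)]
  traj <- run_simulation(s0, 3 * ps$L, net$w)
  expect_equal(traj$detected_period, ps$L)
  expect_equal(traj$convergence_step, 0)
  # s(t) = s(t + L) along the whole trajectory
  expect_identical(traj$states[, 1:(2 * ps$L)],
                   traj$states[, ps$L + 1:(2 * ps$L)])
  short <- run_simulation(s0, 1, net$w)
  expect_equal(ncol(short$states), 2)
})

test_that("cycle detection finds the smallest period and earliest onset", {
  mk <- function(cols) structure(list(states = cols), class = "trajectory")
  A <- c(1, 1); B <- c(1, -1); C <- c(-1, -1)
  expect_equal(detect_cycle(mk(cbind(A, B, A, B, A, B)), 5),
               list(period = 2, onset = 0L))
  expect_equal(detect_cycle(mk(cbind(A, A, A)), 2),
               list(period = 1, onset = 0L))
  expect_equal(detect_cycle(mk(cbind(C, A, B, A, B)), 4),
               list(period = 2, onset = 1L))
  expect_null(detect_cycle(mk(cbind(A, B, C)), 2))
})

test_that("overlap is 1 on the pattern, -1 on the antipattern, small for noise", {
  net <- small_net()
  ps <- net$ps
  j <- pattern_index(2, 3, ps$L)
  s <- ps$xi[, j]
  for (m in c("V", "M", "P"))
    expect_equal(overlap(s, ps, m)[j], 1)
  expect_equal(overlap(-s, ps, "M")[j], -1)
  # random states have |m| < 0.2 at n >= 900 essentially always
  lay <- module_layout()
  big <- generate_patterns(lay, K = 2, L = 2, seed = 3)
  set.seed(11)
  for (i in 1:20) {
    r <- sample(c(-1, 1), 3000, replace = TRUE)
    expect_lt(max(abs(overlap(r, big, "V"))), 0.2)
  }
})

test_that("a strong persistent input pins the visual module to the stimulus", {
  net <- small_net()
  ps <- net$ps
  rngV <- module_ranges(ps$layout)$V
  qv <- ps$xi[rngV, pattern_index(1, 1, ps$L)]
  # strength above any possible weighted field (max |row| sum)
  strength <- max(rowSums(abs(net$w$w))) + 1
  inp <- input_signal(qv, mode = "persistent", strength = strength)
  set.seed(5)
  s0 <- sample(c(-1, 1), layout_total(ps$layout), replace = TRUE)
  traj <- run_simulation(s0, 5, net$w, input = inp)
  for (t in 2:6)
    expect_identical(traj$states[rngV, t], qv)
})

test_that("initialization-mode input writes the probe into the visual block", {
  net <- small_net()
  ps <- net$ps
  rngV <- module_ranges(ps$layout)$V
  qv <- -ps$xi[rngV, 1]
  s0 <- ps$xi[, 1]
  traj <- run_simulation(s0, 1, net$w, input = input_signal(qv))
  expect_identical(traj$states[rngV, 1], qv)
})

test_that("trajectories are deterministic and probes reproducible", {
  net <- small_net()
  s0 <- noisy_probe(net$ps, 1, 1, 0.05, seed = 8)
  expect_identical(s0, noisy_probe(net$ps, 1, 1, 0.05, seed = 8))
  expect_equal(sum(s0 != net$ps$xi[, 1]),
               round(0.05 * net$ps$layout$n_visual))
  a <- run_simulation(s0, 10, net$w)
  b <- run_simulation(s0, 10, net$w)
  expect_identical(a$states, b$states)
  rnd <- noisy_probe(net$ps, 1, 1, 0.05, seed = 8, perceiving = "random")
  rngP <- module_ranges(net$ps$layout)$P
  expect_identical(rnd[-rngP][1:90], s0[-rngP][1:90])
})

test_that("noisy basin probes converge back to their cycle", {
  net <- small_net()
  ps <- net$ps
  keys <- apply(ps$xi, 2, paste, collapse = "")
  n_ok <- 0
  for (j in 1:50) {
    mu <- (j - 1) %% ps$K + 1
    s0 <- noisy_probe(ps, mu, 1, 0.05, seed = 100 + j)
    traj <- run_simulation(s0, 5 * ps$L, net$w)
    fin <- paste(traj$states[, ncol(traj$states)], collapse = "")
    hit <- match(fin, keys)
    if (!is.na(hit) && (hit - 1) %/% ps$L + 1 == mu) n_ok <- n_ok + 1
  }
  expect_gte(n_ok, 49)
})

test_that("mean veridical rate degrades monotonically with pooled fan-in", {
  # scaled-down version of the full-size budget sweep: N = 300,
  # budgets proportional to {2100, 1575, 1050, 525} of 2100
  net <- small_net()
  rates <- vapply(c(210, 157, 105, 52), function(b) {
    sw <- run_bottom_up_impairment(net$ps, net$w, budget = b, n_config = 50,
                                   steps = 40, seed = 7)
    unname(sw$frequencies["veridical"])
  }, numeric(1))
  expect_true(all(diff(rates) <= 0))
})
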