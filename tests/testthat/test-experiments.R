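test_that("classification covers the four labels and is total", {
  net <- small_net()
  ps <- net$ps
  L <- ps$L
  # fabricate trajectories from embedded states to hit each label
  mk_traj <- function(cols) structure(list(states = cols, mask = NULL,
                                           convergence_step = NA_integer_),
                                      class = "trajectory")
  on_cycle <- function(mu, n) ps$xi[, pattern_index(mu, (0:(n - 1)) %% L + 1, L)]
  set.seed(2)
  rand_states <- matrix(sample(c(-1, 1), 300 * L, replace = TRUE), 300, L)

  veridical <- classify_outcome(mk_traj(on_cycle(1, 3 * L)), ps, 1)
  expect_equal(veridical$label, "veridical")
  expect_equal(veridical$final_cycle, 1L)

  # pinned on another cycle's perceiving pattern from the start
  hall <- classify_outcome(mk_traj(on_cycle(2, 3 * L)), ps, 1)
  expect_equal(hall$label, "hallucination-like")
  expect_equal(hall$final_cycle, 2L)

  # sustained error then a veridical ending
  trans <- classify_outcome(mk_traj(cbind(on_cycle(2, L + 2), on_cycle(1, 2 * L))),
                            ps, 1)
  expect_equal(trans$label, "transient-error-then-veridical")

  # sub-threshold wandering matches nothing
  nc <- classify_outcome(mk_traj(cbind(rand_states, rand_states, rand_states)),
                         ps, 1)
  expect_equal(nc$label, "non-convergent")
  expect_true(is.na(nc$final_cycle))

  labels <- c(veridical$label, hall$label, trans$label, nc$label)
  expect_true(all(labels %in% pasim:::OUTCOME_LABELS))
  expect_error(classify_outcome(mk_traj(on_cycle(1, 2)), ps, 1), "too short")
})

test_that("intact networks are veridical on every probe (control invariance)", {
  net <- small_net()
  sw <- run_bottom_up_impairment(net$ps, net$w,
                                 budget = net$ps$layout$n_visual +
                                   net$ps$layout$n_memory,
                                 n_config = 5, seed = 3)
  expect_equal(unname(sw$frequencies["veridical"]), 1)
  expect_equal(sum(sw$frequencies), 1)
  expect_equal(nrow(sw$outcomes), 5 * net$ps$K)
})

test_that("a perceiving module with no bottom-up input cannot track the stimulus", {
  # with budget 0 the perceiving module sees nothing from V or M: its
  # trajectory depends only on its own initial state, so showing a
  # different stimulus cannot change what is "perceived" (any residual
  # veridical outcome is a chance hit of the uncommitted start state)
  net <- small_net()
  ps <- net$ps
  mask <- make_lesion(lesion_config(pooled = list(list(target = "P",
                                                       sources = c("V", "M"),
                                                       r = 0)),
                                    seed = 5), ps$layout)
  rngP <- module_ranges(ps$layout)$P
  s1 <- noisy_probe(ps, 1, 1, 0.05, seed = 7, perceiving = "random")
  s2 <- noisy_probe(ps, 2, 1, 0.05, seed = 7, perceiving = "random")
  s2[rngP] <- s1[rngP]                       # same uncommitted percept state
  t1 <- run_simulation(s1, 20, net$w, mask)
  t2 <- run_simulation(s2, 20, net$w, mask)
  expect_identical(t1$states[rngP, ], t2$states[rngP, ])
  expect_false(identical(t1$states[-rngP, ], t2$states[-rngP, ]))
})

test_that("sweeps are reproducible from their seed", {
  net <- small_net()
  a <- run_bottom_up_impairment(net$ps, net$w, budget = 105, n_config = 3,
                                seed = 11)
  b <- run_bottom_up_impairment(net$ps, net$w, budget = 105, n_config = 3,
                                seed = 11)
  expect_identical(a$outcomes, b$outcomes)
  expect_identical(a$seed_manifest, b$seed_manifest)
  expect_error(run_bottom_up_impairment(net$ps, net$w, budget = 1e6),
               "infeasible budget")
})

test_that("zero-amplitude threshold schedules reproduce lesion-only outcomes", {
  net <- small_net()
  les <- lesion_config(pooled = list(list(target = "P",
                                          sources = c("V", "M"), r = 70)),
                       seed = 21)
  sched0 <- threshold_schedule(P = c(A = 0, period = 40))
  tf <- run_threshold_fluctuation(net$ps, net$w, sched0, phases = 0:39,
                                  n_probe = 2, lesion = les, seed = 13)
  # same mask + probe without any schedule, via the single-run interface
  mask <- make_lesion(les, net$ps$layout)
  seeds <- pasim:::derive_seeds(13, 2)
  for (pr in 1:2) {
    s0 <- noisy_probe(net$ps, pr, 1, 0.05, seeds[pr], perceiving = "random")
    tr <- run_simulation(s0, tf$params$steps, net$w, mask)
    oc <- classify_outcome(tr, net$ps, pr)
    labs <- tf$outcomes$label[tf$outcomes$probe == pr]
    expect_true(all(labs == oc$label))
  }
})

test_that("an overwhelming threshold amplitude saturates the perceiving module", {
  net <- small_net()
  ps <- net$ps
  big <- max(rowSums(abs(net$w$w))) + 1
  sched <- threshold_schedule(P = c(A = big, period = 2 * ps$L))
  s0 <- ps$xi[, 1]
  rngP <- module_ranges(ps$layout)$P
  traj <- run_simulation(s0, 2 * ps$L, net$w, schedule = sched)
  # while sin > 0 the threshold forces -1, while sin < 0 it forces +1
  expect_true(all(traj$states[rngP, 3] == -1))          # after theta(1) > 0
  expect_true(all(traj$states[rngP, ps$L + 3] == 1))    # after theta(L+1) < 0
})

test_that("combined-necrosis sweeps report per-cell frequencies and typical labels", {
  net <- small_net()
  cells <- list(
    none = lesion_config(),
    structured = lesion_config(dead = c(V = 9),
                               fan_in = list("M<-V" = 54, "P<-V" = 54))
  )
  cn <- run_combined_necrosis(net$ps, net$w, cells, n_config = 3,
                              n_probe = 4, seed = 19)
  expect_equal(nrow(cn$outcomes), 2 * 3 * 4)
  f <- cn$cell_frequencies
  expect_equal(unname(vapply(f, sum, numeric(1))), c(1, 1))
  expect_equal(unname(f$none["veridical"]), 1)
  expect_true("veridical" %in% cn$typical_labels$none)
  # single-cell, single-config sweeps have frequencies in {0, 1}
  one <- run_combined_necrosis(net$ps, net$w, cells["none"], n_config = 1,
                               n_probe = 1, seed = 23)
  expect_true(all(one$frequencies %in% c(0, 1)))
})

test_that("structured destruction destabilizes at least as much as random spread", {
  # matched total severity: the same number of pruned connections spread
  # over every projection barely perturbs recall, while concentrating them
  # on the bottom-up pathway into P does the damage
  net <- small_net()
  nv <- 90; nm <- 120
  structured <- lesion_config(pooled = list(list(target = "P",
                                                 sources = c("V", "M"),
                                                 r = 42)))
  # slightly more total pruning (15300 vs 15120 connections) spread
  # uniformly over every neuron's full fan-in
  spread <- lesion_config(pooled = list(
    list(target = "V", sources = c("V", "M", "P"), r = 249),
    list(target = "M", sources = c("V", "M", "P"), r = 249),
    list(target = "P", sources = c("V", "M", "P"), r = 249)))
  cn <- run_combined_necrosis(net$ps, net$w,
                              list(structured = structured, spread = spread),
                              n_config = 5, n_probe = net$ps$K, seed = 29)
  bad <- function(cell) {
    f <- cn$cell_frequencies[[cell]]
    unname(f["hallucination-like"] + f["non-convergent"] +
             f["transient-error-then-veridical"])
  }
  expect_gte(bad("structured"), bad("spread"))
})

test_that("sweep outcomes export to CSV and JSON summaries", {
  net <- small_net()
  sw <- run_bottom_up_impairment(net$ps, net$w, budget = 100, n_config = 2,
                                 seed = 37)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_sweep_csv(sw, csv)
  back <- utils::read.csv(csv)
  expect_equal(nrow(back), nrow(sw$outcomes))
  write_sweep_summary(sw, js)
  summ <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(summ$experiment, "bottom_up_impairment")
  expect_equal(sum(unlist(summ$frequencies)), 1)
})
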