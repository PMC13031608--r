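# cheap loop configuration used throughout: 2 factors, 2 base models,
# small search budget
cheap_setup <- function(seed = 1, oracle_seed = 99) {
  cfg <- tiny_oracle_config(seed = oracle_seed)
  orc <- make_oracle(cfg)
  set.seed(1234)
  X <- data.frame(a = runif(12, 0, 10), b = runif(12, 0, 10))
  resp <- oracle_query(orc, X)
  init <- experiment_table(X, response = resp$response,
                           replicate_sd = resp$replicate_sd,
                           n_reps = resp$n_reps)
  lc <- loop_config(space = cfg$space, registry = fast_registry(),
                    outer_folds = 3, inner_folds = 2,
                    n_iterations = 200, batch_size = 4,
                    min_distance = 0.01, seed = seed)
  list(oracle = orc, init = init, config = lc)
}

test_that("a round appends the answered batch and updates the best", {
  s <- cheap_setup()
  st0 <- round_state(s$init)
  st1 <- run_round(st0, s$config, oracle_responder(s$oracle))
  expect_equal(nrow(st1$data), nrow(st0$data) + s$config$batch_size)
  expect_equal(sum(st1$data$round_id == 1), s$config$batch_size)
  expect_gte(st1$best$response, st0$best$response)
  expect_length(st1$history, 1)
})

test_that("a partial responder answer is accepted with a warning", {
  s <- cheap_setup()
  st0 <- round_state(s$init)
  partial <- function(settings, n_reps = NULL) {
    full <- oracle_query(s$oracle, settings, n_reps)
    full[1:2, ]
  }
  expect_warning(st1 <- run_round(st0, s$config, partial),
                 "answered 2 of 4")
  expect_equal(nrow(st1$data), nrow(st0$data) + 2)
})

test_that("convergence rule matches its definition by enumeration", {
  expect_true(check_convergence(c(0.005, 0.008), threshold = 0.01,
                                patience = 2))
  expect_false(check_convergence(numeric(0)))
  expect_false(check_convergence(0.001, threshold = 0.02, patience = 2))
  # threshold 0: converges only on strictly negative improvement --
  # enumerate all small histories over {-0.01, 0, 0.01}
  vals <- c(-0.01, 0, 0.01)
  for (n in 1:3) {
    combos <- expand.grid(rep(list(vals), n))
    for (r in seq_len(nrow(combos))) {
      h <- as.numeric(combos[r, ])
      manual <- n >= 2 && all(tail(h, 2) < 0)
      expect_equal(check_convergence(h, threshold = 0, patience = 2),
                   manual)
    }
  }
})

test_that("max_rounds 0 returns the initial state unchanged", {
  s <- cheap_setup()
  st0 <- round_state(s$init)
  out <- run_loop(s$init, s$config, oracle_responder(s$oracle),
                  max_rounds = 0)
  expect_equal(out$round, 0)
  expect_equal(as.data.frame(out$data), as.data.frame(st0$data))
  expect_length(attr(out, "audit"), 0)
})

test_that("a seeded loop is bit-identical on re-run and audits rounds", {
  s1 <- cheap_setup(); s2 <- cheap_setup()
  r1 <- run_loop(s1$init, s1$config, oracle_responder(s1$oracle),
                 max_rounds = 2)
  r2 <- run_loop(s2$init, s2$config, oracle_responder(s2$oracle),
                 max_rounds = 2)
  expect_identical(as.data.frame(r1$data), as.data.frame(r2$data))
  expect_identical(r1$best, r2$best)
  audit <- attr(r1, "audit")
  expect_length(audit, r1$round)
  expect_equal(vapply(audit, `[[`, 0, "round"), seq_len(r1$round))
})

test_that("the best-so-far response never decreases across rounds", {
  s <- cheap_setup(seed = 3)
  st <- round_state(s$init)
  prev <- st$best$response
  for (k in 1:3) {
    st <- run_round(st, s$config, oracle_responder(s$oracle))
    expect_gte(st$best$response, prev)
    prev <- st$best$response
  }
})

test_that("a persisted state resumes to the same final state", {
  s1 <- cheap_setup()
  full <- run_loop(s1$init, s1$config, oracle_responder(s1$oracle),
                   max_rounds = 3)
  s2 <- cheap_setup()
  dir <- tempfile(); dir.create(dir)
  part <- run_loop(s2$init, s2$config, oracle_responder(s2$oracle),
                   max_rounds = 2, outdir = dir)
  expect_true(file.exists(file.path(dir, "state_2.json")))
  resumed <- read_round_state(file.path(dir, "state_2.json"))
  expect_equal(as.data.frame(resumed$data), as.data.frame(part$data),
               tolerance = 1e-12)
  cont <- run_loop(resumed, s2$config, oracle_responder(s2$oracle),
                   max_rounds = 3)
  expect_equal(as.data.frame(cont$data), as.data.frame(full$data),
               tolerance = 1e-9)
  expect_equal(cont$best$response, full$best$response, tolerance = 1e-9)
  unlink(dir, recursive = TRUE)
})

test_that("synthetic initialization mirrors the screening-plus-ascent seed", {
  orc <- make_oracle(oracle_config())
  init <- initial_synthetic_data(orc)
  expect_equal(nrow(init), 25)
  expect_true(all(init$round_id == 0))
  expect_true(all(!is.na(init$response)))
  expect_equal(sum(startsWith(init$run_id, "screen_")), 20)
  expect_equal(sum(startsWith(init$run_id, "ascent_")), 5)
  # ascent rows carry the published trial settings
  expect_equal(init$volume[21:25], c(50, 75, 100, 125, 150))
})
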