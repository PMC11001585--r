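test_that("the four conditions are the cartesian product of cue dimensions", {
  conds <- task_conditions()
  expect_equal(nrow(conds), 4)
  expect_equal(nrow(dplyr::distinct(conds)), 4)
  expect_setequal(unique(conds$cue_location), c("left", "right"))
  expect_setequal(unique(conds$cue_frequency), c("low", "high"))
})

test_that("correct_action implements the three rule mappings", {
  expect_equal(correct_action("location", "left", "low"), "left")
  expect_equal(correct_action("location", "right", "high"), "right")
  expect_equal(correct_action("frequency", "right", "low"), "left")
  expect_equal(correct_action("frequency", "left", "high"), "right")
  expect_equal(correct_action("frequency_reversed", "left", "low"), "right")
  expect_equal(correct_action("frequency_reversed", "right", "high"), "left")
  expect_error(correct_action("colour", "left", "low"),
               class = "ruleswitch_config_error")
})

test_that("each rule maps exactly two conditions to each action", {
  conds <- task_conditions()
  for (rule in task_rule_names()) {
    acts <- correct_action(rule, conds$cue_location, conds$cue_frequency)
    expect_equal(sum(acts == "left"), 2, info = rule)
    expect_equal(sum(acts == "right"), 2, info = rule)
  }
})

test_that("stay/switch classification partitions conditions correctly", {
  conds <- task_conditions()
  # first switch: 2 stay, 2 switch
  cls1 <- classify_stay_switch("location", "frequency",
                               conds$cue_location, conds$cue_frequency)
  expect_equal(sum(cls1 == "stay"), 2)
  expect_equal(sum(cls1 == "switch"), 2)
  expect_equal(cls1[conds$condition == "left-low"], "stay")
  expect_equal(cls1[conds$condition == "left-high"], "switch")
  # second switch (within the frequency dimension): all four switch
  cls2 <- classify_stay_switch("frequency", "frequency_reversed",
                               conds$cue_location, conds$cue_frequency)
  expect_true(all(cls2 == "switch"))
  expect_error(classify_stay_switch("location", "location", "left", "low"),
               class = "ruleswitch_argument_error")
})

test_that("schedules are blocked, balanced, and seed-deterministic", {
  sch <- generate_schedule(320, 32, seed = 1)
  expect_equal(nrow(sch), 320)
  expect_equal(max(sch$block), 10)
  counts <- table(sch$block, sch$condition)
  expect_true(all(counts == 8))
  # determinism / seed sensitivity
  expect_identical(generate_schedule(32, 32, seed = 5),
                   generate_schedule(32, 32, seed = 5))
  a <- generate_schedule(64, 32, seed = 1)
  b <- generate_schedule(64, 32, seed = 2)
  expect_false(identical(a$condition, b$condition))
  expect_equal(table(b$block, b$condition), table(a$block, a$condition),
               ignore_attr = TRUE)
  expect_error(generate_schedule(30, block_size = 30),
               class = "ruleswitch_argument_error")
})

test_that("schedules stay balanced per block across many seeds", {
  for (s in 1:100) {
    sch <- generate_schedule(64, 32, seed = s)
    expect_true(all(table(sch$block, sch$condition) == 8))
  }
})

test_that("partial blocks are produced by truncating whole blocks", {
  sch <- generate_schedule(40, 32, seed = 3)
  expect_equal(nrow(sch), 40)
  expect_true(all(table(sch$condition[1:32]) == 8))
})

test_that("the environment has 22 states in five temporal groups", {
  env <- make_environment("location")
  expect_equal(env$n_states, 22)
  expect_equal(as.integer(table(env$states$epoch)[c("initial", "cue", "action",
                                                    "outcome", "end")]),
               c(1L, 4L, 8L, 8L, 1L))
})

test_that("env_step follows the episode graph and rewards outcome entry", {
  env <- make_environment("location")
  # initial -> cue, uniformly
  s <- rng_stream(1)
  first <- replicate(4000, env_step(env, 1, stream = s)$state)
  expect_true(all(first %in% 2:5))
  expect_true(all(abs(table(first) / 4000 - 0.25) < 0.05))
  # cue(left-low) + left -> action(left-low, left) -> reward +1
  st <- env_step(env, 2, "left")
  expect_equal(env$states$label[st$state], "action:left-low:left")
  expect_equal(st$reward, 0)
  out <- env_step(env, st$state)
  expect_equal(env$states$label[out$state], "outcome:left-low:reward")
  expect_equal(out$reward, 1)
  expect_equal(env_step(env, out$state)$state, 22)
  # wrong action -> no-reward, -1
  bad <- env_step(env, env_step(env, 2, "right")$state)
  expect_equal(env$states$label[bad$state], "outcome:left-low:noreward")
  expect_equal(bad$reward, -1)
})

test_that("env_step enforces its action contract", {
  env <- make_environment("location")
  expect_error(env_step(env, 2), class = "ruleswitch_contract_error")
  expect_error(env_step(env, 1, "left"), class = "ruleswitch_contract_error")
  expect_error(env_step(env, 6, "left"), class = "ruleswitch_contract_error")
  expect_error(env_step(env, 22), class = "ruleswitch_contract_error")
})

test_that("probabilistic outcome flips occur at the configured rate", {
  env <- make_environment("location", probabilistic = TRUE, p_flip = 0.1)
  s <- rng_stream(42)
  n <- 10000
  flips <- replicate(n, {
    out <- env_step(env, 6, stream = s)  # action:left-low:left is correct
    out$reward < 0
  })
  phat <- mean(flips)
  ci <- qnorm(0.995) * sqrt(0.1 * 0.9 / n)
  expect_true(abs(phat - 0.1) < ci)
})

test_that("environment configs round-trip through YAML", {
  env <- make_environment("frequency", probabilistic = TRUE, p_flip = 0.1)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_env_config(env, path)
  env2 <- read_env_config(path)
  expect_equal(env2$rule, "frequency")
  expect_true(env2$probabilistic)
  expect_equal(env2$p_flip, 0.1)
})

test_that("trial tables round-trip through TSV", {
  sch <- generate_schedule(32, seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trial_table(sch, path)
  back <- read_trial_table(path)
  expect_equal(as.data.frame(back), as.data.frame(sch))
})

test_that("rng streams are independent and reproducible", {
  a <- rng_stream(7)
  b <- rng_stream(7)
  x1 <- a$runif(5)
  # interleaved draws from another stream do not perturb stream b
  rng_stream(99)$runif(100)
  x2 <- b$runif(5)
  expect_identical(x1, x2)
  expect_false(identical(rng_stream(1)$runif(3), rng_stream(2)$runif(3)))
})
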