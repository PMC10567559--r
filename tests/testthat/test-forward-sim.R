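test_that("undirected steps only ever add joins of existing members", {
  set.seed(21)
  p <- new_pool()
  p <- step_undirected(p)
  expect_equal(sort(p$members), c(1, 2))  # only possible join is 1+1
  for (i in 1:20) {
    before <- p$members
    p <- step_undirected(p)
    expect_true(all(before %in% p$members))           # pool never shrinks
    new <- setdiff(p$members, before)
    if (length(new))
      expect_true(new %in% outer(before, before, `+`))  # sum of two members
  }
})

test_that("pool size grows by at most one per step", {
  set.seed(22)
  p <- new_pool()
  for (s in 1:200) p <- step_undirected(p)
  expect_lte(length(p$members), 201L)
  expect_true(1 %in% p$members)
})

test_that("directed steps join the most recent creation", {
  set.seed(23)
  p <- new_pool()
  p <- step_directed(p)
  expect_equal(sort(p$members), c(1, 2))
  expect_equal(p$most_recent, 2)
  p2 <- step_directed(p)
  expect_true(all(setdiff(p2$members, p$members) %in% c(3, 4)))  # 2+1 or 2+2
  # doubling bound: after k novel creations max length <= 2^k
  set.seed(24)
  p <- new_pool()
  for (s in 1:40) p <- step_directed(p)
  expect_lte(max(p$members), 2^(length(p$members) - 1))
})

test_that("joint assembly space matches the doubling-chain example", {
  dag <- joint_assembly_space(c(1, 8))
  expect_equal(sort(dag$nodes$length), c(1, 2, 4, 8))
  expect_equal(sort(dag$nodes$length[dag$nodes$flag == "contingent"]), c(2, 4))
  expect_equal(exploration_ratio(dag), 0.5)
  expect_equal(nrow(dag$edges), 3L)  # one join edge per constructed node

  dag2 <- joint_assembly_space(c(1, 2, 4, 8))
  expect_equal(sort(dag2$nodes$length), c(1, 2, 4, 8))
  expect_equal(sum(dag2$nodes$flag == "contingent"), 0L)
  expect_equal(exploration_ratio(dag2), 1)

  expect_equal(exploration_ratio(joint_assembly_space(1)), 1)
  expect_equal(exploration_ratio(
    joint_assembly_space(c(1, 2^20), chain_limit = 2^16, allow_approx = TRUE)),
    2 / 21)
})

test_that("joint space node counts are bracketed by chain lengths", {
  set.seed(25)
  for (rep in 1:5) {
    obs <- unique(c(1, sample(2:200, 6)))
    dag <- joint_assembly_space(obs)
    chains <- sapply(obs[obs > 1], function(n) addition_chain_min(n)$index)
    expect_lte(nrow(dag$nodes), sum(chains) + 1)
    expect_gte(nrow(dag$nodes), max(chains) + 1)
  }
})

test_that("over-limit lengths are refused unless approximation is allowed", {
  expect_error(joint_assembly_space(c(1, 2^20), chain_limit = 2^16), "1048576")
  dag <- joint_assembly_space(c(1, 2^20), chain_limit = 2^16, allow_approx = TRUE)
  expect_true(dag$approximate)
})

test_that("experiments are reproducible and report both index measures", {
  cfg <- sim_config("undirected", steps = 60, runs = 3, seed = 31)
  r1 <- run_experiment(cfg)
  r2 <- run_experiment(cfg)
  expect_identical(r1$per_run, r2$per_run)
  expect_equal(r1$summary$seed, rep(31L, 5))
  # log2 consistency of the reported max assembly index
  expect_true(all(r1$per_run$max_assembly_index >=
                    floor(r1$per_run$max_assembly_index_log2)))
  expect_true(all(r1$per_run$max_assembly_index <=
                    pmax(2 * r1$per_run$max_assembly_index_log2, 1)))

  one <- run_experiment(sim_config("directed", steps = 1, runs = 1, seed = 1))
  expect_equal(one$per_run$pool_size, 2L)
  expect_equal(one$per_run$exploration_ratio, 1)
})

test_that("undirected draws support the without-replacement variant", {
  set.seed(27)
  p <- new_pool()
  for (i in 1:30) p <- step_undirected(p, replace = FALSE)
  expect_true(1 %in% p$members)
  expect_lte(length(p$members), 31L)
  # a singleton pool can only self-join even without replacement
  expect_equal(sort(step_undirected(new_pool(), replace = FALSE)$members), c(1, 2))
})
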