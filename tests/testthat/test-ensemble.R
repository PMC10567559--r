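test_that("assembly equation matches direct evaluation", {
  expect_equal(assembly_A(ensemble("x", 3, 5)), exp(3) * 4 / 5, tolerance = 1e-12)
  expect_equal(assembly_A(ensemble(c("x", "y"), c(1, 2), c(2, 3))),
               (exp(1) + 2 * exp(2)) / 5, tolerance = 1e-12)
})

test_that("A is zero exactly when every object is a singleton", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(1:8, 1)
    a <- sample(0:6, n, replace = TRUE)
    ens1 <- ensemble(paste0("o", 1:n), a, rep(1, n))
    expect_identical(assembly_A(ens1), 0)
    cn <- rep(1, n); cn[sample(n, 1)] <- 2
    expect_gt(assembly_A(ensemble(paste0("o", 1:n), a, cn)), 0)
  }
})

test_that("A is affine and increasing in any single copy number", {
  base_a <- c(1, 3, 2); base_n <- c(2, 4, 1)
  for (k in 1:3) {
    Avals <- sapply(0:3, function(d) {
      n <- base_n; n[k] <- n[k] + d
      assembly_A(ensemble(c("x", "y", "z"), base_a, n))
    })
    # A * N_T is affine in n_k with positive slope exp(a_k)
    NT <- sapply(0:3, function(d) sum(base_n) + d)
    lhs <- Avals * NT
    expect_equal(diff(lhs), rep(exp(base_a[k]), 3), tolerance = 1e-12)
    expect_true(all(diff(Avals * NT) > 0))
  }
})

test_that("A increases with any assembly index when copies repeat", {
  a <- c(1, 2); n <- c(3, 2)
  A0 <- assembly_A(ensemble(c("x", "y"), a, n))
  expect_gt(assembly_A(ensemble(c("x", "y"), a + c(1, 0), n)), A0)
  expect_gt(assembly_A(ensemble(c("x", "y"), a, n + c(1, 0))), A0)
})

test_that("A is invariant under id relabelling and validates input", {
  expect_equal(assembly_A(ensemble(c("a", "b"), c(1, 2), c(2, 3))),
               assembly_A(ensemble(c("b2", "a2"), c(1, 2), c(2, 3))))
  expect_error(ensemble(character(0), numeric(0), numeric(0)), "empty")
  expect_error(ensemble("x", -1, 2), "non-negative")
  expect_error(ensemble("x", 1, 0), "copy numbers")
  expect_warning(ensemble("x", 1, 2.7), "rounded down")
})

test_that("ensembles assemble from raw objects with multiplicity", {
  ens <- ensemble_from_objects(c("AA", "AA", "A"), kind = "string")
  expect_equal(ens$N, 2L)
  expect_equal(ens$N_T, 3)
  rec <- ens$records[order(ens$records$object_id), ]
  expect_equal(rec$assembly_index, c(0, 1))
  expect_equal(rec$copy_number, c(1, 2))

  ens2 <- ensemble_from_objects(rep(list(4), 5), kind = "homopolymer")
  expect_equal(ens2$N, 1L)
  expect_equal(ens2$N_T, 5)
  expect_equal(ens2$records$assembly_index, 2)  # addition chain 1,2,4

  expect_error(ensemble_from_objects(list(), kind = "string"), "empty")
  expect_error(ensemble_from_objects("AAAA", kind = "string",
                                     index_fn = function(o) stop("boom")),
               "AAAA")
})
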