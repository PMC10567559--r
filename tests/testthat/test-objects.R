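test_that("canonicalization is idempotent and rejects degenerate input", {
  s <- canonicalize("ABBA", "string")
  expect_s3_class(s, "assembly_object")
  expect_equal(s$size, 4L)
  expect_identical(canonicalize(s), s)
  h <- canonicalize(8, "homopolymer")
  expect_equal(h$size, 8)
  expect_error(canonicalize("", "string"), "string")
  expect_error(canonicalize(0, "homopolymer"), "homopolymer")
  expect_error(canonicalize(2.5, "homopolymer"), "homopolymer")
})

test_that("join concatenates strings, adds lengths, and rejects kind mismatches", {
  expect_equal(join(canonicalize("AB", "string"), canonicalize("RA", "string"))$payload,
               "ABRA")
  expect_equal(join(canonicalize("A", "string"), canonicalize("A", "string"))$payload,
               "AA")
  expect_equal(join(canonicalize(2, "homopolymer"), canonicalize(3, "homopolymer"))$size, 5)
  expect_error(join(canonicalize("A", "string"), canonicalize(2, "homopolymer")),
               "different kinds")
})

test_that("assembly index bounds bracket the true index", {
  expect_equal(assembly_index_bounds(canonicalize(8, "homopolymer")),
               c(lower = 3L, upper = 7L))
  expect_equal(assembly_index_bounds(canonicalize("AB", "string")),
               c(lower = 1L, upper = 1L))
  expect_equal(assembly_index_bounds(canonicalize(1000, "homopolymer")),
               c(lower = 10L, upper = 999L))
  for (n in c(2, 5, 17, 40)) {
    b <- assembly_index_bounds(canonicalize(n, "homopolymer"))
    idx <- addition_chain_min(n)$index
    expect_gte(idx, b[["lower"]])
    expect_lte(idx, b[["upper"]])
  }
})

test_that("index of a join is at most index(x) + index(y) + 1", {
  set.seed(41)
  for (rep in 1:20) {
    x <- paste(sample(c("A", "B"), sample(2:6, 1), replace = TRUE), collapse = "")
    y <- paste(sample(c("A", "B"), sample(2:6, 1), replace = TRUE), collapse = "")
    ix <- assembly_index_string(x)$index
    iy <- assembly_index_string(y)$index
    ixy <- assembly_index_string(paste0(x, y))$index
    expect_lte(ixy, ix + iy + 1)
  }
})

test_that("duplication costs at most one extra step", {
  set.seed(42)
  for (rep in 1:15) {
    s <- paste(sample(c("A", "B"), sample(2:8, 1), replace = TRUE), collapse = "")
    expect_lte(assembly_index_string(paste0(s, s))$index,
               assembly_index_string(s)$index + 1)
  }
})

test_that("returned pathways replay to the target", {
  for (s in c("AAAA", "ABRACADABRA", "ABABBA")) {
    r <- assembly_index_string(s)
    rebuilt <- replay_pathway(r$pathway)
    expect_equal(rebuilt$payload, s)
    expect_equal(r$pathway$length, r$index)
  }
  r <- assembly_index(canonicalize(15, "homopolymer"))
  expect_equal(replay_pathway(r$pathway)$payload, 15)
})
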