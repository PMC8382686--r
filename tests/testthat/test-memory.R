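test_that("encoding merges identical observations and separates distinct ones", {
  st <- memory_store()
  st <- encode_instance(st, 1, "high|1", 0.75, round = 3)
  expect_length(st$chunks, 1)
  expect_equal(st$chunks[[1]]$encodings, 3L)

  st <- encode_instance(st, 1, "high|1", 0.75, round = 7)
  expect_length(st$chunks, 1)
  expect_equal(st$chunks[[1]]$encodings, c(3L, 7L))

  st <- encode_instance(st, 1, "high|1", 0.25, round = 9)
  expect_length(st$chunks, 2)

  # different counterparts may encode within the same round
  st <- encode_instance(st, 2, "high|1", 0.25, round = 9)
  expect_length(st$chunks, 3)

  expect_error(encode_instance(st, 1, "high|1", 0.5, round = 5), "clock error")
})

test_that("activation follows the base-level learning equation", {
  # one encoding 1 round ago: ln(1) = 0
  expect_equal(activation(list(encodings = 4), now = 5, d = 0.5), 0)
  # encodings 1 and 4 rounds ago: ln(1 + 4^-0.5) = ln(1.5)
  expect_equal(activation(list(encodings = c(1, 4)), now = 5, d = 0.5),
               log(1.5), tolerance = 1e-9)
  expect_error(activation(list(encodings = integer()), now = 5), "retrieval")
  expect_error(activation(list(encodings = c(1, 4)), now = 4), "after")
})

test_that("activation decays with time and grows with re-encoding", {
  ch <- list(encodings = c(2, 5, 9))
  a10 <- activation(ch, 10)
  a20 <- activation(ch, 20)
  expect_lt(a20, a10)  # monotone decay
  # frequency: re-encoding strictly increases activation at any later time
  ch2 <- list(encodings = c(2, 5, 9, 12))
  expect_gt(activation(ch2, 20), activation(ch, 20))
  # recency: equal counts, later encodings win
  expect_gt(activation(list(encodings = c(5, 9)), 10),
            activation(list(encodings = c(1, 3)), 10))
})

test_that("blending is an activation-weighted convex combination", {
  st <- memory_store(tau = 1)
  st <- encode_instance(st, 1, "ctx", 0.75, 1)
  expect_equal(blended_prediction(st, 1, "ctx", now = 5), 0.75)

  # two chunks with equal activation, values 0.5 and 1.0 -> 0.75
  st3 <- memory_store(tau = 1)
  st3 <- encode_instance(st3, 1, "a", 0.5, 2)
  st3 <- encode_instance(st3, 1, "a", 1.0, 2)  # same round, different values
  expect_equal(blended_prediction(st3, 1, "a", now = 4), 0.75)

  # hand-computed Boltzmann weights: activations 0 and ln 3 with tau = 1
  # give weights 1/(1+3) and 3/(1+3); values 0 and 1 -> 0.75
  st4 <- memory_store(tau = 1)
  st4$chunks <- list(
    list(counterpart = 1, context = "c", value = 0, encodings = 9L),
    list(counterpart = 1, context = "c", value = 1, encodings = c(1L, 8L, 9L))
  )
  # choose 'now' so activations are exactly 0 and ln 3? use direct weights:
  a <- vapply(st4$chunks, activation, numeric(1), now = 10, d = 0.5)
  w <- exp(a - max(a))
  expect_equal(blended_prediction(st4, 1, "c", now = 10),
               sum(w * c(0, 1)) / sum(w), tolerance = 1e-9)
})

test_that("blending falls back to all counterpart chunks and signals no experience", {
  st <- memory_store()
  expect_identical(blended_prediction(st, 1, "ctx", 5), NA_real_)
  st <- encode_instance(st, 1, "other-ctx", 0.6, 1)
  # context mismatch: falls back to the counterpart's chunks
  expect_equal(blended_prediction(st, 1, "ctx", 5), 0.6)
  expect_identical(blended_prediction(st, 2, "ctx", 5), NA_real_)
})

test_that("blended values always lie within the candidate range", {
  withr::with_seed(5, {
    for (rep in 1:20) {
      st <- memory_store(tau = runif(1, 0.1, 2))
      vals <- round(runif(8), 2)
      for (i in seq_along(vals)) {
        st <- encode_instance(st, 1, sample(c("a", "b"), 1), vals[i], i)
      }
      p <- blended_prediction(st, 1, "a", now = 20)
      all_vals <- vapply(st$chunks, `[[`, numeric(1), "value")
      expect_gte(p, min(all_vals))
      expect_lte(p, max(all_vals))
    }
  })
})

test_that("memory stores round-trip through JSONL", {
  st <- memory_store(d = 0.4, tau = 0.3)
  st <- encode_instance(st, 1, "high|1", 0.75, 2)
  st <- encode_instance(st, 1, "high|1", 0.75, 5)
  st <- encode_instance(st, 2, "low|4+", 0.25, 6)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_memory(st, path)
  st2 <- read_memory(path)
  expect_equal(st2$d, 0.4)
  expect_equal(st2$tau, 0.3)
  expect_equal(length(st2$chunks), 2)
  expect_equal(blended_prediction(st2, 1, "high|1", 10),
               blended_prediction(st, 1, "high|1", 10))
})
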