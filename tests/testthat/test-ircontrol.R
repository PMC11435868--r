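# independent NEC timing oracle: build expected tick list directly from the
# protocol constants and the payload's bit string
oracle_nec <- function(payload) {
  bits <- integer(32)
  x <- payload
  for (i in 32:1) {
    bits[i] <- x %% 2
    x <- x %/% 2
  }
  ticks <- c(9000, 4500)
  for (b in bits) {
    ticks <- c(ticks, 562.5, if (b == 1) 1687.5 else 562.5)
  }
  c(ticks, 562.5)
}

test_that("NEC frames have 67 ticks with the protocol's spacings", {
  t0 <- nec_encode(0)
  expect_length(t0, 67L)
  expect_equal(t0[1:2], c(9000, 4500))
  expect_true(all(t0[seq(4, 66, by = 2)] == 562.5))   # all-zero spaces
  t1 <- nec_encode(2^32 - 1)
  expect_length(t1, 67L)
  expect_true(all(t1[seq(4, 66, by = 2)] == 1687.5))  # all-one spaces
  expect_equal(nec_encode(0xA55A00FF), oracle_nec(0xA55A00FF))
  expect_error(nec_encode(-1), "payload")
  expect_error(nec_encode(2^32), "payload")
  expect_error(nec_encode(1.5), "payload")
})

test_that("encode -> decode is the identity over random payloads", {
  set.seed(55)
  payloads <- floor(runif(300, 0, 2^32))
  for (v in payloads) {
    expect_identical(nec_decode(nec_encode(v)), v)
  }
  expect_identical(nec_decode(nec_encode(0xA55A00FF)), 0xA55A00FF)
})

test_that("decoding tolerates timing jitter up to the tolerance and not beyond", {
  set.seed(56)
  v <- 0x20DF10EF
  ticks <- nec_encode(v)
  for (rep in 1:20) {
    jitter <- runif(67, -0.10, 0.10)
    expect_identical(nec_decode(ticks * (1 + jitter)), v)
  }
  # beyond-tolerance distortion must fail monotonically: once the frame is
  # rejected at some magnitude, larger magnitudes also reject
  magnitudes <- seq(0, 0.9, by = 0.05)
  ok <- vapply(magnitudes, function(m) {
    !is.null(nec_decode(ticks * (1 + m)))
  }, logical(1))
  expect_true(ok[1])
  expect_false(ok[length(ok)])
  expect_true(all(diff(as.integer(ok)) <= 0))
})

test_that("non-NEC tick sequences fall through to raw classification", {
  set.seed(57)
  random_ticks <- runif(40, 100, 3000)
  expect_null(nec_decode(c(random_ticks, runif(27, 100, 3000))))
  code <- ir_classify(random_ticks)
  expect_identical(code$protocol, "UNKNOWN_RAW")
  expect_equal(code$ticks_us, random_ticks)
  nec <- ir_classify(nec_encode(42), id = "tv_power")
  expect_identical(nec$protocol, "NEC")
  expect_identical(nec$payload, 42)
})

test_that("unknown-protocol verification accepts iff two recordings agree", {
  set.seed(58)
  true_ticks <- runif(30, 200, 2500)
  expect_false(is.null(verify_unknown(list(true_ticks, true_ticks,
                                           true_ticks))))
  three_different <- list(runif(30, 200, 2500), runif(30, 200, 2500),
                          runif(28, 200, 2500))
  expect_null(verify_unknown(three_different))
  scrambled <- runif(30, 200, 2500)
  acc <- verify_unknown(list(true_ticks, scrambled,
                             true_ticks * (1 + runif(30, -0.05, 0.05))))
  expect_false(is.null(acc))
  expect_equal(acc$ticks_us, true_ticks, tolerance = 0.05)
  expect_error(verify_unknown(list(true_ticks)), "at least 2")
})

test_that("code invariants enforce protocol bit widths and raw tick shape", {
  expect_error(ir_code("x", "NEC", payload = 2^32), "\\[0, 2\\^32\\)")
  expect_error(ir_code("x", "SONY12", payload = 2^12), "2\\^12")
  expect_silent(ir_code("x", "SONY20", payload = 2^20 - 1))
  expect_error(ir_code("x", "RC5", payload = -1), "2\\^14")
  expect_error(ir_code("x", "UNKNOWN_RAW", ticks_us = c(100)), ">= 2")
  expect_error(ir_code("x", "UNKNOWN_RAW", ticks_us = c(100, -5)), ">= 2")
})

test_that("gesture maps validate references and allow many-to-many links", {
  store <- list(tv = ir_code("tv", "NEC", payload = 1),
                amp = ir_code("amp", "NEC", payload = 2))
  map <- gesture_map(list(Fist = c("tv", "amp"), Pinch = "tv"), store)
  expect_s3_class(map, "gesture_map")
  expect_error(gesture_map(list(Fist = "nope"), store), "unknown code id")
})

test_that("a state change transmits every mapped code exactly once", {
  store <- list(tv = ir_code("tv", "NEC", payload = 0x10EF),
                amp = ir_code("amp", "NEC", payload = 0x20EF))
  map <- gesture_map(list(Fist = c("tv", "amp")), store)
  bus <- ir_bus()
  labels <- c(rep("Fist", 20))
  log <- run_decision_stream(labels, queue = prediction_queue())
  for (i in which(log$emit)) actuate(map, "Fist", bus, timestamp = i)
  tx <- bus_log(bus)
  expect_equal(nrow(tx), 2L)                 # one change, two devices
  expect_setequal(tx$code_id, c("tv", "amp"))
  expect_warning(actuate(map, "Wave In", bus), "not mapped")
  expect_equal(nrow(bus_log(bus)), 2L)       # unmapped gesture: no-op
})

test_that("index_increment selects successive codes as boundaries are crossed", {
  store <- list(a = ir_code("a", "NEC", payload = 1),
                b = ir_code("b", "NEC", payload = 2),
                c = ir_code("c", "NEC", payload = 3))
  map <- gesture_map(list(Fist = c("a", "b", "c")), store)
  bus <- ir_bus()
  state <- spatial_state(mode = "index_increment", step = 10)
  r <- spatial_update(state, "Fist", c(yaw = 0, pitch = 0, roll = 0))
  for (yaw in c(12, 25)) {                   # crosses step 1 then step 2
    r <- spatial_update(r$state, "Fist", c(yaw = yaw, pitch = 0, roll = 0))
    actuate(map, "Fist", bus, output = r$output)
  }
  tx <- bus_log(bus)
  expect_equal(tx$code_id, c("a", "b"))
  expect_equal(tx$note, c("index_increment:1", "index_increment:2"))
})

test_that("repeat_rate mode re-transmits at the implied rate over the hold", {
  store <- list(vol = ir_code("vol", "NEC", payload = 7))
  map <- gesture_map(list(Fist = "vol"), store)
  bus <- ir_bus()
  state <- spatial_state(mode = "repeat_rate", rate_scale = 0.1)
  r <- spatial_update(state, "Fist", c(yaw = 0, pitch = 0, roll = 0))
  r <- spatial_update(r$state, "Fist", c(yaw = 50, pitch = 0, roll = 0))
  # output 50 deg * 0.1 = 5 codes/s over a 2 s hold -> 1 + 10 transmissions
  n <- actuate(map, "Fist", bus, output = r$output, hold_s = 2)
  expect_equal(n, 11L)
  expect_equal(nrow(bus_log(bus)), 11L)
})

test_that("IR stores and gesture maps round-trip through JSON and YAML", {
  store <- list(
    tv = ir_code("tv", "NEC", payload = 2^32 - 1,
                 repeat_behaviour = "dedicated_repeat_symbol"),
    mystery = ir_code("mystery", "UNKNOWN_RAW",
                      ticks_us = c(1000.5, 500.25, 1000.5, 1500.75)),
    sony = ir_code("sony", "SONY12", payload = 0x5A5)
  )
  dir <- withr::local_tempdir()
  sp <- file.path(dir, "store.json")
  write_ir_store(store, sp)
  back <- read_ir_store(sp)
  expect_identical(names(back), names(store))
  expect_identical(back$tv$payload, 2^32 - 1)
  expect_identical(back$tv$repeat_behaviour, "dedicated_repeat_symbol")
  expect_equal(back$mystery$ticks_us, store$mystery$ticks_us)
  expect_identical(back$sony$protocol, "SONY12")

  map <- gesture_map(list(Fist = c("tv", "mystery"), Pinch = "tv"), store)
  mp <- file.path(dir, "map.yaml")
  write_gesture_map(map, mp)
  map2 <- read_gesture_map(mp, back)
  expect_identical(map2$mapping, list(Fist = c("tv", "mystery"),
                                      Pinch = "tv"))
})

test_that("the virtual bus mirrors transmissions to a JSON-lines file", {
  store <- list(tv = ir_code("tv", "NEC", payload = 1))
  map <- gesture_map(list(Fist = "tv"), store)
  path <- withr::local_tempfile(fileext = ".jsonl")
  bus <- ir_bus(path = path)
  actuate(map, "Fist", bus, timestamp = 1.5)
  lines <- readLines(path)
  expect_length(lines, 1L)
  entry <- jsonlite::fromJSON(lines[1])
  expect_equal(entry$code_id, "tv")
  expect_equal(entry$timestamp, 1.5)
})
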