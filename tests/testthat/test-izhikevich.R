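test_that("catalog has twenty behaviors with consistent stimulus windows", {
  cat20 <- behavior_catalog()
  expect_length(cat20, 20)
  expect_identical(names(cat20), letters[1:20])
  for (sp in cat20) {
    seg <- sp$stimulus$segments
    if (nrow(seg)) {
      expect_gte(min(seg$start), 0)
      expect_lte(max(seg$end), sp$n_steps * sp$dt + 1e-9)
    }
  }
})

test_that("scale shrinks every sample count proportionally", {
  full <- behavior_catalog()
  small <- behavior_catalog(scale = 0.1)
  for (nm in names(full))
    expect_equal(small[[nm]]$n_steps, round(full[[nm]]$n_steps / 10))
  expect_error(behavior_catalog(names = "z"), "unknown behavior")
})

test_that("the rest state of the quadratic nullcline is a fixed point", {
  tr <- simulate_behavior(toy_spec(I = 0, n = 400))
  expect_true(all(tr$v == -70))
  expect_true(all(tr$u == -14))
  expect_length(tr$spike_times, 0)
})

test_that("a single Euler step matches the hand-evaluated update", {
  # dv = 0.04*4900 - 350 + 140 + 14 + 10 = 10, du = 0.02*(-14 + 14) = 0
  tr <- simulate_behavior(toy_spec(I = 10, dt = 1, n = 2))
  expect_equal(tr$v[2], -60)
  expect_equal(tr$u[2], -14)
})

test_that("tonic spiking fires repeatedly and phasic spiking fires once", {
  cat2 <- behavior_catalog(scale = 0.1, names = c("a", "b"))
  expect_gt(length(simulate_behavior(cat2$a)$spike_times), 1)
  expect_length(simulate_behavior(cat2$b)$spike_times, 1)
})

test_that("simulation is deterministic and clamps spikes at 30 mV", {
  sp <- behavior_catalog(scale = 0.1, names = "c")[[1]]
  tr1 <- simulate_behavior(sp)
  tr2 <- simulate_behavior(sp)
  expect_identical(tr1, tr2)
  expect_lte(max(tr1$v), 30)
  # every recorded spike time lies on a clamped sample
  idx <- round(tr1$spike_times / tr1$dt) + 1
  expect_true(all(tr1$v[idx] == 30))
})

test_that("spike-train extraction is a lossless grid round trip", {
  tr <- list(t = (0:999) * 0.5, v = rep(-65, 1000), u = rep(-13, 1000),
             I = rep(0, 1000), spike_times = c(49.5, 149.5), dt = 0.5,
             name = "toy")
  class(tr) <- "neuron_trace"
  st <- extract_spike_train(tr)
  expect_equal(st$r, 2 / 1000)
  expect_equal(which(st$indicator == 1), c(100, 300))
  expect_equal(st$times, c(49.5, 149.5))
  st2 <- spike_train(st$times, 1000, 0.5)
  expect_identical(st$indicator, st2$indicator)
})

test_that("behavior classification splits one- and multiple-spike traces", {
  mk <- function(k) {
    tr <- list(t = 0:99, v = rep(-65, 100), u = rep(0, 100),
               I = rep(0, 100), spike_times = seq_len(k) * 10, dt = 1,
               name = "toy")
    class(tr) <- "neuron_trace"
    tr
  }
  expect_identical(classify_behavior(mk(1)), "one-spike")
  expect_identical(classify_behavior(mk(7)), "multiple-spike")
  expect_warning(cls <- classify_behavior(mk(0)), "degenerate")
  expect_true(is.na(cls))
})

test_that("overflow without reset is reported with behavior and step", {
  # u frozen far below the nullcline makes v diverge before reaching reset
  sp <- behavior_spec("boom", a = 0, b = 0, c = -65, d = 0, v0 = 40,
                      u0 = 1e300, dt = 1e3, n_steps = 50,
                      stimulus = stimulus_protocol(baseline = 0))
  expect_error(simulate_behavior(sp), "overflow in behavior 'boom'")
})

test_that("halving dt preserves the firing class of every behavior", {
  c1 <- vapply(behavior_catalog(dt = 0.25, scale = 0.25),
               function(sp) length(simulate_behavior(sp)$spike_times),
               integer(1))
  c2 <- vapply(behavior_catalog(dt = 0.125, scale = 0.25),
               function(sp) length(simulate_behavior(sp)$spike_times),
               integer(1))
  expect_identical(c1 == 1, c2 == 1)
  expect_identical(c1 > 1, c2 > 1)
  # one-spike behaviors are exactly dt-stable
  expect_identical(c1[c1 == 1], c2[c1 == 1])
})

test_that("trace and catalog files round-trip through text formats", {
  sp <- behavior_catalog(scale = 0.02, names = "e")[[1]]
  tr <- simulate_behavior(sp)
  f <- tempfile(fileext = ".tsv")
  write_trace(tr, f)
  tr2 <- read_trace(f)
  expect_equal(tr2$v, tr$v, tolerance = 1e-12)
  expect_equal(tr2$spike_times, tr$spike_times)
  expect_equal(tr2$dt, tr$dt)

  y <- tempfile(fileext = ".yaml")
  write_catalog(behavior_catalog(scale = 0.02, names = c("a", "k")), y)
  cat2 <- read_catalog(y)
  expect_identical(names(cat2), c("a", "k"))
  tr_a <- simulate_behavior(cat2$a)
  tr_a0 <- simulate_behavior(behavior_catalog(scale = 0.02, names = "a")[[1]])
  expect_equal(tr_a$v, tr_a0$v)
})
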