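test_that("sphere-constrained ascent solves the linear unit in closed form", {
  set.seed(3)
  w <- rnorm(16)
  rho <- 2.5
  res <- maximize_unit(function(x) sum(w * x), function(x) w, 16,
                       am_config(norm_budget = rho, seed = 5L))
  expect_equal(res$x, rho * w / sqrt(sum(w^2)), tolerance = 1e-6)
  expect_equal(res$value, rho * sqrt(sum(w^2)), tolerance = 1e-9)

  # degenerate zero unit terminates immediately
  res0 <- maximize_unit(function(x) 0, function(x) rep(0, 4), 4, am_config())
  expect_identical(res0$iterations, 1L)

  # non-finite objective is rejected
  expect_error(
    maximize_unit(function(x) NaN, function(x) rep(1, 2), 2, am_config()),
    "non-finite"
  )
})

test_that("ascent on a toy ReLU net matches dense sphere search within 1%", {
  set.seed(7)
  W1 <- matrix(rnorm(3 * 4), 3)
  b1 <- rnorm(3)
  w2 <- rnorm(3)
  f <- function(x) sum(w2 * pmax(as.vector(W1 %*% x) + b1, 0))
  grad <- function(x) {
    z <- as.vector(W1 %*% x) + b1
    as.vector(t(W1) %*% (w2 * (z > 0)))
  }
  res <- maximize_unit(f, grad, 4, am_config(seed = 11L, max_iter = 2000L))
  set.seed(99)
  draws <- matrix(rnorm(1e5 * 4), ncol = 4)
  draws <- draws / sqrt(rowSums(draws^2))
  brute <- max(pmax(sweep(tcrossprod(draws, W1), 2, b1, "+"), 0) %*% w2)
  expect_gt(res$value, 0)
  expect_lt(abs(res$value - brute) / abs(brute), 0.01)
})

test_that("per-channel activation maps have the input-layer geometry", {
  m <- build_model(mini_model_config(seed = 3L), mini_input_shape)
  am <- suppressWarnings(
    activation_maximization(m, am_config(seed = 2L, max_iter = 200L))
  )
  expect_length(am$per_channel, 4L)
  expect_true(all(vapply(am$per_channel, function(x) all(dim(x) == c(8, 8)),
                         logical(1))))
  expect_true(all(vapply(am$per_channel,
                         function(x) abs(sqrt(sum(x^2)) - 1) < 1e-6,
                         logical(1))))
  # achieved activation never below the zero-input response of the same unit
  npos <- (8 - 3 + 1)^2
  h0 <- npos * sum(pmax(m$conv[[1]]$b, 0))
  expect_true(all(am$achieved_activation >= h0 - 1e-9))
  # deterministic given config
  am2 <- suppressWarnings(
    activation_maximization(m, am_config(seed = 2L, max_iter = 200L))
  )
  expect_identical(am$per_channel, am2$per_channel)
})

test_that("ap_cluster honours its degenerate and two-cluster contracts", {
  one <- ap_cluster(3.7)
  expect_identical(one$exemplars, 1L)
  expect_identical(one$labels, 1L)

  same <- ap_cluster(rep(2.5, 12))
  expect_identical(unique(same$labels), 1L)

  r <- ap_cluster(c(1.0, 1.1, 1.2, 8.0, 8.1, 8.2), damping = 0.5)
  expect_length(r$exemplars, 2L)
  expect_equal(canonical_partition(r$labels), c(1L, 1L, 1L, 2L, 2L, 2L))
})

test_that("partitions follow the center/radius/boundary arithmetic", {
  ps <- build_partitions(c(1.0, 1.2, 3.0, 3.4), c(1, 1, 2, 2))
  expect_equal(vapply(ps$partitions, function(p) p$center, numeric(1)),
               c(1.1, 3.2))
  expect_equal(vapply(ps$partitions, function(p) p$radius, numeric(1)),
               c(0.1, 0.2))
  # boundary at the midpoint of the inter-partition gap [1.2, 3.0]
  expect_equal(ps$boundaries, 2.1)
  expect_equal(sum(ps$probabilities), 1)

  single <- build_partitions(rnorm(10), rep(1, 10))
  expect_length(single$boundaries, 0L)
  expect_equal(single$probabilities, 1)

  # overlapping partitions are merged with a warning
  expect_warning(
    merged <- build_partitions(c(1, 3, 2, 4), c(1, 1, 2, 2)),
    "overlap"
  )
  expect_length(merged$partitions, 1L)
  expect_equal(merged$probabilities, 1)

  set.seed(4)
  for (i in 1:10) {
    v <- rnorm(50)
    ps <- suppressWarnings(build_partitions(v, sample(1:3, 50, TRUE)))
    expect_equal(sum(ps$probabilities), 1)
    if (length(ps$boundaries) > 0) {
      expect_true(all(diff(ps$boundaries) > 0))
    }
  }
})

test_that("partition entropy equals known-membership entropy when separated", {
  set.seed(1)
  expect_equal(partition_entropy(c(rnorm(512, 0, 0.05), rnorm(512, 10, 0.05))),
               1.0, tolerance = 1e-9)
  expect_equal(partition_entropy(c(rnorm(768, 0, 0.05), rnorm(256, 10, 0.05))),
               shannon_bits(c(0.75, 0.25)), tolerance = 1e-9)
  expect_equal(partition_entropy(rep(3, 200)), 0)
})

test_that("partition entropy is affine-invariant and bounded by log2(k)", {
  set.seed(2)
  x <- c(rnorm(120, 0, 0.1), rnorm(60, 6, 0.1), rnorm(20, 15, 0.1))
  h <- partition_entropy(x)
  expect_equal(partition_entropy(3.7 * x - 11), h, tolerance = 1e-9)
  expect_equal(partition_entropy(-x), h, tolerance = 1e-9)
  expect_lte(h, log2(3))
  expect_equal(h, shannon_bits(c(120, 60, 20) / 200), tolerance = 1e-9)
})

test_that("uniform-bin entropy matches direct histogram computation", {
  expect_equal(uniform_bin_entropy(rep(1, 50), 10L), 0)
  # k values spread one per bin -> log2(k)
  expect_equal(uniform_bin_entropy(seq(0, 1, length.out = 8), 8L), 3)
  set.seed(5)
  x <- c(rnorm(768, 0, 0.5), rnorm(256, 10, 0.5))
  counts <- graphics::hist(x, breaks = seq(min(x), max(x), length.out = 7),
                           plot = FALSE)$counts
  expect_equal(uniform_bin_entropy(x, 6L), shannon_bits(counts / sum(counts)))
  # equal-width bins slice through the two modes, so the fixed-bin baseline
  # overstates the entropy relative to the adaptive partition (the
  # motivating contrast between the two strategies)
  expect_equal(partition_entropy(x), shannon_bits(c(0.75, 0.25)),
               tolerance = 1e-9)
  expect_gt(uniform_bin_entropy(x, 6L), partition_entropy(x) + 0.2)
})

test_that("channel entropies are per-channel and zero for constant maps", {
  am <- structure(
    list(
      per_channel = list(Fp1 = matrix(0, 8, 8), Fp2 = matrix(1.5, 8, 8)),
      achieved_activation = c(Fp1 = 0, Fp2 = 0),
      iterations = c(1L, 1L), channel_labels = c("Fp1", "Fp2")
    ),
    class = "activation_map"
  )
  ent <- channel_entropies(am)
  expect_equal(unname(ent), c(0, 0))
  expect_named(ent, c("Fp1", "Fp2"))

  # a bimodal channel scores 1 bit regardless of the other channels
  set.seed(6)
  bim <- matrix(c(rnorm(32, 0, 0.01), rnorm(32, 5, 0.01)), 8, 8)
  am$per_channel$Fp2 <- bim
  expect_equal(unname(channel_entropies(am)), c(0, 1), tolerance = 1e-9)
})

test_that("region means follow the five-region 10-20 map", {
  rm <- default_region_map()
  expect_identical(rm$frontal, c("Fp1", "Fp2", "F3", "F4"))
  expect_length(rm, 5L)

  ent <- stats::setNames(rep(0.4, 20), default_montage())
  means <- suppressWarnings(region_means(ent))
  expect_equal(unname(means), rep(0.4, 5))

  ent2 <- ent
  ent2[c("Fp1", "Fp2")] <- 1
  ent2[c("F3", "F4")] <- 0
  m2 <- region_means(ent2)
  expect_equal(unname(m2["frontal"]), 0.5)

  # missing electrode excluded with a warning; empty region flagged NA
  expect_warning(region_means(ent[1:4], list(frontal = c("Fp1", "Zz9"))),
                 "Zz9")
  expect_warning(
    expect_warning(
      m3 <- region_means(ent[1:4], list(ghost = c("Qq1", "Qq2"))),
      "no member"
    ),
    "Qq1"
  )
  expect_true(is.na(m3["ghost"]))
})

test_that("topography rendering writes deterministic images", {
  ent <- stats::setNames(seq(0, 1, length.out = 20), default_montage())
  topo <- entropy_topography(ent)
  p1 <- tempfile(fileext = ".png")
  p2 <- tempfile(fileext = ".png")
  render_topography(topo, "channel", p1)
  render_topography(topo, "channel", p2)
  expect_true(file.exists(p1))
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  p3 <- tempfile(fileext = ".png")
  render_topography(topo, "region", p3)
  expect_true(file.exists(p3))
  bad <- topo
  names(bad$per_channel_entropy)[1] <- "NotAnElectrode"
  expect_error(render_topography(bad, "channel", tempfile(fileext = ".png")),
               "NotAnElectrode")
  unlink(c(p1, p2, p3))
})
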