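# Genome initialisation, mutation and serialisation.

test_that("initialisation builds the declared structure deterministically", {
  g <- init_genome(n_features = 6, n_wavelons = 4,
                   wavelet_set = c("morlet", "mexican_hat", "gauss1", "haar"),
                   seed = 11)
  expect_s3_class(g, "wnn_genome")
  expect_identical(dim(g$switch), c(6L, 4L))
  for (field in c("feat", "w", "alpha", "beta", "rotation")) {
    expect_identical(dim(g[[field]]), c(6L, 4L), info = field)
  }
  expect_length(g$psi, 4)
  expect_length(g$a, 6)
  g2 <- init_genome(6, 4, wavelet_set = c("morlet", "mexican_hat", "gauss1", "haar"),
                    seed = 11)
  expect_identical(g, g2)
  expect_error(init_genome(6, 4, wavelet_set = character(0)),
               "at least one wavelet")
})

test_that("initialised genes stay inside their declared ranges", {
  lo <- list(w = Inf, alpha = Inf, rotation = Inf, wt = Inf, a = Inf, theta = Inf)
  hi <- list(w = -Inf, alpha = -Inf, rotation = -Inf, wt = -Inf, a = -Inf, theta = -Inf)
  set.seed(5)
  for (i in 1:500) {
    g <- init_genome(3, 2, wavelet_set = c("morlet", "haar"))
    expect_true(all(g$feat >= 1 & g$feat <= 3))
    expect_true(all(g$switch %in% 0:1) && all(g$ot %in% 0:1))
    expect_true(all(g$psi %in% 1:2))
    for (f in names(lo)) {
      lo[[f]] <- min(lo[[f]], g[[f]])
      hi[[f]] <- max(hi[[f]], g[[f]])
    }
  }
  expect_gte(lo$alpha, 0)
  expect_lte(hi$alpha, 1)
  for (f in c("w", "rotation", "wt", "a", "theta")) {
    expect_gte(lo[[f]], -1)
    expect_lte(hi[[f]], 1)
  }
  # the uniform draws actually explore the ranges
  expect_lt(lo$w, -0.9)
  expect_gt(hi$w, 0.9)
  expect_lt(lo$alpha, 0.05)
  expect_gt(hi$alpha, 0.95)
})

test_that("mutation at rate 0 is the identity and does not touch the parent", {
  g <- init_genome(4, 3, seed = 2)
  snapshot <- unclass(g)
  m <- mutate_genome(g, rate = 0)
  expect_identical(m, g)
  m2 <- mutate_genome(g, rate = 1)
  expect_identical(unclass(g), snapshot)  # parent unmodified
})

test_that("mutation at rate 1 inverts every binary gene", {
  g <- blank_genome(3, 2)
  g$switch[] <- 1L
  g$ot[] <- 1L
  m <- mutate_genome(g, rate = 1)
  expect_true(all(m$switch == 0L))
  expect_true(all(m$ot == 0L))
})

test_that("categorical mutation resamples among the other list members", {
  set.seed(3)
  g <- init_genome(2, 3, wavelet_set = c("morlet", "mexican_hat"), seed = 3)
  for (i in 1:10) {
    m <- mutate_genome(g, rate = 1)
    # with 2-member lists the only legal move is the other member
    expect_identical(m$feat, 3L - g$feat)
    expect_identical(m$psi, 3L - g$psi)
  }
})

test_that("bounded genes survive arbitrary mutation sequences in range", {
  set.seed(8)
  g <- init_genome(5, 4, wavelet_set = c("morlet", "mexican_hat", "gauss1"))
  for (i in 1:60) {
    g <- mutate_genome(g, rate = 0.5, magnitude = 0.9)
    expect_silent(ewnne:::validate_genome(g))
  }
})

test_that("mutation hits on average rate * G genes", {
  # interior gene values so clamping cannot silently undo a perturbation,
  # and a 2-member wavelet set so every categorical gene has a legal move
  g <- blank_genome(3, 2, wavelet_set = c("mexican_hat", "morlet"))
  g$w[] <- 0.5
  g$alpha[] <- 0.5
  g$beta[] <- 0.3
  g$rotation[] <- -0.4
  g$wt[] <- 0.5
  g$a[] <- 0.2
  g$theta <- 0.1
  G <- 6 * 3 * 2 + 3 * 2 + 3 + 1  # slot genes + per-wavelon genes + a + theta
  rate <- 0.3
  set.seed(14)
  reps <- 300
  changed <- replicate(reps, {
    m <- mutate_genome(g, rate = rate, magnitude = 0.2)
    sum(vapply(c("feat", "switch", "w", "alpha", "beta", "rotation",
                 "psi", "wt", "ot", "a", "theta"),
               function(f) sum(m[[f]] != g[[f]]), numeric(1)))
  })
  se <- sqrt(G * rate * (1 - rate) / reps)
  expect_lt(abs(mean(changed) - rate * G), 3 * se)
})

test_that("serialisation round-trips any genome exactly", {
  set.seed(21)
  for (i in 1:10) {
    g <- init_genome(sample(2:6, 1), sample(1:4, 1),
                     wavelet_set = sample(c("morlet", "mexican_hat", "gauss1", "haar"),
                                          sample(2:4, 1)))
    g <- mutate_genome(g, rate = 0.5)
    path <- withr::local_tempfile(fileext = ".json")
    write_genome(g, path)
    expect_identical(read_genome(path), g)
  }
})

test_that("a hand-written minimal genome file yields a working network", {
  txt <- '{
    "schema": "wnn_genome", "version": 1,
    "n_features": 2, "n_wavelons": 1, "n_inputs": 2,
    "wavelet_set": ["mexican_hat"],
    "feat": [[1], [2]], "switch": [[1], [0]],
    "w": [[1], [1]], "alpha": [[1], [1]], "beta": [[0], [0]],
    "rotation": [[0], [0]],
    "psi": [1], "wt": [1], "ot": [1],
    "a": [0, 0], "theta": 0.25
  }'
  path <- withr::local_tempfile(fileext = ".json")
  writeLines(txt, path)
  g <- read_genome(path)
  # theta + wt * psi((1*0 - 0)/1) = 0.25 + 1
  expect_equal(network_output(g, c(0, 7)), 1.25)
})

test_that("malformed genome text names the offending field", {
  g <- init_genome(2, 1, seed = 4)
  lst <- ewnne:::genome_to_list(g)
  lst$switch[1] <- 2L
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  expect_error(read_genome(path), "switch")
  lst2 <- ewnne:::genome_to_list(g)
  lst2$schema <- "something_else"
  jsonlite::write_json(lst2, path, auto_unbox = TRUE, digits = NA)
  expect_error(read_genome(path), "schema")
})

test_that("pool files carry genomes and manifest through a round trip", {
  set.seed(30)
  pool <- replicate(3, init_genome(3, 2), simplify = FALSE)
  manifest <- data.frame(fold = 1L, run = 1:3, seed = c(5L, 6L, 7L),
                         val_accuracy = c(0.5, 0.75, 1))
  path <- withr::local_tempfile(fileext = ".json")
  write_pool(pool, path, manifest = manifest)
  back <- read_pool(path)
  expect_identical(back$genomes, pool)
  expect_equal(back$manifest$val_accuracy, manifest$val_accuracy)
})
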