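test_that("site orientation handles identical, complementary and mixed sites", {
  id10 <- matrix(rep(c(0L, 1L), 5), nrow = 1)
  same <- rbind(id10, id10)
  expect_equal(orient_sites(same)$sign, c("+", "+"))
  comp <- rbind(id10, 1L - id10)
  expect_equal(orient_sites(comp)$sign, c("+", "-"))
  # oriented matrices coincide after applying the signs
  expect_identical(orient_sites(comp)$oriented[1, ],
                   orient_sites(comp)$oriented[2, ])
  # site with no individual shared with its window: "+" and low-confidence
  x <- rbind(c(0L, 1L, NA, NA), c(NA, NA, 1L, 0L))
  o <- orient_sites(x)
  expect_equal(o$sign[2], "+")
  expect_true(o$low_confidence[2])
  # both-seen calls are uninformative for orientation
  y <- rbind(c(0L, 1L, 0L, 1L), c(2L, 2L, 2L, 2L), c(1L, 0L, 1L, 0L))
  expect_equal(orient_sites(y)$sign[3], "-")
})

test_that("greedy orientation matches the exhaustive pairwise-agreement oracle", {
  # brute force over sign assignments (site 1 fixed to +), maximising total
  # agreement across all site pairs and individuals
  oracle <- function(calls) {
    n <- nrow(calls)
    vals <- lapply(seq_len(n), function(i) {
      v <- calls[i, ]
      v[!is.na(v) & v == 2L] <- NA_integer_
      v
    })
    best <- -Inf
    best_signs <- NULL
    for (mask in 0:(2^(n - 1) - 1)) {
      signs <- c(0L, bitwAnd(bitwShiftR(mask, seq_len(n - 1) - 1L), 1L))
      tot <- 0L
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          a <- if (signs[i] == 1L) 1L - vals[[i]] else vals[[i]]
          b <- if (signs[j] == 1L) 1L - vals[[j]] else vals[[j]]
          tot <- tot + sum(a == b, na.rm = TRUE)
        }
      }
      if (tot > best) {
        best <- tot
        best_signs <- ifelse(signs == 1L, "-", "+")
      }
    }
    list(total = best, signs = best_signs)
  }
  # 3 sites x 6 individuals with one ambiguous (partially missing) site
  calls <- rbind(c(0L, 0L, 1L, 1L, 0L, 1L),
                 c(1L, 1L, 0L, 0L, NA, 0L),
                 c(0L, NA, 1L, 1L, 0L, NA))
  expect_equal(orient_sites(calls)$sign, oracle(calls)$signs)
  # and on scaffold-shaped fixtures (one transmission vector per individual,
  # sites randomly flipped, sparse noisy coverage) greedy matches the oracle
  set.seed(7)
  for (rep in 1:10) {
    transmit <- rbinom(12, 1, 0.5)
    calls <- matrix(rep(transmit, each = 4), 4, 12)
    flip <- rbinom(4, 1, 0.5)
    calls[flip == 1L, ] <- 1L - calls[flip == 1L, ]
    noise <- matrix(runif(48) < 0.05, 4, 12)
    calls[noise] <- 1L - calls[noise]
    calls[matrix(runif(48) < 0.2, 4, 12)] <- NA
    storage.mode(calls) <- "integer"
    expect_equal(orient_sites(calls)$sign, oracle(calls)$signs)
  }
})

test_that("individual phasing segments runs, rejects singletons, imputes gaps", {
  pos <- c(100, 200, 300, 400, 500)
  # clean switch with two supporting calls
  tr <- phase_individual(c(0L, 0L, 0L, 1L, 1L), pos)
  expect_equal(nrow(tr$crossovers), 1L)
  expect_equal(tr$crossovers$mid, 350)
  expect_equal(c(tr$head, tr$tail), c(0L, 1L))
  # isolated discordant singleton: no crossover, rewritten missing
  tr2 <- phase_individual(c(0L, 0L, 1L, 0L, 0L), pos)
  expect_equal(nrow(tr2$crossovers), 0L)
  expect_true(is.na(tr2$phase[3]))
  expect_equal(tr2$phase[-3], rep(0L, 4))
  # missing inside a run is imputed to the run's phase
  tr3 <- phase_individual(c(0L, NA, NA, 0L), c(100, 200, 300, 400))
  expect_equal(tr3$phase, rep(0L, 4))
  expect_equal(nrow(tr3$crossovers), 0L)
  # no informative call: empty track
  tr4 <- phase_individual(rep(NA_integer_, 3), c(1, 2, 3))
  expect_true(is.na(tr4$head) && is.na(tr4$tail))
  expect_equal(tr4$n_informative, 0L)
  # a single informative site still yields an end phase
  tr5 <- phase_individual(c(NA, 1L, NA), c(1, 2, 3))
  expect_equal(c(tr5$head, tr5$tail), c(1L, 1L))
  # trailing singleton does not evidence a crossover (support 2)
  tr6 <- phase_individual(c(0L, 0L, 0L, 1L), c(1, 2, 3, 4))
  expect_equal(nrow(tr6$crossovers), 0L)
  # support threshold is honoured: runs of 2 accepted, of 1 not
  tr7 <- phase_individual(c(0L, 0L, 1L, 1L, 0L), pos, min_switch_support = 2)
  expect_equal(nrow(tr7$crossovers), 1L)
})

test_that("detected crossovers equal truth on noise-free tracks", {
  set.seed(21)
  for (rep in 1:20) {
    n <- 30L
    pos <- sort(sample.int(10000L, n))
    k <- rpois(1, 2)
    # crossovers placed away from the terminal marker interval so that every
    # new run retains >= 2 supporting sites
    cuts <- sort(sample(3:(n - 3), k))
    cuts <- cuts[!duplicated(cuts) & c(TRUE, diff(cuts) >= 2)]
    x <- integer(n)
    ph <- rbinom(1, 1, 0.5)
    prev <- 1L
    for (cut in c(cuts, n + 1L)) {
      x[prev:min(cut - 1L, n)] <- ph
      ph <- 1L - ph
      prev <- cut
    }
    tr <- phase_individual(x, pos)
    expect_equal(nrow(tr$crossovers), length(cuts))
  }
})

test_that("scaffold phasing recovers transmission up to a global label swap", {
  cfg <- sim_config(n_chromosomes = 1, chromosome_length = 2e4,
                    n_offspring = 20, mean_crossovers = 0,
                    mean_depth = 20, genotype_error = 0,
                    cross_mapped_fraction = 0, scaffold_n50 = 1e6, seed = 5)
  sim <- simulate_cross(cfg)
  expect_equal(nrow(sim$catalog), 1L)
  ps <- phase_scaffold(sim$genotypes)
  truth <- sim$truth$haplotypes[1L, ]  # lambda = 0: constant per individual
  agree <- mean(ps$head == truth)
  expect_true(agree %in% c(0, 1))  # exact up to global swap
  expect_identical(ps$head, ps$tail)  # no internal crossover anywhere
  expect_equal(sum(ps$n_crossovers), 0L)
})

test_that("an internal crossover separates head from tail", {
  n <- 40L
  calls <- matrix(0L, n, 3L)
  calls[21:40, 2L] <- 1L     # individual 2 switches mid-scaffold
  calls[, 3L] <- NA_integer_ # individual 3 never covered
  gm <- make_gm(calls)
  ps <- phase_scaffold(gm)
  expect_equal(ps$head[2L], 0L)
  expect_equal(ps$tail[2L], 1L)
  expect_equal(ps$n_crossovers[2L], 1L)
  expect_true(is.na(ps$head[3L]) && is.na(ps$tail[3L]))
  expect_equal(ps$n_informative[3L], 0L)
})

test_that("phasing is equivariant under a global label swap", {
  set.seed(33)
  gm <- random_gm(30, 15)
  swapped <- gm
  swapped$calls[gm$calls == 0L] <- 1L
  swapped$calls[gm$calls == 1L] <- 0L
  a <- phase_scaffold(gm)
  b <- phase_scaffold(swapped)
  expect_identical(b$head, flip_phase(a$head))
  expect_identical(b$tail, flip_phase(a$tail))
  expect_identical(b$n_crossovers, a$n_crossovers)
  for (i in seq_along(a$crossovers)) {
    expect_equal(b$crossovers[[i]]$mid, a$crossovers[[i]]$mid)
  }
})

test_that("phase table round-trips the profiles chaining needs", {
  set.seed(9)
  gm <- random_gm(20, 12)
  gm2 <- random_gm(15, 12)
  gm2$sites$scaffold <- "s2"
  phased <- list(s1 = phase_scaffold(gm), s2 = phase_scaffold(gm2))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_phase_table(phased, tsv)
  back <- read_phase_table(tsv)
  expect_setequal(names(back), c("s1", "s2"))
  expect_identical(back$s1$head, phased$s1$head)
  expect_identical(back$s1$tail, phased$s1$tail)
  expect_identical(back$s2$n_crossovers, phased$s2$n_crossovers)
  expect_identical(back$s1$sample_ids, phased$s1$sample_ids)
})
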