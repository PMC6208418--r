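test_that("depth mask compares per-site totals to the global mean", {
  # per-site totals [10,10,10,100]; mean total 32.5, cap 130 -> nothing masked
  mk <- function(d4) {
    depths <- rbind(matrix(5L, 3, 2), c(d4 / 2, d4 / 2))
    make_gm(matrix(0L, 4, 2), depths = depths)
  }
  expect_equal(nrow(depth_mask(mk(100), 4)), 0L)
  # totals [10,10,10,1000]: cap 4*257.5 = 1030 -> still nothing: with few
  # sites a spike inflates the mean it is compared against
  expect_equal(nrow(depth_mask(mk(1000), 4)), 0L)
  # ten sites [10x9, 2000]: mean total 209, cap 836 -> the spike is masked
  depths10 <- rbind(matrix(5L, 9, 2), c(1000L, 1000L))
  gm10 <- make_gm(matrix(0L, 10, 2), depths = depths10)
  m <- depth_mask(gm10, 4)
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 999)  # 10th site at pos 1000, 0-based
  expect_equal(m$reason, "high_depth")

  # a single site equals the mean and is never masked
  single <- make_gm(matrix(0L, 1, 3), depths = matrix(7L, 1, 3))
  expect_equal(nrow(depth_mask(single, 4)), 0L)

  zero <- make_gm(matrix(NA_integer_, 2, 2), depths = matrix(0L, 2, 2))
  expect_warning(res <- depth_mask(zero, 4), "zero")
  expect_equal(nrow(res), 0L)
})

test_that("parent-informative filter keeps focal-parent-het sites only", {
  gm <- make_gm(matrix(0L, 4, 3),
                parent = c("het", "hom_a", "het", NA))
  out <- parent_informative_filter(gm)
  expect_equal(out$sites$pos, c(100L, 300L))
  # no parent data: identity (reference-free mode)
  gm2 <- make_gm(matrix(0L, 4, 3))
  expect_identical(parent_informative_filter(gm2)$sites, gm2$sites)
  gm3 <- make_gm(matrix(0L, 3, 2), parent = rep("het", 3))
  expect_equal(n_sites(parent_informative_filter(gm3)), 3L)
})

test_that("quality rules apply strict thresholds in cascade order", {
  n <- 188L
  # presence: 17/188 = 9.0% < 10% -> removed
  calls <- matrix(NA_integer_, 1, n)
  calls[1, 1:17] <- 0L
  r <- marker_quality_filter(make_gm(calls))$report
  expect_equal(r$sites_removed, c(1L, 0L, 0L))

  # allele balance: 60/40 minor 40% kept; 80/20 minor 20% removed
  mk_ab <- function(a, b) {
    calls <- matrix(NA_integer_, 1, a + b)
    calls[1, seq_len(a)] <- 0L
    calls[1, a + seq_len(b)] <- 1L
    make_gm(calls)
  }
  expect_equal(marker_quality_filter(mk_ab(60, 40))$report$sites_removed,
               c(0L, 0L, 0L))
  expect_equal(marker_quality_filter(mk_ab(80, 20))$report$sites_removed,
               c(0L, 1L, 0L))
  # exact 30% minor is kept (strict less-than removes)
  expect_equal(marker_quality_filter(mk_ab(70, 30))$report$sites_removed,
               c(0L, 0L, 0L))

  # het excess: 50/188 = 26.6% > 20% -> removed; exactly 20% kept
  mk_het <- function(k, n = 188L) {
    calls <- matrix(rep(c(0L, 1L), length.out = n), 1, n)
    calls[1, seq_len(k)] <- 2L
    make_gm(calls)
  }
  expect_equal(marker_quality_filter(mk_het(50))$report$sites_removed,
               c(0L, 0L, 1L))
  expect_equal(marker_quality_filter(mk_het(20, 100L))$report$sites_removed,
               c(0L, 0L, 0L))
})

test_that("each rule is idempotent and counts match naive brute force", {
  set.seed(101)
  for (rep in 1:5) {
    gm <- random_gm(40, 25, parent = TRUE)
    cfg <- filter_config()
    expect_equal(sum(!linkscaf:::rule_presence_keep(gm, cfg$min_presence)),
                 naive_presence_removed(gm, cfg$min_presence))
    expect_equal(sum(!linkscaf:::rule_minor_keep(gm, cfg$min_minor)),
                 naive_minor_removed(gm, cfg$min_minor))
    expect_equal(sum(!linkscaf:::rule_het_keep(gm, cfg$max_het)),
                 naive_het_removed(gm, cfg$max_het))
    expect_equal(nrow(depth_mask(gm, 4)), naive_depth_removed(gm, 4))
    expect_equal(n_sites(gm) - n_sites(parent_informative_filter(gm)),
                 naive_parent_removed(gm))
    # idempotence: re-apply each rule to its own output
    g1 <- subset_sites(gm, linkscaf:::rule_presence_keep(gm, cfg$min_presence))
    expect_true(all(linkscaf:::rule_presence_keep(g1, cfg$min_presence)))
    g2 <- subset_sites(gm, linkscaf:::rule_minor_keep(gm, cfg$min_minor))
    expect_true(all(linkscaf:::rule_minor_keep(g2, cfg$min_minor)))
    g3 <- parent_informative_filter(gm)
    expect_identical(parent_informative_filter(g3)$sites, g3$sites)
  }
})

# engineered 30-site fixture: every cascade rule removes exactly two sites
cascade_fixture <- function(with_parent = TRUE) {
  n_ind <- 40L
  n_site <- 30L
  phase <- rep(c(0L, 1L), each = 20L)
  calls <- matrix(rep(phase, each = n_site), n_site, n_ind)
  depths <- matrix(1L, n_site, n_ind)
  parent <- rep("het", n_site)
  # depth rule: sites 10,11 at 50x everywhere
  depths[c(10, 11), ] <- 50L
  # parent rule: sites 14,15 homozygous in the focal parent
  parent[c(14, 15)] <- "hom_a"
  # presence rule: sites 17,18 seen in 3/40 individuals
  calls[c(17, 18), ] <- NA_integer_
  calls[c(17, 18), 1:3] <- 0L
  depths[c(17, 18), ] <- 0L
  depths[c(17, 18), 1:3] <- 1L
  # allele balance rule: sites 20,21 split 36/4
  calls[c(20, 21), ] <- 0L
  calls[c(20, 21), 25:28] <- 1L
  # het rule: sites 23,24 both-seen in 10/40
  calls[c(23, 24), 1:10] <- 2L
  depths[c(23, 24), 1:10] <- 2L
  # breakpoint rule: recurrent switch at site 3 (ind 9-16) and site 29 (1-8)
  calls[c(1, 2), 9:16] <- 1L
  calls[c(29, 30), 1:8] <- 1L
  gm <- make_gm(calls, depths, parent = if (with_parent) parent)
  mask <- site_mask(c("s1", "s1"), c(499, 599), c(500, 600), "cross_mapped")
  list(gm = gm, mask = mask)
}

test_that("cascade fixture attrition: every rule removes exactly two sites", {
  fx <- cascade_fixture()
  res <- apply_cascade(fx$gm, cross_mask = fx$mask)
  expect_equal(res$report$rule,
               c("cross_mapped", "high_depth", "parent_het", "presence",
                 "allele_balance", "het_excess", "breakpoint_noise"))
  expect_equal(res$report$sites_removed, rep(2L, 7L))
  expect_equal(res$report$sites_after,
               res$report$sites_before - res$report$sites_removed)
  # chained bookkeeping: each before equals the previous after
  expect_equal(res$report$sites_before[-1L],
               res$report$sites_after[-nrow(res$report)])
  expect_equal(n_sites(res$genotypes), 16L)
  # output is a subset of input sites, order preserved
  expect_true(all(diff(match(res$genotypes$sites$pos, fx$gm$sites$pos)) > 0))
})

test_that("all-pass fixture removes nothing", {
  phase <- rep(c(0L, 1L), each = 15L)
  calls <- matrix(rep(phase, each = 10L), 10L, 30L)
  gm <- make_gm(calls, parent = rep("het", 10L))
  res <- apply_cascade(gm)
  expect_equal(res$report$sites_removed, rep(0L, 7L))
})

test_that("parent data changes only the parent-informative rule", {
  with_p <- apply_cascade(cascade_fixture(TRUE)$gm,
                          cross_mask = cascade_fixture(TRUE)$mask)
  no_p <- apply_cascade(cascade_fixture(FALSE)$gm,
                        cross_mask = cascade_fixture(FALSE)$mask)
  rp <- with_p$report
  rn <- no_p$report
  expect_equal(rn$sites_removed[rn$rule == "parent_het"], 0L)
  other <- rn$rule != "parent_het"
  expect_equal(rn$sites_removed[other], rp$sites_removed[other])
})

test_that("recurrent breakpoint sites are removed, 10% boundary is kept", {
  n_ind <- 40L
  n_site <- 12L
  calls <- matrix(0L, n_site, n_ind)
  # 5/40 = 12.5% of individuals switch at site 7 (> 10%: removed)
  calls[7:12, 1:5] <- 1L
  gm <- make_gm(calls)
  phased <- phase_all(gm)
  out <- breakpoint_noise_filter(gm, phased, max_breakpoint = 0.10)
  expect_equal(setdiff(gm$sites$pos, out$sites$pos), 700)
  # exactly 10% (4/40) is kept: the rule is strictly "more than"
  calls2 <- matrix(0L, n_site, n_ind)
  calls2[7:12, 1:4] <- 1L
  gm2 <- make_gm(calls2)
  out2 <- breakpoint_noise_filter(gm2, phase_all(gm2), max_breakpoint = 0.10)
  expect_equal(n_sites(out2), n_site)
  # no switches anywhere: nothing removed
  gm3 <- make_gm(matrix(0L, 5, 10))
  expect_equal(n_sites(breakpoint_noise_filter(gm3, phase_all(gm3), 0.10)), 5L)
})

test_that("cascade errors when nothing survives", {
  calls <- matrix(NA_integer_, 5, 30)
  calls[, 1] <- 0L  # 1/30 presence everywhere
  gm <- make_gm(calls)
  expect_error(apply_cascade(gm), "relax")
})
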