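test_that("aggregation forms block sums and conserves mass", {
  M <- matrix(1, 4, 4)
  m <- hic_map(M, 1000)
  dom <- make_domains(2, 2, resolution = 1000)
  dm <- aggregate_domains(m, dom)
  expect_equal(dm$M, matrix(4, 2, 2))
  expect_equal(dm$K, c(8, 8))
  expect_equal(dm$total, 12)  # upper triangle incl. diagonal

  # single domain covering all bins
  dm1 <- aggregate_domains(m, make_domains(1, 4, resolution = 1000))
  expect_equal(dm1$M[1, 1], sum(M))

  # uncovered gap bins contribute nowhere
  dom_gap <- dom
  dom_gap$bin_start <- c(0L, 3L)
  dom_gap$bin_end <- c(0L, 3L)
  dmg <- aggregate_domains(m, dom_gap)
  expect_equal(sum(dmg$M), 4)  # cells (0,0), (0,3), (3,0), (3,3)

  expect_error(aggregate_domains(m, dom[0, ]), "empty")

  # conservation identity on an integer synthetic map
  g <- generate_map(synthetic_spec(40, seed = 31))
  gi <- hic_map(round(g$map$matrix), 10000)
  dom4 <- make_domains(4, 10)
  dm4 <- aggregate_domains(gi, dom4)
  expect_identical(sum(dm4$M), sum(gi$matrix))
  expect_identical(sum(dm4$K), sum(dm4$M))
})

test_that("hypergeometric p-values match the enumeration oracle", {
  dm <- list(M = matrix(c(0, 3, 3, 0), 2, 2), K = c(5, 4), total = 20)
  class(dm) <- "domain_matrix"
  expect_equal(hypergeom_pvalue(dm, 1, 2), 155 / 4845, tolerance = 1e-12)
  expect_equal(hypergeom_pvalue(dm, 1, 2),
               oracle_hyper_tail(3, 5, 4, 20), tolerance = 1e-12)

  dm$M[1, 2] <- dm$M[2, 1] <- 0
  expect_equal(hypergeom_pvalue(dm, 1, 2), 1)

  # deterministic draw boundary: K_i = total, k = K_j
  dmb <- list(M = matrix(c(0, 4, 4, 0), 2, 2), K = c(20, 4), total = 20)
  class(dmb) <- "domain_matrix"
  expect_warning(pb <- hypergeom_pvalue(dmb, 1, 2), "forced")
  expect_equal(pb, 1)

  dm$M[1, 2] <- 10
  expect_error(hypergeom_pvalue(dm, 1, 2), "marginal")
})

test_that("Poisson and NB p-values match partial-sum oracles", {
  mk <- function(k, K_i, K_j, total) {
    dm <- list(M = matrix(c(0, k, k, 0), 2, 2), K = c(K_i, K_j),
               total = total)
    class(dm) <- "domain_matrix"
    dm
  }
  # lambda = K_i * K_j / (2 total) = 1, k = 2
  expect_equal(poisson_pvalue(mk(2, 10, 10, 50), 1, 2), 1 - 2 / exp(1),
               tolerance = 1e-12)
  # lambda = 4, k = 4
  expect_equal(poisson_pvalue(mk(4, 20, 20, 50), 1, 2),
               oracle_pois_tail(4, 4), tolerance = 1e-12)
  expect_equal(poisson_pvalue(mk(0, 10, 10, 50), 1, 2), 1)

  # NB closed form: mu = 2, phi = 0.5 -> r = 2, p = 1/2, P(X >= 1) = 3/4
  dm <- mk(1, 20, 10, 50)
  expect_equal(nbinom_pvalue(dm, 1, 2, dispersion = 0.5), 0.75,
               tolerance = 1e-12)
  expect_equal(nbinom_pvalue(mk(0, 20, 10, 50), 1, 2, 0.5), 1)
  # phi = 0 degenerates to Poisson
  expect_equal(nbinom_pvalue(dm, 1, 2, dispersion = 0),
               poisson_pvalue(dm, 1, 2))

  # monotone non-increasing in k for all three tests
  ks <- 0:12
  hyper <- vapply(ks, function(k) hypergeom_pvalue(mk(k, 15, 13, 60), 1, 2),
                  numeric(1))
  pois <- vapply(ks, function(k) poisson_pvalue(mk(k, 15, 13, 60), 1, 2),
                 numeric(1))
  nb <- vapply(ks, function(k) nbinom_pvalue(mk(k, 15, 13, 60), 1, 2, 0.3),
               numeric(1))
  expect_true(all(diff(hyper) <= 1e-15))
  expect_true(all(diff(pois) <= 1e-15))
  expect_true(all(diff(nb) <= 1e-15))
})

test_that("dispersion estimation recovers Poisson and NB data", {
  # synthetic domain matrix with known margins
  mk_dm <- function(counts, K, total, domains = NULL) {
    n <- length(K)
    M <- matrix(0, n, n)
    M[upper.tri(M)] <- counts
    M <- M + t(M)
    dm <- list(M = M, K = K, total = total, domains = domains)
    class(dm) <- "domain_matrix"
    dm
  }
  n <- 80  # 3160 pairs
  K <- rep(2000, n)
  total <- n * 2000 / 2
  mu <- K[1] * K[1] / (2 * total)
  set.seed(55)
  pois_counts <- rpois(n * (n - 1) / 2, mu)
  expect_lt(fit_dispersion(mk_dm(pois_counts, K, total)), 0.05)

  phi <- 0.5
  nb_counts <- rnbinom(n * (n - 1) / 2, size = 1 / phi, mu = mu)
  expect_lt(abs(fit_dispersion(mk_dm(nb_counts, K, total)) - phi), 0.1)

  # constant counts at the mean clip to zero
  expect_equal(fit_dispersion(mk_dm(rep(mu, n * (n - 1) / 2), K, total)), 0)

  small <- mk_dm(rep(1, 3), rep(10, 3), 15)
  expect_error(fit_dispersion(small), "Poisson")
})

test_that("Poisson p-values are calibrated under their own null", {
  set.seed(61)
  n <- 150  # 11175 pairs
  K0 <- runif(n, 800, 1600)
  total0 <- sum(K0) / 2
  M <- matrix(0, n, n)
  idx <- which(upper.tri(M), arr.ind = TRUE)
  mu0 <- K0[idx[, 1]] * K0[idx[, 2]] / (2 * total0)
  M[idx] <- rpois(nrow(idx), mu0)
  M <- M + t(M)
  dm <- list(M = M, K = rowSums(M), total = sum(M[upper.tri(M, diag = TRUE)]))
  class(dm) <- "domain_matrix"
  p <- vapply(seq_len(nrow(idx)), function(r) {
    poisson_pvalue(dm, idx[r, 1], idx[r, 2])
  }, numeric(1))
  expect_gt(mean(p <= 0.05), 0.03)
  expect_lt(mean(p <= 0.05), 0.07)
})

test_that("domain calling flags planted blocks and honours alpha", {
  nd <- 40
  dom <- make_domains(nd, 5)
  blk <- list(list(bins_i = 10:14, bins_j = 110:114, fold = 10))
  g <- generate_map(synthetic_spec(200, seed = 71, gamma = 0,
                                   domain_blocks = blk))
  for (t in c("hypergeometric", "poisson", "nbinom")) {
    dc <- suppressWarnings(call_domain_interactions(g$map, dom, test = t))
    row <- dc[dc$i == 3 & dc$j == 23, ]
    expect_true(row$significant, label = t)
    expect_true(all(dc$q >= dc$p, na.rm = TRUE))
  }
  # alpha = 1 returns every tested pair as significant
  dc1 <- suppressWarnings(call_domain_interactions(g$map, dom,
                                                   test = "poisson",
                                                   alpha = 1))
  expect_true(all(dc1$significant))
  expect_equal(nrow(dc1), nd * (nd - 1) / 2)
  # min_separation excludes adjacent pairs
  dc2 <- suppressWarnings(call_domain_interactions(g$map, dom,
                                                   test = "poisson",
                                                   min_separation = 2))
  expect_true(all(dc2$j - dc2$i >= 2))
  expect_error(call_domain_interactions(g$map, dom, test = "bogus"),
               "unknown test")
})

test_that("domain output tables round-trip and flag significant pairs", {
  nd <- 12
  dom <- make_domains(nd, 5)
  g <- generate_map(synthetic_spec(60, seed = 81, gamma = 0,
      domain_blocks = list(list(bins_i = 0:4, bins_j = 30:34, fold = 10))))
  dc <- suppressWarnings(call_domain_interactions(g$map, dom,
                                                  test = "poisson"))
  out <- withr::local_tempdir()
  files <- write_domain_calls(dc, out)
  p_tab <- utils::read.table(files[1], header = TRUE, sep = "\t")
  q_tab <- utils::read.table(files[2], header = TRUE, sep = "\t")
  expect_equal(nrow(p_tab), nrow(dc))
  expect_equal(p_tab$value, dc$p, tolerance = 1e-15)
  expect_equal(q_tab$value, dc$q, tolerance = 1e-15)
  s_tab <- utils::read.table(files[3], header = TRUE, sep = "\t")
  expect_equal(nrow(s_tab), sum(dc$significant))
})
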