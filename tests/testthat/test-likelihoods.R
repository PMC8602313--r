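test_that("per-read likelihoods follow the biallelic error model", {
  expect_equal(read_likelihood("ALT", 0, 1), 1)
  expect_equal(read_likelihood("ALT", 0.3, 0), 0.1)
  expect_equal(read_likelihood("ALT", 0.01, 0.5), 0.5 * 0.99 + 0.5 * 0.01 / 3)
  expect_equal(read_likelihood("REF", 0.01, 0.5),
               read_likelihood("ALT", 0.01, 0.5))
  # vectorizes over rho
  expect_equal(read_likelihood("REF", 0, c(0, 0.5, 1)), c(1, 0.5, 0))
  expect_error(read_likelihood("OTHER", 0.1, 0.5), "OTHER")
  expect_error(read_likelihood("ALT", 0.1, 1.5), "rho")
})

test_that("single-cell read-set likelihood is an order-invariant product", {
  expect_equal(sc_sample_likelihood(NULL, 0.5), 1)
  two_alt <- tibble::tibble(allele = c("ALT", "ALT"), error_prob = 0.001)
  expect_equal(sc_sample_likelihood(two_alt, 1), 0.999^2)
  reads <- tibble::tibble(allele = c("ALT", "REF", "ALT", "REF", "REF"),
                          base_qual = c(30, 20, 10, 40, 30))
  perm <- reads[c(4, 1, 5, 3, 2), ]
  expect_equal(sc_sample_likelihood(reads, 0.4),
               sc_sample_likelihood(perm, 0.4))
})

test_that("single-cell theta likelihood marginalizes over the distorted grid", {
  # zero coverage: every theta is equally (fully) likely
  expect_equal(sc_theta_likelihood(NULL, c(0, 0.5, 1)), c(1, 1, 1))
  # a single error-free ALT read kills every k but k = 1
  one_alt <- tibble::tibble(allele = "ALT", error_prob = 0)
  expect_equal(sc_theta_likelihood(one_alt, 0), sc_freq_likelihood(1, 1, 0))
  expect_equal(sc_theta_likelihood(one_alt, 1), sc_freq_likelihood(1, 1, 1))
  # mirror: relabel REF<->ALT and swap theta 0<->1
  reads <- tibble::tibble(allele = c("ALT", "ALT", "REF", "REF", "REF"),
                          base_qual = 25)
  flipped <- reads
  flipped$allele <- ifelse(reads$allele == "ALT", "REF", "ALT")
  expect_equal(sc_theta_likelihood(reads, 0),
               sc_theta_likelihood(flipped, 1), tolerance = 1e-13)
  expect_equal(sc_theta_likelihood(reads, 0.5),
               sc_theta_likelihood(flipped, 0.5), tolerance = 1e-13)
})

test_that("bulk likelihoods use the unamplified frequency grid directly", {
  all_alt <- tibble::tibble(allele = rep("ALT", 6), error_prob = 0)
  expect_equal(bulk_theta_likelihood(all_alt, 6), 1)
  one_alt <- tibble::tibble(allele = "ALT", error_prob = 0.003)
  expect_equal(bulk_theta_likelihood(one_alt, 0), 0.001)
  reads <- tibble::tibble(allele = c("ALT", "REF", "REF", "ALT"),
                          base_qual = c(30, 20, 35, 15))
  expect_equal(bulk_theta_likelihood(reads, 2),
               bulk_theta_likelihood(reads[c(3, 1, 4, 2), ], 2))
})

test_that("bulk range likelihoods honour the event bracket semantics", {
  reads <- tibble::tibble(allele = c("ALT", "ALT", "ALT", "REF"),
                          base_qual = 20)
  terms <- bulk_theta_likelihood(reads, 0:4)
  # full interval marginalizes over the whole grid
  expect_equal(bulk_range_likelihood(reads, c(0, 1)), sum(terms))
  # the point interval {1} keeps only m = n
  expect_equal(bulk_range_likelihood(reads, c(1, 1)), terms[5])
  # n = 4: (1/2, 1] keeps m in {3, 4}; [1/2, 1) keeps m in {2, 3}
  open_half <- list(theta_b_lo = 0.5, theta_b_hi = 1,
                    lo_open = TRUE, hi_open = FALSE)
  closed_half <- list(theta_b_lo = 0.5, theta_b_hi = 1,
                      lo_open = FALSE, hi_open = TRUE)
  expect_equal(bulk_range_likelihood(reads, open_half), sum(terms[4:5]))
  expect_equal(bulk_range_likelihood(reads, closed_half), sum(terms[3:4]))
  # an interval holding no grid point has zero likelihood
  narrow <- list(theta_b_lo = 0.26, theta_b_hi = 0.49,
                 lo_open = TRUE, hi_open = TRUE)
  expect_equal(bulk_range_likelihood(reads, narrow), 0)
})

test_that("likelihoods stay finite in log space at deep coverage", {
  deep_cell <- tibble::tibble(allele = rep(c("ALT", "REF"), c(4000, 6000)),
                              base_qual = 30)
  lp <- sc_theta_likelihood(deep_cell, c(0, 0.5, 1), log = TRUE)
  expect_true(all(is.finite(lp)))
  deep_bulk <- tibble::tibble(allele = rep(c("ALT", "REF"), c(5000, 5000)),
                              base_qual = 30)
  expect_true(is.finite(bulk_range_likelihood(deep_bulk, c(0, 1),
                                              log = TRUE)))
})
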