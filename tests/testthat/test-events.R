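test_that("the seven regions are exactly the stated event definitions", {
  er <- event_regions()
  expect_setequal(er$event, names(ora_events))
  hom_alt <- er[er$event == "hom_alt", ]
  expect_equal(hom_alt$theta_s[[1]], 1)
  expect_equal(c(hom_alt$theta_b_lo, hom_alt$theta_b_hi), c(0.5, 1))
  expect_true(hom_alt$lo_open); expect_false(hom_alt$hi_open)
  ado_ref <- er[er$event == "ado_to_ref", ]
  expect_equal(ado_ref$theta_s[[1]], 0)
  expect_equal(c(ado_ref$theta_b_lo, ado_ref$theta_b_hi), c(0.5, 1))
  expect_false(ado_ref$lo_open); expect_true(ado_ref$hi_open)
  err_alt <- er[er$event == "err_alt", ]
  expect_equal(err_alt$theta_s[[1]], c(0.5, 1))
  expect_equal(c(err_alt$theta_b_lo, err_alt$theta_b_hi), c(0, 0))
})

test_that("the events partition every bulk frequency grid", {
  er <- event_regions()
  for (n in 1:50) {
    grid <- (0:n) / n
    for (th in c(0, 0.5, 1)) {
      holds_th <- vapply(er$theta_s, function(s) th %in% s, logical(1))
      cover <- vapply(which(holds_th), function(i) {
        lo_ok <- if (er$lo_open[i]) grid > er$theta_b_lo[i] else
          grid >= er$theta_b_lo[i]
        hi_ok <- if (er$hi_open[i]) grid < er$theta_b_hi[i] else
          grid <= er$theta_b_hi[i]
        lo_ok & hi_ok
      }, logical(n + 1))
      # each grid point lies in exactly one event containing this theta_s
      expect_true(all(rowSums(cover) == 1))
    }
  }
  # the complement of the alt-presence union is hom_ref + err_alt
  alt_presence <- c("ado_to_ref", "err_ref", "het", "ado_to_alt", "hom_alt")
  expect_setequal(setdiff(er$event, alt_presence), c("hom_ref", "err_alt"))
})

test_that("event likelihoods match the flat-prior double sum", {
  # zero-coverage cell under imputation: |theta_s set| times the bulk factor
  bulk <- tibble::tibble(allele = c("ALT", "REF", "ALT"), base_qual = 30)
  for (ev in c("hom_ref", "err_alt", "err_ref")) {
    er <- event_regions()
    reg <- er[er$event == ev, ]
    expect_equal(
      event_likelihood(NULL, bulk, ev, impute = TRUE),
      length(reg$theta_s[[1]]) * bulk_range_likelihood(bulk, reg)
    )
  }
  # a bulk of one read leaves no interior grid point for het
  one <- tibble::tibble(allele = "REF", base_qual = 30)
  cell <- tibble::tibble(allele = c("ALT", "REF"), base_qual = 30)
  expect_equal(event_likelihood(cell, one, "het"), 0)
  expect_error(event_likelihood(cell, one, "nonsense"), "unknown event")
  # tiny instance against the exhaustive linear-space oracle
  ca <- c("ALT", "REF"); ba <- c("ALT", "ALT")
  e20 <- rep(1e-2, 2)
  for (ev in names(ora_events)) {
    expect_equal(
      event_likelihood(tibble::tibble(allele = ca, error_prob = e20),
                       tibble::tibble(allele = ba, error_prob = e20), ev),
      ora_event_lik(ca, e20, ba, e20, ora_events[[ev]]),
      tolerance = 1e-10
    )
  }
})

test_that("posteriors normalize and match exhaustive enumeration on small sites", {
  withr::with_seed(11, {
    for (rep in 1:40) {
      l <- sample(1:4, 1); n <- sample(1:4, 1)
      ca <- sample(c("REF", "ALT"), l, replace = TRUE)
      ba <- sample(c("REF", "ALT"), n, replace = TRUE)
      q <- sample(c(13, 20, 33), l + n, replace = TRUE)
      pu <- tibble::tibble(
        chrom = "c", pos = 1L, ref = "A", alt = "T",
        sample = rep(c("cell", "bulk"), c(l, n)),
        allele = c(ca, ba), base_qual = q
      )
      got <- site_posteriors(pu)
      expect_equal(sum(unlist(got[, posterior_cols])), 1, tolerance = 1e-9)
      want <- ora_posteriors(ca, read_error_prob(q[seq_len(l)]),
                             ba, read_error_prob(q[l + seq_len(n)]))
      expect_equal(unlist(got[, posterior_cols], use.names = FALSE),
                   unname(want), tolerance = 1e-8)
    }
  })
})

test_that("relabeling REF and ALT mirrors the posteriors onto swapped events", {
  withr::with_seed(23, {
    for (rep in 1:50) {
      pu <- random_pileup()
      sw <- pu
      sw$allele <- c(REF = "ALT", ALT = "REF", OTHER = "OTHER")[pu$allele]
      a <- site_posteriors(pu)
      b <- site_posteriors(sw)
      expect_equal(a$p_hom_ref, b$p_hom_alt, tolerance = 1e-12)
      expect_equal(a$p_err_alt, b$p_err_ref, tolerance = 1e-12)
      expect_equal(a$p_ado_to_alt, b$p_ado_to_ref, tolerance = 1e-12)
      expect_equal(a$p_het, b$p_het, tolerance = 1e-12)
      expect_equal(a$k, a$l - sum(sw$allele[sw$sample == "cell"] == "ALT"))
    }
  })
})

test_that("zero-coverage cells are imputed from the bulk alone", {
  # deep near-error-free ALT bulk drives the call to the hom-alt genotype;
  # the hom-alt compound keeps ~3/4 of the mass (the neighbouring grid
  # points feed the het-implying dropout events), matching the oracle
  pu <- make_pileup(character(0), rep("ALT", 50), base_qual = 60)
  got <- genotype_call(site_posteriors(pu, impute = TRUE))
  expect_true(got$imputed)
  expect_equal(got$genotype, "hom_alt")
  want <- ora_posteriors(character(0), numeric(0),
                         rep("ALT", 50), rep(read_error_prob(60), 50),
                         impute = TRUE)
  expect_equal(got$p_gt_hom_alt,
               unname(want[["hom_alt"]] + want[["err_ref"]]),
               tolerance = 1e-8)
  expect_gt(got$p_gt_hom_alt, 0.7)
  # equality with a bulk-only evaluation using unit single-cell factors
  bulk_alleles <- rep(c("ALT", "REF"), c(3, 7))
  pu2 <- make_pileup(character(0), bulk_alleles, base_qual = 30)
  got2 <- site_posteriors(pu2, impute = TRUE)
  er <- event_regions()
  bulk <- tibble::tibble(allele = bulk_alleles, base_qual = 30)
  lik <- vapply(seq_len(7), function(i) {
    length(er$theta_s[[i]]) * bulk_range_likelihood(bulk, er[i, ])
  }, numeric(1))
  expect_equal(unlist(got2[, posterior_cols], use.names = FALSE),
               lik / sum(lik), tolerance = 1e-12)
  # without imputation the site is reported missing
  expect_true(is.na(site_posteriors(pu2)$p_het))
  # and a site with no bulk coverage is uncallable
  pu3 <- make_pileup(c("ALT", "REF"), character(0))
  expect_true(is.na(site_posteriors(pu3)$p_het))
})

test_that("toy sites recover the expected top event", {
  # balanced cell reads with an intermediate-frequency bulk: het wins
  pu <- make_pileup(rep(c("ALT", "REF"), each = 10),
                    rep(c("ALT", "REF"), c(12, 18)), base_qual = 30)
  post <- site_posteriors(pu)
  expect_equal(names(which.max(unlist(post[, posterior_cols]))), "p_het")
  # a lone ALT read absent from a deep REF-only bulk is an amplified error
  pu2 <- make_pileup(rep(c("ALT", "REF"), c(1, 9)), rep("REF", 60),
                     base_qual = 30)
  call2 <- genotype_call(site_posteriors(pu2))
  expect_equal(call2$genotype, "hom_ref")
  expect_gt(call2$p_err_alt + call2$p_hom_ref, 0.7)
  expect_gt(call2$p_err_alt, call2$p_het)
})

test_that("compound posteriors sum members and complement within the partition", {
  pu <- make_pileup(rep(c("ALT", "REF"), c(4, 6)),
                    rep(c("ALT", "REF"), c(10, 20)), base_qual = 30)
  post <- site_posteriors(pu)
  all7 <- c("hom_ref", "err_alt", "ado_to_alt", "het", "ado_to_ref",
            "err_ref", "hom_alt")
  expect_equal(compound_posterior(post, all7), 1, tolerance = 1e-9)
  expect_equal(compound_posterior(post, character(0)), 0)
  alt_presence <- c("ado_to_ref", "err_ref", "het", "ado_to_alt", "hom_alt")
  expect_equal(compound_posterior(post, alt_presence) +
                 compound_posterior(post, c("hom_ref", "err_alt")), 1,
               tolerance = 1e-9)
  expect_error(compound_posterior(post, "hom_ref2"), "unknown event")
})

test_that("genotype calls take the maximum-posterior compound with fixed ties", {
  mk <- function(p) {
    out <- tibble::as_tibble(as.list(stats::setNames(p, posterior_cols)))
    out$l <- 5L; out$k <- 2L; out$n <- 10L; out$m_obs <- 3L
    out
  }
  # hom_alt (0.6) + err_ref (0.1) = 0.7 beats the rest
  ep <- mk(c(0.05, 0.05, 0.05, 0.1, 0.05, 0.1, 0.6))
  got <- genotype_call(ep)
  expect_equal(got$genotype, "hom_alt")
  expect_equal(got$genotype_posterior, 0.7)
  # a dominating dropout event is called heterozygous
  ep2 <- mk(c(0.05, 0.05, 0.02, 0.03, 0.8, 0.02, 0.03))
  expect_equal(genotype_call(ep2)$genotype, "het")
  # an exact three-way tie resolves to hom_ref
  ep3 <- mk(c(1 / 3, 0, 1 / 6, 0, 1 / 6, 0, 1 / 3))
  expect_equal(genotype_call(ep3)$genotype, "hom_ref")
})

test_that("posteriors are invariant to a common likelihood scale", {
  # normalization cancels any constant factor on the event likelihoods:
  # posteriors computed from shifted log likelihoods are unchanged
  pu <- make_pileup(rep(c("ALT", "REF"), c(3, 5)),
                    rep(c("ALT", "REF"), c(8, 12)), base_qual = 25)
  post <- unlist(site_posteriors(pu)[, posterior_cols], use.names = FALSE)
  ll <- vapply(event_regions()$event, function(ev) {
    event_likelihood(pu[pu$sample == "cell", ], pu[pu$sample == "bulk", ],
                     ev, log = TRUE)
  }, numeric(1))
  shifted <- ll + 123.456
  expect_equal(unname(exp(shifted - max(shifted)) /
                        sum(exp(shifted - max(shifted)))),
               post, tolerance = 1e-12)
})
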