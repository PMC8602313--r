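# Independent exhaustive-enumeration oracle for the seven-event posteriors.
# Deliberately naive: plain linear-space arithmetic, its own beta-binomial
# via the gamma function, explicit enumeration of every (theta_s, k, m)
# cell of each event region. Shares no code with the package internals.

# amplification-bias coefficients (slope, intercept), restated here so the
# oracle does not depend on the package's constants object
.ora_coef <- list(
  alpha = c(-0.00003, 0.06857),
  beta = c(0.00745, 2.36749),
  w = c(0.00055, 0.54040),
  alpha1 = c(0.05738, 0.66973),
  alpha2 = c(0.00323, 0.39926)
)

ora_param <- function(name, l) {
  v <- .ora_coef[[name]][1] * l + .ora_coef[[name]][2]
  if (name == "w") min(max(v, 0), 1) else max(v, 1e-6)
}

ora_bb <- function(k, l, a, b) {
  choose(l, k) * (gamma(k + a) * gamma(l - k + b) / gamma(l + a + b)) /
    (gamma(a) * gamma(b) / gamma(a + b))
}

ora_sc_pmf <- function(k, l, theta) {
  if (theta == 0) {
    ora_bb(k, l, ora_param("alpha", l), ora_param("beta", l))
  } else if (theta == 1) {
    ora_bb(k, l, ora_param("beta", l), ora_param("alpha", l))
  } else {
    w <- ora_param("w", l)
    a1 <- ora_param("alpha1", l)
    a2 <- ora_param("alpha2", l)
    w * ora_bb(k, l, a1, a1) + (1 - w) * ora_bb(k, l, a2, a2)
  }
}

ora_read_p <- function(allele, e, rho) {
  if (allele == "ALT") rho * (1 - e) + (1 - rho) * e / 3
  else (1 - rho) * (1 - e) + rho * e / 3
}

ora_reads_p <- function(alleles, es, rho) {
  p <- 1
  for (i in seq_along(alleles)) p <- p * ora_read_p(alleles[i], es[i], rho)
  p
}

# the seven event regions: theta_s members and a grid-membership predicate
ora_events <- list(
  hom_ref = list(th = 0, inb = function(f) f >= 0 & f < 0.5),
  err_alt = list(th = c(0.5, 1), inb = function(f) f == 0),
  ado_to_alt = list(th = 1, inb = function(f) f > 0 & f <= 0.5),
  het = list(th = 0.5, inb = function(f) f > 0 & f < 1),
  ado_to_ref = list(th = 0, inb = function(f) f >= 0.5 & f < 1),
  err_ref = list(th = c(0, 0.5), inb = function(f) f == 1),
  hom_alt = list(th = 1, inb = function(f) f > 0.5 & f <= 1)
)

ora_event_lik <- function(cell_alleles, cell_e, bulk_alleles, bulk_e, ev,
                          impute = FALSE) {
  l <- length(cell_alleles)
  n <- length(bulk_alleles)
  sc <- 0
  for (th in ev$th) {
    if (l == 0) {
      sc <- sc + 1 # empty product times BB(0, 0) = 1
    } else {
      for (k in 0:l) {
        sc <- sc + ora_reads_p(cell_alleles, cell_e, k / l) *
          ora_sc_pmf(k, l, th)
      }
    }
  }
  blk <- 0
  for (m in 0:n) {
    if (ev$inb(m / n)) blk <- blk + ora_reads_p(bulk_alleles, bulk_e, m / n)
  }
  sc * blk
}

ora_posteriors <- function(cell_alleles, cell_e, bulk_alleles, bulk_e,
                           impute = FALSE) {
  lik <- vapply(ora_events, function(ev) {
    ora_event_lik(cell_alleles, cell_e, bulk_alleles, bulk_e, ev, impute)
  }, numeric(1))
  lik / sum(lik)
}

# build a one-site pileup tibble from read class/quality vectors
make_pileup <- function(cell_alleles, bulk_alleles, base_qual = 30,
                        chrom = "chr1", pos = 100L, ref = "A", alt = "T") {
  tibble::tibble(
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    sample = c(rep("cell", length(cell_alleles)),
               rep("bulk", length(bulk_alleles))),
    allele = c(cell_alleles, bulk_alleles),
    base_qual = base_qual
  )
}

# random pileup generator for property tests
random_pileup <- function(max_l = 20, max_n = 30, quals = c(10, 20, 30, 40)) {
  l <- sample(1:max_l, 1)
  n <- sample(1:max_n, 1)
  tibble::tibble(
    chrom = "chr1", pos = 1L, ref = "A", alt = "T",
    sample = c(rep("cell", l), rep("bulk", n)),
    allele = sample(c("REF", "ALT", "OTHER"), l + n, replace = TRUE,
                    prob = c(0.5, 0.4, 0.1)),
    base_qual = sample(quals, l + n, replace = TRUE)
  )
}

posterior_cols <- paste0("p_", c("hom_ref", "err_alt", "ado_to_alt", "het",
                                 "ado_to_ref", "err_ref", "hom_alt"))
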