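# Shared fixture builders. All fixtures are generated in code so the
# suite carries no binary data.

small_cohort <- function(n = 120, n_snps = 4, seed = 42, ...) {
  generate_cohort(cohort_config(n_individuals = n, n_snps = n_snps,
                                n_mirnas = n_snps, seed = seed, ...))
}

fast_spec <- function(n_boot = 200, seed = 99, ...) {
  bootstrap_spec(n_boot = n_boot, seed = seed, ...)
}

# fixture with planted per-stage failures: 20 pairs -> 16 -> 13 -> 11 -> 6
planted_cascade <- function() {
  n <- 200
  ids <- sprintf("i%03d", 1:n)
  mirnas <- sprintf("hsa-miR-%d-5p", 101:120)
  set.seed(404)
  expr_n <- matrix(runif(20 * n, 1, 50), 20, n, dimnames = list(mirnas, ids))
  expr_t <- expr_n
  # 4 miRNAs unexpressed anywhere (pairs 1-4)
  expr_n[1:4, ] <- 0; expr_t[1:4, ] <- 0
  # 5 miRNAs below 5% non-tumor prevalence (pairs 12-16): 2% expressing
  for (j in 12:16) { expr_n[j, ] <- 0; expr_n[j, 1:4] <- 5 }
  geno <- t(vapply(1:20, function(i) generate_genotypes(n, 0.3), integer(n)))
  rownames(geno) <- sprintf("rs%03d", 1:20); colnames(geno) <- ids
  # 3 SNPs missing genotypes (pairs 5-7): drop from the matrix
  geno <- geno[-(5:7), , drop = FALSE]
  # 2 SNPs monomorphic (pairs 8-9)
  geno["rs008", ] <- 0L
  geno["rs009", ] <- 2L
  pairs <- data.frame(snp_id = sprintf("rs%03d", 1:20),
                      mirna_name = mirnas, matched = TRUE,
                      stringsAsFactors = FALSE)
  list(pairs = pairs, expr_n = expr_n, expr_t = expr_t, geno = geno)
}

# Independent brute-force BH step-up: for each p, the smallest
# q such that p would be declared at FDR level q by the step-up rule.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    r <- which(ord == i)               # rank of p[i] (stable)
    cand <- vapply(r:m, function(j) p[ord[j]] * m / j, numeric(1))
    adj[i] <- min(1, min(cand))
  }
  adj
}

# Independent HWE enumeration oracle: exact probabilities from choose()
# directly (conditional on allele counts), p = sum of probs <= observed.
hwe_oracle <- function(n_AA, n_AB, n_BB) {
  n <- n_AA + n_AB + n_BB
  n_a <- 2 * n_AA + n_AB               # count allele A as written
  n_minor <- min(n_a, 2 * n - n_a)
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  prob <- vapply(hets, function(h) {
    hom_minor <- (n_minor - h) / 2
    hom_major <- n - hom_minor - h
    exp(lchoose(n, hom_minor) + lchoose(n - hom_minor, h) +
          h * log(2) + lfactorial(n_minor) + lfactorial(2 * n - n_minor) -
          lfactorial(2 * n)) / 1
  }, numeric(1))
  prob <- prob / sum(prob)             # guard numerical drift
  p_obs <- prob[match(n_AB, hets)]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-10)]))
}
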