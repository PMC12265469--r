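# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# A small structured cohort with planted QTLs, used across gwas/gs tests.
small_cohort <- function() {
  fixture("small_cohort", function() {
    spec <- sim_cohort_spec(n_samples = 120, n_snps = 400, n_pops = 2,
                            fst = 0.1, ld_block_len = 10, n_qtl = 8,
                            h2 = 0.6, seed = 42)
    G <- filter_snps(simulate_genotypes(spec))
    sim <- simulate_phenotypes(G, spec)
    list(spec = spec, G = G, pheno = sim$pheno, qtl = sim$qtl,
         K = kinship(G))
  })
}

# A batch of labelled leaves shared by image tests.
small_leaves <- function() {
  fixture("small_leaves", function() {
    generate_leaf_dataset(24, size = 64, seed = 7,
                          fractions = rep(c(0.05, 0.3, 0.55, 0.9), 6))
  })
}

# Independent brute-force footrule: positional scan, no vectorized tricks.
footrule_oracle <- function(a, b) {
  total <- 0L
  for (el in a) {
    pa <- which(a == el)
    pb <- which(b == el)
    total <- total + abs(pa - pb)
  }
  total
}

# All permutations of 1..n (small n only).
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}
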