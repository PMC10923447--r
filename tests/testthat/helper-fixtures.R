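# shared fixtures and independent oracles, built in code at test time

# k Gaussian blobs in 3 features; centers sep within-sds apart on the axes
gen_blobs <- function(n, k, sep = 6, seed = 1) {
  set.seed(seed)
  centers <- matrix(c(0, 0, 0,
                      sep, 0, 0,
                      0, sep, 0,
                      0, 0, sep,
                      sep, sep, sep), ncol = 3, byrow = TRUE)[seq_len(k), ,
                                                              drop = FALSE]
  lab <- sample(rep_len(seq_len(k), n))
  x <- centers[lab, , drop = FALSE] + matrix(rnorm(n * 3), n)
  rownames(x) <- sprintf("s%d", seq_len(n))
  list(x = x, lab = lab)
}

# planted two-cohort scenario: four phenotype-separated case components,
# components A / D coupled to high / low GRS, one SNP carrying most of the
# coupling weight so it is the enriched variant the contrast should find
planted_cfg <- function(seed, n_case = 400, n_healthy = 400,
                        top_snp = "rs1530496", w = 6, delta = 0.3,
                        mode = "planted") {
  pan <- default_panel()
  v <- data.frame(rsid = pan$rsid, gene = pan$gene, p = pan$maf)
  v$effect_weight <- ifelse(v$rsid == top_snp, w, 1)
  cl <- data.frame(
    name = c("A", "B", "C", "D"),
    weight = c(0.30, 0.25, 0.23, 0.22),
    onset_mean = c(55, 10, 28, 68), onset_sd = c(5, 5, 5, 5),
    fev1_mean = c(102, 95, 42, 55), fev1_sd = c(7, 7, 7, 7),
    delta = c(delta, 0, 0, -delta),
    female_p = c(0.6, 0.5, 0.5, 0.55),
    atopy_p = c(0.6, 0.8, 0.6, 0.6),
    eos_p = c(0.4, 0.5, 0.5, 0.4))
  sim_config(data.frame(name = c("t1", "t2"), n_healthy = n_healthy,
                        n_case = n_case),
             v, cl, seed = seed, mode = mode)
}

# HWE enumeration oracle: direct conditional probabilities of every
# heterozygote count from the factorial formula (independent of the
# package's recurrence-free log-space implementation path)
hwe_enum_oracle <- function(n_AA, n_AB, n_BB) {
  n <- n_AA + n_AB + n_BB
  nA <- 2 * n_AA + n_AB
  nB <- 2 * n_BB + n_AB
  hets <- seq(nA %% 2, min(nA, nB), by = 2)
  pr <- vapply(hets, function(h) {
    naa <- (nA - h) / 2
    nbb <- (nB - h) / 2
    exp(lfactorial(n) - lfactorial(naa) - lfactorial(h) - lfactorial(nbb) +
          h * log(2) + lfactorial(nA) + lfactorial(nB) - lfactorial(2 * n))
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[hets == n_AB]
  min(1, sum(pr[pr <= obs * (1 + 1e-10)]))
}

# tightness oracle: plain-loop evaluation of
# xi = -N * sum_k 0.5 * log(gv_k + within-variance_k)
xi_oracle <- function(x, members, gv) {
  xs <- x[members, , drop = FALSE]
  N <- length(members)
  total <- 0
  for (k in seq_len(ncol(x))) {
    wv <- sum((xs[, k] - mean(xs[, k]))^2) / N
    total <- total + 0.5 * log(gv[k] + wv)
  }
  -N * total
}
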