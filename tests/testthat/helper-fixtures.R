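# Small in-code fixtures shared across the suite.

# minimal layout: nt targets, 3 housekeeping, optional controls
tiny_layout <- function(nt = 4, nc = 0, lod_ct = 35) {
  panel_layout(
    assay_ids = c(sprintf("miR-%02d", seq_len(nt)),
                  c("SNORD38B", "U6-snRNA", "SNORD49A"),
                  if (nc > 0) sprintf("CTRL-%02d", seq_len(nc))),
    roles = c(rep("target", nt), rep("housekeeping", 3),
              rep("control", nc)),
    lod_ct = lod_ct)
}

# ct_table with constant housekeeping (mean 21) and given target ΔCt matrix
tiny_ct <- function(dct_matrix, layout = tiny_layout(ncol(dct_matrix))) {
  n <- nrow(dct_matrix)
  hk <- matrix(rep(c(20, 21, 22), each = n), n, 3)
  targets <- dct_matrix + 21   # hk mean = 21 per sample
  ctrls <- matrix(25, n, sum(layout$roles == "control"))
  m <- cbind(targets, hk, ctrls)
  dimnames(m) <- list(sprintf("S%02d", seq_len(n)), layout$assay_ids)
  ct_table(m, layout)
}

tiny_meta <- function(n_cancer, n_healthy, n_mutant = 0) {
  ids <- sprintf("S%02d", seq_len(n_cancer + n_healthy))
  sample_meta(data.frame(
    sample_id = ids,
    group = c(rep("cancer", n_cancer), rep("healthy", n_healthy)),
    pole_status = c(rep("mutant", n_mutant),
                    rep("wildtype", n_cancer - n_mutant),
                    rep("not_applicable", n_healthy)),
    age = 60, bmi = 28, grade = rep_len(c("G1", "G2", "G3"),
                                        n_cancer + n_healthy),
    stringsAsFactors = FALSE))
}

# exact hypergeometric upper tail by enumeration over all C(N, n) draws is
# infeasible; instead enumerate the overlap pmf combinatorially:
# P(X = j) = C(K, j) C(N-K, n-j) / C(N, n), p = sum_{j >= k} P(X = j)
hyper_tail_enum <- function(k, K, N, n) {
  js <- max(0, n - (N - K)):min(K, n)
  pmf <- choose(K, js) * choose(N - K, n - js) / choose(N, n)
  sum(pmf[js >= k])
}

# noncentral-t power by numerical integration of the noncentral t density
# (independent of stats::pt's ncp path): P(|T| > tc), T = (Z + ncp)/sqrt(V/df)
power_numint_oracle <- function(delta, sd, n_a, n_b, alpha, df) {
  ncp <- delta / (sd * sqrt(1 / n_a + 1 / n_b))
  tc <- qt(1 - alpha / 2, df)
  # condition on the chi-square denominator and integrate over it
  f <- function(u) {
    s <- sqrt(u / df)
    (pnorm(-tc * s - ncp) + pnorm(tc * s - ncp, lower.tail = FALSE)) *
      dchisq(u, df)
  }
  integrate(f, 0, Inf, rel.tol = 1e-10)$value
}
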