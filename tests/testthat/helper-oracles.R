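# Independent oracles used by unit and acceptance tests. These re-derive the
# statistics from their definitions (direct loops / full enumeration) and
# deliberately share no code with the package implementations.

# Weighted KS running sum evaluated literally from the definition.
oracle_running_sum <- function(scores, in_set, p = 1) {
  n <- length(scores)
  nh <- sum(in_set)
  wh <- sum(abs(scores[in_set])^p)
  rs <- numeric(n)
  acc <- 0
  for (i in seq_len(n)) {
    if (in_set[i]) {
      acc <- acc + (if (wh > 0) abs(scores[i])^p / wh else 1 / nh)
    } else {
      acc <- acc - 1 / (n - nh)
    }
    rs[i] <- acc
  }
  rs
}

oracle_es <- function(scores, in_set, p = 1) {
  rs <- oracle_running_sum(scores, in_set, p)
  rs[which(abs(rs) >= max(abs(rs)) - 1e-9)[1]]
}

# Unweighted two-sample KS statistic, signed, by direct evaluation.
oracle_ks <- function(n, hit_positions) {
  in_set <- seq_len(n) %in% hit_positions
  k <- length(hit_positions)
  d <- cumsum(ifelse(in_set, 1 / k, -1 / (n - k)))
  d[which(abs(d) >= max(abs(d)) - 1e-9)[1]]
}

# Hypergeometric upper-tail by summation of the pmf from its formula.
oracle_hyper_upper <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# One-sided (greater) Fisher p of a 2x2 table by enumeration.
oracle_fisher_greater <- function(a, b, c, d) {
  oracle_hyper_upper(a, a + b, a + b + c + d, a + c)
}

# Exact two-sided Wilcoxon rank-sum p by enumerating all assignments.
oracle_wilcoxon <- function(x, y, alternative = "two.sided") {
  nx <- length(x); ny <- length(y)
  all_v <- c(x, y)
  combs <- utils::combn(nx + ny, nx)
  r_obs <- sum(rank(all_v)[seq_len(nx)])
  stats <- apply(combs, 2, function(idx) sum(rank(all_v)[idx]))
  mu <- nx * (nx + ny + 1) / 2
  switch(alternative,
         less = mean(stats <= r_obs),
         greater = mean(stats >= r_obs),
         two.sided = mean(abs(stats - mu) >= abs(r_obs - mu)))
}

# Exact PWM score survival function by enumerating all 4^w windows on the
# same discretization grid as the DP (integer bins of the score matrix).
oracle_pwm_pvalues <- function(score_matrix, background, bin = 0.01) {
  w <- ncol(score_matrix)
  smi <- round(score_matrix / bin)
  grids <- rep(list(1:4), w)
  combos <- as.matrix(expand.grid(grids))
  scores <- numeric(nrow(combos))
  probs <- numeric(nrow(combos))
  for (r in seq_len(nrow(combos))) {
    scores[r] <- sum(smi[cbind(combos[r, ], seq_len(w))])
    probs[r] <- prod(background[combos[r, ]])
  }
  function(s) sum(probs[scores >= round(s / bin)])
}

# NG86 site and difference counting re-derived independently: synonymous
# site fractions by direct mutation enumeration, pathway averaging by
# explicit permutation of edit orders (stop-traversing paths dropped, all
# kept if none survives), Jukes-Cantor applied at the end.
oracle_ng86 <- function(s1, s2) {
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  syn_sites <- function(cod) {
    aa <- code[cod]
    tot <- 0
    for (p in 1:3) for (b in bases) {
      if (b == substr(cod, p, p)) next
      m <- cod; substr(m, p, p) <- b
      if (code[m] == aa) tot <- tot + 1 / 3
    }
    tot
  }
  perms_of <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms_of(v[-i])) out <- c(out, list(c(v[i], rest)))
    }
    out
  }
  S <- N <- Sd <- Nd <- 0
  for (k in seq_len(nchar(s1) / 3)) {
    c1 <- substr(s1, 3 * k - 2, 3 * k); c2 <- substr(s2, 3 * k - 2, 3 * k)
    if (grepl("[^ACGT]", paste0(c1, c2))) next
    if (code[c1] == "*" || code[c2] == "*") next
    S <- S + (syn_sites(c1) + syn_sites(c2)) / 2
    N <- N + 3 - (syn_sites(c1) + syn_sites(c2)) / 2
    pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (!length(pos)) next
    res <- list()
    for (ord in perms_of(pos)) {
      cur <- c1; sy <- ns <- 0; ok <- TRUE
      for (p in ord) {
        nxt <- cur; substr(nxt, p, p) <- substr(c2, p, p)
        if (code[nxt] == "*") ok <- FALSE
        if (code[cur] == code[nxt]) sy <- sy + 1 else ns <- ns + 1
        cur <- nxt
      }
      res[[length(res) + 1]] <- c(sy, ns, ok)
    }
    mat <- do.call(rbind, res)
    use <- if (any(mat[, 3] == 1)) mat[mat[, 3] == 1, , drop = FALSE] else mat
    Sd <- Sd + mean(use[, 1]); Nd <- Nd + mean(use[, 2])
  }
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = Sd, Nd = Nd,
       dS = jc(if (S > 0) Sd / S else 0), dN = jc(if (N > 0) Nd / N else 0))
}

# Small shared fixture: a compact three-species simulated study.
tiny_study <- function(n_genes = 200, n_reps = 5, seed = 42, ...) {
  sim_config(n_genes = n_genes, n_reps_per_group = n_reps, seed = seed, ...)
}
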