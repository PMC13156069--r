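# Independent brute-force oracles used to check the package's statistics.
# These enumerate permutations directly and share no code with the
# implementation under test.

oracle_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in oracle_perms(n - 1L))
    for (k in 0:(n - 1L))
      out[[length(out) + 1L]] <- append(p, n, after = k)
  out
}

oracle_spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

oracle_spearman_p <- function(x, y) {
  obs <- abs(oracle_spearman_rho(x, y))
  perms <- oracle_perms(length(y))
  hits <- vapply(perms, function(p)
    abs(oracle_spearman_rho(x, y[p])) >= obs - 1e-12, logical(1))
  mean(hits)
}

oracle_kw_H <- function(values, grp) {
  r <- rank(values)
  N <- length(values)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(seq_len(N), grp, function(ix)
      length(ix) * (mean(r[ix]) - (N + 1) / 2)^2))
  tt <- table(values)
  H / (1 - sum(tt^3 - tt) / (N^3 - N))
}

oracle_kw_exact_p <- function(groups) {
  values <- unlist(groups)
  grp <- rep(seq_along(groups), lengths(groups))
  obs <- oracle_kw_H(values, grp)
  perms <- oracle_perms(length(values))
  hits <- vapply(perms, function(p)
    oracle_kw_H(values[p], grp) >= obs - 1e-12, logical(1))
  mean(hits)
}

oracle_jt_stat <- function(values, grp) {
  jt <- 0
  k <- max(grp)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    xi <- values[grp == i]; xj <- values[grp == j]
    for (a in xi) for (b in xj)
      jt <- jt + (a < b) + 0.5 * (a == b)
  }
  jt
}

oracle_jt_exact_p <- function(groups) {
  values <- unlist(groups)
  grp <- rep(seq_along(groups), lengths(groups))
  obs <- oracle_jt_stat(values, grp)
  perms <- oracle_perms(length(values))
  hits <- vapply(perms, function(p)
    oracle_jt_stat(values[p], grp) >= obs - 1e-12, logical(1))
  mean(hits)
}

oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}

# minimal PDB writer for structure fixtures (built in code, text only)
write_tiny_pdb <- function(path, protein, ligand) {
  # protein/ligand: data.frames with x, y, z, resno (protein), elesy
  lines <- character()
  serial <- 1L
  for (i in seq_len(nrow(protein))) {
    lines <- c(lines, sprintf(
      "ATOM  %5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      serial, "CA", "ALA", protein$resno[i],
      protein$x[i], protein$y[i], protein$z[i], 1, 0, protein$elesy[i]))
    serial <- serial + 1L
  }
  for (i in seq_len(nrow(ligand))) {
    lines <- c(lines, sprintf(
      "HETATM%5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      serial, "C1", "LIG", 900L,
      ligand$x[i], ligand$y[i], ligand$z[i], 1, 0, ligand$elesy[i]))
    serial <- serial + 1L
  }
  writeLines(c(lines, "END"), path)
  path
}

# shared small training fixture: linear data in two blocks
make_linear_bundles <- function(n = 80, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * 5), n, 5)
  beta <- c(1.5, -2, 0.5, 3, -1)
  y <- drop(X %*% beta) + 0.3
  bundles <- lapply(seq_len(n), function(i)
    feature_bundle("p.A2V", "metformin",
                   list(embedding = X[i, 1:3], ligand = X[i, 4:5])))
  list(bundles = bundles, X = X, y = y, beta = beta)
}
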