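# shared fixtures built in code

# minimal 3-row raw survey CSV exercising numbers, ranges, symbols and blanks
write_tiny_survey_csv <- function(path) {
  df <- tibble::tibble(
    record_id = c("r1", "r2", "r3"),
    site_id = c("site01", "site01", "site07"),
    substrate = c("artificial", "artificial", "natural"),
    year = c(2004L, 2005L, 2004L),
    elevation_lwl_m = c(-2, -5, -3),
    slope_deg = c(45, 60, 30),
    method = c("quadrat", "spot_check", "manta"),
    total = c("10", "R", "20-30"),
    acropora = c("+", "0", "12"),
    pocillopora = c("R", "", "5"),
    montipora = c("4", "0", "+"),
    porites = c("3", "0", "2"),
    faviidae = c("0", "0", "R"),
    millepora = c("", "0", "0"),
    other_hard = c("0", "0", "1")
  )
  readr::write_csv(df, path, progress = FALSE)
  path
}

# random strictly-positive closed composition
random_composition <- function(n_parts, names = NULL) {
  x <- stats::rexp(n_parts) + 0.01
  x <- x / sum(x)
  if (!is.null(names)) names(x) <- names
  x
}

# fast block config for model tests: 6 years (108 quadrats)
small_block_cfg <- function(seed, ...) {
  block_sim_config(seed = seed, years = 1:6, ...)
}

# direct Gower-centering PERMANOVA oracle (one factor), with exhaustive
# permutation enumeration for tiny n
permanova_oracle <- function(d, group) {
  m <- as.matrix(d)
  n <- nrow(m)
  A <- -0.5 * m^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  ss_total <- sum(diag(G))
  pseudo_f_for <- function(g) {
    H <- model.matrix(~g)  # hat matrix of the one-factor model
    P <- H %*% solve(crossprod(H)) %*% t(H)
    ss_model <- sum(diag(P %*% G %*% P))
    df1 <- length(unique(g)) - 1
    df2 <- n - length(unique(g))
    (ss_model / df1) / ((ss_total - ss_model) / df2)
  }
  f_obs <- pseudo_f_for(factor(group))
  perms <- combinat_perms(n)
  f_perm <- apply(perms, 1, function(idx) pseudo_f_for(factor(group[idx])))
  list(pseudo_f = f_obs,
       p_exact = mean(f_perm >= f_obs - 1e-12),
       ss_total = ss_total)
}

# all permutations of 1..n (n <= 7)
combinat_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- combinat_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}
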