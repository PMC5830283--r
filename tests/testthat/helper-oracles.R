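# Brute-force oracles, independent of the package's quadrature path.

# dense-grid trapezoid marginal log-likelihood for a 2-D bank
trapezoidLoglik <- function(responses, bank, rho, lim = 6, npts = 201) {
  g <- seq(-lim, lim, length.out = npts)
  G <- as.matrix(expand.grid(g, g))
  h <- g[2L] - g[1L]
  pr <- exp(-(G[, 1]^2 + G[, 2]^2 - 2 * rho * G[, 1] * G[, 2]) /
              (2 * (1 - rho^2))) / (2 * pi * sqrt(1 - rho^2))
  tabs <- lapply(bank@items, PatternSeverity:::categoryProbMatrix, thetaMat = G)
  ll <- 0
  for (i in seq_len(nrow(responses))) {
    L <- pr
    for (j in seq_len(ncol(responses))) {
      x <- responses[i, j]
      if (!is.na(x)) L <- L * tabs[[j]][, x + 1L]
    }
    ll <- ll + log(sum(L) * h^2)
  }
  ll
}

# dense-grid posterior mean of theta for one respondent
trapezoidEap <- function(response, bank, rho, lim = 6, npts = 201) {
  g <- seq(-lim, lim, length.out = npts)
  G <- as.matrix(expand.grid(g, g))
  pr <- exp(-(G[, 1]^2 + G[, 2]^2 - 2 * rho * G[, 1] * G[, 2]) /
              (2 * (1 - rho^2))) / (2 * pi * sqrt(1 - rho^2))
  L <- pr
  for (j in seq_len(length(response))) {
    x <- response[j]
    if (!is.na(x))
      L <- L * PatternSeverity:::categoryProbMatrix(bank@items[[j]], G)[, x + 1L]
  }
  colSums(G * L) / sum(L)
}

# finite-difference directional item information
fdItemInformation <- function(item, theta, direction, h = 1e-5) {
  m <- length(item@d)
  total <- 0
  for (t in 0:m) {
    pp <- categoryProb(item, theta + h * direction, t)
    pm <- categoryProb(item, theta - h * direction, t)
    p0 <- categoryProb(item, theta, t)
    total <- total + ((pp - pm) / (2 * h))^2 / p0
  }
  total
}
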