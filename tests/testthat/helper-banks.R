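# Toy banks and fixtures built in code.

# two-factor bank with moderate boundaries: every category well populated
toyBank2D <- function(link = "probit") {
  mk <- function(id, a, d) itemParameters(id, a = a, d = d, link = link)
  itemBank(list(
    mk("t1", c(1.8, 0), c(1.2, 0, -1.2)),
    mk("t2", c(1.1, 0), c(1.5, 0.2, -1.0)),
    mk("t3", c(0, 2.0), c(1.0, -0.2, -1.4)),
    mk("t4", c(0, 0.9), c(0.8, -0.4, -1.6))),
    dimensionNames = c("f1", "f2"))
}

# three binary-ish items on two dimensions, for E-step oracle checks
toyBank3 <- function(link = "probit") {
  mk <- function(id, a, d) itemParameters(id, a = a, d = d, link = link)
  itemBank(list(
    mk("o1", c(1.5, 0), c(0.5, -0.8)),
    mk("o2", c(0.8, 0), c(0.2)),
    mk("o3", c(0, 1.2), c(0.9, -0.5))),
    dimensionNames = c("f1", "f2"))
}

# one-dimensional two-item binary bank for the grid-search oracle
toyBank1D <- function() {
  itemBank(list(
    itemParameters("u1", a = 1.2, d = 0.3),
    itemParameters("u2", a = 0.7, d = -0.4)),
    dimensionNames = "f")
}

publishedA <- c(2.03, 2.19, 1.29, 0.84, 1.12, 2.21, 1.48, 0.94, 0.98)
publishedD <- list(c(-0.15, -2.60, -5.39), c(-0.83, -3.10, -5.91),
                c(-0.39, -3.71, -4.65), c(-2.51, -4.78, -6.19),
                c(-1.10, -3.29, -5.78), c(-1.95, -5.66, -7.11),
                c(-0.95, -3.67, -5.59), c(-2.51, -5.19, -6.30),
                c(-0.49, -2.74, -3.88))
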