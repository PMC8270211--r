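# Independent oracles and fixture builders shared across tests.

# the four equally likely child genotypes given the parents (transmission
# combinations, duplicates kept)
pseudo_children <- function(gm, gf) {
  am <- c(floor(gm / 2), ceiling(gm / 2))   # mother's two alleles
  af <- c(floor(gf / 2), ceiling(gf / 2))
  as.vector(outer(am, af, "+"))
}

# generic conditional-logistic maximization over the pseudo-control
# likelihood, independent of the closed form: root of the score via
# uniroot, observed information for the standard error
clogit_oracle <- function(trios) {
  sets <- lapply(seq_len(nrow(trios)), function(i)
    pseudo_children(trios$g_mother[i], trios$g_father[i]))
  gc <- trios$g_child
  score <- function(b) {
    s <- 0
    for (i in seq_along(sets)) {
      w <- exp(b * sets[[i]])
      s <- s + gc[i] - sum(sets[[i]] * w) / sum(w)
    }
    s
  }
  info <- function(b) {
    v <- 0
    for (i in seq_along(sets)) {
      w <- exp(b * sets[[i]]); w <- w / sum(w)
      mu <- sum(sets[[i]] * w)
      v <- v + sum(sets[[i]]^2 * w) - mu^2
    }
    v
  }
  bhat <- uniroot(score, c(-8, 8), extendInt = "yes", tol = 1e-13)$root
  list(beta = bhat, se = 1 / sqrt(info(bhat)))
}

# unascertained random trios (parents HWE, child Mendelian), optionally
# guaranteed informative and non-degenerate
random_informative_trios <- function(n, maf) {
  repeat {
    gm <- rbinom(n, 2, maf); gf <- rbinom(n, 2, maf)
    gc <- rbinom(n, 1, gm / 2) + rbinom(n, 1, gf / 2)
    tr <- data.frame(g_child = gc, g_mother = gm, g_father = gf)
    cnt <- trioverlap:::.count_transmissions(tr)
    if (cnt$t > 0 && cnt$u > 0) return(tr)
  }
}

# reference quadrature for the normal product tail, independent of the
# package's series / Gauss-Laguerre implementation
npt_integrate <- function(u) {
  u <- abs(u)
  if (u == 0) return(1)
  f <- function(y) besselK(u + y, 0, expon.scaled = TRUE) * exp(-y)
  2 / pi * exp(-u) * integrate(f, 0, Inf, rel.tol = 1e-13, abs.tol = 0)$value
}

# frozen quadrature fixtures (verified against Monte Carlo during
# development; the MC cross-check is re-run in the acceptance suite)
NPT_FIXTURES <- c(`0.5` = 0.4097882041634011,
                  `1`   = 0.2089936630046523,
                  `2`   = 0.06182888947559226,
                  `5`   = 0.002170196102690330,
                  `12`  = 1.349728340800031e-6)
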