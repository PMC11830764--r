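# Independent brute-force / quadrature oracles. These deliberately avoid
# the package's code paths (and, where possible, the base functions the
# package itself calls).

# Pearson r from the raw sum formula.
oracle_pearson <- function(a, b) {
  n <- length(a)
  num <- n * sum(a * b) - sum(a) * sum(b)
  den <- sqrt((n * sum(a^2) - sum(a)^2) * (n * sum(b^2) - sum(b)^2))
  num / den
}

# Spearman rho as rank-then-Pearson with midranks.
oracle_spearman <- function(a, b) {
  oracle_pearson(rank(a, ties.method = "average"),
                 rank(b, ties.method = "average"))
}

# Benjamini-Hochberg q-values from the textbook step-up formula.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# Naive per-group code scores by explicit subsetting (no shared helpers).
oracle_code_score <- function(tab, code, scope = "participant") {
  if (code == "nonrotated_preceding_upcoming") {
    return(-oracle_code_score(tab, "rotated_preceding", scope))
  }
  if (scope == "participant") {
    keys <- unique(tab$participant)
    get <- function(k) tab[tab$participant == k, ]
  } else {
    keys <- unique(paste(tab$participant, tab$held_out))
    get <- function(k) {
      parts <- as.integer(strsplit(k, " ")[[1]])
      tab[tab$participant == parts[1] & tab$held_out == parts[2], ]
    }
  }
  vapply(keys, function(k) {
    s <- get(k)
    if (code == "schema") {
      mean(s$similarity[s$same_schema]) - mean(s$similarity[!s$same_schema])
    } else if (code == "path") {
      mean(s$similarity[s$path_relation == 1]) -
        mean(s$similarity[s$path_relation == 2])
    } else if (code == "current_ritual") {
      w <- s[s$stage_relation == "within", ]
      mean(w$similarity[w$same_ritual]) - mean(w$similarity[!w$same_ritual])
    } else if (code == "rotated_preceding") {
      a <- s[s$template_stage == 2 & s$heldout_stage == 3, ]
      b <- s[s$template_stage == 3 & s$heldout_stage == 2, ]
      d1 <- mean(a$similarity[!a$template_is_predecessor]) -
        mean(a$similarity[a$template_is_predecessor])
      d2 <- mean(b$similarity[!b$template_is_successor]) -
        mean(b$similarity[b$template_is_successor])
      (d1 + d2) / 2
    } else {
      stop("unknown code in oracle: ", code)
    }
  }, numeric(1))
}

# Gauss-Legendre nodes/weights by Golub-Welsch (no quadrature packages).
oracle_gauss_legendre <- function(n, a, b) {
  i <- seq_len(n - 1)
  off <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- off
  J[cbind(i + 1, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  list(x = (b - a) / 2 * x + (a + b) / 2, w = (b - a) / 2 * w)
}

# JZS BF-01 by fixed Gauss-Legendre quadrature after the substitution
# delta = r * tan(phi) (so the Cauchy prior becomes uniform in phi).
oracle_jzs_bf01 <- function(t, n, tail = "two_sided", r = 0.707) {
  nu <- n - 1
  f <- function(phi) {
    suppressWarnings(stats::dt(t, df = nu, ncp = sqrt(n) * r * tan(phi)))
  }
  if (tail == "greater") {
    gl <- oracle_gauss_legendre(400, 0, pi / 2 - 1e-12)
    m1 <- (2 / pi) * sum(gl$w * vapply(gl$x, f, numeric(1)))
  } else {
    gl <- oracle_gauss_legendre(400, -pi / 2 + 1e-12, pi / 2 - 1e-12)
    m1 <- (1 / pi) * sum(gl$w * vapply(gl$x, f, numeric(1)))
  }
  stats::dt(t, df = nu) / m1
}
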