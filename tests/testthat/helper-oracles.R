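# Independent brute-force oracles used to cross-check the agreement and
# regression statistics. Deliberately avoid lm/t.test/cor.test: normal
# equations, explicit average ranks, closed-form t.

ols_oracle <- function(y, X) {
  X <- cbind(1, as.matrix(X))
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  n <- length(y); p <- ncol(X) - 1
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  list(beta = drop(beta),
       sigma = sqrt(rss / (n - p - 1)),
       r2_adjusted = 1 - (1 - r2) * (n - 1) / (n - p - 1))
}

# average ranks by explicit sorting (ties get the mean of their positions)
rank_oracle <- function(x) {
  ord <- order(x)
  r <- numeric(length(x))
  i <- 1
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && x[ord[j + 1]] == x[ord[i]]) j <- j + 1
    r[ord[i:j]] <- mean(i:j)
    i <- j + 1
  }
  r
}

spearman_oracle <- function(a, b) {
  ra <- rank_oracle(a); rb <- rank_oracle(b)
  num <- sum((ra - mean(ra)) * (rb - mean(rb)))
  den <- sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  num / den
}

paired_t_oracle <- function(d) {
  n <- length(d)
  se <- sqrt(sum((d - mean(d))^2) / (n - 1)) / sqrt(n)
  tstat <- mean(d) / se
  q <- qt(0.975, n - 1)
  list(mean = mean(d),
       ci = c(mean(d) - q * se, mean(d) + q * se),
       p = 2 * pt(-abs(tstat), n - 1))
}

sd_oracle <- function(x) sqrt(sum((x - mean(x))^2) / (length(x) - 1))

# a tiny valid record table used across tests
fixture_records <- function() {
  test_records(tibble::tibble(
    id = c("a", "b", "c"),
    sex = c("male", "female", "male"),
    age = c(40, 40, 55),
    body_mass = c(80, 64, 75),
    po_standard = 30,
    po_high = c(150, 150, 130),
    hr_standard = c(90, 90, 95),
    hr_high = c(150, 150, 145)
  ))
}
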