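# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: manual trapezoid sums, the projection form of the
# receptor-noise quadratic, and full outcome enumeration for the binomial.

# manual trapezoid rule
trapz_oracle <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# General receptor-noise chromatic distance as a quadratic form: the
# Mahalanobis distance of the receptor contrast vector within the
# achromatic-invariant subspace, M = W^-1 - W^-1 1 1' W^-1 / (1' W^-1 1),
# W = diag(omega^2). Equivalent to the published closed forms for n = 2, 3
# but derived and coded independently of them.
rnl_quadratic_oracle <- function(delta_f, omega) {
  a <- 1 / omega^2
  M <- diag(a) - outer(a, a) / sum(a)
  sqrt(drop(t(delta_f) %*% M %*% delta_f))
}

# Two-sided exact binomial p by brute enumeration of all 2^n outcome
# sequences (n <= 12): mass of every sequence whose success-count point
# probability does not exceed the observed one (with float-tie tolerance).
binom_enum_oracle <- function(successes, n, p0 = 0.5) {
  seqs <- as.matrix(expand.grid(rep(list(0:1), n)))
  k <- rowSums(seqs)
  pr <- p0^k * (1 - p0)^(n - k)
  count_mass <- tapply(pr, k, sum)
  obs_mass <- count_mass[[as.character(successes)]]
  sum(pr[count_mass[as.character(k)] <= obs_mass * (1 + 1e-7)])
}

# a flat-spectrum cone catch record (catches all equal to c)
flat_record <- function(c, system, id = "flat") {
  cone_catch_record(id, stats::setNames(rep(c, length(system$channel_names)),
                                        system$channel_names))
}

# small record factory
rec <- function(..., id = "r", system = NULL) {
  q <- c(...)
  if (!is.null(system)) names(q) <- system$channel_names
  cone_catch_record(id, q)
}
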