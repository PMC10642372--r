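# shared fixtures and independent oracles, built in code at test time

# small two-chromosome arm map for constructed-profile tests
mini_arm_map <- function() {
  data.frame(chrom = c("chr8", "chr8", "chr13", "chr17"),
             arm = c("8p", "8q", "13q", "17p"),
             start = c(0, 50e6, 20e6, 0),
             end = c(50e6, 150e6, 100e6, 25e6))
}

# profile with a prescribed number of gain/loss/normal bins per arm
mini_profile <- function(sample_id, arm_calls, map = mini_arm_map(),
                         n_bins = 10) {
  rows <- list()
  for (a in names(arm_calls)) {
    i <- match(a, map$arm)
    width <- (map$end[i] - map$start[i]) / n_bins
    starts <- map$start[i] + (seq_len(n_bins) - 1) * width
    calls <- arm_calls[[a]]
    stopifnot(length(calls) == n_bins)
    rows[[a]] <- data.frame(chrom = map$chrom[i], start = starts,
                            end = starts + width, call = calls)
  }
  bins <- do.call(rbind, rows)
  bins$log2ratio <- c(gain = 0.58, loss = -1, normal = 0)[bins$call]
  cn_profile(sample_id, bins)
}

# independent conditional-likelihood oracle: per set, enumerate every
# within-set case relabeling to form the conditional probability directly,
# with no numerical stabilisation
enum_loglik <- function(beta, data, xcols) {
  ll <- 0
  for (s in unique(data$set)) {
    d <- data[data$set == s, , drop = FALSE]
    X <- as.matrix(d[, xcols, drop = FALSE])
    score <- as.numeric(exp(X %*% beta))
    denom <- 0
    for (j in seq_len(nrow(d))) denom <- denom + score[j]
    ll <- ll + log(score[d$case] / denom)
  }
  ll
}

# random matched instance with continuous + binary covariates
random_matched_instance <- function(n_sets, size = 3, seed) {
  set.seed(seed)
  data.frame(
    set = rep(sprintf("s%03d", seq_len(n_sets)), each = size),
    case = as.vector(replicate(n_sets, sample(seq_len(size)) == 1L)),
    x1 = rnorm(n_sets * size),
    x2 = rbinom(n_sets * size, 1, 0.4)
  )
}

# central finite differences of a scalar function
fd_gradient <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}
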