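## brute-force Shannon MI over an explicit joint table (independent oracle)
brute_force_mi <- function(s, r) {
  tab <- table(s, r)
  n <- sum(tab)
  p <- tab / n
  ps <- rowSums(p)
  pr <- colSums(p)
  total <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    if (p[i, j] > 0) total <- total + p[i, j] * log2(p[i, j] / (ps[i] * pr[j]))
  }
  total
}

## a small synthetic session shared across tests
small_session <- function(n_trials = 12, n_astro = 4, n_neuron = 4,
                          seed = 42, ...) {
  cfg <- synth_config(n_trials = n_trials, seed = seed)
  tun <- make_tuning(n_astro_soma = n_astro, n_astro_process = 0,
                     n_neuron = n_neuron, config = cfg, seed = seed + 1)
  simulate_session(cfg, tun, ...)
}

## exact conditionally independent pair: empirical joint counts are the
## product of the empirical marginals within every stimulus bin
exact_cond_indep_pair <- function(n_s = 4, counts1 = c(3, 5), counts2 = c(4, 2)) {
  s <- integer(0); r1 <- integer(0); r2 <- integer(0)
  for (k in seq_len(n_s)) {
    c1 <- counts1 + k          # vary marginals across stimuli
    c2 <- rev(counts2) + k
    for (a in seq_along(c1)) for (b in seq_along(c2)) {
      m <- c1[a] * c2[b]
      s <- c(s, rep(k, m)); r1 <- c(r1, rep(a, m)); r2 <- c(r2, rep(b, m))
    }
  }
  list(s = s, r1 = r1, r2 = r2)
}

## one-hot separable population dataset for decoder sanity checks
onehot_dataset <- function(G, reps = 40, noise = 0.01, seed = 1,
                           informative = TRUE) {
  set.seed(seed)
  y <- sample(rep(seq_len(G), each = reps))
  X <- matrix(0, length(y), G)
  if (informative) X[cbind(seq_along(y), y)] <- 1
  X <- X + matrix(stats::rnorm(length(X), 0, noise), nrow(X))
  list(X = X, y = y, G = G)
}

running_frames <- function(trajectory, trials) {
  unlist(lapply(seq_len(nrow(trials)),
                function(i) trials$start[i]:trials$end[i]), use.names = FALSE)
}
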