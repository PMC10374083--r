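# Shared fixtures: the canonical illustration regimes and a deterministic
# grid of random compositions used by the oracle-equivalence tests.

p_default <- selection_params(s = -0.01, eps_w = 1e-3, eps_b = -1e-4)
p_s1 <- selection_params(s = 0, eps_w = 1e-3, eps_b = -1e-4)

# random (comp, b) grid with b <= 40, x <= 30, reproducible
random_composition_grid <- function(n, seed = 20260925) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    b <- sample(5:40, 1)
    x_B_max <- min(b, 15)
    x_anc <- sample(0:x_B_max, 1)
    x_rep <- sample(0:(x_B_max - x_anc), 1)
    x_new <- sample(0:(30 - min(30, x_anc + x_rep)), 1)
    list(comp = haplotype_composition(x_new, x_anc, x_rep), b = b)
  })
}

random_params <- function(seed = 1, max_effect = 1e-3) {
  set.seed(seed)
  selection_params(s = stats::runif(1, -max_effect, max_effect),
                   eps_w = stats::runif(1, 0, max_effect),
                   eps_b = stats::runif(1, -max_effect, 0))
}

# factor-count bound for the exact-vs-approx comparison: total number of
# direct plus pairwise factors entering carrier and resident fitness
n_terms_haploid <- function(comp, b) {
  n_carrier <- (comp$x_A + b - comp$x_B) +
    choose(comp$x_A, 2) + choose(b - comp$x_B, 2) +
    comp$x_A * (b - comp$x_B)
  n_resident <- b + choose(b, 2)
  n_carrier + n_resident
}
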