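# Independent oracles and small fixture builders used across the suite.

# Exact Shapley values by subset enumeration (coalitional definition),
# for a deterministic value function with a single fixed background row.
exact_shapley <- function(f, x, bg_row) {
  M <- length(x)
  v <- function(S) {
    z <- bg_row
    z[S] <- x[S]
    f(matrix(z, nrow = 1))
  }
  all_subsets <- function(set) {
    if (!length(set)) return(list(integer(0)))
    unlist(lapply(0:length(set), function(k)
      utils::combn(set, k, simplify = FALSE)), recursive = FALSE)
  }
  phi <- numeric(M)
  for (i in seq_len(M)) {
    for (S in all_subsets(setdiff(seq_len(M), i))) {
      w <- factorial(length(S)) * factorial(M - length(S) - 1) /
        factorial(M)
      phi[i] <- phi[i] + w * (v(c(S, i)) - v(S))
    }
  }
  phi
}

# Brute-force NSGA-II selection: repeated peeling of the non-dominated set
# plus direct crowding-distance computation on the split front.
brute_nsga_select <- function(M, k) {
  n <- nrow(M)
  remaining <- seq_len(n)
  sel <- integer(0)
  dominates <- function(i, j) all(M[i, ] <= M[j, ]) && any(M[i, ] < M[j, ])
  while (length(sel) < k) {
    nd <- remaining[vapply(remaining, function(i)
      !any(vapply(remaining, function(j) j != i && dominates(j, i),
                  logical(1))), logical(1))]
    if (length(sel) + length(nd) <= k) {
      sel <- c(sel, nd)
      remaining <- setdiff(remaining, nd)
    } else {
      Mf <- M[nd, , drop = FALSE]
      nf <- nrow(Mf)
      cd <- numeric(nf)
      if (nf <= 2) cd[] <- Inf
      else for (c in seq_len(ncol(Mf))) {
        o <- order(Mf[, c])
        rng <- Mf[o[nf], c] - Mf[o[1], c]
        cd[o[c(1, nf)]] <- Inf
        if (rng > 0) for (i in 2:(nf - 1))
          cd[o[i]] <- cd[o[i]] + (Mf[o[i + 1], c] - Mf[o[i - 1], c]) / rng
      }
      sel <- c(sel, nd[order(-cd)][seq_len(k - length(sel))])
    }
  }
  sort(sel)
}

# Wrap a raw 5-objective matrix (already on the maximization scale used by
# individuals) into evaluated GA individuals.
population_from_objectives <- function(obj) {
  lapply(seq_len(nrow(obj)), function(i) {
    ind <- wormtox:::new_individual(rep(TRUE, 3))
    ind$objectives <- c(mcc_train = obj[i, 1], mcc_val = obj[i, 2],
                        bs_train = obj[i, 3], bs_val = obj[i, 4],
                        penalty = obj[i, 5])
    ind
  })
}

# Small labelled descriptor matrix with one perfectly separating
# descriptor plus noise.
toy_separable_dm <- function(n_per_class = 10, n_noise = 2, seed = 1,
                             gap = 1) {
  withr::local_seed(seed)
  n <- 2 * n_per_class
  x1 <- c(stats::runif(n_per_class, gap, gap + 1),
          stats::runif(n_per_class, -gap - 1, -gap))
  noise <- matrix(stats::rnorm(n * n_noise), n, n_noise)
  x <- cbind(x1, noise)
  colnames(x) <- c("sep", paste0("nz", seq_len(n_noise)))
  descriptor_matrix(x, labels = rep(c("toxic", "nontoxic"),
                                    each = n_per_class))
}

# XOR-structured data: the class is predictable only from the pair.
toy_xor_dm <- function(n = 200, seed = 1) {
  withr::local_seed(seed)
  a <- stats::rbinom(n, 1, 0.5)
  b <- stats::rbinom(n, 1, 0.5)
  y <- xor(a == 1, b == 1)
  x <- cbind(x1 = a + stats::rnorm(n, 0, 0.1),
             x2 = b + stats::rnorm(n, 0, 0.1))
  descriptor_matrix(x, labels = ifelse(y, "toxic", "nontoxic"))
}

# A small synthetic benchmark reused by the model-level unit tests.
small_benchmark <- function(seed = 7) {
  generate_dataset(synthetic_config(
    n_compounds = 200, n_descriptors = 30, n_informative = 4,
    n_nonlinear = 1, correlated_block_size = 4, n_constant = 2,
    toxic_fraction = 0.7, seed = seed))
}
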