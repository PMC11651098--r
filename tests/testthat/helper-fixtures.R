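# small deterministic fixtures and independent oracles used across tests

toy_table <- function(counts, genus = NULL, microcosms = NULL, cycle = NULL) {
  abundance_table(as.matrix(counts), genus = genus, microcosms = microcosms,
                  cycle = cycle)
}

# a hand-built two-genus pool with unit capacity factors, so closed-form
# expectations hold exactly
flat_pool <- function(fitness = c(0, 0), genus = c("gA", "gB"),
                      antagonism = 0, self_limitation = 0) {
  n <- length(fitness)
  structure(list(genus = genus, abundance = rep(1 / n, n), fitness = fitness,
                 yield = rep(2e-8, n), cue = rep(0.25, n), kmod = rep(1, n),
                 antagonism = matrix(antagonism, n, n) - diag(rep(antagonism, n)),
                 self_limitation = self_limitation, config = NULL),
            class = "regional_pool")
}

# independent Bray-Curtis (hand formula, no vegan)
bc_hand <- function(x, y) 1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))

# ---------------------------------------------------------------------------
# brute-force enumeration of the Raup-Crick null for one community:
# richness-preserving taxon draw weighted by occupancy (sequential sampling
# without replacement), one individual per drawn taxon, remaining individuals
# multinomial with probability proportional to regional relative abundance of
# the drawn taxa. Returns a list(counts = matrix, prob = vector).

enumerate_subsets <- function(weights, r) {
  n <- length(weights)
  acc <- list()
  rec <- function(chosen, remaining, prob) {
    if (length(chosen) == r) {
      key <- paste(sort(chosen), collapse = ",")
      acc[[key]] <<- (if (is.null(acc[[key]])) 0 else acc[[key]]) + prob
      return(invisible())
    }
    for (i in remaining) {
      w <- weights[i] / sum(weights[remaining])
      rec(c(chosen, i), setdiff(remaining, i), prob * w)
    }
  }
  rec(integer(0), which(weights > 0), 1)
  list(subset = lapply(names(acc), function(k) as.integer(strsplit(k, ",")[[1]])),
       prob = as.numeric(unlist(acc)))
}

compositions_of <- function(total, parts) {
  if (parts == 1) return(matrix(total, 1, 1))
  out <- NULL
  for (first in 0:total) {
    rest <- compositions_of(total - first, parts - 1)
    out <- rbind(out, cbind(first, rest))
  }
  unname(out)
}

enumerate_null_community <- function(rich, total, occupancy, regional) {
  subs <- enumerate_subsets(occupancy, rich)
  n_tax <- length(occupancy)
  counts <- NULL
  probs <- NULL
  for (k in seq_along(subs$subset)) {
    S <- subs$subset[[k]]
    pS <- subs$prob[k]
    extra <- total - rich
    comps <- compositions_of(extra, length(S))
    pr <- regional[S] / sum(regional[S])
    for (ci in seq_len(nrow(comps))) {
      v <- numeric(n_tax)
      v[S] <- 1 + comps[ci, ]
      counts <- rbind(counts, v)
      probs <- c(probs, pS * stats::dmultinom(comps[ci, ], prob = pr))
    }
  }
  list(counts = counts, prob = probs)
}

# exact null Bray-Curtis distribution (atoms + probabilities) for a
# two-community instance
enumerate_null_bc <- function(m) {
  occupancy <- rowSums(m > 0)
  regional <- rowSums(m) / sum(m)
  rich <- colSums(m > 0)
  totals <- colSums(m)
  c1 <- enumerate_null_community(rich[1], totals[1], occupancy, regional)
  c2 <- enumerate_null_community(rich[2], totals[2], occupancy, regional)
  vals <- numeric(0)
  prbs <- numeric(0)
  for (i in seq_along(c1$prob)) {
    for (j in seq_along(c2$prob)) {
      vals <- c(vals, bc_hand(c1$counts[i, ], c2$counts[j, ]))
      prbs <- c(prbs, c1$prob[i] * c2$prob[j])
    }
  }
  key <- round(vals, 12)
  agg <- tapply(prbs, key, sum)
  atoms <- as.numeric(names(agg))
  ord <- order(atoms)
  list(atoms = atoms[ord], prob = as.numeric(agg)[ord])
}
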