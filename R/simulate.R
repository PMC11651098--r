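#' Configuration for a simulated metacommunity experiment
#'
#' Bundles every knob of the simulator: the regional pool, the
#' dispersal-limited colonisation, the semi-continuous growth cycles and the
#' final homogenizing-dispersal (coalescence) event. Defaults emulate the
#' design of a 20-microcosm freshwater experiment: ~100 genera, six 1:10
#' transfer cycles, read depths near a 2,911-read rarefaction floor.
#'
#' @param n_genera Number of genera in the regional pool (default 120,
#'   matching the genus count observed in comparable freshwater microcosm
#'   metacommunities).
#' @param n_microcosms Number of replicate microcosms (default 20).
#' @param inoculum_cells Cells seeded per microcosm at colonisation. This is
#'   a free parameter of the design (inoculum cell numbers are rarely
#'   reported); the default (5e4, i.e. 1/200 of the carrying capacity) is
#'   small enough that rare genera are dispersal-limited while common ones
#'   reach every microcosm.
#' @param dilution Fraction of each culture transferred to fresh medium
#'   (default 0.1, a 1:10 transfer).
#' @param n_cycles Number of semi-continuous growth cycles after C0
#'   (default 6).
#' @param carrying_capacity Baseline stationary-phase population per microcosm
#'   (cells; default 1e7). The realised capacity is modulated by the
#'   genus-specific capacity factors of the resident community.
#' @param fitness_sd Standard deviation of per-genus log growth-rate
#'   differences, per generation (default 0.3). Within a cycle the growth
#'   advantage compounds over the `log(capacity / inoculum)` e-folds of
#'   population growth.
#' @param interaction_strength Scale of the pairwise antagonism matrix
#'   (default 0.1); 0 switches interactions off.
#' @param self_limitation Strength of intraspecific density dependence
#'   (default 1.4), entering the growth exponent as `self_limitation *
#'   sqrt(p)` for a genus at frequency `p`. Intraspecific competition
#'   exceeding interspecific competition stabilises coexistence, so local
#'   richness declines gradually instead of collapsing to monocultures; the
#'   square-root form lets dominants emerge while protecting the rare tail.
#' @param fitness_abundance_cor Correlation between log-fitness and log
#'   regional abundance (default -0.6): the strongest growers on the supplied
#'   substrate are rare in the source pool (rare-biosphere bloomers), which
#'   makes their colonisation of individual microcosms stochastic and drives
#'   the divergence of dominants under dispersal limitation.
#' @param founder_sd Standard deviation of the priority (founder) effect:
#'   each genus's realised per-generation fitness in a microcosm deviates
#'   from its pool value by a fixed microcosm-specific offset drawn at
#'   colonisation (default 0.45). It stands for colonisation contingency --
#'   which genotype or micro-colony establishes first when a handful of
#'   cells seed a sterile flask -- and it is what lets replicate microcosms
#'   diverge and lock into distinct community types under identical
#'   conditions. The offsets persist through transfers (the established
#'   community re-seeds itself) but not through the coalescence event: a
#'   dense, well-mixed inoculum leaves no room for colonisation contingency,
#'   so the post-coalescence cycle sorts on pool fitness alone.
#' @param turnover_efolds Additional e-folds of selection per cycle from
#'   stationary-phase turnover (default 0, i.e. selection only during net
#'   growth): after reaching carrying capacity a community keeps cycling
#'   biomass for the rest of the incubation, so positive values add
#'   post-growth selection.
#' @param read_depth Reads drawn per microcosm when emulating 16S read counts
#'   (default 3000, just above the 2,911 rarefaction floor used downstream).
#' @param abundance_sdlog sdlog of the lognormal regional abundance
#'   distribution (default 1).
#' @param yield_c Mean carbon yield per cell (ug C; default 2e-8).
#' @param cue_base Baseline genus-level carbon use efficiency (default 0.2).
#' @param cue_fitness_link Slope tying a genus's logit-CUE to its
#'   per-generation log-fitness (default 4): competitive sorting then drags
#'   community CUE upward across cycles, as observed in serial-transfer
#'   microcosms.
#' @param seed Integer seed; the whole experiment is reproducible from it.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genera = 120, n_microcosms = 20, inoculum_cells = 5e4,
                       dilution = 0.1, n_cycles = 6, carrying_capacity = 1e7,
                       fitness_sd = 0.3, interaction_strength = 0.1, self_limitation = 1.4,
                       fitness_abundance_cor = -0.6, founder_sd = 0.45, turnover_efolds = 0,
                       read_depth = 3000, abundance_sdlog = 1,
                       yield_c = 2e-8, cue_base = 0.2, cue_fitness_link = 4,
                       seed = NULL) {
  cfg <- list(n_genera = n_genera, n_microcosms = n_microcosms,
              inoculum_cells = inoculum_cells, dilution = dilution,
              n_cycles = n_cycles, carrying_capacity = carrying_capacity,
              fitness_sd = fitness_sd, interaction_strength = interaction_strength,
              self_limitation = self_limitation,
              fitness_abundance_cor = fitness_abundance_cor,
              founder_sd = founder_sd, turnover_efolds = turnover_efolds,
              read_depth = read_depth, abundance_sdlog = abundance_sdlog,
              yield_c = yield_c, cue_base = cue_base,
              cue_fitness_link = cue_fitness_link, seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  num_pos <- c("n_genera", "n_microcosms", "inoculum_cells", "carrying_capacity",
               "read_depth", "yield_c")
  for (f in num_pos) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("invalid config: `", f, "` must be a positive number", call. = FALSE)
    }
  }
  if (cfg$n_genera < 1) stop("invalid config: n_genera must be >= 1", call. = FALSE)
  if (cfg$dilution <= 0 || cfg$dilution >= 1) {
    stop("invalid config: `dilution` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (cfg$n_cycles < 0) stop("invalid config: `n_cycles` must be >= 0", call. = FALSE)
  if (cfg$fitness_sd < 0 || cfg$interaction_strength < 0 ||
      (cfg$self_limitation %||% 0) < 0) {
    stop("invalid config: spreads must be non-negative", call. = FALSE)
  }
  if (abs(cfg$fitness_abundance_cor %||% 0) > 1) {
    stop("invalid config: `fitness_abundance_cor` must lie in [-1, 1]", call. = FALSE)
  }
  if ((cfg$founder_sd %||% 0) < 0 || (cfg$turnover_efolds %||% 0) < 0) {
    stop("invalid config: `founder_sd` and `turnover_efolds` must be non-negative",
         call. = FALSE)
  }
  invisible(cfg)
}

#' Generate a regional species pool
#'
#' Emulates the prefiltered lake-water inoculum: lognormal regional relative
#' abundances, per-genus log-fitness, genus-level carbon traits (yield, CUE,
#' capacity factor) and an optional pairwise antagonism matrix.
#'
#' @param config A [sim_config()].
#' @return A list of class `regional_pool` with elements `genus`, `abundance`
#'   (sums to 1), `fitness`, `yield`, `cue`, `kmod` and `antagonism` (square,
#'   zero diagonal).
#' @export
generate_pool <- function(config) {
  validate_sim_config(config)
  if (config$n_genera < 2) stop("invalid config: n_genera must be >= 2 for a pool", call. = FALSE)
  draw <- function() {
    n <- config$n_genera
    genus <- sprintf("g%03d", seq_len(n))
    lab <- stats::rnorm(n, 0, config$abundance_sdlog)
    ab <- exp(lab)
    ab <- ab / sum(ab)
    # rare-biosphere bloomers: log-fitness anticorrelated with log abundance
    rho <- config$fitness_abundance_cor %||% 0
    z <- if (config$abundance_sdlog > 0) lab / config$abundance_sdlog else numeric(n)
    fitness <- config$fitness_sd * (rho * z + sqrt(1 - rho^2) * stats::rnorm(n))
    yield <- config$yield_c * stats::rlnorm(n, 0, 0.2)
    cue <- stats::plogis(stats::qlogis(config$cue_base) +
                           config$cue_fitness_link * fitness + stats::rnorm(n, 0, 0.3))
    kmod <- stats::rlnorm(n, 0, 0.3)
    A <- matrix(stats::runif(n * n, 0, 2 * config$interaction_strength), n, n)
    diag(A) <- 0
    structure(list(genus = genus, abundance = ab, fitness = fitness,
                   yield = yield, cue = cue, kmod = kmod, antagonism = A,
                   self_limitation = config$self_limitation %||% 0,
                   config = config),
              class = "regional_pool")
  }
  if (!is.null(config$seed)) withr::with_seed(config$seed, draw()) else draw()
}

#' @export
print.regional_pool <- function(x, ...) {
  cat("<regional_pool>", length(x$genus), "genera; top regional share",
      sprintf("%.3f", max(x$abundance)), "\n")
  invisible(x)
}

#' Dispersal-limited colonisation of sterile microcosms
#'
#' Each microcosm receives an independent multinomial draw of
#' `inoculum_cells` cells from the regional relative abundances. Small
#' inocula leave rare genera behind in most microcosms, which is exactly the
#' dispersal limitation the design aims for.
#'
#' @param pool A `regional_pool`.
#' @param config A [sim_config()].
#' @return An abundance table (cells, cycle attribute unset) with one column
#'   per microcosm.
#' @export
colonize <- function(pool, config) {
  stopifnot(inherits(pool, "regional_pool"))
  validate_sim_config(config)
  if (config$inoculum_cells < 1) stop("invalid config: inoculum_cells must be >= 1", call. = FALSE)
  counts <- stats::rmultinom(config$n_microcosms, size = round(config$inoculum_cells),
                             prob = pool$abundance)
  colnames(counts) <- sprintf("m%02d", seq_len(config$n_microcosms))
  abundance_table(counts, genus = pool$genus)
}

#' One semi-continuous growth-and-transfer cycle
#'
#' Deterministic within-cycle growth followed by a stochastic transfer. Each
#' genus's cells are multiplied by `exp((fitness - antagonism pressure) * G)`,
#' where `G = log(carrying_capacity / inoculated cells)` is the number of
#' e-folds of population growth in the cycle (relative fitness acts per
#' generation, so a cycle starting from a small inoculum sorts more strongly);
#' the community is then renormalised to its realised carrying capacity, and a fixed
#' transfer volume (`dilution` of the culture) is drawn as a multinomial
#' sample of cells. Microcosms with no cells stay empty: there is no dispersal
#' between microcosms. Bulk measurements (cells, biomass-C produced,
#' substrate-C consumed, CUE) are computed from the realised growth.
#'
#' @param table Abundance table of inoculated cells (start of the cycle).
#' @param pool The `regional_pool` the experiment was seeded from.
#' @param config A [sim_config()].
#' @param fitness_offset Optional genus x microcosm matrix of founder-effect
#'   fitness offsets (default 0; see [sim_config()]).
#' @return A list with `table` (cells transferred to the next cycle), `grown`
#'   (the stationary-phase community that was sampled and measured) and `bulk`
#'   (a tibble: microcosm, cells, biomass_c, substrate_c, cue).
#' @export
grow_transfer_cycle <- function(table, pool, config, fitness_offset = NULL) {
  stopifnot(inherits(pool, "regional_pool"))
  validate_sim_config(config)
  m <- count_matrix(table)
  if (!identical(rownames(m), pool$genus)) stop("table and pool genus universes differ", call. = FALSE)
  if (is.null(fitness_offset)) fitness_offset <- matrix(0, nrow(m), ncol(m))
  grown <- m * 0
  out <- m * 0
  bulk <- vector("list", ncol(m))
  for (j in seq_len(ncol(m))) {
    cells <- m[, j]
    tot <- sum(cells)
    if (tot == 0) {
      bulk[[j]] <- tibble::tibble(microcosm = colnames(m)[j], cells = 0,
                                  biomass_c = 0, substrate_c = 0, cue = NA_real_)
      next
    }
    p <- cells / tot
    pressure <- as.numeric(pool$antagonism %*% p) +
      (pool$self_limitation %||% 0) * sqrt(p)
    # growth advantages compound over the cycle's e-folds of population growth
    efolds <- max(log(config$carrying_capacity / tot), 0) +
      (config$turnover_efolds %||% 0)
    w <- cells * exp((pool$fitness + fitness_offset[, j] - pressure) * efolds)
    cap <- config$carrying_capacity * sum((w / sum(w)) * pool$kmod)
    grown_j <- w / sum(w) * cap
    produced <- pmax(grown_j - cells, 0)
    biomass <- sum(produced * pool$yield)
    consumed <- sum(produced * pool$yield / pool$cue) * exp(stats::rnorm(1, 0, 0.05))
    grown[, j] <- grown_j
    n_keep <- round(cap * config$dilution)
    out[, j] <- stats::rmultinom(1, size = n_keep, prob = grown_j)
    bulk[[j]] <- tibble::tibble(microcosm = colnames(m)[j], cells = cap,
                                biomass_c = biomass, substrate_c = consumed,
                                cue = if (consumed > 0) biomass / consumed else NA_real_)
  }
  list(table = abundance_table(out, genus = pool$genus),
       grown = abundance_table(round(grown), genus = pool$genus),
       bulk = dplyr::bind_rows(bulk))
}

#' Homogenizing dispersal: pool, dilute, redistribute
#'
#' All source microcosms are mixed at equal volume (the pooled count of a
#' genus is the exact sum of its counts across microcosms), then each new
#' microcosm receives an independent multinomial inoculum from the pooled
#' composition at transfer scale.
#'
#' @param table Abundance table whose microcosm columns are the communities to
#'   merge (at least 2).
#' @param config A [sim_config()]; `n_microcosms` new microcosms are seeded
#'   with `round(carrying_capacity * dilution)` cells each.
#' @return An abundance table of the freshly seeded microcosms; the exact
#'   pooled counts are attached as attribute `"pooled"`.
#' @export
coalesce <- function(table, config) {
  validate_sim_config(config)
  m <- count_matrix(table)
  if (ncol(m) < 2L) stop("coalescence needs at least 2 source microcosms", call. = FALSE)
  pooled <- rowSums(m)
  if (sum(pooled) == 0) stop("empty pool: all source microcosms are empty", call. = FALSE)
  size <- round(config$carrying_capacity * config$dilution)
  counts <- stats::rmultinom(config$n_microcosms, size = size, prob = pooled)
  colnames(counts) <- sprintf("m%02d", seq_len(config$n_microcosms))
  res <- abundance_table(counts, genus = rownames(m))
  attr(res, "pooled") <- pooled
  res
}

#' Emulate 16S read sampling from cell counts
#'
#' Per microcosm, a multinomial sample of `read_depth` reads is drawn from the
#' cell proportions, emulating shotgun-derived 16S read counts at a fixed
#' sequencing effort.
#'
#' @param table Abundance table of cells.
#' @param read_depth Reads per microcosm (>= 1).
#' @param seed Optional seed for this draw alone.
#' @return An abundance table of read counts; microcosms with zero cells get
#'   zero reads and are flagged in attribute `"empty_microcosms"` (with a
#'   warning).
#' @export
sample_reads <- function(table, read_depth, seed = NULL) {
  if (!is.numeric(read_depth) || read_depth < 1) stop("read_depth must be >= 1", call. = FALSE)
  m <- count_matrix(table)
  draw <- function() {
    out <- m * 0
    for (j in seq_len(ncol(m))) {
      if (sum(m[, j]) == 0) next
      out[, j] <- stats::rmultinom(1, size = round(read_depth), prob = m[, j])
    }
    out
  }
  out <- if (!is.null(seed)) withr::with_seed(seed, draw()) else draw()
  empty <- colnames(m)[colSums(m) == 0]
  if (length(empty) > 0) warning("zero-cell microcosm(s) yield zero reads: ",
                                 paste(empty, collapse = ", "))
  res <- abundance_table(out, genus = rownames(m))
  attr(res, "cycle") <- attr(table, "cycle")
  attr(res, "empty_microcosms") <- empty
  res
}

#' Simulate a full dispersal-manipulation experiment
#'
#' Runs colonisation, `n_cycles + 1` growth cycles (C0..Cn), the coalescence
#' event and one post-coalescence growth cycle, read-sampling every cycle's
#' community. The whole run is reproducible from `config$seed`: a single RNG
#' stream is seeded once and consumed by the sub-operations in order.
#'
#' @param config A [sim_config()].
#' @return An object of class `melo_experiment`: list with `tables` (named
#'   list of read-count abundance tables, `C0` .. `C<n>` plus the
#'   post-coalescence cycle), `cells` (the matching stationary-phase cell
#'   tables), `bulk` (one tibble across cycles), `pool`, and `config`.
#' @export
simulate_experiment <- function(config) {
  validate_sim_config(config)
  run <- function() {
    cfg <- config
    cfg$seed <- NULL
    pool <- generate_pool(cfg)
    state <- colonize(pool, cfg)
    # founder-effect offsets: fixed per genus and microcosm until coalescence
    offsets <- matrix(stats::rnorm(cfg$n_genera * cfg$n_microcosms, 0,
                                   cfg$founder_sd %||% 0),
                      cfg$n_genera, cfg$n_microcosms)
    tables <- list()
    cells <- list()
    bulk <- list()
    for (cyc in 0:cfg$n_cycles) {
      step <- grow_transfer_cycle(state, pool, cfg, fitness_offset = offsets)
      id <- paste0("C", cyc)
      tab <- sample_reads(step$grown, cfg$read_depth)
      attr(tab, "cycle") <- cyc
      tables[[id]] <- tab
      cells[[id]] <- step$grown
      bulk[[id]] <- dplyr::mutate(step$bulk, cycle = cyc, .before = 1)
      state <- step$table
    }
    # coalescence: mix the stationary C<n> communities, redistribute, grow once
    mixed <- coalesce(cells[[paste0("C", cfg$n_cycles)]], cfg)
    # the priority-effect offsets do not carry over: the coalesced microcosms
    # are re-founded from a dense, well-mixed inoculum, which leaves no room
    # for colonisation contingency, so growth sorts on the pool fitness alone
    step <- grow_transfer_cycle(mixed, pool, cfg)
    cyc <- cfg$n_cycles + 1L
    id <- paste0("C", cyc)
    tab <- sample_reads(step$grown, cfg$read_depth)
    attr(tab, "cycle") <- cyc
    tables[[id]] <- tab
    cells[[id]] <- step$grown
    bulk[[id]] <- dplyr::mutate(step$bulk, cycle = cyc, .before = 1)
    structure(list(tables = tables, cells = cells,
                   bulk = dplyr::bind_rows(bulk), pool = pool, config = config,
                   coalescence_cycle = cyc),
              class = "melo_experiment")
  }
  if (!is.null(config$seed)) withr::with_seed(config$seed, run()) else run()
}

#' @export
print.melo_experiment <- function(x, ...) {
  cat("<melo_experiment>", length(x$tables), "cycles (",
      paste(names(x$tables), collapse = ", "), ");",
      x$config$n_microcosms, "microcosms,", x$config$n_genera, "genera\n")
  invisible(x)
}
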